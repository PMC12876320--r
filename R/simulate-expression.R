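# Synthetic donor-paired bilateral expression cohorts.
#
# The generator emulates the design of a postmortem atlas in which every
# donor contributes both hemispheres of every cortical area: counts follow a
# negative-binomial model with log2-scale donor, area, hemisphere and
# gene-specific lateralization effects, plus a log-normal library-size
# multiplier so normalization is exercised downstream.

#' Specification for a synthetic bilateral expression cohort
#'
#' Describes a donor-paired cohort: every donor contributes a left and a
#' right sample of every listed cortical area (minus an optional missingness
#' mask).  Counts are negative binomial with mean
#' \eqn{\mu = m_g \cdot 2^{d + a + \delta[hemi=R]} \cdot s} where \eqn{m_g}
#' is the gene baseline, \eqn{d} a donor effect, \eqn{a} an optional
#' gene-by-area effect, \eqn{\delta} the injected lateralization (log2 units,
#' applied to the right hemisphere of the target area) and \eqn{s} the
#' sample library-size multiplier.
#'
#' @param n_genes number of genes.
#' @param n_donors number of donors.
#' @param areas character vector of area labels (e.g. Brodmann areas).
#' @param baseline_mean mean count of a typical gene (default 100).
#' @param dispersion negative-binomial dispersion phi, so that
#'   \eqn{Var = \mu + \phi \mu^2}.  Values near 0 give Poisson-like counts.
#' @param lateralized_genes data frame with columns `gene`, `area`,
#'   `log2fc`: genes given a right-over-left log2 effect in one area.
#'   An optional `donors` column (comma-separated donor IDs, e.g.
#'   `"donor01,donor03"`; NA = all donors) restricts an effect to a donor
#'   subset, supporting trait-linked lateralization such as
#'   handedness-dependent asymmetry.  `NULL` for a null cohort.
#' @param donor_sd sd of the per-donor log2 effect.
#' @param gene_sd sd of per-gene log2 baseline variation around
#'   `baseline_mean` (gives a realistic mean spread; 0 for identical genes).
#' @param area_sd sd of per-gene-by-area log2 effects (default 0).
#' @param libsize_sd sd of the log-normal per-sample library-size
#'   multiplier (default 0.2).
#' @param covariates optional per-donor data frame with columns `donor`,
#'   `sex`, `age`, `handedness`, `family_history`, `language_disorder`;
#'   generated if omitted.
#' @param missing optional data frame (`donor`, `hemisphere`, `area`) of
#'   samples to drop, supporting incomplete designs.
#' @param seed integer RNG seed; a fixed seed reproduces the cohort exactly.
#' @return object of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(n_genes, n_donors, areas,
                                baseline_mean = 100, dispersion = 0.1,
                                lateralized_genes = NULL,
                                donor_sd = 0.2, gene_sd = 1, area_sd = 0,
                                libsize_sd = 0.2,
                                covariates = NULL, missing = NULL,
                                seed = 1L) {
  n_genes  <- check_count(n_genes, "n_genes")
  n_donors <- check_count(n_donors, "n_donors")
  if (!is.character(areas) || length(areas) < 1L || anyDuplicated(areas))
    abort_field("areas", "must be a non-empty character vector without duplicates")
  baseline_mean <- check_positive(baseline_mean, "baseline_mean")
  if (length(dispersion) != 1L || !is.numeric(dispersion) || dispersion < 0)
    abort_field("dispersion", "must be a single non-negative number")
  genes <- sprintf("gene%05d", seq_len(n_genes))
  if (!is.null(lateralized_genes)) {
    need <- c("gene", "area", "log2fc")
    if (!is.data.frame(lateralized_genes) || !all(need %in% names(lateralized_genes)))
      abort_field("lateralized_genes", "must be a data frame with columns gene, area, log2fc")
    if (!all(lateralized_genes$gene %in% genes))
      abort_field("lateralized_genes", "genes outside the simulated gene universe")
    if (!all(lateralized_genes$area %in% areas))
      abort_field("lateralized_genes", "areas outside the simulated area list")
  }
  if (!is.null(covariates) &&
      (!is.data.frame(covariates) || nrow(covariates) != n_donors))
    abort_field("covariates", "must have one row per donor")
  structure(list(
    n_genes = n_genes, n_donors = n_donors, areas = areas,
    baseline_mean = baseline_mean, dispersion = as.numeric(dispersion),
    lateralized_genes = lateralized_genes,
    donor_sd = check_nonneg(donor_sd, "donor_sd"),
    gene_sd = check_nonneg(gene_sd, "gene_sd"),
    area_sd = check_nonneg(area_sd, "area_sd"),
    libsize_sd = check_nonneg(libsize_sd, "libsize_sd"),
    covariates = covariates, missing = missing,
    seed = check_count(seed, "seed", min = 0L), genes = genes
  ), class = "expression_sim_spec")
}

check_nonneg <- function(x, field) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0)
    abort_field(field, "must be a single non-negative number")
  as.numeric(x)
}

# evaluate code under a local RNG seed, restoring global RNG state after
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

sanitize_id <- function(x) gsub("[^A-Za-z0-9_.]+", ".", x)

#' Simulate a donor-paired bilateral count matrix
#'
#' @param spec an [expression_sim_spec()].
#' @return list with `counts` (integer matrix, genes x samples), `meta`
#'   (sample metadata data frame: sample_id, donor, hemisphere, area, sex,
#'   age, handedness, family_history, language_disorder) and `truth` (the
#'   injected lateralization effects, one row per gene-area effect).
#' @export
simulate_expression <- function(spec) {
  if (!inherits(spec, "expression_sim_spec"))
    abort_field("spec", "must be built by expression_sim_spec()")
  with_seed(spec$seed, {
    donors <- sprintf("donor%02d", seq_len(spec$n_donors))
    grid <- expand.grid(hemisphere = c("L", "R"), area = spec$areas,
                        donor = donors, stringsAsFactors = FALSE)
    grid <- grid[, c("donor", "hemisphere", "area")]
    if (!is.null(spec$missing)) {
      key <- function(d) paste(d$donor, d$hemisphere, d$area)
      grid <- grid[!(key(grid) %in% key(spec$missing)), , drop = FALSE]
    }
    grid$sample_id <- sanitize_id(paste(grid$donor, grid$area, grid$hemisphere,
                                        sep = "_"))

    cov <- spec$covariates
    if (is.null(cov)) {
      cov <- data.frame(
        donor = donors,
        sex = sample(c("M", "F"), spec$n_donors, replace = TRUE),
        age = sample(63:87, spec$n_donors, replace = TRUE),
        handedness = sample(c("R", "L"), spec$n_donors, replace = TRUE,
                            prob = c(0.9, 0.1)),
        family_history = sample(c("no", "yes"), spec$n_donors, replace = TRUE,
                                prob = c(0.9, 0.1)),
        language_disorder = "no",
        stringsAsFactors = FALSE
      )
    }
    meta <- merge(grid, cov, by = "donor", sort = FALSE)
    meta <- meta[order(match(meta$sample_id, grid$sample_id)),
                 c("sample_id", "donor", "hemisphere", "area",
                   setdiff(names(cov), "donor"))]
    rownames(meta) <- NULL

    n_s <- nrow(meta)
    gene_base <- spec$baseline_mean * 2^rnorm(spec$n_genes, 0, spec$gene_sd)
    donor_eff <- setNames(rnorm(spec$n_donors, 0, spec$donor_sd), donors)
    area_eff <- matrix(0, spec$n_genes, length(spec$areas),
                       dimnames = list(spec$genes, spec$areas))
    if (spec$area_sd > 0)
      area_eff[] <- rnorm(length(area_eff), 0, spec$area_sd)
    libmult <- rlnorm(n_s, 0, spec$libsize_sd)

    # per-donor lateralization matrices: effects may target donor subsets
    lg <- spec$lateralized_genes
    lat_for <- function(donor) {
      lat <- matrix(0, spec$n_genes, length(spec$areas),
                    dimnames = list(spec$genes, spec$areas))
      if (!is.null(lg) && nrow(lg) > 0) {
        use <- if ("donors" %in% names(lg)) {
          is.na(lg$donors) | vapply(strsplit(lg$donors, ","), function(d)
            donor %in% trimws(d), logical(1))
        } else rep(TRUE, nrow(lg))
        sub <- lg[use, , drop = FALSE]
        if (nrow(sub))
          lat[cbind(match(sub$gene, spec$genes),
                    match(sub$area, spec$areas))] <- sub$log2fc
      }
      lat
    }
    lat_by_donor <- lapply(setNames(donors, donors), lat_for)

    counts <- matrix(0L, spec$n_genes, n_s,
                     dimnames = list(spec$genes, meta$sample_id))
    size <- if (spec$dispersion > 0) 1 / spec$dispersion else Inf
    for (j in seq_len(n_s)) {
      a <- meta$area[j]
      lat <- lat_by_donor[[meta$donor[j]]]
      mu <- gene_base *
        2^(donor_eff[[meta$donor[j]]] + area_eff[, a] +
             if (meta$hemisphere[j] == "R") lat[, a] else 0) * libmult[j]
      counts[, j] <- if (is.finite(size))
        rnbinom(spec$n_genes, mu = mu, size = size)
      else
        stats::rpois(spec$n_genes, lambda = mu)
    }
    storage.mode(counts) <- "integer"

    truth <- if (is.null(lg))
      data.frame(gene = character(), area = character(), log2fc = numeric())
    else lg[, intersect(c("gene", "area", "log2fc", "donors"), names(lg))]
    list(counts = counts, meta = meta, truth = truth)
  })
}
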