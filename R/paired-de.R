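# Donor-paired differential expression for the lateralized atlas.
#
# Two contrast classes over a bilateral cohort: left-versus-right within an
# area (LR) and area-versus-area within a hemisphere (WH_L, WH_R), always
# with donor as a blocking factor.  The default engine is a weighted paired
# linear model on log-CPM with empirical-Bayes variance moderation; a
# negative-binomial Wald engine is available for count-scale fidelity.
# Multiple testing is controlled at four levels: within contrast, globally,
# within contrast family, and within functional module.

#' Default area-to-module map for speech-related cortical areas
#'
#' The six functional modules used for module-level FDR control: Broca
#' (BA44, BA45), Wernicke (BA22, BA21), Geschwind (BA39, BA40), primary
#' auditory (BA41, BA42), ventral sensorimotor (BA6, BA4, BA3/1/2), and
#' other (BA9, BA37).
#'
#' @return named character vector, area label to module name.
#' @export
default_module_map <- function() {
  c("BA44" = "Broca", "BA45" = "Broca",
    "BA22" = "Wernicke", "BA21" = "Wernicke",
    "BA39" = "Geschwind", "BA40" = "Geschwind",
    "BA41" = "primary auditory", "BA42" = "primary auditory",
    "BA6" = "ventral sensorimotor", "BA4" = "ventral sensorimotor",
    "BA3/1/2" = "ventral sensorimotor",
    "BA9" = "other", "BA37" = "other")
}

#' Build a donor-paired contrast specification
#'
#' Restricts to donors contributing both conditions, requires at least two
#' such donors, and records a covariate ledger: each sample-level covariate
#' is admitted only if it varies among the donors used (constant or
#' all-missing covariates are dropped, with the reason recorded).  Numeric
#' covariates are median-imputed and robustly standardized; categorical
#' covariates are mode-imputed.
#'
#' @param meta sample metadata (`sample_id`, `donor`, `hemisphere`, `area`,
#'   plus covariate columns).
#' @param family `"LR"` (left vs right within `area_a`), `"WH_L"` or
#'   `"WH_R"` (area_a vs area_b within one hemisphere).
#' @param area_a,area_b area labels; for LR, `area_b` defaults to `area_a`.
#' @param covariates candidate covariate column names present in `meta`.
#' @return object of class `contrast_spec`: `family`, `area_a`, `area_b`,
#'   `donors_used`, `sample_ids`, `condition` (factor with the reference
#'   level first: L for LR, `area_b` for WH), `donor` (factor), `ledger`
#'   (per-covariate admission record), `covariate_data` (imputed,
#'   standardized design columns for admitted covariates).
#' @export
build_contrast <- function(meta, family = c("LR", "WH_L", "WH_R"),
                           area_a, area_b = NULL,
                           covariates = c("sex", "age", "handedness",
                                          "family_history",
                                          "language_disorder")) {
  family <- match.arg(family)
  if (is.null(area_b)) area_b <- area_a
  if (family == "LR" && !identical(area_a, area_b))
    stop("LR contrasts compare hemispheres within one area")
  if (family != "LR" && identical(area_a, area_b))
    stop("WH contrasts need two different areas")
  for (a in unique(c(area_a, area_b)))
    if (!a %in% meta$area) stop("area not present in metadata: ", a)

  if (family == "LR") {
    sub <- meta[meta$area == area_a, , drop = FALSE]
    cond_of <- sub$hemisphere
    levels_ref <- c("L", "R")   # reference L, coefficient is R minus L
  } else {
    hemi <- if (family == "WH_L") "L" else "R"
    sub <- meta[meta$hemisphere == hemi & meta$area %in% c(area_a, area_b), ,
                drop = FALSE]
    cond_of <- sub$area
    levels_ref <- c(area_b, area_a)  # reference area_b, coef area_a - area_b
  }
  both <- vapply(split(cond_of, sub$donor),
                 function(v) all(levels_ref %in% v), logical(1))
  donors_used <- sort(names(both)[both])
  if (length(donors_used) < 2)
    stop(sprintf("contrast %s %s vs %s has %d donor(s) with both conditions; at least 2 required",
                 family, area_a, area_b, length(donors_used)))
  dropped <- setdiff(unique(sub$donor), donors_used)
  sub <- sub[sub$donor %in% donors_used, , drop = FALSE]
  cond <- factor(if (family == "LR") sub$hemisphere else sub$area,
                 levels = levels_ref)

  ledger <- list()
  cov_data <- list()
  for (cv in intersect(covariates, names(meta))) {
    per_donor <- vapply(donors_used, function(d) {
      v <- sub[[cv]][sub$donor == d]
      v <- v[!is.na(v) & v != ""]
      if (length(v)) as.character(v[1]) else NA_character_
    }, character(1))
    vals <- sub[[cv]]
    if (all(is.na(vals) | vals == "")) {
      ledger[[cv]] <- list(included = FALSE, reason = "all_missing")
    } else if (length(unique(per_donor[!is.na(per_donor)])) <= 1) {
      ledger[[cv]] <- list(included = FALSE, reason = "constant")
    } else if (is.numeric(vals)) {
      med <- median(vals, na.rm = TRUE)
      vals[is.na(vals)] <- med
      sc <- mad(vals)
      if (sc == 0) sc <- sd(vals)
      ledger[[cv]] <- list(included = TRUE, reason = "varies",
                           impute = med, center = med, scale = sc)
      cov_data[[cv]] <- (vals - med) / sc
    } else {
      vals[is.na(vals) | vals == ""] <- names(which.max(table(vals)))
      mode_val <- names(which.max(table(vals)))
      ledger[[cv]] <- list(included = TRUE, reason = "varies",
                           impute = mode_val)
      f <- factor(vals)
      mm <- model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, levels(f)[-1])
      cov_data[[cv]] <- mm
    }
  }

  structure(list(
    family = family, area_a = area_a, area_b = area_b,
    donors_used = donors_used, donors_dropped = dropped,
    sample_ids = sub$sample_id,
    condition = cond,
    donor = factor(sub$donor),
    ledger = ledger,
    covariate_data = cov_data
  ), class = "contrast_spec")
}

#' Subset-level expression filter
#'
#' A gene is retained for a contrast iff its total count across the
#' contrast's samples is at least `min_total` and it is nonzero in at
#' least `min_nonzero` of those samples.
#'
#' @param counts count matrix, genes x samples.
#' @param spec a [build_contrast()] specification (or a character vector of
#'   sample IDs).
#' @param min_total minimum subset total count (default 10).
#' @param min_nonzero minimum number of samples with a positive count
#'   (default 3).
#' @return character vector of retained gene IDs.
#' @export
filter_genes <- function(counts, spec, min_total = 10, min_nonzero = 3) {
  ids <- if (inherits(spec, "contrast_spec")) spec$sample_ids else spec
  sub <- counts[, ids, drop = FALSE]
  keep <- rowSums(sub) >= min_total & rowSums(sub > 0) >= min_nonzero
  rownames(sub)[keep]
}

# design matrix: intercept + donor blocks + admitted covariates + condition
# (condition last, so the tested coefficient is the final column)
contrast_design <- function(spec) {
  n <- length(spec$sample_ids)
  parts <- list(`(Intercept)` = rep(1, n))
  if (nlevels(spec$donor) > 1) {
    dm <- model.matrix(~spec$donor)[, -1, drop = FALSE]
    colnames(dm) <- paste0("donor", levels(spec$donor)[-1])
    parts$donor <- dm
  }
  for (cv in names(spec$covariate_data)) parts[[cv]] <- spec$covariate_data[[cv]]
  cm <- model.matrix(~spec$condition)[, -1, drop = FALSE]
  colnames(cm) <- paste0("condition", levels(spec$condition)[-1])
  parts$condition <- cm
  X <- do.call(cbind, lapply(parts, as.matrix))
  colnames(X) <- unlist(lapply(names(parts), function(nm) {
    p <- parts[[nm]]
    if (is.matrix(p)) colnames(p) else nm
  }))
  X
}

# drop aliased (rank-deficient) columns; the condition column must survive
resolve_design <- function(X, on_aliased = c("drop", "error")) {
  on_aliased <- match.arg(on_aliased)
  qrx <- qr(X)
  if (qrx$rank == ncol(X)) return(X)
  keep <- qrx$pivot[seq_len(qrx$rank)]
  aliased <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
  if (any(grepl("^condition", aliased)))
    stop("condition coefficient is aliased; design is degenerate")
  if (on_aliased == "error")
    stop("design not full rank; aliased columns: ",
         paste(aliased, collapse = ", "))
  message("dropping aliased design column(s): ",
          paste(aliased, collapse = ", "))
  X[, sort(keep), drop = FALSE]
}

#' Fit one donor-paired contrast
#'
#' Default engine `moderated_t`: per-gene weighted least squares on TMM
#' log-CPM with inverse-variance precision weights from a fitted
#' mean-variance trend (binned running median of residual sd against
#' average log-CPM, linearly interpolated), residual variances shrunk by
#' empirical Bayes toward a common prior — posterior variance
#' \eqn{(d_0 s_0^2 + d s^2)/(d_0 + d)} — giving a moderated t on
#' \eqn{d_0 + d} degrees of freedom.  Engine `nb_wald`: negative-binomial
#' log-link fit with trend-shrunken dispersions and a Wald z on the
#' condition coefficient, with no outlier-based filtering.  Two-sided p in
#' both engines.
#'
#' Donor-level covariates admitted by the ledger are aliased with the donor
#' blocks whenever every donor has a single covariate value; by default
#' such columns are dropped from the design (with a message) rather than
#' raising, so the blocking factor always carries the adjustment.  Set
#' `on_aliased = "error"` for a strict design check.
#'
#' @param counts count matrix covering the contrast's samples.
#' @param spec a [build_contrast()] specification.
#' @param engine `"moderated_t"` (default) or `"nb_wald"` (requires
#'   DESeq2).
#' @param prior_df override for the empirical-Bayes prior degrees of
#'   freedom (`NULL` = estimate by moments; `0` = no moderation, the
#'   ordinary weighted paired t-test).
#' @param min_total,min_nonzero expression-filter thresholds, see
#'   [filter_genes()].
#' @param on_aliased what to do with aliased design columns.
#' @param trend use mean-variance precision weights (default TRUE).
#' @return data frame (`gene_id`, `log2fc`, `statistic`, `p`, `flag`) with
#'   attributes `family`, `area_a`, `area_b`, `spec`.
#' @export
fit_contrast <- function(counts, spec, engine = c("moderated_t", "nb_wald"),
                         prior_df = NULL, min_total = 10, min_nonzero = 3,
                         on_aliased = c("drop", "error"), trend = TRUE) {
  engine <- match.arg(engine)
  if (!inherits(spec, "contrast_spec"))
    stop("spec must be built by build_contrast()")
  genes <- filter_genes(counts, spec, min_total, min_nonzero)
  if (!length(genes)) stop("no genes pass the expression filter")
  sub <- counts[genes, spec$sample_ids, drop = FALSE]
  X <- resolve_design(contrast_design(spec), on_aliased)
  cond_idx <- grep("^condition", colnames(X))
  out <- if (engine == "moderated_t") {
    fit_moderated_t(sub, X, cond_idx, prior_df = prior_df, trend = trend)
  } else {
    fit_nb_wald(sub, X, cond_idx)
  }
  attr(out, "family") <- spec$family
  attr(out, "area_a") <- spec$area_a
  attr(out, "area_b") <- spec$area_b
  attr(out, "spec") <- spec
  out
}

# weighted LS + empirical-Bayes moderation on log-CPM
fit_moderated_t <- function(sub, X, cond_idx, prior_df = NULL, trend = TRUE) {
  n <- ncol(sub); p <- ncol(X); d <- n - p
  if (d < 1) stop("no residual degrees of freedom (n = ", n, ", p = ", p, ")")
  sf <- tmm_factors(sub)
  lc <- log_cpm(sub, sf)$values
  G <- nrow(lc)

  # first pass: unweighted fit, residual sd and fitted values for the trend
  fit0 <- lm.fit(X, t(lc))
  res0 <- as.matrix(fit0$residuals)
  s0_g <- sqrt(colSums(res0^2) / d)
  fitted0 <- t(lc) - res0
  amean <- rowMeans(lc)

  W <- matrix(1, n, G)
  if (trend && G >= 10) {
    tr <- sd_trend(amean, s0_g)
    pred <- matrix(tr(as.vector(fitted0)), n, G)
    W <- 1 / pred^2
  }

  beta <- se_unsc <- s2 <- numeric(G)
  # degenerate genes: constant on the count scale (no evidence at all) or
  # constant in log-CPM
  const <- apply(sub, 1, function(r) all(r == r[1]))
  for (g in seq_len(G)) {
    y <- lc[g, ]
    if (const[g]) next
    if (var(y) < 1e-12) { const[g] <- TRUE; next }
    w <- W[, g]
    A <- crossprod(X, X * w)
    b <- crossprod(X, w * y)
    Ai <- solve(A)
    bt <- Ai %*% b
    r <- y - as.vector(X %*% bt)
    beta[g] <- bt[cond_idx]
    se_unsc[g] <- sqrt(Ai[cond_idx, cond_idx])
    s2[g] <- sum(w * r^2) / d
  }

  eb <- squeeze_var(s2[!const], d, prior_df = prior_df)
  s2_post <- rep(NA_real_, G)
  s2_post[!const] <- (eb$d0 * eb$s0_2 + d * s2[!const]) / (eb$d0 + d)
  if (is.infinite(eb$d0)) s2_post[!const] <- eb$s0_2
  df_total <- eb$d0 + d

  stat <- beta / (se_unsc * sqrt(s2_post))
  pval <- if (is.finite(df_total)) 2 * pt(-abs(stat), df_total)
          else 2 * pnorm(-abs(stat))
  stat[const] <- NA_real_
  pval[const] <- 1
  beta[const] <- 0
  data.frame(gene_id = rownames(sub), log2fc = beta, statistic = stat,
             p = pval, flag = ifelse(const, "zero_variance", ""),
             stringsAsFactors = FALSE)
}

# binned running-median trend of residual sd against average log-CPM,
# linearly interpolated and held constant beyond the bin range
sd_trend <- function(amean, s, nbins = NULL) {
  ok <- s > 0 & is.finite(amean)
  if (sum(ok) < 10) {
    const <- max(median(s[ok]), 1e-6)
    return(function(x) rep(const, length(x)))
  }
  if (is.null(nbins)) nbins <- max(10L, min(50L, floor(sum(ok) / 20)))
  x <- amean[ok]; y <- s[ok]
  brk <- quantile(x, probs = seq(0, 1, length.out = nbins + 1))
  bin <- cut(x, unique(brk), include.lowest = TRUE)
  bx <- tapply(x, bin, median)
  by <- tapply(y, bin, median)
  keep <- !is.na(bx) & !is.na(by)
  bx <- bx[keep]; by <- pmax(by[keep], 1e-6)
  if (length(bx) < 2) {
    const <- max(median(y), 1e-6)
    return(function(z) rep(const, length(z)))
  }
  function(z) approx(bx, by, xout = z, rule = 2)$y
}

# moment estimation of the scaled inverse-chi-square prior on residual
# variances: log s^2 is log s0^2 + log-F noise; the excess spread of
# e = log s^2 - digamma(d/2) + log(d/2) over trigamma(d/2) identifies d0
squeeze_var <- function(s2, d, prior_df = NULL) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (!length(s2)) return(list(d0 = 0, s0_2 = 1))
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  if (!is.null(prior_df)) {
    d0 <- prior_df
    s0_2 <- if (d0 == 0) NA_real_
            else if (is.infinite(d0)) exp(mean(e))
            else exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    if (d0 == 0) s0_2 <- 1  # unused: posterior reduces to s^2
    return(list(d0 = d0, s0_2 = s0_2))
  }
  if (length(s2) < 2) return(list(d0 = Inf, s0_2 = exp(mean(e))))
  excess <- var(e) - trigamma(d / 2)
  if (excess <= 0) return(list(d0 = Inf, s0_2 = exp(mean(e))))
  d0 <- 2 * trigamma_inverse(excess)
  s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

# Newton solve of trigamma(x) = y
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

# negative-binomial Wald engine via DESeq2, outlier filtering disabled
fit_nb_wald <- function(sub, X, cond_idx) {
  if (!requireNamespace("DESeq2", quietly = TRUE))
    stop("engine 'nb_wald' requires the DESeq2 package")
  cd <- data.frame(dummy = factor(rep("a", ncol(sub))),
                   row.names = colnames(sub))
  dds <- DESeq2::DESeqDataSetFromMatrix(countData = sub, colData = cd,
                                        design = ~1)
  dds <- suppressMessages(DESeq2::DESeq(dds, full = X, betaPrior = FALSE,
                                        test = "Wald", quiet = TRUE,
                                        minReplicatesForReplace = Inf))
  res <- DESeq2::results(dds, name = colnames(X)[cond_idx],
                         cooksCutoff = FALSE, independentFiltering = FALSE)
  data.frame(gene_id = rownames(sub),
             log2fc = res$log2FoldChange,
             statistic = res$stat,
             p = ifelse(is.na(res$pvalue), 1, res$pvalue),
             flag = ifelse(is.na(res$pvalue), "undefined", ""),
             stringsAsFactors = FALSE)
}

#' Multi-level multiple-testing adjustment across contrasts
#'
#' Adds four Benjamini-Hochberg FDR levels to a set of contrast results:
#' `q_contrast` (within each contrast), `q_global` (pooling all genes and
#' contrasts), `q_family` (pooling contrasts of the same family: all LR
#' contrasts across areas, all WH_L, all WH_R), and `q_module` (pooling
#' contrasts whose areas fall in one functional module).  A WH contrast
#' whose two areas sit in different modules is labeled `mixed` and gets no
#' module-level q.
#'
#' @param results list of [fit_contrast()] tables (with their attributes).
#' @param module_map named character vector, area to module
#'   (default [default_module_map()]).
#' @return list of augmented data frames (same order/names), each with
#'   columns `q_contrast`, `q_global`, `q_family`, `module_label`,
#'   `q_module`.
#' @export
adjust_multilevel <- function(results, module_map = default_module_map()) {
  stopifnot(is.list(results), length(results) > 0)
  meta <- lapply(results, function(r) {
    fam <- attr(r, "family"); a <- attr(r, "area_a"); b <- attr(r, "area_b")
    if (is.null(fam) || is.null(a) || is.null(b))
      stop("results must carry fit_contrast() attributes")
    for (ar in unique(c(a, b)))
      if (!ar %in% names(module_map)) stop("area not in module map: ", ar)
    mod <- if (module_map[[a]] == module_map[[b]]) module_map[[a]] else "mixed"
    list(family = fam, module = mod)
  })
  results <- lapply(results, function(r) {
    r$q_contrast <- p.adjust(r$p, method = "BH")
    r
  })
  pool_adjust <- function(idx, col) {
    ps <- unlist(lapply(results[idx], `[[`, "p"), use.names = FALSE)
    qs <- p.adjust(ps, method = "BH")
    ofs <- 0
    for (i in idx) {
      n <- nrow(results[[i]])
      results[[i]][[col]] <<- qs[ofs + seq_len(n)]
      ofs <- ofs + n
    }
  }
  pool_adjust(seq_along(results), "q_global")
  fams <- vapply(meta, `[[`, "", "family")
  for (f in unique(fams)) pool_adjust(which(fams == f), "q_family")
  mods <- vapply(meta, `[[`, "", "module")
  for (i in seq_along(results)) {
    results[[i]]$module_label <- mods[i]
    results[[i]]$q_module <- NA_real_
  }
  for (m in setdiff(unique(mods), "mixed")) pool_adjust(which(mods == m), "q_module")
  results
}
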