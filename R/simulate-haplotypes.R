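# Synthetic haplotype panels and variant-integration resources.
#
# These generators produce the record shapes consumed by the variant
# cascade (GWAS tables, LD tables, eQTL tables, enhancer intervals) with
# known ground truth: the emitted LD table is computed from the emitted
# haplotype panel by compute_r2(), so the two agree by construction.

#' Specification for a synthetic haplotype panel with LD blocks
#'
#' Loci are grouped into LD blocks.  Within a block every locus is a noisy
#' copy of a latent block haplotype: allele copied with probability
#' `1 - flip`, flipped otherwise, which yields pairwise r-squared values
#' concentrated around `(1 - 2*flip)^4`-ish levels; `target_r2 = 1` (flip 0)
#' gives perfect LD.  Loci in different blocks are independent.
#'
#' @param n_snps total number of loci.
#' @param haplotype_panel_size number of haplotypes (>= 2).
#' @param ld_blocks data frame with columns `n_loci` and `target_r2`
#'   (target pairwise r-squared in [0,1]); remaining loci are independent.
#' @param maf minor-allele frequency of the latent block haplotypes
#'   (default 0.3).
#' @param chrom chromosome label for emitted positions.
#' @param spacing_bp spacing between consecutive locus positions.
#' @param seed integer RNG seed.
#' @return object of class `variant_sim_spec`.
#' @export
variant_sim_spec <- function(n_snps, haplotype_panel_size,
                             ld_blocks = NULL, maf = 0.3,
                             chrom = "chr17", spacing_bp = 1000L,
                             seed = 1L) {
  n_snps <- check_count(n_snps, "n_snps")
  haplotype_panel_size <- check_count(haplotype_panel_size,
                                      "haplotype_panel_size", min = 2L)
  if (!is.null(ld_blocks)) {
    if (!is.data.frame(ld_blocks) ||
        !all(c("n_loci", "target_r2") %in% names(ld_blocks)))
      abort_field("ld_blocks", "must be a data frame with columns n_loci, target_r2")
    if (sum(ld_blocks$n_loci) > n_snps)
      abort_field("ld_blocks", "block loci exceed n_snps")
    if (any(ld_blocks$target_r2 < 0 | ld_blocks$target_r2 > 1))
      abort_field("ld_blocks", "target_r2 must lie in [0,1]")
  }
  structure(list(
    n_snps = n_snps, haplotype_panel_size = haplotype_panel_size,
    ld_blocks = ld_blocks, maf = check_fraction(maf, "maf"),
    chrom = chrom, spacing_bp = check_count(spacing_bp, "spacing_bp"),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "variant_sim_spec")
}

#' Simulate a haplotype panel and its derived LD table
#'
#' @param spec a [variant_sim_spec()].
#' @return list with `panel` (0/1 matrix, haplotypes x loci), `loci`
#'   (data frame: rsid, chrom, pos, block), and `ld` (data frame: rsid_a,
#'   rsid_b, r2) computed from the panel by [compute_r2()] for all pairs
#'   within a block plus adjacent independent loci.  Monomorphic loci yield
#'   missing r2 with a warning.
#' @export
simulate_haplotypes <- function(spec) {
  if (!inherits(spec, "variant_sim_spec"))
    abort_field("spec", "must be built by variant_sim_spec()")
  with_seed(spec$seed, {
    n <- spec$haplotype_panel_size
    blocks <- spec$ld_blocks
    block_id <- integer(0)
    if (!is.null(blocks))
      block_id <- rep(seq_len(nrow(blocks)), blocks$n_loci)
    block_id <- c(block_id, rep(0L, spec$n_snps - length(block_id)))

    panel <- matrix(0L, n, spec$n_snps)
    b_prev <- -1L
    latent <- NULL
    for (j in seq_len(spec$n_snps)) {
      b <- block_id[j]
      if (b == 0L) {
        panel[, j] <- rbinom(n, 1L, spec$maf)
      } else {
        if (b != b_prev) {
          latent <- rbinom(n, 1L, spec$maf)
          b_prev <- b
        }
        r2t <- blocks$target_r2[b]
        if (r2t >= 1) {
          panel[, j] <- latent
        } else {
          # copy latent haplotype with flip probability chosen so that the
          # correlation between two such copies is near the block target
          flip <- (1 - r2t^(1 / 4)) / 2
          flips <- rbinom(n, 1L, flip)
          panel[, j] <- as.integer(xor(latent == 1L, flips == 1L))
        }
      }
    }
    loci <- data.frame(
      rsid = sprintf("rs%06d", seq_len(spec$n_snps)),
      chrom = spec$chrom,
      pos = seq_len(spec$n_snps) * spec$spacing_bp,
      block = block_id,
      stringsAsFactors = FALSE
    )
    colnames(panel) <- loci$rsid
    ld <- ld_table_from_panel(panel, loci)
    list(panel = panel, loci = loci, ld = ld)
  })
}

# all within-block pairs plus consecutive independent pairs, r2 via compute_r2
ld_table_from_panel <- function(panel, loci) {
  pairs <- list()
  for (b in unique(loci$block[loci$block > 0])) {
    idx <- which(loci$block == b)
    if (length(idx) >= 2) {
      cmb <- utils::combn(idx, 2)
      pairs[[length(pairs) + 1L]] <- t(cmb)
    }
  }
  free <- which(loci$block == 0)
  if (length(free) >= 2)
    pairs[[length(pairs) + 1L]] <- cbind(free[-length(free)], free[-1])
  if (!length(pairs))
    return(data.frame(rsid_a = character(), rsid_b = character(),
                      r2 = numeric()))
  pr <- do.call(rbind, pairs)
  r2 <- vapply(seq_len(nrow(pr)), function(k) {
    a <- panel[, pr[k, 1]]
    b <- panel[, pr[k, 2]]
    r2_from_haplotypes(a, b)
  }, numeric(1))
  if (anyNA(r2))
    warning("monomorphic locus in panel: r2 recorded as missing for ",
            sum(is.na(r2)), " pair(s)")
  data.frame(rsid_a = loci$rsid[pr[, 1]], rsid_b = loci$rsid[pr[, 2]],
             r2 = r2, stringsAsFactors = FALSE)
}

# counts of the four two-locus haplotypes from 0/1 vectors, then compute_r2
r2_from_haplotypes <- function(a, b) {
  compute_r2(n_AB = sum(a == 1 & b == 1), n_Ab = sum(a == 1 & b == 0),
             n_aB = sum(a == 0 & b == 1), n_ab = sum(a == 0 & b == 0))
}

#' Simulate a toy variant-integration resource bundle
#'
#' Builds internally consistent GWAS, eQTL and enhancer tables around a
#' haplotype panel, with known overlap structure, for exercising the
#' sentinel-to-eGene cascade end to end.
#'
#' @param spec a [variant_sim_spec()].
#' @param n_traits number of traits assigned to sentinel-eligible variants.
#' @param sentinel_fraction fraction of loci given association P below the
#'   sentinel threshold.
#' @param egene_fraction fraction of variants given a cis-eQTL record.
#' @param tissues character vector of tissue labels for eQTL records.
#' @param n_se,n_te numbers of super-enhancer and typical-enhancer
#'   intervals to scatter over the locus span.
#' @param enhancer_width width (bp) of each enhancer interval.
#' @return list with `gwas`, `panel`, `loci`, `ld`, `eqtl`, `enhancers`.
#' @export
simulate_variant_resources <- function(spec, n_traits = 3,
                                       sentinel_fraction = 0.2,
                                       egene_fraction = 0.3,
                                       tissues = paste0("brain_", 1:13),
                                       n_se = 5, n_te = 5,
                                       enhancer_width = 2000L) {
  hap <- simulate_haplotypes(spec)
  with_seed(stage_seed(spec$seed, 7L), {
    loci <- hap$loci
    n <- nrow(loci)
    is_sent <- runif(n) < sentinel_fraction
    p <- ifelse(is_sent, 10^runif(n, -12, -5.05), 10^runif(n, -4.9, -0.1))
    gwas <- data.frame(
      rsid = loci$rsid, chrom = loci$chrom, pos = loci$pos,
      ref = "A", alt = "G",
      trait = paste0("trait", sample.int(n_traits, n, replace = TRUE)),
      p = p, stringsAsFactors = FALSE
    )
    has_e <- runif(n) < egene_fraction
    eqtl <- do.call(rbind, lapply(which(has_e), function(i) {
      k <- sample.int(3, 1)
      data.frame(rsid = loci$rsid[i],
                 gene_id = sprintf("EG%03d", (i %% 40) + 1),
                 tissue = sample(tissues, k),
                 slope = rnorm(k, 0, 0.5),
                 p = 10^runif(k, -10, -2),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(eqtl))
      eqtl <- data.frame(rsid = character(), gene_id = character(),
                         tissue = character(), slope = numeric(),
                         p = numeric())
    span <- max(loci$pos) + enhancer_width
    starts <- sort(sample.int(span, n_se + n_te))
    enh <- data.frame(
      chrom = spec$chrom,
      start = starts,
      end = pmin(starts + enhancer_width, span + enhancer_width),
      kind = sample(rep(c("SE", "TE"), c(n_se, n_te))),
      tissue = "brain",
      stringsAsFactors = FALSE
    )
    c(hap, list(gwas = gwas, eqtl = eqtl, enhancers = enh))
  })
}
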