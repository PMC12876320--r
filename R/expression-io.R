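# Expression matrix I/O and the small normalization utilities used
# throughout the atlas: TMM size factors, log-CPM, TPM, CV ranking,
# Z-scores and the 2^-ddCt qPCR fold change.

#' Write a count matrix and its sample metadata as TSV
#'
#' Counts: genes as rows, header = sample IDs (first column `gene_id`).
#' Metadata: one row per sample.
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param meta sample metadata data frame with a `sample_id` column.
#' @param counts_path,meta_path output paths.
#' @return invisibly, the two paths.
#' @export
write_counts <- function(counts, meta, counts_path, meta_path) {
  validate_counts(counts, meta)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write_tsv(df, counts_path)
  write_tsv(meta, meta_path)
  invisible(c(counts_path, meta_path))
}

#' Read a count matrix and its sample metadata from TSV
#'
#' Validates the pair: unique IDs, non-negative integer counts, and an
#' exact match between count columns and metadata sample IDs.  Writing with
#' [write_counts()] then reading back is the identity.
#'
#' @param counts_path TSV with a `gene_id` column then one column per sample.
#' @param meta_path TSV with one row per sample (`sample_id`, `donor`,
#'   `hemisphere`, `area`, covariates).
#' @return list with `counts` (integer matrix) and `meta` (data frame).
#' @export
read_counts <- function(counts_path, meta_path) {
  df <- read_tsv(counts_path)
  if (names(df)[1] != "gene_id")
    stop("counts file must have `gene_id` as its first column")
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene_id
  storage.mode(counts) <- "integer"
  meta <- read_tsv(meta_path, colClasses = "character")
  if ("age" %in% names(meta)) meta$age <- as.numeric(meta$age)
  validate_counts(counts, meta)
  list(counts = counts, meta = meta)
}

validate_counts <- function(counts, meta = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene and sample IDs as dimnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and complete")
  if (any(counts != floor(counts)))
    stop("counts must be integers")
  if (!is.null(meta)) {
    if (!"sample_id" %in% names(meta))
      stop("metadata must have a `sample_id` column")
    miss <- setdiff(colnames(counts), meta$sample_id)
    extra <- setdiff(meta$sample_id, colnames(counts))
    if (length(miss))
      stop("metadata missing sample(s): ", paste(miss, collapse = ", "))
    if (length(extra))
      stop("metadata has sample(s) absent from counts: ",
           paste(extra, collapse = ", "))
    if (anyDuplicated(meta$sample_id))
      stop("duplicate sample IDs in metadata")
    for (f in intersect(c("hemisphere", "area"), names(meta)))
      if (anyNA(meta[[f]]) || any(meta[[f]] == ""))
        stop("metadata column `", f, "` must be non-missing")
    if ("hemisphere" %in% names(meta) &&
        !all(meta$hemisphere %in% c("L", "R")))
      stop("hemisphere must be L or R")
  }
  invisible(TRUE)
}

#' Trimmed mean of M-values (TMM) size factors
#'
#' Library-scaling factors computed as the doubly trimmed mean of per-gene
#' log2 expression ratios (M-values) against a reference sample, the
#' classic trimmed-mean-of-M-values normalization for count data.  The
#' reference is the sample whose library size is closest to the median
#' library size.  Genes with a zero count in either sample are excluded;
#' the remaining genes are trimmed symmetrically by `trim_logratio` on M
#' and `trim_abs` on A (average log intensity) before averaging.  Factors
#' are rescaled so their geometric mean is 1.
#'
#' @param counts count matrix, genes x samples (>= 2 samples).
#' @param trim_logratio two-sided trim fraction on M-values (default 0.3).
#' @param trim_abs two-sided trim fraction on A-values (default 0.05).
#' @param ref_sample optional sample ID or index to use as reference.
#' @return named numeric vector of positive factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_logratio = 0.3, trim_abs = 0.05,
                        ref_sample = NULL) {
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("all-zero sample(s): ", paste(colnames(counts)[lib == 0],
                                       collapse = ", "))
  if (is.null(ref_sample)) {
    ref <- which.min(abs(lib - median(lib)))
  } else {
    ref <- if (is.character(ref_sample)) match(ref_sample, colnames(counts))
           else as.integer(ref_sample)
    if (is.na(ref) || ref < 1 || ref > ncol(counts))
      stop("unknown reference sample")
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
             trim_logratio, trim_abs)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# trimmed mean of M-values of one sample against the reference
tmm_pair <- function(x, r, nx, nr, trim_m, trim_a) {
  keep <- x > 0 & r > 0
  if (!any(keep)) return(1)
  px <- x[keep] / nx
  pr <- r[keep] / nr
  m <- log2(px / pr)
  a <- 0.5 * log2(px * pr)
  ok <- is.finite(m) & is.finite(a)
  m <- m[ok]; a <- a[ok]
  if (!length(m)) return(1)
  if (max(abs(m)) < 1e-10) return(1)  # pure depth scaling
  keep2 <- double_trim(m, trim_m) & double_trim(a, trim_a)
  if (!any(keep2)) return(1)
  2^mean(m[keep2])
}

# TRUE for values inside the two-sided trim (rank-based, matching a
# brute-force sort-and-drop implementation)
double_trim <- function(v, frac) {
  n <- length(v)
  lo <- floor(n * frac) + 1
  hi <- n + 1 - (floor(n * frac) + 1)
  rk <- rank(v, ties.method = "first")
  rk >= lo & rk <= hi
}

#' Log2 counts per million
#'
#' \eqn{\log_2((count + prior) / (\text{effective library size}) \times 10^6)}
#' where the effective library size is the column sum times its
#' normalization factor.
#'
#' @param counts count matrix, genes x samples.
#' @param size_factors per-sample positive factors (e.g. [tmm_factors()]);
#'   default 1 for all samples.
#' @param prior_count stabilizing offset added to every count
#'   (default 0.5; must be > 0 when any count is 0).
#' @return list of class `normalized_matrix`: `values`, `unit = "logCPM"`,
#'   `size_factors`.
#' @export
log_cpm <- function(counts, size_factors = NULL, prior_count = 0.5) {
  if (is.null(size_factors)) size_factors <- rep(1, ncol(counts))
  if (any(size_factors <= 0)) stop("size factors must be positive")
  if (prior_count < 0) stop("prior_count must be >= 0")
  if (prior_count == 0 && any(counts == 0))
    stop("prior_count 0 with zero counts would give -Inf log-CPM")
  eff <- colSums(counts) * size_factors
  vals <- log2(sweep(counts + prior_count, 2, eff, "/") * 1e6)
  normalized_matrix(vals, "logCPM", size_factors)
}

normalized_matrix <- function(values, unit, size_factors = NULL) {
  stopifnot(unit %in% c("logCPM", "TPM", "zscore"))
  structure(list(values = values, unit = unit,
                 size_factors = size_factors),
            class = "normalized_matrix")
}

#' Transcripts per million from counts and gene lengths
#'
#' Counts are divided by gene length (kb) and rescaled so every sample
#' sums to one million.
#'
#' @param counts count matrix, genes x samples.
#' @param gene_lengths named numeric vector or data frame
#'   (`gene_id`, `length_bp`) covering every gene in `counts`.
#' @return `normalized_matrix` with unit `"TPM"`.
#' @export
tpm_from_counts <- function(counts, gene_lengths) {
  if (is.data.frame(gene_lengths))
    gene_lengths <- setNames(gene_lengths$length_bp, gene_lengths$gene_id)
  len <- gene_lengths[rownames(counts)]
  if (anyNA(len))
    stop("missing gene length for: ",
         paste(head(rownames(counts)[is.na(len)], 5), collapse = ", "))
  if (any(len <= 0)) stop("gene lengths must be positive")
  rate <- counts / (len / 1e3)
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("TPM undefined for all-zero sample(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  normalized_matrix(sweep(rate, 2, tot, "/") * 1e6, "TPM")
}

#' Coefficient-of-variation ranking of genes
#'
#' Per-gene CV = sd/mean (sample sd, n-1 denominator) on the values given,
#' with the top `top_fraction` most variable genes flagged.  Ties are
#' broken by gene ID order; zero-mean genes have undefined CV and are
#' excluded with a warning.
#'
#' @param values a `normalized_matrix` or plain matrix (genes x samples).
#' @param top_fraction fraction of ranked genes to flag (default 0.2).
#' @return data frame: `gene_id`, `cv`, `rank` (1 = most variable, NA when
#'   undefined), `top` (logical).
#' @export
cv_rank <- function(values, top_fraction = 0.2) {
  m <- if (inherits(values, "normalized_matrix")) values$values else values
  if (ncol(m) < 2) stop("CV needs at least 2 samples")
  top_fraction <- check_fraction(top_fraction, "top_fraction")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  cv <- ifelse(mu == 0, NA_real_, s / mu)
  if (anyNA(cv))
    warning(sum(is.na(cv)), " zero-mean gene(s) excluded from CV ranking")
  ord <- order(-cv, rownames(m), na.last = TRUE)
  rk <- rep(NA_integer_, length(cv))
  rk[ord[seq_len(sum(!is.na(cv)))]] <- seq_len(sum(!is.na(cv)))
  n_top <- floor(sum(!is.na(cv)) * top_fraction)
  data.frame(gene_id = rownames(m), cv = cv, rank = rk,
             top = !is.na(rk) & rk <= n_top, stringsAsFactors = FALSE)
}

#' Per-gene Z-score normalization
#'
#' Centers and scales each gene to mean 0, sd 1.  Constant genes are set
#' to zero with a warning.
#'
#' @param values a `normalized_matrix` or plain matrix (genes x samples).
#' @return `normalized_matrix` with unit `"zscore"` and attributes
#'   `center`/`scale` recording the per-gene mean and sd.
#' @export
zscore <- function(values) {
  m <- if (inherits(values, "normalized_matrix")) values$values else values
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  flat <- s == 0 | is.na(s)
  if (any(flat)) {
    warning(sum(flat), " constant gene(s) set to zero in Z-scoring")
    s[flat] <- 1
  }
  z <- (m - mu) / s
  z[flat, ] <- 0
  out <- normalized_matrix(z, "zscore")
  attr(out, "center") <- mu
  attr(out, "scale") <- s
  out
}

#' qPCR relative fold change by the 2^-ddCt method
#'
#' \eqn{2^{-[(Ct_{target,test} - Ct_{ref,test}) -
#'          (Ct_{target,ctrl} - Ct_{ref,ctrl})]}}
#'
#' @param ct_target_test,ct_ref_test cycle thresholds in the test condition
#'   for the target and reference gene.
#' @param ct_target_ctrl,ct_ref_ctrl the same in the control condition.
#' @return fold change (1 = no change).
#' @export
ddct_fold_change <- function(ct_target_test, ct_ref_test,
                             ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl)
  if (length(cts) != 4 || !all(is.finite(cts)) || any(cts <= 0))
    stop("all four Ct values must be finite and positive")
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
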