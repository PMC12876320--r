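# Lateralization summary statistics over adjusted contrast results:
# significant-gene counts and log10(n+1) maps, delta/Jaccard dumbbells
# ranking area pairs by interhemispheric divergence, overlap with external
# disease gene sets, and per-gene left-right Wilcoxon tests.

#' Count significant genes per contrast
#'
#' @param results a single adjusted contrast table or a list of them.
#' @param q_field which adjustment level to threshold
#'   (default `"q_contrast"`).
#' @param alpha significance threshold (default 0.05, i.e. FDR < 0.05).
#' @return named integer vector (or scalar for a single table).
#' @export
count_significant <- function(results, q_field = "q_contrast", alpha = 0.05) {
  one <- function(r) {
    if (!q_field %in% names(r)) stop("unknown q_field: ", q_field)
    sum(r[[q_field]] < alpha, na.rm = TRUE)
  }
  if (is.data.frame(results)) one(results)
  else vapply(results, one, integer(1))
}

#' log10(n + 1) transform of significant-gene counts
#'
#' The scale used for significant-gene count maps.
#'
#' @param counts non-negative counts (vector or matrix).
#' @return log10(counts + 1), same shape.
#' @export
log_count_map <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  log10(counts + 1)
}

#' Jaccard distance between two gene sets
#'
#' \eqn{J = 1 - |A \cap B| / |A \cup B|}; 1 for disjoint non-empty sets,
#' 0 for equal sets.  Two empty sets are defined as distance 0 (they are
#' equal), with a warning.
#'
#' @param set_a,set_b character vectors (duplicates ignored).
#' @return J in [0, 1].
#' @export
jaccard_distance <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  if (!length(a) && !length(b)) {
    warning("both sets empty; Jaccard distance defined as 0")
    return(0)
  }
  1 - length(intersect(a, b)) / length(union(a, b))
}

#' Dumbbell table of interhemispheric divergence per area pair
#'
#' For every within-hemisphere area pair tested in both hemispheres,
#' collects the significant-gene sets of the WH_L and WH_R contrasts and
#' summarizes them as n_left, n_right, delta = |n_left - n_right| and the
#' Jaccard distance J between the two sets.  Rows are ranked by delta
#' descending, ties by J descending, then by pair label.
#'
#' @param left_results,right_results lists of adjusted WH contrast tables
#'   for the left and right hemisphere (with [fit_contrast()] attributes).
#' @param q_field,alpha significance rule for set construction
#'   (default `q_contrast` < 0.05).
#' @return data frame: area_a, area_b, n_left, n_right, delta, jaccard,
#'   rank.
#' @export
dumbbell_table <- function(left_results, right_results,
                           q_field = "q_contrast", alpha = 0.05) {
  key_of <- function(r) paste(attr(r, "area_a"), attr(r, "area_b"), sep = " vs ")
  sig_set <- function(r) {
    if (!q_field %in% names(r)) stop("unknown q_field: ", q_field)
    r$gene_id[!is.na(r[[q_field]]) & r[[q_field]] < alpha]
  }
  lk <- vapply(left_results, key_of, character(1))
  rk <- vapply(right_results, key_of, character(1))
  only <- c(setdiff(lk, rk), setdiff(rk, lk))
  if (length(only))
    warning("area pair(s) present in one hemisphere only, excluded: ",
            paste(only, collapse = "; "))
  common <- intersect(lk, rk)
  if (!length(common))
    return(data.frame(area_a = character(), area_b = character(),
                      n_left = integer(), n_right = integer(),
                      delta = integer(), jaccard = numeric(),
                      rank = integer()))
  rows <- lapply(common, function(k) {
    L <- sig_set(left_results[[match(k, lk)]])
    R <- sig_set(right_results[[match(k, rk)]])
    j <- if (!length(L) && !length(R)) 0
         else jaccard_distance(L, R)
    data.frame(area_a = attr(left_results[[match(k, lk)]], "area_a"),
               area_b = attr(left_results[[match(k, lk)]], "area_b"),
               n_left = length(L), n_right = length(R),
               delta = abs(length(L) - length(R)), jaccard = j,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pair_label <- paste(out$area_a, out$area_b, sep = " vs ")
  ord <- order(-out$delta, -out$jaccard, pair_label)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Overlap of a cohort DEG set with external disease DEG sets
#'
#' Fraction of cohort genes detected as differentially expressed in at
#' least one external disease dataset.
#'
#' @param cohort_set character vector of cohort DEG IDs (non-empty).
#' @param disease_sets list of character vectors, one per disease dataset.
#' @return list: `n_overlap`, `n_total`, `percent` (100 x overlap/total,
#'   rounded to 1 decimal).
#' @export
external_overlap <- function(cohort_set, disease_sets) {
  cohort <- unique(cohort_set)
  if (!length(cohort)) stop("cohort set must be non-empty")
  pool <- unique(unlist(disease_sets))
  n_overlap <- sum(cohort %in% pool)
  list(n_overlap = n_overlap, n_total = length(cohort),
       percent = round(100 * n_overlap / length(cohort), 1))
}

#' Left-right Wilcoxon test for one gene in one area
#'
#' Paired (default): signed-rank test on per-donor right-minus-left
#' differences, using donors with both hemispheres.  Unpaired: rank-sum
#' test between right and left samples.  Exact null distribution for small
#' n without ties, normal approximation with continuity correction
#' otherwise.
#'
#' @param values a `normalized_matrix` or plain matrix (genes x samples).
#' @param meta sample metadata (`sample_id`, `donor`, `hemisphere`,
#'   `area`).
#' @param gene gene ID (must be a row of `values`).
#' @param area area label.
#' @param paired signed-rank on donor pairs (default TRUE).
#' @return list: `statistic`, `p`, `n` (pairs after zero-difference
#'   removal, or per-group sizes), `flag`.
#' @export
wilcoxon_lr <- function(values, meta, gene, area, paired = TRUE) {
  m <- if (inherits(values, "normalized_matrix")) values$values else values
  if (!gene %in% rownames(m)) stop("unknown gene: ", gene)
  sub <- meta[meta$area == area, , drop = FALSE]
  if (!nrow(sub)) stop("unknown area: ", area)
  v <- m[gene, sub$sample_id]
  flag <- ""
  if (paired) {
    donors <- unique(sub$donor)
    pairs <- vapply(donors, function(d) {
      l <- sub$sample_id[sub$donor == d & sub$hemisphere == "L"]
      r <- sub$sample_id[sub$donor == d & sub$hemisphere == "R"]
      if (length(l) == 1 && length(r) == 1) v[r] - v[l] else NA_real_
    }, numeric(1))
    dif <- pairs[!is.na(pairs)]
    if (length(dif) < 2) stop("need at least 2 donor pairs in ", area)
    nz <- dif[dif != 0]
    if (!length(nz))
      return(list(statistic = NA_real_, p = 1, n = 0,
                  flag = "all_differences_zero"))
    exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
    wt <- suppressWarnings(
      wilcox.test(nz, exact = exact, correct = TRUE))
    list(statistic = unname(wt$statistic), p = wt$p.value,
         n = length(nz), flag = flag)
  } else {
    r <- v[sub$sample_id[sub$hemisphere == "R"]]
    l <- v[sub$sample_id[sub$hemisphere == "L"]]
    if (length(r) < 2 || length(l) < 2)
      stop("need at least 2 samples per hemisphere in ", area)
    if (all(c(r, l) == c(r, l)[1]))
      return(list(statistic = NA_real_, p = 1, n = c(length(r), length(l)),
                  flag = "all_tied"))
    exact <- (length(r) + length(l)) <= 25 && !any(duplicated(c(r, l)))
    wt <- suppressWarnings(
      wilcox.test(r, l, exact = exact, correct = TRUE))
    list(statistic = unname(wt$statistic), p = wt$p.value,
         n = c(n_right = length(r), n_left = length(l)), flag = flag)
  }
}
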