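# Leave-one-donor-out probabilistic handedness inference.
#
# In each fold, right-versus-left contrasts fit on the training donors
# within each region yield a signed weight vector of moderated t
# statistics; the held-out donor's right-minus-left log-CPM differences
# are projected onto it to give region laterality scores, which are
# averaged into language and motor indices; a Gaussian class-conditional
# Bayes rule maps the language index to a posterior probability of right
# handedness.

#' Default language and motor region sets
#'
#' Language: Broca (BA44, BA45), Wernicke (BA22, BA21) and Geschwind
#' (BA39, BA40) areas.  Motor: ventral sensorimotor areas (BA4, BA6,
#' BA3/1/2).
#'
#' @return list with `language` and `motor` character vectors.
#' @export
default_region_sets <- function() {
  list(language = c("BA44", "BA45", "BA22", "BA21", "BA39", "BA40"),
       motor = c("BA4", "BA6", "BA3/1/2"))
}

#' Train a signed weight vector for one region, excluding one donor
#'
#' Fits the right-versus-left moderated-t contrast (donor-blocked, with
#' precision weights) on the training donors only; the moderated t
#' statistics are the weights.
#'
#' @param counts count matrix, genes x samples.
#' @param meta sample metadata.
#' @param region area label.
#' @param held_out_donor donor ID to exclude (NULL for no exclusion).
#' @param ... passed to [fit_contrast()].
#' @return list of class `weight_vector`: `region`, `gene_ids`, `w`,
#'   `training_donors`.
#' @export
train_weights <- function(counts, meta, region, held_out_donor = NULL, ...) {
  train_meta <- meta
  if (!is.null(held_out_donor)) {
    if (!held_out_donor %in% meta$donor)
      stop("unknown donor: ", held_out_donor)
    train_meta <- meta[meta$donor != held_out_donor, , drop = FALSE]
  }
  spec <- build_contrast(train_meta, family = "LR", area_a = region)
  if (!is.null(held_out_donor) && held_out_donor %in% spec$donors_used)
    stop("held-out donor leaked into the training set")
  res <- fit_contrast(counts[, spec$sample_ids, drop = FALSE], spec, ...)
  w <- res$statistic
  w[!is.finite(w)] <- 0
  structure(list(region = region, gene_ids = res$gene_id, w = w,
                 training_donors = spec$donors_used),
            class = "weight_vector")
}

#' Project a donor's right-minus-left differences onto a weight vector
#'
#' Forms \eqn{d_g = \mathrm{logCPM}_{R,g} - \mathrm{logCPM}_{L,g}} for the
#' donor's pair of samples in the weight vector's region and returns the
#' projection \eqn{\sum_g w_g d_g} (dot) or its cosine-normalized version
#' \eqn{\sum w_g d_g / (\lVert w\rVert\,\lVert d\rVert)} (default).
#' Genes absent from the donor's matrix are dropped (fraction recorded).
#'
#' @param counts count matrix including the donor's samples.
#' @param meta sample metadata.
#' @param donor donor ID.
#' @param weights a [train_weights()] object.
#' @param normalization `"cosine"` (default) or `"dot"`.
#' @param prior_count log-CPM offset.
#' @return list of class `laterality_score`: `donor`, `region`, `score`,
#'   `n_genes`, `dropped_fraction`, `flag`.
#' @export
project_donor <- function(counts, meta, donor, weights,
                          normalization = c("cosine", "dot"),
                          prior_count = 0.5) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(weights, "weight_vector"))
  sub <- meta[meta$donor == donor & meta$area == weights$region, ,
              drop = FALSE]
  l <- sub$sample_id[sub$hemisphere == "L"]
  r <- sub$sample_id[sub$hemisphere == "R"]
  if (length(l) != 1 || length(r) != 1)
    return(structure(list(donor = donor, region = weights$region,
                          score = NA_real_, n_genes = 0,
                          dropped_fraction = 1,
                          flag = "missing_hemisphere"),
                     class = "laterality_score"))
  genes <- intersect(weights$gene_ids, rownames(counts))
  dropped <- 1 - length(genes) / length(weights$gene_ids)
  pair <- counts[genes, c(l, r), drop = FALSE]
  lc <- log_cpm(pair, prior_count = prior_count)$values
  d <- lc[, 2] - lc[, 1]
  w <- weights$w[match(genes, weights$gene_ids)]
  s <- sum(w * d)
  if (normalization == "cosine") {
    den <- sqrt(sum(w^2)) * sqrt(sum(d^2))
    s <- if (den > 0) s / den else 0
  }
  structure(list(donor = donor, region = weights$region, score = s,
                 n_genes = length(genes), dropped_fraction = dropped,
                 flag = ""),
            class = "laterality_score")
}

#' Average region laterality scores into language and motor indices
#'
#' @param scores list of [project_donor()] scores for one donor.
#' @param language_regions,motor_regions region label sets.
#' @return list: `language_index`, `motor_index`, `n_language`, `n_motor`
#'   (numbers of defined region scores that entered each mean).
#' @export
region_indices <- function(scores,
                           language_regions = default_region_sets()$language,
                           motor_regions = default_region_sets()$motor) {
  pull <- function(regions) {
    v <- vapply(scores, function(s)
      if (s$region %in% regions) s$score else NA_real_, numeric(1))
    v[!is.na(v)]
  }
  lang <- pull(language_regions)
  mot <- pull(motor_regions)
  if (!length(lang)) stop("no defined language-region scores")
  if (!length(mot)) stop("no defined motor-region scores")
  list(language_index = mean(lang), motor_index = mean(mot),
       n_language = length(lang), n_motor = length(mot))
}

#' Posterior probability of right handedness from a language index
#'
#' Gaussian class-conditional Bayes rule with shared sd:
#' \deqn{P(R \mid s) = \pi\,\phi(s;\mu_R,\sigma) /
#'   [\pi\,\phi(s;\mu_R,\sigma) + (1-\pi)\,\phi(s;\mu_L,\sigma)]}
#'
#' @param language_index laterality score s.
#' @param prior prior probability of right handedness (default 0.9,
#'   the approximate population rate).
#' @param mu_r,mu_l class-conditional means for right-/left-handed.
#' @param sigma shared class-conditional sd (> 0).
#' @return list: `posterior`, `language_index`, `prior`.
#' @export
posterior_handedness <- function(language_index, prior = 0.9,
                                 mu_r = 1, mu_l = -1, sigma = 1) {
  if (prior <= 0 || prior >= 1) stop("prior must be in (0, 1)")
  if (sigma <= 0) {
    if (mu_r == mu_l) stop("degenerate model: mu_r = mu_l with sigma <= 0")
    stop("sigma must be > 0")
  }
  # log-space form of pi*phi_R / (pi*phi_R + (1-pi)*phi_L): robust to
  # density underflow far from both class means
  llr <- ((language_index - mu_l)^2 - (language_index - mu_r)^2) /
    (2 * sigma^2)
  post <- stats::plogis(log(prior / (1 - prior)) + llr)
  list(posterior = post, language_index = language_index, prior = prior)
}

#' Leave-one-donor-out handedness inference
#'
#' For each donor: train region weight vectors on the remaining donors,
#' project the held-out donor, average into language and motor indices,
#' and map the language index to a posterior probability of right
#' handedness.  Class-conditional parameters are calibrated per fold on
#' the training donors' own language indices by handedness class (shared
#' pooled sd); when a class is absent they fall back to
#' \eqn{(+\hat\sigma, -\hat\sigma, \hat\sigma)} with \eqn{\hat\sigma} the
#' sd of all training indices.
#'
#' @param counts count matrix, genes x samples.
#' @param meta sample metadata (needs `handedness` for calibration).
#' @param language_regions,motor_regions region sets (defaults:
#'   [default_region_sets()]).
#' @param prior prior probability of right handedness.
#' @param normalization projection normalization, see [project_donor()].
#' @param ... passed to [fit_contrast()] via [train_weights()].
#' @return data frame, one row per donor: donor, language_index,
#'   motor_index, posterior, mu_r, mu_l, sigma; attribute `fold_report`
#'   lists per-fold training donors and weight-vector hashes.
#' @export
lodo_run <- function(counts, meta,
                     language_regions = default_region_sets()$language,
                     motor_regions = default_region_sets()$motor,
                     prior = 0.9, normalization = "cosine", ...) {
  donors <- sort(unique(meta$donor))
  if (length(donors) < 3) stop("leave-one-donor-out needs at least 3 donors")
  regions <- intersect(c(language_regions, motor_regions),
                       unique(meta$area))
  if (!length(regions)) stop("no requested region present in metadata")
  hand_of <- vapply(donors, function(d) {
    h <- meta$handedness[meta$donor == d]
    as.character(h[1])
  }, character(1))

  fold_report <- list()
  rows <- lapply(donors, function(held) {
    wts <- lapply(regions, function(rg)
      train_weights(counts, meta, rg, held_out_donor = held, ...))
    names(wts) <- regions
    fold_report[[held]] <<- list(
      training_donors = setdiff(donors, held),
      weight_hash = hash_object(wts))
    # held-out donor's indices
    sc <- lapply(wts, function(w)
      project_donor(counts, meta, held, w, normalization = normalization))
    idx <- region_indices(sc, language_regions, motor_regions)
    # calibration: each training donor's language index computed as if it
    # were held out (nested leave-one-out), so the class-conditional
    # means live on the same scale as the held-out projection; with too
    # few donors for nesting, fall back to in-sample projection
    train_donors <- setdiff(donors, held)
    train_idx <- vapply(train_donors, function(d) {
      w_d <- if (length(train_donors) >= 3) {
        lapply(wts, function(w) {
          m2 <- meta[!meta$donor %in% c(held, d), , drop = FALSE]
          train_weights(counts, m2, w$region, held_out_donor = NULL, ...)
        })
      } else wts
      s <- lapply(w_d, function(w)
        project_donor(counts, meta, d, w, normalization = normalization))
      region_indices(s, language_regions, motor_regions)$language_index
    }, numeric(1))
    cls <- hand_of[setdiff(donors, held)]
    sig_hat <- if (length(train_idx) >= 2) sd(train_idx) else 1
    if (!is.finite(sig_hat) || sig_hat == 0) sig_hat <- 1
    r_idx <- train_idx[cls == "R"]
    l_idx <- train_idx[cls == "L"]
    if (length(r_idx) >= 1 && length(l_idx) >= 1) {
      mu_r <- mean(r_idx); mu_l <- mean(l_idx)
      pooled <- c(r_idx - mu_r, l_idx - mu_l)
      sigma <- if (length(pooled) >= 3) sd(pooled) else sig_hat
      if (!is.finite(sigma) || sigma == 0) sigma <- sig_hat
    } else {
      mu_r <- sig_hat; mu_l <- -sig_hat; sigma <- sig_hat
    }
    post <- posterior_handedness(idx$language_index, prior = prior,
                                 mu_r = mu_r, mu_l = mu_l, sigma = sigma)
    data.frame(donor = held, handedness = hand_of[[held]],
               language_index = idx$language_index,
               motor_index = idx$motor_index,
               posterior = post$posterior,
               mu_r = mu_r, mu_l = mu_l, sigma = sigma,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fold_report") <- fold_report
  out
}
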