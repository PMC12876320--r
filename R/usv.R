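# Ultrasonic vocalization pipeline: spectrogram, threshold detection,
# acoustic feature extraction, contour clustering, group comparisons.
#
# Detection follows simple spectral rules: frames whose in-band power
# exceeds 1.5x the mean frame power are active; runs of active frames
# (bridged across short gaps) become candidate segments; candidates are
# kept when longer than 5 ms with spectral purity above 25%.

#' Compute a band-limited power spectrogram
#'
#' Hann-windowed short-time FFT (default 512-point, 50% overlap), with the
#' returned bins restricted to the analysis band (default 25-110 kHz).
#' Frame times refer to the window start.
#'
#' @param waveform numeric vector.
#' @param sample_rate sampling rate in Hz.
#' @param fft_length FFT window length in samples (power of two,
#'   default 512).
#' @param overlap fraction of window overlap in [0, 1) (default 0.5).
#' @param band analysis band in Hz (default c(25e3, 110e3)); clipped to
#'   Nyquist; use NULL for the full band.
#' @return list of class `usv_spectrogram`: `power` (bins x frames),
#'   `freqs` (Hz), `times` (s, window starts), `hop_s`, `sample_rate`,
#'   `fft_length`.
#' @export
usv_spectrogram <- function(waveform, sample_rate, fft_length = 512,
                            overlap = 0.5, band = c(25e3, 110e3)) {
  if (fft_length < 2 || bitwAnd(fft_length, fft_length - 1L) != 0)
    stop("fft_length must be a power of two")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (length(waveform) < fft_length)
    stop("waveform shorter than one FFT window")
  if (!is.null(band) && band[1] >= sample_rate / 2)
    stop("analysis band lies above Nyquist for this sample rate")
  hop <- as.integer(round(fft_length * (1 - overlap)))
  sg <- signal::specgram(waveform, n = fft_length, Fs = sample_rate,
                         window = signal::hanning(fft_length),
                         overlap = fft_length - hop)
  power <- Mod(sg$S)^2
  freqs <- as.numeric(sg$f)
  # frame k covers samples (k-1)*hop + 1 .. (k-1)*hop + fft_length
  times <- (seq_len(ncol(power)) - 1) * hop / sample_rate
  if (!is.null(band)) {
    keep <- freqs >= band[1] & freqs <= min(band[2], sample_rate / 2)
    power <- power[keep, , drop = FALSE]
    freqs <- freqs[keep]
  }
  structure(list(power = power, freqs = freqs, times = times,
                 hop_s = hop / sample_rate, sample_rate = sample_rate,
                 fft_length = fft_length),
            class = "usv_spectrogram")
}

#' Detect USV segments in a spectrogram
#'
#' Frames whose summed in-band power exceeds `power_mult` times the mean
#' frame power are active.  Runs of active frames merged across gaps of at
#' most `max_gap_ms` form candidates; a candidate is a USV iff its
#' duration exceeds `min_duration_ms` and its spectral purity (mean
#' per-frame fraction of power in the peak bin) exceeds `min_purity`.
#'
#' @param spec a [usv_spectrogram()].
#' @param power_mult intensity threshold multiplier (default 1.5).
#' @param min_duration_ms minimum duration in ms (default 5, strict `>`).
#' @param min_purity minimum spectral purity (default 0.25, strict `>`).
#' @param max_gap_ms frame-gap bridging in ms (default 5).
#' @return data frame, one row per segment: onset (s), duration (s),
#'   offset (s), first_frame, last_frame, spectral_purity, f_lo, f_hi
#'   (band limits).  Zero rows when nothing is detected.
#' @export
detect_segments <- function(spec, power_mult = 1.5, min_duration_ms = 5,
                            min_purity = 0.25, max_gap_ms = 5) {
  stopifnot(inherits(spec, "usv_spectrogram"))
  frame_power <- colSums(spec$power)
  active <- frame_power > power_mult * mean(frame_power)
  empty <- data.frame(onset = numeric(), duration = numeric(),
                      offset = numeric(), first_frame = integer(),
                      last_frame = integer(), spectral_purity = numeric(),
                      f_lo = numeric(), f_hi = numeric())
  if (!any(active)) return(empty)
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg <- data.frame(first = starts[runs$values], last = ends[runs$values])
  # bridge short gaps between consecutive active runs
  max_gap_frames <- floor(max_gap_ms / 1000 / spec$hop_s)
  if (nrow(seg) > 1) {
    merged <- seg[1, , drop = FALSE]
    for (i in 2:nrow(seg)) {
      gap <- seg$first[i] - merged$last[nrow(merged)] - 1L
      if (gap <= max_gap_frames)
        merged$last[nrow(merged)] <- seg$last[i]
      else merged <- rbind(merged, seg[i, ])
    }
    seg <- merged
  }
  hop <- spec$hop_s
  win_s <- spec$fft_length / spec$sample_rate
  thr <- power_mult * mean(frame_power)
  rows <- lapply(seq_len(nrow(seg)), function(i) {
    fr <- seg$first[i]:seg$last[i]
    p <- spec$power[, fr, drop = FALSE]
    purity <- mean(apply(p, 2, max) / pmax(colSums(p), .Machine$double.eps))
    # sub-frame boundary refinement: an edge frame triggers once the
    # Hann^2-weighted energy of its signal coverage crosses the threshold;
    # inverting the Hann^2 energy CDF at thr/P (P the segment's typical
    # frame power) gives the trigger coverage d0, which removes the
    # duty-cycle-dependent bias up to half a hop
    p_seg <- median(frame_power[fr])
    d0 <- win_s * hann2_cdf_inv(min(1, thr / p_seg))
    onset <- spec$times[seg$first[i]] + win_s - d0 - hop / 2
    offset <- spec$times[seg$last[i]] + d0 + hop / 2
    if (offset <= onset) {  # degenerate short run: fall back to frame span
      onset <- spec$times[seg$first[i]]
      offset <- spec$times[seg$last[i]] + win_s
    }
    data.frame(onset = onset, duration = offset - onset, offset = offset,
               first_frame = seg$first[i], last_frame = seg$last[i],
               spectral_purity = purity,
               f_lo = min(spec$freqs), f_hi = max(spec$freqs))
  })
  out <- do.call(rbind, rows)
  out <- out[out$duration * 1000 > min_duration_ms &
               out$spectral_purity > min_purity, , drop = FALSE]
  if (!nrow(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Extract the frequency contour of one segment
#'
#' Per-frame frequency of maximum amplitude, restricted to the analysis
#' band.
#'
#' @param spec a [usv_spectrogram()].
#' @param segment one row of [detect_segments()] output.
#' @return data frame: time (s), frequency (Hz), amplitude (linear).
#' @export
extract_contour <- function(spec, segment) {
  fr <- segment$first_frame:segment$last_frame
  p <- spec$power[, fr, drop = FALSE]
  peak <- apply(p, 2, which.max)
  data.frame(time = spec$times[fr],
             frequency = spec$freqs[peak],
             amplitude = sqrt(p[cbind(peak, seq_along(fr))]))
}

#' Extract acoustic features for detected segments
#'
#' Fifteen features per segment, computed from the contour (per-frame
#' argmax frequency): duration; peak frequency (at the global power
#' maximum); average, maximum, minimum, start, end and median contour
#' frequency; delta frequency (|start - end|); bandwidth (max - min);
#' frequency sd; pause duration (onset minus previous offset; missing for
#' the first call); pause-to-USV duration ratio; jitter (mean absolute
#' successive contour-frequency difference over mean frequency); shimmer
#' (same on contour peak amplitudes).
#'
#' @param spec a [usv_spectrogram()].
#' @param segments [detect_segments()] output (rows in time order).
#' @return data frame, one row per segment, durations/pauses in ms and
#'   frequencies in Hz, plus a `flag` column (`"single_frame"` where
#'   dispersion features are degenerate).
#' @export
extract_features <- function(spec, segments) {
  if (!nrow(segments))
    return(data.frame())
  prev_offset <- c(NA_real_, segments$offset[-nrow(segments)])
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    ct <- extract_contour(spec, segments[i, ])
    f <- ct$frequency
    a <- ct$amplitude
    one <- length(f) == 1
    p <- spec$power[, segments$first_frame[i]:segments$last_frame[i],
                    drop = FALSE]
    peak_bin <- arrayInd(which.max(p), dim(p))
    pause <- (segments$onset[i] - prev_offset[i]) * 1000
    dur_ms <- segments$duration[i] * 1000
    data.frame(
      duration = dur_ms,
      peak_freq = spec$freqs[peak_bin[1]],
      avg_freq = mean(f),
      max_freq = max(f),
      min_freq = min(f),
      start_freq = f[1],
      end_freq = f[length(f)],
      median_freq = median(f),
      delta_freq = abs(f[1] - f[length(f)]),
      bandwidth = max(f) - min(f),
      stddev_freq = if (one) 0 else sd(f),
      pause_duration = pause,
      pause_to_usv_ratio = pause / dur_ms,
      jitter = if (one) 0 else mean(abs(diff(f))) / mean(f),
      shimmer = if (one) 0 else mean(abs(diff(a))) / mean(a),
      flag = if (one) "single_frame" else ""
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster syllable contours by k-means
#'
#' Contours are linearly resampled to a fixed length, z-scored per
#' resampled dimension, and clustered with Lloyd's k-means, run
#' `repetitions` times from distinct seeded initializations with the
#' lowest-inertia solution kept.  k is either fixed or chosen by mean
#' silhouette width over 2..min(k_max, n-1).  Identical contours collapse
#' to a single cluster (flagged).
#'
#' @param contours list of contour data frames ([extract_contour()]) or
#'   numeric vectors of contour frequencies.
#' @param k fixed cluster count, or `NULL` to select by silhouette.
#' @param k_max maximum clusters considered (default 100).
#' @param repetitions k-means restarts (default 3).
#' @param resample_points fixed contour length (default 32).
#' @param animal optional per-contour animal IDs for proportion vectors.
#' @param seed RNG seed for the initializations.
#' @return list of class `syllable_clusters`: `k`, `assignments`,
#'   `centroids`, `inertia`, `silhouette` (NA when k fixed),
#'   `proportions` (per-animal fraction vectors, rows summing to 1),
#'   `flag`.
#' @export
cluster_syllables <- function(contours, k = NULL, k_max = 100,
                              repetitions = 3, resample_points = 32,
                              animal = NULL, seed = 1L) {
  n <- length(contours)
  if (n < 2) stop("need at least 2 contours")
  feat <- t(vapply(contours, function(ct) {
    f <- if (is.data.frame(ct)) ct$frequency else as.numeric(ct)
    if (length(f) == 1) rep(f, resample_points)
    else approx(seq_along(f), f, n = resample_points)$y
  }, numeric(resample_points)))
  mu <- colMeans(feat)
  s <- apply(feat, 2, sd)
  s[s == 0] <- 1
  z <- sweep(sweep(feat, 2, mu), 2, s, "/")

  if (all(apply(z, 2, function(col) max(col) - min(col) < 1e-12))) {
    prop <- proportions_by_animal(rep(1L, n), 1L, animal)
    return(structure(list(k = 1L, assignments = rep(1L, n),
                          centroids = matrix(colMeans(z), 1),
                          inertia = 0, silhouette = NA_real_,
                          proportions = prop,
                          flag = "identical_contours"),
                     class = "syllable_clusters"))
  }

  n_distinct <- nrow(unique(z))
  run_k <- function(kk) {
    best <- NULL
    for (r in seq_len(repetitions)) {
      fit <- with_seed(stage_seed(seed, kk * 1000 + r),
                       kmeans(z, centers = kk, algorithm = "Lloyd",
                              iter.max = 100, nstart = 1))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
  }

  flag <- ""
  if (is.null(k)) {
    ks <- 2:min(k_max, n - 1, n_distinct)
    sil <- vapply(ks, function(kk) {
      fit <- run_k(kk)
      mean_silhouette(z, fit$cluster)
    }, numeric(1))
    k <- ks[which.max(sil)]
    sil_best <- max(sil)
  } else {
    if (k < 1 || k > n) stop("k must be in 1..n")
    if (k > n_distinct) {
      k <- n_distinct
      flag <- "k_reduced_to_distinct_contours"
    }
    sil_best <- NA_real_
  }
  fit <- run_k(k)
  structure(list(k = k, assignments = fit$cluster,
                 centroids = fit$centers, inertia = fit$tot.withinss,
                 silhouette = sil_best,
                 proportions = proportions_by_animal(fit$cluster, k, animal),
                 flag = flag),
            class = "syllable_clusters")
}

# fraction of a Hann window's squared-taper energy within the first
# (or, by symmetry, last) u of the window, and its inverse
hann2_cdf <- function(u) {
  (1.5 * u - sin(2 * pi * u) / pi + sin(4 * pi * u) / (8 * pi)) / 1.5
}

hann2_cdf_inv <- function(f) {
  if (f <= 0) return(0)
  if (f >= 1) return(1)
  stats::uniroot(function(u) hann2_cdf(u) - f, c(0, 1), tol = 1e-9)$root
}

# mean silhouette width from a Euclidean distance matrix
mean_silhouette <- function(z, cluster) {
  d <- as.matrix(stats::dist(z))
  n <- nrow(d)
  sil <- vapply(seq_len(n), function(i) {
    own <- cluster == cluster[i]
    a <- if (sum(own) > 1) mean(d[i, own & seq_len(n) != i]) else 0
    others <- setdiff(unique(cluster), cluster[i])
    if (!length(others)) return(0)
    b <- min(vapply(others, function(cl) mean(d[i, cluster == cl]),
                    numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

proportions_by_animal <- function(assignments, k, animal) {
  if (is.null(animal)) animal <- rep("all", length(assignments))
  tab <- table(animal, factor(assignments, levels = seq_len(k)))
  prop <- sweep(unclass(tab), 1, rowSums(tab), "/")
  prop
}

#' Mann-Whitney comparison of per-animal feature values
#'
#' Computes per-animal means first (the animal is the unit of analysis),
#' then a two-sided rank-sum test per feature between the two groups:
#' exact for combined n <= 20 without ties, normal approximation with tie
#' correction otherwise.
#'
#' @param features data frame of per-call features plus `animal` and
#'   `group` columns, or a per-animal data frame (one row per animal).
#' @param group_a,group_b group labels to compare.
#' @param feature_cols features to test (default: all numeric columns).
#' @return data frame: feature, statistic (U), p, n_a, n_b, flag.
#' @export
compare_groups <- function(features, group_a, group_b,
                           feature_cols = NULL) {
  stopifnot(all(c("animal", "group") %in% names(features)))
  if (is.null(feature_cols))
    feature_cols <- names(features)[vapply(features, is.numeric, logical(1))]
  per_animal <- aggregate(features[feature_cols],
                          by = list(animal = features$animal,
                                    group = features$group),
                          FUN = function(v) mean(v, na.rm = TRUE))
  rows <- lapply(feature_cols, function(fc) {
    a <- per_animal[[fc]][per_animal$group == group_a]
    b <- per_animal[[fc]][per_animal$group == group_b]
    if (length(a) < 2 || length(b) < 2)
      stop("need at least 2 animals per group for ", fc)
    if (length(unique(c(a, b))) == 1)
      return(data.frame(feature = fc, statistic = NA_real_, p = 1,
                        n_a = length(a), n_b = length(b),
                        flag = "all_tied"))
    exact <- (length(a) + length(b)) <= 20 && !any(duplicated(c(a, b)))
    wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
    data.frame(feature = fc, statistic = unname(wt$statistic),
               p = wt$p.value, n_a = length(a), n_b = length(b), flag = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @importFrom stats aggregate dist
NULL
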