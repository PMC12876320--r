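# USV pipeline: spectrogram fidelity, threshold detection, features,
# contours, clustering, group comparisons.

test_that("the spectrogram localizes a pure tone to within one bin", {
  fs <- 375000
  aud <- simulate_usv_audio(usv_sim_spec(
    syllables = data.frame(onset = 0.02, duration = 0.03, type = "tone",
                           f_start = 50e3, f_end = 50e3, amplitude = 0.5),
    noise_floor = 0, seed = 1))
  sp <- usv_spectrogram(aud$waveform, fs)
  bin_hz <- fs / 512
  mid <- round(ncol(sp$power) / 2)
  peak <- sp$freqs[which.max(sp$power[, mid])]
  expect_lt(abs(peak - 50e3), bin_hz)
  expect_equal(sp$hop_s, 256 / fs)
  expect_true(all(sp$freqs >= 25e3 & sp$freqs <= 110e3))

  # silence: negligible power everywhere
  quiet <- usv_spectrogram(rep(0, 4096), fs)
  expect_equal(max(quiet$power), 0)

  expect_error(usv_spectrogram(rnorm(100), fs), "shorter")
  expect_error(usv_spectrogram(rnorm(4096), fs, fft_length = 500),
               "power of two")
  expect_error(usv_spectrogram(rnorm(4096), 40000), "Nyquist")
})

test_that("band-limited spectral power tracks waveform energy", {
  # Parseval-style check: in-band power of an in-band tone scales with
  # the squared amplitude of the waveform
  fs <- 375000
  mk <- function(a) simulate_usv_audio(usv_sim_spec(
    syllables = data.frame(onset = 0.01, duration = 0.04, type = "tone",
                           f_start = 60e3, f_end = 60e3, amplitude = a),
    noise_floor = 0, seed = 1))$waveform
  p1 <- sum(usv_spectrogram(mk(0.2), fs)$power)
  p2 <- sum(usv_spectrogram(mk(0.4), fs)$power)
  expect_equal(p2 / p1, 4, tolerance = 1e-3)
})

test_that("detection finds nothing in noise and rejects sub-threshold calls", {
  fs <- 375000
  noise <- simulate_usv_audio(usv_sim_spec(noise_floor = 0.01,
                                           padding_s = 0.5, seed = 2))
  sp <- usv_spectrogram(noise$waveform, fs)
  expect_equal(nrow(detect_segments(sp)), 0)

  # a 4 ms call fails the strict > 5 ms duration rule
  short <- simulate_usv_audio(usv_sim_spec(
    syllables = data.frame(onset = 0.05, duration = 0.004, type = "tone",
                           f_start = 50e3, f_end = 50e3, amplitude = 0.5),
    noise_floor = 0.005, ramp_s = 0.00025, padding_s = 0.3, seed = 3))
  segs <- detect_segments(usv_spectrogram(short$waveform, fs),
                          min_duration_ms = 5)
  expect_equal(nrow(segs), 0)
})

test_that("detection is exact on the 20-syllable fixture", {
  aud <- simulate_usv_audio(usv_fixture_spec())
  sp <- usv_spectrogram(aud$waveform, aud$sample_rate)
  segs <- detect_segments(sp)
  # precision = recall = 1
  expect_equal(nrow(segs), nrow(aud$truth))
  matches <- match_segments(segs, aud$truth)
  expect_false(anyNA(matches))
  expect_equal(sort(matches), seq_len(nrow(segs)))
  hop <- sp$hop_s
  expect_lt(max(abs(segs$onset[matches] - aud$truth$onset)), hop)
  expect_lt(max(abs(segs$duration[matches] - aud$truth$duration)), 2 * hop)
  expect_true(all(segs$spectral_purity > 0.25))
})

test_that("features sit within one bin / one hop of ground truth", {
  aud <- simulate_usv_audio(usv_fixture_spec())
  sp <- usv_spectrogram(aud$waveform, aud$sample_rate)
  segs <- detect_segments(sp)
  feats <- extract_features(sp, segs)
  bin_hz <- aud$sample_rate / 512
  tone <- which(aud$truth$type == "tone")
  chirp <- which(aud$truth$type == "chirp")

  for (col in c("peak_freq", "avg_freq", "max_freq", "min_freq",
                "start_freq", "end_freq", "median_freq"))
    expect_lt(max(abs(feats[[col]][tone] - 50e3)), bin_hz)
  expect_lt(max(feats$bandwidth[tone]), bin_hz)
  expect_lt(max(feats$delta_freq[tone]), bin_hz)
  expect_lt(max(feats$jitter[tone]), 0.01)

  expect_lt(max(abs(feats$min_freq[chirp] - 40e3)), bin_hz)
  expect_lt(max(abs(feats$max_freq[chirp] - 47.5e3)), bin_hz)
  expect_lt(max(abs(feats$start_freq[chirp] - 40e3)), bin_hz)
  expect_lt(max(abs(feats$end_freq[chirp] - 47.5e3)), bin_hz)
  expect_lt(max(abs(feats$delta_freq[chirp] - 7.5e3)), bin_hz)
  expect_lt(max(abs(feats$bandwidth[chirp] - 7.5e3)), bin_hz)

  # pauses: 85 ms spacing minus 15 ms calls = 70 ms
  expect_true(is.na(feats$pause_duration[1]))
  expect_lt(max(abs(feats$pause_duration[-1] - 70)), 2 * sp$hop_s * 1000)
  expect_lt(max(abs(feats$pause_to_usv_ratio[-1] - 70 / 15)), 0.5)
})

test_that("contours track tone flatness, chirp slope, and FM period", {
  fs <- 375000
  aud <- simulate_usv_audio(usv_sim_spec(
    syllables = data.frame(
      onset = c(0.05, 0.15, 0.25),
      duration = c(0.02, 0.03, 0.04),
      type = c("tone", "chirp", "sine_fm"),
      f_start = c(50e3, 40e3, 45e3),
      f_end = c(50e3, 80e3, 55e3),
      amplitude = 0.5,
      fm_rate = c(NA, NA, 100)),
    noise_floor = 0.003, ramp_s = 0.00025, seed = 4))
  sp <- usv_spectrogram(aud$waveform, fs)
  segs <- detect_segments(sp)
  expect_equal(nrow(segs), 3)

  # tone: flat contour
  ct1 <- extract_contour(sp, segs[1, ])
  expect_lt(max(ct1$frequency) - min(ct1$frequency), fs / 512 + 1)

  # chirp: fitted slope within 5% of (f_end - f_start) / duration
  ct2 <- extract_contour(sp, segs[2, ])
  inner <- ct2[3:(nrow(ct2) - 2), ]  # avoid edge frames
  slope <- coef(lm(frequency ~ time, inner))[2]
  expect_lt(abs(slope - (80e3 - 40e3) / 0.03) / ((80e3 - 40e3) / 0.03),
            0.05)

  # sinusoidal FM: dominant contour period within one hop of 1/fm_rate
  ct3 <- extract_contour(sp, segs[3, ])
  f <- ct3$frequency - mean(ct3$frequency)
  ac <- acf(f, lag.max = length(f) - 1, plot = FALSE)$acf[, 1, 1]
  # first local maximum after the zero-lag peak
  lag <- which(diff(sign(diff(ac))) == -2)[1] + 1
  period_s <- (lag - 1) * sp$hop_s
  expect_lt(abs(period_s - 1 / 100), sp$hop_s)
})

test_that("features are invariant to global amplitude scaling", {
  aud <- simulate_usv_audio(usv_fixture_spec())
  sp1 <- usv_spectrogram(aud$waveform, aud$sample_rate)
  sp2 <- usv_spectrogram(aud$waveform * 0.25, aud$sample_rate)
  s1 <- detect_segments(sp1); s2 <- detect_segments(sp2)
  expect_equal(nrow(s1), nrow(s2))
  f1 <- extract_features(sp1, s1); f2 <- extract_features(sp2, s2)
  num <- vapply(f1, is.numeric, logical(1))
  expect_equal(f1[num], f2[num], tolerance = 1e-8)
})

test_that("clustering separates call families perfectly and degenerates safely", {
  aud <- simulate_usv_audio(usv_fixture_spec())
  sp <- usv_spectrogram(aud$waveform, aud$sample_rate)
  segs <- detect_segments(sp)
  contours <- lapply(seq_len(nrow(segs)), function(i)
    extract_contour(sp, segs[i, ]))
  truth_lab <- as.integer(factor(aud$truth$type))

  cl <- cluster_syllables(contours, k = 2, seed = 5)
  expect_equal(ari_oracle(cl$assignments, truth_lab), 1)
  if (requireNamespace("mclust", quietly = TRUE))
    expect_equal(mclust::adjustedRandIndex(cl$assignments, truth_lab), 1)

  # silhouette selection lands on two families when calls carry natural
  # within-family variation (identical duplicate contours degenerate the
  # silhouette toward oversplitting, so jitter the call frequencies)
  set.seed(7)
  jit <- lapply(1:20, function(i) {
    if (i %% 2 == 1) rep(50e3 + runif(1, -1e3, 1e3), 32)
    else seq(40e3 + runif(1, -1e3, 1e3), 47.5e3 + runif(1, -1e3, 1e3),
             length.out = 32)
  })
  cl_sil <- cluster_syllables(jit, k = NULL, k_max = 8, seed = 5)
  expect_equal(cl_sil$k, 2)
  expect_equal(ari_oracle(cl_sil$assignments, rep(1:2, 10)), 1)

  # determinism
  cl2 <- cluster_syllables(contours, k = 2, seed = 5)
  expect_identical(cl$assignments, cl2$assignments)

  # identical contours collapse to one flagged cluster
  same <- replicate(6, data.frame(frequency = rep(5e4, 10)),
                    simplify = FALSE)
  cl3 <- cluster_syllables(same, seed = 1)
  expect_equal(cl3$k, 1)
  expect_equal(cl3$flag, "identical_contours")

  # per-animal proportions sum to one
  cl4 <- cluster_syllables(contours, k = 2,
                           animal = rep(c("m1", "m2"), 10), seed = 5)
  expect_equal(unname(rowSums(cl4$proportions)), c(1, 1))
})

test_that("group comparisons are exact on per-animal means", {
  f <- data.frame(animal = rep(paste0("m", 1:6), each = 4),
                  group = rep(c("ctl", "oe"), each = 12),
                  peak = c(rep(1:3, each = 4), rep(4:6, each = 4)))
  out <- compare_groups(f, "ctl", "oe", feature_cols = "peak")
  expect_equal(out$p, 0.1)  # (1,2,3) vs (4,5,6) enumeration
  expect_equal(out$p, rank_sum_oracle(1:3, 4:6))

  tied <- f; tied$peak <- 5
  out2 <- compare_groups(tied, "ctl", "oe", feature_cols = "peak")
  expect_equal(out2$p, 1)
  expect_equal(out2$flag, "all_tied")

  # enumeration agreement for random combined n <= 10
  set.seed(66)
  for (i in 1:10) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    va <- sample(1000, na); vb <- sample(1000, nb)
    ff <- data.frame(animal = paste0("a", seq_len(na + nb)),
                     group = rep(c("A", "B"), c(na, nb)),
                     x = c(va, vb))
    out3 <- compare_groups(ff, "A", "B", feature_cols = "x")
    expect_equal(out3$p, rank_sum_oracle(va, vb), tolerance = 1e-12)
  }
})
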