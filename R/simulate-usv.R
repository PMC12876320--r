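# Synthetic ultrasonic vocalization audio with analytic ground truth.
#
# Syllables are tones, linear chirps or sinusoidally frequency-modulated
# calls with raised-cosine amplitude envelopes (no spectral splatter at the
# edges), embedded in Gaussian white noise.  Ground-truth onset, duration
# and frequency extrema are known exactly by construction.

#' Specification for a synthetic USV recording
#'
#' @param syllables data frame with one row per syllable and columns:
#'   `onset` (s), `duration` (s), `type` (one of `"tone"`, `"chirp"`,
#'   `"sine_fm"`), `f_start` (Hz), `f_end` (Hz), `amplitude` (linear, in
#'   (0, 1]), and for `sine_fm` optionally `fm_rate` (Hz, default 100).
#'   `f_start`/`f_end` are the instantaneous-frequency endpoints of a
#'   chirp; for `sine_fm` the carrier sweeps sinusoidally between them.
#'   May have zero rows (silence).
#' @param sample_rate sampling rate in Hz (default 375000, a typical
#'   ultrasonic recording rate).
#' @param noise_floor RMS amplitude of additive Gaussian white noise.
#' @param ramp_s raised-cosine on/off ramp length in seconds.
#' @param padding_s silence appended after the last syllable.
#' @param seed integer RNG seed (noise realization).
#' @return object of class `usv_sim_spec`.
#' @export
usv_sim_spec <- function(syllables = NULL, sample_rate = 375000,
                         noise_floor = 0.001, ramp_s = 0.002,
                         padding_s = 0.05, seed = 1L) {
  sample_rate <- check_positive(sample_rate, "sample_rate")
  if (is.null(syllables))
    syllables <- data.frame(onset = numeric(), duration = numeric(),
                            type = character(), f_start = numeric(),
                            f_end = numeric(), amplitude = numeric())
  need <- c("onset", "duration", "type", "f_start", "f_end", "amplitude")
  if (!is.data.frame(syllables) || !all(need %in% names(syllables)))
    abort_field("syllables",
                "must be a data frame with columns onset, duration, type, f_start, f_end, amplitude")
  if (nrow(syllables) > 0) {
    if (!all(syllables$type %in% c("tone", "chirp", "sine_fm")))
      abort_field("syllables", "type must be tone, chirp or sine_fm")
    nyq <- sample_rate / 2
    if (any(syllables$f_start >= nyq | syllables$f_end >= nyq))
      abort_field("syllables", "frequencies must be below Nyquist")
    if (any(syllables$duration <= 0) || any(syllables$onset < 0))
      abort_field("syllables", "onsets must be >= 0 and durations > 0")
    ord <- order(syllables$onset)
    syllables <- syllables[ord, , drop = FALSE]
    offs <- syllables$onset + syllables$duration
    if (nrow(syllables) > 1 &&
        any(syllables$onset[-1] < offs[-nrow(syllables)]))
      abort_field("syllables", "syllables must not overlap in time")
  }
  structure(list(
    syllables = syllables, sample_rate = sample_rate,
    noise_floor = check_nonneg(noise_floor, "noise_floor"),
    ramp_s = check_nonneg(ramp_s, "ramp_s"),
    padding_s = check_nonneg(padding_s, "padding_s"),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "usv_sim_spec")
}

#' Simulate a USV waveform with ground-truth segment table
#'
#' @param spec a [usv_sim_spec()].
#' @return list with `waveform` (numeric vector in [-1, 1]),
#'   `sample_rate`, and `truth` (data frame: onset, duration, type,
#'   f_start, f_end, f_min, f_max — the true instantaneous-frequency
#'   extrema of each syllable).
#' @export
simulate_usv_audio <- function(spec) {
  if (!inherits(spec, "usv_sim_spec"))
    abort_field("spec", "must be built by usv_sim_spec()")
  fs <- spec$sample_rate
  syl <- spec$syllables
  total_s <- if (nrow(syl)) max(syl$onset + syl$duration) + spec$padding_s
             else spec$padding_s
  n <- max(1L, ceiling(total_s * fs))
  wave <- with_seed(spec$seed,
                    if (spec$noise_floor > 0) rnorm(n, 0, spec$noise_floor)
                    else numeric(n))
  if (nrow(syl)) {
    for (i in seq_len(nrow(syl))) {
      i0 <- floor(syl$onset[i] * fs) + 1L
      len <- round(syl$duration[i] * fs)
      t <- (seq_len(len) - 1) / fs
      f0 <- syl$f_start[i]; f1 <- syl$f_end[i]
      phase <- switch(syl$type[i],
        tone  = 2 * pi * f0 * t,
        chirp = 2 * pi * (f0 * t + (f1 - f0) / (2 * syl$duration[i]) * t^2),
        sine_fm = {
          fm <- if ("fm_rate" %in% names(syl) && is.finite(syl$fm_rate[i]))
            syl$fm_rate[i] else 100
          fc <- (f0 + f1) / 2; fd <- (f1 - f0) / 2
          # instantaneous frequency fc + fd*sin(2 pi fm t)
          2 * pi * (fc * t - fd / (2 * pi * fm) * (cos(2 * pi * fm * t) - 1))
        })
      env <- raised_cosine_env(len, round(spec$ramp_s * fs))
      seg <- syl$amplitude[i] * env * sin(phase)
      idx <- i0:(i0 + len - 1L)
      wave[idx] <- wave[idx] + seg
    }
  }
  truth <- if (nrow(syl)) {
    data.frame(
      onset = syl$onset, duration = syl$duration, type = syl$type,
      f_start = syl$f_start, f_end = syl$f_end,
      f_min = pmin(syl$f_start, syl$f_end),
      f_max = pmax(syl$f_start, syl$f_end)
    )
  } else {
    data.frame(onset = numeric(), duration = numeric(), type = character(),
               f_start = numeric(), f_end = numeric(), f_min = numeric(),
               f_max = numeric())
  }
  list(waveform = wave, sample_rate = fs, truth = truth)
}

raised_cosine_env <- function(len, ramp) {
  env <- rep(1, len)
  ramp <- min(ramp, floor(len / 2))
  if (ramp > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
    env[seq_len(ramp)] <- up
    env[(len - ramp + 1L):len] <- rev(up)
  }
  env
}

#' Write a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer for the recording format used in ultrasonic
#' work (mono, 16-bit PCM, arbitrary sample rate).
#'
#' @param waveform numeric vector in [-1, 1] (clipped otherwise).
#' @param path output file path.
#' @param sample_rate sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, path, sample_rate) {
  pcm <- as.integer(pmax(-32767, pmin(32767, round(waveform * 32767))))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path WAV file written by [write_wav()] or any mono 16-bit PCM
#'   RIFF/WAVE file.
#' @return list with `waveform` (numeric in [-1, 1]) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)
  sample_rate <- NULL
  repeat {
    tag <- readChar(con, 4)
    if (length(tag) == 0 || nchar(tag) < 4) stop("no data chunk in ", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (tag == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L)
        stop("only mono PCM WAV supported")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      ba_bits <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (ba_bits[2] != 16L) stop("only 16-bit PCM WAV supported")
      if (size > 16) readBin(con, raw(), n = size - 16L)
    } else if (tag == "data") {
      pcm <- readBin(con, integer(), n = size / 2L, size = 2,
                     endian = "little", signed = TRUE)
      break
    } else {
      readBin(con, raw(), n = size)
    }
  }
  if (is.null(sample_rate)) stop("no fmt chunk in ", path)
  list(waveform = pcm / 32767, sample_rate = sample_rate)
}
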