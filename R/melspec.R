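#' Spectrogram configuration
#'
#' Short-time analysis parameters for the Log-Mel front end. Defaults follow
#' the standard 8 kHz speech setup: 1024-sample frames (128 ms), 256-sample
#' hop (32 ms), 64 Mel bands spanning 0 Hz to Nyquist.
#'
#' @param n_fft Frame/FFT length in samples (even, >= 2).
#' @param hop Hop length in samples, `0 < hop <= n_fft`.
#' @param n_mels Number of triangular Mel filters.
#' @param sample_rate Sampling rate of the analyzed waveform, Hz.
#' @param f_min,f_max Frequency range of the filterbank in Hz;
#'   `f_max` defaults to Nyquist.
#' @param log_epsilon Additive floor inside the logarithm; sets the value of
#'   silent bins to `log(log_epsilon)`.
#' @return A `spectrogram_config` list.
#' @export
spectrogram_config <- function(n_fft = 1024L, hop = 256L, n_mels = 64L,
                               sample_rate = 8000, f_min = 0,
                               f_max = sample_rate / 2,
                               log_epsilon = 1e-9) {
  stopifnot(n_fft >= 2, n_fft %% 2 == 0, hop > 0, hop <= n_fft,
            n_mels >= 1, f_min >= 0, f_min < f_max,
            f_max <= sample_rate / 2 + 1e-9, log_epsilon > 0)
  structure(list(
    n_fft = as.integer(n_fft), hop = as.integer(hop),
    n_mels = as.integer(n_mels), sample_rate = sample_rate,
    f_min = f_min, f_max = f_max, log_epsilon = log_epsilon
  ), class = "spectrogram_config")
}

#' Periodic Hann window
#'
#' `w[n] = 0.5 * (1 - cos(2*pi*n / n_fft))` for `n = 0, ..., n_fft - 1`.
#' The periodic variant is the standard analysis window for the STFT; its
#' sum over a full period is exactly `n_fft / 2`.
#'
#' @param n_fft Window length, at least 2.
#' @return Numeric vector of length `n_fft`.
#' @export
hann_window <- function(n_fft) {
  if (n_fft < 2) stop("n_fft must be at least 2", call. = FALSE)
  n <- seq_len(n_fft) - 1
  0.5 * (1 - cos(2 * pi * n / n_fft))
}

#' Slice a waveform into windowed analysis frames
#'
#' Frame `m` (0-based) covers samples `m*hop .. m*hop + n_fft - 1` and is
#' multiplied elementwise by the Hann window. Only frames lying wholly inside
#' the signal are taken (no centering, no partial frames), so
#' `T = floor((n - n_fft) / hop) + 1`.
#'
#' @param x A mono [waveform()] or numeric vector with at least `n_fft`
#'   samples.
#' @param config A [spectrogram_config()].
#' @return A `T x n_fft` matrix of windowed frames.
#' @export
frame_signal <- function(x, config = spectrogram_config()) {
  if (inherits(x, "waveform")) x <- x$samples
  n <- length(x)
  if (n < config$n_fft) {
    stop(sprintf("signal (%d samples) shorter than one frame (%d)",
                 n, config$n_fft), call. = FALSE)
  }
  n_frames <- (n - config$n_fft) %/% config$hop + 1L
  starts <- (seq_len(n_frames) - 1L) * config$hop
  idx <- outer(starts, seq_len(config$n_fft), `+`)  # T x n_fft sample indices
  frames <- matrix(x[idx], nrow = n_frames)
  sweep(frames, 2L, hann_window(config$n_fft), `*`)
}

#' One-sided power spectrum of each frame
#'
#' Squared modulus of the DFT of each row, retaining the non-negative
#' frequencies `k = 0 .. n_fft/2` (513 bins for `n_fft = 1024`).
#'
#' @param frames A `T x n_fft` matrix (rows are frames), `n_fft` even.
#' @return A `T x (n_fft/2 + 1)` non-negative matrix.
#' @export
power_spectrum <- function(frames) {
  if (!is.matrix(frames)) frames <- matrix(frames, nrow = 1)
  n_fft <- ncol(frames)
  if (n_fft %% 2 != 0) stop("frame length must be even", call. = FALSE)
  spec <- stats::mvfft(t(frames))            # n_fft x T, DFT down each column
  p <- Mod(spec[seq_len(n_fft / 2 + 1), , drop = FALSE])^2
  t(p)
}

#' Mel frequency scale (HTK convention)
#'
#' `mel(f) = 2595 * log10(1 + f/700)`; strictly increasing, with exact
#' inverse [mel_to_hz()].
#'
#' @param f Frequency in Hz, non-negative.
#' @return Mel value(s).
#' @export
hz_to_mel <- function(f) {
  if (any(f < 0)) stop("frequency must be non-negative", call. = FALSE)
  2595 * log10(1 + f / 700)
}

#' @rdname hz_to_mel
#' @param m Mel value(s), non-negative.
#' @export
mel_to_hz <- function(m) {
  if (any(m < 0)) stop("mel value must be non-negative", call. = FALSE)
  700 * (10^(m / 2595) - 1)
}

#' Triangular Mel filterbank
#'
#' `n_mels` triangular filters with apexes at Mel-equally-spaced center
#' frequencies between `f_min` and `f_max` (`n_mels + 2` boundary points).
#' Each filter peaks at 1 at its center and falls linearly to 0 at its
#' neighbors' centers; weights are evaluated at the FFT bin frequencies
#' `k * sample_rate / n_fft`. No area normalization is applied.
#'
#' @param config A [spectrogram_config()].
#' @return An `n_mels x (n_fft/2 + 1)` weight matrix with entries in `[0, 1]`.
#' @export
mel_filterbank <- function(config = spectrogram_config()) {
  n_bins <- config$n_fft / 2 + 1
  mel_pts <- seq(hz_to_mel(config$f_min), hz_to_mel(config$f_max),
                 length.out = config$n_mels + 2)
  hz_pts <- mel_to_hz(mel_pts)
  bin_freq <- (seq_len(n_bins) - 1) * config$sample_rate / config$n_fft

  fb <- matrix(0, nrow = config$n_mels, ncol = n_bins)
  for (j in seq_len(config$n_mels)) {
    lo <- hz_pts[j]; ctr <- hz_pts[j + 1]; hi <- hz_pts[j + 2]
    up <- (bin_freq - lo) / (ctr - lo)
    down <- (hi - bin_freq) / (hi - ctr)
    fb[j, ] <- pmax(0, pmin(up, down))
  }
  if (any(rowSums(fb) == 0)) {
    stop("filterbank has an empty filter: n_mels too large for the FFT ",
         "resolution", call. = FALSE)
  }
  fb
}

#' Log-Mel spectrogram
#'
#' Frames the waveform, takes the one-sided power spectrum of each frame,
#' projects it through the triangular Mel filterbank, and log-compresses:
#' `L[m, j] = log(S[m, j] + log_epsilon)` (natural log). For the default
#' 24,000-sample input this yields a 90 x 64 matrix.
#'
#' @param x A preprocessed mono [waveform()] (or numeric vector at
#'   `config$sample_rate`).
#' @param config A [spectrogram_config()].
#' @return An object of class `logmel`: list with `values` (`T x n_mels`
#'   matrix), `frame_rate` (frames per second) and `config`.
#' @export
logmel <- function(x, config = spectrogram_config()) {
  if (inherits(x, "waveform") &&
      !isTRUE(all.equal(x$sample_rate, config$sample_rate))) {
    stop(sprintf("waveform rate %g does not match spectrogram config rate %g",
                 x$sample_rate, config$sample_rate), call. = FALSE)
  }
  frames <- frame_signal(x, config)
  p <- power_spectrum(frames)
  s <- p %*% t(mel_filterbank(config))
  structure(list(
    values = log(s + config$log_epsilon),
    frame_rate = config$sample_rate / config$hop,
    config = config
  ), class = "logmel")
}

#' @export
print.logmel <- function(x, ...) {
  cat(sprintf("<logmel: %d frames x %d mel bands, %.1f frames/s>\n",
              nrow(x$values), ncol(x$values), x$frame_rate))
  invisible(x)
}

#' Reference Log-Mel pipeline by direct DFT summation
#'
#' Evaluates the same framing/window/DFT/filterbank/log chain as [logmel()]
#' but computes each DFT coefficient as an explicit O(n^2) sum. Intended as
#' an independent numerical check of the fast FFT path, not for production
#' use.
#'
#' @inheritParams logmel
#' @return A `T x n_mels` matrix.
#' @export
logmel_reference <- function(x, config = spectrogram_config()) {
  frames <- frame_signal(x, config)
  n_fft <- config$n_fft
  k <- 0:(n_fft / 2)
  n <- 0:(n_fft - 1)
  ang <- -2 * pi * outer(n, k) / n_fft      # n_fft x (n_fft/2+1)
  re <- frames %*% cos(ang)
  im <- frames %*% sin(ang)
  p <- re^2 + im^2
  s <- p %*% t(mel_filterbank(config))
  log(s + config$log_epsilon)
}
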