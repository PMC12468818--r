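#' Waveform container
#'
#' A waveform is a numeric sample vector (nominal amplitude range `[-1, 1]`)
#' together with its sampling rate in Hz. Multichannel audio is represented as
#' a `channels x n` matrix until collapsed by [to_mono()].
#'
#' @param samples Numeric vector (mono) or matrix with one channel per row.
#' @param sample_rate Sampling rate in Hz, positive.
#' @return An object of class `waveform` with fields `samples` and
#'   `sample_rate`.
#' @export
waveform <- function(samples, sample_rate) {
  if (!is.numeric(samples)) stop("samples must be numeric", call. = FALSE)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 ||
      sample_rate <= 0) {
    stop("sample_rate must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(samples))) {
    stop("waveform samples must be finite", call. = FALSE)
  }
  structure(list(samples = samples, sample_rate = as.numeric(sample_rate)),
            class = "waveform")
}

#' @rdname waveform
#' @param x Object to coerce.
#' @export
as_waveform <- function(x) {
  if (inherits(x, "waveform")) return(x)
  stop("not a waveform", call. = FALSE)
}

#' @export
print.waveform <- function(x, ...) {
  n <- if (is.matrix(x$samples)) ncol(x$samples) else length(x$samples)
  ch <- if (is.matrix(x$samples)) nrow(x$samples) else 1L
  cat(sprintf("<waveform: %d samples, %d channel(s), %g Hz, %.3f s>\n",
              n, ch, x$sample_rate, n / x$sample_rate))
  invisible(x)
}

#' Preprocessing configuration
#'
#' Defines the standard form every clip is reduced to before feature
#' extraction: a fixed sampling rate and a fixed duration, hence a fixed
#' number of samples `target_length = round(target_rate * target_duration)`.
#' Defaults give 3 s at 8 kHz, i.e. 24,000 samples.
#'
#' @param target_rate Target sampling rate in Hz.
#' @param target_duration Target clip duration in seconds.
#' @return A `preproc_config` list with `target_rate`, `target_duration`,
#'   `target_length`.
#' @export
preproc_config <- function(target_rate = 8000, target_duration = 3.0) {
  stopifnot(target_rate > 0, target_duration > 0)
  structure(list(
    target_rate = target_rate,
    target_duration = target_duration,
    target_length = as.integer(round(target_rate * target_duration))
  ), class = "preproc_config")
}

#' Collapse multichannel audio to mono
#'
#' Channels are averaged samplewise. Mono input is returned unchanged.
#'
#' @param w A [waveform()]; multichannel audio has one channel per matrix row.
#' @return A mono [waveform()].
#' @export
to_mono <- function(w) {
  w <- as_waveform(w)
  if (!is.matrix(w$samples)) return(w)
  if (nrow(w$samples) == 0) stop("waveform has zero channels", call. = FALSE)
  waveform(colMeans(w$samples), w$sample_rate)
}

#' Band-limited resampling
#'
#' Resamples a mono waveform to `target_rate` using polyphase filtering
#' (`signal::resample`), which low-pass filters before rate conversion so
#' content below the new Nyquist frequency is preserved without aliasing.
#' The output length is `round(n * target_rate / sample_rate)` within one
#' sample.
#'
#' @param w A mono [waveform()].
#' @param target_rate Target sampling rate in Hz.
#' @return A [waveform()] at `target_rate`.
#' @export
resample_wave <- function(w, target_rate) {
  w <- as_waveform(w)
  if (is.matrix(w$samples)) stop("resample_wave() expects mono audio",
                                 call. = FALSE)
  if (!is.numeric(target_rate) || length(target_rate) != 1 ||
      target_rate <= 0) {
    stop("target_rate must be a single positive number", call. = FALSE)
  }
  if (isTRUE(all.equal(w$sample_rate, target_rate))) {
    return(waveform(w$samples, target_rate))
  }
  # reduce rate ratio to smallest integers (rates are integral Hz in practice)
  p <- round(target_rate)
  q <- round(w$sample_rate)
  g <- .gcd(p, q)
  y <- signal::resample(w$samples, p = p / g, q = q / g)
  n_expect <- round(length(w$samples) * target_rate / w$sample_rate)
  if (abs(length(y) - n_expect) > 1) {
    # trim/pad the filter transient so the length contract holds
    y <- y[seq_len(min(length(y), n_expect))]
    if (length(y) < n_expect) y <- c(y, numeric(n_expect - length(y)))
  }
  waveform(as.numeric(y), target_rate)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Pad or truncate to the configured length
#'
#' Shorter clips are right-padded with zeros; longer clips keep their first
#' `target_length` samples. The input must already be at the target rate.
#'
#' @param w A mono [waveform()] at `config$target_rate`.
#' @param config A [preproc_config()].
#' @return A [waveform()] with exactly `config$target_length` samples.
#' @export
fix_length <- function(w, config = preproc_config()) {
  w <- as_waveform(w)
  if (is.matrix(w$samples)) stop("fix_length() expects mono audio",
                                 call. = FALSE)
  if (!isTRUE(all.equal(w$sample_rate, config$target_rate))) {
    stop(sprintf("sample rate %g does not match target rate %g; resample first",
                 w$sample_rate, config$target_rate), call. = FALSE)
  }
  n <- length(w$samples)
  N <- config$target_length
  x <- if (n >= N) w$samples[seq_len(N)] else c(w$samples, numeric(N - n))
  waveform(x, config$target_rate)
}

#' Standardize a clip to fixed rate and length
#'
#' The composition mono-mixdown, band-limited resampling, and zero-pad/
#' truncate. Under the defaults every clip becomes 24,000 samples at 8 kHz.
#' The operation is idempotent: a clip already in standard form passes
#' through unchanged (up to resampler numerical tolerance when rates match,
#' in which case it is exactly unchanged).
#'
#' @param w A [waveform()] (mono or multichannel).
#' @param config A [preproc_config()].
#' @return A mono [waveform()] of `config$target_length` samples at
#'   `config$target_rate`.
#' @export
preprocess <- function(w, config = preproc_config()) {
  fix_length(resample_wave(to_mono(w), config$target_rate), config)
}
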