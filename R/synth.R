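#' Synthetic vocalization corpus configuration
#'
#' Parameters of the harmonic voice simulator used to generate labelled
#' corpora with the statistical shape of a cold-pressor pain-speech study:
#' many speakers, a few seconds of voiced audio per clip, and four-way
#' aligned labels (pain/non-pain, intensity, thermal condition). Pain raises
#' the fundamental frequency (F0), the acoustic energy, and the
#' cycle-to-cycle F0 jitter, with effect sizes growing with intensity; the
#' thermal condition is marked by the amplitude-modulation rate. All effect
#' sizes are configurable so separation between classes can be widened,
#' shrunk, or removed entirely.
#'
#' @param n_speakers Number of simulated speakers.
#' @param clips_per_speaker Clips generated per speaker.
#' @param sample_rate Output sampling rate in Hz.
#' @param duration_mean,duration_sd Clip duration distribution in seconds
#'   (normal, truncated to `[0.5, 6]`).
#' @param base_f0_range Speaker base F0 interval in Hz.
#' @param intensity_f0_gain Relative F0 increase per intensity level; must be
#'   strictly increasing from `none` to `severe`.
#' @param intensity_energy_gain_db Energy gain in dB per intensity level.
#' @param jitter_pct Cycle-to-cycle relative F0 perturbation (percent of F0)
#'   per intensity level.
#' @param thermal_am_rate Amplitude-modulation rate in Hz for the `cold` and
#'   `warm` conditions.
#' @param noise_snr_db Signal-to-noise ratio of added white noise in dB;
#'   `Inf` disables noise.
#' @param pain_fraction Fraction of each speaker's clips labelled pain.
#' @param intensity_mix Categorical distribution of `mild`/`moderate`/
#'   `severe` among pain clips.
#' @param seed Integer seed; identical configs produce bit-identical corpora.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_speakers = 51L, clips_per_speaker = 138L,
                         sample_rate = 8000, duration_mean = 2.6,
                         duration_sd = 0.6,
                         base_f0_range = c(110, 220),
                         intensity_f0_gain = c(none = 0.00, mild = 0.10,
                                               moderate = 0.20, severe = 0.35),
                         intensity_energy_gain_db = c(none = 0, mild = 2,
                                                      moderate = 4, severe = 7),
                         jitter_pct = c(none = 0.3, mild = 0.8,
                                        moderate = 1.3, severe = 2.0),
                         thermal_am_rate = c(cold = 6.0, warm = 3.0),
                         noise_snr_db = 25,
                         pain_fraction = 0.5,
                         intensity_mix = c(mild = 0.6, moderate = 0.25,
                                           severe = 0.15),
                         seed = 0L) {
  stopifnot(n_speakers >= 1, clips_per_speaker >= 1, sample_rate > 0,
            duration_mean > 0, duration_sd >= 0,
            length(base_f0_range) == 2, base_f0_range[1] > 0,
            base_f0_range[1] <= base_f0_range[2],
            all(names(intensity_f0_gain) == c("none", "mild", "moderate",
                                              "severe")),
            all(diff(intensity_f0_gain) > 0) || all(intensity_f0_gain == 0),
            all(thermal_am_rate > 0),
            pain_fraction >= 0, pain_fraction <= 1,
            abs(sum(intensity_mix) - 1) < 1e-9)
  structure(list(
    n_speakers = as.integer(n_speakers),
    clips_per_speaker = as.integer(clips_per_speaker),
    sample_rate = sample_rate,
    duration_mean = duration_mean, duration_sd = duration_sd,
    base_f0_range = base_f0_range,
    intensity_f0_gain = intensity_f0_gain,
    intensity_energy_gain_db = intensity_energy_gain_db,
    jitter_pct = jitter_pct,
    thermal_am_rate = thermal_am_rate,
    noise_snr_db = noise_snr_db,
    pain_fraction = pain_fraction,
    intensity_mix = intensity_mix,
    seed = as.integer(seed)
  ), class = "synth_config")
}

.intensity_levels <- c("none", "mild", "moderate", "severe")
.thermal_levels <- c("cold", "warm")

#' Draw speaker profiles
#'
#' Each speaker gets a base F0 drawn uniformly from `base_f0_range`, a
#' spectral tilt (harmonic roll-off, dB per octave), and an amplitude scale,
#' all from the config seed.
#'
#' @param config A [synth_config()].
#' @return Data frame with columns `speaker_id`, `base_f0`,
#'   `spectral_tilt_db_per_octave`, `amplitude_scale`.
#' @export
make_speakers <- function(config = synth_config()) {
  if (config$n_speakers < 1) stop("n_speakers must be >= 1", call. = FALSE)
  with_seed(config$seed, {
    data.frame(
      speaker_id = sprintf("spk%03d", seq_len(config$n_speakers)),
      base_f0 = stats::runif(config$n_speakers, config$base_f0_range[1],
                             config$base_f0_range[2]),
      spectral_tilt_db_per_octave = stats::runif(config$n_speakers, -14, -8),
      amplitude_scale = stats::runif(config$n_speakers, 0.7, 1.0),
      stringsAsFactors = FALSE
    )
  })
}

#' Synthesize one vocalization clip
#'
#' A harmonic source at `base_f0 * (1 + f0_gain[intensity])` with ten
#' harmonics rolled off by the speaker's spectral tilt, cycle-level F0
#' jitter, amplitude modulation at the thermal condition's rate (depth 0.4),
#' an intensity-dependent energy gain, and additive white noise at the
#' configured SNR.
#'
#' @param profile One row of [make_speakers()] output (list or data frame
#'   row with `base_f0`, `spectral_tilt_db_per_octave`, `amplitude_scale`).
#' @param intensity One of `"none"`, `"mild"`, `"moderate"`, `"severe"`.
#' @param thermal One of `"cold"`, `"warm"`.
#' @param duration Clip duration in seconds, positive.
#' @param config A [synth_config()].
#' @param seed Integer seed; identical arguments give identical samples.
#' @return A mono [waveform()] of `round(duration * sample_rate)` samples.
#' @export
synth_clip <- function(profile, intensity, thermal, duration,
                       config = synth_config(), seed = 0L) {
  if (!intensity %in% .intensity_levels) {
    stop("unknown intensity level: ", intensity, call. = FALSE)
  }
  if (!thermal %in% .thermal_levels) {
    stop("unknown thermal level: ", thermal, call. = FALSE)
  }
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  fs <- config$sample_rate
  n <- round(duration * fs)
  f0 <- profile$base_f0 * (1 + config$intensity_f0_gain[[intensity]])
  jit <- config$jitter_pct[[intensity]] / 100
  tilt <- profile$spectral_tilt_db_per_octave

  with_seed(seed, {
    # per-cycle F0 with multiplicative jitter, expanded to sample level
    n_cycles <- ceiling(duration * f0 * 1.5) + 2
    jit_eps <- if (jit > 0) stats::rnorm(n_cycles, 0, jit) else numeric(n_cycles)
    cyc_f0 <- f0 * (1 + jit_eps)
    cyc_f0 <- pmax(cyc_f0, f0 * 0.5)
    cyc_len <- pmax(1L, round(fs / cyc_f0))
    f0_inst <- rep(cyc_f0, times = cyc_len)[seq_len(n)]
    phase <- 2 * pi * cumsum(f0_inst) / fs

    n_harm <- 10L
    sig <- numeric(n)
    for (k in seq_len(n_harm)) {
      amp <- 10^(tilt * log2(k) / 20)
      sig <- sig + amp * sin(k * phase)
    }

    tt <- (seq_len(n) - 1) / fs
    am <- 1 + 0.4 * sin(2 * pi * config$thermal_am_rate[[thermal]] * tt)
    sig <- sig * am

    gain <- 10^(config$intensity_energy_gain_db[[intensity]] / 20)
    sig <- sig * gain * profile$amplitude_scale

    if (is.finite(config$noise_snr_db)) {
      sig_rms <- sqrt(mean(sig^2))
      noise_rms <- sig_rms * 10^(-config$noise_snr_db / 20)
      sig <- sig + stats::rnorm(n, 0, noise_rms)
    }
    waveform(sig, fs)
  })
}

#' Plan a corpus: labels and durations without audio
#'
#' Assigns the full label structure deterministically from the config seed:
#' per speaker, `round(clips_per_speaker * pain_fraction)` clips are pain
#' (so corpus-level class proportions match `pain_fraction` to within one
#' clip per speaker); intensities of pain clips are drawn from
#' `intensity_mix`; thermal labels are drawn 50/50 independently of pain;
#' durations come from the truncated normal duration model. No audio is
#' rendered.
#'
#' @param config A [synth_config()].
#' @return Data frame of clip records: `clip_id`, `speaker_id`, `pain`
#'   (`"non-pain"`/`"pain"`), `intensity`, `thermal`, `duration`, `seed`
#'   (per-clip synthesis seed).
#' @export
corpus_plan <- function(config = synth_config()) {
  speakers <- make_speakers(config)
  with_seed(config$seed + 1L, {
    rows <- lapply(seq_len(config$n_speakers), function(s) {
      m <- config$clips_per_speaker
      n_pain <- round(m * config$pain_fraction)
      pain <- sample(c(rep("pain", n_pain), rep("non-pain", m - n_pain)))
      intensity <- ifelse(pain == "pain",
                          sample(names(config$intensity_mix), m, replace = TRUE,
                                 prob = config$intensity_mix),
                          "none")
      thermal <- sample(.thermal_levels, m, replace = TRUE)
      duration <- pmin(6, pmax(0.5, stats::rnorm(m, config$duration_mean,
                                                 config$duration_sd)))
      data.frame(
        clip_id = sprintf("%s_clip%04d", speakers$speaker_id[s], seq_len(m)),
        speaker_id = speakers$speaker_id[s],
        pain = pain, intensity = intensity, thermal = thermal,
        duration = duration,
        stringsAsFactors = FALSE
      )
    })
    plan <- do.call(rbind, rows)
    # independent per-clip synthesis seeds, kept within 32-bit integer range
    plan$seed <- (config$seed * 7919L + seq_len(nrow(plan)) * 104729L) %%
      2147483647L
    plan
  })
}

#' Generate a synthetic labelled corpus on disk
#'
#' Renders every clip of [corpus_plan()] to a 16-bit PCM mono WAV
#' (peak-normalized to 0.9 full scale before quantization) and writes a
#' metadata CSV with columns
#' `clip_id,speaker_id,pain,intensity,thermal,duration,path`.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if missing).
#' @return The corpus table (data frame), invisibly also written to
#'   `<out_dir>/metadata.csv`.
#' @export
synth_corpus <- function(config = synth_config(), out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  speakers <- make_speakers(config)
  plan <- corpus_plan(config)
  plan$path <- file.path(out_dir, paste0(plan$clip_id, ".wav"))
  for (i in seq_len(nrow(plan))) {
    prof <- speakers[speakers$speaker_id == plan$speaker_id[i], ]
    w <- synth_clip(prof, plan$intensity[i], plan$thermal[i],
                    plan$duration[i], config, seed = plan$seed[i])
    write_wav(.normalize_for_pcm(w), plan$path[i])
  }
  meta <- plan[, c("clip_id", "speaker_id", "pain", "intensity", "thermal",
                   "duration", "path")]
  utils::write.csv(meta, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE)
  meta
}

# Scale for 16-bit quantization. A single corpus-wide constant (chosen so
# the loudest possible clip -- severe gain, shallow tilt, AM crest -- peaks
# near 0.9 full scale) is used instead of per-clip peak normalization, so
# the between-clip energy differences that carry the intensity label are
# preserved in the written audio. Clips that would still clip are scaled
# down individually as a safety net.
.normalize_for_pcm <- function(w, fixed_scale = 0.12) {
  w$samples <- w$samples * fixed_scale
  peak <- max(abs(w$samples))
  if (peak > 0.999) w$samples <- w$samples * (0.999 / peak)
  w
}

#' Estimate the fundamental frequency of a clip
#'
#' Autocorrelation-based F0 estimate over a plausible voice range, used to
#' validate that generated corpora have the intended class separation.
#'
#' @param w A mono [waveform()].
#' @param f_min,f_max Search range in Hz.
#' @return Estimated F0 in Hz.
#' @export
estimate_f0 <- function(w, f_min = 80, f_max = 400) {
  x <- w$samples - mean(w$samples)
  fs <- w$sample_rate
  lag_min <- max(2L, floor(fs / f_max))
  lag_max <- min(length(x) - 1L, ceiling(fs / f_min))
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  lags <- lag_min:lag_max
  fs / lags[which.max(ac[lags + 1])]
}

#' Root-mean-square amplitude
#'
#' @param w A mono [waveform()] or numeric vector.
#' @return RMS value.
#' @export
rms <- function(w) {
  x <- if (inherits(w, "waveform")) w$samples else w
  sqrt(mean(x^2))
}
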