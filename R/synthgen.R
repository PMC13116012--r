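# Synthetic trial-structured intracranial dataset generator.
#
# Signal model per trial and channel:
#   x(t) = pink noise + line-noise sinusoids (60/120/180 Hz)
#          + carrier_amp * g(t) * carrier(t)
# where carrier(t) is a unit-envelope frequency-modulated tone confined to
# the high-gamma band, and g(t) is the per-trial envelope gain:
#   g = base + area-level trial noise + channel-level trial noise
#       + planted category effects (inside their region x time window)
#       + planted cross-region coupling contributions.
# Category effects therefore modulate the multiplicative gain of the
# band-limited carrier only, so they are invisible outside 70-170 Hz.

#' Cortical region table
#'
#' Electrode counts per region, hemisphere and Brodmann area for the cohort
#' the generator emulates (subdural grids/strips over frontal, temporal and
#' parietal cortex in 19 subjects; depth and high-impedance contacts already
#' excluded).
#'
#' @return A data.frame with columns `region`, `hemisphere`, `brodmann_area`
#'   (character label; compound parcels keep their first area as label) and
#'   `n_electrodes`.
#' @export
ba_table <- function() {
  data.frame(
    region = rep(c("Anterior prefrontal", "dlPFC", "Pars opercularis",
                   "Pars triangularis", "Pars orbitalis", "Premotor/SMA",
                   "Primary motor", "Primary somatosensory", "SMG",
                   "Angular gyrus", "STG", "MTG", "Fusiform", "Other"),
                 each = 2),
    hemisphere = rep(c("L", "R"), 14),
    brodmann_area = rep(c("10", "9", "44", "45", "47", "6", "4", "1", "40",
                          "39", "22", "21", "37", "other"), each = 2),
    n_electrodes = c(91, 27, 53, 43, 17, 20, 47, 16, 28, 9, 21, 39, 14, 20,
                     18, 45, 11, 52, 14, 7, 54, 56, 88, 49, 23, 19, 91, 90),
    stringsAsFactors = FALSE
  )
}

#' Planted category effect (ground truth for recovery tests)
#'
#' Describes a standardized body-minus-nonbody envelope-gain difference
#' localized to one region and one time window inside the 0-500 ms
#' prespeech span.
#'
#' @param brodmann_area Region label (character or integer).
#' @param hemisphere `"L"` or `"R"`.
#' @param window_ms Length-2 numeric, window start/end in ms after word
#'   onset; must lie inside \[0, 500\].
#' @param effect_size_d Standardized mean difference (Cohen's d) of the
#'   window-mean envelope gain, body minus nonbody.
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(brodmann_area, hemisphere, window_ms, effect_size_d) {
  stopifnot(length(window_ms) == 2, is.finite(effect_size_d))
  if (window_ms[1] < 0 || window_ms[2] > 500 || window_ms[1] >= window_ms[2])
    stop_config("effect window must lie inside [0, 500] ms")
  structure(list(brodmann_area = as.character(brodmann_area),
                 hemisphere = hemisphere, window_ms = as.numeric(window_ms),
                 effect_size_d = effect_size_d),
            class = "planted_effect")
}

#' Planted cross-region coupling (ground truth for recovery tests)
#'
#' A shared per-trial latent z ~ N(0,1) loads on the source area's envelope
#' gain inside the source window and on the target area's gain inside the
#' target window, with symmetric weights chosen from the variance budget so
#' the expected simple-regression R^2 between the two window-mean gains
#' equals `target_r2`.
#'
#' @param source_area,target_area Region labels.
#' @param source_hemisphere,target_hemisphere `"L"` or `"R"`.
#' @param source_window,target_window Window index 1..10 on the 100 ms /
#'   50 ms step grid.
#' @param target_r2 Desired coupling strength in \[0, 1).
#' @return An object of class `planted_coupling`.
#' @export
planted_coupling <- function(source_area, source_hemisphere, source_window,
                             target_area, target_hemisphere, target_window,
                             target_r2) {
  if (!source_window %in% 1:10 || !target_window %in% 1:10)
    stop_config("window indices must lie on the 10-window grid")
  if (target_r2 < 0 || target_r2 >= 1)
    stop_config("target_r2 must lie in [0, 1)")
  structure(list(source_area = as.character(source_area),
                 source_hemisphere = source_hemisphere,
                 source_window = as.integer(source_window),
                 target_area = as.character(target_area),
                 target_hemisphere = target_hemisphere,
                 target_window = as.integer(target_window),
                 target_r2 = target_r2),
            class = "planted_coupling")
}

#' Synthetic dataset configuration
#'
#' Defaults emulate the recording conditions of the word-reading cohort:
#' 19 subjects, 34 single-presentation trials each (balanced 17/17 body vs.
#' nonbody by default), epochs spanning -1000..+3000 ms around word onset,
#' 1/f background with line noise at 60/120/180 Hz, high-gamma (70-170 Hz)
#' carrier whose envelope gain carries the planted structure, speech onsets
#' drawn from N(881, 228) ms truncated below at 500 ms, and occasional
#' interictal-spike artifacts.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials Trials (words) per subject; every subject shares the same
#'   word list and category assignment.
#' @param n_body Number of body-category words (the remainder are nonbody).
#' @param areas data.frame with columns `brodmann_area`, `hemisphere`
#'   describing the simulated regions.
#' @param channels_per_area Electrodes per region per subject.
#' @param sample_rate Sampling rate in Hz; must exceed twice the upper band
#'   edge. The default 1000 Hz is Nyquist-safe for 170 Hz; 2000 Hz matches
#'   the clinical amplifier and is available here.
#' @param epoch_ms Length-2 epoch span in ms relative to word onset.
#' @param pink_exponent Spectral slope of the 1/f background.
#' @param pink_sd Standard deviation of the background noise.
#' @param line_noise_freqs,line_noise_amp Line-noise frequencies (Hz) and
#'   per-frequency sinusoid amplitudes.
#' @param hg_band Length-2 high-gamma band (Hz) for the carrier.
#' @param carrier_amp Carrier amplitude per unit gain.
#' @param base_gain Baseline envelope gain.
#' @param envelope_gain_sd SD of the area-level per-trial gain fluctuation
#'   (shared by channels within a region).
#' @param channel_gain_sd SD of the additional channel-level gain jitter.
#' @param effects List of [planted_effect()] objects.
#' @param couplings List of [planted_coupling()] objects.
#' @param ied_rate Per-trial probability of an interictal-spike artifact.
#' @param ied_amp_factor Artifact peak amplitude as a multiple of the
#'   channel background level.
#' @param onset_mean_ms,onset_sd_ms,onset_min_ms Speech-onset distribution
#'   parameters (normal, truncated below).
#' @param impedance_bad_rate Fraction of channels given a high impedance so
#'   the exclusion stage has work to do.
#' @param seed Integer seed; a fixed seed makes [generate_dataset()] output
#'   byte-identical.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 19,
                         n_trials = 34,
                         n_body = 17,
                         areas = data.frame(
                           brodmann_area = c("9", "20", "40", "37"),
                           hemisphere = "L",
                           stringsAsFactors = FALSE),
                         channels_per_area = 10,
                         sample_rate = 1000,
                         epoch_ms = c(-1000, 3000),
                         pink_exponent = 1,
                         pink_sd = 1,
                         line_noise_freqs = c(60, 120, 180),
                         line_noise_amp = c(1, 0.5, 0.25),
                         hg_band = c(70, 170),
                         carrier_amp = 2,
                         base_gain = 1,
                         envelope_gain_sd = 0.25,
                         channel_gain_sd = 0.1,
                         effects = list(),
                         couplings = list(),
                         ied_rate = 0.05,
                         ied_amp_factor = 3,
                         onset_mean_ms = 881,
                         onset_sd_ms = 228,
                         onset_min_ms = 500,
                         impedance_bad_rate = 0.05,
                         seed = 1) {
  if (n_subjects < 1 || channels_per_area < 1 || n_trials < 1)
    stop_config("all counts must be >= 1")
  if (n_body < 1 || n_body >= n_trials)
    stop_config("n_body must leave at least one trial in each category")
  if (hg_band[1] >= hg_band[2])
    stop_config("invalid band: low edge (%g) must be below high edge (%g)",
                hg_band[1], hg_band[2])
  if (sample_rate <= 2 * hg_band[2])
    stop_config("sample_rate (%g) must exceed twice the upper band edge (%g)",
                sample_rate, hg_band[2])
  if (epoch_ms[1] >= epoch_ms[2]) stop_config("invalid epoch span")
  if (inherits(effects, "planted_effect")) effects <- list(effects)
  if (inherits(couplings, "planted_coupling")) couplings <- list(couplings)
  cfg <- list(n_subjects = n_subjects, n_trials = n_trials, n_body = n_body,
              areas = areas, channels_per_area = channels_per_area,
              sample_rate = sample_rate, epoch_ms = epoch_ms,
              pink_exponent = pink_exponent, pink_sd = pink_sd,
              line_noise_freqs = line_noise_freqs,
              line_noise_amp = line_noise_amp, hg_band = hg_band,
              carrier_amp = carrier_amp, base_gain = base_gain,
              envelope_gain_sd = envelope_gain_sd,
              channel_gain_sd = channel_gain_sd,
              effects = effects, couplings = couplings,
              ied_rate = ied_rate, ied_amp_factor = ied_amp_factor,
              onset_mean_ms = onset_mean_ms, onset_sd_ms = onset_sd_ms,
              onset_min_ms = onset_min_ms,
              impedance_bad_rate = impedance_bad_rate,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' Sample speech-onset times
#'
#' Draws from a normal distribution truncated below, reproducing the
#' behavioral onset statistics (mean 881 ms, SD 228 ms, earliest 500 ms)
#' via inverse-CDF sampling.
#'
#' @param n Number of onsets (>= 1).
#' @param mean_ms,sd_ms,min_ms Distribution parameters. `sd_ms = 0`
#'   degenerates to all onsets equal to `mean_ms`.
#' @param seed Optional seed; `NULL` uses the ambient RNG stream.
#' @return Numeric vector of onset times in ms.
#' @export
sample_speech_onsets <- function(n, mean_ms = 881, sd_ms = 228, min_ms = 500,
                                 seed = NULL) {
  if (length(n) != 1 || !is.finite(n) || n < 1)
    stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  if (sd_ms <= 0) return(rep(mean_ms, n))
  with_seed(seed, {
    lo <- pnorm((min_ms - mean_ms) / sd_ms)
    u <- runif(n, lo, 1)
    mean_ms + sd_ms * qnorm(u)
  })
}

# --- internal signal builders -----------------------------------------------

# 1/f^beta noise, one column per series, via spectral shaping of white noise.
gen_pink <- function(n_samples, n_series, sample_rate, exponent, sd_target) {
  f <- c(0, pmin(seq_len(n_samples - 1), n_samples - seq_len(n_samples - 1))) *
    sample_rate / n_samples
  h <- c(0, f[-1]^(-exponent / 2))
  h <- h / sqrt(mean(h^2))
  w <- matrix(rnorm(n_samples * n_series), n_samples, n_series)
  x <- Re(stats::mvfft(stats::mvfft(w) * h, inverse = TRUE)) / n_samples
  x * sd_target
}

# Unit-envelope FM carrier confined to the band: instantaneous frequency
# wanders smoothly inside (low+5, high-5); Hilbert envelope is 1 by
# construction, so the planted gain is the envelope.
gen_carrier <- function(n_samples, n_series, sample_rate, band) {
  fc <- mean(band)
  dev_max <- (band[2] - band[1]) / 2 - 5
  w <- matrix(rnorm(n_samples * n_series), n_samples, n_series)
  f <- c(0, pmin(seq_len(n_samples - 1), n_samples - seq_len(n_samples - 1))) *
    sample_rate / n_samples
  k <- exp(-(f / 4)^2)  # ~4 Hz smoothing: slow frequency wander
  sm <- Re(stats::mvfft(stats::mvfft(w) * k, inverse = TRUE)) / n_samples
  sm <- sm / sqrt(mean(k^2))          # restore unit variance
  f_inst <- fc + pmax(pmin(sm * dev_max / 2.5, dev_max), -dev_max)
  phase <- apply(f_inst, 2, cumsum) * (2 * pi / sample_rate)
  phase <- sweep(phase, 2, runif(n_series, 0, 2 * pi), `+`)
  cos(phase)
}

# Biphasic interictal-spike waveform on [0,1): flat-top main phase over the
# first 70% of the duration, opposite-polarity rebound over the rest.
# Peak absolute amplitude is 1.
transient_wave <- function(n_samples) {
  tukey <- function(n, r = 0.5) {
    if (n <= 1) return(rep(1, n))
    t <- seq(0, 1, length.out = n)
    w <- rep(1, n)
    edge <- t < r / 2
    w[edge] <- 0.5 * (1 + cos(pi * (2 * t[edge] / r - 1)))
    edge <- t > 1 - r / 2
    w[edge] <- 0.5 * (1 + cos(pi * (2 * (1 - t[edge]) / r - 1)))
    w
  }
  n1 <- max(1L, round(0.7 * n_samples))
  n2 <- n_samples - n1
  c(tukey(n1, 0.3), -0.3 * tukey(max(n2, 0)))
}

# Robust per-channel background level: 1.4826 x median absolute deviation of
# the channel's raw signal over the prestimulus baselines of all its trials.
channel_background <- function(signals, times, channel, baseline_ms = c(-300, 0)) {
  sel <- times >= baseline_ms[1] & times < baseline_ms[2]
  x <- as.vector(signals[, channel, sel])
  stats::mad(x, center = stats::median(x))
}

window_time_span <- function(w) c(50 * (w - 1), 50 * (w - 1) + 100)

#' Generate a synthetic trial-structured dataset
#'
#' Produces a word-aligned multichannel dataset: every subject shares the
#' same 34-word list and category assignment, so trial row `t` of the signal
#' array holds, for each channel, that channel's subject's presentation of
#' word `t`. See the package vignette for the full signal model.
#'
#' @param config A [synth_config()] object.
#' @return An object of class `raw_dataset`: list with `signals`
#'   (trials x channels x samples array), `sample_rate`, `epoch_ms`, `times`
#'   (ms, one per sample), `channels` (data.frame: channel_id, subject_id,
#'   hemisphere, brodmann_area, impedance_kohm, is_bad), `trials`
#'   (data.frame: trial_id, subject_id, word_id, category, speech_onset_ms,
#'   rejected) and `truth` (the planted effects/couplings).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  fs <- cfg$sample_rate
  S <- as.integer(round((cfg$epoch_ms[2] - cfg$epoch_ms[1]) / 1000 * fs))
  times <- cfg$epoch_ms[1] + (seq_len(S) - 1) * 1000 / fs
  n_areas <- nrow(cfg$areas)
  n_ch_sub <- n_areas * cfg$channels_per_area
  n_ch <- cfg$n_subjects * n_ch_sub
  Tn <- cfg$n_trials

  set.seed(cfg$seed)

  # channel metadata
  sub_ids <- sprintf("S%02d", seq_len(cfg$n_subjects))
  ch_area <- rep(rep(cfg$areas$brodmann_area, each = cfg$channels_per_area),
                 cfg$n_subjects)
  ch_hemi <- rep(rep(cfg$areas$hemisphere, each = cfg$channels_per_area),
                 cfg$n_subjects)
  ch_sub <- rep(sub_ids, each = n_ch_sub)
  channels <- data.frame(
    channel_id = sprintf("%s_BA%s%s_c%02d", ch_sub, ch_area, ch_hemi,
                         rep(seq_len(cfg$channels_per_area),
                             n_areas * cfg$n_subjects)),
    subject_id = ch_sub, hemisphere = ch_hemi, brodmann_area = ch_area,
    impedance_kohm = round(runif(n_ch, 1, 9), 2),
    is_bad = FALSE, stringsAsFactors = FALSE)
  hi <- runif(n_ch) < cfg$impedance_bad_rate
  channels$impedance_kohm[hi] <- round(runif(sum(hi), 10.5, 25), 2)

  # trial metadata: shared word list, per-subject onsets
  categories <- rep(c("body", "nonbody"),
                    c(cfg$n_body, Tn - cfg$n_body))
  trials <- data.frame(
    trial_id = sprintf("%s_w%02d", rep(sub_ids, each = Tn),
                       rep(seq_len(Tn), cfg$n_subjects)),
    subject_id = rep(sub_ids, each = Tn),
    word_id = rep(seq_len(Tn), cfg$n_subjects),
    category = rep(categories, cfg$n_subjects),
    speech_onset_ms = sample_speech_onsets(Tn * cfg$n_subjects,
                                           cfg$onset_mean_ms, cfg$onset_sd_ms,
                                           cfg$onset_min_ms),
    rejected = FALSE, stringsAsFactors = FALSE)

  # per-trial gain components
  gain_sd_tot <- sqrt(cfg$envelope_gain_sd^2 + cfg$channel_gain_sd^2)
  area_key <- paste0(cfg$areas$brodmann_area, "/", cfg$areas$hemisphere)
  # area-level noise: [trial-record, area]; channel jitter: [trial, channel]
  area_noise <- array(rnorm(cfg$n_subjects * Tn * n_areas,
                            sd = cfg$envelope_gain_sd),
                      dim = c(Tn, cfg$n_subjects, n_areas))
  ch_noise <- matrix(rnorm(Tn * n_ch, sd = cfg$channel_gain_sd), Tn, n_ch)
  cpl_z <- lapply(cfg$couplings, function(cp) rnorm(Tn))

  signals <- array(0, dim = c(Tn, n_ch, S))
  cat_sign <- ifelse(categories == "body", 0.5, -0.5)

  for (s in seq_len(cfg$n_subjects)) {
    n_tc <- Tn * n_ch_sub
    pink <- gen_pink(S, n_tc, fs, cfg$pink_exponent, cfg$pink_sd)
    carrier <- gen_carrier(S, n_tc, fs, cfg$hg_band)
    line <- matrix(0, S, n_tc)
    for (i in seq_along(cfg$line_noise_freqs)) {
      f0 <- cfg$line_noise_freqs[i]
      phi <- runif(n_tc, 0, 2 * pi)
      line <- line + cfg$line_noise_amp[i] *
        (sin(2 * pi * f0 * times / 1000) %o% cos(phi) +
         cos(2 * pi * f0 * times / 1000) %o% sin(phi))
    }
    # gain matrix [S, n_tc]; columns ordered channel-major (trials within
    # channel) to match the fill below
    ch_local <- rep(seq_len(n_ch_sub), each = Tn)
    tr_local <- rep(seq_len(Tn), n_ch_sub)
    ch_global <- (s - 1) * n_ch_sub + ch_local
    a_of_ch <- rep(seq_len(n_areas), each = cfg$channels_per_area)[ch_local]
    g_const <- cfg$base_gain +
      area_noise[cbind(tr_local, s, a_of_ch)] +
      ch_noise[cbind(tr_local, ch_global)]
    G <- matrix(rep(g_const, each = S), S, n_tc)
    for (ef in cfg$effects) {
      in_area <- cfg$areas$brodmann_area[a_of_ch] == ef$brodmann_area &
        cfg$areas$hemisphere[a_of_ch] == ef$hemisphere
      if (!any(in_area)) next
      t_in <- times >= ef$window_ms[1] & times < ef$window_ms[2]
      delta <- ef$effect_size_d * gain_sd_tot
      add <- delta * cat_sign[tr_local] * in_area
      G[t_in, ] <- G[t_in, , drop = FALSE] +
        matrix(rep(add, each = sum(t_in)), sum(t_in), n_tc)
    }
    for (ci in seq_along(cfg$couplings)) {
      cp <- cfg$couplings[[ci]]
      rho <- sqrt(cp$target_r2)
      # variance budget for the area-mean window gain: area-level noise plus
      # channel jitter averaged over the area's channels; symmetric weights
      # a = b give expected simple-regression R^2 = (a^2/(a^2+s^2))^2 = rho^2
      s_eff <- sqrt(cfg$envelope_gain_sd^2 +
                    cfg$channel_gain_sd^2 / cfg$channels_per_area)
      wt <- if (rho > 0) s_eff * sqrt(rho / (1 - rho)) else 0
      z <- cpl_z[[ci]]
      for (side in c("source", "target")) {
        aa <- cp[[paste0(side, "_area")]]
        hh <- cp[[paste0(side, "_hemisphere")]]
        wsp <- window_time_span(cp[[paste0(side, "_window")]])
        in_area <- cfg$areas$brodmann_area[a_of_ch] == aa &
          cfg$areas$hemisphere[a_of_ch] == hh
        if (!any(in_area)) next
        t_in <- times >= wsp[1] & times < wsp[2]
        add <- wt * z[tr_local] * in_area
        G[t_in, ] <- G[t_in, , drop = FALSE] +
          matrix(rep(add, each = sum(t_in)), sum(t_in), n_tc)
      }
    }
    G[G < 0] <- 0
    x <- pink + line + cfg$carrier_amp * G * carrier
    for (j in seq_len(n_ch_sub)) {
      cols <- (j - 1) * Tn + seq_len(Tn)
      signals[, (s - 1) * n_ch_sub + j, ] <- t(x[, cols])
    }
  }

  ds <- structure(list(signals = signals, sample_rate = fs,
                       epoch_ms = cfg$epoch_ms, times = times,
                       channels = channels, trials = trials,
                       truth = list(effects = cfg$effects,
                                    couplings = cfg$couplings),
                       config = cfg),
                  class = "raw_dataset")

  # occasional interictal-spike artifacts
  if (cfg$ied_rate > 0) {
    hit <- runif(nrow(trials)) < cfg$ied_rate
    for (i in which(hit)) {
      sub <- trials$subject_id[i]
      chs <- which(channels$subject_id == sub)
      ch <- chs[sample.int(length(chs), 1)]
      at <- runif(1, cfg$epoch_ms[1] + 300, cfg$epoch_ms[2] - 300)
      dur <- runif(1, 30, 150)
      ds <- inject_ied(ds, trials$trial_id[i], channels$channel_id[ch],
                       amplitude_factor = cfg$ied_amp_factor,
                       duration_ms = dur, at_ms = at)
    }
  }
  ds
}

#' Inject an interictal-spike artifact into one trial and channel
#'
#' Adds a biphasic transient whose peak absolute amplitude is
#' `amplitude_factor` times the channel's robust background level (1.4826 x
#' MAD of the raw signal over the prestimulus baselines of all that
#' channel's trials). The rest of the array is untouched.
#'
#' @param dataset A `raw_dataset`.
#' @param trial_id,channel_id Identifiers of the target trial and channel.
#' @param amplitude_factor Peak amplitude as a multiple of background.
#' @param duration_ms Transient duration (> 0).
#' @param at_ms Onset time of the transient (ms relative to word onset).
#' @return A modified copy of `dataset`.
#' @export
inject_ied <- function(dataset, trial_id, channel_id, amplitude_factor,
                       duration_ms, at_ms = 150) {
  stopifnot(inherits(dataset, "raw_dataset"))
  if (duration_ms <= 0) stop("duration_ms must be > 0", call. = FALSE)
  ti <- match(trial_id, dataset$trials$trial_id)
  ci <- match(channel_id, dataset$channels$channel_id)
  if (is.na(ti)) stop_config("unknown trial_id '%s'", trial_id)
  if (is.na(ci)) stop_config("unknown channel_id '%s'", channel_id)
  if (dataset$channels$subject_id[ci] != dataset$trials$subject_id[ti])
    stop_config("trial '%s' and channel '%s' belong to different subjects",
                trial_id, channel_id)
  if (amplitude_factor == 0) return(dataset)
  word <- dataset$trials$word_id[ti]
  bg <- channel_background(dataset$signals, dataset$times, ci)
  n <- max(2L, round(duration_ms / 1000 * dataset$sample_rate))
  i0 <- which.min(abs(dataset$times - at_ms))
  idx <- i0 + seq_len(n) - 1L
  idx <- idx[idx <= length(dataset$times)]
  wv <- transient_wave(n)[seq_along(idx)]
  dataset$signals[word, ci, idx] <- dataset$signals[word, ci, idx] +
    amplitude_factor * bg * wv
  dataset
}
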