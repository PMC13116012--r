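# Preprocessing: common average reference, notch filtering, channel
# exclusion, interictal-discharge trial rejection, high-gamma envelope
# extraction and prestimulus baseline normalization.
#
# All filtering is zero-phase: filters are designed as Butterworth IIR
# prototypes (signal::butter) and applied in the frequency domain with the
# squared magnitude response |H|^2, the transfer realized by forward-backward
# filtering, so no latency shift can bias the 50 ms feature grid.

#' Preprocessing configuration
#'
#' @param notch_freqs Line-noise frequencies to remove (Hz).
#' @param hg_band High-gamma band edges (Hz).
#' @param impedance_max Channels with impedance strictly above this (kOhm)
#'   are excluded.
#' @param ied_amp_factor Excursion threshold as a multiple of the robust
#'   background level.
#' @param ied_dur_range Excursion durations (ms) that flag a trial.
#' @param baseline_ms Prestimulus baseline window (ms relative to word onset).
#' @param envelope_method `"analytic"` (band-pass + analytic-signal
#'   magnitude, the default) or `"morlet"` (wavelet filterbank band-averaged
#'   amplitude).
#' @param baseline_per_trial If `TRUE`, z-score each trial against its own
#'   baseline instead of the channel's pooled baseline moments.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(notch_freqs = c(60, 120, 180),
                              hg_band = c(70, 170),
                              impedance_max = 10,
                              ied_amp_factor = 2,
                              ied_dur_range = c(20, 200),
                              baseline_ms = c(-300, 0),
                              envelope_method = c("analytic", "morlet"),
                              baseline_per_trial = FALSE) {
  if (hg_band[1] >= hg_band[2]) stop_config("invalid band edges")
  structure(list(notch_freqs = notch_freqs, hg_band = hg_band,
                 impedance_max = impedance_max,
                 ied_amp_factor = ied_amp_factor,
                 ied_dur_range = ied_dur_range, baseline_ms = baseline_ms,
                 envelope_method = match.arg(envelope_method),
                 baseline_per_trial = baseline_per_trial),
            class = "preprocess_config")
}

# --- internal frequency-domain machinery ------------------------------------

# Apply a real gain vector (length S, one per FFT bin) to a vector, a
# samples-by-series matrix, or a trials x channels x samples array.
apply_fft_gain <- function(x, gain) {
  filt_mat <- function(m) Re(stats::mvfft(stats::mvfft(m) * gain,
                                          inverse = TRUE)) / nrow(m)
  if (is.array(x) && length(dim(x)) == 3) {
    d <- dim(x)
    m <- matrix(aperm(x, c(3, 1, 2)), nrow = d[3])
    out <- filt_mat(m)
    return(aperm(array(out, dim = c(d[3], d[1], d[2])), c(2, 3, 1)))
  }
  if (is.matrix(x)) return(filt_mat(x))
  as.vector(filt_mat(matrix(x, ncol = 1)))
}

fft_bin_freqs <- function(n, fs) {
  c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
}

# Squared-magnitude (zero-phase) Butterworth response at given frequencies.
butter_gain2 <- function(n_order, edges_hz, type, freqs_hz, fs) {
  ba <- signal::butter(n_order, edges_hz / (fs / 2), type = type)
  z <- exp(-1i * 2 * pi * freqs_hz / fs)
  num <- as.vector(outer(z, seq_along(ba$b) - 1, `^`) %*% ba$b)
  den <- as.vector(outer(z, seq_along(ba$a) - 1, `^`) %*% ba$a)
  Mod(num / den)^2
}

n_samples_of <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) dim(x)[3]
  else if (is.matrix(x)) nrow(x) else length(x)
}

# --- operations -------------------------------------------------------------

#' Common average reference
#'
#' Subtracts, per trial and sample, the mean over good channels from every
#' channel. In the full pipeline this is applied within subject.
#'
#' @param signals trials x channels x samples array.
#' @param good_channel_mask Logical vector over channels; at least two must
#'   be good.
#' @return Array of the same shape.
#' @export
common_average_reference <- function(signals,
                                     good_channel_mask = rep(TRUE, dim(signals)[2])) {
  stopifnot(length(dim(signals)) == 3)
  if (sum(good_channel_mask) < 2)
    stop("common average reference needs at least 2 good channels",
         call. = FALSE)
  avg <- colMeans(aperm(signals[, good_channel_mask, , drop = FALSE],
                        c(2, 1, 3)))          # trials x samples
  signals - aperm(array(avg, dim = c(dim(signals)[1], dim(signals)[3],
                                     dim(signals)[2])), c(1, 3, 2))
}

#' Notch filter at line-noise frequencies
#'
#' Zero-phase band-stop filtering (order-2 Butterworth, +/-2 Hz stop band
#' per frequency, squared-magnitude response). Tones at a notch frequency
#' are attenuated by far more than 20 dB; content 15 Hz or more away passes
#' essentially unchanged.
#'
#' @param signals Vector, samples x series matrix, or trials x channels x
#'   samples array.
#' @param sample_rate Sampling rate (Hz).
#' @param notch_freqs Frequencies to remove; all must be below Nyquist.
#' @return Same shape as `signals`.
#' @export
notch_filter <- function(signals, sample_rate, notch_freqs = c(60, 120, 180)) {
  if (any(notch_freqs >= sample_rate / 2))
    stop_config("notch frequency at or above Nyquist (%g Hz)", sample_rate / 2)
  n <- n_samples_of(signals)
  f <- fft_bin_freqs(n, sample_rate)
  gain <- rep(1, n)
  for (f0 in notch_freqs)
    gain <- gain * butter_gain2(2, c(f0 - 2, f0 + 2), "stop", f, sample_rate)
  apply_fft_gain(signals, gain)
}

#' Exclude bad channels
#'
#' Channels with impedance strictly above `impedance_max` (the clinical
#' criterion is > 10 kOhm; exactly 10 is retained) or flagged bad are
#' excluded.
#'
#' @param channels data.frame with columns `channel_id`, `impedance_kohm`,
#'   `is_bad`.
#' @param impedance_max Threshold in kOhm.
#' @return Character vector of retained channel ids.
#' @export
exclude_bad_channels <- function(channels, impedance_max = 10) {
  if (nrow(channels) == 0) return(character(0))
  stopifnot(all(channels$impedance_kohm >= 0))
  keep <- channels$impedance_kohm <= impedance_max & !channels$is_bad
  channels$channel_id[keep]
}

#' Detect trials contaminated by interictal epileptiform discharges
#'
#' A trial is flagged when any of its subject's channels contains a
#' contiguous excursion whose smoothed rectified amplitude exceeds
#' `ied_amp_factor` times the channel's robust background level (1.4826 x
#' MAD over that channel's prestimulus baselines, pooled across trials) and
#' whose duration lies within `ied_dur_range` (20-200 ms). The rectified
#' trace is smoothed with a 10 ms moving average and sub-threshold gaps
#' shorter than 5 ms are bridged, so a discharge's zero crossings and brief
#' background dips do not fragment its excursion.
#'
#' @param dataset A `raw_dataset`.
#' @param cfg A [preprocess_config()].
#' @return Logical vector, one flag per row of `dataset$trials`.
#' @export
detect_ied_trials <- function(dataset, cfg = preprocess_config()) {
  stopifnot(inherits(dataset, "raw_dataset"))
  fs <- dataset$sample_rate
  span <- dataset$epoch_ms[2] - dataset$epoch_ms[1]
  if (span <= cfg$ied_dur_range[2])
    stop("epoch must be longer than the maximum discharge duration",
         call. = FALSE)
  k <- max(1L, round(0.010 * fs))
  min_run <- ceiling(cfg$ied_dur_range[1] / 1000 * fs)
  max_run <- floor(cfg$ied_dur_range[2] / 1000 * fs)
  n_tr <- nrow(dataset$trials)
  flags <- rep(FALSE, n_tr)
  word_of <- dataset$trials$word_id
  for (ci in seq_len(nrow(dataset$channels))) {
    bg <- channel_background(dataset$signals, dataset$times, ci,
                             cfg$baseline_ms)
    if (!is.finite(bg) || bg < 1e-12) {
      warning(sprintf("channel %s has zero background; skipped",
                      dataset$channels$channel_id[ci]))
      next
    }
    sub <- dataset$channels$subject_id[ci]
    rows <- which(dataset$trials$subject_id == sub)
    x <- abs(t(dataset$signals[, ci, , drop = TRUE]))   # samples x words
    if (is.null(dim(x))) x <- matrix(x, ncol = 1)
    sm <- as.matrix(stats::filter(x, rep(1 / k, k), sides = 2))
    sm[is.na(sm)] <- 0
    above <- matrix(sm > cfg$ied_amp_factor * bg, nrow(sm))
    gap <- max(1L, round(0.005 * fs))
    for (r in rows) {
      if (flags[r]) next
      a <- above[, word_of[r]]
      runs <- rle(a)
      # morphological closing: bridge sub-threshold gaps < 5 ms
      interior <- runs$values == FALSE & runs$lengths <= gap &
        seq_along(runs$values) > 1 & seq_along(runs$values) < length(runs$values)
      if (any(interior)) {
        runs$values[interior] <- TRUE
        a <- inverse.rle(runs)
        runs <- rle(a)
      }
      hit <- runs$values & runs$lengths >= min_run & runs$lengths <= max_run
      if (any(hit)) flags[r] <- TRUE
    }
  }
  flags
}

#' High-gamma amplitude envelope
#'
#' Default backend: zero-phase band-pass (order-4 Butterworth magnitude,
#' 70-170 Hz) followed by the analytic-signal magnitude. Alternative
#' backend: Morlet wavelet filterbank (7 cycles, 10 Hz spacing across the
#' band), averaging per-frequency analytic amplitudes with a filterbank
#' gain calibration so an in-band unit tone yields an envelope of 1.
#'
#' @param signals Vector, samples x series matrix, or trials x channels x
#'   samples array.
#' @param sample_rate Sampling rate (Hz).
#' @param hg_band Band edges (Hz); upper edge must be below Nyquist.
#' @param method `"analytic"` or `"morlet"`.
#' @return Nonnegative envelope, same shape as `signals`.
#' @export
hg_envelope <- function(signals, sample_rate, hg_band = c(70, 170),
                        method = c("analytic", "morlet")) {
  method <- match.arg(method)
  if (hg_band[1] >= hg_band[2]) stop_config("invalid band edges")
  if (hg_band[2] >= sample_rate / 2)
    stop_config("band edge %g Hz at or above Nyquist", hg_band[2])
  n <- n_samples_of(signals)
  f <- fft_bin_freqs(n, sample_rate)
  analytic_weight <- function(n) {
    h <- numeric(n)
    h[1] <- 1
    if (n %% 2 == 0) {
      h[2:(n / 2)] <- 2; h[n / 2 + 1] <- 1
    } else h[2:((n + 1) / 2)] <- 2
    h
  }
  env_mat <- function(m, gain) {
    spec <- stats::mvfft(m) * gain * analytic_weight(nrow(m))
    Mod(stats::mvfft(spec, inverse = TRUE)) / nrow(m)
  }
  run <- function(fun) {
    if (is.array(signals) && length(dim(signals)) == 3) {
      d <- dim(signals)
      m <- matrix(aperm(signals, c(3, 1, 2)), nrow = d[3])
      out <- fun(m)
      aperm(array(out, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
    } else if (is.matrix(signals)) fun(signals)
    else as.vector(fun(matrix(signals, ncol = 1)))
  }
  if (method == "analytic") {
    gain <- sqrt(butter_gain2(4, hg_band, "pass", f, sample_rate))
    run(function(m) env_mat(m, gain))
  } else {
    centers <- seq(hg_band[1] + 5, hg_band[2] - 5, by = 10)
    n_cycles <- 7
    # frequency-domain Gaussian kernels, jointly normalized so the summed
    # filterbank response is exactly 1 anywhere the bank has appreciable
    # gain: an in-band unit tone then yields an envelope of 1 regardless of
    # where it falls between kernel centers
    kerns <- vapply(centers, function(f0)
      exp(-0.5 * ((f - f0) / (f0 / n_cycles))^2), numeric(length(f)))
    total <- rowSums(kerns)
    norm <- ifelse(total >= 0.01, 1 / pmax(total, 0.01), 0)
    run(function(m) {
      acc <- 0
      for (j in seq_along(centers)) acc <- acc + env_mat(m, kerns[, j] * norm)
      acc
    })
  }
}

#' Baseline-normalize an envelope
#'
#' Per channel, z-scores the envelope using the mean and SD of its
#' prestimulus baseline samples pooled across that channel's non-rejected
#' trials (or per trial when `per_trial = TRUE`).
#'
#' @param envelope trials x channels x samples array.
#' @param times Sample times (ms relative to word onset).
#' @param baseline_ms Baseline window.
#' @param rejected Logical per trial row (words); rejected trials do not
#'   contribute baseline statistics but are still transformed.
#' @param per_trial Use per-trial instead of pooled baseline moments.
#' @return List with `envelope` (z-units, same shape) and `degenerate`
#'   (logical per channel: baseline SD below 1e-12, division guarded).
#' @export
baseline_normalize <- function(envelope, times, baseline_ms = c(-300, 0),
                               rejected = rep(FALSE, dim(envelope)[1]),
                               per_trial = FALSE) {
  stopifnot(length(dim(envelope)) == 3)
  sel <- times >= baseline_ms[1] & times < baseline_ms[2]
  if (!any(sel)) stop_config("baseline window outside the epoch")
  n_ch <- dim(envelope)[2]
  degenerate <- logical(n_ch)
  out <- envelope
  for (c_i in seq_len(n_ch)) {
    if (per_trial) {
      base <- envelope[, c_i, sel, drop = FALSE]
      m <- apply(base, 1, mean)
      s <- apply(base, 1, stats::sd)
      bad <- s < 1e-12
      if (any(bad)) { degenerate[c_i] <- TRUE; s[bad] <- 1 }
      out[, c_i, ] <- (envelope[, c_i, ] - m) / s
    } else {
      base <- as.vector(envelope[!rejected, c_i, sel])
      m <- mean(base)
      s <- stats::sd(base)
      if (!is.finite(s) || s < 1e-12) {
        degenerate[c_i] <- TRUE
        warning(sprintf("channel %d: baseline SD ~ 0; flagged bad", c_i))
        s <- 1
      }
      out[, c_i, ] <- (envelope[, c_i, ] - m) / s
    }
  }
  list(envelope = out, degenerate = degenerate)
}

#' Run the full preprocessing chain
#'
#' Fixed stage order: common average reference (within subject, over good
#' channels) -> notch filtering -> impedance-based channel exclusion ->
#' discharge trial rejection -> high-gamma envelope -> baseline
#' normalization. Excluded channels are dropped (and listed in the result);
#' rejected trials are flagged, never deleted.
#'
#' @param dataset A `raw_dataset`.
#' @param cfg A [preprocess_config()].
#' @return An object of class `envelope_dataset`: `envelope` (trials x
#'   retained channels x samples, z-units), `channels`, `trials` (with
#'   `rejected` updated), `times`, `sample_rate`, `epoch_ms`,
#'   `baseline_ms`, `excluded_channels`, `truth`.
#' @export
preprocess <- function(dataset, cfg = preprocess_config()) {
  stopifnot(inherits(dataset, "raw_dataset"))
  keep_ids <- exclude_bad_channels(dataset$channels, cfg$impedance_max)
  good <- dataset$channels$channel_id %in% keep_ids
  sig <- dataset$signals
  for (sub in unique(dataset$channels$subject_id)) {
    chs <- which(dataset$channels$subject_id == sub)
    gm <- good[chs]
    if (sum(gm) < 2) next
    sig[, chs, ] <- common_average_reference(sig[, chs, , drop = FALSE], gm)
  }
  sig <- notch_filter(sig, dataset$sample_rate, cfg$notch_freqs)
  ds_f <- dataset
  ds_f$signals <- sig
  rejected <- detect_ied_trials(ds_f, cfg)
  trials <- dataset$trials
  trials$rejected <- trials$rejected | rejected

  env <- hg_envelope(sig[, good, , drop = FALSE], dataset$sample_rate,
                     cfg$hg_band, cfg$envelope_method)
  channels <- dataset$channels[good, , drop = FALSE]
  rownames(channels) <- NULL
  # a word is excluded from a channel's baseline pool if rejected for the
  # channel's subject; with word-aligned rows use the per-subject flags
  norm_env <- env
  degenerate <- logical(sum(good))
  for (sub in unique(channels$subject_id)) {
    chs <- which(channels$subject_id == sub)
    rej <- trials$rejected[trials$subject_id == sub][
      order(trials$word_id[trials$subject_id == sub])]
    bn <- baseline_normalize(env[, chs, , drop = FALSE], dataset$times,
                             cfg$baseline_ms, rejected = rej,
                             per_trial = cfg$baseline_per_trial)
    norm_env[, chs, ] <- bn$envelope
    degenerate[chs] <- bn$degenerate
  }
  channels$is_bad <- channels$is_bad | degenerate
  structure(list(envelope = norm_env, channels = channels, trials = trials,
                 times = dataset$times, sample_rate = dataset$sample_rate,
                 epoch_ms = dataset$epoch_ms, baseline_ms = cfg$baseline_ms,
                 excluded_channels = dataset$channels$channel_id[!good],
                 truth = dataset$truth),
            class = "envelope_dataset")
}
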