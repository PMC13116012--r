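# Generator contracts: trial bookkeeping, determinism, onset distribution,
# spectral content, and recovery of planted ground truth by an independent
# envelope oracle.

test_that("every subject gets exactly 34 trials with shared word list", {
  cfg <- quick_cfg(n_subjects = 2, channels_per_area = 2,
                   areas = data.frame(brodmann_area = "9", hemisphere = "L"),
                   seed = 3)
  ds <- generate_dataset(cfg)
  counts <- table(ds$trials$subject_id)
  expect_true(all(counts == 34))
  for (s in unique(ds$trials$subject_id)) {
    tr <- ds$trials[ds$trials$subject_id == s, ]
    expect_false(any(duplicated(tr$word_id)))
  }
  # categories aligned across subjects
  by_word <- tapply(ds$trials$category, ds$trials$word_id,
                    function(x) length(unique(x)))
  expect_true(all(by_word == 1))
  expect_equal(sum(ds$trials$category == "body"), 2 * 17)
  expect_false(any(duplicated(ds$channels$channel_id)))
  expect_true(all(is.finite(ds$signals)))
  expect_equal(dim(ds$signals)[3],
               (cfg$epoch_ms[2] - cfg$epoch_ms[1]) / 1000 * cfg$sample_rate)
})

test_that("identical config yields byte-identical output", {
  cfg <- quick_cfg(n_subjects = 1, channels_per_area = 2,
                   areas = data.frame(brodmann_area = "9", hemisphere = "L"),
                   ied_rate = 0.3, seed = 11)
  expect_identical(generate_dataset(cfg), generate_dataset(cfg))
})

test_that("config validation rejects impossible bands and rates", {
  expect_error(synth_config(hg_band = c(170, 70)), "invalid band")
  expect_error(synth_config(sample_rate = 300), "twice the upper band edge")
  expect_error(synth_config(n_subjects = 0), "counts")
})

test_that("speech onsets follow the truncated normal with 500 ms floor", {
  o <- sample_speech_onsets(10000, seed = 2)
  expect_gte(min(o), 500)
  # oracle: numeric integration of the truncated-normal mean
  f <- function(x) x * dnorm(x, 881, 228)
  mass <- 1 - pnorm(500, 881, 228)
  mu_trunc <- integrate(f, 500, Inf)$value / mass
  expect_lt(abs(mean(o) - mu_trunc), 10)
  # degenerate hook
  expect_equal(sample_speech_onsets(5, sd_ms = 0), rep(881, 5))
  expect_error(sample_speech_onsets(0), "n must be")
})

test_that("no planted effect gives near-zero category difference", {
  cfg <- quick_cfg(n_trials = 200, n_body = 100, channels_per_area = 2,
                   areas = data.frame(brodmann_area = "9", hemisphere = "L"),
                   seed = 5)
  ds <- generate_dataset(cfg)
  body <- ds$trials$category == "body"
  wm <- vapply(seq_len(200), function(i)
    oracle_window_mean(ds, i, 1, c(0, 100)), 0.0)
  expect_lt(abs(cohens_d(wm, body)), 0.2)
})

test_that("planted effect is recovered at the stated effect size", {
  cfg <- quick_cfg(n_trials = 200, n_body = 100, channels_per_area = 2,
                   areas = data.frame(brodmann_area = "9", hemisphere = "L"),
                   effects = planted_effect("9", "L", c(0, 100), 2.0),
                   seed = 6)
  ds <- generate_dataset(cfg)
  body <- ds$trials$category == "body"
  wm <- vapply(seq_len(200), function(i)
    oracle_window_mean(ds, i, 1, c(0, 100)), 0.0)
  d_hat <- cohens_d(wm, body)
  expect_lt(abs(d_hat - 2.0), 0.4)
  # effect confined to its window: the 300-400 ms window shows none
  wm_out <- vapply(seq_len(200), function(i)
    oracle_window_mean(ds, i, 1, c(300, 400)), 0.0)
  expect_lt(abs(cohens_d(wm_out, body)), 0.3)
})

test_that("background spectral slope matches the pink exponent", {
  cfg <- quick_cfg(channels_per_area = 1, carrier_amp = 0,
                   line_noise_amp = c(0, 0, 0),
                   areas = data.frame(brodmann_area = "9", hemisphere = "L"),
                   epoch_ms = c(-1000, 3000), seed = 8)
  ds <- generate_dataset(cfg)
  x <- as.vector(t(ds$signals[1:10, 1, ]))   # 10 concatenated trials
  n <- length(x)
  pw <- Mod(stats::fft(x))[2:(n / 2)]^2 / n
  fr <- (1:(n / 2 - 1)) * ds$sample_rate / n
  sel <- fr >= 1 & fr <= 300
  # periodogram fit on log-log binned spectrum
  bins <- cut(log(fr[sel]), 30)
  lp <- tapply(log(pw[sel]), bins, mean)
  lf <- tapply(log(fr[sel]), bins, mean)
  slope <- stats::coef(stats::lm(lp ~ lf))[2]
  expect_lt(abs(slope - (-cfg$pink_exponent)), 0.3)
})

test_that("planted coupling realizes the target R2 between window gains", {
  cfg <- quick_cfg(n_trials = 250, n_body = 125, channels_per_area = 4,
                   areas = data.frame(brodmann_area = c("9", "40"),
                                      hemisphere = "L"),
                   couplings = planted_coupling("9", "L", 3, "40", "L", 6, 0.5),
                   seed = 9)
  ds <- generate_dataset(cfg)
  src_ch <- which(ds$channels$brodmann_area == "9")
  tgt_ch <- which(ds$channels$brodmann_area == "40")
  gains <- function(chs, win) {
    rowMeans(vapply(chs, function(ch) vapply(seq_len(250), function(i)
      oracle_window_mean(ds, i, ch, win), 0.0), numeric(250)))
  }
  g_src <- gains(src_ch, c(100, 200))   # window 3
  g_tgt <- gains(tgt_ch, c(250, 350))   # window 6
  r2 <- stats::cor(g_src, g_tgt)^2
  expect_lt(abs(r2 - 0.5), 0.12)
})

test_that("inject_ied is additive, local, and validates its ids", {
  fx <- small_pipeline_fixture()
  ds <- fx$ds
  ds0 <- inject_ied(ds, ds$trials$trial_id[1], ds$channels$channel_id[1],
                    amplitude_factor = 0, duration_ms = 60)
  expect_identical(ds0$signals, ds$signals)
  ds1 <- inject_ied(ds, ds$trials$trial_id[2], ds$channels$channel_id[1],
                    amplitude_factor = 3, duration_ms = 60)
  diff <- ds1$signals - ds$signals
  expect_true(all(diff[-2, , ] == 0))
  expect_true(all(diff[2, -1, ] == 0))
  expect_gt(max(abs(diff[2, 1, ])), 0)
  expect_error(inject_ied(ds, "nope", ds$channels$channel_id[1], 3, 60),
               "unknown trial_id")
  expect_error(inject_ied(ds, ds$trials$trial_id[1], "nope", 3, 60),
               "unknown channel_id")
})
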