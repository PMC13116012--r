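# Signal-processing contracts: CAR arithmetic, notch attenuation, channel
# exclusion boundary, discharge detection, envelope fidelity on pure tones,
# and baseline z-scoring.

test_that("common average reference removes the cross-channel mean", {
  # all channels identical -> zero
  x <- aperm(array(rnorm(50), dim = c(50, 1, 3)), c(2, 3, 1))
  expect_equal(max(abs(common_average_reference(x))), 0)
  # hand arithmetic: [1, 3] -> [-1, +1]
  y <- array(c(1, 3), dim = c(1, 2, 1))
  expect_equal(as.vector(common_average_reference(y)), c(-1, 1))
  # post-CAR good-channel mean ~ 0 on random input
  z <- array(rnorm(4 * 5 * 100), dim = c(4, 5, 100))
  good <- c(TRUE, TRUE, TRUE, FALSE, TRUE)
  zc <- common_average_reference(z, good)
  m <- apply(zc[, good, ], c(1, 3), mean)
  expect_lt(max(abs(m)), 1e-10)
  expect_error(common_average_reference(z, c(TRUE, rep(FALSE, 4))),
               "at least 2 good channels")
})

test_that("notch filter attenuates line tones and passes neighbors", {
  fs <- 1000
  t <- (0:999) / fs
  rms <- function(x) sqrt(mean(x^2))
  s60 <- sin(2 * pi * 60 * t)
  expect_lte(rms(notch_filter(s60, fs)) / rms(s60), 0.1)
  s100 <- sin(2 * pi * 100 * t)
  expect_lt(abs(rms(notch_filter(s100, fs)) / rms(s100) - 1), 0.05)
  dc <- rep(2, 1000)
  expect_lt(max(abs(notch_filter(dc, fs) - dc)), 1e-6)
  expect_error(notch_filter(s60, fs, notch_freqs = 600), "Nyquist")
})

test_that("impedance exclusion is strictly greater-than 10 kOhm", {
  ch <- data.frame(channel_id = c("a", "b", "c", "d"),
                   impedance_kohm = c(12, 10, 9, 2),
                   is_bad = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(exclude_bad_channels(ch), c("b", "c"))
  expect_equal(exclude_bad_channels(ch[0, ]), character(0))
})

test_that("discharge detector obeys the amplitude and duration rules", {
  fx <- small_pipeline_fixture()
  ds <- fx$ds
  ch <- ds$channels$channel_id[1]
  expect_false(any(detect_ied_trials(ds)))
  ds_pos <- inject_ied(ds, "S01_w03", ch, amplitude_factor = 3,
                       duration_ms = 60)
  expect_true(detect_ied_trials(ds_pos)[3])
  ds_neg <- inject_ied(ds, "S01_w05", ch, amplitude_factor = 3,
                       duration_ms = 5)
  expect_false(detect_ied_trials(ds_neg)[5])
  # all-zero signals: zero background, channels skipped with warning
  ds0 <- ds
  ds0$signals[] <- 0
  w <- capture_warnings(fl <- detect_ied_trials(ds0))
  expect_true(all(grepl("zero background", w)))
  expect_length(w, nrow(ds$channels))
  expect_false(any(fl))
})

test_that("discharge detector type-I rate stays low on clean noise", {
  cfg <- quick_cfg(channels_per_area = 4,
                   areas = data.frame(brodmann_area = c("9", "40"),
                                      hemisphere = "L"), seed = 77)
  ds <- generate_dataset(cfg)
  expect_lt(mean(detect_ied_trials(ds)), 0.10)
})

test_that("envelope backends are faithful on pure tones", {
  fs <- 1000
  t <- (0:999) / fs
  interior <- 150:850
  for (m in c("analytic", "morlet")) {
    e100 <- hg_envelope(sin(2 * pi * 100 * t), fs, method = m)
    expect_lt(max(abs(e100[interior] - 1)), 0.05)
    e30 <- hg_envelope(sin(2 * pi * 30 * t), fs, method = m)
    expect_lt(max(e30[interior]), 0.1)
  }
  expect_equal(hg_envelope(rep(0, 1000), fs), rep(0, 1000))
  expect_error(hg_envelope(rnorm(100), 300, hg_band = c(70, 170)), "Nyquist")
})

test_that("envelope scales linearly with the input before normalization", {
  set.seed(4)
  x <- rnorm(1000)
  e1 <- hg_envelope(x, 1000)
  e3 <- hg_envelope(3 * x, 1000)
  expect_equal(e3, 3 * e1, tolerance = 1e-10)
})

test_that("baseline normalization z-scores against pooled baseline moments", {
  times <- seq(-300, 499, by = 1)
  # constant envelope equal to its own baseline mean -> all zeros... guarded
  env <- array(1, dim = c(2, 1, length(times)))
  expect_warning(bn <- baseline_normalize(env, times), "SD ~ 0")
  expect_true(all(bn$envelope == 0))
  expect_true(bn$degenerate[1])
  # hand arithmetic: baseline mean 1.0, SD 0.5 -> value 2.0 maps to z = 2
  env2 <- array(0, dim = c(2, 1, length(times)))
  base_idx <- which(times < 0)
  env2[1, 1, base_idx] <- 0.5
  env2[2, 1, base_idx] <- 1.5
  env2[, 1, times >= 0] <- 2.0
  bn2 <- baseline_normalize(env2, times)
  expect_equal(mean(bn2$envelope[, 1, times >= 0]), 2.0, tolerance = 0.01)
  # property: pooled baseline samples ~ N(0, 1) after the transform
  set.seed(5)
  env3 <- array(abs(rnorm(3 * 2 * length(times), 5, 2)),
                dim = c(3, 2, length(times)))
  bn3 <- baseline_normalize(env3, times)
  pooled <- as.vector(bn3$envelope[, , base_idx])
  expect_lt(abs(mean(pooled)), 0.01)
  expect_lt(abs(stats::sd(pooled) - 1), 0.01)
})

test_that("the full preprocessing chain is deterministic and shaped right", {
  fx <- small_pipeline_fixture()
  env1 <- preprocess(fx$ds)
  expect_identical(env1$envelope, fx$env$envelope)
  expect_s3_class(env1, "envelope_dataset")
  expect_equal(dim(env1$envelope)[1], 34)
  expect_true(all(env1$envelope[is.finite(env1$envelope)] > -Inf))
  # excluded channels are dropped and listed
  expect_equal(dim(env1$envelope)[2] + length(env1$excluded_channels),
               nrow(fx$ds$channels))
})
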