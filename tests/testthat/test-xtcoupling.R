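# Cross-temporal regression: R^2 arithmetic against closed forms, null
# calibration, permutation p values, and the seed-and-grow cluster rule
# against an exhaustive connected-components oracle.

test_that("region timecourse averages the retained channels", {
  fx <- small_pipeline_fixture()
  ft <- fx$feats
  one <- ft$channels$channel_id[1]
  tc1 <- region_timecourse(ft, "9", "L", one)
  expect_equal(unname(tc1$values), unname(ft$values[, 1, ]))
  # two channels with features x and -x cancel
  vals <- ft$values[, 1:2, , drop = FALSE]
  vals[, 2, ] <- -vals[, 1, ]
  ft2 <- make_feature_tensor(vals, ft$trials$category)
  tc2 <- region_timecourse(ft2, "9", "L", ft2$channels$channel_id)
  expect_lt(max(abs(tc2$values)), 1e-12)
  # category scope filters rows
  tcb <- region_timecourse(ft, "9", "L", one, scope = "body")
  expect_equal(nrow(tcb$values), sum(ft$trials$category == "body"))
  expect_message(expect_null(region_timecourse(ft, "9", "L", character(0))),
                 "skipped")
})

test_that("cross-temporal R2 matches closed-form OLS", {
  # x = [1,2,3], y = [2,4,7]: SSE = 1/6, SST = 38/3, R2 = 75/76
  r2 <- cross_temporal_r2(matrix(c(1, 2, 3)), matrix(c(2, 4, 7)))
  expect_equal(as.numeric(r2), 75 / 76, tolerance = 1e-12)
  expect_equal(as.numeric(r2), 0.9868, tolerance = 1e-3)
  # identical source and target: unit diagonal
  set.seed(2)
  m <- matrix(rnorm(30 * 10), 30, 10)
  expect_equal(unname(diag(cross_temporal_r2(m, m))), rep(1, 10))
  # symmetry: simple-regression R2 equals squared correlation both ways
  m2 <- matrix(rnorm(30 * 10), 30, 10)
  expect_equal(cross_temporal_r2(m, m2),
               t(cross_temporal_r2(m2, m)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # independence: mean R2 ~ 1/(n-1)
  set.seed(5)
  means <- replicate(300, mean(cross_temporal_r2(matrix(rnorm(300), 30),
                                                 matrix(rnorm(300), 30))))
  expect_lt(abs(mean(means) - 1 / 29), 0.5 / 29)
  # degenerate predictor: flagged zero, not an error
  z <- matrix(rnorm(30), 30, 1)
  const <- matrix(1, 30, 1)
  rz <- cross_temporal_r2(const, z)
  expect_equal(as.numeric(rz), 0)
  expect_true(attr(rz, "degenerate")[1, 1])
  expect_error(cross_temporal_r2(matrix(1:2), matrix(1:2)), "fewer than 3")
})

test_that("coupling permutation p values behave and are seed-stable", {
  set.seed(6)
  m <- matrix(rnorm(30 * 10), 30, 10)
  cfg <- cluster_config(n_perms = 400, seed = 9)
  nl <- coupling_null(m, m, cfg)
  expect_equal(unname(diag(nl$p)), rep(1 / 401, 10))
  expect_identical(nl$p, coupling_null(m, m, cfg)$p)
  expect_error(coupling_null(m, m, cluster_config(n_perms = 50)), ">= 100")
  # calibration on independent data
  rates <- vapply(1:20, function(r) {
    set.seed(100 + r)
    a <- matrix(rnorm(300), 30); b <- matrix(rnorm(300), 30)
    mean(coupling_null(a, b, cluster_config(n_perms = 200, seed = r))$p <= 0.05)
  }, 0.0)
  expect_lt(abs(mean(rates) - 0.05), 0.03)
})

test_that("seed-and-grow clusters match hand-built cases", {
  cfg <- cluster_config()
  zero <- matrix(0, 10, 10)
  qs <- matrix(1e-4, 10, 10)
  expect_length(find_clusters(zero, qs, cfg), 0)
  # 3 x 2 block of r2 = 0.25, all significant: one cluster, size 6, peak 0.25
  r2 <- zero; r2[4:6, 7:8] <- 0.25
  cl <- find_clusters(r2, qs, cfg)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size, 6)
  expect_equal(cl[[1]]$peak_r2, 0.25)
  # 2 x 2 block of 0.5: below the 5-pixel minimum
  r2b <- zero; r2b[1:2, 1:2] <- 0.5
  expect_length(find_clusters(r2b, qs, cfg), 0)
  # non-significant cells cannot join a cluster
  qs2 <- qs; qs2[5, 7] <- 0.5
  r2c <- zero; r2c[4:6, 7:8] <- 0.25
  cl2 <- find_clusters(r2c, qs2, cfg)
  expect_length(cl2, 1)
  expect_equal(cl2[[1]]$size, 5)
})

test_that("find_clusters equals the exhaustive connected-components oracle", {
  skip_if_not_installed("igraph")
  cfg <- cluster_config()
  set.seed(14)
  for (i in 1:1000) {
    r2 <- matrix(runif(100)^2, 10, 10)
    q <- matrix(runif(100)^0.5, 10, 10)
    got <- find_clusters(r2, q, cfg)
    want <- cluster_oracle(r2, q, cfg)
    expect_equal(length(got), length(want))
    if (length(got) > 0)
      expect_setequal(vapply(got, function(cl) cell_key(cl$cells), ""),
                      vapply(want, cell_key, ""))
  }
})

test_that("a planted coupling is detected as a cluster containing its cell", {
  fx_cfg <- quick_cfg(n_trials = 200, n_body = 100, channels_per_area = 6,
                      areas = data.frame(brodmann_area = c("9", "40"),
                                         hemisphere = "L"),
                      couplings = planted_coupling("9", "L", 3,
                                                   "40", "L", 6, 0.5),
                      seed = 17)
  ds <- generate_dataset(fx_cfg)
  env <- preprocess(ds)
  ft <- window_features(env)
  mp <- coupling_map(ft, "9", "L", "40", "L", ft$channels$channel_id,
                     cfg = cluster_config(n_perms = 300, seed = 4))
  expect_gte(length(mp$clusters), 1)
  keys <- apply(mp$clusters[[1]]$cells, 1, paste, collapse = ",")
  expect_true("3,6" %in% keys)
  expect_lt(abs(mp$clusters[[1]]$peak_r2 - 0.5), 0.12)
})

test_that("aligned trace report has the pair x window x role layout", {
  empty <- aligned_trace_report(list(), list(), list())
  expect_equal(nrow(empty), 0)
  expect_true(all(c("pair", "role", "window_ms", "mean_hg", "accuracy",
                    "in_cluster_span") %in% names(empty)))
  # constructed pair with a source -> target lag
  mk_curve <- function(peak_w) structure(list(
    accuracy = replace(rep(0.5, 10), peak_w, 0.9),
    windows_ms = seq(50, 500, 50), area = "9", hemisphere = "L"),
    class = "decoding_curve")
  mk_tc <- function(peak_w) structure(list(
    values = matrix(rep(replace(rep(0, 10), peak_w, 2), each = 5), 5),
    windows_ms = seq(50, 500, 50)), class = "region_timecourse")
  curves <- list(src = mk_curve(3), tgt = mk_curve(7))
  tcs <- list(src = mk_tc(3), tgt = mk_tc(7))
  cl <- structure(list(cells = cbind(3, 6:8), size = 3, peak_r2 = 0.4,
                       peak_cell = c(3, 7),
                       bbox = list(source = c(3, 3), target = c(6, 8))),
                  class = "cluster")
  rep1 <- aligned_trace_report(curves, tcs,
                               list(list(source = "src", target = "tgt",
                                         cluster = cl)))
  expect_equal(nrow(rep1), 1 * 10 * 2)
  src_rows <- rep1[rep1$role == "source", ]
  tgt_rows <- rep1[rep1$role == "target", ]
  expect_lt(which.max(src_rows$mean_hg), which.max(tgt_rows$mean_hg))
  expect_equal(sum(src_rows$in_cluster_span), 1)
  expect_equal(sum(tgt_rows$in_cluster_span), 3)
  # missing inputs are reported, not fatal
  rep2 <- aligned_trace_report(curves, tcs,
                               list(list(source = "src", target = "missing")))
  expect_true("absent" %in% rep2$status)
})
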