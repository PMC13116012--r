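# Group-matrix assembly, time-resolved decoding behavior on planted and
# null data, invariances, and the classifier-comparison table.

two_subject_tensor <- function(rejected_word = NULL) {
  set.seed(31)
  n_ch <- 6   # 3 per subject
  vals <- array(rnorm(34 * n_ch * 10), dim = c(34, n_ch, 10))
  channels <- data.frame(
    channel_id = c(sprintf("S01_c%d", 1:3), sprintf("S02_c%d", 1:3)),
    subject_id = rep(c("S01", "S02"), each = 3),
    hemisphere = "L", brodmann_area = "9", impedance_kohm = 5,
    is_bad = FALSE, stringsAsFactors = FALSE)
  trials <- data.frame(
    trial_id = sprintf("%s_w%02d", rep(c("S01", "S02"), each = 34), 1:34),
    subject_id = rep(c("S01", "S02"), each = 34),
    word_id = rep(1:34, 2),
    category = rep(rep(c("body", "nonbody"), each = 17), 2),
    speech_onset_ms = 881, rejected = FALSE, stringsAsFactors = FALSE)
  if (!is.null(rejected_word))
    trials$rejected[trials$subject_id == "S02" &
                    trials$word_id == rejected_word] <- TRUE
  structure(list(values = vals, grid = window_grid(), channels = channels,
                 trials = trials,
                 truth = list(effects = list(), couplings = list())),
            class = "feature_tensor")
}

test_that("group matrix concatenates retained channels across subjects", {
  ft <- two_subject_tensor()
  gm <- build_group_matrix(ft, "9", "L", ft$channels$channel_id)
  expect_equal(ncol(gm$matrices[[1]]), 6)
  expect_equal(nrow(gm$matrices[[1]]), 34)
  # word rejected in one subject drops that row for the whole group
  gm2 <- build_group_matrix(two_subject_tensor(rejected_word = 7), "9", "L",
                            ft$channels$channel_id)
  expect_equal(nrow(gm2$matrices[[1]]), 33)
  expect_false(7 %in% gm2$word_ids)
  # single subject: the group matrix is that subject's matrix
  gm1 <- build_group_matrix(ft, "9", "L", sprintf("S01_c%d", 1:3))
  expect_equal(unname(gm1$matrices[[4]]),
               unname(ft$values[, 1:3, 4]))
  # no retained channels: NULL with a notice, not an exception
  expect_message(gm0 <- build_group_matrix(ft, "9", "L", character(0)),
                 "skipped")
  expect_null(gm0)
})

test_that("decoding hits ceiling on separable data and the planted window", {
  gm <- with_seed_local <- NULL
  set.seed(7)
  gm <- random_gm(n = 34, p = 4, effect = 5, windows = 4)
  cv <- decode_timecourse(gm, classifier_spec("svm"), seed = 3)
  expect_equal(cv$accuracy[4], 1.0)
  expect_true(all(cv$accuracy >= 0 & cv$accuracy <= 1))
  expect_equal(cv$accuracy, rowMeans(cv$fold_acc, na.rm = TRUE))
  # argmax recovery over repeats (milder effect)
  hits <- 0
  for (r in 1:20) {
    set.seed(300 + r)
    gmr <- random_gm(n = 34, p = 4, effect = 1.2, windows = 4)
    cvr <- decode_timecourse(gmr, seed = r)
    if (which.max(cvr$accuracy) == 4) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.90)
})

test_that("label-independent features decode at chance", {
  accs <- vapply(1:50, function(r) {
    set.seed(500 + r)
    gm <- random_gm(n = 34, p = 4)
    mean(decode_timecourse(gm, seed = r)$accuracy)
  }, 0.0)
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("decoding is invariant to column order and joint row/label permutation", {
  set.seed(11)
  gm <- random_gm(n = 34, p = 6, effect = 1, windows = c(3, 4))
  y01 <- as.integer(gm$labels == levels(gm$labels)[1])
  fold <- with(list(), {set.seed(2); prespeech:::make_stratified_folds(y01, 5)})
  a1 <- prespeech:::cpp_cv_curve(gm$matrices, y01, fold, 5, 1.0)
  perm_cols <- sample(6)
  mats_p <- lapply(gm$matrices, function(m) m[, perm_cols])
  a2 <- prespeech:::cpp_cv_curve(mats_p, y01, fold, 5, 1.0)
  expect_equal(a1, a2, tolerance = 1e-9)
  # joint permutation of rows, labels, and fold ids
  pr <- sample(34)
  mats_r <- lapply(gm$matrices, function(m) m[pr, ])
  a3 <- prespeech:::cpp_cv_curve(mats_r, y01[pr], fold[pr], 5, 1.0)
  expect_equal(rowMeans(a1), rowMeans(a3), tolerance = 1e-9)
  expect_error(decode_timecourse(make_gm(gm$matrices, rep("body", 34))),
               "both categories")
})

test_that("the compiled max-margin backend agrees with the reference SVM", {
  skip_if_not_installed("e1071")
  diffs <- vapply(1:20, function(r) {
    set.seed(700 + r)
    X <- matrix(rnorm(30 * 5), 30, 5)
    y <- rep(c(0L, 1L), 15)
    X[y == 1, ] <- X[y == 1, ] + 1
    Xte <- matrix(rnorm(20 * 5), 20, 5)
    yte <- rep(c(0L, 1L), 10)
    Xte[yte == 1, ] <- Xte[yte == 1, ] + 1
    mine <- prespeech:::cpp_svm_predict(X, y, Xte, 1.0)
    mu <- colMeans(X); s <- apply(X, 2, sd)
    Xs <- scale(X, mu, s); Xts <- scale(Xte, mu, s)
    fit <- e1071::svm(Xs, factor(y), kernel = "linear", cost = 1,
                      scale = FALSE)
    ref <- as.integer(as.character(predict(fit, Xts)))
    mean(mine != ref)
  }, 0.0)
  expect_lt(mean(diffs), 0.05)
})

test_that("classifier comparison is a fair paired test with FDR", {
  set.seed(9)
  gm <- random_gm(n = 34, p = 4, effect = 4, windows = 1:10)
  specs <- list(classifier_spec("svm"), classifier_spec("svm"))
  cc <- compare_classifiers(gm, specs, seed = 5)
  expect_equal(cc$pairwise$mean_diff[1], 0)
  expect_equal(cc$pairwise$p[1], 1)
  # strongly separable data: all three backends at ceiling
  specs3 <- list(classifier_spec("svm"), classifier_spec("lda"),
                 classifier_spec("rf", n_trees = 100))
  cc3 <- compare_classifiers(gm, specs3, seed = 5)
  expect_true(all(cc3$summary$mean_accuracy >= 0.9))
  expect_equal(cc3$pairwise$q, bh_fdr(cc3$pairwise$p)$q)
  expect_error(compare_classifiers(gm, specs[1]), "at least 2")
})
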