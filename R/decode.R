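# Group-level time-resolved decoding per (hemisphere, Brodmann area).

#' Classifier specification
#'
#' The menu mirrors the three families compared in the analysis: linear
#' max-margin (`"svm"`, the default and the backend used for permutation
#' statistics), linear discriminant analysis (`"lda"`), and a randomized
#' tree ensemble (`"rf"`, 500 trees).
#'
#' @param kind One of `"svm"`, `"lda"`, `"rf"`.
#' @param cost Margin penalty for the linear max-margin classifier.
#' @param n_trees Trees for the ensemble backend.
#' @param seed Seed for stochastic backends.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm", "lda", "rf"), cost = 1,
                            n_trees = 500, seed = 1) {
  structure(list(kind = match.arg(kind), cost = cost,
                 n_trees = n_trees, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Build the group feature matrices for one region
#'
#' Pools the retained channels of all subjects within one (hemisphere,
#' Brodmann area): one matrix per window, one row per word retained
#' (non-rejected) in every contributing subject, columns ordered by subject
#' then channel id.
#'
#' @param features A `feature_tensor`.
#' @param area,hemisphere Region label and hemisphere.
#' @param retained_channels Channel ids retained by [select_channels()].
#' @param trial_policy `"all"` (default): cross-validate over all
#'   non-rejected word-aligned trials; `"evaluation"`: restrict to the
#'   held-out evaluation words.
#' @param evaluation_ids Word ids for the `"evaluation"` policy.
#' @return `NULL` (with a message) when the region has no retained
#'   channels; otherwise an object of class `group_matrix`: `matrices`
#'   (list of 10 trials x channels matrices), `labels` (factor), `word_ids`,
#'   `channels`, `area`, `hemisphere`.
#' @export
build_group_matrix <- function(features, area, hemisphere, retained_channels,
                               trial_policy = c("all", "evaluation"),
                               evaluation_ids = NULL) {
  stopifnot(inherits(features, "feature_tensor"))
  trial_policy <- match.arg(trial_policy)
  ch <- features$channels
  in_area <- ch$brodmann_area == as.character(area) &
    ch$hemisphere == hemisphere & ch$channel_id %in% retained_channels
  if (!any(in_area)) {
    message(sprintf("area %s/%s: no retained channels; skipped",
                    area, hemisphere))
    return(NULL)
  }
  cols <- which(in_area)
  cols <- cols[order(ch$subject_id[cols], ch$channel_id[cols])]
  subs <- unique(ch$subject_id[cols])
  # intersection policy: a word must be clean in every contributing subject
  tr <- features$trials
  keep_words <- sort(unique(tr$word_id))
  for (s in subs) {
    ok <- tr$word_id[tr$subject_id == s & !tr$rejected]
    keep_words <- intersect(keep_words, ok)
  }
  if (trial_policy == "evaluation") {
    if (is.null(evaluation_ids))
      stop_config("evaluation policy requires evaluation_ids")
    keep_words <- intersect(keep_words, evaluation_ids)
  }
  keep_words <- sort(keep_words)
  cat_of <- tr$category[match(keep_words, tr$word_id)]
  mats <- lapply(seq_len(features$grid$n_windows), function(k) {
    m <- features$values[keep_words, cols, k, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = length(keep_words))
    colnames(m) <- ch$channel_id[cols]
    m
  })
  structure(list(matrices = mats, labels = factor(cat_of),
                 word_ids = keep_words, channels = ch$channel_id[cols],
                 area = as.character(area), hemisphere = hemisphere,
                 grid = features$grid),
            class = "group_matrix")
}

# R-side CV for the lda / rf backends (the svm backend runs in compiled
# code); same fold structure and within-fold standardization.
r_cv_curve <- function(mats, y01, fold, k, spec) {
  W <- length(mats)
  out <- matrix(NA_real_, W, k)
  for (w in seq_len(W)) {
    X <- mats[[w]]
    for (f in seq_len(k)) {
      tr <- fold != f
      te <- !tr
      if (!any(te) || length(unique(y01[tr])) < 2) next
      mu <- colMeans(X[tr, , drop = FALSE])
      s <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      s[s < 1e-12] <- 1
      Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, s, `/`)
      Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, s, `/`)
      pred <- if (spec$kind == "lda") {
        fit <- suppressWarnings(MASS::lda(Xtr, grouping = factor(y01[tr]),
                                          tol = 1e-8))
        as.integer(as.character(predict(fit, Xte)$class))
      } else {
        fit <- randomForest::randomForest(Xtr, y = factor(y01[tr]),
                                          ntree = spec$n_trees)
        as.integer(as.character(predict(fit, Xte)))
      }
      out[w, f] <- mean(pred == y01[te])
    }
  }
  out
}

#' Time-resolved group decoding
#'
#' Stratified k-fold cross-validated classification accuracy for each of
#' the 10 windows, averaged over folds; per-fold values are retained for
#' the permutation statistics. Deterministic given `seed`.
#'
#' @param gm A `group_matrix` from [build_group_matrix()].
#' @param spec A [classifier_spec()].
#' @param n_folds Cross-validation folds (default 5).
#' @param seed Seed for the fold draw (and stochastic backends).
#' @return An object of class `decoding_curve`: `accuracy` (length 10),
#'   `fold_acc` (10 x folds), `windows_ms`, `area`, `hemisphere`,
#'   `classifier`, `n_trials`.
#' @export
decode_timecourse <- function(gm, spec = classifier_spec(), n_folds = 5,
                              seed = 1) {
  stopifnot(inherits(gm, "group_matrix"))
  y01 <- as.integer(gm$labels == levels(gm$labels)[1])
  if (length(unique(y01)) < 2)
    stop("both categories must be present", call. = FALSE)
  fold <- with_seed(seed, make_stratified_folds(y01, n_folds))
  fa <- if (spec$kind == "svm") {
    cpp_cv_curve(gm$matrices, y01, fold, n_folds, spec$cost)
  } else {
    with_seed(spec$seed, r_cv_curve(gm$matrices, y01, fold, n_folds, spec))
  }
  structure(list(accuracy = rowMeans(fa, na.rm = TRUE), fold_acc = fa,
                 windows_ms = gm$grid$labels_ms, area = gm$area,
                 hemisphere = gm$hemisphere, classifier = spec$kind,
                 n_trials = length(y01)),
            class = "decoding_curve")
}

#' Compare classifier backends on one region
#'
#' Runs each classifier with the identical fold structure, reports the mean
#' 0-500 ms accuracy per backend, and tests every backend pair with
#' two-sided paired signed-rank tests across the (fold x window) accuracy
#' pairs, Benjamini-Hochberg corrected across pairs.
#'
#' @param gm A `group_matrix`.
#' @param specs List of [classifier_spec()] objects (>= 2).
#' @param n_folds Cross-validation folds.
#' @param seed Fold seed shared by all backends.
#' @return List with `summary` (data.frame: classifier, mean_accuracy) and
#'   `pairwise` (data.frame: a, b, mean_diff, p, q).
#' @export
compare_classifiers <- function(gm, specs, n_folds = 5, seed = 1) {
  if (length(specs) < 2) stop("need at least 2 classifier specs", call. = FALSE)
  curves <- lapply(specs, function(sp)
    decode_timecourse(gm, sp, n_folds = n_folds, seed = seed))
  kinds <- vapply(specs, function(sp) sp$kind, "")
  summ <- data.frame(classifier = kinds,
                     mean_accuracy = vapply(curves, function(cv)
                       mean(cv$accuracy), 0.0))
  pairs <- utils::combn(seq_along(specs), 2)
  res <- data.frame(a = kinds[pairs[1, ]], b = kinds[pairs[2, ]],
                    mean_diff = NA_real_, p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    xa <- as.vector(curves[[pairs[1, i]]]$fold_acc)
    xb <- as.vector(curves[[pairs[2, i]]]$fold_acc)
    ok <- is.finite(xa) & is.finite(xb)
    d <- xa[ok] - xb[ok]
    res$mean_diff[i] <- mean(d)
    res$p[i] <- if (all(d == 0)) 1 else
      suppressWarnings(stats::wilcox.test(xa[ok], xb[ok], paired = TRUE,
                                          exact = FALSE)$p.value)
  }
  res$q <- bh_fdr(res$p)$q
  list(summary = summ, pairwise = res)
}
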