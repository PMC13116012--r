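# Sliding-window feature extraction and leakage-controlled channel selection.

#' The 10-window sliding grid
#'
#' 100 ms windows advanced in 50 ms steps across the 0-500 ms prespeech
#' span: window k covers \[50(k-1), 50(k-1)+100) ms. Windows are labeled by
#' their centers (50k ms) by default, reconciling reported peak times of
#' 50-500 ms with window starts of 0-450 ms; start labeling is available.
#'
#' @param label `"center"` (default) or `"start"` window time labeling.
#' @return An object of class `window_grid` with fields `window_length_ms`,
#'   `step_ms`, `n_windows`, `starts_ms`, `labels_ms`.
#' @export
window_grid <- function(label = c("center", "start")) {
  label <- match.arg(label)
  starts <- seq(0, 450, by = 50)
  structure(list(window_length_ms = 100, step_ms = 50, n_windows = 10L,
                 starts_ms = starts,
                 labels_ms = if (label == "center") starts + 50 else starts,
                 label = label),
            class = "window_grid")
}

#' Windowed mean high-gamma features
#'
#' For every trial, channel and window, the arithmetic mean of the
#' baseline-normalized envelope over samples whose times fall in
#' \[50(k-1), 50(k-1)+100) ms (half-open).
#'
#' @param env An `envelope_dataset` (from [preprocess()]).
#' @param grid A [window_grid()].
#' @return An object of class `feature_tensor`: `values` (trials x channels
#'   x 10 array), `grid`, `channels`, `trials`.
#' @export
window_features <- function(env, grid = window_grid()) {
  stopifnot(inherits(env, "envelope_dataset"))
  last_end <- grid$starts_ms[grid$n_windows] + grid$window_length_ms
  if (env$times[1] > 0 || env$times[length(env$times)] < last_end - 1000 / env$sample_rate)
    stop_config("epoch does not cover [0, %g) ms", last_end)
  d <- dim(env$envelope)
  vals <- array(NA_real_, dim = c(d[1], d[2], grid$n_windows))
  for (k in seq_len(grid$n_windows)) {
    sel <- env$times >= grid$starts_ms[k] &
      env$times < grid$starts_ms[k] + grid$window_length_ms
    vals[, , k] <- colMeans(aperm(env$envelope[, , sel, drop = FALSE],
                                  c(3, 1, 2)), dims = 1)
  }
  structure(list(values = vals, grid = grid, channels = env$channels,
                 trials = env$trials, truth = env$truth),
            class = "feature_tensor")
}

#' Channel-selection configuration
#'
#' @param selection_fraction Fraction of trials reserved for channel
#'   selection (the rest are held out), default 0.70.
#' @param n_folds Stratified cross-validation folds, default 5.
#' @param retain_threshold Channels are retained when mean fold accuracy is
#'   strictly above this (chance = 0.50).
#' @param seed Seed for the split and fold draws.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(selection_fraction = 0.70, n_folds = 5,
                             retain_threshold = 0.50, seed = 1) {
  if (selection_fraction <= 0 || selection_fraction > 1)
    stop_config("selection_fraction must lie in (0, 1]")
  if (n_folds < 2) stop_config("need at least 2 folds")
  structure(list(selection_fraction = selection_fraction, n_folds = n_folds,
                 retain_threshold = retain_threshold, seed = as.integer(seed)),
            class = "selection_config")
}

#' Split words into selection and evaluation sets
#'
#' Stratified 70/30 split over the shared word list: per category,
#' floor(fraction x n) words go to the selection set, with the rounding
#' remainder distributed by largest fractional part (ties broken by seeded
#' draw). The two sets are disjoint and exhaustive; the same split applies
#' to every subject since words are aligned.
#'
#' @param trials Trial data.frame (`word_id`, `category`; multi-subject
#'   tables are reduced to unique words).
#' @param cfg A [selection_config()].
#' @return List with `selection_ids` and `evaluation_ids` (word ids).
#' @export
split_trials <- function(trials, cfg = selection_config()) {
  words <- unique(trials[, c("word_id", "category")])
  words <- words[order(words$word_id), ]
  tab <- table(words$category)
  if (length(tab) < 2 || any(tab < 2))
    stop("need at least 2 non-rejected trials per category", call. = FALSE)
  with_seed(cfg$seed, {
    f <- cfg$selection_fraction
    base <- floor(f * as.numeric(tab))
    extra_total <- round(f * nrow(words)) - sum(base)
    frac <- f * as.numeric(tab) - base
    # order categories by fractional remainder, random tie-break
    ord <- order(-frac, sample.int(length(tab)))
    add <- integer(length(tab))
    if (extra_total > 0) add[ord[seq_len(min(extra_total, length(tab)))]] <- 1L
    sel <- integer(0)
    for (i in seq_along(tab)) {
      cat_words <- words$word_id[words$category == names(tab)[i]]
      n_take <- min(base[i] + add[i], length(cat_words))
      sel <- c(sel, sample(cat_words, n_take))
    }
    list(selection_ids = sort(sel),
         evaluation_ids = sort(setdiff(words$word_id, sel)))
  })
}

#' Per-channel selection by cross-validated decoding
#'
#' Each channel is evaluated independently on the selection trials with
#' fivefold stratified cross-validated linear max-margin classification of
#' its 10 window features (features standardized within each training
#' fold); a channel is retained iff its mean fold accuracy strictly exceeds
#' the chance threshold (> 0.50). Evaluation trials never enter this stage.
#'
#' @param features A `feature_tensor`.
#' @param selection_ids Word ids reserved for selection (from
#'   [split_trials()]).
#' @param cfg A [selection_config()].
#' @return List with `retained` (channel ids), `accuracy` (named mean CV
#'   accuracy per channel).
#' @export
select_channels <- function(features, selection_ids, cfg = selection_config()) {
  stopifnot(inherits(features, "feature_tensor"))
  n_ch <- dim(features$values)[2]
  acc <- rep(NA_real_, n_ch)
  names(acc) <- features$channels$channel_id
  with_seed(cfg$seed, {
    for (ci in seq_len(n_ch)) {
      sub <- features$channels$subject_id[ci]
      tr <- features$trials[features$trials$subject_id == sub, ]
      tr <- tr[order(tr$word_id), ]
      use <- tr$word_id[tr$word_id %in% selection_ids & !tr$rejected]
      if (length(use) < 4) next
      y <- as.integer(tr$category[match(use, tr$word_id)] == "body")
      if (length(unique(y)) < 2) next
      k <- cfg$n_folds
      if (length(use) < k) {
        warning(sprintf("channel %s: folds reduced to %d trials",
                        names(acc)[ci], length(use)))
        k <- length(use)
      }
      X <- features$values[use, ci, , drop = TRUE]
      if (is.null(dim(X))) X <- matrix(X, nrow = length(use))
      fold <- make_stratified_folds(y, k)
      fa <- cpp_cv_fold_acc(X, y, fold, k, 1.0)
      acc[ci] <- mean(fa, na.rm = TRUE)
    }
  })
  list(retained = names(acc)[!is.na(acc) & acc > cfg$retain_threshold],
       accuracy = acc)
}
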