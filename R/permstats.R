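# Permutation-based significance for decoding curves: label-shuffle nulls,
# add-one empirical p values, Benjamini-Hochberg FDR across windows within
# each region, time-shuffle thresholds, and peak/trough identification.

#' Permutation-statistics configuration
#'
#' @param n_label_perms Label-shuffle draws (2,000 in the full analysis;
#'   500 is the reduced desk-scale mode).
#' @param n_time_perms Time-shuffle draws (default 1,000).
#' @param alpha FDR level.
#' @param tail `"upper"` for decoding peaks, `"lower"` for below-chance
#'   troughs.
#' @param time_quantile Pooled-null quantile defining the time-shuffle
#'   threshold.
#' @param seed Seed for the permutation streams.
#' @return An object of class `stats_config`.
#' @export
stats_config <- function(n_label_perms = 2000, n_time_perms = 1000,
                         alpha = 0.05, tail = c("upper", "lower"),
                         time_quantile = 0.95, seed = 1) {
  if (n_label_perms < 100 || n_time_perms < 100)
    stop_config("permutation counts below 100 are statistically meaningless")
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must lie in (0, 1)")
  structure(list(n_label_perms = as.integer(n_label_perms),
                 n_time_perms = as.integer(n_time_perms), alpha = alpha,
                 tail = match.arg(tail), time_quantile = time_quantile,
                 seed = as.integer(seed)),
            class = "stats_config")
}

#' Label-shuffle null distribution
#'
#' Each draw permutes the category labels uniformly at random and re-runs
#' the identical stratified-fold / classifier procedure over all windows,
#' yielding the null distribution of fold-mean accuracies.
#'
#' @param gm A `group_matrix`.
#' @param spec A [classifier_spec()].
#' @param B Number of draws (>= 100).
#' @param n_folds Cross-validation folds.
#' @param seed Seed for the permutation stream.
#' @return B x n_windows matrix of null fold-mean accuracies.
#' @export
label_shuffle_null <- function(gm, spec = classifier_spec(), B = 2000,
                               n_folds = 5, seed = 1) {
  stopifnot(inherits(gm, "group_matrix"))
  if (B < 100) stop_config("B must be >= 100")
  y01 <- as.integer(gm$labels == levels(gm$labels)[1])
  n <- length(y01)
  with_seed(seed, {
    labels <- matrix(0L, n, B)
    folds <- matrix(0L, n, B)
    for (b in seq_len(B)) {
      yp <- y01[sample.int(n)]
      labels[, b] <- yp
      folds[, b] <- make_stratified_folds(yp, n_folds)
    }
    if (spec$kind == "svm") {
      cpp_null_curves(gm$matrices, labels, folds, n_folds, spec$cost)
    } else {
      out <- matrix(NA_real_, B, length(gm$matrices))
      for (b in seq_len(B)) {
        fa <- r_cv_curve(gm$matrices, labels[, b], folds[, b], n_folds, spec)
        out[b, ] <- rowMeans(fa, na.rm = TRUE)
      }
      out
    }
  })
}

#' Add-one empirical p value
#'
#' `p = (1 + #(null >= observed)) / (B + 1)` for the upper tail (lower tail
#' analogous with <=); never returns 0 under finite permutations.
#'
#' @param observed Observed statistic.
#' @param null Vector of null draws (nonempty).
#' @param tail `"upper"` or `"lower"`.
#' @return p value in (0, 1\].
#' @export
empirical_p <- function(observed, null, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (length(null) == 0) stop("null distribution is empty", call. = FALSE)
  hits <- if (tail == "upper") sum(null >= observed) else sum(null <= observed)
  (1 + hits) / (length(null) + 1)
}

#' Benjamini-Hochberg step-up FDR
#'
#' Classic step-up procedure: reject the hypotheses with the `i` smallest p
#' values, where `i` is the largest index with `p_(i) <= i * alpha / m`;
#' q values are the monotone-enforced adjusted values capped at 1.
#'
#' @param p Vector of p values in (0, 1\].
#' @param alpha FDR level.
#' @return List with `rejected` (logical) and `q` (adjusted values).
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p values must lie in (0, 1]", call. = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  list(rejected = q <= alpha, q = q)
}

#' Time-shuffle threshold
#'
#' Each draw destroys the temporal alignment of the feature tensor by
#' permuting the window-index assignment independently for every trial
#' (consistently across channels), then re-runs the 10-window decoding with
#' a fresh fold draw; the threshold is the pooled `time_quantile`
#' percentile of all null accuracies for the region. A window whose
#' observed accuracy exceeds this threshold carries temporally specific
#' information: its accuracy cannot be reproduced once window identities
#' are scrambled within trials.
#'
#' @param gm A `group_matrix`.
#' @param spec A [classifier_spec()].
#' @param B Number of draws (>= 100).
#' @param n_folds Cross-validation folds.
#' @param time_quantile Pooled-null percentile.
#' @param seed Seed.
#' @return Scalar threshold (accuracy units).
#' @export
time_shuffle_threshold <- function(gm, spec = classifier_spec(), B = 1000,
                                   n_folds = 5, time_quantile = 0.95,
                                   seed = 1) {
  stopifnot(inherits(gm, "group_matrix"))
  if (B < 100) stop_config("B must be >= 100")
  y01 <- as.integer(gm$labels == levels(gm$labels)[1])
  W <- length(gm$matrices)
  n <- length(y01)
  with_seed(seed, {
    pool <- matrix(NA_real_, B, W)
    for (b in seq_len(B)) {
      # per-trial window permutation, consistent across channels
      sig <- vapply(seq_len(n), function(i) sample.int(W), integer(W))
      mats <- lapply(seq_len(W), function(k) {
        m <- gm$matrices[[1]]
        for (i in seq_len(n)) m[i, ] <- gm$matrices[[sig[k, i]]][i, ]
        m
      })
      fold <- make_stratified_folds(y01, n_folds)
      fa <- if (spec$kind == "svm") {
        cpp_cv_curve(mats, y01, fold, n_folds, spec$cost)
      } else r_cv_curve(mats, y01, fold, n_folds, spec)
      pool[b, ] <- rowMeans(fa, na.rm = TRUE)
    }
    as.numeric(stats::quantile(as.vector(pool), time_quantile, na.rm = TRUE))
  })
}

#' Peak or trough of a decoding curve among qualifying windows
#'
#' The peak is the maximum accuracy among windows passing both the FDR and
#' the time-shuffle criteria (the trough is the minimum among lower-tail
#' qualifiers); ties go to the earliest window; `NULL` when no window
#' qualifies.
#'
#' @param curve A `decoding_curve`.
#' @param qualifies Logical mask over windows (both criteria combined).
#' @param mode `"peak"` or `"trough"`.
#' @return List with `window`, `window_ms`, `value`, or `NULL`.
#' @export
find_extremes <- function(curve, qualifies, mode = c("peak", "trough")) {
  mode <- match.arg(mode)
  stopifnot(length(curve$accuracy) == length(qualifies))
  idx <- which(qualifies)
  if (length(idx) == 0) return(NULL)
  v <- curve$accuracy[idx]
  best <- if (mode == "peak") idx[which.max(v)] else idx[which.min(v)]
  # which.max/min take the first (earliest) index on exact ties
  list(window = best, window_ms = curve$windows_ms[best],
       value = curve$accuracy[best])
}

#' Full significance analysis for one region's decoding curve
#'
#' Combines the label-shuffle null (empirical p per window, BH-FDR across
#' the region's windows), the time-shuffle threshold, and upper/lower tail
#' peak and trough identification.
#'
#' @param gm A `group_matrix`.
#' @param spec A [classifier_spec()].
#' @param cfg A [stats_config()].
#' @param n_folds Cross-validation folds.
#' @return List with `table` (data.frame: one row per window with accuracy,
#'   p, q, sig_fdr, time_thresh, sig_time, p_lower, q_lower,
#'   sig_fdr_lower, is_peak, is_trough), `curve`, `peak`, `trough`.
#' @export
decode_significance <- function(gm, spec = classifier_spec(),
                                cfg = stats_config(), n_folds = 5) {
  curve <- decode_timecourse(gm, spec, n_folds = n_folds,
                             seed = stage_seed(cfg$seed, "decode"))
  null <- label_shuffle_null(gm, spec, B = cfg$n_label_perms,
                             n_folds = n_folds,
                             seed = stage_seed(cfg$seed, "label_null"))
  W <- length(curve$accuracy)
  p_up <- vapply(seq_len(W), function(w)
    empirical_p(curve$accuracy[w], null[, w], "upper"), 0.0)
  p_lo <- vapply(seq_len(W), function(w)
    empirical_p(curve$accuracy[w], null[, w], "lower"), 0.0)
  fdr_up <- bh_fdr(p_up, cfg$alpha)
  fdr_lo <- bh_fdr(p_lo, cfg$alpha)
  thr <- time_shuffle_threshold(gm, spec, B = cfg$n_time_perms,
                                n_folds = n_folds,
                                time_quantile = cfg$time_quantile,
                                seed = stage_seed(cfg$seed, "time_null"))
  sig_time_up <- curve$accuracy > thr
  # lower-tail temporal specificity mirrors the threshold below chance
  thr_lo <- 1 - thr
  sig_time_lo <- curve$accuracy < thr_lo
  peak <- find_extremes(curve, fdr_up$rejected & sig_time_up, "peak")
  trough <- find_extremes(curve, fdr_lo$rejected & sig_time_lo, "trough")
  tab <- data.frame(
    area = curve$area, hemisphere = curve$hemisphere,
    window = seq_len(W), window_ms = curve$windows_ms,
    accuracy = curve$accuracy, p = p_up, q = fdr_up$q,
    sig_fdr = fdr_up$rejected, time_thresh = thr, sig_time = sig_time_up,
    p_lower = p_lo, q_lower = fdr_lo$q, sig_fdr_lower = fdr_lo$rejected,
    is_peak = FALSE, is_trough = FALSE)
  if (!is.null(peak)) tab$is_peak[peak$window] <- TRUE
  if (!is.null(trough)) tab$is_trough[trough$window] <- TRUE
  list(table = tab, curve = curve, peak = peak, trough = trough,
       null = null, time_threshold = thr)
}
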