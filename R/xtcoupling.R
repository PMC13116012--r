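# Cross-temporal regression between region timecourses: 10 x 10 R^2 grids,
# permutation nulls with BH-FDR across the map, and seed-and-grow
# eight-connected cluster identification.

#' Cluster-identification configuration
#'
#' @param seed_threshold Minimum R^2 for a cluster seed (default 0.20).
#' @param grow_threshold Minimum R^2 for accreted neighbors (default 0.10).
#' @param connectivity 4 or 8 (default 8).
#' @param min_size Minimum cluster size in grid cells (default 5).
#' @param alpha FDR level; every member cell must satisfy q <= alpha.
#' @param n_perms Permutation draws for the null (default 1,000).
#' @param seed Seed for the permutation stream.
#' @return An object of class `cluster_config`.
#' @export
cluster_config <- function(seed_threshold = 0.20, grow_threshold = 0.10,
                           connectivity = 8, min_size = 5, alpha = 0.05,
                           n_perms = 1000, seed = 1) {
  if (grow_threshold > seed_threshold)
    stop_config("grow_threshold must not exceed seed_threshold")
  if (!connectivity %in% c(4, 8)) stop_config("connectivity must be 4 or 8")
  if (min_size < 1) stop_config("min_size must be >= 1")
  structure(list(seed_threshold = seed_threshold,
                 grow_threshold = grow_threshold,
                 connectivity = as.integer(connectivity),
                 min_size = as.integer(min_size), alpha = alpha,
                 n_perms = as.integer(n_perms), seed = as.integer(seed)),
            class = "cluster_config")
}

#' Region timecourse: channel-averaged window features per trial
#'
#' Per trial and window, the mean of the normalized high-gamma features
#' across the region's retained channels. Rows are words that are clean
#' (non-rejected) in every contributing subject; the category filter is
#' applied for category-specific scopes.
#'
#' @param features A `feature_tensor`.
#' @param area,hemisphere Region label and hemisphere.
#' @param retained_channels Channel ids retained by selection.
#' @param scope `"combined"`, `"body"`, or `"nonbody"`.
#' @return `NULL` (with a message) when the region has no retained
#'   channels; otherwise an object of class `region_timecourse`: `values`
#'   (trials x 10), `word_ids`, `categories`, `area`, `hemisphere`,
#'   `scope`.
#' @export
region_timecourse <- function(features, area, hemisphere, retained_channels,
                              scope = c("combined", "body", "nonbody")) {
  scope <- match.arg(scope)
  gm <- build_group_matrix(features, area, hemisphere, retained_channels)
  if (is.null(gm)) return(NULL)
  keep <- if (scope == "combined") seq_along(gm$word_ids) else
    which(as.character(gm$labels) == scope)
  vals <- vapply(gm$matrices, function(m)
    rowMeans(m[keep, , drop = FALSE]), numeric(length(keep)))
  if (length(keep) == 1) vals <- matrix(vals, nrow = 1)
  structure(list(values = vals, word_ids = gm$word_ids[keep],
                 categories = as.character(gm$labels)[keep],
                 area = gm$area, hemisphere = hemisphere, scope = scope,
                 windows_ms = gm$grid$labels_ms),
            class = "region_timecourse")
}

# Align two region timecourses on their common words (same order).
align_timecourses <- function(source, target) {
  common <- intersect(source$word_ids, target$word_ids)
  if (length(common) < 3)
    stop("fewer than 3 shared trials between source and target",
         call. = FALSE)
  s <- source; t <- target
  s$values <- source$values[match(common, source$word_ids), , drop = FALSE]
  t$values <- target$values[match(common, target$word_ids), , drop = FALSE]
  s$word_ids <- t$word_ids <- common
  s$categories <- source$categories[match(common, source$word_ids)]
  t$categories <- s$categories
  list(source = s, target = t)
}

#' Cross-temporal R^2 grid
#'
#' Cell (i, j) is the coefficient of determination (1 - SSE/SST) of the
#' ordinary least-squares simple regression of the target's window-j values
#' on the source's window-i values across trials — equal to the squared
#' Pearson correlation of the two columns. Zero-variance predictors give
#' R^2 = 0 and are flagged.
#'
#' @param source,target `region_timecourse` objects over the same trial set
#'   and ordering (or plain trials x windows matrices).
#' @return 10 x 10 matrix (source window x target window) with attribute
#'   `"degenerate"` marking zero-variance cells.
#' @export
cross_temporal_r2 <- function(source, target) {
  S <- if (inherits(source, "region_timecourse")) source$values else source
  T_ <- if (inherits(target, "region_timecourse")) target$values else target
  if (nrow(S) != nrow(T_))
    stop("source and target must share the same trial set", call. = FALSE)
  n <- nrow(S)
  if (n < 3) stop("fewer than 3 trials", call. = FALSE)
  Sc <- sweep(S, 2, colMeans(S))
  Tc <- sweep(T_, 2, colMeans(T_))
  vs <- colSums(Sc^2)
  vt <- colSums(Tc^2)
  cross <- crossprod(Sc, Tc)                     # nS x nT
  denom <- outer(vs, vt)
  deg <- outer(vs < 1e-24, vt < 1e-24, `|`)
  denom[deg] <- 1
  r2 <- cross^2 / denom
  r2[deg] <- 0
  r2 <- pmin(pmax(r2, 0), 1)
  attr(r2, "degenerate") <- deg
  r2
}

#' Permutation null for a coupling map
#'
#' Each draw shuffles the trial correspondence between source and target
#' (rows of the target permuted), breaking the coupling while preserving
#' both margins; per-cell empirical p uses the add-one upper-tail formula,
#' then BH-FDR is applied across the 100 cells of the map.
#'
#' @param source,target Aligned `region_timecourse` objects or matrices.
#' @param cfg A [cluster_config()].
#' @return List with `p` and `q` (10 x 10 grids) and `r2` (observed grid).
#' @export
coupling_null <- function(source, target, cfg = cluster_config()) {
  if (cfg$n_perms < 100) stop_config("n_perms must be >= 100")
  S <- if (inherits(source, "region_timecourse")) source$values else source
  T_ <- if (inherits(target, "region_timecourse")) target$values else target
  obs <- cross_temporal_r2(S, T_)
  n <- nrow(T_)
  with_seed(cfg$seed, {
    exceed <- matrix(0L, nrow(obs), ncol(obs))
    for (b in seq_len(cfg$n_perms)) {
      r2p <- cross_temporal_r2(S, T_[sample.int(n), , drop = FALSE])
      exceed <- exceed + (r2p >= obs)
    }
    p <- (1 + exceed) / (cfg$n_perms + 1)
    q <- matrix(bh_fdr(as.vector(p), cfg$alpha)$q, nrow(p), ncol(p))
    list(p = p, q = q, r2 = obs)
  })
}

neighbors_of <- function(i, j, nr, nc, connectivity) {
  if (connectivity == 8) {
    di <- c(-1, -1, -1, 0, 0, 1, 1, 1)
    dj <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    di <- c(-1, 1, 0, 0)
    dj <- c(0, 0, -1, 1)
  }
  ii <- i + di; jj <- j + dj
  ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
  cbind(ii[ok], jj[ok])
}

#' Seed-and-grow cluster identification on a significance grid
#'
#' Seeds are cells with q <= alpha and R^2 >= `seed_threshold`; each seed
#' is grown by repeated accretion of connected cells with q <= alpha and
#' R^2 >= `grow_threshold`; grown sets that overlap (share a connected
#' region) merge; clusters smaller than `min_size` cells are dropped.
#' Returned sorted by peak R^2, descending.
#'
#' @param r2 10 x 10 (or any) R^2 grid.
#' @param q Matching grid of FDR-adjusted q values.
#' @param cfg A [cluster_config()].
#' @return List of `cluster` objects: `cells` (two-column matrix of
#'   source/target window indices), `size`, `peak_r2`, `peak_cell`,
#'   `bbox` (source range, target range).
#' @export
find_clusters <- function(r2, q, cfg = cluster_config()) {
  stopifnot(all(dim(r2) == dim(q)))
  nr <- nrow(r2); nc <- ncol(r2)
  sig <- q <= cfg$alpha
  seedm <- sig & r2 >= cfg$seed_threshold
  growm <- sig & r2 >= cfg$grow_threshold
  visited <- matrix(FALSE, nr, nc)
  clusters <- list()
  for (s_i in which(seedm)) {
    if (visited[s_i]) next
    # flood fill through the grow-eligible mask from this seed
    i0 <- (s_i - 1) %% nr + 1
    j0 <- (s_i - 1) %/% nr + 1
    stack <- list(c(i0, j0))
    member <- matrix(FALSE, nr, nc)
    member[i0, j0] <- TRUE
    visited[i0, j0] <- TRUE
    while (length(stack) > 0) {
      cell <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      nb <- neighbors_of(cell[1], cell[2], nr, nc, cfg$connectivity)
      for (r in seq_len(nrow(nb))) {
        ii <- nb[r, 1]; jj <- nb[r, 2]
        if (!member[ii, jj] && growm[ii, jj]) {
          member[ii, jj] <- TRUE
          visited[ii, jj] <- TRUE
          stack[[length(stack) + 1]] <- c(ii, jj)
        }
      }
    }
    cells <- which(member, arr.ind = TRUE)
    if (nrow(cells) < cfg$min_size) next
    vals <- r2[member]
    pk <- which.max(vals)
    clusters[[length(clusters) + 1]] <- structure(list(
      cells = unname(cells), size = nrow(cells), peak_r2 = max(vals),
      peak_cell = unname(cells[pk, ]),
      bbox = list(source = range(cells[, 1]), target = range(cells[, 2]))),
      class = "cluster")
  }
  if (length(clusters) > 1)
    clusters <- clusters[order(-vapply(clusters, function(cl) cl$peak_r2, 0.0))]
  clusters
}

#' Full coupling map for a source-target region pair
#'
#' Builds the aligned timecourses for one scope, computes the R^2 grid, the
#' permutation null with per-map FDR, and the surviving clusters.
#'
#' @param features A `feature_tensor`.
#' @param source_area,source_hemisphere,target_area,target_hemisphere Pair
#'   definition.
#' @param retained_channels Channel ids retained by selection.
#' @param scope `"combined"`, `"body"`, or `"nonbody"`.
#' @param cfg A [cluster_config()].
#' @return `NULL` when either region has no retained channels; otherwise an
#'   object of class `coupling_map`: `r2`, `p`, `q` (10 x 10 grids),
#'   `clusters`, pair metadata and `n_trials`.
#' @export
coupling_map <- function(features, source_area, source_hemisphere,
                         target_area, target_hemisphere, retained_channels,
                         scope = c("combined", "body", "nonbody"),
                         cfg = cluster_config()) {
  scope <- match.arg(scope)
  src <- region_timecourse(features, source_area, source_hemisphere,
                           retained_channels, scope)
  tgt <- region_timecourse(features, target_area, target_hemisphere,
                           retained_channels, scope)
  if (is.null(src) || is.null(tgt)) return(NULL)
  al <- align_timecourses(src, tgt)
  nl <- coupling_null(al$source, al$target, cfg)
  structure(list(r2 = nl$r2, p = nl$p, q = nl$q,
                 clusters = find_clusters(nl$r2, nl$q, cfg),
                 source_area = as.character(source_area),
                 source_hemisphere = source_hemisphere,
                 target_area = as.character(target_area),
                 target_hemisphere = target_hemisphere, scope = scope,
                 n_trials = nrow(al$source$values),
                 windows_ms = src$windows_ms),
            class = "coupling_map")
}

#' Aligned decoding / activity traces for significant pairs
#'
#' For each source-target pair, emits a tidy table of window-wise mean
#' high-gamma amplitude (across trials and channels), decoding accuracy,
#' and the cluster's source/target window spans — the ingredients of the
#' aligned-trace comparison plots.
#'
#' @param curves Named list of `decoding_curve` objects, keyed
#'   `"area/hemisphere"`.
#' @param timecourses Named list of `region_timecourse` objects, same keys.
#' @param pairs List of pairs: each a list with `source`, `target` (keys
#'   into the two lists) and optionally `cluster` (a `cluster` object).
#' @return data.frame with one row per pair x role x window: `pair`,
#'   `role`, `area_key`, `window_ms`, `mean_hg`, `accuracy`,
#'   `in_cluster_span`, `status`.
#' @export
aligned_trace_report <- function(curves, timecourses, pairs) {
  cols <- c("pair", "role", "area_key", "window_ms", "mean_hg", "accuracy",
            "in_cluster_span", "status")
  rows <- list()
  for (pi in seq_along(pairs)) {
    pr <- pairs[[pi]]
    for (role in c("source", "target")) {
      key <- pr[[role]]
      cv <- curves[[key]]
      tc <- timecourses[[key]]
      if (is.null(cv) || is.null(tc)) {
        rows[[length(rows) + 1]] <- data.frame(
          pair = pi, role = role, area_key = key,
          window_ms = NA_real_, mean_hg = NA_real_, accuracy = NA_real_,
          in_cluster_span = NA, status = "absent")
        next
      }
      span <- if (!is.null(pr$cluster)) {
        w <- if (role == "source") pr$cluster$bbox$source else
          pr$cluster$bbox$target
        seq(w[1], w[2])
      } else integer(0)
      rows[[length(rows) + 1]] <- data.frame(
        pair = pi, role = role, area_key = key,
        window_ms = cv$windows_ms,
        mean_hg = colMeans(tc$values),
        accuracy = cv$accuracy,
        in_cluster_span = seq_along(cv$accuracy) %in% span,
        status = "ok")
    }
  }
  if (length(rows) == 0)
    return(stats::setNames(data.frame(matrix(ncol = length(cols), nrow = 0)),
                           cols))
  do.call(rbind, rows)
}
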