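# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; oracles are deliberately written as
# brute-force / closed-form routines independent of the package internals.

# Desk-scale generator config: one subject, short epoch that still covers
# the baseline (-300..0) and the feature span (0..550).
quick_cfg <- function(..., seed = 1) {
  args <- list(...)
  defaults <- list(n_subjects = 1, epoch_ms = c(-400, 700), ied_rate = 0,
                   seed = seed)
  for (nm in names(defaults))
    if (!nm %in% names(args)) args[[nm]] <- defaults[[nm]]
  do.call(synth_config, args)
}

# Cache one small preprocessed dataset per test run (several tests share it).
.fixture_cache <- new.env(parent = emptyenv())
small_pipeline_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    cfg <- quick_cfg(
      areas = data.frame(brodmann_area = c("9", "40"), hemisphere = "L",
                         stringsAsFactors = FALSE),
      channels_per_area = 4,
      effects = planted_effect("9", "L", c(150, 250), 2.0),
      seed = 42)
    ds <- generate_dataset(cfg)
    env <- preprocess(ds)
    feats <- window_features(env)
    .fixture_cache$small <- list(cfg = cfg, ds = ds, env = env, feats = feats)
  }
  .fixture_cache$small
}

# Build a feature_tensor directly from an array, skipping the signal level.
make_feature_tensor <- function(values, categories,
                                subject_id = "S01",
                                brodmann_area = "9", hemisphere = "L") {
  n_tr <- dim(values)[1]
  n_ch <- dim(values)[2]
  channels <- data.frame(
    channel_id = sprintf("%s_t%02d", subject_id, seq_len(n_ch)),
    subject_id = subject_id,
    hemisphere = rep_len(hemisphere, n_ch),
    brodmann_area = rep_len(brodmann_area, n_ch),
    impedance_kohm = 5, is_bad = FALSE, stringsAsFactors = FALSE)
  trials <- data.frame(
    trial_id = sprintf("%s_w%02d", subject_id, seq_len(n_tr)),
    subject_id = subject_id, word_id = seq_len(n_tr),
    category = categories, speech_onset_ms = 881, rejected = FALSE,
    stringsAsFactors = FALSE)
  structure(list(values = values, grid = window_grid(), channels = channels,
                 trials = trials,
                 truth = list(effects = list(), couplings = list())),
            class = "feature_tensor")
}

# Group matrix straight from a list of per-window matrices.
make_gm <- function(mats, labels, area = "9", hemisphere = "L") {
  structure(list(matrices = mats, labels = factor(labels),
                 word_ids = seq_len(nrow(mats[[1]])),
                 channels = paste0("c", seq_len(ncol(mats[[1]]))),
                 area = area, hemisphere = hemisphere, grid = window_grid()),
            class = "group_matrix")
}

# Random two-class feature matrices: `effect` added to the body rows of the
# listed windows.
random_gm <- function(n = 34, p = 6, effect = 0, windows = integer(0),
                      n_body = n %/% 2) {
  labels <- rep(c("body", "nonbody"), c(n_body, n - n_body))
  mats <- lapply(1:10, function(k) {
    m <- matrix(rnorm(n * p), n, p)
    if (k %in% windows) m[labels == "body", ] <- m[labels == "body", ] + effect
    m
  })
  make_gm(mats, labels)
}

# Independent envelope oracle: binary FFT band mask, rectification (scaled
# by pi/2, the inverse mean of |sin|), no analytic signal machinery.
oracle_envelope <- function(x, fs, band = c(70, 170)) {
  n <- length(x)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  mask <- as.numeric(f >= band[1] & f <= band[2])
  xb <- Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
  abs(xb) * pi / 2
}

# Window-mean oracle envelope for one trial/channel over one time window.
oracle_window_mean <- function(ds, trial_row, channel, window_ms) {
  word <- ds$trials$word_id[trial_row]
  env <- oracle_envelope(ds$signals[word, channel, ], ds$sample_rate)
  sel <- ds$times >= window_ms[1] & ds$times < window_ms[2]
  mean(env[sel])
}

# Pooled-SD Cohen's d.
cohens_d <- function(x, g) {
  a <- x[g]; b <- x[!g]
  (mean(a) - mean(b)) / sqrt((stats::var(a) + stats::var(b)) / 2)
}

# Brute-force Benjamini-Hochberg step-up, straight from the definition.
bh_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  crit <- seq_len(m) * alpha / m
  k <- which(ps <= crit)
  rejected <- logical(m)
  if (length(k) > 0) rejected[o[seq_len(max(k))]] <- TRUE
  q_sorted <- rev(cummin(rev(pmin(m * ps / seq_len(m), 1))))
  q <- numeric(m)
  q[o] <- q_sorted
  list(rejected = rejected, q = q)
}

# Exhaustive two-tier connected-components cluster oracle on a grid, using
# igraph components over the grow-eligible cells.
cluster_oracle <- function(r2, q, cfg) {
  nr <- nrow(r2); nc <- ncol(r2)
  sig <- q <= cfg$alpha
  growm <- sig & r2 >= cfg$grow_threshold
  seedm <- sig & r2 >= cfg$seed_threshold
  cells <- which(growm, arr.ind = TRUE)
  if (nrow(cells) == 0) return(list())
  adj <- function(a, b) {
    di <- abs(cells[a, 1] - cells[b, 1])
    dj <- abs(cells[a, 2] - cells[b, 2])
    if (cfg$connectivity == 8) max(di, dj) == 1 else di + dj == 1
  }
  edges <- c()
  if (nrow(cells) > 1)
    for (a in 1:(nrow(cells) - 1)) for (b in (a + 1):nrow(cells))
      if (adj(a, b)) edges <- c(edges, a, b)
  g <- igraph::make_empty_graph(n = nrow(cells), directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  out <- list()
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    mem <- cells[idx, , drop = FALSE]
    has_seed <- any(seedm[mem])
    if (!has_seed || nrow(mem) < cfg$min_size) next
    out[[length(out) + 1]] <- mem[order(mem[, 1], mem[, 2]), , drop = FALSE]
  }
  out
}

# Canonical sortable representation of a cluster cell set.
cell_key <- function(cells) paste(sort(paste(cells[, 1], cells[, 2])),
                                  collapse = ";")
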