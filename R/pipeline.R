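# End-to-end orchestration: synth -> preprocess -> features -> selection ->
# group decoding -> permutation statistics -> cross-temporal coupling ->
# report tables, from a single config with counter-based seed fan-out.

#' Pipeline configuration
#'
#' @param synth A [synth_config()] for self-contained runs, or `NULL` to
#'   start from `input_dir`.
#' @param input_dir Dataset container directory (used when `synth` is
#'   `NULL`).
#' @param out_dir Output directory for the result tables.
#' @param preprocess A [preprocess_config()].
#' @param selection A [selection_config()].
#' @param stats A [stats_config()].
#' @param cluster A [cluster_config()].
#' @param classifiers List of [classifier_spec()]s; the first is the main
#'   backend, the rest enter the classifier comparison.
#' @param pairs `"auto"` (enumerate early-source to late-target pairs among
#'   regions with significant peaks, early being peaks at <= 250 ms) or an
#'   explicit list of lists with `source_area`, `source_hemisphere`,
#'   `target_area`, `target_hemisphere`.
#' @param scopes Coupling scopes to compute.
#' @param trial_policy Trial policy for group decoding (see
#'   [build_group_matrix()]).
#' @param seed Global seed; fans out to per-stage seeds.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), input_dir = NULL,
                            out_dir = tempfile("prespeech_run_"),
                            preprocess = preprocess_config(),
                            selection = selection_config(),
                            stats = stats_config(),
                            cluster = cluster_config(),
                            classifiers = list(classifier_spec("svm")),
                            pairs = "auto",
                            scopes = c("combined", "body", "nonbody"),
                            trial_policy = "all",
                            seed = 1) {
  if (is.null(synth) && is.null(input_dir))
    stop_config("either synth or input_dir must be given")
  structure(list(synth = synth, input_dir = input_dir, out_dir = out_dir,
                 preprocess = preprocess, selection = selection,
                 stats = stats, cluster = cluster,
                 classifiers = classifiers, pairs = pairs, scopes = scopes,
                 trial_policy = trial_policy, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes the stages in fixed order and writes result tables under
#' `out_dir`: `curves.csv` (per region/window/classifier accuracies),
#' `significance.csv`, `peaks.csv` (one row per region, Table-3-shaped:
#' region, peak time, peak accuracy, q; regions without retained channels
#' appear with status `"skipped"`), `coupling_cells.csv`, `clusters.csv`,
#' `aligned_traces.csv` and `manifest.json`. A failing region is logged and
#' skipped, never fatal for the others.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed0 <- config$seed
  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  # --- data -----------------------------------------------------------------
  ds <- if (!is.null(config$synth)) {
    cfg <- config$synth
    cfg$seed <- stage_seed(seed0, "synth")
    generate_dataset(cfg)
  } else read_dataset(config$input_dir)

  env <- preprocess(ds, config$preprocess)
  feats <- window_features(env)

  sel_cfg <- config$selection
  sel_cfg$seed <- stage_seed(seed0, "split")
  split <- split_trials(env$trials, sel_cfg)
  selection <- select_channels(feats, split$selection_ids, sel_cfg)
  note("channels: %d total, %d excluded, %d retained",
       nrow(ds$channels), length(env$excluded_channels),
       length(selection$retained))
  note("trials rejected: %d of %d", sum(env$trials$rejected),
       nrow(env$trials))

  areas <- unique(env$channels[, c("brodmann_area", "hemisphere")])
  main_spec <- config$classifiers[[1]]
  st_cfg <- config$stats
  st_cfg$seed <- stage_seed(seed0, "stats")

  curves <- list()
  sig_tables <- list()
  peak_rows <- list()
  cmp_rows <- list()
  for (ai in seq_len(nrow(areas))) {
    a <- areas$brodmann_area[ai]
    h <- areas$hemisphere[ai]
    key <- paste0(a, "/", h)
    res <- tryCatch({
      gm <- build_group_matrix(feats, a, h, selection$retained,
                               trial_policy = config$trial_policy,
                               evaluation_ids = split$evaluation_ids)
      if (is.null(gm)) {
        peak_rows[[key]] <- data.frame(
          area = a, hemisphere = h, n_channels = 0, peak_time_ms = NA,
          peak_accuracy = NA, q = NA, status = "skipped")
        NULL
      } else {
        sg <- decode_significance(gm, main_spec, st_cfg)
        curves[[key]] <- sg$curve
        sig_tables[[key]] <- sg$table
        pk <- sg$peak
        peak_rows[[key]] <- data.frame(
          area = a, hemisphere = h, n_channels = length(gm$channels),
          peak_time_ms = if (is.null(pk)) NA else pk$window_ms,
          peak_accuracy = if (is.null(pk)) NA else pk$value,
          q = if (is.null(pk)) NA else sg$table$q[pk$window],
          status = if (is.null(pk)) "no_significant_peak" else "ok")
        if (length(config$classifiers) >= 2) {
          cc <- compare_classifiers(gm, config$classifiers,
                                    seed = stage_seed(seed0, "compare"))
          cc$summary$area <- a
          cc$summary$hemisphere <- h
          cmp_rows[[key]] <- cc$summary
        }
        gm
      }
    }, error = function(e) {
      note("area %s: failed (%s); skipped", key, conditionMessage(e))
      peak_rows[[key]] <- data.frame(
        area = a, hemisphere = h, n_channels = NA, peak_time_ms = NA,
        peak_accuracy = NA, q = NA, status = "error")
      NULL
    })
  }
  peaks <- do.call(rbind, peak_rows)
  rownames(peaks) <- NULL

  # --- coupling -------------------------------------------------------------
  cl_cfg <- config$cluster
  cl_cfg$seed <- stage_seed(seed0, "coupling")
  pair_list <- config$pairs
  if (identical(pair_list, "auto")) {
    ok <- peaks[peaks$status == "ok", , drop = FALSE]
    early <- ok[ok$peak_time_ms <= 250, , drop = FALSE]
    late <- ok[ok$peak_time_ms > 250, , drop = FALSE]
    pair_list <- list()
    if (nrow(early) > 0 && nrow(late) > 0)
      for (i in seq_len(nrow(early))) for (j in seq_len(nrow(late)))
        pair_list[[length(pair_list) + 1]] <- list(
          source_area = early$area[i], source_hemisphere = early$hemisphere[i],
          target_area = late$area[j], target_hemisphere = late$hemisphere[j])
  }
  maps <- list()
  for (pr in pair_list) for (sc in config$scopes) {
    mp <- tryCatch(
      coupling_map(feats, pr$source_area, pr$source_hemisphere,
                   pr$target_area, pr$target_hemisphere,
                   selection$retained, scope = sc, cfg = cl_cfg),
      error = function(e) {
        note("pair %s/%s -> %s/%s (%s) failed: %s", pr$source_area,
             pr$source_hemisphere, pr$target_area, pr$target_hemisphere,
             sc, conditionMessage(e))
        NULL
      })
    if (!is.null(mp))
      maps[[paste(pr$source_area, pr$source_hemisphere, pr$target_area,
                  pr$target_hemisphere, sc, sep = "_")]] <- mp
  }

  # --- aligned traces -------------------------------------------------------
  tc_all <- list()
  trace_pairs <- list()
  for (nm in names(maps)) {
    mp <- maps[[nm]]
    if (length(mp$clusters) == 0) next
    skey <- paste0(mp$source_area, "/", mp$source_hemisphere)
    tkey <- paste0(mp$target_area, "/", mp$target_hemisphere)
    for (k in c(skey, tkey)) if (is.null(tc_all[[k]])) {
      parts <- strsplit(k, "/")[[1]]
      tc_all[[k]] <- region_timecourse(feats, parts[1], parts[2],
                                       selection$retained)
    }
    trace_pairs[[length(trace_pairs) + 1]] <-
      list(source = skey, target = tkey, cluster = mp$clusters[[1]])
  }
  traces <- aligned_trace_report(curves, tc_all, trace_pairs)

  # --- tables ---------------------------------------------------------------
  wr <- function(df, name) utils::write.csv(
    df, file.path(config$out_dir, name), row.names = FALSE)
  curve_tab <- do.call(rbind, lapply(names(curves), function(k) {
    cv <- curves[[k]]
    folds <- cv$fold_acc
    colnames(folds) <- paste0("fold", seq_len(ncol(folds)))
    cbind(data.frame(area = cv$area, hemisphere = cv$hemisphere,
                     window_ms = cv$windows_ms, classifier = cv$classifier,
                     mean_accuracy = cv$accuracy),
          as.data.frame(folds))
  }))
  wr(curve_tab %||% data.frame(), "curves.csv")
  wr(do.call(rbind, sig_tables) %||% data.frame(), "significance.csv")
  wr(peaks, "peaks.csv")
  if (length(cmp_rows) > 0) wr(do.call(rbind, cmp_rows), "classifiers.csv")
  cells <- do.call(rbind, lapply(names(maps), function(nm) {
    mp <- maps[[nm]]
    cl_id <- matrix(NA_integer_, 10, 10)
    for (i in seq_along(mp$clusters))
      cl_id[mp$clusters[[i]]$cells] <- i
    data.frame(pair = nm, scope = mp$scope,
               source_window_ms = rep(mp$windows_ms, 10),
               target_window_ms = rep(mp$windows_ms, each = 10),
               r2 = as.vector(mp$r2), p = as.vector(mp$p),
               q = as.vector(mp$q), cluster_id = as.vector(cl_id))
  }))
  wr(cells %||% data.frame(), "coupling_cells.csv")
  cl_tab <- do.call(rbind, lapply(names(maps), function(nm) {
    mp <- maps[[nm]]
    if (length(mp$clusters) == 0) return(NULL)
    do.call(rbind, lapply(seq_along(mp$clusters), function(i) {
      cl <- mp$clusters[[i]]
      data.frame(pair = nm, cluster = i, size = cl$size,
                 peak_r2 = cl$peak_r2,
                 peak_source_window = cl$peak_cell[1],
                 peak_target_window = cl$peak_cell[2])
    }))
  }))
  wr(cl_tab %||% data.frame(), "clusters.csv")
  wr(traces, "aligned_traces.csv")

  manifest <- list(
    seed = seed0,
    stage_seeds = list(synth = stage_seed(seed0, "synth"),
                       split = stage_seed(seed0, "split"),
                       stats = stage_seed(seed0, "stats"),
                       coupling = stage_seed(seed0, "coupling")),
    n_channels_total = nrow(ds$channels),
    n_channels_excluded = length(env$excluded_channels),
    n_channels_retained = length(selection$retained),
    n_trials_rejected = sum(env$trials$rejected),
    n_areas = nrow(areas), n_maps = length(maps),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    log = log_lines)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(out_dir = config$out_dir, dataset = ds, envelope = env,
                 features = feats, split = split, selection = selection,
                 curves = curves, significance = sig_tables, peaks = peaks,
                 maps = maps, traces = traces, manifest = manifest))
}
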