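#!/usr/bin/env Rscript
# Stage 5: aligned traces and classifier comparison.
#
# For every pair with a surviving cluster, emits the aligned decoding /
# mean-HG trace table; also compares the linear max-margin, linear
# discriminant, and randomized-tree backends on the strongest region with
# paired signed-rank tests (BH-corrected). Writes aligned_traces.csv and
# classifiers.csv, then prints the workflow summary.

source("analysis/00_config.R")

st <- load_features_and_selection()
clusters <- read.csv(file.path(RESULTS_DIR, "clusters.csv"),
                     colClasses = c(pair = "character"))
peaks <- read.csv(file.path(RESULTS_DIR, "peaks.csv"),
                  colClasses = c(area = "character"))
scfg <- study_stats_config()

# curves and timecourses for the regions entering trace pairs
keys_needed <- character(0)
trace_pairs <- list()
if (nrow(clusters) > 0) {
  combined <- clusters[clusters$scope == "combined", , drop = FALSE]
  use <- if (nrow(combined) > 0) combined else clusters
  for (i in seq_len(nrow(use))) {
    pr <- strsplit(use$pair[i], "->")[[1]]
    skey <- sub("(.*)([LR])$", "\\1/\\2", pr[1])
    tkey <- sub("(.*)([LR])$", "\\1/\\2", pr[2])
    keys_needed <- union(keys_needed, c(skey, tkey))
    cl <- structure(list(
      cells = cbind(match(use$peak_source_ms[i], seq(50, 500, 50)),
                    match(use$peak_target_ms[i], seq(50, 500, 50))),
      size = use$size[i], peak_r2 = use$peak_r2[i],
      peak_cell = c(match(use$peak_source_ms[i], seq(50, 500, 50)),
                    match(use$peak_target_ms[i], seq(50, 500, 50))),
      bbox = list(source = rep(match(use$peak_source_ms[i],
                                     seq(50, 500, 50)), 2),
                  target = rep(match(use$peak_target_ms[i],
                                     seq(50, 500, 50)), 2))),
      class = "cluster")
    trace_pairs[[i]] <- list(source = skey, target = tkey, cluster = cl)
  }
}
curves <- list(); tcs <- list()
for (k in keys_needed) {
  parts <- strsplit(k, "/")[[1]]
  gm <- build_group_matrix(st$feats, parts[1], parts[2],
                           st$selection$retained)
  if (is.null(gm)) next
  curves[[k]] <- decode_timecourse(gm, classifier_spec("svm"),
                                   seed = prespeech:::stage_seed(GLOBAL_SEED,
                                                                "decode"))
  tcs[[k]] <- region_timecourse(st$feats, parts[1], parts[2],
                                st$selection$retained)
}
traces <- aligned_trace_report(curves, tcs, trace_pairs)
write.csv(traces, file.path(RESULTS_DIR, "aligned_traces.csv"),
          row.names = FALSE)

# classifier comparison on the region with the best peak
ok <- peaks[peaks$status == "ok", , drop = FALSE]
if (nrow(ok) > 0) {
  best <- ok[which.max(ok$peak_accuracy), ]
  gm <- build_group_matrix(st$feats, best$area, best$hemisphere,
                           st$selection$retained)
  cc <- compare_classifiers(gm, list(classifier_spec("svm"),
                                     classifier_spec("lda"),
                                     classifier_spec("rf")),
                            seed = prespeech:::stage_seed(GLOBAL_SEED,
                                                          "compare"))
  cc$summary$area <- best$area
  write.csv(cc$summary, file.path(RESULTS_DIR, "classifiers.csv"),
            row.names = FALSE)
  cat(sprintf("classifier comparison on BA %s/%s:\n", best$area,
              best$hemisphere))
  print(cc$summary, row.names = FALSE)
  cat("pairwise signed-rank q-values:",
      paste(sprintf("%s-vs-%s %.3f", cc$pairwise$a, cc$pairwise$b,
                    cc$pairwise$q), collapse = ", "), "\n")
}

cat("\n== workflow summary ==\n")
print(peaks[, c("area", "hemisphere", "peak_time_ms", "peak_accuracy",
                "q", "status")], row.names = FALSE)
if (nrow(clusters) > 0) {
  cat("\ncoupling clusters:\n")
  print(clusters, row.names = FALSE)
} else cat("\nno coupling clusters survived\n")
cat("\nwrote aligned_traces.csv and classifiers.csv under", RESULTS_DIR, "\n")
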