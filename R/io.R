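# Dataset container: a directory holding the signal array (RDS) plus
# plain-text metadata (TSV) and a JSON header, so datasets round-trip
# between pipeline stages and channel metadata stays greppable.

#' Write a dataset container
#'
#' Writes `signals.rds` (or `envelope.rds`), `channels.tsv`, `trials.tsv`
#' and `meta.json` into `dir`.
#'
#' @param dataset A `raw_dataset` or `envelope_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  is_env <- inherits(dataset, "envelope_dataset")
  saveRDS(if (is_env) dataset$envelope else dataset$signals,
          file.path(dir, if (is_env) "envelope.rds" else "signals.rds"))
  utils::write.table(dataset$channels, file.path(dir, "channels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(dataset$trials, file.path(dir, "trials.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(class = class(dataset), sample_rate = dataset$sample_rate,
               epoch_ms = dataset$epoch_ms,
               baseline_ms = dataset$baseline_ms %||% NULL,
               excluded_channels = dataset$excluded_channels %||% character(0))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a dataset container written by [write_dataset()]
#'
#' @param dir Container directory.
#' @return A `raw_dataset` or `envelope_dataset`.
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  is_env <- "envelope_dataset" %in% meta$class
  arr <- readRDS(file.path(dir, if (is_env) "envelope.rds" else "signals.rds"))
  channels <- utils::read.delim(file.path(dir, "channels.tsv"),
                                colClasses = c(brodmann_area = "character"))
  trials <- utils::read.delim(file.path(dir, "trials.tsv"))
  fs <- meta$sample_rate
  times <- meta$epoch_ms[1] + (seq_len(dim(arr)[3]) - 1) * 1000 / fs
  out <- list(channels = channels, trials = trials, sample_rate = fs,
              epoch_ms = meta$epoch_ms, times = times,
              truth = list(effects = list(), couplings = list()))
  if (is_env) {
    out$envelope <- arr
    out$baseline_ms <- meta$baseline_ms
    out$excluded_channels <- as.character(unlist(meta$excluded_channels))
    class(out) <- "envelope_dataset"
  } else {
    out$signals <- arr
    class(out) <- "raw_dataset"
  }
  out
}
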