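#' Tidy long-format table of decoding results
#'
#' @param results a single `decoding_result`, a `valid`/`invalid` pair
#'   from [run_decoding_suite()], or a list of such pairs (one per
#'   subject).
#' @return data frame with columns `subject`, `analysis`, `validity`,
#'   `time_s`, `accuracy`.
#' @export
decoding_to_table <- function(results) {
  flatten <- function(x) {
    if (inherits(x, "decoding_result")) return(list(x))
    do.call(c, lapply(x, flatten))
  }
  do.call(rbind, lapply(flatten(results), function(r) {
    data.frame(subject = r$subject_id, analysis = r$analysis,
               validity = r$validity, time_s = r$times_s,
               accuracy = r$accuracy)
  }))
}

#' Write a tidy table to a tab-separated file
#'
#' @param table a data frame (e.g. from [decoding_to_table()],
#'   [bin_decoding()] or [summarize_design()]'s `cell_counts`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tidy_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save or load epochs
#'
#' Epochs are stored as a single R serialization (array, time axis,
#' metadata and rejection mask together); the events table alone can be
#' exchanged with other tools via [write_events_tsv()].
#'
#' @param ep an `eeg_epochs` object.
#' @param path file path (`.rds`).
#' @return `save_epochs` returns `path` invisibly; `load_epochs` the
#'   `eeg_epochs` object.
#' @export
save_epochs <- function(ep, path) {
  stopifnot(inherits(ep, "eeg_epochs"))
  saveRDS(ep, path)
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  ep <- readRDS(path)
  stopifnot(inherits(ep, "eeg_epochs"))
  ep
}
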