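#' Write / read a continuous recording
#'
#' Portable plain-text container: a directory holding `signal.tsv` (one row
#' per sample, one column per channel), `events.csv` and `meta.json` (the
#' sampling rate). Event sample indices are 0-based.
#'
#' @param rec a [continuous_recording()].
#' @param dir directory path (created if missing).
#' @return `write_recording` returns `dir` invisibly; `read_recording`
#'   returns the [continuous_recording()].
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "continuous_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(data.table::as.data.table(rec$signal),
                     file.path(dir, "signal.tsv"), sep = "\t")
  data.table::fwrite(rec$events, file.path(dir, "events.csv"))
  jsonlite::write_json(list(fs = rec$fs, kind = "continuous_recording"),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  sig <- as.matrix(data.table::fread(file.path(dir, "signal.tsv"), sep = "\t"))
  dimnames(sig) <- NULL
  events <- as.data.frame(data.table::fread(file.path(dir, "events.csv")))
  continuous_recording(sig, meta$fs, events)
}

#' Write / read an epoch set
#'
#' Directory with `epochs.tsv` (one row per epoch, `T * C` columns in
#' time-major order), `meta.csv` (per-epoch labels and stimulus metadata)
#' and `meta.json` (T, C, fs).
#'
#' @param x an [epoch_set()].
#' @param dir directory path.
#' @export
write_epochs <- function(x, dir) {
  stopifnot(inherits(x, "epoch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(x$epochs)
  flat <- matrix(x$epochs, nrow = d[1])
  data.table::fwrite(data.table::as.data.table(flat),
                     file.path(dir, "epochs.tsv"), sep = "\t")
  data.table::fwrite(data.frame(label = x$labels, code = x$codes,
                                character_index = x$character_index,
                                repetition_index = x$repetition_index),
                     file.path(dir, "meta.csv"))
  jsonlite::write_json(list(n_samples = d[2], n_channels = d[3], fs = x$fs,
                            kind = "epoch_set"),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  flat <- as.matrix(data.table::fread(file.path(dir, "epochs.tsv"), sep = "\t"))
  md <- as.data.frame(data.table::fread(file.path(dir, "meta.csv")))
  epochs <- array(flat, c(nrow(flat), meta$n_samples, meta$n_channels))
  epoch_set(epochs, md$label, md$code, md$character_index,
            md$repetition_index, meta$fs)
}
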