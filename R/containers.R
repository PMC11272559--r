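#' Continuous multichannel EEG recording
#'
#' Bundles a multichannel signal with its sampling rate and a table of
#' stimulus events. Event positions are stored as 0-based sample indices
#' (`sample_index = round(event_time * fs)`), which keeps index arithmetic
#' under decimation exact.
#'
#' @param signal numeric matrix, time x channels, in microvolts.
#' @param fs sampling rate in Hz.
#' @param events data.frame with columns `sample_index` (0-based), `code`
#'   (1-6 rows, 7-12 columns for the speller; 0 for RSVP), `is_target`
#'   (0/1), `character_index`, `repetition_index` (NA for RSVP).
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(signal, fs, events) {
  assert_that(is.matrix(signal) && is.numeric(signal), "signal must be a numeric matrix")
  assert_that(is_scalar(fs) && fs > 0, "fs must be a positive scalar")
  needed <- c("sample_index", "code", "is_target", "character_index", "repetition_index")
  assert_that(is.data.frame(events) && all(needed %in% names(events)),
              "events must contain columns ", paste(needed, collapse = ", "))
  assert_that(all(events$sample_index >= 0) && all(events$sample_index < nrow(signal)),
              "event sample_index out of signal range")
  structure(list(signal = signal, fs = fs, events = as.data.frame(events)),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d samples x %d channels @ %g Hz (%.1f s), %d events (%d targets)\n",
              nrow(x$signal), ncol(x$signal), x$fs, nrow(x$signal) / x$fs,
              nrow(x$events), sum(x$events$is_target)))
  invisible(x)
}

#' Stack of stimulus-locked epochs
#'
#' @param epochs numeric array n x T x C (epochs, samples, channels).
#' @param labels integer vector of 0/1 target labels, length n.
#' @param codes,character_index,repetition_index per-epoch stimulus metadata.
#' @param fs sampling rate in Hz.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, labels, codes, character_index, repetition_index, fs) {
  assert_that(is.array(epochs) && length(dim(epochs)) == 3, "epochs must be an n x T x C array")
  n <- dim(epochs)[1]
  assert_that(length(labels) == n, "labels length must match epoch count")
  assert_that(all(labels %in% c(0, 1)), "labels must be 0/1")
  for (v in list(codes, character_index, repetition_index))
    assert_that(length(v) == n, "per-epoch metadata length must match epoch count")
  structure(list(epochs = epochs, labels = as.integer(labels), codes = codes,
                 character_index = character_index,
                 repetition_index = repetition_index, fs = fs),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %d epochs of %d samples x %d channels @ %g Hz (%d targets / %d non-targets)\n",
              d[1], d[2], d[3], x$fs, sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

#' Subset an epoch set by epoch index
#' @param x an [epoch_set()].
#' @param idx integer or logical index over epochs.
#' @export
subset_epochs <- function(x, idx) {
  stopifnot(inherits(x, "epoch_set"))
  epoch_set(x$epochs[idx, , , drop = FALSE], x$labels[idx], x$codes[idx],
            x$character_index[idx], x$repetition_index[idx], x$fs)
}

#' Per-epoch feature vectors
#'
#' @param features numeric matrix n x f (one feature vector per epoch).
#' @param labels 0/1 target labels.
#' @param codes,character_index,repetition_index per-epoch stimulus metadata.
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(features, labels, codes = rep(NA_integer_, nrow(features)),
                        character_index = rep(NA_integer_, nrow(features)),
                        repetition_index = rep(NA_integer_, nrow(features))) {
  assert_that(is.matrix(features) && is.numeric(features), "features must be a numeric matrix")
  n <- nrow(features)
  assert_that(length(labels) == n, "labels length must match feature rows")
  structure(list(features = features, labels = as.integer(labels), codes = codes,
                 character_index = character_index,
                 repetition_index = repetition_index),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d x %d (%d targets)\n", nrow(x$features),
              ncol(x$features), sum(x$labels == 1, na.rm = TRUE)))
  invisible(x)
}

#' @rdname subset_epochs
#' @export
subset_features <- function(x, idx) {
  stopifnot(inherits(x, "feature_set"))
  feature_set(x$features[idx, , drop = FALSE], x$labels[idx], x$codes[idx],
              x$character_index[idx], x$repetition_index[idx])
}

#' Concatenate two feature sets row-wise
#' @param a,b [feature_set()] objects with matching feature dimension.
#' @export
combine_features <- function(a, b) {
  stopifnot(inherits(a, "feature_set"), inherits(b, "feature_set"))
  assert_that(ncol(a$features) == ncol(b$features), "feature dimensions differ")
  feature_set(rbind(a$features, b$features), c(a$labels, b$labels),
              c(a$codes, b$codes), c(a$character_index, b$character_index),
              c(a$repetition_index, b$repetition_index))
}
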