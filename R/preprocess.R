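#' Zero-phase band-pass filter a recording
#'
#' Cascaded Butterworth high-pass and low-pass sections (4th order each by
#' default), applied forward-backward per channel so that the filter is
#' zero-phase and does not displace ERP peak latencies.
#'
#' @param rec a [continuous_recording()].
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order Butterworth order of each section.
#' @return The filtered [continuous_recording()] (events unchanged).
#' @export
bandpass_filter <- function(rec, low, high, order = 4) {
  stopifnot(inherits(rec, "continuous_recording"))
  assert_that(is_scalar(low) && is_scalar(high) && low > 0 && low < high &&
                high < rec$fs / 2,
              "band edges must satisfy 0 < low < high < fs/2")
  nyq <- rec$fs / 2
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  sig <- apply(rec$signal, 2, function(x)
    signal::filtfilt(lp, signal::filtfilt(hp, x)))
  continuous_recording(sig, rec$fs, rec$events)
}

#' Downsample a recording by an integer factor
#'
#' Applies an anti-aliasing low-pass (8th-order Butterworth at 80% of the
#' target Nyquist, forward-backward) before keeping every `factor`-th
#' sample. Event sample indices are remapped by the same factor
#' (`floor(sample_index / factor)`, exact for indices that are multiples of
#' the factor).
#'
#' @param rec a [continuous_recording()].
#' @param target_fs target sampling rate; `fs / target_fs` must be an integer.
#' @return The decimated [continuous_recording()].
#' @export
downsample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "continuous_recording"))
  assert_that(is_scalar(target_fs) && target_fs > 0, "target_fs must be positive")
  factor <- rec$fs / target_fs
  assert_that(abs(factor - round(factor)) < 1e-9 && factor >= 1,
              "fs must be an integer multiple of target_fs")
  factor <- as.integer(round(factor))
  if (factor == 1L) return(rec)
  aa <- signal::butter(8, 0.8 / factor, type = "low")
  keep <- seq(1L, nrow(rec$signal), by = factor)
  sig <- apply(rec$signal, 2, function(x) signal::filtfilt(aa, x)[keep])
  events <- rec$events
  events$sample_index <- events$sample_index %/% factor
  continuous_recording(sig, target_fs, events)
}

#' Cut stimulus-locked epochs out of a recording
#'
#' Each event yields one epoch covering `[window[1], window[2])` seconds
#' relative to the event onset (`T = round(diff(window) * fs)` samples, so
#' a 665 ms window at 240 Hz gives 160 samples and a 0.7 s window at 64 Hz
#' gives 45). Events whose window would run past either end of the
#' recording are dropped with a message.
#'
#' @param rec a [continuous_recording()] with at least one event.
#' @param window numeric length-2, epoch start and end in seconds relative
#'   to event onset.
#' @return An [epoch_set()].
#' @export
extract_epochs <- function(rec, window = c(0, 0.665)) {
  stopifnot(inherits(rec, "continuous_recording"))
  assert_that(length(window) == 2 && window[2] > window[1],
              "window must be (start, end) with end > start")
  assert_that(nrow(rec$events) > 0, "recording has no events")
  n_t <- round((window[2] - window[1]) * rec$fs)
  assert_that(n_t >= 1, "window too short for the sampling rate")
  offset <- round(window[1] * rec$fs)
  start <- rec$events$sample_index + offset          # 0-based first sample
  ok <- start >= 0 & (start + n_t) <= nrow(rec$signal)
  n_drop <- sum(!ok)
  if (n_drop > 0)
    message(sprintf("extract_epochs: dropped %d event(s) whose window exceeds the recording", n_drop))
  if (!any(ok))
    stop(errorCondition("no epochs survive the window bounds",
                        class = c("p300tl_empty_result", "error")))
  ev <- rec$events[ok, , drop = FALSE]
  start <- start[ok]
  n <- nrow(ev)
  n_c <- ncol(rec$signal)
  epochs <- array(0, c(n, n_t, n_c))
  for (i in seq_len(n))
    epochs[i, , ] <- rec$signal[(start[i] + 1L):(start[i] + n_t), ]
  epoch_set(epochs, ev$is_target, ev$code, ev$character_index,
            ev$repetition_index, rec$fs)
}
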