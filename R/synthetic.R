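#' ERP waveform template
#'
#' Describes a stereotyped event-related potential as a Gaussian bump in
#' time: the P300 is a positive deflection peaking roughly 300 ms after an
#' attended stimulus. The spatial pattern is a per-channel weight in [0, 1];
#' the default is a smooth unimodal topography with its maximum around 70%
#' of the channel range, mimicking the centro-parietal focus of the P300.
#'
#' @param duration template support in seconds.
#' @param peak_latency time of the peak in seconds (nominal 0.3).
#' @param peak_width Gaussian standard deviation of the bump in seconds.
#' @param amplitude peak amplitude in microvolts.
#' @param n_channels number of channels (used when `channel_weights` is NULL).
#' @param channel_weights optional per-channel scale in [0, 1].
#' @return An object of class `erp_template`.
#' @export
erp_template <- function(duration = 0.6, peak_latency = 0.3, peak_width = 0.06,
                         amplitude = 8, n_channels = 64, channel_weights = NULL) {
  assert_that(is_scalar(duration) && duration > 0, "duration must be positive")
  assert_that(is_scalar(peak_latency) && peak_latency >= 0, "peak_latency must be >= 0")
  assert_that(is_scalar(peak_width) && peak_width > 0, "peak_width must be positive")
  assert_that(is_scalar(amplitude), "amplitude must be finite")
  if (is.null(channel_weights)) {
    ch <- seq_len(n_channels)
    channel_weights <- exp(-0.5 * ((ch - 0.7 * n_channels) / (0.25 * n_channels))^2)
  }
  assert_that(all(is.finite(channel_weights)) && all(channel_weights >= 0) &&
                all(channel_weights <= 1), "channel_weights must lie in [0,1]")
  structure(list(duration = duration, peak_latency = peak_latency,
                 peak_width = peak_width, amplitude = amplitude,
                 channel_weights = as.numeric(channel_weights)),
            class = "erp_template")
}

#' Render an ERP template at a sampling rate
#'
#' @param template an [erp_template()].
#' @param fs sampling rate in Hz.
#' @return Numeric matrix, `round(duration * fs)` samples x channels. The
#'   peak falls within one sample of `peak_latency`; the bump is truncated
#'   to zero beyond four standard deviations from the peak.
#' @export
render_erp_template <- function(template, fs) {
  stopifnot(inherits(template, "erp_template"))
  assert_that(is_scalar(fs) && fs > 0, "fs must be positive")
  n <- round(template$duration * fs)
  assert_that(n >= 2, "duration * fs must cover at least 2 samples")
  t <- (seq_len(n) - 1) / fs
  z <- (t - template$peak_latency) / template$peak_width
  w <- exp(-0.5 * z^2)
  w[abs(z) > 4] <- 0
  template$amplitude * outer(w, template$channel_weights)
}

#' Cross-subject shift
#'
#' A linear, invertible perturbation applied to a simulated subject's
#' signal: an orthogonal channel mixing close to the identity (a rotation
#' of geodesic length `strength` on the orthogonal group), a scalar gain,
#' and a latency offset. This emulates the moderate electrode-placement and
#' anatomy differences between subjects that Euclidean alignment is meant
#' to remove; real cross-subject shifts are far from arbitrary, so the
#' rotation is kept small by default.
#'
#' @param n_channels channel count.
#' @param seed integer seed controlling the draw.
#' @param strength rotation magnitude (0 = identity mixing).
#' @param gain_sd standard deviation of the log-gain.
#' @param latency_sd standard deviation (seconds) of the latency offset.
#' @param mixing,gain,latency_shift explicit values overriding the draw.
#' @return An object of class `subject_shift`.
#' @export
subject_shift <- function(n_channels, seed = 1, strength = 0.2, gain_sd = 0.15,
                          latency_sd = 0.01, mixing = NULL, gain = NULL,
                          latency_shift = NULL) {
  drawn <- with_seed(seed, {
    a <- matrix(rnorm(n_channels^2), n_channels, n_channels)
    skew <- (a - t(a)) / sqrt(2)
    skew <- skew / max(1e-12, svd(skew)$d[1])   # largest principal angle = strength
    list(mixing = pracma::expm(strength * skew),
         gain = exp(rnorm(1, sd = gain_sd)),
         latency_shift = rnorm(1, sd = latency_sd))
  })
  mixing <- mixing %||% drawn$mixing
  gain <- gain %||% drawn$gain
  latency_shift <- latency_shift %||% drawn$latency_shift
  assert_that(is.matrix(mixing) && nrow(mixing) == n_channels &&
                ncol(mixing) == n_channels, "mixing must be channels x channels")
  assert_that(kappa(mixing, exact = TRUE) < 1e6, "mixing matrix is ill-conditioned")
  structure(list(mixing = mixing, gain = gain, latency_shift = latency_shift),
            class = "subject_shift")
}

#' @rdname subject_shift
#' @export
identity_shift <- function(n_channels) {
  structure(list(mixing = diag(n_channels), gain = 1, latency_shift = 0),
            class = "subject_shift")
}

#' Speller simulation settings
#'
#' Defaults reproduce the classic row/column matrix-speller oddball
#' paradigm: 12 intensifications (6 rows + 6 columns) per repetition, 15
#' repetitions per character, 64 channels sampled at 240 Hz, a 175 ms
#' stimulus-onset asynchrony (100 ms flash + 75 ms gap) and a 2.5 s pause
#' before each character.
#'
#' @param n_characters number of spelled characters.
#' @param n_repetitions repetitions per character (1-15).
#' @param n_channels,fs montage size and sampling rate.
#' @param soa seconds between intensification onsets.
#' @param inter_character_gap pause before each character, seconds.
#' @param noise_scale background EEG standard deviation, microvolts (default 5,
#'   giving single-trial detectability comparable to published ERP systems).
#' @param latency_jitter_sd per-epoch Gaussian jitter of the ERP onset, seconds.
#' @param subject_seed integer seed; identical seeds give bit-identical sessions.
#' @return A `speller_config` list.
#' @export
speller_config <- function(n_characters, n_repetitions = 15, n_channels = 64,
                           fs = 240, soa = 0.175, inter_character_gap = 2.5,
                           noise_scale = 5, latency_jitter_sd = 0.02,
                           subject_seed = 1) {
  assert_that(is_count(n_characters) && n_characters >= 1, "n_characters must be >= 1")
  assert_that(is_count(n_repetitions) && n_repetitions >= 1 && n_repetitions <= 15,
              "n_repetitions must be in 1..15")
  assert_that(is_scalar(noise_scale) && noise_scale >= 0, "noise_scale must be >= 0")
  structure(list(n_characters = n_characters, n_repetitions = n_repetitions,
                 n_intensifications = 12L, n_channels = n_channels, fs = fs,
                 soa = soa, inter_character_gap = inter_character_gap,
                 noise_scale = noise_scale, latency_jitter_sd = latency_jitter_sd,
                 subject_seed = subject_seed),
            class = "speller_config")
}

#' RSVP simulation settings
#'
#' Defaults follow a rapid serial visual presentation target-detection
#' paradigm: 5 stimuli per second, roughly 1 target per 10 stimuli, 8
#' channels. The native sampling rate is 2048 Hz in the emulated recordings;
#' pass `fs = 64` to generate directly at the analysis rate.
#'
#' @param n_trials number of presented stimuli.
#' @param target_fraction proportion of targets in (0, 1).
#' @param n_channels,fs montage size and sampling rate.
#' @param rate stimuli per second.
#' @param noise_scale,latency_jitter_sd as in [speller_config()].
#' @param subject_seed integer seed.
#' @return An `rsvp_config` list.
#' @export
rsvp_config <- function(n_trials, target_fraction = 0.1, n_channels = 8,
                        fs = 2048, rate = 5, noise_scale = 5,
                        latency_jitter_sd = 0.02, subject_seed = 1) {
  assert_that(is_count(n_trials) && n_trials >= 1, "n_trials must be >= 1")
  assert_that(is_scalar(target_fraction) && target_fraction > 0 && target_fraction < 1,
              "target_fraction must be in (0,1)")
  assert_that(is_scalar(rate) && rate > 0, "rate must be positive")
  assert_that(fs >= 2 * rate, "fs too low for the stimulus rate")
  structure(list(n_trials = n_trials, target_fraction = target_fraction,
                 n_channels = n_channels, fs = fs, rate = rate,
                 noise_scale = noise_scale,
                 latency_jitter_sd = latency_jitter_sd,
                 subject_seed = subject_seed),
            class = "rsvp_config")
}

#' The 6x6 speller alphabet
#'
#' Letters A-Z followed by digits 0-9, laid out row-major: row codes are
#' 1-6, column codes 7-12, and the spelled symbol is the row/column
#' intersection.
#'
#' @return A 6x6 character matrix.
#' @export
speller_alphabet <- function() {
  matrix(c(LETTERS, as.character(0:9)), nrow = 6, ncol = 6, byrow = TRUE)
}

# background EEG: AR(1) with coefficient 0.95 (1/f-like spectrum) plus white
# noise, mixed 80/20 in power, scaled to a marginal sd of noise_scale
make_background_noise <- function(n_samples, n_channels, noise_scale) {
  if (noise_scale == 0) return(matrix(0, n_samples, n_channels))
  phi <- 0.95
  ar <- apply(matrix(rnorm(n_samples * n_channels), n_samples, n_channels), 2,
              function(e) stats::filter(e, phi, method = "recursive"))
  ar <- ar * sqrt(1 - phi^2)           # unit marginal sd
  wh <- matrix(rnorm(n_samples * n_channels), n_samples, n_channels)
  noise_scale * (sqrt(0.8) * ar + sqrt(0.2) * wh)
}

# add `wave` (samples x channels) into `sig` starting at 0-based sample
# index `at`, clipping at the edges
add_wave_at <- function(sig, wave, at) {
  n <- nrow(sig); m <- nrow(wave)
  lo <- max(0L, at); hi <- min(n - 1L, at + m - 1L)
  if (hi < lo) return(sig)
  sig[(lo + 1L):(hi + 1L), ] <- sig[(lo + 1L):(hi + 1L), ] +
    wave[(lo - at + 1L):(hi - at + 1L), , drop = FALSE]
  sig
}

#' Simulate a matrix-speller session
#'
#' Generates a continuous recording of a subject spelling `truth`: for each
#' character and repetition the 12 row/column codes flash once in random
#' order, the two codes intersecting the truth character elicit an ERP
#' (the template, with per-epoch latency jitter), and everything is passed
#' through the subject's channel mixing and gain before background noise is
#' added.
#'
#' @param cfg a [speller_config()].
#' @param template an [erp_template()]; its channel weights must match
#'   `cfg$n_channels`.
#' @param shift a [subject_shift()].
#' @param truth character vector of symbols from [speller_alphabet()],
#'   length `cfg$n_characters`.
#' @return A [continuous_recording()] whose event table has one row per
#'   intensification.
#' @export
simulate_speller_session <- function(cfg, template, shift, truth) {
  stopifnot(inherits(cfg, "speller_config"), inherits(template, "erp_template"),
            inherits(shift, "subject_shift"))
  alphabet <- speller_alphabet()
  assert_that(length(truth) == cfg$n_characters,
              "truth length must equal n_characters")
  pos <- match(truth, alphabet)   # column-major position in the 6x6 grid
  assert_that(!anyNA(pos), "truth contains characters outside the 6x6 alphabet")
  row_code <- (pos - 1L) %% 6L + 1L
  col_code <- (pos - 1L) %/% 6L + 7L
  assert_that(length(template$channel_weights) == cfg$n_channels,
              "template channel_weights must match cfg$n_channels")

  rep_dur <- cfg$n_intensifications * cfg$soa
  char_dur <- cfg$inter_character_gap + cfg$n_repetitions * rep_dur
  total <- cfg$n_characters * char_dur + template$duration + 1
  n_samples <- ceiling(total * cfg$fs)
  wave <- render_erp_template(template, cfg$fs)

  with_seed(cfg$subject_seed, {
    ev <- vector("list", cfg$n_characters * cfg$n_repetitions)
    i <- 0L
    for (ci in seq_len(cfg$n_characters)) {
      t_char <- (ci - 1) * char_dur + cfg$inter_character_gap
      for (ri in seq_len(cfg$n_repetitions)) {
        codes <- sample.int(12L)
        onset <- t_char + (ri - 1) * rep_dur + (seq_len(12L) - 1) * cfg$soa
        i <- i + 1L
        ev[[i]] <- data.frame(
          sample_index = round(onset * cfg$fs), code = codes,
          is_target = as.integer(codes == row_code[ci] | codes == col_code[ci]),
          character_index = ci, repetition_index = ri)
      }
    }
    events <- do.call(rbind, ev)

    erp <- matrix(0, n_samples, cfg$n_channels)
    tgt <- which(events$is_target == 1L)
    jit <- rnorm(length(tgt), sd = cfg$latency_jitter_sd)
    for (j in seq_along(tgt)) {
      at <- events$sample_index[tgt[j]] +
        round((jit[j] + shift$latency_shift) * cfg$fs)
      erp <- add_wave_at(erp, wave, as.integer(at))
    }
    sig <- shift$gain * (erp %*% t(shift$mixing)) +
      make_background_noise(n_samples, cfg$n_channels, cfg$noise_scale)
    continuous_recording(sig, cfg$fs, events)
  })
}

#' Simulate an RSVP session
#'
#' Stimuli are presented at `cfg$rate` per second; exactly
#' `round(n_trials * target_fraction)` of them, chosen at random, are
#' targets and elicit the ERP template.
#'
#' @inheritParams simulate_speller_session
#' @param cfg an [rsvp_config()].
#' @return A [continuous_recording()] with one event per stimulus
#'   (`code` 0, `character_index`/`repetition_index` NA).
#' @export
simulate_rsvp_session <- function(cfg, template, shift) {
  stopifnot(inherits(cfg, "rsvp_config"), inherits(template, "erp_template"),
            inherits(shift, "subject_shift"))
  assert_that(length(template$channel_weights) == cfg$n_channels,
              "template channel_weights must match cfg$n_channels")
  isi <- 1 / cfg$rate
  lead_in <- 2
  total <- lead_in + cfg$n_trials * isi + template$duration + 1
  n_samples <- ceiling(total * cfg$fs)
  wave <- render_erp_template(template, cfg$fs)
  n_targets <- round(cfg$n_trials * cfg$target_fraction)

  with_seed(cfg$subject_seed, {
    onset <- lead_in + (seq_len(cfg$n_trials) - 1) * isi
    is_target <- integer(cfg$n_trials)
    is_target[sample.int(cfg$n_trials, n_targets)] <- 1L
    events <- data.frame(sample_index = round(onset * cfg$fs), code = 0L,
                         is_target = is_target,
                         character_index = NA_integer_,
                         repetition_index = NA_integer_)
    erp <- matrix(0, n_samples, cfg$n_channels)
    tgt <- which(is_target == 1L)
    jit <- rnorm(length(tgt), sd = cfg$latency_jitter_sd)
    for (j in seq_along(tgt)) {
      at <- events$sample_index[tgt[j]] +
        round((jit[j] + shift$latency_shift) * cfg$fs)
      erp <- add_wave_at(erp, wave, as.integer(at))
    }
    sig <- shift$gain * (erp %*% t(shift$mixing)) +
      make_background_noise(n_samples, cfg$n_channels, cfg$noise_scale)
    continuous_recording(sig, cfg$fs, events)
  })
}
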