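make_rec <- function(sig, fs, events = NULL) {
  if (is.null(events))
    events <- data.frame(sample_index = 0L, code = 1L, is_target = 1L,
                         character_index = 1L, repetition_index = 1L)
  continuous_recording(sig, fs, events)
}

test_that("band-pass removes DC and preserves in-band sinusoids", {
  fs <- 240
  t <- seq(0, 30, by = 1 / fs)
  dc <- make_rec(matrix(1, length(t), 1), fs)
  out <- bandpass_filter(dc, 0.1, 30)
  expect_lt(sum(out$signal^2) / length(t), 0.01)    # < 1% of input energy

  sine <- make_rec(cbind(sin(2 * pi * 10 * t)), fs)
  mid <- seq(length(t) %/% 4, 3 * length(t) %/% 4)
  amp <- max(abs(bandpass_filter(sine, 0.1, 30)$signal[mid, 1]))
  expect_gte(amp, 0.95)
  expect_lte(amp, 1.05)

  out_of_band <- make_rec(cbind(sin(2 * pi * 60 * t)), fs)
  expect_lt(max(abs(bandpass_filter(out_of_band, 0.1, 30)$signal[mid, 1])), 0.05)
})

test_that("band edges are validated against the Nyquist rate", {
  rec <- make_rec(matrix(0, 100, 1), 100)
  expect_error(bandpass_filter(rec, 30, 30), class = "p300tl_invalid_argument")
  expect_error(bandpass_filter(rec, 30, 10), class = "p300tl_invalid_argument")
  expect_error(bandpass_filter(rec, 0.1, 60), class = "p300tl_invalid_argument")
})

test_that("downsampling scales length, remaps events, and suppresses aliases", {
  fs <- 2048
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  ev <- data.frame(sample_index = c(0L, 1024L), code = 1L, is_target = 0L,
                   character_index = 1L, repetition_index = 1L)
  rec <- make_rec(cbind(sin(2 * pi * 10 * t)), fs, ev)
  out <- downsample(rec, 64)
  expect_equal(nrow(out$signal), 64)
  expect_equal(out$fs, 64)
  expect_equal(out$events$sample_index, c(0L, 32L))
  mid <- 16:48
  expect_gt(max(abs(out$signal[mid, 1])), 0.9)      # passband survives

  alias <- make_rec(cbind(sin(2 * pi * 100 * t)), fs, ev)  # above 32 Hz Nyquist
  out_a <- downsample(alias, 64)
  expect_lt(max(abs(out_a$signal[mid, 1])), 1e-4)

  expect_error(downsample(rec, 60), class = "p300tl_invalid_argument")
})

test_that("epoching reproduces the published input shapes", {
  ev <- data.frame(sample_index = c(0L, 200L), code = 1:2, is_target = c(1L, 0L),
                   character_index = 1L, repetition_index = 1:2)
  rec64 <- make_rec(matrix(rnorm(500 * 64), 500, 64), 240, ev)
  ep <- extract_epochs(rec64, c(0, 0.665))
  expect_equal(dim(ep$epochs), c(2, 160, 64))       # 160 x 64

  rec8 <- make_rec(matrix(rnorm(200 * 8), 200, 8), 64, ev[1, ])
  ep8 <- extract_epochs(rec8, c(0, 0.7))
  expect_equal(dim(ep8$epochs)[2:3], c(45, 8))      # 45 samples x 8 channels
})

test_that("events whose window leaves the recording are dropped with a message", {
  ev <- data.frame(sample_index = c(0L, 90L), code = 1:2, is_target = 0L,
                   character_index = 1L, repetition_index = 1:2)
  rec <- make_rec(matrix(0, 100, 2), 100, ev)
  expect_message(ep <- extract_epochs(rec, c(0, 0.5)), "dropped 1")
  expect_equal(dim(ep$epochs)[1], 1)
  expect_error(suppressMessages(extract_epochs(rec, c(0.5, 1.5))),
               class = "p300tl_empty_result")
})

test_that("epochs are exactly time-locked to event samples", {
  sig <- matrix(0, 100, 1)
  sig[51, 1] <- 7                                    # 0-based sample 50
  ev <- data.frame(sample_index = 50L, code = 1L, is_target = 1L,
                   character_index = 1L, repetition_index = 1L)
  ep <- extract_epochs(make_rec(sig, 100, ev), c(0, 0.1))
  expect_equal(ep$epochs[1, , 1], c(7, rep(0, 9)))
})

test_that("speller epochs inherit the 2:10 target ratio per repetition", {
  s <- sim_speller(seed = 5, identity_shift(4), n_char = 2, truth_seed = 6,
                   nch = 4, tpl = tpl_small(4), n_rep = 3)
  ep <- suppressMessages(extract_epochs(s$rec, c(0, 0.665)))
  expect_equal(dim(ep$epochs)[1], 2 * 3 * 12)
  tab <- table(ep$labels, paste(ep$character_index, ep$repetition_index))
  expect_true(all(tab["1", ] == 2))
  expect_true(all(tab["0", ] == 10))
})

test_that("filtering commutes with epoching on interior events", {
  fs <- 240
  with_seed(8, sig <- matrix(rnorm(fs * 10 * 2), fs * 10, 2))
  ev <- data.frame(sample_index = c(1000L, 1400L), code = 1:2, is_target = 0L,
                   character_index = 1L, repetition_index = 1:2)
  rec <- make_rec(sig, fs, ev)
  filtered_then_epoched <- extract_epochs(bandpass_filter(rec, 1, 30), c(0, 0.5))
  # oracle: filter only a padded local segment, then cut the same epoch out
  pad <- 3 * fs                                      # 3 s of context each side
  n_t <- 120
  seg_epoch <- function(i) {
    seg_rows <- (ev$sample_index[i] - pad + 1):(ev$sample_index[i] + n_t + pad)
    seg <- make_rec(sig[seg_rows, , drop = FALSE], fs,
                    data.frame(sample_index = pad, code = 1L, is_target = 0L,
                               character_index = 1L, repetition_index = 1L))
    extract_epochs(bandpass_filter(seg, 1, 30), c(0, 0.5))$epochs[1, , ]
  }
  for (i in 1:2)
    expect_equal(filtered_then_epoched$epochs[i, , ], seg_epoch(i),
                 tolerance = 1e-3)
})
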