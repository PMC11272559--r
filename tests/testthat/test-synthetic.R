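test_that("rendered template peaks at the nominal latency and is zero off-support", {
  tpl <- erp_template(duration = 0.6, peak_latency = 0.3, peak_width = 0.05,
                      amplitude = 5, n_channels = 4)
  w <- render_erp_template(tpl, fs = 240)
  expect_equal(dim(w), c(144, 4))
  trace <- apply(w, 1, max)
  expect_lte(abs((which.max(trace) - 1) - 0.3 * 240), 1)
  expect_equal(w[1, ], rep(0, 4))        # > 4 sd before the peak

  expect_equal(render_erp_template(erp_template(amplitude = 0, n_channels = 3),
                                   100),
               matrix(0, 60, 3))
  tpl_eq <- erp_template(n_channels = 3, channel_weights = rep(0.5, 3))
  w_eq <- render_erp_template(tpl_eq, 100)
  expect_equal(w_eq[, 1], w_eq[, 2])
  expect_equal(w_eq[, 2], w_eq[, 3])
})

test_that("template construction rejects degenerate arguments", {
  expect_error(erp_template(duration = -1), class = "p300tl_invalid_argument")
  expect_error(erp_template(peak_width = 0), class = "p300tl_invalid_argument")
  expect_error(render_erp_template(erp_template(duration = 0.005), fs = 100),
               class = "p300tl_invalid_argument")
})

test_that("speller schedule: every repetition has all 12 codes and exactly 2 targets", {
  s <- sim_speller(seed = 7, identity_shift(4), n_char = 3, truth_seed = 1,
                   nch = 4, tpl = tpl_small(4), noise = 0, n_rep = 4)
  ev <- s$rec$events
  expect_equal(nrow(ev), 3 * 4 * 12)
  alphabet <- speller_alphabet()
  for (ci in 1:3) {
    pos <- which(alphabet == s$truth[ci], arr.ind = TRUE)
    for (ri in 1:4) {
      rep_ev <- ev[ev$character_index == ci & ev$repetition_index == ri, ]
      expect_setequal(rep_ev$code, 1:12)
      expect_equal(sum(rep_ev$is_target), 2)
      expect_setequal(rep_ev$code[rep_ev$is_target == 1],
                      c(pos[1, "row"], 6 + pos[1, "col"]))
    }
  }
})

test_that("single character, single repetition gives 12 events with 2 targets", {
  s <- sim_speller(seed = 1, identity_shift(2), n_char = 1, truth_seed = 2,
                   nch = 2, tpl = tpl_small(2), n_rep = 1)
  expect_equal(nrow(s$rec$events), 12)
  expect_equal(sum(s$rec$events$is_target), 2)
})

test_that("simulated sessions are bit-identical under the same seed", {
  a <- sim_speller(seed = 11, subject_shift(4, seed = 2), n_char = 2,
                   truth_seed = 3, nch = 4, tpl = tpl_small(4), n_rep = 2)
  b <- sim_speller(seed = 11, subject_shift(4, seed = 2), n_char = 2,
                   truth_seed = 3, nch = 4, tpl = tpl_small(4), n_rep = 2)
  expect_identical(a$rec$signal, b$rec$signal)
  expect_identical(a$rec$events, b$rec$events)
  c <- sim_speller(seed = 12, subject_shift(4, seed = 2), n_char = 2,
                   truth_seed = 3, nch = 4, tpl = tpl_small(4), n_rep = 2)
  expect_false(identical(a$rec$signal, c$rec$signal))
})

test_that("noise-free identity-shift difference wave reproduces the template", {
  # SOA widened beyond the epoch so neighbouring flashes do not bleed in
  tpl <- tpl_small(3)
  cfg <- speller_config(2, n_repetitions = 3, n_channels = 3, noise_scale = 0,
                        latency_jitter_sd = 0, soa = 0.7, subject_seed = 4)
  rec <- simulate_speller_session(cfg, tpl, identity_shift(3), c("A", "K"))
  ep <- extract_epochs(rec, c(0, tpl$duration))
  diff_wave <- apply(ep$epochs[ep$labels == 1, , ], c(2, 3), mean) -
    apply(ep$epochs[ep$labels == 0, , ], c(2, 3), mean)
  expect_equal(diff_wave, render_erp_template(tpl, cfg$fs), tolerance = 1e-10)
})

test_that("RSVP sessions have the requested trial count, target rate and spacing", {
  cfg <- rsvp_config(500, fs = 64, subject_seed = 9)
  rec <- simulate_rsvp_session(cfg, tpl_small(8), identity_shift(8))
  expect_equal(nrow(rec$events), 500)
  expect_equal(sum(rec$events$is_target), 50)
  # stimulus onsets are 1/rate apart, rounded to the sample grid
  expect_true(all(diff(rec$events$sample_index) %in% c(12, 13)))
  expect_equal(mean(diff(rec$events$sample_index)), 64 / 5, tolerance = 1e-3)
})

test_that("RSVP config rejects degenerate target fractions and rates", {
  expect_error(rsvp_config(100, target_fraction = 0),
               class = "p300tl_invalid_argument")
  expect_error(rsvp_config(100, target_fraction = 1),
               class = "p300tl_invalid_argument")
  expect_error(rsvp_config(100, fs = 8, rate = 5),
               class = "p300tl_invalid_argument")
  expect_error(rsvp_config(0), class = "p300tl_invalid_argument")
})

test_that("speller rejects out-of-alphabet characters and bad repetition counts", {
  cfg <- speller_config(1, n_channels = 2, subject_seed = 1)
  expect_error(simulate_speller_session(cfg, tpl_small(2), identity_shift(2), "@"),
               class = "p300tl_invalid_argument")
  expect_error(speller_config(2, n_repetitions = 16),
               class = "p300tl_invalid_argument")
  expect_error(speller_config(2, n_repetitions = 0),
               class = "p300tl_invalid_argument")
})

test_that("subject shift mixing is orthogonal-like and well conditioned", {
  sh <- subject_shift(6, seed = 3, strength = 0.2)
  expect_lt(kappa(sh$mixing, exact = TRUE), 1.0001)   # rotation
  expect_equal(crossprod(sh$mixing), diag(6), tolerance = 1e-6)
  expect_identical(identity_shift(3)$mixing, diag(3))
})
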