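# Shared small-scale scenario builders. Expensive fixtures are built once
# per test run and memoised in this environment.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

tpl_small <- function(nch = 8) erp_template(n_channels = nch)

# centro-parietal vs frontal topography, for dissimilar-subject scenarios
tpl_frontal <- function(nch = 8) {
  ch <- seq_len(nch)
  erp_template(n_channels = nch, peak_latency = 0.25,
               channel_weights = exp(-0.5 * ((ch - 0.3 * nch) / (0.25 * nch))^2))
}

sim_rsvp_epochs <- function(seed, shift, n = 450, nch = 8, tpl = tpl_small(nch),
                            noise = 5) {
  cfg <- rsvp_config(n, fs = 64, n_channels = nch, noise_scale = noise,
                     subject_seed = seed)
  rec <- simulate_rsvp_session(cfg, tpl, shift)
  rec <- bandpass_filter(rec, 0.15, 28)
  extract_epochs(rec, c(0, 0.7))
}

sim_speller <- function(seed, shift, n_char, truth_seed, nch = 8,
                        tpl = tpl_small(nch), noise = 5, n_rep = 15,
                        jitter = 0.02) {
  truth <- with_seed(truth_seed, sample(speller_alphabet(), n_char, replace = TRUE))
  cfg <- speller_config(n_char, n_repetitions = n_rep, n_channels = nch,
                        noise_scale = noise, latency_jitter_sd = jitter,
                        subject_seed = seed)
  rec <- simulate_speller_session(cfg, tpl, shift, truth)
  list(rec = rec, truth = truth, cfg = cfg)
}

sim_speller_epochs <- function(...) {
  s <- sim_speller(...)
  rec <- bandpass_filter(s$rec, 0.1, 30)
  list(ep = suppressMessages(extract_epochs(rec, c(0, 0.665))), truth = s$truth)
}

concat_ep <- function(a, b) {
  da <- dim(a$epochs)
  db <- dim(b$epochs)
  e <- array(0, c(da[1] + db[1], da[2], da[3]))
  e[seq_len(da[1]), , ] <- a$epochs
  e[da[1] + seq_len(db[1]), , ] <- b$epochs
  epoch_set(e, c(a$labels, b$labels), c(a$codes, b$codes),
            c(a$character_index, b$character_index + max(a$character_index, na.rm = TRUE)),
            c(a$repetition_index, b$repetition_index), a$fs)
}

# random feature clouds for alignment/selection tests
gauss_features <- function(n, f, seed, mix = NULL, shift = 0) {
  with_seed(seed, {
    X <- matrix(rnorm(n * f), n, f)
    if (!is.null(mix)) X <- X %*% mix
    X + shift
  })
}

random_drbm <- function(H, f, seed) {
  with_seed(seed, drbm_params(W = matrix(rnorm(H * f), H, f), c_h = rnorm(H),
                              U = matrix(rnorm(H * 2), H, 2), b = rnorm(2)))
}

# exhaustive marginalization over all 2^H hidden configurations
drbm_conditional_bruteforce <- function(params, x) {
  H <- nrow(params$W)
  configs <- as.matrix(expand.grid(rep(list(0:1), H)))
  un <- vapply(1:2, function(y) {
    s <- params$c_h + params$U[, y] + as.numeric(params$W %*% x)
    sum(exp(params$b[y] + configs %*% s))
  }, numeric(1))
  un / sum(un)
}

# artifact-like contamination: adds a high-amplitude low-frequency burst to
# a random fraction of epochs (both classes), emulating blink/movement
# trials that make indiscriminate source pooling harmful
contaminate_epochs <- function(ep, frac, amp, seed) {
  with_seed(seed, {
    n <- dim(ep$epochs)[1]
    n_t <- dim(ep$epochs)[2]
    n_c <- dim(ep$epochs)[3]
    hit <- sample.int(n, round(frac * n))
    for (i in hit) {
      burst <- stats::filter(rnorm(n_t), 0.97, method = "recursive")
      burst <- amp * as.numeric(burst) / max(1e-9, sd(burst))
      ep$epochs[i, , ] <- ep$epochs[i, , ] + outer(burst, runif(n_c, 0.5, 1))
    }
    attr(ep, "contaminated") <- hit
    ep
  })
}
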