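toy_cfg <- cnn_config(n_samples = 12, n_channels = 3, n_kernels = 4,
                      stride = 4, n_features = 6)

toy_batch <- function(n = 6, seed = 1, cfg = toy_cfg) {
  with_seed(seed, {
    epochs <- array(rnorm(n * cfg$n_samples * cfg$n_channels),
                    c(n, cfg$n_samples, cfg$n_channels))
    epoch_set(epochs, rep_len(c(0L, 1L), n), rep(1L, n), rep(1L, n),
              seq_len(n), 100)
  })
}

test_that("architecture arithmetic matches the two published configurations", {
  d1 <- cnn_config(160, 64, 16, 16, 128)
  expect_equal(d1$positions, 10)                 # (160 - 16) / 16 + 1
  expect_equal(d1$kernel_height, 16)
  expect_equal(d1$positions * d1$n_kernels, 160)
  d2 <- cnn_config(45, 8, 5, 5, 36)
  expect_equal(d2$positions, 9)                  # (45 - 5) / 5 + 1
  expect_equal(d2$positions * d2$n_kernels, 45)
  expect_error(cnn_config(10, 2, 1, 4, 40), class = "p300tl_invalid_argument")
})

test_that("forward pass yields row-normalized probabilities and nonnegative features", {
  m <- build_cnn(toy_cfg, seed = 2)
  data <- toy_batch(5)
  pr <- predict_cnn(m, data)
  expect_equal(dim(pr), c(5, 2))
  expect_equal(rowSums(pr), rep(1, 5))
  expect_true(all(pr > 0))
  fs <- extract_features(m, data)
  expect_equal(dim(fs$features), c(5, 6))
  expect_true(all(fs$features >= 0))
  expect_equal(fs$repetition_index, data$repetition_index)
})

test_that("published feature widths are exposed by the two dataset configurations", {
  m1 <- build_cnn(cnn_config(160, 64, 16, 16, 128), seed = 1)
  e1 <- epoch_set(array(rnorm(2 * 160 * 64), c(2, 160, 64)), c(0L, 1L),
                  1:2, 1:2, 1:2, 240)
  expect_equal(ncol(extract_features(m1, e1)$features), 128)
  m2 <- build_cnn(cnn_config(45, 8, 5, 5, 36), seed = 1)
  e2 <- epoch_set(array(rnorm(2 * 45 * 8), c(2, 45, 8)), c(0L, 1L),
                  1:2, 1:2, 1:2, 64)
  expect_equal(ncol(extract_features(m2, e2)$features), 36)
  expect_equal(ncol(extract_features(m2, e2, layer = "conv")$features), 45)
})

test_that("analytic gradients match central finite differences", {
  m <- build_cnn(toy_cfg, seed = 3)
  data <- toy_batch(3, seed = 4)
  y <- data$labels
  fw <- p300tl:::cnn_forward(m, data$epochs, training = TRUE, want_cache = TRUE)
  g <- p300tl:::cnn_backward(m, fw, y)
  loss_at <- function(mm) {
    f <- p300tl:::cnn_forward(mm, data$epochs, training = TRUE)
    p300tl:::cnn_loss(f, y)
  }
  h <- 1e-5
  with_seed(5, {
    for (grp in names(g)) for (nm in names(g[[grp]])) {
      ga <- g[[grp]][[nm]]
      for (i in sample(length(ga), min(length(ga), 10))) {
        mp <- m; mp$params[[grp]][[nm]][i] <- mp$params[[grp]][[nm]][i] + h
        mn <- m; mn$params[[grp]][[nm]][i] <- mn$params[[grp]][[nm]][i] - h
        fd <- (loss_at(mp) - loss_at(mn)) / (2 * h)
        expect_lt(abs(fd - ga[i]) / max(1e-8, abs(fd) + abs(ga[i])), 1e-4)
      }
    }
  })
})

test_that("zero learning rate is a fixed point of the weights", {
  m <- build_cnn(toy_cfg, seed = 6)
  trained <- train_cnn(m, toy_batch(8, seed = 7),
                       train_config(learning_rate = 0, max_epochs = 3,
                                    validation_fraction = 0, patience = 3, seed = 1))
  for (grp in c("conv", "fc1", "fc2"))
    expect_identical(trained$params[[grp]]$W, m$params[[grp]]$W)
  expect_identical(trained$params$bn0$gamma, m$params$bn0$gamma)
})

test_that("training is deterministic given the seed and separates easy data", {
  # high-amplitude template, no noise: classes are trivially separable
  d <- sim_rsvp_epochs(seed = 21, identity_shift(4), n = 120, nch = 4,
                       tpl = tpl_small(4), noise = 0)
  cfg <- cnn_config(45, 4, 5, 5, 20)
  tc <- train_config(max_epochs = 15, patience = 15, seed = 2)
  m1 <- train_cnn(build_cnn(cfg, seed = 2), d, tc)
  expect_gte(mean((predict_cnn(m1, d)[, 2] > 0.5) == (d$labels == 1)), 0.99)
  expect_lt(tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  m2 <- train_cnn(build_cnn(cfg, seed = 2), d, tc)
  expect_identical(m1$params, m2$params)
})

test_that("weight decay shrinks the fully connected weights", {
  d <- toy_batch(20, seed = 9)
  tc0 <- train_config(weight_decay = 0, max_epochs = 10,
                      validation_fraction = 0, patience = 10, seed = 3)
  tc1 <- train_config(weight_decay = 0.05, max_epochs = 10,
                      validation_fraction = 0, patience = 10, seed = 3)
  m0 <- train_cnn(build_cnn(toy_cfg, seed = 4), d, tc0)
  m1 <- train_cnn(build_cnn(toy_cfg, seed = 4), d, tc1)
  expect_lt(norm(m1$params$fc1$W, "F"), norm(m0$params$fc1$W, "F"))
})

test_that("fine-tuning leaves every frozen parameter bit-identical", {
  src <- sim_rsvp_epochs(seed = 31, identity_shift(4), n = 150, nch = 4,
                         tpl = tpl_small(4))
  tgt <- sim_rsvp_epochs(seed = 32, subject_shift(4, seed = 1), n = 100, nch = 4,
                         tpl = tpl_small(4))
  cfg <- cnn_config(45, 4, 5, 5, 20)
  pre <- train_cnn(build_cnn(cfg, seed = 5), src,
                   train_config(max_epochs = 8, patience = 8, seed = 5))
  ft <- fine_tune(pre, tgt, train_config(max_epochs = 8, patience = 8, seed = 6))
  expect_true(ft$frozen)
  expect_identical(ft$params$bn0, pre$params$bn0)
  expect_identical(ft$params$conv, pre$params$conv)
  expect_identical(ft$params$bn1, pre$params$bn1)
  expect_false(identical(ft$params$fc1, pre$params$fc1))
})

test_that("training rejects single-class data, empty or mismatched input", {
  d <- toy_batch(4)
  d1 <- subset_epochs(d, d$labels == 1)
  expect_error(train_cnn(build_cnn(toy_cfg, 1), d1, train_config(max_epochs = 1)),
               class = "p300tl_invalid_argument")
  m <- build_cnn(toy_cfg, 1)
  wrong <- epoch_set(array(0, c(2, 5, 3)), c(0L, 1L), 1:2, 1:2, 1:2, 100)
  expect_error(fine_tune(m, wrong), "shape")
  empty <- subset_epochs(d, integer(0))
  expect_error(fine_tune(m, empty), class = "p300tl_invalid_argument")
})

test_that("inference uses stored statistics and is batch-composition independent", {
  m <- train_cnn(build_cnn(toy_cfg, seed = 8), toy_batch(16, seed = 10),
                 train_config(max_epochs = 3, validation_fraction = 0,
                              patience = 3, seed = 4))
  d <- toy_batch(6, seed = 11)
  all_at_once <- predict_cnn(m, d)
  one_by_one <- t(vapply(1:6, function(i)
    predict_cnn(m, subset_epochs(d, i))[1, ], numeric(2)))
  expect_equal(all_at_once, one_by_one, tolerance = 1e-12)
})
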