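#' CNN architecture settings
#'
#' Describes the compact six-layer network used for P300 vs non-P300
#' classification: input batch normalization, one convolutional layer whose
#' kernels span all channels (shape `kernel_height x C`, temporal stride
#' `stride`), a second batch normalization, ReLU, a fully connected layer of
#' `n_features` units (the deep-feature layer), ReLU, a 2-unit fully
#' connected layer and softmax. The speller configuration is
#' `cnn_config(160, 64, n_kernels = 16, stride = 16, n_features = 128)`;
#' the RSVP configuration is `cnn_config(45, 8, 5, 5, n_features = 36)`.
#' The kernel height defaults to the stride (about a tenth of the epoch).
#'
#' @param n_samples epoch length T in samples.
#' @param n_channels channel count C.
#' @param n_kernels number of convolution kernels K.
#' @param stride temporal stride S.
#' @param n_features width f of the first fully connected layer.
#' @param kernel_height kernel extent in samples (default: `stride`).
#' @return A `cnn_config` list; `$positions` holds the number of temporal
#'   positions `floor((T - kernel_height) / stride) + 1`.
#' @export
cnn_config <- function(n_samples, n_channels, n_kernels, stride, n_features,
                       kernel_height = NULL) {
  kernel_height <- kernel_height %||% stride
  for (v in list(n_samples, n_channels, n_kernels, stride, n_features, kernel_height))
    assert_that(is_count(v) && v >= 1, "cnn_config arguments must be positive integers")
  positions <- floor((n_samples - kernel_height) / stride) + 1
  assert_that(positions >= 1, "kernel taller than the epoch")
  assert_that(n_kernels * positions >= n_features,
              "flattened convolution output (K * positions) must be >= n_features")
  structure(list(n_samples = as.integer(n_samples), n_channels = as.integer(n_channels),
                 n_kernels = as.integer(n_kernels), stride = as.integer(stride),
                 kernel_height = as.integer(kernel_height),
                 n_features = as.integer(n_features),
                 positions = as.integer(positions), classes = 2L),
            class = "cnn_config")
}

#' Optimization settings for network training
#'
#' Stochastic gradient descent with momentum, L2 weight decay, an internal
#' validation split for model selection and early stopping.
#'
#' @param learning_rate SGD step size.
#' @param momentum momentum factor.
#' @param weight_decay L2 penalty on weight matrices (not biases or batch
#'   normalization parameters).
#' @param batch_size minibatch size.
#' @param max_epochs maximum passes over the training split.
#' @param patience epochs without validation improvement before stopping.
#' @param validation_fraction fraction of the data held out for model
#'   selection (0 disables the split; training loss is then monitored).
#' @param seed integer seed controlling initialization and shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.01, momentum = 0.9,
                         weight_decay = 5e-4, batch_size = 64,
                         max_epochs = 100, patience = 10,
                         validation_fraction = 0.1, seed = 1) {
  assert_that(is_scalar(learning_rate) && learning_rate >= 0,
              "learning_rate must be >= 0")
  assert_that(is_scalar(validation_fraction) && validation_fraction >= 0 &&
                validation_fraction < 1, "validation_fraction must be in [0,1)")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay,
                 batch_size = if (is.finite(batch_size)) as.integer(batch_size) else Inf,
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 validation_fraction = validation_fraction, seed = as.integer(seed)),
            class = "train_config")
}

new_bn <- function(m) list(gamma = rep(1, m), beta = rep(0, m),
                           mean = rep(0, m), var = rep(1, m))

#' Initialize a CNN model
#'
#' He-style Gaussian initialization for the convolution and fully connected
#' weights; batch normalization starts at the identity transform.
#'
#' @param cfg a [cnn_config()].
#' @param seed integer seed for the weight draw.
#' @return A `cnn_model` object.
#' @export
build_cnn <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "cnn_config"))
  khc <- cfg$kernel_height * cfg$n_channels
  pk <- cfg$positions * cfg$n_kernels
  params <- with_seed(seed, list(
    bn0 = new_bn(cfg$n_samples * cfg$n_channels),
    conv = list(W = matrix(rnorm(khc * cfg$n_kernels, sd = sqrt(2 / khc)),
                           khc, cfg$n_kernels),
                b = rep(0, cfg$n_kernels)),
    bn1 = new_bn(cfg$n_kernels),
    fc1 = list(W = matrix(rnorm(pk * cfg$n_features, sd = sqrt(2 / pk)),
                          pk, cfg$n_features),
               b = rep(0, cfg$n_features)),
    fc2 = list(W = matrix(rnorm(cfg$n_features * 2, sd = sqrt(1 / cfg$n_features)),
                          cfg$n_features, 2),
               b = rep(0, 2))))
  patch_idx <- lapply(seq_len(cfg$positions), function(p) {
    rows <- (p - 1L) * cfg$stride + seq_len(cfg$kernel_height)
    as.integer(outer(rows, (seq_len(cfg$n_channels) - 1L) * cfg$n_samples, `+`))
  })
  structure(list(cfg = cfg, params = params, patch_idx = patch_idx,
                 frozen = FALSE, history = NULL),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("<cnn_model> input %dx%d | conv %d kernels %dx%d stride %d -> %d positions | fc %d -> 2%s\n",
              cfg$n_samples, cfg$n_channels, cfg$n_kernels, cfg$kernel_height,
              cfg$n_channels, cfg$stride, cfg$positions, cfg$n_features,
              if (x$frozen) " | feature layers frozen" else ""))
  invisible(x)
}

bn_eps <- 1e-5
bn_momentum <- 0.1

bn_forward <- function(x, bn, training) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x * x) - mu^2
    v[v < 0] <- 0
    bn$mean <- (1 - bn_momentum) * bn$mean + bn_momentum * mu
    bn$var <- (1 - bn_momentum) * bn$var + bn_momentum * v
  } else {
    mu <- bn$mean
    v <- bn$var
  }
  istd <- 1 / sqrt(v + bn_eps)
  xhat <- row_scale(row_center(x, mu), istd)
  list(y = row_scale(xhat, bn$gamma) + rep(bn$beta, each = nrow(x)),
       xhat = xhat, istd = istd, bn = bn)
}

# gradient through batch statistics (training-mode normalization)
bn_backward <- function(dy, xhat, istd, gamma, training) {
  m <- nrow(dy)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- row_scale(dy, gamma)
  dx <- if (training) {
    row_scale(dxhat - rep(colMeans(dxhat), each = m) -
                xhat * rep(colMeans(dxhat * xhat), each = m), istd)
  } else {
    row_scale(dxhat, istd)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Forward pass. X is an n x T x C array (or a single T x C matrix).
# `training` selects batch statistics (and running-stat updates) in the
# batch-norm layers; frozen models always use stored running statistics.
cnn_forward <- function(model, X, training = FALSE, want_cache = FALSE) {
  cfg <- model$cfg
  if (is.matrix(X)) X <- array(X, c(1L, dim(X)))
  assert_that(dim(X)[2] == cfg$n_samples && dim(X)[3] == cfg$n_channels,
              "epoch shape does not match the model configuration")
  n <- dim(X)[1]
  p <- model$params
  bn_train <- training && !model$frozen
  xf <- matrix(X, nrow = n)
  f0 <- bn_forward(xf, p$bn0, bn_train)
  if (bn_train) model$params$bn0 <- f0$bn

  np <- cfg$positions
  khc <- cfg$kernel_height * cfg$n_channels
  Xp <- matrix(0, n * np, khc)
  for (q in seq_len(np))
    Xp[((q - 1L) * n + 1L):(q * n), ] <- f0$y[, model$patch_idx[[q]], drop = FALSE]
  Zc <- Xp %*% p$conv$W + rep(p$conv$b, each = n * np)
  f1 <- bn_forward(Zc, p$bn1, bn_train)
  if (bn_train) model$params$bn1 <- f1$bn
  H1 <- relu(f1$y)
  Fmat <- matrix(array(H1, c(n, np, cfg$n_kernels)), n, np * cfg$n_kernels)

  A1 <- Fmat %*% p$fc1$W + rep(p$fc1$b, each = n)
  H2 <- relu(A1)
  logits <- H2 %*% p$fc2$W + rep(p$fc2$b, each = n)
  logp <- logits - row_logsumexp(logits)
  out <- list(probs = exp(logp), logp = logp, feats = H2, conv_feats = Fmat,
              model = model)
  if (want_cache)
    out$cache <- list(xf = xf, f0 = f0, Xp = Xp, f1 = f1, bnout1 = f1$y,
                      Fmat = Fmat, A1 = A1, H2 = H2, n = n,
                      bn_train = bn_train)
  out
}

# Mean cross-entropy of labels y (0/1) under a forward result.
cnn_loss <- function(fw, y) -mean(fw$logp[cbind(seq_along(y), y + 1L)])

# Backward pass for the mean cross-entropy loss. Returns gradients for the
# trainable parameter groups; feature-layer gradients are omitted when the
# model is frozen.
cnn_backward <- function(model, fw, y) {
  cfg <- model$cfg
  cc <- fw$cache
  n <- cc$n
  Y <- matrix(0, n, 2)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  dlogits <- (fw$probs - Y) / n
  p <- model$params
  g <- list(fc2 = list(W = crossprod(cc$H2, dlogits), b = colSums(dlogits)))
  dH2 <- tcrossprod(dlogits, p$fc2$W)
  dA1 <- dH2 * (cc$A1 > 0)
  g$fc1 <- list(W = crossprod(cc$Fmat, dA1), b = colSums(dA1))
  if (model$frozen) return(g)

  np <- cfg$positions
  dFmat <- tcrossprod(dA1, p$fc1$W)
  dH1 <- matrix(array(dFmat, c(n, np, cfg$n_kernels)), n * np, cfg$n_kernels)
  dBn1 <- dH1 * (cc$bnout1 > 0)
  b1 <- bn_backward(dBn1, cc$f1$xhat, cc$f1$istd, p$bn1$gamma, cc$bn_train)
  g$bn1 <- list(gamma = b1$dgamma, beta = b1$dbeta)
  dZc <- b1$dx
  g$conv <- list(W = crossprod(cc$Xp, dZc), b = colSums(dZc))
  dXp <- tcrossprod(dZc, p$conv$W)
  dxb <- matrix(0, n, cfg$n_samples * cfg$n_channels)
  for (q in seq_len(np)) {
    idx <- model$patch_idx[[q]]
    dxb[, idx] <- dxb[, idx] + dXp[((q - 1L) * n + 1L):(q * n), , drop = FALSE]
  }
  b0 <- bn_backward(dxb, cc$f0$xhat, cc$f0$istd, p$bn0$gamma, cc$bn_train)
  g$bn0 <- list(gamma = b0$dgamma, beta = b0$dbeta)
  g
}

# parameter tensors updated by SGD; weight decay applies to $decay only
trainable_paths <- function(frozen) {
  fc <- list(list(grp = "fc1", nm = "W", decay = TRUE),
             list(grp = "fc1", nm = "b", decay = FALSE),
             list(grp = "fc2", nm = "W", decay = TRUE),
             list(grp = "fc2", nm = "b", decay = FALSE))
  if (frozen) return(fc)
  c(list(list(grp = "bn0", nm = "gamma", decay = FALSE),
         list(grp = "bn0", nm = "beta", decay = FALSE),
         list(grp = "conv", nm = "W", decay = TRUE),
         list(grp = "conv", nm = "b", decay = FALSE),
         list(grp = "bn1", nm = "gamma", decay = FALSE),
         list(grp = "bn1", nm = "beta", decay = FALSE)),
    fc)
}

#' Train a CNN with SGD
#'
#' Minibatch stochastic gradient descent with momentum and L2 weight decay
#' on the cross-entropy loss. A `validation_fraction` split of the data is
#' held out for model selection: the returned model is the one with the
#' best validation loss, and training stops early after `patience` epochs
#' without improvement. For a frozen (fine-tuning) model only the two fully
#' connected layers are updated and the batch-normalization layers run on
#' their stored statistics.
#'
#' @param model a [build_cnn()] model.
#' @param data an [epoch_set()] containing both classes.
#' @param cfg a [train_config()].
#' @return The trained `cnn_model`; `$history` is a data.frame of per-epoch
#'   training and validation loss.
#' @export
train_cnn <- function(model, data, cfg = train_config()) {
  stopifnot(inherits(model, "cnn_model"), inherits(data, "epoch_set"),
            inherits(cfg, "train_config"))
  y <- data$labels
  assert_that(length(unique(y)) == 2, "training data must contain both classes")
  n <- dim(data$epochs)[1]
  with_seed(cfg$seed, {
    n_val <- round(cfg$validation_fraction * n)
    perm <- sample.int(n)
    val_idx <- head(perm, n_val)
    tr_idx <- tail(perm, n - n_val)
    vel <- list()
    paths <- trainable_paths(model$frozen)
    best <- model
    best_loss <- Inf
    wait <- 0L
    hist <- vector("list", cfg$max_epochs)
    eval_loss <- function(m, idx) {
      fw <- cnn_forward(m, data$epochs[idx, , , drop = FALSE])
      cnn_loss(fw, y[idx])
    }
    for (ep in seq_len(cfg$max_epochs)) {
      ord <- sample(tr_idx)
      starts <- seq(1L, length(ord), by = cfg$batch_size)
      batch_losses <- numeric(length(starts))
      batch_sizes <- numeric(length(starts))
      bi <- 0L
      for (s in starts) {
        b <- ord[s:min(s + cfg$batch_size - 1L, length(ord))]
        fw <- cnn_forward(model, data$epochs[b, , , drop = FALSE],
                          training = TRUE, want_cache = TRUE)
        model <- fw$model
        bi <- bi + 1L
        batch_losses[bi] <- cnn_loss(fw, y[b])
        batch_sizes[bi] <- length(b)
        g <- cnn_backward(model, fw, y[b])
        for (pt in paths) {
          key <- paste(pt$grp, pt$nm)
          w <- model$params[[pt$grp]][[pt$nm]]
          grad <- g[[pt$grp]][[pt$nm]]
          if (pt$decay && cfg$weight_decay > 0) grad <- grad + cfg$weight_decay * w
          v <- (vel[[key]] %||% 0) * cfg$momentum - cfg$learning_rate * grad
          vel[[key]] <- v
          model$params[[pt$grp]][[pt$nm]] <- w + v
        }
      }
      tl <- sum(batch_losses * batch_sizes) / sum(batch_sizes)
      vl <- if (n_val > 0) eval_loss(model, val_idx) else eval_loss(model, tr_idx)
      hist[[ep]] <- data.frame(epoch = ep, train_loss = tl, val_loss = vl)
      if (vl < best_loss - 1e-12) {
        best_loss <- vl
        best <- model
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    best$history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
    best
  })
}

#' Fine-tune a pre-trained CNN on target-subject data
#'
#' Freezes the generic feature-extraction layers learned on the source
#' subject -- the input batch normalization, the convolutional layer and
#' the post-convolution batch normalization -- and retrains only the two
#' fully connected layers on the target data. Frozen parameters (including
#' batch-normalization running statistics) are bit-identical before and
#' after fine-tuning.
#'
#' @param pretrained a trained `cnn_model`.
#' @param target_data an [epoch_set()] matching the model's input shape.
#' @param cfg a [train_config()].
#' @return The fine-tuned `cnn_model` (with `$frozen = TRUE`).
#' @export
fine_tune <- function(pretrained, target_data, cfg = train_config()) {
  stopifnot(inherits(pretrained, "cnn_model"), inherits(target_data, "epoch_set"))
  assert_that(dim(target_data$epochs)[1] > 0, "target data is empty")
  assert_that(dim(target_data$epochs)[2] == pretrained$cfg$n_samples &&
                dim(target_data$epochs)[3] == pretrained$cfg$n_channels,
              "target epochs do not match the pre-trained model shape")
  pretrained$frozen <- TRUE
  train_cnn(pretrained, target_data, cfg)
}

#' Extract deep features from epochs
#'
#' Runs the network in inference mode (stored batch-normalization
#' statistics) and returns the post-ReLU activations of the first fully
#' connected layer -- the deep features the rest of the transfer pipeline
#' operates on. `layer = "conv"` instead returns the flattened post-ReLU
#' convolution output.
#'
#' @param model a `cnn_model`.
#' @param data an [epoch_set()].
#' @param layer `"fc1"` (default) or `"conv"`.
#' @return A [feature_set()] of dimension n x f (or n x K*positions), with
#'   epoch metadata carried over. All values are nonnegative.
#' @export
extract_features <- function(model, data, layer = c("fc1", "conv")) {
  stopifnot(inherits(model, "cnn_model"), inherits(data, "epoch_set"))
  layer <- match.arg(layer)
  fw <- cnn_forward(model, data$epochs)
  feats <- if (layer == "fc1") fw$feats else fw$conv_feats
  feature_set(feats, data$labels, data$codes, data$character_index,
              data$repetition_index)
}

#' Class probabilities from a CNN
#'
#' @param model a `cnn_model`.
#' @param data an [epoch_set()].
#' @return n x 2 matrix of softmax probabilities (columns: non-target, target).
#' @export
predict_cnn <- function(model, data) {
  stopifnot(inherits(model, "cnn_model"), inherits(data, "epoch_set"))
  cnn_forward(model, data$epochs)$probs
}
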