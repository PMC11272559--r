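#' Discriminative restricted Boltzmann machine parameters
#'
#' A two-class RBM with `H` binary hidden units, trained directly on the
#' conditional label distribution. Marginalizing the hidden layer gives the
#' exact, tractable conditional
#' `p(y | x) proportional to exp(b_y + sum_j softplus(c_j + U_jy + W_j . x))`,
#' so no sampling is needed for either prediction or the gradient.
#'
#' @param W H x f input-to-hidden weights.
#' @param c_h hidden biases (length H).
#' @param U H x 2 class-to-hidden weights.
#' @param b class biases (length 2; column 1 = non-target, 2 = target).
#' @return A `drbm_params` object.
#' @export
drbm_params <- function(W, c_h, U, b) {
  assert_that(is.matrix(W) && is.matrix(U) && nrow(U) == nrow(W) &&
                ncol(U) == 2 && length(c_h) == nrow(W) && length(b) == 2,
              "inconsistent DRBM parameter shapes")
  assert_that(all(is.finite(W)) && all(is.finite(c_h)) && all(is.finite(U)) &&
                all(is.finite(b)), "DRBM parameters must be finite")
  structure(list(W = W, c_h = as.numeric(c_h), U = U, b = as.numeric(b)),
            class = "drbm_params")
}

#' @export
print.drbm_params <- function(x, ...) {
  cat(sprintf("<drbm_params> %d hidden units, %d input features\n",
              nrow(x$W), ncol(x$W)))
  invisible(x)
}

# n x 2 matrix of unnormalized log-probabilities (negative free energies)
drbm_logits <- function(params, X) {
  M <- tcrossprod(X, params$W)                      # n x H
  vapply(1:2, function(y)
    params$b[y] + rowSums(softplus(row_center(M, -(params$c_h + params$U[, y])))),
    numeric(nrow(X)))
}

#' Exact DRBM conditional class probabilities
#'
#' @param params a [drbm_params()].
#' @param x a feature vector, or an n x f matrix of feature vectors.
#' @return An n x 2 matrix of probabilities `p(y | x)` (rows sum to 1),
#'   computed with log-sum-exp stabilization.
#' @export
drbm_conditional <- function(params, x) {
  stopifnot(inherits(params, "drbm_params"))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  assert_that(all(is.finite(X)), "input features must be finite")
  assert_that(ncol(X) == ncol(params$W), "feature dimension mismatch")
  a <- drbm_logits(params, X)
  if (!is.matrix(a)) a <- matrix(a, nrow = 1)
  exp(a - row_logsumexp(a))
}

# mean conditional log-likelihood and its exact analytic gradient
drbm_objective <- function(params, X, y) {
  n <- nrow(X)
  a <- drbm_logits(params, X)
  if (!is.matrix(a)) a <- matrix(a, nrow = 1)
  logp <- a - row_logsumexp(a)
  p <- exp(logp)
  Y <- matrix(0, n, 2)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  resid <- Y - p                                     # n x 2
  M <- tcrossprod(X, params$W)
  dW <- matrix(0, nrow(params$W), ncol(params$W))
  dc <- numeric(nrow(params$W))
  dU <- matrix(0, nrow(params$W), 2)
  for (cls in 1:2) {
    G <- sigmoid(row_center(M, -(params$c_h + params$U[, cls])))  # n x H
    Gr <- G * resid[, cls]
    dU[, cls] <- colSums(Gr) / n
    dc <- dc + dU[, cls]
    dW <- dW + crossprod(Gr, X) / n
  }
  list(value = mean(logp[cbind(seq_len(n), y + 1L)]),
       grad = list(W = dW, c_h = dc, U = dU, b = colSums(resid) / n))
}

# exact reparameterizations of the DRBM between the raw feature space and
# the per-feature standardized space z = (x - mu) / sdv: the hidden input
# c_j + W_j . x is preserved, so p(y|x) is unchanged
drbm_to_std <- function(params, mu, sdv) {
  Wz <- params$W * rep(sdv, each = nrow(params$W))
  drbm_params(Wz, params$c_h + as.numeric(params$W %*% mu), params$U, params$b)
}

drbm_from_std <- function(params, mu, sdv) {
  Wr <- params$W / rep(sdv, each = nrow(params$W))
  drbm_params(Wr, params$c_h - as.numeric(Wr %*% mu), params$U, params$b)
}

#' Train a discriminative RBM
#'
#' Maximizes the mean conditional log-likelihood `log p(y | x)` by
#' minibatch stochastic gradient ascent using the exact analytic gradient
#' (no sampling is involved: the two-class conditional is tractable).
#' Inputs are used as real-valued features. Parameters are initialized from
#' N(0, 0.01^2) under the seed in `opt`.
#'
#' With `standardize = TRUE` (the default) the optimization runs on
#' per-feature z-scored inputs, which makes the fixed learning rate
#' well-conditioned regardless of the feature scale; the returned
#' parameters are converted back to the raw feature space by an exact
#' reparameterization, so predictions always take raw features.
#'
#' @param data a [feature_set()] containing both classes.
#' @param H number of hidden units (default 10).
#' @param opt a [train_config()]; only `learning_rate` (default 0.05),
#'   `batch_size`, `max_epochs` (default 200) and `seed` are used. Use
#'   `batch_size = Inf` for full-batch ascent.
#' @param alpha generative-objective weight of the hybrid variant; only the
#'   purely discriminative model (`alpha = 0`) is implemented, since the
#'   generative term would require Monte Carlo sampling of the joint.
#' @param standardize optimize in the z-scored feature space (see above).
#' @return A [drbm_params()] object with the objective trace (mean
#'   conditional log-likelihood per epoch) in `attr(, "history")`.
#' @export
train_drbm <- function(data, H = 10,
                       opt = train_config(learning_rate = 0.05, max_epochs = 200),
                       alpha = 0, standardize = TRUE) {
  stopifnot(inherits(data, "feature_set"))
  assert_that(alpha == 0, "only the discriminative objective (alpha = 0) is implemented")
  X <- data$features
  y <- data$labels
  assert_that(length(unique(y)) == 2, "training data must contain both classes")
  n <- nrow(X)
  f <- ncol(X)
  mu <- rep(0, f)
  sdv <- rep(1, f)
  if (standardize) {
    mu <- colMeans(X)
    sdv <- sqrt(colMeans(X * X) - mu^2)
    sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
    X <- row_scale(row_center(X, mu), 1 / sdv)
  }
  with_seed(opt$seed, {
    params <- drbm_params(W = matrix(rnorm(H * f, sd = 0.01), H, f),
                          c_h = rnorm(H, sd = 0.01),
                          U = matrix(rnorm(H * 2, sd = 0.01), H, 2),
                          b = rnorm(2, sd = 0.01))
    if (standardize) params <- drbm_to_std(params, mu, sdv)
    bs <- if (is.finite(opt$batch_size)) opt$batch_size else n
    hist <- numeric(opt$max_epochs)
    for (ep in seq_len(opt$max_epochs)) {
      ord <- if (bs >= n) seq_len(n) else sample.int(n)
      for (s in seq(1L, n, by = bs)) {
        b_idx <- ord[s:min(s + bs - 1L, n)]
        g <- drbm_objective(params, X[b_idx, , drop = FALSE], y[b_idx])$grad
        params$W <- params$W + opt$learning_rate * g$W
        params$c_h <- params$c_h + opt$learning_rate * g$c_h
        params$U <- params$U + opt$learning_rate * g$U
        params$b <- params$b + opt$learning_rate * g$b
      }
      hist[ep] <- drbm_objective(params, X, y)$value
    }
    if (standardize) params <- drbm_from_std(params, mu, sdv)
    attr(params, "history") <- hist
    params
  })
}

#' Per-epoch target probability from a DRBM
#'
#' @param params a [drbm_params()].
#' @param feats a [feature_set()] of matching dimension.
#' @return Numeric vector of `p(target | x)`, one value per epoch;
#'   thresholding at 0.5 yields hard labels.
#' @export
predict_drbm <- function(params, feats) {
  stopifnot(inherits(feats, "feature_set"))
  drbm_conditional(params, feats$features)[, 2]
}
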