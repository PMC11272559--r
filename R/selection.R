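#' Distance-based source sample selection
#'
#' Builds a target reference `r` as the arithmetic mean of the (aligned)
#' target feature vectors, computes the Euclidean distance from every
#' source feature vector to `r`, and keeps the `k` closest source samples.
#' This discards source trials least similar to the target distribution
#' and so mitigates negative transfer. Distance ties are broken by lower
#' source index.
#'
#' @param target_feats a [feature_set()] (or matrix) of aligned target features.
#' @param source_feats a [feature_set()] (or matrix) of aligned source
#'   features, same dimension.
#' @param k number of source samples to keep, `1 <= k <= N_S` (`k = 0` is
#'   allowed and selects nothing).
#' @return A `selection_result` with `indices` (the k selected source row
#'   indices, in order of increasing distance), `distances` (ascending
#'   Euclidean distances) and `reference` (the target mean vector).
#' @export
select_source_samples <- function(target_feats, source_feats, k) {
  Yt <- if (inherits(target_feats, "feature_set")) target_feats$features else target_feats
  Ys <- if (inherits(source_feats, "feature_set")) source_feats$features else source_feats
  assert_that(is.matrix(Yt) && nrow(Yt) >= 1, "target set must be non-empty")
  assert_that(is.matrix(Ys) && nrow(Ys) >= 1, "source set must be non-empty")
  assert_that(ncol(Yt) == ncol(Ys), "feature dimensions differ")
  assert_that(is_count(k) && k <= nrow(Ys), "k must be an integer in 0..N_S")
  r <- colMeans(Yt)
  d <- sqrt(rowSums(row_center(Ys, r)^2))
  ord <- order(d)                       # stable: ties resolved by lower index
  idx <- head(ord, k)
  structure(list(indices = idx, distances = d[idx], reference = r,
                 all_distances = d),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d of %d source samples selected (max distance %.4g)\n",
              length(x$indices), length(x$all_distances),
              if (length(x$distances)) max(x$distances) else NA_real_))
  invisible(x)
}

#' Performance-based source subject selection
#'
#' Trains one classifier per candidate source subject on that subject's
#' full training set, evaluates each on a held-out fraction of the target
#' subject's training data (the last `eval_fraction` of trials in session
#' order), and returns the candidate with the highest evaluation accuracy.
#' Ties are broken in favor of the earliest candidate.
#'
#' @param candidates named list of [epoch_set()]s, one per source subject.
#' @param target_train the target subject's training [epoch_set()].
#' @param eval_fraction fraction of target training trials used for
#'   evaluation, in (0, 1).
#' @param trainer a function `f(epoch_set)` returning a prediction function
#'   `g(epoch_set) -> 0/1 labels`; defaults to [drbm_epoch_trainer()].
#' @return The name (subject id) of the selected candidate; the per-subject
#'   accuracies are attached as attribute `"accuracy"`.
#' @export
select_source_subject <- function(candidates, target_train, eval_fraction = 0.2,
                                  trainer = drbm_epoch_trainer()) {
  assert_that(is.list(candidates) && length(candidates) >= 1,
              "need at least one candidate")
  assert_that(is_scalar(eval_fraction) && eval_fraction > 0 && eval_fraction < 1,
              "eval_fraction must be in (0,1)")
  stopifnot(inherits(target_train, "epoch_set"))
  ids <- names(candidates) %||% as.character(seq_along(candidates))
  n <- dim(target_train$epochs)[1]
  n_eval <- round(eval_fraction * n)
  assert_that(n_eval >= 1, "evaluation split is empty")
  eval_set <- subset_epochs(target_train, (n - n_eval + 1L):n)
  acc <- vapply(candidates, function(ep) {
    pred <- trainer(ep)(eval_set)
    mean(pred == eval_set$labels)
  }, numeric(1))
  structure(ids[which.max(acc)], accuracy = stats::setNames(acc, ids))
}

#' Default subject-selection classifier
#'
#' Returns a trainer closure for [select_source_subject()]: a discriminative
#' RBM fit on flattened, z-scored epochs.
#'
#' @param H hidden units.
#' @param opt a [train_config()] for the RBM (the defaults follow
#'   [train_drbm()]).
#' @export
drbm_epoch_trainer <- function(H = 10, opt = train_config(learning_rate = 0.05,
                                                          max_epochs = 100)) {
  function(train_ep) {
    X <- matrix(train_ep$epochs, nrow = dim(train_ep$epochs)[1])
    mu <- colMeans(X)
    sdv <- apply(X, 2, sd)
    sdv[sdv < 1e-12] <- 1
    Z <- row_scale(row_center(X, mu), 1 / sdv)
    params <- train_drbm(feature_set(Z, train_ep$labels), H = H, opt = opt)
    function(test_ep) {
      Xt <- matrix(test_ep$epochs, nrow = dim(test_ep$epochs)[1])
      Zt <- row_scale(row_center(Xt, mu), 1 / sdv)
      as.integer(predict_drbm(params, feature_set(Zt, test_ep$labels)) > 0.5)
    }
  }
}
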