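#' Inverse square root of a symmetric nonnegative-definite matrix
#'
#' Computed by symmetric eigendecomposition with a ridge: eigenvalues are
#' floored at zero and shifted by `eps`, so the result `W` satisfies
#' `W %*% (M + eps * I) %*% W = I` to high accuracy even when `M` is rank
#' deficient (as the second-moment matrix of ReLU features often is when
#' the number of trials is small or units are correlated).
#'
#' @param M symmetric nonnegative-definite matrix.
#' @param eps positive ridge added to the eigenvalues.
#' @return A symmetric matrix `W = (M + eps I)^(-1/2)`.
#' @export
inv_sqrt <- function(M, eps = 1e-8) {
  assert_that(is.matrix(M) && nrow(M) == ncol(M) && all(is.finite(M)),
              "M must be a finite square matrix")
  scale <- max(abs(M), 1e-12)
  assert_that(max(abs(M - t(M))) <= 1e-8 * scale, "M must be symmetric")
  assert_that(is_scalar(eps) && eps > 0, "eps must be positive")
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  assert_that(min(e$values) > -1e-6 * scale - eps / 2,
              "M must be nonnegative definite")
  lam <- pmax(e$values, 0) + eps
  e$vectors %*% (t(e$vectors) / sqrt(lam))
}

default_eps <- function(R) max(1e-6 * sum(diag(R)) / nrow(R), 1e-12)

new_alignment_reference <- function(R, n_seen, eps, eps_auto = FALSE) {
  structure(list(R = R, n_seen = as.integer(n_seen), eps = eps,
                 eps_auto = eps_auto, W = inv_sqrt(R, eps)),
            class = "alignment_reference")
}

#' Euclidean-alignment reference from a feature set
#'
#' The reference matrix is the mean outer product of the feature vectors,
#' `R = (1/N) sum_n y_n y_n'` (the uncentered second moment), and its
#' regularized inverse square root `W = (R + eps I)^(-1/2)` is cached as
#' the alignment map.
#'
#' @param feats a [feature_set()] (or plain matrix) with N >= 1 rows.
#' @param eps ridge for the inversion; default `1e-6 * trace(R) / f`, a
#'   scale-aware floor that vanishes in the well-conditioned limit.
#' @return An `alignment_reference` with fields `R`, `n_seen`, `eps`, `W`.
#' @export
compute_reference <- function(feats, eps = NULL) {
  Y <- if (inherits(feats, "feature_set")) feats$features else feats
  assert_that(is.matrix(Y) && nrow(Y) >= 1, "need at least one feature vector")
  assert_that(all(is.finite(Y)), "features must be finite")
  R <- crossprod(Y) / nrow(Y)
  new_alignment_reference(R, nrow(Y), eps %||% default_eps(R),
                          eps_auto = is.null(eps))
}

#' An empty alignment reference
#'
#' Starting point for online reference accumulation; its map is the
#' identity until the first trial arrives.
#'
#' @param f feature dimension.
#' @param eps ridge used once trials accumulate (NULL: scale-aware default).
#' @export
empty_reference <- function(f, eps = NULL) {
  structure(list(R = matrix(0, f, f), n_seen = 0L, eps = eps,
                 eps_auto = is.null(eps), W = diag(f)),
            class = "alignment_reference")
}

#' @export
print.alignment_reference <- function(x, ...) {
  cat(sprintf("<alignment_reference> f = %d, n_seen = %d, eps = %s\n",
              nrow(x$R), x$n_seen, format(x$eps %||% NA)))
  invisible(x)
}

#' Align features into the whitened Euclidean space
#'
#' Maps every feature vector by the reference's inverse square root,
#' `y_tilde = W y`. A set aligned with its own reference has mean outer
#' product equal to the identity (up to the `eps` ridge and any null
#' directions of the reference).
#'
#' @param feats a [feature_set()].
#' @param ref an [compute_reference()] result of matching dimension.
#' @return The aligned [feature_set()].
#' @export
align_features <- function(feats, ref) {
  stopifnot(inherits(feats, "feature_set"), inherits(ref, "alignment_reference"))
  assert_that(ncol(feats$features) == nrow(ref$R),
              "feature dimension does not match the reference")
  feature_set(feats$features %*% ref$W, feats$labels, feats$codes,
              feats$character_index, feats$repetition_index)
}

#' Update an alignment reference with one unlabeled trial
#'
#' Running-mean update `R <- (n R + y y') / (n + 1)`; the cached inverse
#' square root is recomputed, so after streaming all N trials the online
#' reference equals the offline one computed from the same trials.
#'
#' @param ref an `alignment_reference`.
#' @param y a single feature vector.
#' @return The updated `alignment_reference`.
#' @export
online_update <- function(ref, y) {
  stopifnot(inherits(ref, "alignment_reference"))
  y <- as.numeric(y)
  assert_that(all(is.finite(y)), "feature vector must be finite")
  assert_that(length(y) == nrow(ref$R), "feature dimension mismatch")
  n <- ref$n_seen
  R <- (n * ref$R + tcrossprod(y)) / (n + 1)
  eps <- if (isTRUE(ref$eps_auto)) default_eps(R) else ref$eps %||% default_eps(R)
  new_alignment_reference(R, n + 1L, eps, eps_auto = isTRUE(ref$eps_auto))
}
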