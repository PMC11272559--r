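#' Decode one spelled character from per-epoch target scores
#'
#' For each of the 12 row/column codes the target probabilities are summed
#' over the first `Nr` repetitions; the predicted row is the highest-scoring
#' code among 1-6, the predicted column the highest among 7-12 (ties broken
#' by the lowest code), and the decoded symbol is their intersection in the
#' 6x6 matrix.
#'
#' @param scores data.frame with columns `code` (1-12), `repetition_index`
#'   and `p_target`, covering every code for repetitions `1..Nr` of one
#'   character.
#' @param Nr number of repetitions to accumulate.
#' @param alphabet the 6x6 symbol matrix (default [speller_alphabet()]).
#' @return The decoded symbol (length-1 character).
#' @export
decode_character <- function(scores, Nr, alphabet = speller_alphabet()) {
  assert_that(is.data.frame(scores) &&
                all(c("code", "repetition_index", "p_target") %in% names(scores)),
              "scores must have columns code, repetition_index, p_target")
  assert_that(is_count(Nr) && Nr >= 1, "Nr must be a positive integer")
  use <- scores[scores$repetition_index <= Nr, , drop = FALSE]
  counts <- table(factor(use$code, levels = 1:12))
  assert_that(all(counts == Nr),
              "scores must cover each of the 12 codes exactly once per repetition 1..Nr")
  s <- vapply(1:12, function(cd) sum(use$p_target[use$code == cd]), numeric(1))
  row <- which.max(s[1:6])
  col <- which.max(s[7:12])
  alphabet[row, col]
}

#' Decode a full speller session over all repetition budgets
#'
#' @param scores data.frame with columns `character_index`, `code`,
#'   `repetition_index`, `p_target` (one row per epoch).
#' @param Nr_range repetition budgets to evaluate (default `1:15`, clipped
#'   to the repetitions present).
#' @param alphabet the 6x6 symbol matrix.
#' @return A `speller_result`: a characters x budgets matrix of predicted
#'   symbols (columns named by Nr).
#' @export
decode_session <- function(scores, Nr_range = NULL, alphabet = speller_alphabet()) {
  assert_that(all(c("character_index", "code", "repetition_index", "p_target")
                  %in% names(scores)), "missing score columns")
  max_rep <- max(scores$repetition_index)
  Nr_range <- Nr_range %||% seq_len(min(15, max_rep))
  assert_that(all(Nr_range >= 1 & Nr_range <= max_rep), "Nr outside available repetitions")
  chars <- sort(unique(scores$character_index))
  pred <- matrix(NA_character_, length(chars), length(Nr_range),
                 dimnames = list(NULL, as.character(Nr_range)))
  for (i in seq_along(chars)) {
    sc <- scores[scores$character_index == chars[i], , drop = FALSE]
    for (j in seq_along(Nr_range))
      pred[i, j] <- decode_character(sc, Nr_range[j], alphabet)
  }
  structure(list(predictions = pred, characters = chars, Nr = Nr_range),
            class = "speller_result")
}

#' @export
print.speller_result <- function(x, ...) {
  cat(sprintf("<speller_result> %d characters x %d repetition budgets (Nr %s)\n",
              nrow(x$predictions), length(x$Nr),
              paste(range(x$Nr), collapse = "-")))
  invisible(x)
}

#' Character-recognition accuracy per repetition budget
#'
#' @param result a [decode_session()] result.
#' @param truth character vector of true symbols, one per decoded character.
#' @return Named numeric vector: percent of characters decoded correctly at
#'   each repetition budget, in `[0, 100]`.
#' @export
accuracy_curve <- function(result, truth) {
  stopifnot(inherits(result, "speller_result"))
  assert_that(length(truth) == nrow(result$predictions),
              "truth length must match the number of decoded characters")
  100 * colMeans(result$predictions == truth)
}

#' Information transfer rate of the speller
#'
#' `bits = log2(N) + P log2(P) + (1 - P) log2((1 - P) / (N - 1))` bits per
#' selection (with the convention `0 log 0 = 0`), and one selection takes
#' `T = 2.5 + (0.100 + 0.075) * 12 * Nr` seconds: a 2.5 s pause plus 12
#' intensifications of 100 ms flash + 75 ms gap per repetition.
#'
#' @param P character recognition accuracy, in `[0, 1]` (vectorized).
#' @param Nr number of repetitions per character, 1-15.
#' @param N alphabet size (36 for the 6x6 speller).
#' @return ITR in bits per minute.
#' @export
itr <- function(P, Nr, N = 36) {
  assert_that(all(is.finite(P)) && all(P >= 0) && all(P <= 1),
              "P must lie in [0,1]")
  assert_that(all(Nr >= 1 & Nr <= 15 & Nr == round(Nr)), "Nr must be an integer in 1..15")
  xlogx <- function(p) ifelse(p > 0, p * log2(p), 0)
  bits <- log2(N) + xlogx(P) + ifelse(P < 1, (1 - P) * log2((1 - P) / (N - 1)), 0)
  t_char <- 2.5 + (0.100 + 0.075) * 12 * Nr
  bits * 60 / t_char
}

#' Balanced classification accuracy
#'
#' The mean of the per-class accuracies, `(n1/m1 + n2/m2) / 2`, which is
#' insensitive to class prevalence and therefore suited to the ~1:9
#' target:non-target imbalance of RSVP data.
#'
#' @param m1 number of true target trials (>= 1).
#' @param n1 number of correctly classified target trials.
#' @param m2 number of true non-target trials (>= 1).
#' @param n2 number of correctly classified non-target trials.
#' @return BCA as a proportion in `[0, 1]`.
#' @export
bca <- function(m1, n1, m2, n2) {
  assert_that(is_count(m1) && m1 >= 1 && is_count(m2) && m2 >= 1,
              "both classes must contain at least one trial")
  assert_that(is_count(n1) && n1 <= m1 && is_count(n2) && n2 <= m2,
              "correct counts cannot exceed class sizes")
  (n1 / m1 + n2 / m2) / 2
}

#' BCA from true and predicted labels
#'
#' @param truth,pred 0/1 label vectors (1 = target).
#' @return BCA as a proportion.
#' @export
bca_from_labels <- function(truth, pred) {
  assert_that(length(truth) == length(pred), "label vectors differ in length")
  bca(m1 = sum(truth == 1), n1 = sum(truth == 1 & pred == 1),
      m2 = sum(truth == 0), n2 = sum(truth == 0 & pred == 0))
}
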