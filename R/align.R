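#' Banded Viterbi alignment of a peptide against a profile HMM
#'
#' Computes the best-scoring local alignment (local in both model and
#' target: alignments enter and exit at match states) under the classic
#' M/I/D profile-HMM recurrences, restricted to the diagonal band
#' `|(i - j) - (i0 - j0)| <= d` around the seed anchor.  Scores are in bits.
#' Ties in the max are broken with M > I > D preference, so tracebacks are
#' reproducible.
#'
#' @param model A [to_scoring()] model.
#' @param target Peptide string.
#' @param anchor Integer pair `(i0, j0)`: the seed's first match state and
#'   its 1-based position in the target; defines the band's central diagonal.
#' @param d Band half-width (default 20).
#' @param traceback Return the state path? (default TRUE)
#' @return An object of class `banded_alignment`: `score` (bits), `band`,
#'   `anchor`, `model_span`, `target_span` and (optionally) `path`, a tibble
#'   of `(state, i, j)` steps.
#' @export
banded_viterbi <- function(model, target, anchor, d = 20L, traceback = TRUE) {
  stopifnot(inherits(model, "scoring_model"), d >= 1, length(anchor) >= 2)
  i0 <- as.integer(anchor[1]); j0 <- as.integer(anchor[2])
  n <- nchar(target)
  if (i0 < 1 || i0 > model$L || j0 < 1 || j0 > n)
    stop("anchor outside model/target bounds", call. = FALSE)
  res <- cpp_local_viterbi(model$emit_M, model$emit_I, model$tr,
                           aa_codes(target), as.integer(d), i0 - j0,
                           traceback)
  path <- NULL
  mspan <- tspan <- c(NA_integer_, NA_integer_)
  if (traceback && length(res$state)) {
    path <- tibble(state = as.character(res$state),
                   i = as.integer(res$i), j = as.integer(res$j))
    mspan <- c(path$i[1], res$i_end)
    tspan <- c(path$j[1], res$j_end)
  }
  structure(list(score = res$score, band = as.integer(d),
                 anchor = c(i0 = i0, j0 = j0),
                 model_span = mspan, target_span = tspan, path = path),
            class = "banded_alignment")
}

#' @export
print.banded_alignment <- function(x, ...) {
  cat(sprintf("<banded_alignment> score %.3f bits, band %d, anchor (%d, %d)\n",
              x$score, x$band, x$anchor[1], x$anchor[2]))
  invisible(x)
}

#' Unbanded Viterbi score and parse
#'
#' The best local (in model and target) parse of the target under the model,
#' with traceback.  Equal to [banded_viterbi()] once the band covers the
#' whole dynamic-programming matrix.
#'
#' @param model A [to_scoring()] model.
#' @param target Non-empty peptide string.
#' @return List with `score` (bits) and `path` (tibble of `state`, `i`, `j`).
#' @export
full_viterbi <- function(model, target) {
  stopifnot(inherits(model, "scoring_model"), nchar(target) >= 1)
  res <- cpp_local_viterbi(model$emit_M, model$emit_I, model$tr,
                           aa_codes(target),
                           model$L + nchar(target) + 1L, 0L, TRUE)
  path <- if (length(res$state)) {
    tibble(state = as.character(res$state),
           i = as.integer(res$i), j = as.integer(res$j))
  }
  list(score = res$score, path = path)
}

#' Forward (all-parse) score
#'
#' The log2 of the summed probability-odds over every local parse of the
#' target -- the log-sum-exp analogue of [full_viterbi()], and always at
#' least the Viterbi score.  Used for full-model contig verification.
#'
#' @inheritParams full_viterbi
#' @return Score in bits.
#' @export
forward_score <- function(model, target) {
  stopifnot(inherits(model, "scoring_model"), nchar(target) >= 1)
  cpp_local_forward(model$emit_M, model$emit_I, model$tr, aa_codes(target),
                    model$L + nchar(target) + 1L, 0L)
}

# batch scorer over a list of targets (used by null calibration)
score_batch <- function(model, targets, forward = FALSE) {
  cpp_score_batch(model$emit_M, model$emit_I, model$tr,
                  lapply(targets, aa_codes), forward)
}
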