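#' Convert a profile HMM to log-odds scoring form
#'
#' Emissions become bit scores (`log2(p / background)`) and transitions
#' become `log2` probabilities, the currency used by every aligner in the
#' package.  Zero probabilities map to a large negative sentinel that is
#' immune to overflow under addition, so any path through them scores as
#' minus infinity.
#'
#' @param hmm A [profile_hmm].
#' @param background Optional length-20 probability vector; defaults to the
#'   model's own background (the file's `COMPO` line, or uniform).
#' @return An object of class `scoring_model` with elements `L`, `name`,
#'   `emit_M` and `emit_I` (`L x 20` bit-score matrices), `tr` (`L x 7`
#'   log2-probability matrix for source nodes `1..L`), `tr0` (begin-node
#'   transitions), `background` and `consensus` (per-position argmax residue).
#' @export
to_scoring <- function(hmm, background = NULL) {
  stopifnot(inherits(hmm, "profile_hmm"))
  bg <- background %||% hmm$background
  stopifnot(length(bg) == 20, abs(sum(bg) - 1) < 1e-3)
  bg <- bg / sum(bg)
  lo <- function(p) {
    s <- log2(sweep(p, 2, bg, "/"))
    s[p <= 0] <- NEG_SENTINEL
    s
  }
  l2 <- function(p) {
    s <- suppressWarnings(log2(p))
    s[p <= 0] <- NEG_SENTINEL
    s
  }
  emit_M <- lo(hmm$match_emit)
  cons_idx <- apply(emit_M, 1, which.max)
  structure(
    list(L = hmm$L, name = hmm$name,
         emit_M = emit_M, emit_I = lo(hmm$insert_emit),
         tr = l2(hmm$trans[-1, , drop = FALSE]),
         tr0 = l2(hmm$trans[1, , drop = FALSE]),
         background = as.numeric(bg),
         consensus = AA[cons_idx]),
    class = "scoring_model")
}

#' @export
print.scoring_model <- function(x, ...) {
  cat(sprintf("<scoring_model> %s: %d match states, consensus %s%s\n",
              x$name, x$L, paste(head(x$consensus, 30), collapse = ""),
              if (x$L > 30) "..." else ""))
  invisible(x)
}

#' Recover emission probabilities from a scoring model
#'
#' Inverse transform used by tests: `2^score * background` per cell.
#'
#' @param model A `scoring_model`.
#' @param which `"M"` or `"I"`.
#' @return An `L x 20` probability matrix.
#' @keywords internal
inverse_scoring <- function(model, which = c("M", "I")) {
  which <- match.arg(which)
  s <- if (which == "M") model$emit_M else model$emit_I
  p <- sweep(2^s, 2, model$background, "*")
  p[s <= NEG_SENTINEL / 2] <- 0
  p
}
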