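#' Maximum seed score of a model window
#'
#' The highest log-odds score (bits) achievable by any k-residue sequence
#' emitted from the `k` consecutive match states starting at `i0`: the sum of
#' the per-position maxima of the match emission scores.  Transition terms
#' are excluded (configurable seeding is purely emission-based; see the
#' methods vignette).
#'
#' @param model A [to_scoring()] model.
#' @param i0 1-based first match state of the window.
#' @param k Window length.
#' @return Score in bits.
#' @export
max_seed_score <- function(model, i0, k) {
  stopifnot(i0 >= 1, i0 + k - 1 <= model$L)
  sum(apply(model$emit_M[i0:(i0 + k - 1), , drop = FALSE], 1, max))
}

#' Find seed matches between a model and a read database
#'
#' For each window of `k` consecutive match states, candidate reads are
#' fetched from the reduced-alphabet index by the window's consensus k-gram
#' (the per-position argmax emission mapped to its reduced class), then
#' scored in the full alphabet as the sum of match emission scores.  A
#' candidate is kept when its seed score reaches `theta` times the window's
#' maximum seed score.  Windows whose maximum seed score is not positive
#' yield no seeds (a scale cutoff is meaningless below zero and such windows
#' cannot anchor a credible alignment).
#'
#' @param model A [to_scoring()] model.
#' @param db The [read_db] the index was built from.
#' @param index A [build_kgram_index()] index.
#' @param theta Score scale in (0, 1] (default 0.8).
#' @return A tibble with columns `read`, `offset` (1-based position of the
#'   k-gram in the read), `i0` (first match state), `k`, `seed_score` and
#'   `max_score`, sorted by descending `seed_score` with ties broken by
#'   `(read, i0, offset)`.
#' @export
find_seeds <- function(model, db, index, theta = 0.8) {
  stopifnot(theta > 0, theta <= 1, inherits(index, "kgram_index"))
  k <- index$k
  L <- model$L
  if (L < k) {
    return(tibble(read = integer(), offset = integer(), i0 = integer(),
                  k = integer(), seed_score = numeric(), max_score = numeric()))
  }
  rowmax <- apply(model$emit_M, 1, max)
  cmax <- c(0, cumsum(rowmax))
  win_max <- cmax[(k + 1):(L + 1)] - cmax[1:(L - k + 1)]  # per-window max score
  cons_red <- reduce_seq(paste(model$consensus, collapse = ""),
                         index$alphabet_map)
  out <- vector("list", L - k + 1)
  for (i0 in seq_len(L - k + 1)) {
    if (win_max[i0] <= 0) next
    key <- substr(cons_red, i0, i0 + k - 1)
    idxs <- index$table[[key]]
    if (is.null(idxs)) next
    rd <- index$read[idxs]
    off <- index$offset[idxs]
    grams <- substring(db$seq[rd], off, off + k - 1)
    codes <- matrix(.aa_tab[utf8ToInt(paste(grams, collapse = ""))],
                    ncol = k, byrow = TRUE)
    sc <- rowSums(matrix(model$emit_M[cbind(rep(i0:(i0 + k - 1),
                                                each = nrow(codes)),
                                            as.vector(codes) + 1L)],
                         ncol = k))
    keep <- sc >= theta * win_max[i0] - 1e-9
    if (any(keep)) {
      out[[i0]] <- tibble(read = rd[keep], offset = off[keep], i0 = i0,
                          k = k, seed_score = sc[keep],
                          max_score = win_max[i0])
    }
  }
  res <- bind_rows(out)
  if (!nrow(res)) {
    return(tibble(read = integer(), offset = integer(), i0 = integer(),
                  k = integer(), seed_score = numeric(), max_score = numeric()))
  }
  arrange(res, desc(.data$seed_score), .data$read, .data$i0, .data$offset)
}
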