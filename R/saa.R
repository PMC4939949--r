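#' Assembly parameter set
#'
#' Defaults follow the tool's standard operating point: seed length 6,
#' minimum assembly overlap 10, alignment band 20, maximum assembly depth 5
#' per direction, P-value cutoff 0.05 for candidate contigs and E-value
#' cutoff 0.01 for full-model verification.  The seed score scale `theta`
#' (0.8) and the score drop-off (10 bits) are the package's own defaults for
#' mechanisms whose magnitudes are tool-internal.
#'
#' @param k Seed length.
#' @param theta Seed score scale in (0, 1].
#' @param min_overlap Minimum suffix-prefix overlap for extension links.
#' @param band Alignment band half-width.
#' @param max_depth Maximum read-extensions per direction from the seed read.
#' @param dropoff Abandon a branch once its score falls this many bits below
#'   the branch's best.
#' @param pvalue_cutoff Candidate-contig significance cutoff.
#' @param evalue_cutoff Full-model verification cutoff.
#' @param null_n Null-calibration sample size.
#' @return A list of class `saa_params`.
#' @export
saa_params <- function(k = 6L, theta = 0.8, min_overlap = 10L, band = 20L,
                       max_depth = 5L, dropoff = 10, pvalue_cutoff = 0.05,
                       evalue_cutoff = 0.01, null_n = 200L) {
  stopifnot(k >= 3, theta > 0, theta <= 1, min_overlap >= 1, band >= 1,
            max_depth >= 0, dropoff > 0, pvalue_cutoff > 0, evalue_cutoff > 0,
            null_n >= 1)
  structure(list(k = as.integer(k), theta = theta,
                 min_overlap = as.integer(min_overlap), band = as.integer(band),
                 max_depth = as.integer(max_depth), dropoff = dropoff,
                 pvalue_cutoff = pvalue_cutoff, evalue_cutoff = evalue_cutoff,
                 null_n = as.integer(null_n)),
            class = "saa_params")
}

# sample n background peptide sequences with lengths drawn from `lengths`
sample_background_seqs <- function(n, lengths, background = rep(1 / 20, 20)) {
  len <- sample(lengths, n, replace = TRUE)
  vapply(len, function(l) {
    paste(sample(AA, l, replace = TRUE, prob = background), collapse = "")
  }, character(1))
}

# Gumbel (EVD) fit by method of moments
fit_gumbel <- function(x) {
  beta <- sd(x) * sqrt(6) / pi
  mu <- mean(x) - 0.57721566490153286 * beta
  list(mu = mu, beta = beta)
}

gumbel_sf <- function(s, fit) {
  # P(S >= s); guard the beta -> 0 degenerate case
  if (!is.finite(fit$beta) || fit$beta <= 0) return(as.numeric(s < fit$mu))
  -expm1(-exp(-(s - fit$mu) / fit$beta))
}

#' P-value of an alignment score from a null calibration sample
#'
#' Fits a Gumbel (extreme-value) distribution by the method of moments to
#' the scores of background-sampled sequences and returns the upper-tail
#' probability of the observed score.  With fewer than 30 calibration scores
#' the fit is refused and an empirical rank P-value
#' `(1 + #{null >= s}) / (N + 1)` is used instead.  Monotone decreasing in
#' the score.  These P-values rank candidate contigs; the pipeline's
#' precision is anchored by full-model E-value verification.
#'
#' For local alignment the null-score location grows with the logarithm of
#' the target length; when `score_len` and `calibration_len` are supplied
#' the fitted Gumbel location is shifted by `beta * ln(score_len /
#' calibration_len)` per score, so sequences of different lengths are judged
#' against a length-matched null.
#'
#' @param model A `scoring_model` (recorded for provenance; the calibration
#'   sample already determines the null).
#' @param score Numeric vector of scores in bits.
#' @param calibration Numeric vector of null scores (see
#'   [null_viterbi_scores()]).
#' @param score_len Optional lengths of the scored sequences (recycled).
#' @param calibration_len Optional length at which the calibration sample
#'   was drawn; required for the length correction.
#' @return P-values in `[0, 1]`, same length as `score`.
#' @export
score_pvalue <- function(model, score, calibration, score_len = NULL,
                         calibration_len = NULL) {
  n <- length(calibration)
  if (n < 30) {
    return(vapply(score, function(s) (1 + sum(calibration >= s)) / (n + 1),
                  numeric(1)))
  }
  fit <- fit_gumbel(calibration)
  if (is.null(score_len) || is.null(calibration_len)) {
    return(vapply(score, gumbel_sf, numeric(1), fit = fit))
  }
  score_len <- rep_len(score_len, length(score))
  vapply(seq_along(score), function(q) {
    gumbel_sf(score[q], list(mu = fit$mu +
                               fit$beta * log(score_len[q] / calibration_len),
                             beta = fit$beta))
  }, numeric(1))
}

#' Null Viterbi score sample for P-value calibration
#'
#' Scores of `n` background-sampled sequences (lengths drawn from the given
#' length set) under the model, computed with the unbanded local Viterbi
#' scorer.
#'
#' @param model A `scoring_model`.
#' @param lengths Length pool for the null sequences.
#' @param n Sample size (default 200).
#' @param seed RNG seed.
#' @param forward Score with the forward algorithm instead of Viterbi.
#' @return Numeric vector of `n` scores in bits.
#' @export
null_viterbi_scores <- function(model, lengths, n = 200L, seed = NULL,
                                forward = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- sample_background_seqs(n, lengths, model$background)
  as.numeric(score_batch(model, seqs, forward = forward))
}

.empty_contigs <- function() {
  tibble(family = character(), contig_id = character(), seq = character(),
         length = integer(), score = numeric(), i0 = integer(),
         j0 = integer(), n_reads = integer(), reads = list())
}

#' Assemble candidate contigs for one protein family
#'
#' The simultaneous alignment and assembly loop.  Seeds are processed in
#' descending score order; each seed's read starts a contig that is
#' alternately extended C- and N-terminally along the extension links of its
#' terminating reads, re-running the banded Viterbi alignment after every
#' extension.  A branch is abandoned when (a) its score falls more than
#' `dropoff` bits below the branch's best, (b) the extension depth in that
#' direction exceeds `max_depth`, or (c) the successor read was already
#' consumed at a nearby model position by an equal-or-better contig.  The
#' best-scoring contig along each maximal path is emitted.
#'
#' @param model A [to_scoring()] model.
#' @param db A [read_db].
#' @param kgram_index A [build_kgram_index()] index (same `k` as `params`).
#' @param link_index A [build_extension_links()] index (same `min_overlap`).
#' @param params An [saa_params()] set.
#' @return A tibble of candidate contigs: `family`, `contig_id`, `seq`,
#'   `length`, `score` (bits), anchor `i0`/`j0`, `n_reads` and a `reads`
#'   list-column of `(read, offset)` tibbles.
#' @export
assemble_family <- function(model, db, kgram_index, link_index,
                            params = saa_params()) {
  stopifnot(kgram_index$k == params$k,
            link_index$min_overlap == params$min_overlap)
  seeds <- find_seeds(model, db, kgram_index, theta = params$theta)
  if (!nrow(seeds)) return(.empty_contigs())
  consumed <- new.env(hash = TRUE, parent = emptyenv())
  lens <- nchar(db$seq)
  out <- list()
  n_out <- 0L

  rkey <- function(read, mpos) {
    paste0(read, ":", 10L * as.integer(round(mpos / 10)))
  }
  consumed_at_least <- function(key, sc) {
    v <- consumed[[key]]
    !is.null(v) && v >= sc
  }
  node_score <- function(seq, i0, j0) {
    cpp_local_viterbi(model$emit_M, model$emit_I, model$tr, aa_codes(seq),
                      params$band, i0 - j0, FALSE)$score
  }
  # model position of a read whose first residue sits at contig offset `off`,
  # assuming the anchor diagonal
  read_mpos <- function(i0, j0, off) i0 - (j0 - 1L) + (off - 1L)

  emit_contig <- function(node) {
    n_out <<- n_out + 1L
    out[[n_out]] <<- tibble(
      family = model$name, contig_id = sprintf("%s_c%04d", model$name, n_out),
      seq = node$seq, length = nchar(node$seq), score = node$score,
      i0 = node$i0, j0 = node$j0, n_reads = nrow(node$reads),
      reads = list(node$reads))
    for (r in seq_len(nrow(node$reads))) {
      key <- rkey(node$reads$read[r],
                  read_mpos(node$i0, node$j0, node$reads$offset[r]))
      consumed[[key]] <- max(consumed[[key]] %||% -Inf, node$score)
    }
  }

  children_of <- function(node, dir) {
    if (dir == "C") {
      ends <- node$reads$offset + lens[node$reads$read] - 1L
      term <- node$reads$read[which.max(ends)]
      adj <- link_index$fwd[[term]]
      if (is.null(adj) || !nrow(adj)) return(list())
      lapply(seq_len(nrow(adj)), function(q) {
        succ <- adj$to[q]; o <- adj$overlap[q]
        ext <- substr(db$seq[succ], o + 1L, lens[succ])
        if (!nzchar(ext)) return(NULL)
        off <- max(ends) - o + 1L
        list(seq = paste0(node$seq, ext),
             reads = bind_rows(node$reads, tibble(read = succ, offset = off)),
             i0 = node$i0, j0 = node$j0,
             cdepth = node$cdepth + 1L, ndepth = node$ndepth,
             new_read = succ, new_off = off)
      })
    } else {
      term <- node$reads$read[which.min(node$reads$offset)]
      adj <- link_index$rev[[term]]
      if (is.null(adj) || !nrow(adj)) return(list())
      lapply(seq_len(nrow(adj)), function(q) {
        pred <- adj$from[q]; o <- adj$overlap[q]
        shift <- lens[pred] - o
        if (shift <= 0L) return(NULL)
        ext <- substr(db$seq[pred], 1L, shift)
        reads <- node$reads
        reads$offset <- reads$offset + shift
        reads <- bind_rows(tibble(read = pred, offset = 1L), reads)
        list(seq = paste0(ext, node$seq),
             reads = reads, i0 = node$i0, j0 = node$j0 + shift,
             cdepth = node$cdepth, ndepth = node$ndepth + 1L,
             new_read = pred, new_off = 1L)
      })
    }
  }

  extend <- function(node, path_best, prefer, visited) {
    if (node$score > path_best$score) path_best <- node
    dirs <- if (prefer == "C") c("C", "N") else c("N", "C")
    expanded <- FALSE
    for (dir in dirs) {
      if (dir == "C" && node$cdepth >= params$max_depth) next
      if (dir == "N" && node$ndepth >= params$max_depth) next
      kids <- children_of(node, dir)
      any_kid <- FALSE
      for (kid in kids) {
        if (is.null(kid)) next
        vkey <- as.character(kid$new_read)
        if (!is.null(visited[[vkey]])) next  # within-seed read redundancy
        key <- rkey(kid$new_read, read_mpos(kid$i0, kid$j0, kid$new_off))
        kid$score <- node_score(kid$seq, kid$i0, kid$j0)
        if (kid$score < path_best$score - params$dropoff) next
        if (consumed_at_least(key, kid$score)) next
        consumed[[key]] <- kid$score  # eager cross-seed redundancy marking
        visited[[vkey]] <- TRUE
        any_kid <- TRUE
        extend(kid, path_best, if (dir == "C") "N" else "C", visited)
      }
      if (any_kid) { expanded <- TRUE; break }
    }
    if (!expanded) emit_contig(path_best)
    invisible(NULL)
  }

  for (s in seq_len(nrow(seeds))) {
    sd_read <- seeds$read[s]
    # anchor of the seeding read: its k-gram at seeds$offset matches state i0
    j0 <- seeds$offset[s]
    i0 <- seeds$i0[s]
    key <- rkey(sd_read, read_mpos(i0, j0, 1L))
    node <- list(seq = db$seq[sd_read],
                 reads = tibble(read = sd_read, offset = 1L),
                 i0 = i0, j0 = j0, cdepth = 0L, ndepth = 0L)
    node$score <- node_score(node$seq, i0, j0)
    if (consumed_at_least(key, node$score)) next
    consumed[[key]] <- node$score
    visited <- new.env(hash = TRUE, parent = emptyenv())
    visited[[as.character(sd_read)]] <- TRUE
    extend(node, node, "C", visited)
  }
  if (!n_out) return(.empty_contigs())
  bind_rows(out)
}

#' Recalibrate contigs by cross-contig assembly
#'
#' Greedily merges contigs of one family that share an exact suffix-prefix
#' overlap of at least `min_overlap` residues (longest overlap first);
#' merged contigs inherit the union of constituent reads, and merged
#' sequences are re-scored with the banded aligner.  Identical duplicates
#' collapse, and no returned contig is a substring of another.
#'
#' @param contigs A candidate-contig tibble from [assemble_family()].
#' @param min_overlap Minimum merge overlap.
#' @param model Optional `scoring_model`; when given, merged contigs are
#'   re-scored.
#' @param band Band half-width for re-scoring.
#' @param db Optional [read_db]; when given, a merge whose constituent reads
#'   no longer tile the merged sequence exactly is skipped and both inputs
#'   are kept.
#' @return A tibble with the same columns as the input.
#' @export
recalibrate <- function(contigs, min_overlap = 10L, model = NULL, band = 20L,
                        db = NULL) {
  if (!nrow(contigs)) return(contigs)
  # collapse identical sequences, keeping the best-scoring representative
  contigs <- contigs |>
    arrange(desc(.data$score)) |>
    distinct(.data$seq, .keep_all = TRUE)
  rows <- lapply(seq_len(nrow(contigs)), function(i) contigs[i, ])
  blocked <- character(0)  # merge pairs that produced inconsistent reads
  repeat {
    nr <- length(rows)
    if (nr < 2) break
    # candidate merges via the suffix-keyed overlap kernel (greedy: longest)
    seqs <- vapply(rows, function(r) r$seq, character(1))
    cand <- cpp_overlap_links(seqs, as.integer(min_overlap))
    if (nrow(cand)) {
      cand <- cand[!(paste(seqs[cand$from], seqs[cand$to]) %in% blocked), ,
                   drop = FALSE]
      cand <- cand[order(-cand$overlap), , drop = FALSE]
    }
    if (!nrow(cand)) break
    best <- list(a = cand$from[1], b = cand$to[1], o = cand$overlap[1])
    A <- rows[[best$a]]; B <- rows[[best$b]]; o <- best$o
    shift <- nchar(A$seq) - o
    merged_seq <- paste0(A$seq, substr(B$seq, o + 1L, nchar(B$seq)))
    rb <- B$reads[[1]]
    rb$offset <- rb$offset + shift
    reads <- distinct(bind_rows(A$reads[[1]], rb),
                      .data$read, .data$offset)
    if (!is.null(db)) {
      rl <- nchar(db$seq[reads$read])
      ok <- all(substring(merged_seq, reads$offset, reads$offset + rl - 1L) ==
                  db$seq[reads$read])
      if (!ok) {  # skip this merge, keep both inputs
        blocked <- c(blocked, paste(A$seq, B$seq))
        next
      }
    }
    sc <- max(A$score, B$score)
    if (!is.null(model)) {
      sc <- cpp_local_viterbi(model$emit_M, model$emit_I, model$tr,
                              aa_codes(merged_seq), as.integer(band),
                              A$i0 - A$j0, FALSE)$score
    }
    merged <- A
    merged$seq <- merged_seq
    merged$length <- nchar(merged_seq)
    merged$score <- sc
    merged$n_reads <- nrow(reads)
    merged$reads <- list(reads)
    rows <- c(rows[-c(best$a, best$b)], list(merged))
  }
  res <- bind_rows(rows)
  # substring removal: drop contigs contained in a longer one
  ord <- order(-nchar(res$seq))
  keep <- rep(TRUE, nrow(res))
  for (q in seq_along(ord)) {
    i <- ord[q]
    if (!keep[i]) next
    for (p in seq_len(q - 1L)) {
      j <- ord[p]
      if (keep[j] && grepl(res$seq[i], res$seq[j], fixed = TRUE)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  res <- res[keep, , drop = FALSE]
  res$contig_id <- sprintf("%s_r%04d", res$family, seq_len(nrow(res)))
  res
}
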