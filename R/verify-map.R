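#' Verify candidate contigs against the full model
#'
#' Each contig is re-scored with the unbanded forward algorithm over the
#' whole model and assigned an E-value `N_eff * P(score)`, where `P` comes
#' from a Gumbel fit to length-corrected null forward scores of
#' background-sampled sequences, and the effective database size `N_eff` is
#' the number of reads the candidates were selected from (candidate contigs
#' are the best survivors of a search over the whole read database, so the
#' expected count of equally good null hits must be scaled by that search
#' size).  Contigs failing the cutoff are dropped unless
#' `keep_all = TRUE` (in which case all rows are returned with a `verified`
#' flag).  A custom verifier -- e.g. an external HMMER-compatible search --
#' may be supplied instead via `verifier`.
#'
#' @param contigs Candidate-contig tibble ([assemble_family()] /
#'   [recalibrate()] output).
#' @param model A [to_scoring()] model.
#' @param evalue_cutoff Significance cutoff (default 0.01); must be positive.
#' @param null_n Null sample size (default 200).
#' @param n_eff Effective search-space size; defaults to the number of
#'   candidate contigs, but callers holding the read database should pass
#'   its read count.
#' @param seed RNG seed for the null sample.
#' @param keep_all Return failing contigs too, flagged?
#' @param verifier Optional function `f(seqs) -> logical` replacing the
#'   internal significance test.
#' @return The contig tibble with `forward_score`, `evalue` and `verified`
#'   columns, restricted to verified contigs unless `keep_all`.
#' @export
verify_contigs <- function(contigs, model, evalue_cutoff = 0.01,
                           null_n = 200L, n_eff = NULL, seed = NULL,
                           keep_all = FALSE, verifier = NULL) {
  if (evalue_cutoff <= 0) stop("evalue_cutoff must be positive", call. = FALSE)
  if (!nrow(contigs)) {
    out <- contigs
    out$forward_score <- numeric(0)
    out$evalue <- numeric(0)
    out$verified <- logical(0)
    return(out)
  }
  if (!is.null(verifier)) {
    contigs$forward_score <- NA_real_
    contigs$evalue <- NA_real_
    contigs$verified <- as.logical(verifier(contigs$seq))
  } else {
    fwd <- as.numeric(score_batch(model, contigs$seq, forward = TRUE))
    lens <- nchar(contigs$seq)
    l0 <- as.integer(round(median(lens)))
    null <- null_viterbi_scores(model, l0, n = null_n,
                                seed = seed, forward = TRUE)
    p <- score_pvalue(model, fwd, null, score_len = lens,
                      calibration_len = l0)
    n_eff <- n_eff %||% nrow(contigs)
    contigs$forward_score <- fwd
    contigs$evalue <- pmin(n_eff * p, n_eff)
    contigs$verified <- contigs$evalue <= evalue_cutoff
  }
  if (keep_all) contigs else filter(contigs, .data$verified)
}

#' Recruit database reads onto trusted contigs
#'
#' A read is recruited when some contig admits an ungapped placement
#' covering strictly more than `min_portion` of the read with at most
#' `max_mismatch` substitutions; placements may run off contig ends, with
#' only the overlapping portion counting toward the fraction.  The best
#' placement per read/contig pair (fewest mismatches, then longest overlap)
#' is reported.  `X` counts as a mismatch against everything.
#'
#' @param db A [read_db].
#' @param verified Verified-contig tibble (needs `contig_id`, `seq`,
#'   `family`; `evalue` is carried through when present).
#' @param max_mismatch Maximum substitutions (default 3).
#' @param min_portion Strict lower bound on the mapped fraction (default 0.6).
#' @return A tibble of assignments: `read` (handle), `read_id`, `family`,
#'   `contig_id`, `offset`, `mismatches`, `overlap`, `fraction`, plus
#'   `evalue` when available.
#' @export
map_reads <- function(db, verified, max_mismatch = 3L, min_portion = 0.6) {
  empty <- tibble(read = integer(), read_id = character(),
                  family = character(), contig_id = character(),
                  offset = integer(), mismatches = integer(),
                  overlap = integer(), fraction = numeric(),
                  evalue = numeric())
  if (!nrow(verified)) return(empty)
  hits <- as_tibble(cpp_map_reads(db$seq, verified$seq,
                                  as.integer(max_mismatch), min_portion))
  if (!nrow(hits)) return(empty)
  out <- tibble(
    read = hits$read,
    read_id = db$id[hits$read],
    family = verified$family[hits$contig],
    contig_id = verified$contig_id[hits$contig],
    offset = hits$offset,
    mismatches = hits$mismatches,
    overlap = hits$overlap,
    fraction = hits$overlap / nchar(db$seq[hits$read]),
    evalue = if ("evalue" %in% names(verified))
      verified$evalue[hits$contig] else NA_real_)
  # one row per read and family: best contig placement
  out |>
    arrange(.data$mismatches, desc(.data$overlap)) |>
    distinct(.data$read, .data$family, .keep_all = TRUE)
}

#' Resolve reads recruited by several families
#'
#' Each read keeps only the assignment whose contig has the most significant
#' (smallest) E-value; ties are broken by fewer mismatches, then by
#' lexicographic family name.
#'
#' @param assignments A [map_reads()] tibble (possibly concatenated across
#'   families).
#' @return The tibble with at most one row per read.
#' @export
resolve_multi_family <- function(assignments) {
  if (!nrow(assignments)) return(assignments)
  assignments |>
    arrange(.data$evalue, .data$mismatches, .data$family) |>
    distinct(.data$read, .keep_all = TRUE)
}
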