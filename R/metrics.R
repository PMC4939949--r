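#' Recall, precision and F-measure of a read prediction
#'
#' Exact set arithmetic over read identifiers: `TP` are predicted reads that
#' are truly homologous, `FP` predicted non-homologous reads, `FN`
#' un-predicted homologous reads.  `recall = TP/(TP+FN)`,
#' `precision = TP/(TP+FP)` and `F = 2RP/(R+P)` (harmonic mean).  With an
#' empty truth set the recall (and F) are undefined and returned as `NaN`
#' with `undefined = TRUE`.
#'
#' @param predicted Character vector (or set) of predicted read ids.
#' @param truth Character vector of true homologous read ids.
#' @return One-row tibble: `tp`, `fp`, `fn`, `recall`, `precision`,
#'   `f_measure`, `undefined`.
#' @export
recall_precision_f <- function(predicted, truth) {
  predicted <- unique(as.character(predicted))
  truth <- unique(as.character(truth))
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  recall <- if (tp + fn > 0) tp / (tp + fn) else NaN
  precision <- if (tp + fp > 0) tp / (tp + fp) else NaN
  f <- f_measure(recall, precision)
  tibble(tp = tp, fp = fp, fn = fn, recall = recall, precision = precision,
         f_measure = f, undefined = length(truth) == 0)
}

#' Harmonic mean of recall and precision
#'
#' @param recall,precision Rates in `[0, 1]`.
#' @return `2 * R * P / (R + P)`, or `NaN` when undefined, 0 when both are 0.
#' @export
f_measure <- function(recall, precision) {
  ifelse(is.nan(recall) | is.nan(precision), NaN,
         ifelse(recall + precision > 0,
                2 * recall * precision / (recall + precision), 0))
}

#' Reads per kilobase per million (RPKM)
#'
#' Depth- and length-normalized family abundance.  The reference length of a
#' protein-family model is its match-state count; because the kilobase is a
#' nucleotide unit the default converts it to nucleotide-equivalent length
#' (`aa * 3`) before normalizing (`basis = "nt"`); `basis = "aa"` divides by
#' the amino-acid length directly.
#'
#' @param count Recruited read count (vectorized).
#' @param model_len Model length in match states.
#' @param total_reads Library size (total reads in the database).
#' @param basis `"nt"` (default) or `"aa"`.
#' @return RPKM values.
#' @export
rpkm <- function(count, model_len, total_reads, basis = c("nt", "aa")) {
  basis <- match.arg(basis)
  stopifnot(all(total_reads > 0), all(model_len > 0))
  kb <- model_len * (if (basis == "nt") 3 else 1) / 1000
  count / kb / (total_reads / 1e6)
}

#' N50 of a contig length set
#'
#' The smallest length `l` such that contigs of length at least `l` together
#' hold at least half the total assembled residues.  An empty set yields 0
#' (flagged via the `"empty"` attribute).
#'
#' @param lengths Integer vector of contig lengths.
#' @return The N50 length.
#' @export
n50 <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (!length(lengths)) return(structure(0, empty = TRUE))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Normalized N50
#'
#' N50 over the length of the querying protein-family model: for protein
#' contigs `N50 / L`, for nucleotide contigs `N50 / (3 * L)` (the codon
#' length).
#'
#' @param lengths Contig lengths (aa for `space = "protein"`, nt for
#'   `space = "nucleotide"`).
#' @param model_len Model length in match states (aa).
#' @param space `"protein"` or `"nucleotide"`.
#' @return The normalized N50 fraction.
#' @export
normalized_n50 <- function(lengths, model_len, space = c("protein", "nucleotide")) {
  space <- match.arg(space)
  stopifnot(model_len > 0)
  as.numeric(n50(lengths)) / (model_len * (if (space == "protein") 1 else 3))
}

#' Read- and contig-level assembly precision
#'
#' True contigs (`t.c.`) are those passing the supplied verifier; true reads
#' (`t.r.`) are reads that map (under the standard mapping rules) onto a
#' true contig.  `c.P. = #trueContigs / #totalContigs` and
#' `r.P. = #trueReads / #totalReads`, where the totals cover all (length-
#' filtered) contigs and all reads mapping onto them.  The optional length
#' filter keeps protein contigs strictly longer than 60 aa (equivalently
#' nucleotide contigs strictly longer than 180 nt).
#'
#' @param contigs Contig tibble (`contig_id`, `seq`, `family`).
#' @param db A [read_db] of the peptide reads.
#' @param verifier Function `f(seqs) -> logical` deciding contig truth
#'   (e.g. full-model significance at E <= 0.01).
#' @param model_len Model length for the normalized N50.
#' @param space `"protein"` or `"nucleotide"` for the N50 normalization.
#' @param length_filter Apply the >60 aa (180 nt) contig filter?
#' @param max_mismatch,min_portion Mapping thresholds.
#' @return One-row tibble: `total_contigs`, `true_contigs`,
#'   `contig_precision`, `total_reads`, `true_reads`, `read_precision`,
#'   `n50`, `normalized_n50`.
#' @export
contig_read_precision <- function(contigs, db, verifier, model_len,
                                  space = c("protein", "nucleotide"),
                                  length_filter = TRUE,
                                  max_mismatch = 3L, min_portion = 0.6) {
  space <- match.arg(space)
  if (length_filter && nrow(contigs)) {
    aa_len <- nchar(contigs$seq)
    contigs <- contigs[aa_len > 60, , drop = FALSE]
  }
  if (!nrow(contigs)) {
    return(tibble(total_contigs = 0L, true_contigs = 0L,
                  contig_precision = NaN, total_reads = 0L, true_reads = 0L,
                  read_precision = NaN, n50 = 0,
                  normalized_n50 = 0))
  }
  is_true <- as.logical(verifier(contigs$seq))
  all_map <- map_reads(db, contigs, max_mismatch, min_portion)
  true_map <- map_reads(db, contigs[is_true, , drop = FALSE],
                        max_mismatch, min_portion)
  total_reads <- length(unique(all_map$read))
  true_reads <- length(unique(true_map$read))
  lens <- nchar(contigs$seq) * (if (space == "nucleotide") 3L else 1L)
  tibble(total_contigs = nrow(contigs), true_contigs = sum(is_true),
         contig_precision = sum(is_true) / nrow(contigs),
         total_reads = total_reads, true_reads = true_reads,
         read_precision = if (total_reads > 0) true_reads / total_reads else NaN,
         n50 = as.numeric(n50(lens)),
         normalized_n50 = normalized_n50(lens, model_len, space))
}

#' Per-family evaluation of read assignments against ground truth
#'
#' @param assignments A resolved assignment tibble (`read_id`, `family`).
#' @param truth Ground-truth tibble (`read_id`, `family`).
#' @return A tibble with one [recall_precision_f()] row per family present
#'   in either table, plus a macro-average row (`family = "average"`).
#' @export
evaluate_assignments <- function(assignments, truth) {
  fams <- sort(union(unique(assignments$family), unique(truth$family)))
  rows <- lapply(fams, function(f) {
    r <- recall_precision_f(assignments$read_id[assignments$family == f],
                            truth$read_id[truth$family == f])
    mutate(r, family = f, .before = 1)
  })
  per <- bind_rows(rows)
  avg <- tibble(family = "average", tp = sum(per$tp), fp = sum(per$fp),
                fn = sum(per$fn),
                recall = mean(per$recall, na.rm = TRUE),
                precision = mean(per$precision, na.rm = TRUE),
                f_measure = NA_real_, undefined = FALSE)
  avg$f_measure <- f_measure(avg$recall, avg$precision)
  bind_rows(per, avg)
}
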