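#' Search profile HMMs against a peptide read database
#'
#' The full pipeline for one or more query families against one database:
#' build the k-gram and extension-link indexes (or reuse prebuilt ones),
#' then per family seed, extend and assemble candidate contigs
#' ([assemble_family()]), merge them ([recalibrate()]), rank them by
#' banded-score P-value, verify survivors against the full model
#' ([verify_contigs()]), recruit reads onto trusted contigs ([map_reads()])
#' and finally resolve reads hit by several families to the most significant
#' one ([resolve_multi_family()]).
#'
#' @param models A [profile_hmm], list of them, or path to a `.hmm` file.
#' @param db A [read_db] or path to a peptide FASTA.
#' @param params An [saa_params()] set.
#' @param seed RNG seed for the null calibrations.
#' @param kgram_index,link_index Optional prebuilt indexes.
#' @param verifier Optional external contig verifier, passed to
#'   [verify_contigs()].
#' @return An object of class `saa_result`: tibbles `contigs` (all
#'   recalibrated candidates with `pvalue`, `forward_score`, `evalue`,
#'   `verified`), `assignments` (one row per recruited read after
#'   family resolution), `families` (per-family summary with read counts and
#'   RPKM), plus `params` and `total_reads`.
#' @export
saa_search <- function(models, db, params = saa_params(), seed = 1L,
                       kgram_index = NULL, link_index = NULL,
                       verifier = NULL) {
  if (is.character(models)) models <- parse_hmm(models)
  if (inherits(models, "profile_hmm")) models <- list(models)
  if (is.character(db)) db <- load_reads(db)
  kgram_index <- kgram_index %||% build_kgram_index(db, k = params$k)
  link_index <- link_index %||% build_extension_links(db, params$min_overlap)
  all_contigs <- list()
  all_assign <- list()
  fam_rows <- list()
  for (m in models) {
    sm <- to_scoring(m)
    cand <- assemble_family(sm, db, kgram_index, link_index, params)
    n_cand <- nrow(cand)
    cand <- recalibrate(cand, params$min_overlap, model = sm,
                        band = params$band, db = db)
    if (nrow(cand)) {
      l0 <- as.integer(round(median(nchar(cand$seq))))
      null_v <- null_viterbi_scores(sm, l0, n = params$null_n, seed = seed)
      cand$pvalue <- score_pvalue(sm, cand$score, null_v,
                                  score_len = nchar(cand$seq),
                                  calibration_len = l0)
      cand <- filter(cand, .data$pvalue <= params$pvalue_cutoff)
    }
    ver <- verify_contigs(cand, sm, evalue_cutoff = params$evalue_cutoff,
                          null_n = params$null_n, n_eff = db$n, seed = seed,
                          keep_all = TRUE, verifier = verifier)
    all_contigs[[m$name]] <- ver
    trusted <- filter(ver, .data$verified)
    asn <- map_reads(db, trusted, max_mismatch = 3L, min_portion = 0.6)
    all_assign[[m$name]] <- asn
    fam_rows[[m$name]] <- tibble(
      family = m$name, model_len = m$L, n_candidates = n_cand,
      n_contigs = nrow(ver), n_verified = nrow(trusted))
  }
  contigs <- bind_rows(all_contigs)
  assignments <- resolve_multi_family(bind_rows(all_assign))
  families <- bind_rows(fam_rows)
  counts <- assignments |>
    group_by(.data$family) |>
    summarise(n_reads = dplyr::n_distinct(.data$read))
  families <- left_join(families, counts, by = "family") |>
    mutate(n_reads = ifelse(is.na(.data$n_reads), 0L, .data$n_reads),
           rpkm = rpkm(.data$n_reads, .data$model_len, db$n))
  structure(list(contigs = contigs, assignments = assignments,
                 families = families, params = params,
                 total_reads = db$n, seed = seed),
            class = "saa_result")
}

#' @export
print.saa_result <- function(x, ...) {
  cat(sprintf(paste0("<saa_result> %d famil%s, %d/%d contigs verified, ",
                     "%d reads recruited of %d\n"),
              nrow(x$families), if (nrow(x$families) == 1) "y" else "ies",
              sum(x$contigs$verified), nrow(x$contigs),
              nrow(x$assignments), x$total_reads))
  invisible(x)
}

#' Per-family abundance from read assignments
#'
#' Raw recruited-read counts per family, normalized to RPKM against the
#' model length (in nucleotide-equivalent kilobases by default) and the
#' database size.
#'
#' @param assignments A resolved assignment tibble (`read`, `family`).
#' @param model_lens Named vector of model lengths (match states) per family.
#' @param total_reads Database size.
#' @param basis RPKM length basis, `"nt"` or `"aa"`.
#' @return Tibble: `family`, `count`, `model_len`, `rpkm`.
#' @export
abundance <- function(assignments, model_lens, total_reads,
                      basis = c("nt", "aa")) {
  basis <- match.arg(basis)
  tibble(family = names(model_lens),
         model_len = as.numeric(model_lens)) |>
    left_join(assignments |>
                group_by(.data$family) |>
                summarise(count = dplyr::n_distinct(.data$read)),
              by = "family") |>
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count),
           rpkm = rpkm(.data$count, .data$model_len, total_reads, basis))
}
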