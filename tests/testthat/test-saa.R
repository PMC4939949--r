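make_family_fixture <- function(L = 60, coverage = 10, error = 0,
                                n_decoys = 20, seed = 5) {
  set.seed(seed)
  hmm <- sim_family_hmm(L, conservation = 0.92, name = "fixfam", seed = seed)
  hom <- sample_from_hmm(hmm)
  prot <- tibble::tibble(
    id = c("hom1", paste0("dec", seq_len(n_decoys))),
    seq = c(hom$seq, vapply(seq_len(n_decoys),
                            function(i) random_peptide(80), character(1))),
    family = c("fixfam", rep(NA_character_, n_decoys)),
    region_start = c(1L, rep(NA_integer_, n_decoys)),
    region_end = c(nchar(hom$seq), rep(NA_integer_, n_decoys)))
  sim <- simulate_reads(prot, coverage = coverage, read_len = 33,
                        error_rate = error)
  list(hmm = hmm, sm = to_scoring(hmm), homolog = hom$seq,
       db = read_db(sim$reads$seq, sim$reads$id), truth = sim$truth)
}

test_that("a database holding the whole homolog yields that read as a contig", {
  set.seed(2)
  hmm <- sim_family_hmm(50, conservation = 0.92, seed = 2)
  hom <- sample_from_hmm(hmm)$seq
  db <- read_db(c(hom, vapply(1:5, function(i) random_peptide(40),
                              character(1))))
  ki <- build_kgram_index(db, k = 6)
  li <- build_extension_links(db, 10)
  p <- saa_params(theta = 0.5)
  contigs <- assemble_family(to_scoring(hmm), db, ki, li, p)
  expect_gte(nrow(contigs), 1)
  expect_true(hom %in% contigs$seq)
})

test_that("max_depth = 0 restricts contigs to single reads", {
  fx <- make_family_fixture()
  ki <- build_kgram_index(fx$db, k = 6)
  li <- build_extension_links(fx$db, 10)
  contigs <- assemble_family(fx$sm, fx$db, ki, li, saa_params(max_depth = 0))
  expect_true(all(contigs$n_reads == 1))
  expect_true(all(contigs$seq %in% fx$db$seq))
})

test_that("error-free 10X assembly reconstructs most of the homolog", {
  fx <- make_family_fixture(L = 80, coverage = 10, error = 0)
  ki <- build_kgram_index(fx$db, k = 6)
  li <- build_extension_links(fx$db, 10)
  contigs <- assemble_family(fx$sm, fx$db, ki, li, saa_params())
  contigs <- recalibrate(contigs, 10, model = fx$sm, db = fx$db)
  # longest contig covers >= 90% of the emitted homolog
  best <- contigs$seq[which.max(contigs$length)]
  expect_gte(nchar(best), 0.9 * nchar(fx$homolog))
  expect_true(grepl(best, fx$homolog, fixed = TRUE) ||
                grepl(fx$homolog, best, fixed = TRUE))
})

test_that("every contig's reads tile its sequence exactly", {
  fx <- make_family_fixture(L = 70, coverage = 8, error = 0.01, seed = 9)
  ki <- build_kgram_index(fx$db, k = 6)
  li <- build_extension_links(fx$db, 10)
  contigs <- assemble_family(fx$sm, fx$db, ki, li, saa_params())
  expect_gt(nrow(contigs), 0)
  for (q in seq_len(nrow(contigs))) {
    rd <- contigs$reads[[q]]
    rl <- nchar(fx$db$seq[rd$read])
    expect_identical(substring(contigs$seq[q], rd$offset, rd$offset + rl - 1),
                     fx$db$seq[rd$read])
    # consecutive reads overlap by at least min_overlap
    if (nrow(rd) > 1) {
      rd <- rd[order(rd$offset), ]
      ends <- rd$offset + rl[order(rd$offset)] - 1
      expect_true(all(ends[-nrow(rd)] - rd$offset[-1] + 1 >= 10))
    }
    # full coverage of the contig, no gaps
    expect_equal(min(rd$offset), 1L)
    expect_equal(max(rd$offset + rl - 1), contigs$length[q])
  }
})

test_that("assembly is deterministic for fixed parameters", {
  fx <- make_family_fixture(seed = 13)
  ki <- build_kgram_index(fx$db, k = 6)
  li <- build_extension_links(fx$db, 10)
  c1 <- assemble_family(fx$sm, fx$db, ki, li, saa_params())
  c2 <- assemble_family(fx$sm, fx$db, ki, li, saa_params())
  expect_identical(c1, c2)
})

test_that("recalibration merges overlapping contigs and removes substrings", {
  base <- random_peptide(80)
  mk <- function(seq, off = 1L) {
    tibble::tibble(family = "f", contig_id = "x", seq = seq,
                   length = nchar(seq), score = 10, i0 = 1L, j0 = 1L,
                   n_reads = 1L,
                   reads = list(tibble::tibble(read = 1L, offset = off)))
  }
  # 15-residue exact overlap
  a <- substr(base, 1, 40)
  b <- substr(base, 26, 70)
  merged <- recalibrate(dplyr::bind_rows(mk(a), mk(b)), 10)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$length, 40 + 45 - 15)
  expect_equal(merged$seq, substr(base, 1, 70))

  # identical duplicates collapse
  dup <- recalibrate(dplyr::bind_rows(mk(a), mk(a)), 10)
  expect_equal(nrow(dup), 1)

  # substring-free output, checked against a brute-force containment scan
  set.seed(8)
  pieces <- lapply(1:8, function(i) {
    st <- sample(1:50, 1)
    mk(substr(base, st, st + sample(15:30, 1)))
  })
  out <- recalibrate(dplyr::bind_rows(pieces), 10)
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      if (i != j) expect_false(grepl(out$seq[i], out$seq[j], fixed = TRUE))
    }
  }
})

test_that("P-values are calibrated, monotone and tail-bounded", {
  sm <- to_scoring(sim_family_hmm(50, seed = 4))
  null <- null_viterbi_scores(sm, lengths = 60, n = 200, seed = 1)
  # far beyond the calibration maximum: P below 1/N
  expect_lt(score_pvalue(sm, max(null) + 10, null), 1 / 200)
  # at the calibration median: P about one half
  expect_equal(score_pvalue(sm, median(null), null), 0.5, tolerance = 0.1)
  # monotone decreasing in score
  s <- seq(min(null) - 5, max(null) + 5, length.out = 50)
  p <- score_pvalue(sm, s, null)
  expect_true(all(diff(p) <= 1e-12))
  # small samples fall back to the empirical rank
  p_emp <- score_pvalue(sm, median(null[1:10]), null[1:10])
  expect_gte(p_emp, 1 / 11)
  expect_lte(p_emp, 1)
})

test_that("coverage does not shrink the longest verified contig (trend)", {
  longest <- function(cov, seed) {
    fx <- make_family_fixture(L = 60, coverage = cov, error = 0.01,
                              n_decoys = 10, seed = seed)
    ki <- build_kgram_index(fx$db, k = 6)
    li <- build_extension_links(fx$db, 10)
    contigs <- assemble_family(fx$sm, fx$db, ki, li, saa_params())
    contigs <- recalibrate(contigs, 10, model = fx$sm, db = fx$db)
    ver <- verify_contigs(contigs, fx$sm, seed = 1)
    if (nrow(ver)) max(ver$length) else 0
  }
  seeds <- 1:10
  lo <- vapply(seeds, function(s) longest(2, s), numeric(1))
  hi <- vapply(seeds, function(s) longest(10, s), numeric(1))
  expect_gte(mean(hi), mean(lo))
})
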