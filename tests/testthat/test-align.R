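test_that("a single-state model scores a single residue by its emission", {
  me <- matrix(1 / 20, 1, 20)
  me[1, ] <- c(0.5, 0.5, rep(0, 18))
  hmm <- profile_hmm("one", me, matrix(1 / 20, 1, 20),
                     matrix(c(.9, .05, .05, .7, .3, 1, 0), 2, 7, byrow = TRUE))
  sm <- to_scoring(hmm)
  aln <- banded_viterbi(sm, "A", anchor = c(1, 1), d = 1)
  expect_equal(aln$score, unname(sm$emit_M[1, 1]), tolerance = 1e-12)
  expect_identical(aln$path$state, "M")
  # single-parse degenerate case: forward equals viterbi
  expect_equal(forward_score(sm, "A"), full_viterbi(sm, "A")$score,
               tolerance = 1e-9)
})

test_that("viterbi and forward match exhaustive parse enumeration", {
  for (s in 1:12) {
    hmm <- random_hmm(sample(2:4, 1), seed = 100 + s)
    sm <- to_scoring(hmm)
    tgt <- random_peptide(sample(2:6, 1))
    expect_equal(full_viterbi(sm, tgt)$score, oracle_viterbi(sm, tgt),
                 tolerance = 1e-9)
    expect_equal(forward_score(sm, tgt), oracle_forward(sm, tgt),
                 tolerance = 1e-9)
  }
})

test_that("banded score converges to the full score as the band widens", {
  set.seed(17)
  for (s in 1:10) {
    hmm <- random_hmm(sample(4:10, 1), seed = 200 + s)
    sm <- to_scoring(hmm)
    n <- sample(4:12, 1)
    tgt <- random_peptide(n)
    full <- full_viterbi(sm, tgt)$score
    prev <- -Inf
    for (d in c(1, 2, 4, 8, sm$L + n)) {
      sc <- banded_viterbi(sm, tgt, anchor = c(1, 1), d = d,
                           traceback = FALSE)$score
      expect_gte(sc + 1e-12, prev)
      prev <- sc
    }
    expect_equal(prev, full, tolerance = 1e-9)
    expect_lte(full, forward_score(sm, tgt) + 1e-9)
  }
})

test_that("a narrow band excludes off-diagonal alignments", {
  # insert-tolerant model (I->I = 0.9): a consensus target with a 30-residue
  # insertion aligns across the gap only when the band admits the diagonal
  # shift
  L <- 40
  cons_chr <- strsplit(strrep("WCGPHKFYDE", 4), "")[[1]]
  me <- matrix(0.01 / 19, L, 20)
  me[cbind(seq_len(L), match(cons_chr, aa_letters))] <- 0.99
  tr <- matrix(rep(c(0.9, 0.05, 0.05, 0.1, 0.9, 0.7, 0.3), each = L + 1),
               L + 1, 7)
  tr[L + 1, ] <- c(0.95, 0.05, 0, 0.1, 0.9, 1, 0)
  hmm <- profile_hmm("insname", me, matrix(1 / 20, L, 20), tr)
  sm <- to_scoring(hmm)
  cons <- paste(sm$consensus, collapse = "")
  tgt <- paste0(substr(cons, 1, 20), random_peptide(30), substr(cons, 21, 40))
  narrow <- banded_viterbi(sm, tgt, anchor = c(1, 1), d = 20,
                           traceback = FALSE)$score
  wide <- banded_viterbi(sm, tgt, anchor = c(1, 1), d = 60,
                         traceback = FALSE)$score
  expect_gt(wide, narrow)
  expect_equal(wide, full_viterbi(sm, tgt)$score, tolerance = 1e-9)
})

test_that("the consensus target scores near the sum of emission maxima", {
  hmm <- peaked_hmm(strsplit("WCGPHKFYDE", "")[[1]], 0.99)
  sm <- to_scoring(hmm)
  cons <- paste(sm$consensus, collapse = "")
  sc <- full_viterbi(sm, cons)$score
  expect_equal(sc, sum(apply(sm$emit_M, 1, max)), tolerance = 0.5)
})

test_that("reversing a non-palindromic target changes the score", {
  sm <- to_scoring(random_hmm(6, seed = 77))
  tgt <- "ACDEFGHIKL"
  rtg <- paste(base::rev(strsplit(tgt, "")[[1]]), collapse = "")
  expect_false(isTRUE(all.equal(full_viterbi(sm, tgt)$score,
                                full_viterbi(sm, rtg)$score)))
})

test_that("forward dominates viterbi on random instances", {
  for (s in 1:20) {
    sm <- to_scoring(random_hmm(sample(2:6, 1), seed = 300 + s))
    tgt <- random_peptide(sample(3:9, 1))
    expect_gte(forward_score(sm, tgt) + 1e-9, full_viterbi(sm, tgt)$score)
  }
})

test_that("tracebacks are legal state sequences and deterministic", {
  sm <- to_scoring(random_hmm(8, seed = 55))
  tgt <- random_peptide(12)
  a1 <- full_viterbi(sm, tgt)
  a2 <- full_viterbi(sm, tgt)
  expect_identical(a1, a2)
  p <- a1$path
  expect_identical(p$state[1], "M")
  expect_identical(p$state[nrow(p)], "M")
  if (nrow(p) > 1) {
    for (q in 2:nrow(p)) {
      di <- p$i[q] - p$i[q - 1]
      dj <- p$j[q] - p$j[q - 1]
      expect_true(switch(p$state[q],
                         M = di == 1 && dj == 1,
                         I = di == 0 && dj == 1,
                         D = di == 1 && dj == 0))
      if (p$state[q] == "I") expect_true(p$state[q - 1] %in% c("M", "I"))
      if (p$state[q] == "D") expect_true(p$state[q - 1] %in% c("M", "D"))
    }
  }
  # path score re-derives the reported score
  sc <- 0
  codes <- profasm:::aa_codes(tgt) + 1
  for (q in seq_len(nrow(p))) {
    if (p$state[q] == "M") sc <- sc + sm$emit_M[p$i[q], codes[p$j[q]]]
    if (p$state[q] == "I") sc <- sc + sm$emit_I[p$i[q], codes[p$j[q]]]
    if (q > 1) {
      key <- paste0(p$state[q - 1], p$state[q])
      col <- match(key, c("MM", "MI", "MD", "IM", "II", "DM", "DD"))
      row <- if (p$state[q - 1] %in% c("M")) {
        if (p$state[q] == "I") p$i[q - 1] else p$i[q - 1]
      } else p$i[q - 1]
      sc <- sc + sm$tr[row, col]
    }
  }
  expect_equal(unname(sc), a1$score, tolerance = 1e-9)
})
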