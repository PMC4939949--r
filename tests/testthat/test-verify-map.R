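contig_row <- function(seq, family = "f", id = "c1", evalue = 1e-4) {
  tibble::tibble(family = family, contig_id = id, seq = seq,
                 length = nchar(seq), score = 0, i0 = 1L, j0 = 1L,
                 n_reads = 0L, reads = list(tibble::tibble()),
                 evalue = evalue)
}

test_that("model-sampled contigs verify and background contigs do not", {
  hmm <- sim_family_hmm(80, seed = 3)
  sm <- to_scoring(hmm)
  pass_true <- pass_bg <- logical(10)
  for (s in 1:10) {
    set.seed(1000 + s)
    truec <- sample_from_hmm(hmm)$seq
    bgc <- random_peptide(80)
    v1 <- verify_contigs(contig_row(truec), sm, seed = s)
    v2 <- verify_contigs(contig_row(bgc), sm, seed = s)
    pass_true[s] <- nrow(v1) == 1
    pass_bg[s] <- nrow(v2) == 1
  }
  expect_gte(sum(pass_true), 9)
  expect_lte(sum(pass_bg), 1)
})

test_that("verification handles empty input and bad cutoffs", {
  sm <- to_scoring(sim_family_hmm(20, seed = 1))
  empty <- contig_row("A")[0, ]
  out <- verify_contigs(empty, sm)
  expect_equal(nrow(out), 0)
  expect_true(all(c("forward_score", "evalue", "verified") %in% names(out)))
  expect_error(verify_contigs(contig_row("ACD"), sm, evalue_cutoff = 0))
})

test_that("the mapper enforces its mismatch and portion thresholds exactly", {
  contig <- random_peptide(100)
  # an exact 33-residue substring is recruited with zero mismatches
  read0 <- substr(contig, 20, 52)
  # fully overlapping read with 4 substitutions is rejected
  ch <- strsplit(read0, "")[[1]]
  for (pos in c(3, 10, 20, 30)) {
    ch[pos] <- setdiff(aa_letters, ch[pos])[1]
  }
  read4 <- paste(ch, collapse = "")
  # 3 substitutions is the boundary: accepted
  ch3 <- strsplit(read0, "")[[1]]
  for (pos in c(3, 10, 20)) ch3[pos] <- setdiff(aa_letters, ch3[pos])[1]
  read3 <- paste(ch3, collapse = "")
  # 19 of 33 residues overlapping the contig end = 57.6% <= 60%: rejected
  read_end <- paste0(substr(contig, 82, 100), random_peptide(14))
  # 20 of 33 = 60.6% > 60%: accepted
  read_end2 <- paste0(substr(contig, 81, 100), random_peptide(13))
  db <- read_db(c(read0, read4, read3, read_end, read_end2),
                c("exact", "mm4", "mm3", "end19", "end20"))
  asn <- map_reads(db, contig_row(contig))
  expect_setequal(asn$read_id, c("exact", "mm3", "end20"))
  expect_equal(asn$mismatches[asn$read_id == "exact"], 0)
  expect_equal(asn$offset[asn$read_id == "exact"], 20)
  expect_equal(asn$mismatches[asn$read_id == "mm3"], 3)
  expect_equal(asn$overlap[asn$read_id == "end20"], 20)
})

test_that("'X' counts as a mismatch in mapping", {
  contig <- random_peptide(50)
  rd <- substr(contig, 1, 33)
  rx <- paste0("XXXX", substr(rd, 5, 33))
  db <- read_db(c(rx), "xread")
  expect_equal(nrow(map_reads(db, contig_row(contig))), 0)  # 4 X = 4 mismatches
  rx3 <- paste0("XXX", substr(rd, 4, 33))
  expect_equal(map_reads(db <- read_db(rx3, "x3"), contig_row(contig))$mismatches, 3)
})

test_that("recruitment is monotone in its thresholds", {
  set.seed(6)
  contig <- random_peptide(120)
  reads <- vapply(1:40, function(i) {
    st <- sample(1:85, 1)
    s <- substr(contig, st, st + 32)
    ch <- strsplit(s, "")[[1]]
    nmut <- sample(0:5, 1)
    if (nmut > 0) {
      idx <- sample(length(ch), nmut)
      ch[idx] <- vapply(ch[idx], function(a) setdiff(aa_letters, a)[1],
                        character(1))
    }
    paste(ch, collapse = "")
  }, character(1))
  db <- read_db(reads)
  base <- map_reads(db, contig_row(contig), max_mismatch = 2, min_portion = 0.7)
  more_mm <- map_reads(db, contig_row(contig), max_mismatch = 4, min_portion = 0.7)
  less_p <- map_reads(db, contig_row(contig), max_mismatch = 2, min_portion = 0.5)
  expect_true(all(base$read %in% more_mm$read))
  expect_true(all(base$read %in% less_p$read))
})

test_that("multi-family hits resolve to the most significant contig", {
  asn <- tibble::tibble(
    read = c(1L, 1L, 2L, 3L, 3L, 3L),
    read_id = c("r1", "r1", "r2", "r3", "r3", "r3"),
    family = c("A", "B", "A", "C", "B", "A"),
    contig_id = paste0("c", 1:6),
    offset = 1L, mismatches = c(1L, 0L, 0L, 2L, 2L, 2L),
    overlap = 33L, fraction = 1,
    evalue = c(1e-5, 1e-3, 1e-2, 1e-4, 1e-4, 1e-4))
  res <- resolve_multi_family(asn)
  expect_equal(nrow(res), 3)
  expect_equal(res$family[res$read == 1], "A")     # smallest E-value wins
  expect_equal(res$family[res$read == 2], "A")     # single hit unchanged
  expect_equal(res$family[res$read == 3], "A")     # E tie, mm tie -> name
  # brute-force per-read argmin over E agrees
  for (r in unique(asn$read)) {
    sub <- asn[asn$read == r, ]
    sub <- sub[order(sub$evalue, sub$mismatches, sub$family), ]
    expect_equal(res$family[res$read == r], sub$family[1])
  }
  expect_equal(anyDuplicated(res$read), 0L)
})

test_that("error-free truth reads overlapping a true contig are all recruited", {
  set.seed(12)
  hmm <- sim_family_hmm(80, seed = 12)
  hom <- sample_from_hmm(hmm)$seq
  prot <- tibble::tibble(id = "h", seq = hom, family = "fam",
                         region_start = 1L, region_end = nchar(hom))
  sim <- simulate_reads(prot, coverage = 8, read_len = 33, error_rate = 0)
  db <- read_db(sim$reads$seq, sim$reads$id)
  asn <- map_reads(db, contig_row(hom, family = "fam"))
  expect_setequal(asn$read_id, sim$truth$read_id)  # recall exactly 1
  expect_true(all(asn$mismatches == 0))
})
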