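# Independent oracles and tiny model builders shared across tests.
# Everything here is deliberately brute-force and separate from the package's
# own code paths.

# A fully specified small profile HMM with random (Dirichlet-ish) emissions
# and well-behaved transitions.
random_hmm <- function(L, seed = 1, name = "rnd") {
  set.seed(seed)
  rdir <- function(n) {
    x <- matrix(rgamma(n * 20, shape = 0.5), n, 20)
    x / rowSums(x)
  }
  tr_int <- function() {
    m <- runif(3, 0.05, 1); m <- m / sum(m)
    i <- runif(2, 0.05, 1); i <- i / sum(i)
    d <- runif(2, 0.05, 1); d <- d / sum(d)
    c(m, i, d)
  }
  trans <- t(replicate(L + 1, tr_int()))
  trans[L + 1, ] <- c(0.9, 0.1, 0, 0.7, 0.3, 1, 0)
  profile_hmm(name, rdir(L), rdir(L), trans)
}

aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_peptide <- function(n) paste(sample(aa_letters, n, replace = TRUE),
                                    collapse = "")

# --- exhaustive parse enumeration -------------------------------------------
# Every local parse enters at a match state, traverses the M/I/D recurrences
# and exits at a match state.  Returns the scores (bits) of all parses.
enumerate_parse_scores <- function(model, target) {
  codes <- profasm:::aa_codes(target) + 1L  # 1-based; 0 = X
  L <- model$L
  n <- length(codes)
  eM <- function(i, j) if (codes[j] == 0) -2 else model$emit_M[i, codes[j]]
  eI <- function(i, j) if (codes[j] == 0) -2 else model$emit_I[i, codes[j]]
  tr <- model$tr
  scores <- numeric(0)
  recurse <- function(state, i, j, sc) {
    if (state == "M") scores[length(scores) + 1L] <<- sc
    if (state == "M") {
      if (i < L && j < n) recurse("M", i + 1, j + 1, sc + tr[i, 1] + eM(i + 1, j + 1))
      if (j < n) recurse("I", i, j + 1, sc + tr[i, 2] + eI(i, j + 1))
      if (i < L) recurse("D", i + 1, j, sc + tr[i, 3])
    } else if (state == "I") {
      if (i < L && j < n) recurse("M", i + 1, j + 1, sc + tr[i, 4] + eM(i + 1, j + 1))
      if (j < n) recurse("I", i, j + 1, sc + tr[i, 5] + eI(i, j + 1))
    } else {
      if (i < L && j < n) recurse("M", i + 1, j + 1, sc + tr[i, 6] + eM(i + 1, j + 1))
      if (i < L) recurse("D", i + 1, j, sc + tr[i, 7])
    }
  }
  for (i1 in seq_len(L)) {
    for (s in seq_len(n)) recurse("M", i1, s, eM(i1, s))
  }
  scores
}

oracle_viterbi <- function(model, target) max(enumerate_parse_scores(model, target))

oracle_forward <- function(model, target) {
  sc <- enumerate_parse_scores(model, target)
  m <- max(sc)
  m + log2(sum(2^(sc - m)))
}

# --- brute-force overlap scan -----------------------------------------------
oracle_overlaps <- function(seqs, min_overlap) {
  n <- length(seqs)
  out <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      li <- nchar(seqs[i]); lj <- nchar(seqs[j])
      found <- 0L
      for (o in rev(seq_len(min(li, lj - 1L)))) {
        if (o < min_overlap) break
        if (substr(seqs[i], li - o + 1L, li) == substr(seqs[j], 1L, o)) {
          found <- o
          break
        }
      }
      if (found >= min_overlap)
        out[[length(out) + 1L]] <- data.frame(from = i, to = j, overlap = found)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) data.frame(from = integer(), to = integer(),
                               overlap = integer()) else res
}

# --- brute-force seeding scan -----------------------------------------------
# All read k-grams against all model windows, restricted to the
# reduced-alphabet pre-filter and to windows with a positive maximum score.
oracle_seeds <- function(model, db, k, theta) {
  red <- profasm:::reduce_seq
  cons <- paste(model$consensus, collapse = "")
  out <- list()
  for (i0 in seq_len(model$L - k + 1)) {
    win <- model$emit_M[i0:(i0 + k - 1), , drop = FALSE]
    mx <- sum(apply(win, 1, max))
    if (mx <= 0) next
    key <- red(substr(cons, i0, i0 + k - 1))
    for (r in seq_len(db$n)) {
      len <- nchar(db$seq[r])
      if (len < k) next
      for (j0 in seq_len(len - k + 1)) {
        gram <- substr(db$seq[r], j0, j0 + k - 1)
        if (red(gram) != key) next
        codes <- profasm:::aa_codes(gram) + 1L
        if (any(codes == 0)) next
        sc <- sum(win[cbind(seq_len(k), codes)])
        if (sc >= theta * mx - 1e-9)
          out[[length(out) + 1L]] <- data.frame(read = r, offset = j0,
                                                i0 = i0, seed_score = sc)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) data.frame(read = integer(), offset = integer(),
                               i0 = integer(), seed_score = numeric()) else res
}

# --- misc -------------------------------------------------------------------
oracle_n50 <- function(lengths) {
  if (!length(lengths)) return(0)
  s <- sort(lengths, decreasing = TRUE)
  tot <- sum(s)
  run <- 0
  for (x in s) {
    run <- run + x
    if (run >= tot / 2) return(x)
  }
}

# a tiny near-deterministic model whose consensus dominates
peaked_hmm <- function(cons, conservation = 0.95, name = "peak") {
  L <- length(cons)
  me <- matrix((1 - conservation) / 19, L, 20)
  me[cbind(seq_len(L), match(cons, aa_letters))] <- conservation
  tr <- matrix(rep(c(0.98, 0.01, 0.01, 0.7, 0.3, 0.7, 0.3), each = L + 1),
               L + 1, 7)
  tr[L + 1, ] <- c(0.99, 0.01, 0, 0.7, 0.3, 1, 0)
  profile_hmm(name, me, matrix(1 / 20, L, 20), tr)
}
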