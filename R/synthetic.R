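#' Construct a toy conserved-family profile HMM
#'
#' Builds a profile HMM around a random consensus: each match state emits its
#' consensus residue with probability `conservation` and spreads the rest
#' uniformly over the other 19 residues; inserts emit the background.
#' Transition probabilities use a fixed conserved-domain operating point
#' (M->M 0.97, M->I = M->D 0.015, I->M 0.7, D->M 0.7), with clean terminal
#' rows.  These models are the package's synthetic study condition -- see
#' the methods vignette for the rationale.
#'
#' @param L Number of match states.
#' @param conservation Consensus emission probability (default 0.9).
#' @param name Model name.
#' @param seed RNG seed for the consensus draw.
#' @return A [profile_hmm].
#' @export
sim_family_hmm <- function(L, conservation = 0.9, name = "toyfam",
                           seed = NULL) {
  stopifnot(L >= 2, conservation > 0.05, conservation < 1)
  if (!is.null(seed)) set.seed(seed)
  cons <- sample(AA, L, replace = TRUE)
  match_emit <- matrix((1 - conservation) / 19, L, 20)
  match_emit[cbind(seq_len(L), match(cons, AA))] <- conservation
  insert_emit <- matrix(1 / 20, L, 20)
  tr_int <- c(MM = 0.97, MI = 0.015, MD = 0.015, IM = 0.7, II = 0.3,
              DM = 0.7, DD = 0.3)
  trans <- matrix(rep(tr_int, each = L + 1), L + 1, 7)
  # terminal rows: node L exits to the end state
  trans[L + 1, ] <- c(0.985, 0.015, 0, 0.7, 0.3, 1, 0)
  profile_hmm(name, match_emit, insert_emit, trans)
}

#' Sample a homolog sequence from a profile HMM
#'
#' Stochastic traversal of the model from the begin state: transitions and
#' emissions are drawn from the model's probabilities, and both the emitted
#' peptide and the generating state path are returned.
#'
#' @param hmm A [profile_hmm].
#' @param seed RNG seed (same seed, same sequence).
#' @return List with `seq` (peptide string) and `path` (character vector of
#'   states such as `"M3"`, `"I3"`, `"D4"`).
#' @export
sample_from_hmm <- function(hmm, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- hmm$L
  res <- character(0)
  path <- character(0)
  state <- "M"; i <- 0L  # begin state = node 0 in M
  repeat {
    row <- hmm$trans[i + 1L, ]
    if (state == "M") {
      nxt <- sample(c("M", "I", "D"), 1, prob = row[c("MM", "MI", "MD")])
    } else if (state == "I") {
      nxt <- sample(c("M", "I"), 1, prob = row[c("IM", "II")])
    } else {
      nxt <- sample(c("M", "D"), 1, prob = row[c("DM", "DD")])
    }
    if (nxt == "I") {
      # insert at node i (node-0 inserts emit the background)
      p <- if (i >= 1L) hmm$insert_emit[i, ] else hmm$background
      res <- c(res, sample(AA, 1, prob = p))
      path <- c(path, paste0("I", i))
      state <- "I"
    } else {
      i <- i + 1L
      if (i > L) break
      if (nxt == "M") {
        res <- c(res, sample(AA, 1, prob = hmm$match_emit[i, ]))
        path <- c(path, paste0("M", i))
      } else {
        path <- c(path, paste0("D", i))
      }
      state <- nxt
    }
  }
  list(seq = paste(res, collapse = ""), path = path)
}

#' Fragment proteins into error-bearing peptide reads with truth labels
#'
#' Each protein is sampled uniformly with full-length reads at its coverage
#' (`round(coverage * length / read_len)` reads); substitution errors are
#' i.i.d. at `error_rate` (an erroneous position is replaced by a uniformly
#' drawn different residue).  A read is truth-labeled for a family when it
#' overlaps that family's homologous region by strictly more than 60% of the
#' read, mirroring the read-mapping truth rule.  Proteins shorter than the
#' read length are emitted whole as one read.
#'
#' @param proteins Tibble with columns `id`, `seq`, `family` (`NA` for
#'   decoys), `region_start`, `region_end` (homologous region bounds).
#' @param coverage Per-protein coverage (scalar or vector, default 4).
#' @param read_len Read length in amino acids (default 33, the translation
#'   of a 100 bp sequencing read).
#' @param error_rate Per-residue substitution rate (default 0.01).
#' @param seed RNG seed.
#' @return List with `reads` (tibble `id`, `seq`, `source`, `start`) and
#'   `truth` (tibble `read_id`, `family`).
#' @export
simulate_reads <- function(proteins, coverage = 4, read_len = 33L,
                           error_rate = 0.01, seed = NULL) {
  stopifnot(nrow(proteins) > 0, all(coverage > 0),
            error_rate >= 0, error_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  coverage <- rep_len(coverage, nrow(proteins))
  out <- vector("list", nrow(proteins))
  truth <- vector("list", nrow(proteins))
  for (p in seq_len(nrow(proteins))) {
    pseq <- proteins$seq[p]
    plen <- nchar(pseq)
    rl <- min(read_len, plen)
    nr <- if (plen <= read_len) 1L else
      max(1L, as.integer(round(coverage[p] * plen / read_len)))
    starts <- if (plen == rl) rep(1L, nr) else
      sample.int(plen - rl + 1L, nr, replace = TRUE)
    seqs <- substring(pseq, starts, starts + rl - 1L)
    if (error_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        ch <- .split1(s)
        hit <- runif(length(ch)) < error_rate
        if (any(hit)) {
          ch[hit] <- vapply(ch[hit], function(a) {
            sample(setdiff(AA, a), 1)
          }, character(1))
        }
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    ids <- sprintf("%s_r%05d", proteins$id[p], seq_len(nr))
    out[[p]] <- tibble(id = ids, seq = seqs, source = proteins$id[p],
                       start = as.integer(starts))
    if (!is.na(proteins$family[p])) {
      ov <- pmin(starts + rl - 1L, proteins$region_end[p]) -
        pmax(starts, proteins$region_start[p]) + 1L
      lab <- ov > 0.6 * rl
      if (any(lab)) {
        truth[[p]] <- tibble(read_id = ids[lab], family = proteins$family[p])
      }
    }
  }
  list(reads = bind_rows(out),
       truth = bind_rows(truth) %||%
         tibble(read_id = character(), family = character()))
}

#' Simulate a synthetic peptide-read metagenome with ground truth
#'
#' The package's study-condition generator: builds `n_families` toy
#' conserved-family models, samples `n_homologs` homolog proteins from each
#' (optionally embedded in random flanking sequence), adds background decoy
#' proteins, and fragments everything into error-bearing peptide reads with
#' per-read ground-truth labels.
#'
#' @param n_families Number of query families (default 5).
#' @param L_range Model length range in match states (default 150-300).
#' @param n_homologs Homolog proteins per family (default 3).
#' @param n_decoys Decoy proteins (default 200).
#' @param decoy_len Decoy length range (default 100-300 aa).
#' @param coverage Sequencing coverage (scalar or per-protein; default 4).
#' @param read_len Read length (default 33 aa).
#' @param error_rate Substitution error rate (default 0.01).
#' @param conservation Family conservation (default 0.9).
#' @param flank_len Random flanking residues on each side of a homolog
#'   region (default 0: homologs are standalone domain proteins).
#' @param seed RNG seed; recorded in the returned config.
#' @return List: `models` (list of [profile_hmm]), `proteins` tibble, `db`
#'   ([read_db]), `reads` tibble, `truth` tibble, and `config` (the
#'   effective parameters, including the seed).
#' @export
sim_metagenome <- function(n_families = 5L, L_range = c(150L, 300L),
                           n_homologs = 3L, n_decoys = 200L,
                           decoy_len = c(100L, 300L), coverage = 4,
                           read_len = 33L, error_rate = 0.01,
                           conservation = 0.9, flank_len = 0L, seed = 1L) {
  set.seed(seed)
  Ls <- if (n_families > 1)
    as.integer(round(seq(L_range[1], L_range[2], length.out = n_families)))
  else L_range[1]
  models <- lapply(seq_len(n_families), function(f) {
    sim_family_hmm(Ls[f], conservation = conservation,
                   name = sprintf("fam%02d", f))
  })
  prot <- list()
  for (f in seq_len(n_families)) {
    for (h in seq_len(n_homologs)) {
      s <- sample_from_hmm(models[[f]])
      fl1 <- fl2 <- ""
      if (flank_len > 0) {
        fl1 <- paste(sample(AA, flank_len, replace = TRUE), collapse = "")
        fl2 <- paste(sample(AA, flank_len, replace = TRUE), collapse = "")
      }
      prot[[length(prot) + 1L]] <- tibble(
        id = sprintf("fam%02d_h%02d", f, h),
        seq = paste0(fl1, s$seq, fl2),
        family = models[[f]]$name,
        region_start = nchar(fl1) + 1L,
        region_end = nchar(fl1) + nchar(s$seq))
    }
  }
  for (d in seq_len(n_decoys)) {
    dl <- sample(seq(decoy_len[1], decoy_len[2]), 1)
    prot[[length(prot) + 1L]] <- tibble(
      id = sprintf("decoy%04d", d),
      seq = paste(sample(AA, dl, replace = TRUE), collapse = ""),
      family = NA_character_, region_start = NA_integer_,
      region_end = NA_integer_)
  }
  proteins <- bind_rows(prot)
  sim <- simulate_reads(proteins, coverage = coverage, read_len = read_len,
                        error_rate = error_rate)
  list(models = models, proteins = proteins,
       db = read_db(sim$reads$seq, sim$reads$id),
       reads = sim$reads, truth = sim$truth,
       config = list(n_families = n_families, L = Ls,
                     n_homologs = n_homologs, n_decoys = n_decoys,
                     decoy_len = decoy_len, coverage = coverage,
                     read_len = read_len, error_rate = error_rate,
                     conservation = conservation, flank_len = flank_len,
                     seed = seed))
}
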