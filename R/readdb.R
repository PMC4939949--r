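#' Build a read database from sequences in memory
#'
#' @param seqs Character vector of peptide sequences (uppercase, 20 amino
#'   acids plus `X`).
#' @param ids Read identifiers; duplicates are made unique by suffixing.
#' @return An object of class `read_db` with elements `id`, `seq`, `n` and
#'   `total_residues` (the RPKM library-size denominator).
#' @export
read_db <- function(seqs, ids = NULL) {
  seqs <- toupper(as.character(seqs))
  n <- length(seqs)
  if (n == 0) stop("read database is empty", call. = FALSE)
  ids <- as.character(ids %||% paste0("read_", seq_len(n)))
  stopifnot(length(ids) == n)
  bad <- stringr::str_detect(seqs, "[^ACDEFGHIKLMNPQRSTVWYX]")
  if (any(bad))
    stop("non-amino-acid characters in record(s): ",
         paste(head(ids[bad], 5), collapse = ", "), call. = FALSE)
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = ".")
  structure(list(id = ids, seq = seqs, n = n,
                 total_residues = sum(nchar(seqs))),
            class = "read_db")
}

#' Load short peptide reads from a FASTA file
#'
#' Reads are validated against the amino-acid alphabet (`X` allowed); inputs
#' that look nucleotide (at least 95% `ACGTN` residues) are rejected, since
#' the search expects the translated-peptide output of a fragmentary gene
#' caller, not raw sequencing reads.
#'
#' @param path FASTA file of peptide reads.
#' @return A [read_db].
#' @export
load_reads <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop(path, ": empty FASTA", call. = FALSE)
  seqs <- toupper(as.character(aa))
  ids <- sub("\\s.*$", "", names(aa))
  res <- table(factor(.split1(paste(seqs, collapse = "")),
                      levels = c(LETTERS)))
  frac_nt <- sum(res[c("A", "C", "G", "T", "N")]) / sum(res)
  if (frac_nt >= 0.95)
    stop(path, ": looks like nucleotide sequence (", round(100 * frac_nt),
         "% ACGTN); supply translated peptide reads", call. = FALSE)
  read_db(seqs, ids)
}

#' @export
print.read_db <- function(x, ...) {
  cat(sprintf("<read_db> %d reads, %d residues (mean length %.1f)\n",
              x$n, x$total_residues, x$total_residues / x$n))
  invisible(x)
}

#' The GBMR4 reduced amino-acid alphabet
#'
#' Four classes: \{G\}, \{P\}, \{A,D,K,E,R,N,T,S,Q\} and
#' \{Y,F,L,I,V,M,C,W,H\}.  `X` maps to its own class and never matches any
#' k-gram.  Used to pre-filter seed candidates: a 20-letter k-gram lookup is
#' collapsed to at most `4^k` keys while conservative substitutions stay
#' within one class.
#'
#' @return A named character vector mapping each residue (plus `X`) to its
#'   class letter.
#' @export
gbmr4 <- function() {
  map <- c(G = "g", P = "p",
           setNames(rep("a", 9), c("A", "D", "K", "E", "R", "N", "T", "S", "Q")),
           setNames(rep("h", 9), c("Y", "F", "L", "I", "V", "M", "C", "W", "H")),
           X = "x")
  map[c(AA, "X")]
}

#' Reduce a peptide string to a reduced-alphabet encoding
#'
#' @param seq Peptide string(s).
#' @param map A residue-to-class map such as [gbmr4()].
#' @return Reduced string(s) of the same length.
#' @keywords internal
reduce_seq <- function(seq, map = gbmr4()) {
  chartr(paste(names(map), collapse = ""), paste(map, collapse = ""), seq)
}

#' Build the reduced-alphabet k-gram seed index
#'
#' Every position `1..len - k + 1` of every read is entered exactly once
#' under the reduced encoding of its k-gram; reads shorter than `k`
#' contribute nothing.
#'
#' @param db A [read_db].
#' @param k Gram length (default 6, the seed length).
#' @param alphabet_map Residue-to-class map (default [gbmr4()]).
#' @return An object of class `kgram_index`: parallel vectors `read` and
#'   `offset` plus `table`, a list mapping each reduced k-gram to entry
#'   indices.
#' @export
build_kgram_index <- function(db, k = 6L, alphabet_map = gbmr4()) {
  stopifnot(inherits(db, "read_db"), k >= 3)
  red <- reduce_seq(db$seq, alphabet_map)
  nk <- pmax(0L, nchar(db$seq) - as.integer(k) + 1L)
  read_idx <- rep.int(seq_len(db$n), nk)
  off <- unlist(lapply(nk, seq_len), use.names = FALSE) %||% integer(0)
  keys <- substring(red[read_idx], off, off + k - 1L)
  structure(list(k = as.integer(k), alphabet_map = alphabet_map,
                 read = read_idx, offset = as.integer(off),
                 table = split(seq_along(keys), keys)),
            class = "kgram_index")
}

#' @export
print.kgram_index <- function(x, ...) {
  cat(sprintf("<kgram_index> k=%d, %d entries under %d reduced keys\n",
              x$k, length(x$read), length(x$table)))
  invisible(x)
}

#' Build extension links (the suffix-prefix overlap graph)
#'
#' For every ordered pair of reads the maximal exact suffix-prefix overlap
#' `o` with `min_overlap <= o <= min(len1, len2)` and `o < len(successor)`
#' (a link must add at least one residue) is recorded.  Construction is by
#' suffix-keyed hashing, not an all-pairs scan.  `links_rev` is the exact
#' transpose of `links_fwd`.
#'
#' @param db A [read_db].
#' @param min_overlap Minimum overlap length (default 10).
#' @return An object of class `link_index`: a `links` tibble
#'   (`from`, `to`, `overlap`) plus per-read adjacency lists `fwd` and `rev`.
#' @export
build_extension_links <- function(db, min_overlap = 10L) {
  stopifnot(inherits(db, "read_db"), min_overlap >= 1)
  links <- as_tibble(cpp_overlap_links(db$seq, as.integer(min_overlap)))
  fwd <- vector("list", db$n)
  rev <- vector("list", db$n)
  if (nrow(links)) {
    sp <- split(links[c("to", "overlap")], factor(links$from, levels = seq_len(db$n)))
    fwd <- lapply(sp, as.data.frame)
    sp <- split(links[c("from", "overlap")], factor(links$to, levels = seq_len(db$n)))
    rev <- lapply(sp, as.data.frame)
  }
  structure(list(min_overlap = as.integer(min_overlap), links = links,
                 fwd = fwd, rev = rev),
            class = "link_index")
}

#' @export
print.link_index <- function(x, ...) {
  cat(sprintf("<link_index> %d links at min overlap %d\n",
              nrow(x$links), x$min_overlap))
  invisible(x)
}

#' Write a read database to FASTA
#'
#' @param db A [read_db].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads <- function(db, path) {
  x <- Biostrings::AAStringSet(setNames(db$seq, db$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
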