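#' Construct a profile HMM
#'
#' A profile HMM describes a protein family as a chain of `L` match states
#' with position-specific emission distributions over the 20 amino acids,
#' flanked by insert and delete states.  Transitions follow the classic
#' seven-transition core topology (M->M, M->I, M->D, I->M, I->I, D->M, D->D);
#' transition rows are indexed by *source node*, with node 0 holding the
#' begin-state transitions used when sampling sequences from the model.
#'
#' @param name Model name.
#' @param match_emit `L x 20` matrix of match emission probabilities (columns
#'   in `ACDEFGHIKLMNPQRSTVWY` order); rows must sum to 1.
#' @param insert_emit `L x 20` matrix of insert emission probabilities.
#' @param trans `(L + 1) x 7` matrix of transition probabilities, rows for
#'   nodes `0..L`, columns `MM, MI, MD, IM, II, DM, DD`.
#' @param background Length-20 background distribution (default uniform).
#' @param desc Optional free-text description.
#' @param tol Validation tolerance; models decoded from files use a looser
#'   tolerance matching their printed precision.
#' @return An object of class `profile_hmm`.
#' @export
profile_hmm <- function(name, match_emit, insert_emit, trans,
                        background = rep(1 / 20, 20), desc = "",
                        tol = 1e-6) {
  match_emit <- as.matrix(match_emit)
  insert_emit <- as.matrix(insert_emit)
  trans <- as.matrix(trans)
  L <- nrow(match_emit)
  stopifnot(L >= 1, ncol(match_emit) == 20, ncol(insert_emit) == 20,
            nrow(insert_emit) == L, ncol(trans) == 7, nrow(trans) == L + 1,
            length(background) == 20)
  colnames(match_emit) <- colnames(insert_emit) <- AA
  colnames(trans) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  obj <- structure(
    list(name = name, L = L, match_emit = match_emit,
         insert_emit = insert_emit, trans = trans,
         background = as.numeric(background), desc = desc),
    class = "profile_hmm")
  validate_profile_hmm(obj, tol = tol)
  obj
}

#' Validate profile HMM invariants
#'
#' Checks that emission rows and the background sum to one and that outgoing
#' transition probabilities from M, I and D sum to one at every interior node.
#' Terminal nodes (0 and L) are checked leniently (sums must not exceed one),
#' matching the conventions of HMMER-format files where some terminal
#' transitions are structurally zero.
#'
#' @param x A `profile_hmm`.
#' @param tol Numeric tolerance.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_profile_hmm <- function(x, tol = 1e-6) {
  chk <- function(v, what) {
    if (any(abs(v - 1) > tol))
      stop(sprintf("profile_hmm '%s': %s must sum to 1 (max dev %.2e)",
                   x$name, what, max(abs(v - 1))), call. = FALSE)
  }
  chk(rowSums(x$match_emit), "match emission rows")
  chk(rowSums(x$insert_emit), "insert emission rows")
  chk(sum(x$background), "background")
  tr <- x$trans
  interior <- if (x$L >= 2) 2:x$L else integer(0)  # rows for nodes 1..L-1
  if (length(interior)) {
    chk(rowSums(tr[interior, 1:3, drop = FALSE]), "M transitions (interior)")
    chk(rowSums(tr[interior, 4:5, drop = FALSE]), "I transitions (interior)")
    chk(rowSums(tr[interior, 6:7, drop = FALSE]), "D transitions (interior)")
  }
  if (any(tr < -tol | tr > 1 + tol))
    stop("profile_hmm: transition probabilities outside [0, 1]", call. = FALSE)
  invisible(x)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm> %s: %d match states\n", x$name, x$L))
  invisible(x)
}

.prob2field <- function(p) {
  ifelse(p <= 0, "*", sprintf("%.5f", -log(p)))
}

.field2prob <- function(tok) {
  ifelse(tok == "*", 0, exp(-suppressWarnings(as.numeric(tok))))
}

#' Parse profile HMMs from a HMMER3 text file
#'
#' Reads one or more amino-acid profile HMMs from the plain-text HMMER3
#' format (`HMMER3/b` and `HMMER3/f` headers are accepted).  Emission and
#' transition fields are stored in the file as negative natural logarithms of
#' probabilities; `*` denotes probability zero.  The `COMPO` line, when
#' present, supplies the model's background distribution.
#'
#' @param path Path to a `.hmm` file.
#' @return A list of [profile_hmm] objects.
#' @export
parse_hmm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  models <- list()
  i <- 1L
  perr <- function(ln, msg) stop(sprintf("%s: line %d: %s", path, ln, msg),
                                 call. = FALSE)
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (!grepl("^HMMER3", lines[i]))
      perr(i, "expected a 'HMMER3' header line")
    hdr_line <- i
    name <- NULL; leng <- NULL; alph <- NULL; desc <- ""
    i <- i + 1L
    # header key/value section up to the 'HMM' column-header line
    while (i <= length(lines) && !grepl("^HMM\\s", lines[i])) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(tok) >= 2) {
        key <- tok[1]
        if (key == "NAME") name <- tok[2]
        if (key == "LENG") leng <- as.integer(tok[2])
        if (key == "ALPH") alph <- tok[2]
        if (key == "DESC") desc <- paste(tok[-1], collapse = " ")
      }
      i <- i + 1L
    }
    if (i > length(lines)) perr(hdr_line, "truncated record: no 'HMM' line")
    if (is.null(name)) perr(hdr_line, "missing NAME")
    if (is.null(leng) || is.na(leng) || leng < 1) perr(hdr_line, "missing or invalid LENG")
    if (is.null(alph) || toupper(alph) != "AMINO")
      perr(hdr_line, sprintf("alphabet '%s' is not amino", alph %||% "?"))
    sym <- strsplit(trimws(lines[i]), "\\s+")[[1]][-1]
    if (length(sym) != 20 || !all(sym == AA))
      perr(i, "HMM symbol line does not list the 20 amino acids in order")
    i <- i + 2L  # skip the transition-name header line
    background <- rep(1 / 20, 20)
    # optional COMPO line
    if (i <= length(lines) && grepl("^\\s*COMPO\\b", lines[i])) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(tok) < 21) perr(i, "COMPO line too short")
      background <- .field2prob(tok[2:21])
      i <- i + 1L
    }
    read_vals <- function(nf, what) {
      if (i > length(lines)) perr(i - 1L, paste("truncated record:", what))
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(tok) < nf) perr(i, sprintf("%s: expected %d fields", what, nf))
      v <- .field2prob(tok[seq_len(nf)])
      if (any(is.na(v))) perr(i, paste("non-numeric field in", what))
      i <<- i + 1L
      v
    }
    # node 0: insert emissions + begin transitions
    read_vals(20, "node 0 insert emissions")  # values unused (background inserts)
    tr0 <- read_vals(7, "node 0 transitions")
    match_emit <- matrix(0, leng, 20)
    insert_emit <- matrix(0, leng, 20)
    trans <- matrix(0, leng + 1, 7)
    trans[1, ] <- tr0
    for (k in seq_len(leng)) {
      if (i > length(lines)) perr(i - 1L, "truncated record inside node block")
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(tok) < 21) perr(i, "match emission line too short")
      if (suppressWarnings(as.integer(tok[1])) != k)
        perr(i, sprintf("expected node %d, found '%s'", k, tok[1]))
      match_emit[k, ] <- .field2prob(tok[2:21])
      i <- i + 1L
      insert_emit[k, ] <- read_vals(20, "insert emission line")
      trans[k + 1, ] <- read_vals(7, "transition line")
    }
    if (i > length(lines) || trimws(lines[i]) != "//")
      perr(min(i, length(lines)), "record does not end with '//'")
    i <- i + 1L
    models[[length(models) + 1L]] <-
      profile_hmm(name, match_emit, insert_emit, trans,
                  background = background, desc = desc, tol = 1e-3)
  }
  if (!length(models)) stop(path, ": no HMM records found", call. = FALSE)
  models
}

#' Write profile HMMs to a HMMER3 text file
#'
#' Inverse of [parse_hmm()]: probabilities are encoded as negative natural
#' logs, zeros as `*`.  Round-tripping a parsed model reproduces its
#' parameters to the printed precision.
#'
#' @param models A `profile_hmm` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hmm <- function(models, path) {
  if (inherits(models, "profile_hmm")) models <- list(models)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in models) {
    w <- function(...) writeLines(sprintf(...), con)
    w("HMMER3/f [profasm | %s]", as.character(utils::packageVersion("profasm")))
    w("NAME  %s", m$name)
    if (nzchar(m$desc)) w("DESC  %s", m$desc)
    w("LENG  %d", m$L)
    w("ALPH  amino")
    w("HMM          %s", paste(sprintf("%8s", AA), collapse = " "))
    w("            %s", paste(sprintf("%8s",
      c("m->m", "m->i", "m->d", "i->m", "i->i", "d->m", "d->d")),
      collapse = " "))
    w("  COMPO   %s", paste(sprintf("%8s", .prob2field(m$background)),
                            collapse = " "))
    w("          %s", paste(sprintf("%8s", .prob2field(m$background)),
                            collapse = " "))
    w("          %s", paste(sprintf("%8s", .prob2field(m$trans[1, ])),
                            collapse = " "))
    for (k in seq_len(m$L)) {
      w("  %5d   %s", k, paste(sprintf("%8s", .prob2field(m$match_emit[k, ])),
                               collapse = " "))
      w("          %s", paste(sprintf("%8s", .prob2field(m$insert_emit[k, ])),
                              collapse = " "))
      w("          %s", paste(sprintf("%8s", .prob2field(m$trans[k + 1, ])),
                              collapse = " "))
    }
    writeLines("//", con)
  }
  invisible(path)
}
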