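#' Read and validate protein sequences from a FASTA file
#'
#' Sequences are upper-cased and validated against the 20 standard residues
#' plus the degenerate codes X, B, Z, U, O and J.  Identifiers are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return An \code{AAStringSet} with identifiers as names.
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # read without alphabet restriction first so illegal characters can be
  # reported per record instead of failing inside the parser
  raw <- Biostrings::readBStringSet(path)
  if (!length(raw)) stop("FASTA file contains no sequences: ", path)
  ids <- vapply(strsplit(names(raw), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  chars <- toupper(as.character(raw))
  allowed <- c(residueOrder(), DEGENERATE_RESIDUES)
  bad <- vapply(chars, function(s) {
    ch <- strsplit(s, "")[[1]]
    length(ch) == 0L || any(!ch %in% allowed)
  }, logical(1))
  if (any(bad))
    stop("sequence(s) with illegal characters or zero length: ",
         paste(ids[bad], collapse = ", "))
  seqs <- Biostrings::AAStringSet(chars)
  names(seqs) <- ids
  seqs
}

# extract score rows from a PSI-BLAST ascii PSSM: position, residue letter,
# then at least 20 integer log-odds fields
.pssmRowPattern <- "^\\s*([0-9]+)\\s+([A-Za-z])((\\s+-?[0-9]+(\\.[0-9]+)?){20,})"

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the dialect produced by \code{psiblast -out_ascii_pssm}: two header
#' lines, then one row per query residue holding the position index, the
#' residue letter, 20 integer log-odds columns, 20 weighted-percentage
#' columns and two trailing statistics, followed by footer lines.  Only the
#' first (signed log-odds) block is retained; the percentage block is
#' ignored.
#'
#' @param path Path to the PSSM file.
#' @param expectedSequence Optional residue string; when given, the file's
#'   residue column must match it exactly.
#' @param identifier Identifier to attach; defaults to the file name without
#'   the .pssm extension.
#' @return A \code{\link{PSSMMatrix}}.
#' @export
parseAsciiPssm <- function(path, expectedSequence = NULL, identifier = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  if (is.null(identifier))
    identifier <- sub("\\.pssm$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  hits <- regmatches(lines, regexec(.pssmRowPattern, lines))
  isRow <- lengths(hits) > 0
  if (!any(isRow))
    stop("no PSSM score rows found in ", path)
  rowIdx <- which(isRow)
  pos <- integer(0); res <- character(0); scores <- list()
  for (k in seq_along(rowIdx)) {
    ln <- rowIdx[k]
    m <- hits[[ln]]
    fields <- strsplit(trimws(m[4]), "\\s+")[[1]]
    if (length(fields) < 20L)
      stop("truncated PSSM row at line ", ln, " of ", path,
           ": expected at least 20 score fields, found ", length(fields))
    vals <- suppressWarnings(as.numeric(fields[1:20]))
    if (any(is.na(vals)) || any(vals != round(vals)))
      stop("non-integer log-odds score at line ", ln, " of ", path)
    p <- as.integer(m[2])
    if (p != k)
      stop("non-consecutive position index at line ", ln, " of ", path,
           ": expected ", k, ", found ", p)
    pos <- c(pos, p)
    res <- c(res, toupper(m[3]))
    scores[[k]] <- vals
  }
  E <- do.call(rbind, scores)
  colnames(E) <- residueOrder()
  if (!is.null(expectedSequence)) {
    expected <- strsplit(toupper(as.character(expectedSequence)), "")[[1]]
    if (length(expected) != length(res))
      stop("PSSM for '", identifier, "' has ", length(res),
           " rows but the sequence has ", length(expected), " residues")
    mism <- which(expected != res)
    if (length(mism))
      stop("PSSM residue column mismatch for '", identifier,
           "' at position(s) ", paste(utils::head(mism, 5), collapse = ", "),
           " (file line ", rowIdx[mism[1]], ")")
  }
  new("PSSMMatrix", identifier = identifier, E = E, residues = res)
}

#' Softmax-standardize a PSSM into a profile
#'
#' Each signed log-odds row E_i is mapped to a probability distribution
#' A_i(j) = exp(E_ij) / sum_j' exp(E_ij'), computed with per-row maximum
#' subtraction so that arbitrarily large integer scores remain finite; where
#' the naive formula does not overflow the two agree to machine precision.
#'
#' @param pssm A \code{\link{PSSMMatrix}}.
#' @return A \code{\link{StandardizedProfile}} with origin "pssm".
#' @export
#' @examples
#' E <- matrix(0L, 1, 20, dimnames = list(NULL, residueOrder()))
#' p <- standardizePssm(new("PSSMMatrix", identifier = "x", E = E,
#'                          residues = "A"))
#' p@A[1, ]  # all 0.05
standardizePssm <- function(pssm) {
  stopifnot(is(pssm, "PSSMMatrix"))
  validObject(pssm)
  E <- pssm@E
  mx <- apply(E, 1, max)
  ex <- exp(E - mx)
  A <- ex / rowSums(ex)
  colnames(A) <- residueOrder()
  new("StandardizedProfile", identifier = pssm@identifier, A = A,
      origin = "pssm")
}

#' One-hot profile fallback for sequences without a PSSM
#'
#' A standard residue gets a unit row (probability 1 on its own column);
#' degenerate residues (X, B, Z, U, O, J) get a uniform row (all 0.05), the
#' zero-information choice.  Downstream, a one-hot profile makes the
#' descriptor pipeline reduce exactly to amphiphilic pseudo-amino-acid
#' composition on the raw sequence.
#'
#' @param sequence A residue string, \code{AAString}, or a single-element
#'   \code{AAStringSet}.
#' @param identifier Identifier to attach (taken from names when available).
#' @return A \code{\link{StandardizedProfile}} with origin "one_hot".
#' @export
oneHotProfile <- function(sequence, identifier = "") {
  if (is(sequence, "AAStringSet")) {
    if (length(sequence) != 1L) stop("expected a single sequence")
    if (!nzchar(identifier) && !is.null(names(sequence)))
      identifier <- names(sequence)[1]
    sequence <- as.character(sequence[[1]])
  }
  sequence <- toupper(as.character(sequence))
  ch <- strsplit(sequence, "")[[1]]
  if (!length(ch)) stop("empty sequence")
  ord <- residueOrder()
  A <- matrix(0, nrow = length(ch), ncol = 20,
              dimnames = list(NULL, ord))
  std <- match(ch, ord)
  for (i in seq_along(ch)) {
    if (is.na(std[i])) {
      if (!ch[i] %in% DEGENERATE_RESIDUES)
        stop("illegal residue '", ch[i], "' at position ", i)
      A[i, ] <- 0.05
    } else {
      A[i, std[i]] <- 1
    }
  }
  new("StandardizedProfile", identifier = identifier, A = A,
      origin = "one_hot")
}

#' Load standardized profiles for a set of sequences
#'
#' For each sequence, looks for \code{<identifier>.pssm} in \code{pssmDir};
#' if found, the PSSM is parsed, validated against the sequence and softmax
#' standardized; if absent (or \code{pssmDir} is NULL) the one-hot fallback
#' is used, which degrades the representation to plain amphiphilic
#' pseudo-amino-acid composition for that sequence.  The number of fallbacks
#' is reported via \code{message()}.
#'
#' @param sequences An \code{AAStringSet} with identifiers as names.
#' @param pssmDir Directory of per-sequence PSSM files, or NULL.
#' @return Named list of \code{\link{StandardizedProfile}} objects, in input
#'   order; attribute \code{origins} is the per-sequence origin flag vector.
#' @export
loadProfiles <- function(sequences, pssmDir = NULL) {
  stopifnot(is(sequences, "AAStringSet"))
  if (!length(sequences)) stop("no sequences supplied")
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all sequences must be named with identifiers")
  profiles <- vector("list", length(sequences))
  origins <- character(length(sequences))
  for (i in seq_along(sequences)) {
    pssmPath <- if (is.null(pssmDir)) "" else
      file.path(pssmDir, paste0(ids[i], ".pssm"))
    if (nzchar(pssmPath) && file.exists(pssmPath)) {
      pssm <- parseAsciiPssm(pssmPath,
                             expectedSequence = as.character(sequences[[i]]),
                             identifier = ids[i])
      profiles[[i]] <- standardizePssm(pssm)
    } else {
      profiles[[i]] <- oneHotProfile(as.character(sequences[[i]]),
                                     identifier = ids[i])
    }
    origins[i] <- profiles[[i]]@origin
  }
  nFallback <- sum(origins == "one_hot")
  if (nFallback > 0)
    message(nFallback, " of ", length(sequences),
            " sequence(s) had no PSSM; one-hot fallback used")
  names(profiles) <- ids
  attr(profiles, "origins") <- origins
  profiles
}

#' Suggest a psiblast command line for generating PSSMs
#'
#' Convenience helper only: returns the command string for producing an
#' ASCII PSSM with the settings the method assumes (three iterations,
#' e-value threshold 0.001).  The package never runs psiblast itself.
#'
#' @param fasta Query FASTA path.
#' @param db BLAST database name.
#' @param out Output PSSM path.
#' @return The command line as a single string.
#' @export
psiblastCommand <- function(fasta, db = "swissprot", out = "query.pssm") {
  sprintf("psiblast -query %s -db %s -num_iterations 3 -evalue 0.001 -out_ascii_pssm %s",
          fasta, db, out)
}
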