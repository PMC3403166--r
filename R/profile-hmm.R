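## Profile-HMM construction, plain-text serialization, and Viterbi scanning.
## Emission scores are log2-odds in bits against a uniform 0.25 background;
## transition scores are log2 probabilities. The scanner applies local
## alignment semantics: free entry into any match state, free exit after any
## match state, flanking read residues cost nothing.

.DNA <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Watson-Crick complement of the reversed string; N maps to N and the
#' other IUPAC ambiguity codes map to their complements.
#'
#' @param x character vector of DNA strings (IUPAC alphabet).
#' @return character vector of reverse complements, names preserved.
#' @examples
#' revComp(c("AAAC", "ACGT"))
#' @export
revComp <- function(x) {
  bad <- grepl("[^ACGTUNRYSWKMBDHVacgtunryswkmbdhv]", x)
  if (any(bad))
    stop("non-IUPAC character in sequence(s): ",
         paste(head(which(bad), 5L), collapse = ", "), call. = FALSE)
  revcomp_cpp(toupper(chartr("Uu", "Tt", x)))
}

#' Build a profile HMM from an ungapped seed alignment
#'
#' Match-state emissions are maximum-likelihood estimates from the
#' alignment columns with a +1 pseudocount per base; insert states emit at
#' the background distribution; transitions use a global prior of
#' 0.9/0.05/0.05 out of every state (match to match/insert/delete, and
#' likewise out of insert and delete states). Underlying probabilities are
#' checked to sum to 1 within 1e-9 before conversion to log-odds.
#'
#' @param alignment [Biostrings::DNAStringSet] (or character vector) of
#'   equal-length ungapped sequences.
#' @param name model name (single token).
#' @return a [ProfileHMM-class] object.
#' @export
buildProfileHMM <- function(alignment, name = "ssu16") {
  seqs <- toupper(as.character(alignment))
  if (length(seqs) < 1L) stop("need at least one seed sequence", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1L)
    stop("seed alignment must be ungapped with equal lengths", call. = FALSE)
  M <- nchar(seqs[1L])
  mat <- do.call(rbind, strsplit(seqs, ""))
  matchProb <- t(apply(mat, 2L, function(col) {
    counts <- table(factor(col, levels = .DNA)) + 1  # +1 pseudocount
    as.numeric(counts) / sum(counts)
  }))
  colnames(matchProb) <- .DNA
  stopifnot(all(abs(rowSums(matchProb) - 1) < 1e-9))
  insertProb <- matrix(0.25, nrow = max(M - 1L, 0L), ncol = 4L,
                       dimnames = list(NULL, .DNA))
  trans <- matrix(rep(log2(c(0.9, 0.05, 0.05)), 3L),
                  nrow = max(M - 1L, 0L), ncol = 9L, byrow = TRUE)
  colnames(trans) <- c("MM", "MI", "MD", "IM", "II", "ID", "DM", "DI", "DD")
  new("ProfileHMM", name = name,
      matchEmissions = log2(matchProb / 0.25),
      insertEmissions = log2(insertProb / 0.25),
      transitions = trans)
}

#' @describeIn ProfileHMM-class number of match states.
#' @param x,object a ProfileHMM.
#' @export
hmmLength <- function(x) nrow(x@matchEmissions)

#' @describeIn ProfileHMM-class match-state emission log-odds (bits).
#' @export
matchEmissions <- function(x) x@matchEmissions

setMethod("show", "ProfileHMM", function(object) {
  cat("ProfileHMM '", object@name, "': ", hmmLength(object),
      " match states\n", sep = "")
})

#' Write a profile HMM to its plain-text format
#'
#' Versioned header (`PHMM1`), then NAME/LENGTH/ALPH lines, one `MATCH`
#' and `INSERT` line per state with four emission log-odds (bits), and one
#' `TRANS` line per position with the nine transition log2 probabilities
#' (MM MI MD IM II ID DM DI DD).
#'
#' @param hmm a [ProfileHMM-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProfileHMM <- function(hmm, path) {
  stopifnot(is(hmm, "ProfileHMM"))
  M <- hmmLength(hmm)
  num <- function(v) paste(sprintf("%.8f", v), collapse = " ")
  lines <- c("PHMM1",
             paste("NAME", hmm@name),
             paste("LENGTH", M),
             "ALPH A C G T")
  for (j in seq_len(M))
    lines <- c(lines, paste("MATCH", j, num(hmm@matchEmissions[j, ])))
  for (j in seq_len(M - 1L))
    lines <- c(lines, paste("INSERT", j, num(hmm@insertEmissions[j, ])))
  for (j in seq_len(M - 1L))
    lines <- c(lines, paste("TRANS", j, num(hmm@transitions[j, ])))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a profile HMM from its plain-text format
#'
#' @param path file written by [writeProfileHMM()].
#' @return a [ProfileHMM-class].
#' @export
readProfileHMM <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1L] != "PHMM1")
    stop("not a PHMM1 file: '", path, "'", call. = FALSE)
  fields <- strsplit(trimws(lines), "\\s+")
  key <- vapply(fields, `[`, "", 1L)
  getOne <- function(k) {
    i <- which(key == k)
    if (length(i) != 1L) stop("expected exactly one ", k, " line", call. = FALSE)
    fields[[i]][-1L]
  }
  name <- getOne("NAME")[1L]
  M <- as.integer(getOne("LENGTH")[1L])
  parseBlock <- function(k, n, valuesPerLine) {
    idx <- which(key == k)
    if (length(idx) != n)
      stop("expected ", n, " ", k, " lines, found ", length(idx), call. = FALSE)
    out <- matrix(NA_real_, nrow = n, ncol = valuesPerLine)
    for (i in idx) {
      v <- fields[[i]][-1L]
      j <- as.integer(v[1L])
      vals <- as.numeric(v[-1L])
      if (j < 1L || j > n || length(vals) != valuesPerLine || anyNA(vals))
        stop("malformed ", k, " line ", i, " in '", path, "'", call. = FALSE)
      out[j, ] <- vals
    }
    out
  }
  matchEm <- parseBlock("MATCH", M, 4L)
  colnames(matchEm) <- .DNA
  insEm <- if (M > 1L) parseBlock("INSERT", M - 1L, 4L) else
    matrix(numeric(0), 0L, 4L)
  colnames(insEm) <- .DNA
  trans <- if (M > 1L) parseBlock("TRANS", M - 1L, 9L) else
    matrix(numeric(0), 0L, 9L)
  colnames(trans) <- c("MM", "MI", "MD", "IM", "II", "ID", "DM", "DI", "DD")
  new("ProfileHMM", name = name, matchEmissions = matchEm,
      insertEmissions = insEm, transitions = trans)
}

#' Viterbi scan of one sequence against a profile HMM
#'
#' Computes the maximum total log-odds over all state paths under local
#' alignment semantics (free entry into any match state at any read
#' position, free exit after any match state, zero-cost flanking), and one
#' maximizing path. Ties among predecessors are broken deterministically,
#' preferring match over delete over insert states. Residues other than
#' A/C/G/T emit at the background distribution (0 bits).
#'
#' @param hmm a [ProfileHMM-class].
#' @param residues a single DNA string (or length-1 DNAStringSet).
#' @return list with `score` (bits), `path` (data.frame with columns state
#'   in M/I/D, model index, read position), `readStart`/`readEnd` (0-based
#'   half-open) and `modelStart`/`modelEnd` (match states covered).
#' @examples
#' hmm <- buildProfileHMM(c("ACGTACGT", "ACGTACGT"))
#' viterbi(hmm, "TTACGTACGTTT")$score
#' @export
viterbi <- function(hmm, residues) {
  stopifnot(is(hmm, "ProfileHMM"))
  residues <- toupper(as.character(residues))
  if (length(residues) != 1L || !nzchar(residues))
    stop("residues must be one non-empty DNA string", call. = FALSE)
  r <- viterbi_cpp(hmm@matchEmissions, hmm@insertEmissions,
                   hmm@transitions, residues)
  path <- as.data.frame(r$path)
  path$state <- c("M", "I", "D")[path$state]
  list(score = r$score, path = path,
       readStart = r$readStart, readEnd = r$readEnd,
       modelStart = r$modelStart, modelEnd = r$modelEnd)
}
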