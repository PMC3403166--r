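## Readers and writers for every external format the pipeline touches.
## Sequences travel as Biostrings::DNAStringSet with the FASTA description in
## mcols()$description and FASTQ qualities (Phred+33 strings) in
## mcols()$quality. Record order is preserved everywhere: downstream merge
## determinism depends on it.

.isGzPath <- function(path) grepl("\\.gz$", path, ignore.case = TRUE)

.sniffFormat <- function(path) {
  con <- if (.isGzPath(path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  b <- readBin(con, "raw", n = 1L)
  if (length(b) == 0L) return("empty")
  ch <- rawToChar(b)
  if (ch == ">") "fasta" else if (ch == "@") "fastq"
  else stop("cannot detect sequence format of '", path,
            "': first byte is neither '>' nor '@'", call. = FALSE)
}

## locate the first malformed FASTQ record so parse errors can name a line
.diagnoseFastq <- function(path) {
  lines <- readLines(path)
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "@"))
      stop("FASTQ parse error at line ", i, " of '", path,
           "': expected '@' header", call. = FALSE)
    if (i + 3L > length(lines))
      stop("FASTQ parse error at line ", i, " of '", path,
           "': truncated record", call. = FALSE)
    if (!startsWith(lines[i + 2L], "+"))
      stop("FASTQ parse error at line ", i + 2L, " of '", path,
           "': expected '+' separator", call. = FALSE)
    if (nchar(lines[i + 1L]) != nchar(lines[i + 3L]))
      stop("FASTQ parse error at line ", i + 3L, " of '", path,
           "': quality length ", nchar(lines[i + 3L]),
           " != sequence length ", nchar(lines[i + 1L]), call. = FALSE)
    i <- i + 4L
  }
  invisible(NULL)
}

.diagnoseFasta <- function(path) {
  lines <- readLines(path)
  hdr <- which(startsWith(lines, ">"))
  for (h in hdr) {
    nxt <- if (h == length(lines)) "" else lines[h + 1L]
    if (startsWith(nxt, ">") || !nzchar(gsub("\\s", "", nxt)))
      stop("FASTA parse error at line ", h, " of '", path,
           "': header without sequence", call. = FALSE)
  }
  invisible(NULL)
}

.splitHeader <- function(x) {
  id <- sub("\\s.*$", "", x)
  desc <- sub("^\\S+\\s*", "", x)
  list(id = id, desc = desc)
}

#' Read sequences from FASTA or FASTQ
#'
#' Records are returned in file order (order is load-bearing for the
#' deterministic-merge contract). Lowercase residues are uppercased and U
#' is mapped to T; other IUPAC ambiguity codes are preserved. Gzipped files
#' are read transparently by extension.
#'
#' @param path input file; `.gz` accepted.
#' @param format "fasta", "fastq" or "auto" (detected from the first byte:
#'   `>` vs `@`).
#' @return A [Biostrings::DNAStringSet]; names are record ids,
#'   `mcols()$description` holds the free-text description, and for FASTQ
#'   `mcols()$quality` holds Phred+33 quality strings.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1 first read", "acgt"), fa)
#' readSequences(fa)
#' @export
readSequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  if (format == "auto") {
    format <- .sniffFormat(path)
    if (format == "empty")
      return(DNAStringSet())
  }
  qual <- NULL
  # read as raw strings first: U/u must be remapped to T before the DNA
  # alphabet is enforced (Biostrings would reject or drop them)
  if (format == "fastq") {
    .diagnoseFastq(path)
    x <- tryCatch(
      Biostrings::readBStringSet(path, format = "fastq",
                                 with.qualities = TRUE),
      error = function(e) stop("FASTQ parse error in '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    qual <- as.character(mcols(x)$qualities)
    seqs <- as.character(x)
    hdr <- .splitHeader(names(x))
  } else {
    x <- tryCatch(
      Biostrings::readBStringSet(path, format = "fasta"),
      error = function(e) {
        .diagnoseFasta(path)
        stop("FASTA parse error in '", path, "': ", conditionMessage(e),
             call. = FALSE)
      })
    if (any(width(x) == 0L)) .diagnoseFasta(path)
    seqs <- as.character(x)
    hdr <- .splitHeader(names(x))
  }
  if (any(!nzchar(hdr$id)))
    stop("record with empty id in '", path, "'", call. = FALSE)
  seqs <- toupper(chartr("Uu", "Tt", seqs))
  out <- tryCatch(DNAStringSet(seqs), error = function(e)
    stop("parse error in '", path, "': ", conditionMessage(e),
         call. = FALSE))
  names(out) <- hdr$id
  mcols(out)$description <- hdr$desc
  if (!is.null(qual)) mcols(out)$quality <- qual
  out
}

#' Write sequences to FASTA or FASTQ
#'
#' The inverse of [readSequences()]: writing then reading returns the same
#' records in the same order. FASTQ output requires qualities in
#' `mcols(records)$quality`.
#'
#' @param records a [Biostrings::DNAStringSet] as returned by
#'   [readSequences()].
#' @param path output file.
#' @param format "fasta", "fastq" or "auto" (from the file extension;
#'   defaults to fasta).
#' @return `path`, invisibly.
#' @export
writeSequences <- function(records, path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("fastq", "fq")) "fastq" else "fasta"
  }
  desc <- mcols(records)$description
  hdr <- names(records)
  if (!is.null(desc)) {
    has <- !is.na(desc) & nzchar(desc)
    hdr[has] <- paste(hdr[has], desc[has])
  }
  lines <- character(0)
  seqs <- as.character(records)
  if (format == "fastq") {
    qual <- mcols(records)$quality
    if (is.null(qual))
      stop("FASTQ output requires mcols(records)$quality", call. = FALSE)
    lines <- as.vector(rbind(paste0("@", hdr), seqs, "+", qual))
  } else {
    lines <- as.vector(rbind(paste0(">", hdr), seqs))
  }
  con <- if (.isGzPath(path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a taxonomy map
#'
#' Two-column tab-separated file: reference sequence id, then the raw
#' semicolon-delimited rank-prefixed lineage string (Greengenes dialect,
#' e.g. `k__Bacteria; p__Firmicutes; ...`).
#'
#' @param path TSV path; `.gz` accepted.
#' @return named character vector mapping reference id to raw lineage
#'   string.
#' @export
readTaxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    colClasses = "character", quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) return(setNames(character(0), character(0)))
  if (ncol(tab) < 2L)
    stop("taxonomy TSV must have >= 2 tab-separated columns", call. = FALSE)
  ids <- tab[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate reference id(s) in taxonomy: ",
         paste(dup, collapse = ", "), call. = FALSE)
  setNames(tab[[2L]], ids)
}

#' Write a taxonomy map
#'
#' @param taxonomy named character vector (id to lineage string).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeTaxonomy <- function(taxonomy, path) {
  writeLines(paste(names(taxonomy), taxonomy, sep = "\t"), path)
  invisible(path)
}

.HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' An empty tabular hit table
#'
#' @return zero-row data.frame with the 12 standard similarity-search
#'   columns (query id, subject id, percent identity, alignment length,
#'   mismatches, gap opens, query start/end, subject start/end, E-value,
#'   bit score).
#' @export
emptyHits <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             pident = numeric(0), length = integer(0),
             mismatch = integer(0), gapopen = integer(0),
             qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0),
             evalue = numeric(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)
}

.validateHits <- function(hits) {
  if (!all(.HIT_COLUMNS %in% names(hits)))
    stop("hit table must have the 12 standard columns", call. = FALSE)
  if (nrow(hits)) {
    if (any(hits$pident < 0 | hits$pident > 100))
      stop("percent identity out of [0, 100]", call. = FALSE)
    if (any(hits$qstart > hits$qend))
      stop("query start must not exceed query end", call. = FALSE)
    if (any(hits$evalue < 0)) stop("E-value must be >= 0", call. = FALSE)
    if (any(!is.finite(hits$bitscore)))
      stop("bit score must be finite", call. = FALSE)
  }
  hits[, .HIT_COLUMNS]
}

#' Write alignment hits in 12-column tabular format
#'
#' Tab-separated with the standard column order, no header; identity with
#' two decimals, E-value in scientific notation (BLAST tabular dialect).
#' Coordinates are 1-based inclusive; minus-strand hits carry subject
#' start > subject end.
#'
#' @param hits data.frame as produced by [alignToReference()] or
#'   [emptyHits()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeTabularHits <- function(hits, path) {
  hits <- .validateHits(hits)
  lines <- if (nrow(hits) == 0L) character(0) else
    paste(hits$qseqid, hits$sseqid, sprintf("%.2f", hits$pident),
          hits$length, hits$mismatch, hits$gapopen, hits$qstart, hits$qend,
          hits$sstart, hits$send, sprintf("%.6e", hits$evalue),
          sprintf("%.4f", hits$bitscore), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read alignment hits from 12-column tabular format
#'
#' @param path TSV path written by [writeTabularHits()] (or any BLAST-style
#'   12-column tabular file).
#' @return data.frame with the standard 12 columns.
#' @export
readTabularHits <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  if (file.size(path) == 0L || length(readLines(path, n = 1L)) == 0L)
    return(emptyHits())
  tab <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                    col.names = .HIT_COLUMNS,
                    colClasses = c("character", "character", "numeric",
                                   "integer", "integer", "integer",
                                   "integer", "integer", "integer",
                                   "integer", "numeric", "numeric"),
                    stringsAsFactors = FALSE)
  .validateHits(tab)
}
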