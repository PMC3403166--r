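## Step 1: locate 16S rRNA fragments in shotgun reads by profile-HMM
## Viterbi search on both strands and excise them in rRNA sense orientation.

#' Scan reads for 16S rRNA fragments on both strands
#'
#' Runs the local Viterbi scanner on each read and its reverse complement,
#' keeps the better-scoring strand per read (ties go to plus), and reports
#' hits with score at or above `minScore`. Reads are processed in
#' contiguous chunks balanced by residue count; the merged output is
#' identical for every chunk count, and hits come back in read order.
#'
#' @param reads [Biostrings::DNAStringSet] of reads (names are read ids).
#' @param hmm a [ProfileHMM-class].
#' @param minScore reporting threshold in bits. The default of 25 sits
#'   above the largest background score expected when a model of a few
#'   hundred match states is scanned against short reads (the null maximum
#'   grows like the log of the model-length x read-length search space),
#'   while true 16S fragments of 60 nt or more at a few percent divergence
#'   score over 40 bits.
#' @param chunks number of chunks (>= 1).
#' @return data.frame with columns read, strand (+/-), readStart, readEnd
#'   (0-based half-open, on the reported strand), modelStart, modelEnd
#'   (match states covered) and score (bits).
#' @seealso [extractFragments()], [viterbi()]
#' @export
scanReads <- function(reads, hmm, minScore = 25, chunks = 1L) {
  stopifnot(is(hmm, "ProfileHMM"), is.finite(minScore), chunks >= 1L)
  ids <- names(reads)
  if (is.null(ids)) stop("reads must be named", call. = FALSE)
  n <- length(reads)
  empty <- data.frame(read = character(0), strand = character(0),
                      readStart = integer(0), readEnd = integer(0),
                      modelStart = integer(0), modelEnd = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  plan <- chunkPlan(width(reads), chunks)
  seqs <- as.character(reads)
  parts <- vector("list", length(plan@chunks))
  for (ci in seq_along(plan@chunks)) {
    ord <- plan@chunks[[ci]]
    h <- scan_reads_cpp(seqs[ord], hmm@matchEmissions, hmm@insertEmissions,
                        hmm@transitions, minScore)
    if (nrow(h)) h$ord <- ord[h$ord]
    parts[[ci]] <- h
  }
  hits <- do.call(rbind, parts)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  hits <- hits[order(hits$ord), , drop = FALSE]  # read order; <=1 hit per read
  data.frame(read = ids[hits$ord], strand = hits$strand,
             readStart = hits$readStart, readEnd = hits$readEnd,
             modelStart = hits$modelStart, modelEnd = hits$modelEnd,
             score = hits$score, stringsAsFactors = FALSE, row.names = NULL)
}

#' Extract 16S fragments from reads given scan hits
#'
#' Fragment ids are `<read id>|<strand>|<start>-<end>`. Minus-strand hit
#' intervals refer to the reverse complement of the read, so minus
#' fragments are excised from the reverse-complemented read, i.e. written
#' in rRNA sense orientation.
#'
#' @param reads [Biostrings::DNAStringSet] the hits refer to.
#' @param hits data.frame from [scanReads()].
#' @return [Biostrings::DNAStringSet] of fragments, in hit order.
#' @export
extractFragments <- function(reads, hits) {
  if (nrow(hits) == 0L) return(DNAStringSet())
  missing <- setdiff(hits$read, names(reads))
  if (length(missing))
    stop("hit refers to unknown read(s): ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  seqs <- as.character(reads[hits$read])
  minus <- hits$strand == "-"
  seqs[minus] <- revComp(seqs[minus])
  w <- nchar(seqs)
  bad <- hits$readStart < 0L | hits$readEnd > w | hits$readStart >= hits$readEnd
  if (any(bad))
    stop("hit interval outside read bounds for read(s): ",
         paste(head(hits$read[bad], 5L), collapse = ", "), call. = FALSE)
  frag <- substring(seqs, hits$readStart + 1L, hits$readEnd)
  out <- DNAStringSet(frag)
  names(out) <- sprintf("%s|%s|%d-%d", hits$read, hits$strand,
                        hits$readStart, hits$readEnd)
  out
}

#' Length distribution of extracted fragments
#'
#' @param fragments [Biostrings::DNAStringSet] (or integer lengths).
#' @return a [LengthDistribution-class] with histogram (length -> count),
#'   n, min, max and mean.
#' @export
lengthDistribution <- function(fragments) {
  lens <- if (is.numeric(fragments)) as.integer(fragments) else
    width(fragments)
  if (length(lens) == 0L)
    return(new("LengthDistribution", histogram = integer(0), n = 0L,
               min = NA_real_, max = NA_real_, mean = NA_real_))
  tab <- table(lens)
  new("LengthDistribution",
      histogram = setNames(as.integer(tab), names(tab)),
      n = length(lens), min = min(lens), max = max(lens),
      mean = mean(lens))
}

setMethod("show", "LengthDistribution", function(object) {
  cat("LengthDistribution: n =", object@n)
  if (object@n > 0L)
    cat(sprintf(", min = %g, max = %g, mean = %.2f",
                object@min, object@max, object@mean))
  cat("\n")
})

#' @describeIn lengthDistribution histogram as a two-column data.frame
#'   (length, count).
#' @param x a LengthDistribution.
#' @export
lengthTable <- function(x) {
  stopifnot(is(x, "LengthDistribution"))
  data.frame(length = as.integer(names(x@histogram)),
             count = as.integer(x@histogram), row.names = NULL)
}

#' Write a length distribution as TSV plus a plain-text summary
#'
#' @param x a [LengthDistribution-class].
#' @param prefix output path prefix; writes `<prefix>.lengths.tsv` and
#'   `<prefix>.lengths.txt`.
#' @return character vector of the two paths, invisibly.
#' @export
writeLengthDistribution <- function(x, prefix) {
  tsv <- paste0(prefix, ".lengths.tsv")
  txt <- paste0(prefix, ".lengths.txt")
  write.table(lengthTable(x), tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  summary <- if (x@n == 0L) "fragments: 0" else
    sprintf("fragments: %d\nmin: %g\nmax: %g\nmean: %.2f",
            x@n, x@min, x@max, x@mean)
  writeLines(summary, txt)
  invisible(c(tsv, txt))
}
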