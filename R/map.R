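## Step 2: map extracted fragments to the 16S reference database with a
## seed-and-extend aligner organized as problem decomposition, (chunk-)
## parallel computing and deterministic result combination.

#' Decompose queries into balanced contiguous chunks
#'
#' Exactly `min(nChunks, n)` contiguous chunks, greedily balanced by total
#' residue count: each chunk closes once its load reaches the running
#' target (remaining residues / remaining chunks), while always leaving at
#' least one query per remaining chunk. Deterministic; concatenating the
#' chunks restores the input order, which is what makes merged
#' chunk-parallel results identical to serial execution.
#'
#' @param lengths integer residue counts per query (or a DNAStringSet,
#'   whose widths are used).
#' @param nChunks target chunk count (>= 1).
#' @return a [ChunkPlan-class]; zero chunks for an empty query set.
#' @export
chunkPlan <- function(lengths, nChunks) {
  if (is(lengths, "DNAStringSet")) lengths <- width(lengths)
  stopifnot(nChunks >= 1L)
  n <- length(lengths)
  if (n == 0L) return(new("ChunkPlan", chunks = list(), loads = numeric(0)))
  k <- min(as.integer(nChunks), n)
  chunks <- vector("list", k)
  loads <- numeric(k)
  start <- 1L
  for (ci in seq_len(k)) {
    remChunks <- k - ci + 1L
    if (ci == k) { end <- n } else {
      target <- sum(lengths[start:n]) / remChunks
      end <- start
      load <- lengths[start]
      while (load < target && (n - end) > (remChunks - 1L)) {
        end <- end + 1L
        load <- load + lengths[end]
      }
    }
    chunks[[ci]] <- start:end
    loads[ci] <- sum(lengths[start:end])
    start <- end + 1L
  }
  new("ChunkPlan", chunks = chunks, loads = loads)
}

setMethod("show", "ChunkPlan", function(object) {
  cat("ChunkPlan:", length(object@chunks), "chunk(s),",
      sum(lengths(object@chunks)), "queries\n")
})

#' @describeIn chunkPlan number of chunks in a plan.
#' @param plan a ChunkPlan.
#' @export
nChunks <- function(plan) length(plan@chunks)

#' Karlin-Altschul parameters for an ungapped scoring scheme
#'
#' Solves the characteristic equation
#' \eqn{\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1} for \eqn{\lambda} by
#' root finding, then computes K by the classical partial-sum series for
#' lattice score distributions. Background is uniform over A/C/G/T.
#'
#' @param match positive match reward.
#' @param mismatch negative mismatch penalty.
#' @return list with `lambda` (nats per score unit), `K`, and `H` (relative
#'   entropy, nats per aligned pair).
#' @examples
#' karlinAltschul(1, -2)  # lambda ~ 1.33, K ~ 0.62
#' @export
karlinAltschul <- function(match, mismatch) {
  stopifnot(match > 0, mismatch < 0)
  pMatch <- 0.25            # P(aligned pair matches) at uniform background
  p <- c(pMatch, 1 - pMatch)
  s <- c(match, mismatch)
  lambda <- uniroot(function(l) sum(p * exp(l * s)) - 1,
                    lower = 1e-9, upper = 20, tol = 1e-12)$root
  H <- lambda * sum(s * p * exp(lambda * s))
  d <- .gcd(abs(match), abs(mismatch))   # lattice span of the score walk
  # sigma = sum_k (1/k) [ P(S_k >= 0) + E(e^{lambda S_k}; S_k < 0) ],
  # S_k the k-step random walk of pair scores; terms decay geometrically
  sigma <- 0
  cs <- s; cp <- p
  for (k in 1:80) {
    if (k > 1L) {
      ns <- outer(cs, s, "+")
      np <- outer(cp, p, "*")
      agg <- tapply(as.numeric(np), as.numeric(ns), sum)
      cs <- as.numeric(names(agg)); cp <- as.numeric(agg)
    }
    pos <- sum(cp[cs >= 0])
    neg <- sum(cp[cs < 0] * exp(lambda * cs[cs < 0]))
    term <- (pos + neg) / k
    sigma <- sigma + term
    if (k > 5L && term < 1e-12) break
  }
  K <- lambda * d * exp(-2 * sigma) / (H * (1 - exp(-lambda * d)))
  list(lambda = lambda, K = K, H = H)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Construct a scoring scheme
#'
#' Defaults (+1/-2, gap open -5, gap extend -2) suit short 16S fragments
#' at a few percent divergence. Lambda and K are derived from the ungapped
#' scheme via [karlinAltschul()].
#'
#' @param match positive integer match reward.
#' @param mismatch negative integer mismatch penalty.
#' @param gapOpen negative integer gap-open penalty.
#' @param gapExtend negative integer gap-extension penalty.
#' @return a [ScoringScheme-class].
#' @export
scoringScheme <- function(match = 1L, mismatch = -2L, gapOpen = -5L,
                          gapExtend = -2L) {
  ka <- karlinAltschul(match, mismatch)
  new("ScoringScheme", match = as.integer(match),
      mismatch = as.integer(mismatch), gapOpen = as.integer(gapOpen),
      gapExtend = as.integer(gapExtend), lambda = ka$lambda, K = ka$K)
}

setMethod("show", "ScoringScheme", function(object) {
  cat(sprintf(
    "ScoringScheme: match %+d mismatch %+d gap %+d/%+d lambda %.4f K %.4f\n",
    object@match, object@mismatch, object@gapOpen, object@gapExtend,
    object@lambda, object@K))
})

#' Build a word index over a reference database
#'
#' Records every word of length `w` of every reference together with its
#' (reference, offset) position; words containing non-ACGT codes are not
#' indexed.
#'
#' @param references named [Biostrings::DNAStringSet].
#' @param w word length (default 16; long enough for specific 16S seeds,
#'   short enough to survive a few percent divergence in ~100 nt
#'   fragments).
#' @return a [ReferenceIndex-class].
#' @export
buildReferenceIndex <- function(references, w = 16L) {
  stopifnot(is(references, "DNAStringSet"))
  if (is.null(names(references)))
    stop("references must be named", call. = FALSE)
  w <- as.integer(w)
  seqs <- as.character(references)
  rows <- lapply(seq_along(seqs), function(t) {
    s <- seqs[[t]]
    n <- nchar(s)
    if (n < w) return(NULL)
    starts <- seq_len(n - w + 1L)
    kmers <- substring(s, starts, starts + w - 1L)
    keep <- !grepl("[^ACGT]", kmers)
    if (!any(keep)) return(NULL)
    data.frame(kmer = kmers[keep], ref = t, offset = starts[keep] - 1L,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(kmer = character(0), ref = integer(0),
                      offset = integer(0), stringsAsFactors = FALSE)
  new("ReferenceIndex", references = references, w = w, kmerTable = tab)
}

setMethod("show", "ReferenceIndex", function(object) {
  cat("ReferenceIndex:", length(object@references), "reference(s), w =",
      object@w, "(", nrow(object@kmerTable), "indexed words )\n")
})

#' @describeIn buildReferenceIndex the indexed reference sequences.
#' @param index a ReferenceIndex.
#' @export
referenceSequences <- function(index) index@references

.bitScore <- function(score, scheme)
  (scheme@lambda * score - log(scheme@K)) / log(2)

.eValue <- function(score, scheme, m, n)
  scheme@K * m * n * exp(-scheme@lambda * score)

## shared post-processing of raw kernel rows into 12-column tabular hits
.rowsToHits <- function(raw, qnames, qwidths, index, scheme, maxEvalue) {
  if (nrow(raw) == 0L) return(emptyHits())
  dbSize <- sum(width(index@references))
  m <- qwidths[raw$query]
  bit <- .bitScore(raw$score, scheme)
  ev <- .eValue(raw$score, scheme, m, dbSize)
  minus <- raw$strand == "-"
  # kernel coordinates are 0-based half-open on the aligned (possibly
  # reverse-complemented) query strand; convert to the 1-based tabular
  # convention here and only here. Minus-strand hits keep ascending query
  # coordinates and carry descending subject coordinates.
  qstart <- ifelse(minus, m - raw$qe + 1L, raw$qs + 1L)
  qend <- ifelse(minus, m - raw$qs, raw$qe)
  sstart <- ifelse(minus, raw$se, raw$ss + 1L)
  send <- ifelse(minus, raw$ss + 1L, raw$se)
  hits <- data.frame(
    qseqid = qnames[raw$query],
    sseqid = names(index@references)[raw$ref],
    pident = round(100 * raw$matches / raw$length, 2L),
    length = raw$length, mismatch = raw$mismatch, gapopen = raw$gapopen,
    qstart = as.integer(qstart), qend = as.integer(qend),
    sstart = as.integer(sstart), send = as.integer(send),
    evalue = ev, bitscore = bit, stringsAsFactors = FALSE)
  qord <- raw$query
  keep <- hits$evalue <= maxEvalue
  hits <- hits[keep, , drop = FALSE]
  qord <- qord[keep]
  # per query: descending bit score, then ascending subject id
  hits <- hits[order(qord, -hits$bitscore, hits$sseqid), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Align one query to the reference database
#'
#' Seed-and-extend on both query strands: shared words are found through
#' the index, co-diagonal seeds merged, each merged seed extended ungapped
#' with X-drop (X = 20 score units), and a banded gapped extension
#' (band 16) run around the best ungapped segment per reference. Raw
#' scores are converted to bit scores and E-values with the scheme's
#' Karlin-Altschul parameters; hits with E-value at most `maxEvalue` are
#' returned sorted by descending bit score then ascending subject id.
#'
#' @param query a single named sequence ([Biostrings::DNAStringSet] of
#'   length 1, or a named character string).
#' @param index a [ReferenceIndex-class].
#' @param scheme a [ScoringScheme-class].
#' @param maxEvalue E-value cutoff (default 1e-5).
#' @param xdrop,band heuristic extension parameters.
#' @return data.frame of tabular hits (see [emptyHits()] for columns).
#' @export
alignToReference <- function(query, index, scheme = scoringScheme(),
                             maxEvalue = 1e-5, xdrop = 20L, band = 16L) {
  if (is.character(query)) query <- DNAStringSet(query)
  stopifnot(length(query) == 1L)
  if (is.null(names(query)))
    stop("query must be named", call. = FALSE)
  .alignBatch(query, index, scheme, maxEvalue, xdrop, band)
}

.alignBatch <- function(queries, index, scheme, maxEvalue, xdrop, band) {
  raw <- align_batch_cpp(as.character(queries),
                         as.character(index@references), index@w,
                         scheme@match, scheme@mismatch, scheme@gapOpen,
                         scheme@gapExtend, as.integer(xdrop),
                         as.integer(band))
  .rowsToHits(raw, names(queries), width(queries), index, scheme, maxEvalue)
}

#' Chunk-parallel mapping of fragments with deterministic merge
#'
#' Decomposes the fragments into `nChunks` balanced contiguous chunks,
#' aligns each chunk, and recombines the per-chunk results in original
#' query order. The merged output equals the concatenation of per-query
#' [alignToReference()] results and is identical for every chunk count and
#' for any chunk completion order.
#'
#' @param fragments named [Biostrings::DNAStringSet].
#' @param index a [ReferenceIndex-class].
#' @param scheme a [ScoringScheme-class].
#' @param nChunks chunk count (>= 1).
#' @param maxEvalue E-value cutoff.
#' @param xdrop,band heuristic extension parameters.
#' @param .chunkOrder internal: permutation of chunk indices simulating
#'   out-of-order chunk completion; the merged result is unaffected.
#' @return data.frame of tabular hits in original query order.
#' @export
parallelMap <- function(fragments, index, scheme = scoringScheme(),
                        nChunks = 1L, maxEvalue = 1e-5, xdrop = 20L,
                        band = 16L, .chunkOrder = NULL) {
  if (length(fragments) == 0L) return(emptyHits())
  if (is.null(names(fragments)))
    stop("fragments must be named", call. = FALSE)
  plan <- chunkPlan(width(fragments), nChunks)
  k <- length(plan@chunks)
  if (is.null(.chunkOrder)) .chunkOrder <- seq_len(k)
  stopifnot(identical(sort(.chunkOrder), seq_len(k)))
  parts <- vector("list", k)
  for (ci in .chunkOrder)          # completion order is irrelevant:
    parts[[ci]] <- .alignBatch(fragments[plan@chunks[[ci]]], index, scheme,
                               maxEvalue, xdrop, band)
  out <- do.call(rbind, parts)     # recombination follows plan order
  rownames(out) <- NULL
  out
}

#' Best hit for one query
#'
#' Highest bit score; ties broken by lowest E-value, then lexicographically
#' smallest subject id.
#'
#' @param hits data.frame of tabular hits for a single query.
#' @return one-row data.frame, or NULL when `hits` is empty.
#' @export
bestHit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  ord <- order(-hits$bitscore, hits$evalue, hits$sseqid)
  hits[ord[1L], , drop = FALSE]
}
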