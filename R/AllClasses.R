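#' @import methods
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Profile hidden Markov model for 16S rRNA detection
#'
#' A position-specific model with match, insert and delete states over the
#' DNA alphabet. Emission scores are log2-odds against a uniform 0.25
#' background (bits); transition scores are log2 probabilities. Match state
#' \eqn{j} emits one residue; insert state \eqn{j} (between match \eqn{j}
#' and \eqn{j+1}) emits residues not represented by the model; delete state
#' \eqn{j} skips match \eqn{j} without emitting. There is no transition into
#' a delete state before the first match column and none out of a delete
#' state after the last.
#'
#' @slot name single-token model name.
#' @slot matchEmissions numeric M x 4 matrix (columns A, C, G, T) of
#'   match-state emission log-odds in bits.
#' @slot insertEmissions numeric (M-1) x 4 matrix of insert-state emission
#'   log-odds in bits.
#' @slot transitions numeric (M-1) x 9 matrix of transition log2
#'   probabilities with columns MM, MI, MD, IM, II, ID, DM, DI, DD; row
#'   \eqn{j} holds the moves out of position \eqn{j}.
#' @seealso [buildProfileHMM()], [viterbi()], [scanReads()]
#' @exportClass ProfileHMM
setClass("ProfileHMM",
  representation(
    name = "character",
    matchEmissions = "matrix",
    insertEmissions = "matrix",
    transitions = "matrix"
  )
)

.checkEmissionMatrix <- function(m, what, tol = 1e-5) {
  if (ncol(m) != 4L)
    return(sprintf("%s must have 4 columns (A, C, G, T)", what))
  if (nrow(m) > 0L) {
    p <- rowSums(2^m * 0.25)
    if (any(abs(p - 1) > tol))
      return(sprintf(
        "%s rows %s: underlying emission probabilities do not sum to 1",
        what, paste(which(abs(p - 1) > tol), collapse = ",")))
  }
  NULL
}

setValidity("ProfileHMM", function(object) {
  msg <- character()
  M <- nrow(object@matchEmissions)
  if (length(object@name) != 1L || !nzchar(object@name) ||
      grepl("\\s", object@name))
    msg <- c(msg, "name must be a single non-empty token")
  if (M < 1L) msg <- c(msg, "model must have at least one match state")
  if (nrow(object@insertEmissions) != max(M - 1L, 0L))
    msg <- c(msg, "insertEmissions must have M-1 rows")
  if (nrow(object@transitions) != max(M - 1L, 0L) ||
      (M > 1L && ncol(object@transitions) != 9L))
    msg <- c(msg, "transitions must be an (M-1) x 9 matrix")
  e <- .checkEmissionMatrix(object@matchEmissions, "matchEmissions")
  if (!is.null(e)) msg <- c(msg, e)
  e <- .checkEmissionMatrix(object@insertEmissions, "insertEmissions")
  if (!is.null(e)) msg <- c(msg, e)
  if (M > 1L) {
    tr <- 2^object@transitions
    for (grp in list(1:3, 4:6, 7:9)) {
      s <- rowSums(tr[, grp, drop = FALSE])
      if (any(abs(s - 1) > 1e-5))
        msg <- c(msg, "transition probabilities out of each state must sum to 1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Decomposition of a query set into balanced contiguous chunks
#'
#' Chunks partition the query ordinals; concatenating the chunks in order
#' restores the original query order, which is what makes the merged result
#' of chunk-parallel processing identical to serial execution.
#'
#' @slot chunks list of integer vectors of query ordinals (contiguous,
#'   in order).
#' @slot loads numeric residue load per chunk.
#' @seealso [chunkPlan()], [parallelMap()], [scanReads()]
#' @exportClass ChunkPlan
setClass("ChunkPlan",
  representation(chunks = "list", loads = "numeric")
)

setValidity("ChunkPlan", function(object) {
  ord <- unlist(object@chunks, use.names = FALSE)
  if (length(ord) && !identical(as.integer(ord), seq_along(ord)))
    return("chunks must be contiguous and restore the original query order")
  if (length(object@loads) != length(object@chunks))
    return("one load per chunk required")
  TRUE
})

#' Alignment scoring scheme with Karlin-Altschul statistics
#'
#' Match/mismatch/affine-gap integer scores plus the Karlin-Altschul
#' parameters lambda (nats per raw score unit) and K used to convert raw
#' local-alignment scores into bit scores and E-values:
#' \deqn{S' = (\lambda S - \ln K)/\ln 2, \quad E = K m n e^{-\lambda S}.}
#'
#' @slot match positive integer match reward.
#' @slot mismatch negative integer mismatch penalty.
#' @slot gapOpen negative integer gap-open penalty.
#' @slot gapExtend negative integer per-residue gap-extension penalty
#'   (a gap of length L scores gapOpen + L * gapExtend).
#' @slot lambda positive Karlin-Altschul scale for the ungapped scheme.
#' @slot K positive Karlin-Altschul prefactor.
#' @seealso [scoringScheme()], [karlinAltschul()]
#' @exportClass ScoringScheme
setClass("ScoringScheme",
  representation(
    match = "integer", mismatch = "integer",
    gapOpen = "integer", gapExtend = "integer",
    lambda = "numeric", K = "numeric"
  )
)

setValidity("ScoringScheme", function(object) {
  msg <- character()
  if (object@match <= 0L) msg <- c(msg, "match reward must be positive")
  if (object@mismatch >= 0L || object@gapOpen >= 0L || object@gapExtend >= 0L)
    msg <- c(msg, "mismatch and gap penalties must be negative")
  if (object@lambda <= 0) msg <- c(msg, "lambda must be positive")
  if (object@K <= 0) msg <- c(msg, "K must be positive")
  if (length(msg)) msg else TRUE
})

#' Word index over a 16S reference database
#'
#' Ordered reference sequences plus a lookup table of all their words
#' (k-mers) of length \code{w}. Words containing non-ACGT codes are not
#' indexed. The index drives seed finding in [alignToReference()].
#'
#' @slot references [Biostrings::DNAStringSet] of reference sequences,
#'   names are reference ids.
#' @slot w integer word length.
#' @slot kmerTable data.frame with columns kmer, ref (ordinal), offset
#'   (0-based) listing every indexed word occurrence.
#' @seealso [buildReferenceIndex()], [alignToReference()]
#' @exportClass ReferenceIndex
setClass("ReferenceIndex",
  representation(references = "DNAStringSet", w = "integer",
                 kmerTable = "data.frame")
)

setValidity("ReferenceIndex", function(object) {
  if (object@w < 4L || object@w > 31L)
    return("word length must be in [4, 31]")
  if (!all(c("kmer", "ref", "offset") %in% names(object@kmerTable)))
    return("kmerTable must have columns kmer, ref, offset")
  TRUE
})

#' Fragment length distribution
#'
#' Histogram plus summary statistics of extracted 16S fragment lengths.
#'
#' @slot histogram named integer vector, names are lengths (nt).
#' @slot n,min,max,mean numeric summaries (min/max/mean are NA when n = 0).
#' @seealso [lengthDistribution()]
#' @exportClass LengthDistribution
setClass("LengthDistribution",
  representation(histogram = "integer", n = "integer",
                 min = "numeric", max = "numeric", mean = "numeric")
)

setValidity("LengthDistribution", function(object) {
  if (sum(object@histogram) != object@n)
    return("histogram counts must sum to n")
  TRUE
})

#' Per-sample taxonomic profile
#'
#' Fragment-level taxonomic assignments for one sample plus the counts
#' accumulated along each lineage path at the six tree ranks (phylum,
#' class, order, family, genus, species).
#'
#' @slot sampleId single sample identifier.
#' @slot assignments data.frame with columns fragment, subject, identity,
#'   lineage (raw lineage string, NA when unclassified), status
#'   ("classified" or "unclassified").
#' @slot counts data.frame with columns rank, path (semicolon-joined names
#'   from phylum down), name, count.
#' @slot totalClassified,totalUnclassified integer totals; their sum is the
#'   number of fragments.
#' @seealso [assignTaxonomy()], [classificationReport()],
#'   [buildConsensusTree()]
#' @exportClass SampleProfile
setClass("SampleProfile",
  representation(
    sampleId = "character",
    assignments = "data.frame",
    counts = "data.frame",
    totalClassified = "integer",
    totalUnclassified = "integer"
  )
)

setValidity("SampleProfile", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-empty string")
  if (nrow(object@assignments) !=
      object@totalClassified + object@totalUnclassified)
    msg <- c(msg, "totals must sum to the number of fragments")
  # at each rank, counts sum to the classified fragments whose lineage
  # reaches that rank -- so never more than totalClassified
  if (nrow(object@counts)) {
    bad <- vapply(split(object@counts$count, object@counts$rank), sum, 0) >
      object@totalClassified
    if (any(bad)) msg <- c(msg, "rank counts exceed classified total")
  }
  if (length(msg)) msg else TRUE
})

#' Consensus taxonomy tree across samples
#'
#' The union of all observed lineage paths, one ranked level per taxonomic
#' rank (phylum through species, at most six levels below the root; the
#' kingdom is collapsed into the root). Every node carries one count and
#' one normalized proportion per sample; proportions are counts divided by
#' that sample's total classified fragments.
#'
#' @slot nodes data.frame in depth-first order with columns id, parent
#'   (id, NA for root), rank, name, path, depth. Children of each node are
#'   ordered by descending pooled count, ties alphabetical.
#' @slot counts numeric matrix (nodes x samples).
#' @slot proportions numeric matrix (nodes x samples).
#' @slot samples character vector of sample ids (column order).
#' @slot totals named numeric total classified fragments per sample.
#' @seealso [buildConsensusTree()], [renderTreeNewick()], [renderTreeSVG()],
#'   [comparisonTable()]
#' @exportClass ConsensusTree
setClass("ConsensusTree",
  representation(
    nodes = "data.frame", counts = "matrix", proportions = "matrix",
    samples = "character", totals = "numeric"
  )
)

setValidity("ConsensusTree", function(object) {
  msg <- character()
  if (anyDuplicated(object@samples))
    msg <- c(msg, "sample ids must be unique")
  if (nrow(object@counts) != nrow(object@nodes) ||
      nrow(object@proportions) != nrow(object@nodes))
    msg <- c(msg, "one matrix row per node required")
  if (nrow(object@nodes) && max(object@nodes$depth) > 6L)
    msg <- c(msg, "tree depth must not exceed 6 ranked levels")
  if (length(msg)) msg else TRUE
})

#' Weighted-average speed-up summary
#'
#' Holds per-input (weight, speed-up) pairs and their weighted average,
#' weighting each input's speed-up by its sequence count (or 16S fragment
#' count), so large inputs dominate the summary.
#'
#' @slot weights nonnegative numeric weights (sequence or fragment counts).
#' @slot values positive speed-up ratios.
#' @slot weightedAverage the weighted mean of values.
#' @seealso [speedupSummary()], [weightedAverage()]
#' @exportClass SpeedupSummary
setClass("SpeedupSummary",
  representation(weights = "numeric", values = "numeric",
                 weightedAverage = "numeric")
)

setValidity("SpeedupSummary", function(object) {
  msg <- character()
  if (length(object@weights) < 1L ||
      length(object@weights) != length(object@values))
    msg <- c(msg, "need >= 1 (weight, value) pair of equal length")
  if (any(object@weights < 0) || sum(object@weights) <= 0)
    msg <- c(msg, "weights must be nonnegative with positive sum")
  if (any(object@values <= 0)) msg <- c(msg, "speed-ups must be positive")
  wa <- object@weightedAverage
  if (wa < min(object@values) - 1e-12 || wa > max(object@values) + 1e-12)
    msg <- c(msg, "weighted average must lie within [min, max] of values")
  if (length(msg)) msg else TRUE
})

#' Synthetic community specification
#'
#' Everything needed to simulate one metagenomic sample with known ground
#' truth: the reference taxa with their relative abundances, the read and
#' fragment geometry, the substitution rate, the fraction of reads carrying
#' a planted 16S fragment, the strand probability and the seed.
#'
#' @slot taxa data.frame with columns id, lineage, abundance (abundances
#'   sum to 1).
#' @slot references [Biostrings::DNAStringSet], one per taxon.
#' @slot nReads,readLength integer read geometry.
#' @slot fragLenRange integer length-2 planted fragment length range (nt).
#' @slot subRate per-base substitution probability in planted fragments.
#' @slot plantedFraction fraction of reads carrying a fragment.
#' @slot strandProb probability a planted fragment lies on the plus strand.
#' @slot seed integer random seed.
#' @seealso [communitySpec()], [generateSample()]
#' @exportClass CommunitySpec
setClass("CommunitySpec",
  representation(
    taxa = "data.frame", references = "DNAStringSet",
    nReads = "integer", readLength = "integer", fragLenRange = "integer",
    subRate = "numeric", plantedFraction = "numeric", strandProb = "numeric",
    seed = "integer"
  )
)

setValidity("CommunitySpec", function(object) {
  msg <- character()
  if (abs(sum(object@taxa$abundance) - 1) > 1e-9)
    msg <- c(msg, "abundances must sum to 1 within 1e-9")
  for (r in c(object@subRate, object@plantedFraction, object@strandProb))
    if (r < 0 || r > 1) msg <- c(msg, "rates must lie in [0, 1]")
  if (length(object@fragLenRange) != 2L ||
      object@fragLenRange[1] > object@fragLenRange[2])
    msg <- c(msg, "fragLenRange must be an ordered length-2 range")
  if (object@fragLenRange[2] > object@readLength)
    msg <- c(msg, "fragments must fit within a read")
  if (nrow(object@taxa) != length(object@references))
    msg <- c(msg, "one reference sequence per taxon required")
  if (length(msg)) msg else TRUE
})

#' Pipeline configuration
#'
#' Stage parameters for an end-to-end run. In "targeted16s" mode the input
#' reads are 16S amplicons and the extraction stage is skipped: reads are
#' used directly as fragments.
#'
#' @slot mode "shotgun" or "targeted16s".
#' @slot minScore Viterbi reporting threshold in bits.
#' @slot wordLength seed word length for the mapper.
#' @slot maxEvalue E-value cutoff for reported hits.
#' @slot minIdentity percent-identity floor for taxonomic assignment.
#' @slot threads chunk count used by the parallel contract.
#' @slot seed integer seed recorded in the run manifest.
#' @seealso [pipelineConfig()], [runPipeline()]
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(
    mode = "character", minScore = "numeric", wordLength = "integer",
    maxEvalue = "numeric", minIdentity = "numeric", threads = "integer",
    seed = "integer"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (!object@mode %in% c("shotgun", "targeted16s"))
    msg <- c(msg, "mode must be 'shotgun' or 'targeted16s'")
  if (object@threads < 1L) msg <- c(msg, "threads must be >= 1")
  if (!is.finite(object@minScore)) msg <- c(msg, "minScore must be finite")
  if (object@maxEvalue <= 0) msg <- c(msg, "maxEvalue must be positive")
  if (length(msg)) msg else TRUE
})
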