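## Synthetic fixture generator: reference databases, taxonomies and read
## sets with known ground truth, so every pipeline stage is testable
## without any download. All outputs are fully determined by the seed.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

.randSeq <- function(n, len) {
  chars <- sample(.DNA, n * len, replace = TRUE)
  if (n == 1L) return(paste(chars, collapse = ""))
  do.call(paste0, as.data.frame(matrix(chars, nrow = n),
                                stringsAsFactors = FALSE))
}

## substitute each position with probability rate, always to a different base
.mutate <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, nSub = 0L))
  chars <- strsplit(seq, "")[[1L]]
  hit <- runif(length(chars)) < rate
  for (i in which(hit))
    chars[i] <- sample(setdiff(.DNA, chars[i]), 1L)
  list(seq = paste(chars, collapse = ""), nSub = sum(hit))
}

#' Generate a synthetic 16S reference database
#'
#' `nTaxa` reference sequences evolved from one random ancestor along a
#' star topology, each position substituted with the taxon's divergence
#' probability (drawn uniformly from 2-15%). Each taxon gets a distinct
#' full lineage over a generated six-rank nomenclature (taxa share phyla
#' in groups of four and classes in groups of two, so the tree has real
#' internal structure). The sequences are equal-length and ungapped, so
#' the set doubles as the profile-HMM seed alignment.
#'
#' @param nTaxa number of reference taxa.
#' @param seqLength reference length in nt (default 400, a marker-region
#'   scale that keeps the model compact).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return list with `references` (named [Biostrings::DNAStringSet]),
#'   `taxonomy` (named character, Greengenes dialect), `seedAlignment`
#'   (the same set, usable directly by [buildProfileHMM()]), `divergences`
#'   and `ancestor`.
#' @export
generateReference <- function(nTaxa, seqLength = 400L, seed = 1L) {
  stopifnot(nTaxa >= 1L, seqLength >= 50L)
  .withSeed(seed, {
    ancestor <- .randSeq(1L, seqLength)
    divergences <- runif(nTaxa, 0.02, 0.15)
    seqs <- character(nTaxa)
    for (i in seq_len(nTaxa))
      seqs[i] <- .mutate(ancestor, divergences[i])$seq
    ids <- sprintf("ref%03d", seq_len(nTaxa))
    lineage <- vapply(seq_len(nTaxa), function(i) {
      sprintf(paste0("k__Bacteria; p__Phylum%02d; c__Class%02d; ",
                     "o__Order%02d; f__Family%02d; g__Genus%02d; s__sp%02d"),
              (i - 1L) %/% 4L + 1L, (i - 1L) %/% 2L + 1L, i, i, i, i)
    }, "")
    refs <- DNAStringSet(setNames(seqs, ids))
    list(references = refs, taxonomy = setNames(lineage, ids),
         seedAlignment = refs, divergences = setNames(divergences, ids),
         ancestor = ancestor)
  })
}

#' Specify a synthetic community
#'
#' @param reference output of [generateReference()] (or a list with
#'   `references` and `taxonomy`).
#' @param abundances per-taxon relative abundances summing to 1 (default
#'   uniform).
#' @param nReads total reads in the sample.
#' @param readLength read length in nt (default 100, short-read scale).
#' @param fragLenRange planted 16S fragment length range (nt).
#' @param subRate per-base substitution probability in planted fragments.
#' @param plantedFraction fraction of reads carrying a planted fragment.
#' @param strandProb probability a planted fragment is on the plus strand.
#' @param seed integer seed.
#' @return a [CommunitySpec-class].
#' @export
communitySpec <- function(reference, abundances = NULL, nReads = 4000L,
                          readLength = 100L, fragLenRange = c(60L, 100L),
                          subRate = 0.01, plantedFraction = 0.5,
                          strandProb = 0.5, seed = 1L) {
  refs <- reference$references
  tax <- reference$taxonomy
  n <- length(refs)
  if (is.null(abundances)) abundances <- rep(1 / n, n)
  taxa <- data.frame(id = names(refs), lineage = unname(tax[names(refs)]),
                     abundance = abundances, stringsAsFactors = FALSE)
  new("CommunitySpec", taxa = taxa, references = refs,
      nReads = as.integer(nReads), readLength = as.integer(readLength),
      fragLenRange = as.integer(fragLenRange), subRate = subRate,
      plantedFraction = plantedFraction, strandProb = strandProb,
      seed = as.integer(seed))
}

setMethod("show", "CommunitySpec", function(object) {
  cat("CommunitySpec:", nrow(object@taxa), "taxa,", object@nReads,
      "reads of", object@readLength, "nt, planted fraction",
      object@plantedFraction, "\n")
})

## deterministic largest-remainder allocation of n among proportions p
.allocateCounts <- function(p, n) {
  base <- floor(p * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- p * n - base
    extra <- order(-frac, seq_along(p))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate one metagenomic sample with known ground truth
#'
#' Reads are i.i.d. uniform background DNA; the planted fraction carries a
#' contiguous fragment of a reference 16S sequence (interval uniform
#' within the reference, strand by the strand probability, substitutions
#' at the stated rate). Planted read counts per taxon follow the
#' abundances by deterministic largest-remainder rounding, emulating a
#' mock community of defined composition. Everything is determined by the
#' spec's seed.
#'
#' @param spec a [CommunitySpec-class].
#' @return list with `reads` (named [Biostrings::DNAStringSet] with
#'   Phred+33 qualities in `mcols()$quality`) and `truth` (data.frame with
#'   one row per planted read: read, taxon, lineage, refStart/refEnd
#'   (0-based half-open), strand, readStart (0-based fragment offset in
#'   the read), fragLen, nSub).
#' @export
generateSample <- function(spec) {
  stopifnot(is(spec, "CommunitySpec"))
  .withSeed(spec@seed, {
    n <- spec@nReads
    rl <- spec@readLength
    nPlanted <- round(spec@plantedFraction * n)
    reads <- .randSeq(n, rl)
    truth <- NULL
    if (nPlanted > 0L) {
      plantedAt <- sort(sample(n, nPlanted))
      taxonOf <- sample(rep(seq_len(nrow(spec@taxa)),
                            .allocateCounts(spec@taxa$abundance, nPlanted)))
      refSeqs <- as.character(spec@references)
      rows <- vector("list", nPlanted)
      for (k in seq_len(nPlanted)) {
        t <- taxonOf[k]
        ref <- refSeqs[[t]]
        L <- sample(spec@fragLenRange[1L]:spec@fragLenRange[2L], 1L)
        s0 <- sample.int(nchar(ref) - L + 1L, 1L) - 1L
        mut <- .mutate(substr(ref, s0 + 1L, s0 + L), spec@subRate)
        plus <- runif(1L) < spec@strandProb
        insert <- if (plus) mut$seq else revComp(mut$seq)
        off <- sample.int(rl - L + 1L, 1L) - 1L
        read <- reads[plantedAt[k]]
        substr(read, off + 1L, off + L) <- insert
        reads[plantedAt[k]] <- read
        rows[[k]] <- data.frame(
          read = plantedAt[k], taxon = spec@taxa$id[t],
          lineage = spec@taxa$lineage[t], refStart = s0, refEnd = s0 + L,
          strand = if (plus) "+" else "-", readStart = off, fragLen = L,
          nSub = mut$nSub, stringsAsFactors = FALSE)
      }
      truth <- do.call(rbind, rows)
    }
    ids <- sprintf("read%05d", seq_len(n))
    out <- DNAStringSet(setNames(reads, ids))
    mcols(out)$description <- rep("", n)
    mcols(out)$quality <- rep(strrep("I", rl), n)
    if (is.null(truth))
      truth <- data.frame(read = character(0), taxon = character(0),
                          lineage = character(0), refStart = integer(0),
                          refEnd = integer(0), strand = character(0),
                          readStart = integer(0), fragLen = integer(0),
                          nSub = integer(0), stringsAsFactors = FALSE)
    else truth$read <- ids[truth$read]
    list(reads = out, truth = truth)
  })
}

#' Recall of planted fragments from scan hits
#'
#' A planted fragment counts as recovered when its read has a hit on the
#' same strand whose interval overlaps the planted interval by at least
#' `minOverlap` of the planted length. Minus-strand hit intervals (which
#' refer to the reverse-complemented read) are converted back to read
#' coordinates before comparison.
#'
#' @param hits data.frame from [scanReads()].
#' @param truth truth table from [generateSample()].
#' @param readLength read length used to convert minus-strand intervals.
#' @param minOverlap minimum overlap fraction of the planted length.
#' @return recall in [0, 1]; NA when the truth table is empty.
#' @export
plantedRecall <- function(hits, truth, readLength, minOverlap = 0.5) {
  if (nrow(truth) == 0L) return(NA_real_)
  hit <- hits[match(truth$read, hits$read), , drop = FALSE]
  found <- !is.na(hit$read) & hit$strand == truth$strand
  hs <- ifelse(hit$strand == "-", readLength - hit$readEnd, hit$readStart)
  he <- ifelse(hit$strand == "-", readLength - hit$readStart, hit$readEnd)
  ov <- pmax(0, pmin(he, truth$readStart + truth$fragLen) -
                pmax(hs, truth$readStart))
  mean(found & ov >= minOverlap * truth$fragLen, na.rm = FALSE)
}
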