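# Shared fixtures and independent oracles. Everything is generated in code;
# the oracles are deliberately naive so they stay independent of the
# implementation paths they check.

DNA4 <- c("A", "C", "G", "T")

randSeq <- function(n) paste(sample(DNA4, n, replace = TRUE), collapse = "")

mutateSeq <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- runif(length(ch)) < rate
  for (i in which(hit)) ch[i] <- sample(setdiff(DNA4, ch[i]), 1)
  paste(ch, collapse = "")
}

# random valid profile HMM with Dirichlet emissions and transitions
randomHMM <- function(M) {
  dirich <- function(n) { g <- rgamma(n, 1) + 1e-6; g / sum(g) }
  me <- t(replicate(M, dirich(4)))
  ie <- if (M > 1) t(replicate(M - 1, dirich(4))) else
    matrix(numeric(0), 0, 4)
  tr <- if (M > 1)
    t(replicate(M - 1, c(dirich(3), dirich(3), dirich(3)))) else
    matrix(numeric(0), 0, 9)
  colnames(me) <- c("A", "C", "G", "T")
  if (nrow(ie)) colnames(ie) <- c("A", "C", "G", "T")
  if (M > 1)
    colnames(tr) <- c("MM", "MI", "MD", "IM", "II", "ID", "DM", "DI", "DD")
  new("ProfileHMM", name = "rnd", matchEmissions = log2(me / 0.25),
      insertEmissions = log2(ie / 0.25), transitions = log2(tr))
}

# brute-force Viterbi oracle: enumerate every state path with free entry
# into any match state, free exit after any match state
bruteViterbi <- function(hmm, seq) {
  M <- nrow(hmm@matchEmissions)
  L <- nchar(seq)
  code <- match(strsplit(seq, "")[[1]], DNA4)
  emM <- function(j, i) if (is.na(code[i])) 0 else
    hmm@matchEmissions[j, code[i]]
  emI <- function(j, i) if (is.na(code[i])) 0 else
    hmm@insertEmissions[j, code[i]]
  tr <- hmm@transitions
  best <- -Inf
  recur <- function(type, i, j, sc) {
    if (type == "M" && sc > best) best <<- sc
    if (j > M - 1) return(invisible())
    if (i < L) {
      recur("M", i + 1, j + 1,
            sc + tr[j, switch(type, M = "MM", I = "IM", D = "DM")] +
              emM(j + 1, i + 1))
      recur("I", i + 1, j,
            sc + tr[j, switch(type, M = "MI", I = "II", D = "DI")] +
              emI(j, i + 1))
    }
    recur("D", i, j + 1,
          sc + tr[j, switch(type, M = "MD", I = "ID", D = "DD")])
  }
  for (i0 in seq_len(L)) for (j0 in seq_len(M))
    recur("M", i0, j0, emM(j0, i0))
  unname(best)
}

# +1/-2 substitution matrix matching the default scoring scheme, for the
# exhaustive local-alignment oracle (Biostrings::pairwiseAlignment)
swSubMat <- local({
  m <- matrix(-2L, 4, 4, dimnames = list(DNA4, DNA4))
  diag(m) <- 1L
  m
})

# exhaustive local-alignment optimum under the default scheme
swOptimum <- function(q, r)
  Biostrings::pairwiseAlignment(Biostrings::DNAString(q),
                                Biostrings::DNAString(r), type = "local",
                                substitutionMatrix = swSubMat,
                                gapOpening = 5, gapExtension = 2,
                                scoreOnly = TRUE)

# recover the raw alignment score from a reported bit score
rawScore <- function(bitscore, scheme)
  (bitscore * log(2) + log(scheme@K)) / scheme@lambda

# a query/reference pair sharing one planted, mutated segment
seededPair <- function(qlen, rlen, shared, rate = 0.05) {
  core <- randSeq(shared)
  q <- randSeq(qlen)
  r <- randSeq(rlen)
  qpos <- sample(qlen - shared + 1, 1)
  rpos <- sample(rlen - shared + 1, 1)
  substr(q, qpos, qpos + shared - 1) <- mutateSeq(core, rate)
  substr(r, rpos, rpos + shared - 1) <- mutateSeq(core, rate)
  list(q = q, r = r)
}

# SampleProfile built from hand-constructed lineage strings (one fragment
# per entry), bypassing alignment: drive classify/compare tests directly
profileFromLineages <- function(sampleId, lineages, nUnclassified = 0L) {
  n <- length(lineages) + nUnclassified
  frags <- sprintf("%s_frag%03d", sampleId, seq_len(n))
  tax <- setNames(lineages, sprintf("%s_ref%03d", sampleId,
                                    seq_along(lineages)))
  hits <- emptyHits()
  if (length(lineages)) {
    hits <- data.frame(
      qseqid = frags[seq_along(lineages)], sseqid = names(tax),
      pident = 100, length = 100L, mismatch = 0L, gapopen = 0L,
      qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
      evalue = 1e-30, bitscore = 180, stringsAsFactors = FALSE)
  }
  assignTaxonomy(frags, hits, tax, sampleId = sampleId)
}

# abundances used for the recovery experiments (uneven on purpose, so a
# uniform-profile bug cannot sneak through)
RECOVERY_ABUNDANCES <- c(0.35, 0.25, 0.20, 0.12, 0.08)

# genus-level abundance L1 distance between a profile and the generating
# proportions, recomputed from the raw assignment table (independent of
# rankCounts)
genusL1 <- function(profile, spec) {
  asn <- assignments(profile)
  lin <- asn$lineage[asn$status == "classified"]
  genus <- vapply(lin, function(x) parseLineage(x)[["genus"]], "",
                  USE.NAMES = FALSE)
  est <- table(factor(genus,
                      levels = vapply(spec@taxa$lineage, function(x)
                        parseLineage(x)[["genus"]], "", USE.NAMES = FALSE)))
  est <- as.numeric(est) / sum(est)
  sum(abs(est - spec@taxa$abundance))
}
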