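test_that("decomposition produces balanced contiguous chunks", {
  # the thread-count worked example: 240 equal queries over 24 chunks
  plan <- chunkPlan(rep(100L, 240), 24)
  expect_identical(nChunks(plan), 24L)
  expect_true(all(lengths(plan@chunks) == 10L))
  # fewer queries than chunks: one chunk per query
  expect_identical(nChunks(chunkPlan(rep(50L, 5), 24)), 5L)
  # single chunk is the identity
  expect_identical(chunkPlan(rep(1L, 7), 1)@chunks[[1]], 1:7)
  expect_identical(nChunks(chunkPlan(integer(0), 4)), 0L)
})

test_that("chunks partition the queries and stay balanced on even input", {
  set.seed(51)
  for (k in 1:20) {
    n <- sample(1:200, 1)
    lens <- sample(80:120, n, TRUE)          # near-equal residue loads
    nc <- sample(1:12, 1)
    plan <- chunkPlan(lens, nc)
    expect_identical(unlist(plan@chunks), seq_len(n))  # order restored
    if (nChunks(plan) > 1 && n >= 4 * nc)
      expect_lte(max(plan@loads), 2 * min(plan@loads))
  }
})

test_that("Karlin-Altschul solver satisfies the characteristic equation", {
  for (sc in list(c(1, -2), c(1, -3), c(2, -3))) {
    ka <- karlinAltschul(sc[1], sc[2])
    p <- c(0.25, 0.75)
    expect_equal(sum(p * exp(ka$lambda * c(sc[1], sc[2]))), 1,
                 tolerance = 1e-9)
    expect_gt(ka$K, 0)
    expect_gt(ka$H, 0)
  }
  # the standard ungapped nucleotide values for +1/-2
  ka <- karlinAltschul(1, -2)
  expect_equal(ka$lambda, 1.33, tolerance = 0.01)
  expect_equal(ka$K, 0.621, tolerance = 0.01)
})

test_that("reference index records every word at its position", {
  set.seed(52)
  refs <- Biostrings::DNAStringSet(c(a = randSeq(60), b = "CCNCCCCACGTACGTACGTACGTAAA"))
  idx <- buildReferenceIndex(refs, w = 8)
  tab <- idx@kmerTable
  expect_false(any(grepl("N", tab$kmer)))
  seqs <- as.character(refs)
  ok <- mapply(function(k, r, o) substr(seqs[[r]], o + 1, o + 8) == k,
               tab$kmer, tab$ref, tab$offset)
  expect_true(all(ok))
})

test_that("an exact substring aligns at identity 100 with exact coordinates", {
  set.seed(53)
  r <- randSeq(400)
  idx <- buildReferenceIndex(Biostrings::DNAStringSet(c(refA = r)), 16)
  sch <- scoringScheme()
  h <- alignToReference(Biostrings::DNAStringSet(c(q = substr(r, 101, 200))),
                        idx, sch)
  expect_identical(nrow(h), 1L)
  expect_equal(h$pident, 100)
  expect_identical(h$length, 100L)
  expect_identical(h$mismatch, 0L)
  expect_identical(h$gapopen, 0L)
  expect_identical(c(h$sstart, h$send), c(101L, 200L))
  # minus strand: descending subject coordinates, ascending query coordinates
  h2 <- alignToReference(
    Biostrings::DNAStringSet(c(q = unname(revComp(substr(r, 101, 200))))),
    idx, sch)
  expect_identical(c(h2$qstart, h2$qend), c(1L, 100L))
  expect_true(h2$sstart > h2$send)
  expect_identical(c(h2$sstart, h2$send), c(200L, 101L))
})

test_that("queries sharing no word with the database yield no hits", {
  idx <- buildReferenceIndex(
    Biostrings::DNAStringSet(c(refA = strrep("C", 100))), 16)
  # all-A shares no 16-mer with an all-C reference on either strand
  # (its reverse complement is all-T)
  h <- alignToReference(Biostrings::DNAStringSet(c(q = strrep("A", 50))),
                        idx, scoringScheme())
  expect_identical(nrow(h), 0L)
  # and a query shorter than the word length can never seed
  h <- alignToReference(Biostrings::DNAStringSet(c(q = "ACGTACGT")),
                        idx, scoringScheme())
  expect_identical(nrow(h), 0L)
})

test_that("banded scores never exceed the exhaustive local optimum", {
  set.seed(54)
  sch <- scoringScheme()
  n <- 0; eq <- 0
  for (k in 1:60) {
    pr <- seededPair(sample(60:300, 1), sample(80:300, 1), sample(40:60, 1))
    idx <- buildReferenceIndex(Biostrings::DNAStringSet(c(r = pr$r)), 16)
    h <- alignToReference(Biostrings::DNAStringSet(c(q = pr$q)), idx, sch,
                          maxEvalue = Inf)
    h <- h[h$sstart <= h$send, , drop = FALSE]
    if (nrow(h) == 0) next
    n <- n + 1
    raw <- rawScore(h$bitscore[1], sch)
    opt <- swOptimum(pr$q, pr$r)
    expect_lte(raw, opt + 1e-6)
    if (abs(raw - opt) < 1e-6) eq <- eq + 1
  }
  expect_gte(n, 40)
  expect_gte(eq / n, 0.9)
})

test_that("chunked mapping is identical to serial for any chunking", {
  set.seed(55)
  ref <- generateReference(4, 300, seed = 13)
  idx <- buildReferenceIndex(ref$references, 16)
  sch <- scoringScheme()
  frags <- Biostrings::DNAStringSet(vapply(1:50, function(i) {
    t <- sample(4, 1)
    s <- as.character(ref$references[[t]])
    a <- sample(200, 1)
    mutateSeq(substr(s, a, a + sample(60:100, 1)), 0.02)
  }, ""))
  names(frags) <- sprintf("f%02d", 1:50)
  serial <- parallelMap(frags, idx, sch, nChunks = 1)
  for (nc in c(2, 6, 8)) {
    expect_identical(parallelMap(frags, idx, sch, nChunks = nc), serial)
  }
  # shuffled chunk completion order leaves the merged result unchanged
  shuffled <- parallelMap(frags, idx, sch, nChunks = 6,
                          .chunkOrder = c(4L, 1L, 6L, 3L, 5L, 2L))
  expect_identical(shuffled, serial)
  # byte-level check through the serializer
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  writeTabularHits(serial, p1)
  writeTabularHits(parallelMap(frags, idx, sch, nChunks = 8), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("E-values fall with score and scale with database size", {
  set.seed(56)
  r <- randSeq(300)
  sch <- scoringScheme()
  q <- substr(r, 51, 150)
  idx1 <- buildReferenceIndex(Biostrings::DNAStringSet(c(a = r)), 16)
  # second, unrelated reference doubles the database size without adding
  # seeds for this query
  idx2 <- buildReferenceIndex(
    Biostrings::DNAStringSet(c(a = r, b = strrep("C", 300))), 16)
  h1 <- alignToReference(Biostrings::DNAStringSet(c(q = q)), idx1, sch)
  h2 <- alignToReference(Biostrings::DNAStringSet(c(q = q)), idx2, sch)
  expect_equal(h2$evalue[1] / h1$evalue[1], 2, tolerance = 1e-9)
  # shorter (lower-scoring) prefix of the same query has larger E-value
  hshort <- alignToReference(
    Biostrings::DNAStringSet(c(q = substr(q, 1, 50))), idx1, sch)
  expect_gt(hshort$evalue[1], h1$evalue[1])
  expect_lt(hshort$bitscore[1], h1$bitscore[1])
})

test_that("best hit prefers bit score, then E-value, then subject id", {
  h <- data.frame(qseqid = "q", sseqid = c("gg010", "gg002", "gg007"),
                  pident = 99, length = 100L, mismatch = 1L, gapopen = 0L,
                  qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
                  evalue = c(1e-20, 1e-20, 1e-10),
                  bitscore = c(100, 100, 90), stringsAsFactors = FALSE)
  expect_identical(bestHit(h)$sseqid, "gg002")
  expect_identical(bestHit(h[3, ])$sseqid, "gg007")
  expect_null(bestHit(emptyHits()))
})

test_that("a query equal to a reference is its own best hit", {
  ref <- generateReference(6, 300, seed = 17)
  idx <- buildReferenceIndex(ref$references, 16)
  sch <- scoringScheme()
  for (t in c(1, 4, 6)) {
    q <- ref$references[t]
    names(q) <- "self"
    bh <- bestHit(alignToReference(q, idx, sch))
    expect_identical(bh$sseqid, names(ref$references)[t])
    expect_equal(bh$pident, 100)
  }
})
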