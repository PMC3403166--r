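# fixtures shared by the scan tests
.extractFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref <- generateReference(5, 400, seed = 11)
      cache <<- list(ref = ref, hmm = buildProfileHMM(ref$seedAlignment))
    }
    cache
  }
})

test_that("scan output is identical for every chunk count", {
  fx <- .extractFixture()
  spec <- communitySpec(fx$ref, nReads = 100, seed = 21)
  reads <- generateSample(spec)$reads
  h1 <- scanReads(reads, fx$hmm, chunks = 1)
  h7 <- scanReads(reads, fx$hmm, chunks = 7)
  expect_identical(h1, h7)
  expect_identical(scanReads(reads, fx$hmm, chunks = 100), h1)
})

test_that("a planted consensus copy is found on the plus strand", {
  fx <- .extractFixture()
  refseq <- as.character(fx$ref$references[[2]])
  read <- paste0(strrep("T", 10), substr(refseq, 101, 180), strrep("T", 10))
  reads <- Biostrings::DNAStringSet(c(r1 = read))
  h <- scanReads(reads, fx$hmm)
  expect_identical(nrow(h), 1L)
  expect_identical(h$strand, "+")
  # hit covers the planted interval [10, 90)
  expect_lt(abs(h$readStart - 10), 4)
  expect_lt(abs(h$readEnd - 90), 4)
})

test_that("strand symmetry: reverse-complemented reads score identically", {
  fx <- .extractFixture()
  spec <- communitySpec(fx$ref, nReads = 30, strandProb = 1, seed = 31)
  smp <- generateSample(spec)
  fwd <- scanReads(smp$reads, fx$hmm)
  rc <- Biostrings::DNAStringSet(revComp(as.character(smp$reads)))
  names(rc) <- names(smp$reads)
  rev <- scanReads(rc, fx$hmm)
  common <- intersect(fwd$read, rev$read)
  expect_identical(common, fwd$read)
  expect_equal(fwd$score, rev$score[match(fwd$read, rev$read)])
  expect_true(all(fwd$strand == "+" & rev$strand[match(fwd$read, rev$read)]
                  == "-"))
})

test_that("fragments are sliced on the reported strand with sense orientation", {
  reads <- Biostrings::DNAStringSet(c(r1 = "TTACGTACGT"))
  hits <- data.frame(read = "r1", strand = "+", readStart = 2L,
                     readEnd = 8L, modelStart = 1L, modelEnd = 6L,
                     score = 30, stringsAsFactors = FALSE)
  frag <- extractFragments(reads, hits)
  expect_identical(as.character(frag)[[1]], "ACGTAC")
  expect_identical(names(frag), "r1|+|2-8")
  # minus-strand interval refers to the reverse complement of the read
  hits$strand <- "-"
  frag <- extractFragments(reads, hits)
  expect_identical(as.character(frag)[[1]],
                   substr(unname(revComp("TTACGTACGT")), 3, 8))
  hits$readEnd <- 99L
  expect_error(extractFragments(reads, hits), "outside read bounds")
  hits$read <- "nope"
  expect_error(extractFragments(reads, hits), "unknown read")
})

test_that("length distribution counts and summarizes fragments", {
  d <- lengthDistribution(c(90L, 90L, 100L))
  expect_identical(d@histogram, c(`90` = 2L, `100` = 1L))
  expect_equal(d@mean, 93.33, tolerance = 1e-3)
  expect_identical(d@n, 3L)
  empty <- lengthDistribution(Biostrings::DNAStringSet())
  expect_identical(empty@n, 0L)
  expect_true(is.na(empty@mean))
  p <- withr::local_tempfile()
  writeLengthDistribution(d, p)
  tab <- read.delim(paste0(p, ".lengths.tsv"))
  expect_identical(sum(tab$count), 3L)
})

test_that("planted fragments are recalled and background reads stay silent", {
  fx <- .extractFixture()
  spec <- communitySpec(fx$ref, nReads = 400, subRate = 0.05, seed = 41)
  smp <- generateSample(spec)
  h <- scanReads(smp$reads, fx$hmm)
  expect_gte(plantedRecall(h, smp$truth, spec@readLength), 0.95)
  expect_length(setdiff(h$read, smp$truth$read), 0)
})
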