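test_that("reverse complement is correct, involutive and strict", {
  expect_identical(unname(revComp("ACGT")), "ACGT")  # palindromic
  expect_identical(unname(revComp("AAAC")), "GTTT")
  expect_identical(unname(revComp("ANNGT")), "ACNNT")
  set.seed(1)
  for (k in 1:20) {
    s <- randSeq(sample(1:60, 1))
    expect_identical(unname(revComp(revComp(s))), s)
  }
  expect_error(revComp("ACXGT"), "non-IUPAC")
})

test_that("HMM builder gives pseudocounted ML emissions and prior transitions", {
  hmm <- buildProfileHMM(c("AC", "AC", "AG"), name = "toy")
  # column 1: A seen 3 times of 3 -> (3+1)/(3+4) = 4/7
  expect_equal(unname(hmm@matchEmissions[1, "A"]), log2((4 / 7) / 0.25))
  # column 2: C twice, G once -> C (2+1)/7, G (1+1)/7
  expect_equal(unname(hmm@matchEmissions[2, "C"]), log2((3 / 7) / 0.25))
  expect_equal(unname(hmm@matchEmissions[2, "G"]), log2((2 / 7) / 0.25))
  expect_equal(unname(2^hmm@transitions[1, c("MM", "MI", "MD")]),
               c(0.9, 0.05, 0.05))
  # underlying probabilities sum to 1 in every state
  expect_true(all(abs(rowSums(2^hmm@matchEmissions * 0.25) - 1) < 1e-9))
  expect_error(buildProfileHMM(c("AC", "ACG")), "equal length")
})

test_that("profile HMM text format round-trips", {
  set.seed(2)
  hmm <- randomHMM(7)
  p <- withr::local_tempfile(fileext = ".phmm")
  writeProfileHMM(hmm, p)
  back <- readProfileHMM(p)
  expect_equal(back@matchEmissions, hmm@matchEmissions, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back@insertEmissions, hmm@insertEmissions, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back@transitions, hmm@transitions, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(readProfileHMM(withr::local_tempfile(lines = "junk")),
               "PHMM1")
})

test_that("viterbi scores forced single-state alignments exactly", {
  # one match state emitting A with probability 1: log2(1/0.25) = 2 bits
  me <- matrix(log2(c(1, 0, 0, 0) / 0.25), 1, 4,
               dimnames = list(NULL, c("A", "C", "G", "T")))
  hmm <- new("ProfileHMM", name = "a1", matchEmissions = me,
             insertEmissions = matrix(numeric(0), 0, 4),
             transitions = matrix(numeric(0), 0, 9))
  expect_equal(viterbi(hmm, "A")$score, 2)
  expect_equal(viterbi(hmm, "TTATT")$score, 2)  # free flanking
})

test_that("ambiguity codes emit at background: all-N reads score zero", {
  set.seed(3)
  hmm <- randomHMM(4)
  v <- viterbi(hmm, "NNNNNN")
  # transitions are log-probabilities (negative), so the best path uses a
  # single match state with zero emission contribution
  expect_equal(v$score, 0)
  expect_identical(v$path$state, "M")
})

test_that("viterbi equals brute-force path enumeration on random instances", {
  set.seed(4)
  for (k in 1:60) {
    hmm <- randomHMM(sample(1:5, 1))
    s <- paste(sample(c(DNA4, "N"), sample(1:8, 1), TRUE,
                      prob = c(rep(0.24, 4), 0.04)), collapse = "")
    expect_equal(viterbi(hmm, s)$score, bruteViterbi(hmm, s),
                 tolerance = 1e-9)
  }
})

test_that("viterbi traceback covers a consistent read/model interval", {
  set.seed(5)
  ref <- generateReference(3, 120, seed = 8)
  hmm <- buildProfileHMM(ref$seedAlignment)
  read <- paste0(randSeq(15), substr(as.character(ref$references[[1]]), 21, 90),
                 randSeq(15))
  v <- viterbi(hmm, read)
  expect_gt(v$score, 25)
  expect_lte(v$readEnd, nchar(read))
  expect_gte(v$readStart, 0)
  expect_true(v$modelStart >= 1 && v$modelEnd <= hmmLength(hmm))
  # planted interval recovered up to boundary wobble at diverged columns
  expect_lt(abs(v$readStart - 15), 10)
  expect_lt(abs(v$readEnd - 85), 10)
})
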