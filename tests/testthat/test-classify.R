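test_that("lineage parsing handles full, partial and gapped paths", {
  full <- parseLineage(paste0("k__Bacteria; p__Firmicutes; c__Bacilli; ",
                              "o__Lactobacillales; f__Streptococcaceae; ",
                              "g__Streptococcus; s__mutans"))
  expect_identical(as.character(full),
                   c("Bacteria", "Firmicutes", "Bacilli", "Lactobacillales",
                     "Streptococcaceae", "Streptococcus", "mutans"))
  part <- parseLineage("k__Bacteria; p__Firmicutes")
  expect_identical(unname(part[1:2]), c("Bacteria", "Firmicutes"))
  expect_true(all(is.na(part[3:7])))
  # an empty rank truncates everything below it (prefix-first invariant)
  gap <- parseLineage("k__Bacteria; p__; c__Bacilli")
  expect_identical(unname(gap[1]), "Bacteria")
  expect_true(all(is.na(gap[2:7])))
  expect_error(parseLineage("x__Foo"), "unparseable")
  expect_error(parseLineage("a;b;c;d;e;f;g;h"), "more than 7")
})

test_that("fragments inherit their best hit's lineage above the identity floor", {
  tax <- c(refG = paste0("k__Bacteria; p__P1; c__C1; o__O1; f__F1; ",
                         "g__G1; s__S1"),
           refW = "k__Bacteria; p__P2")
  frags <- sprintf("f%02d", 1:12)
  hits <- data.frame(
    qseqid = c(frags[1:10], "f11"), sseqid = c(rep("refG", 10), "refW"),
    pident = c(rep(99, 10), 80), length = 100L, mismatch = 1L,
    gapopen = 0L, qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
    evalue = 1e-30, bitscore = 150, stringsAsFactors = FALSE)
  prof <- assignTaxonomy(frags, hits, tax, minIdentity = 90)
  expect_identical(totalClassified(prof), 10L)
  expect_identical(totalUnclassified(prof), 2L)  # f11 below floor, f12 no hit
  ct <- rankCounts(prof)
  expect_identical(ct$count[ct$rank == "genus"], 10L)
  expect_identical(ct$name[ct$rank == "genus"], "G1")
  asn <- assignments(prof)
  expect_identical(asn$status[asn$fragment == "f11"], "unclassified")
  expect_identical(asn$status[asn$fragment == "f12"], "unclassified")
})

test_that("a best hit missing from the taxonomy warns and stays unclassified", {
  hits <- data.frame(qseqid = "f1", sseqid = "ghost", pident = 99,
                     length = 100L, mismatch = 0L, gapopen = 0L,
                     qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
                     evalue = 1e-30, bitscore = 150,
                     stringsAsFactors = FALSE)
  expect_warning(prof <- assignTaxonomy("f1", hits, c(other = "k__B")),
                 "ghost")
  expect_identical(totalUnclassified(prof), 1L)
})

test_that("counts are conserved and refined across ranks", {
  set.seed(61)
  # lineages of mixed resolution: some stop at phylum/class/family
  depths <- sample(2:7, 60, TRUE)
  lins <- vapply(depths, function(d) {
    parts <- c("k__Bacteria", sprintf("%s__%s%d",
                                      c("p", "c", "o", "f", "g", "s"),
                                      c("P", "C", "O", "F", "G", "S"),
                                      rep(sample(3, 1), 6)))
    paste(parts[1:d], collapse = "; ")
  }, "")
  prof <- profileFromLineages("mix", lins, nUnclassified = 5L)
  total <- totalClassified(prof) + totalUnclassified(prof)
  expect_identical(total, 65L)
  ct <- rankCounts(prof)
  ranks <- c("phylum", "class", "order", "family", "genus", "species")
  for (ri in seq_along(ranks)) {
    atRank <- sum(ct$count[ct$rank == ranks[ri]])
    # conservation: counts at a rank + lineages terminating above it +
    # unclassified == all fragments
    terminating <- sum(depths < ri + 1)
    expect_identical(atRank + terminating + totalUnclassified(prof), total)
  }
  # refinement: every parent count >= sum of its children
  for (ri in 1:5) {
    child <- ct[ct$rank == ranks[ri + 1], ]
    if (nrow(child) == 0) next
    parentPath <- sub(";[^;]*$", "", child$path)
    sums <- tapply(child$count, parentPath, sum)
    parent <- ct[ct$rank == ranks[ri], ]
    expect_true(all(sums <= parent$count[match(names(sums), parent$path)]))
  }
})

test_that("the classification report separates unclassified and sums to 100%", {
  lins <- rep(paste0("k__B; p__P1; c__C1; o__O1; f__F1; g__G1; s__S1"), 63)
  lins <- c(lins, rep("k__B; p__P2; c__C2; o__O2; f__F2; g__G2; s__S2", 27))
  prof <- profileFromLineages("rep", lins, nUnclassified = 10L)
  rep <- classificationReport(prof)
  expect_true(any(grepl("10.0% of all fragments", rep$summary, fixed = TRUE)))
  for (rank in names(rep$tables)) {
    tab <- rep$tables[[rank]]
    expect_equal(sum(tab$percent), 100, tolerance = 0.01)
  }
  expect_equal(rep$tables$phylum$percent, c(70, 30))
  # empty profile still yields a valid report
  empty <- assignTaxonomy(character(0), emptyHits(), c(r = "k__B"))
  expect_identical(nrow(classificationReport(empty)$tables$genus), 0L)
})
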