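.chainLineage <- function(tag)
  sprintf("k__Bacteria; p__P%s; c__C%s; o__O%s; f__F%s; g__G%s; s__S%s",
          tag, tag, tag, tag, tag, tag)

test_that("a single fully-resolved sample gives one unit-proportion chain", {
  prof <- profileFromLineages("s1", rep(.chainLineage("A"), 20))
  tree <- buildConsensusTree(list(prof))
  nodes <- treeNodes(tree)
  expect_identical(nrow(nodes), 7L)             # root + 6 ranked levels
  expect_identical(max(nodes$depth), 6L)
  expect_true(all(treeProportions(tree)[, "s1"] == 1))
  expect_true(all(treeCounts(tree)[, "s1"] == 20))
})

test_that("samples with disjoint phyla occupy disjoint unit branches", {
  p1 <- profileFromLineages("s1", rep(.chainLineage("A"), 10))
  p2 <- profileFromLineages("s2", rep(.chainLineage("B"), 30))
  tree <- buildConsensusTree(list(p1, p2))
  nodes <- treeNodes(tree)
  phyla <- nodes[nodes$rank == "phylum", ]
  expect_identical(nrow(phyla), 2L)
  expect_identical(sort(phyla$name), c("PA", "PB"))
  pr <- treeProportions(tree)
  iA <- which(nodes$name == "PA"); iB <- which(nodes$name == "PB")
  expect_equal(unname(pr[iA, ]), c(1, 0))
  expect_equal(unname(pr[iB, ]), c(0, 1))
  # children ordered by pooled count: PB (30) before PA (10)
  expect_lt(iB, iA)
  expect_error(buildConsensusTree(list(p1, p1)), "duplicate")
})

# independent path reconstruction: semicolon-joined prefixes per depth
.parseLineagesOracle <- function(lins) {
  t(vapply(lins, function(l) {
    parts <- sub("^[a-z]__", "", trimws(strsplit(l, ";")[[1]]))[-1]
    vapply(1:6, function(d) paste(parts[1:d], collapse = ";"), "")
  }, character(6), USE.NAMES = FALSE))
}

test_that("node proportions equal independently recomputed count ratios", {
  set.seed(71)
  profs <- lapply(sprintf("smp%d", 1:4), function(sid) {
    tags <- sample(c("A", "B", "C"), sample(30:60, 1), TRUE,
                   prob = c(0.5, 0.3, 0.2))
    profileFromLineages(sid, vapply(tags, .chainLineage, ""))
  })
  tree <- buildConsensusTree(profs)
  nodes <- treeNodes(tree)
  pr <- treeProportions(tree)
  # oracle: recompute every node proportion from the raw assignment tables
  for (si in 1:4) {
    asn <- assignments(profs[[si]])
    lin <- .parseLineagesOracle(asn$lineage[asn$status == "classified"])
    for (ni in seq_len(nrow(nodes))[-1]) {
      want <- mean(lin[, nodes$depth[ni]] == nodes$path[ni])
      expect_equal(unname(pr[ni, si]), want, tolerance = 1e-12)
    }
  }
  # order of input profiles does not change the tree
  tree2 <- buildConsensusTree(rev(profs))
  expect_identical(treeNodes(tree2)$path, nodes$path)
  expect_equal(treeProportions(tree2)[, sampleNames(tree)],
               pr, ignore_attr = TRUE)
})

test_that("tree depth never exceeds the six ranked levels", {
  set.seed(72)
  for (k in 1:5) {
    depths <- sample(2:7, 40, TRUE)
    lins <- vapply(depths, function(d) {
      full <- strsplit(.chainLineage(sample(LETTERS[1:4], 1)), "; ")[[1]]
      paste(full[1:d], collapse = "; ")
    }, "")
    tree <- buildConsensusTree(list(profileFromLineages("x", lins)))
    expect_lte(max(treeNodes(tree)$depth), 6L)
  }
})

test_that("newick output is well-formed and readable by a standard parser", {
  p1 <- profileFromLineages("s1", rep(.chainLineage("A"), 10))
  p2 <- profileFromLineages("s2", rep(.chainLineage("B"), 30))
  tree <- buildConsensusTree(list(p1, p2))
  nwk <- renderTreeNewick(tree)
  expect_match(nwk, "^\\(.*\\)root;$")
  phy <- ape::read.tree(text = nwk)
  expect_identical(sort(phy$tip.label), c("SA", "SB"))
  expect_identical(phy$Nnode, 11L)  # root + 2x5 internal rank nodes
  # annotated form carries per-sample proportions as comments
  expect_match(renderTreeNewick(tree, annotations = TRUE),
               "[&p={", fixed = TRUE)
})

test_that("the SVG draws one group per node with one bar per sample", {
  profs <- list(profileFromLineages("s1", rep(.chainLineage("A"), 5)),
                profileFromLineages("s2", rep(.chainLineage("A"), 9)),
                profileFromLineages("s3", rep(.chainLineage("A"), 2)))
  tree <- buildConsensusTree(profs)
  svg <- renderTreeSVG(tree)
  doc <- xml2::read_xml(svg)
  groups <- xml2::xml_find_all(doc, "//*[@class='node']")
  expect_length(groups, 7L)  # root + single six-rank path
  rankGroups <- groups[xml2::xml_attr(groups, "data-rank") != "root"]
  expect_length(rankGroups, 6L)
  for (g in rankGroups)
    expect_length(xml2::xml_find_all(g, ".//*[@class='bar']"), 3L)
})

test_that("comparison table children re-aggregate exactly to their parents", {
  set.seed(73)
  profs <- lapply(c("u", "v"), function(sid) {
    tags <- sample(c("A", "B", "C", "D"), 50, TRUE)
    profileFromLineages(sid, vapply(tags, .chainLineage, ""))
  })
  tree <- buildConsensusTree(profs)
  tab <- comparisonTable(tree)
  ranks <- c("phylum", "class", "order", "family", "genus", "species")
  for (ri in 1:5) {
    parents <- tab[tab$rank == ranks[ri], ]
    children <- tab[tab$rank == ranks[ri + 1], ]
    agg <- rowsum(children[, c("u", "v")],
                  sub(";[^;]*$", "", children$path))
    for (p in parents$path) {
      expect_equal(unlist(agg[p, ]),
                   unlist(parents[parents$path == p, c("u", "v")]),
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
  # phylum proportions sum to 1 per sample (all lineages fully resolved)
  phy <- tab[tab$rank == "phylum", ]
  expect_equal(colSums(phy[, c("u", "v")]), c(u = 1, v = 1))
})
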