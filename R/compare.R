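## Step 4: build the consensus taxonomy tree over all samples and render
## the multi-sample comparison. Node proportions are normalized per sample
## over classified fragments so bars are comparable across samples with
## very different read depths.

#' Build the consensus taxonomy tree across samples
#'
#' The tree is the union of all observed lineage paths: a node exists iff
#' some sample has a nonzero count on that path. Levels below the root are
#' the six ranks phylum through species (kingdom is collapsed into the
#' root). Each node carries one count per sample and the normalized
#' proportion count / total classified of that sample; samples absent at a
#' node get proportion 0. Children are ordered by descending pooled count,
#' ties alphabetical.
#'
#' @param profiles list of [SampleProfile-class] objects with unique
#'   sample ids.
#' @return a [ConsensusTree-class].
#' @export
buildConsensusTree <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  samples <- vapply(profiles, sampleId, "")
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  counts <- lapply(profiles, rankCounts)
  allPaths <- unique(do.call(rbind, lapply(counts, function(x)
    x[, c("rank", "path", "name")])))
  nodes <- data.frame(id = 1L, parent = NA_integer_, rank = "root",
                      name = "root", path = "", depth = 0L,
                      stringsAsFactors = FALSE)
  cmat <- matrix(0, nrow = 1L, ncol = length(samples),
                 dimnames = list(NULL, samples))
  if (!is.null(allPaths) && nrow(allPaths)) {
    rankDepth <- match(allPaths$rank, .TREE_RANKS)
    allPaths <- allPaths[order(rankDepth, allPaths$path), , drop = FALSE]
    nodes <- rbind(nodes, data.frame(
      id = seq_len(nrow(allPaths)) + 1L, parent = NA_integer_,
      rank = allPaths$rank, name = allPaths$name, path = allPaths$path,
      depth = sort(rankDepth), stringsAsFactors = FALSE))
    # parent path = path minus its last component ("" at depth 1 -> root)
    parentPath <- sub(";?[^;]*$", "", nodes$path)
    nodes$parent <- match(parentPath, nodes$path)
    nodes$parent[1L] <- NA_integer_
    cmat <- matrix(0, nrow = nrow(nodes), ncol = length(samples),
                   dimnames = list(NULL, samples))
    for (si in seq_along(profiles)) {
      ct <- counts[[si]]
      if (nrow(ct) == 0L) next
      idx <- match(paste(ct$rank, ct$path), paste(nodes$rank, nodes$path))
      cmat[idx, si] <- ct$count
    }
  }
  totals <- vapply(profiles, totalClassified, 0L)
  cmat[1L, ] <- totals  # root pools every classified fragment
  names(totals) <- samples
  # depth-first order with children sorted by descending pooled count,
  # ties alphabetical
  pooled <- rowSums(cmat)
  childIdx <- split(seq_len(nrow(nodes))[-1L], nodes$parent[-1L])
  ordered <- integer(0)
  visit <- function(i) {
    ordered <<- c(ordered, i)
    kids <- childIdx[[as.character(i)]]
    if (is.null(kids)) return(invisible())
    kids <- kids[order(-pooled[kids], nodes$name[kids])]
    for (k in kids) visit(k)
  }
  visit(1L)
  remap <- match(seq_len(nrow(nodes)), ordered)
  nodes <- nodes[ordered, , drop = FALSE]
  nodes$parent <- remap[nodes$parent]
  nodes$id <- seq_len(nrow(nodes))
  rownames(nodes) <- NULL
  cmat <- cmat[ordered, , drop = FALSE]
  pmat <- sweep(cmat, 2L, ifelse(totals > 0L, totals, 1L), "/")
  new("ConsensusTree", nodes = nodes, counts = cmat, proportions = pmat,
      samples = samples, totals = as.numeric(totals))
}

setMethod("show", "ConsensusTree", function(object) {
  cat("ConsensusTree:", nrow(object@nodes) - 1L, "taxa over",
      length(object@samples), "sample(s), depth",
      max(object@nodes$depth), "\n")
})

#' @describeIn buildConsensusTree node table in depth-first order.
#' @param tree a ConsensusTree.
#' @export
treeNodes <- function(tree) tree@nodes

#' @describeIn buildConsensusTree per-sample count matrix (nodes x samples).
#' @export
treeCounts <- function(tree) tree@counts

#' @describeIn buildConsensusTree per-sample proportion matrix.
#' @export
treeProportions <- function(tree) tree@proportions

#' @describeIn buildConsensusTree sample ids (column order).
#' @export
sampleNames <- function(tree) tree@samples

.newickSafe <- function(x) gsub("[][();:, ']", "_", x)

#' Serialize the consensus tree as Newick
#'
#' Topology with node names; with `annotations = TRUE`, each node label is
#' followed by a bracketed comment carrying the per-sample proportions
#' (`[&p={...}]`), which standard Newick readers that ignore comments can
#' skip. The plain form (default) is parseable by any Newick reader.
#'
#' @param tree a [ConsensusTree-class].
#' @param annotations include per-sample proportions as comments.
#' @return single Newick string, terminated by `;`.
#' @export
renderTreeNewick <- function(tree, annotations = FALSE) {
  nodes <- tree@nodes
  childIdx <- split(nodes$id[-1L], nodes$parent[-1L])
  lab <- function(i) {
    l <- .newickSafe(nodes$name[i])
    if (annotations)
      l <- paste0(l, "[&p={",
                  paste(sprintf("%.6f", tree@proportions[i, ]),
                        collapse = ","), "}]")
    l
  }
  emit <- function(i) {
    kids <- childIdx[[as.character(i)]]
    if (is.null(kids)) return(lab(i))
    paste0("(", paste(vapply(kids, emit, ""), collapse = ","), ")", lab(i))
  }
  paste0(emit(1L), ";")
}

#' Multi-sample comparison table
#'
#' One row per tree node below the root: rank, semicolon-joined taxon
#' path, then one normalized-proportion column per sample.
#'
#' @param tree a [ConsensusTree-class].
#' @return data.frame.
#' @export
comparisonTable <- function(tree) {
  nodes <- tree@nodes
  keep <- nodes$rank != "root"
  out <- data.frame(rank = nodes$rank[keep], path = nodes$path[keep],
                    stringsAsFactors = FALSE)
  props <- tree@proportions[keep, , drop = FALSE]
  for (s in tree@samples) out[[s]] <- props[, s]
  out
}

.SVG_PALETTE <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e",
                  "#e6ab02", "#a6761d", "#666666")

#' Render the consensus tree as an SVG bar-chart tree
#'
#' Left-to-right layout, one ranked level per column. After each node name
#' sits a bar chart with one colored bar per sample, scaled linearly to
#' that sample's proportion relative to the node's maximum across samples
#' (per-node scaling keeps rare taxa visible). A legend maps colors to
#' samples.
#'
#' @param tree a [ConsensusTree-class].
#' @param colWidth,rowHeight layout parameters in pixels.
#' @return single character string holding the SVG document.
#' @export
renderTreeSVG <- function(tree, colWidth = 170, rowHeight = 26) {
  nodes <- tree@nodes
  ns <- length(tree@samples)
  barH <- max(3, floor((rowHeight - 8) / max(ns, 1L)))
  barMax <- 60
  childIdx <- split(nodes$id[-1L], nodes$parent[-1L])
  # leaves at consecutive rows (depth-first order), internals centered
  y <- rep(NA_real_, nrow(nodes))
  leafRow <- 0
  assignY <- function(i) {
    kids <- childIdx[[as.character(i)]]
    if (is.null(kids)) {
      leafRow <<- leafRow + 1
      y[i] <<- leafRow * rowHeight
    } else {
      for (k in kids) assignY(k)
      y[i] <<- mean(y[kids])
    }
  }
  assignY(1L)
  x <- nodes$depth * colWidth + 10
  widthPx <- (max(nodes$depth) + 1) * colWidth + barMax + 120
  heightPx <- (leafRow + 2) * rowHeight + 20 + ns * 16
  out <- c(sprintf(
    paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
           'height="%d" font-family="sans-serif" font-size="11">'),
    round(widthPx), round(heightPx)))
  # edges
  for (i in nodes$id[-1L]) {
    p <- nodes$parent[i]
    out <- c(out, sprintf(
      '<path d="M%.1f,%.1f C%.1f,%.1f %.1f,%.1f %.1f,%.1f" fill="none" stroke="#999"/>',
      x[p] + 4, y[p], (x[p] + x[i]) / 2, y[p], (x[p] + x[i]) / 2, y[i],
      x[i] - 2, y[i]))
  }
  # nodes: label plus one bar per sample
  cols <- rep_len(.SVG_PALETTE, ns)
  for (i in nodes$id) {
    g <- sprintf('<g class="node" data-rank="%s" data-name="%s">',
                 nodes$rank[i], nodes$name[i])
    g <- c(g, sprintf('<text x="%.1f" y="%.1f">%s</text>',
                      x[i], y[i] - 2, nodes$name[i]))
    mx <- max(tree@proportions[i, ], 0)
    for (si in seq_len(ns)) {
      p <- tree@proportions[i, si]
      wpx <- if (mx > 0) barMax * p / mx else 0
      g <- c(g, sprintf(
        '<rect class="bar" x="%.1f" y="%.1f" width="%.2f" height="%d" fill="%s"><title>%s: %.4f</title></rect>',
        x[i], y[i] + (si - 1) * barH, wpx, barH - 1, cols[si],
        tree@samples[si], p))
    }
    out <- c(out, g, "</g>")
  }
  # legend
  ly <- (leafRow + 1) * rowHeight + 10
  out <- c(out, '<g class="legend">')
  for (si in seq_len(ns)) {
    out <- c(out, sprintf(
      '<rect x="10" y="%d" width="12" height="12" fill="%s"/><text x="26" y="%d">%s</text>',
      round(ly + (si - 1) * 16), cols[si], round(ly + (si - 1) * 16 + 10),
      tree@samples[si]))
  }
  out <- c(out, "</g>", "</svg>")
  paste(out, collapse = "\n")
}

#' Write all comparison outputs
#'
#' @param tree a [ConsensusTree-class].
#' @param prefix path prefix; writes `<prefix>.tree.svg`,
#'   `<prefix>.tree.nwk` (annotated) and `<prefix>.comparison.tsv`.
#' @return character vector of written paths, invisibly.
#' @export
writeComparison <- function(tree, prefix) {
  svg <- paste0(prefix, ".tree.svg")
  nwk <- paste0(prefix, ".tree.nwk")
  tsv <- paste0(prefix, ".comparison.tsv")
  writeLines(renderTreeSVG(tree), svg)
  writeLines(renderTreeNewick(tree, annotations = TRUE), nwk)
  tab <- comparisonTable(tree)
  for (s in tree@samples) tab[[s]] <- sprintf("%.8f", tab[[s]])
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(svg, nwk, tsv))
}
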