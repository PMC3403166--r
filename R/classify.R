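## Step 3: turn per-fragment best hits into taxonomic assignments and
## per-sample profiles. Lineages use the Greengenes dialect: semicolon-
## delimited, optionally rank-prefixed tokens (k__, p__, c__, o__, f__,
## g__, s__). The six tree ranks run from phylum to species; the kingdom
## is parsed but collapsed into the tree root.

.RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
            "species")
.RANK_PREFIX <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                  family = "f", genus = "g", species = "s")
.TREE_RANKS <- .RANKS[-1L]

#' Parse a Greengenes-style lineage string
#'
#' Rank prefixes (`k__` ... `s__`) are stripped; an empty prefixed field
#' (`g__` with nothing after) is unfilled; trailing unfilled ranks are
#' allowed. Ranks must be filled prefix-first, so the lineage is truncated
#' at the first gap (a filled rank below an unfilled one is dropped).
#'
#' @param raw semicolon-delimited lineage string.
#' @return named character vector over kingdom...species; unfilled ranks
#'   are NA. The raw string is kept in `attr(, "raw")`.
#' @examples
#' parseLineage("k__Bacteria; p__Firmicutes")
#' @export
parseLineage <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  out <- setNames(rep(NA_character_, 7L), .RANKS)
  attr(out, "raw") <- raw
  toks <- trimws(strsplit(raw, ";", fixed = TRUE)[[1L]])
  if (length(toks) > 7L)
    stop("lineage has more than 7 ranks: '", raw, "'", call. = FALSE)
  for (i in seq_along(toks)) {
    tok <- toks[i]
    if (grepl("^[A-Za-z]__", tok)) {
      pref <- substr(tok, 1L, 1L)
      if (tolower(pref) != .RANK_PREFIX[i])
        stop("unparseable lineage token '", tok, "' at rank ", .RANKS[i],
             " in '", raw, "'", call. = FALSE)
      tok <- substr(tok, 4L, nchar(tok))
    }
    tok <- trimws(tok)
    if (grepl(";", tok, fixed = TRUE))
      stop("lineage name contains ';': '", raw, "'", call. = FALSE)
    out[i] <- if (nzchar(tok)) tok else NA_character_
  }
  # prefix-first invariant: truncate at the first gap
  gap <- which(is.na(out))
  if (length(gap)) out[gap[1L]:7L] <- NA_character_
  attr(out, "raw") <- raw
  out
}

## lineages for many raw strings -> 7-column character matrix
.parseLineages <- function(raws) {
  m <- t(vapply(raws, function(r) as.character(parseLineage(r)),
                character(7L), USE.NAMES = FALSE))
  colnames(m) <- .RANKS
  m
}

## per-rank path counts from a lineage matrix (tree ranks only; paths are
## semicolon-joined names from phylum down to the rank)
.countPaths <- function(lin) {
  rows <- list()
  for (ri in seq_along(.TREE_RANKS)) {
    rank <- .TREE_RANKS[ri]
    cols <- .TREE_RANKS[seq_len(ri)]
    filled <- !is.na(lin[, rank])
    if (!any(filled)) next
    paths <- apply(lin[filled, cols, drop = FALSE], 1L, paste,
                   collapse = ";")
    tab <- table(paths)
    rows[[rank]] <- data.frame(
      rank = rank, path = names(tab),
      name = lin[filled, rank][match(names(tab), paths)],
      count = as.integer(tab), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(rank = character(0), path = character(0),
                      name = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign taxonomy to fragments from their mapping hits
#'
#' Each fragment receives the lineage of its best hit (highest bit score,
#' ties by E-value then subject id) when the hit identity reaches
#' `minIdentity`; otherwise it is Unclassified. A best hit whose subject
#' is missing from the taxonomy leaves the fragment Unclassified with a
#' warning naming the subject. Counts are accumulated along each lineage
#' path at each of the six tree ranks.
#'
#' @param fragments fragment ids (character vector) or a named
#'   [Biostrings::DNAStringSet]; fragments without hits count as
#'   Unclassified.
#' @param hits tabular hit data.frame covering these fragments.
#' @param taxonomy named character vector from [readTaxonomy()].
#' @param minIdentity percent-identity floor (default 90).
#' @param sampleId sample identifier stored in the profile.
#' @return a [SampleProfile-class].
#' @export
assignTaxonomy <- function(fragments, hits, taxonomy, minIdentity = 90,
                           sampleId = "sample") {
  ids <- if (is.character(fragments)) fragments else names(fragments)
  if (is.null(ids)) stop("fragments must be named", call. = FALSE)
  n <- length(ids)
  subject <- rep(NA_character_, n)
  identity <- rep(NA_real_, n)
  lineage <- rep(NA_character_, n)
  if (nrow(hits)) {
    unknownFrag <- setdiff(unique(hits$qseqid), ids)
    if (length(unknownFrag))
      stop("hits refer to unknown fragment(s): ",
           paste(head(unknownFrag, 5L), collapse = ", "), call. = FALSE)
    byFrag <- split(seq_len(nrow(hits)), hits$qseqid)
    for (fid in names(byFrag)) {
      bh <- bestHit(hits[byFrag[[fid]], , drop = FALSE])
      i <- match(fid, ids)
      subject[i] <- bh$sseqid
      identity[i] <- bh$pident
      if (bh$pident < minIdentity) next
      if (!bh$sseqid %in% names(taxonomy)) {
        warning("best-hit subject '", bh$sseqid,
                "' missing from taxonomy; fragment '", fid,
                "' left unclassified", call. = FALSE)
        next
      }
      lineage[i] <- taxonomy[[bh$sseqid]]
    }
  }
  classified <- !is.na(lineage)
  assignments <- data.frame(
    fragment = ids, subject = subject, identity = identity,
    lineage = lineage,
    status = ifelse(classified, "classified", "unclassified"),
    stringsAsFactors = FALSE)
  counts <- if (any(classified))
    .countPaths(.parseLineages(lineage[classified])) else
    .countPaths(matrix(character(0), 0L, 7L,
                       dimnames = list(NULL, .RANKS)))
  new("SampleProfile", sampleId = sampleId, assignments = assignments,
      counts = counts, totalClassified = sum(classified),
      totalUnclassified = sum(!classified))
}

setMethod("show", "SampleProfile", function(object) {
  cat("SampleProfile '", object@sampleId, "': ", object@totalClassified,
      " classified, ", object@totalUnclassified, " unclassified\n",
      sep = "")
})

#' @describeIn SampleProfile-class sample identifier.
#' @param profile a SampleProfile.
#' @export
sampleId <- function(profile) profile@sampleId

#' @describeIn SampleProfile-class fragment-level assignment table.
#' @export
assignments <- function(profile) profile@assignments

#' @describeIn SampleProfile-class per-rank path count table.
#' @export
rankCounts <- function(profile) profile@counts

#' @describeIn SampleProfile-class classified fragment total.
#' @export
totalClassified <- function(profile) profile@totalClassified

#' @describeIn SampleProfile-class unclassified fragment total.
#' @export
totalUnclassified <- function(profile) profile@totalUnclassified

#' Classification report
#'
#' Per-rank tables of counts and percentages. Percentages are computed
#' over classified fragments; the unclassified share of all fragments is
#' reported separately in the header.
#'
#' @param profile a [SampleProfile-class].
#' @return list with `summary` (character lines) and `tables` (named list
#'   of per-rank data.frames with columns path, name, count, percent).
#' @export
classificationReport <- function(profile) {
  total <- profile@totalClassified + profile@totalUnclassified
  uncPct <- if (total > 0L) 100 * profile@totalUnclassified / total else 0
  summary <- c(
    sprintf("sample: %s", profile@sampleId),
    sprintf("fragments: %d", total),
    sprintf("classified: %d", profile@totalClassified),
    sprintf("unclassified: %d (%.1f%% of all fragments)",
            profile@totalUnclassified, uncPct))
  tables <- lapply(setNames(nm = .TREE_RANKS), function(rank) {
    tab <- profile@counts[profile@counts$rank == rank, , drop = FALSE]
    if (nrow(tab) == 0L)
      return(data.frame(path = character(0), name = character(0),
                        count = integer(0), percent = numeric(0),
                        stringsAsFactors = FALSE))
    tab <- tab[order(-tab$count, tab$path), , drop = FALSE]
    data.frame(path = tab$path, name = tab$name, count = tab$count,
               percent = 100 * tab$count / profile@totalClassified,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  list(summary = summary, tables = tables)
}

#' Write a classification report to disk
#'
#' @param profile a [SampleProfile-class].
#' @param prefix path prefix; writes `<prefix>.assignments.tsv`,
#'   `<prefix>.report.txt` and one `<prefix>.<rank>.tsv` per rank.
#' @return character vector of written paths, invisibly.
#' @export
writeClassification <- function(profile, prefix) {
  rep <- classificationReport(profile)
  paths <- character(0)
  p <- paste0(prefix, ".assignments.tsv")
  write.table(profile@assignments, p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, p)
  p <- paste0(prefix, ".report.txt")
  writeLines(rep$summary, p)
  paths <- c(paths, p)
  for (rank in names(rep$tables)) {
    p <- paste0(prefix, ".", rank, ".tsv")
    tab <- rep$tables[[rank]]
    tab$percent <- sprintf("%.4f", tab$percent)
    write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
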