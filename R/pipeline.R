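## End-to-end orchestration of the four steps with a machine-readable run
## manifest. Final outputs are identical for any thread (chunk) count: the
## per-stage work is decomposed into balanced chunks whose results are
## recombined in input order.

#' Build a pipeline configuration
#'
#' Defaults follow the package-wide stage defaults: Viterbi floor 25 bits,
#' word length 16, E-value cutoff 1e-5, identity floor 90%.
#'
#' @param mode "shotgun" (extract 16S fragments first) or "targeted16s"
#'   (amplicon input; reads are used directly as fragments and the
#'   extraction stage is skipped).
#' @param minScore,wordLength,maxEvalue,minIdentity stage parameters.
#' @param threads chunk count for the parallel contract (>= 1).
#' @param seed seed recorded in the manifest.
#' @return a [PipelineConfig-class].
#' @export
pipelineConfig <- function(mode = c("shotgun", "targeted16s"),
                           minScore = 25, wordLength = 16L,
                           maxEvalue = 1e-5, minIdentity = 90,
                           threads = 1L, seed = 1L) {
  mode <- match.arg(mode)
  new("PipelineConfig", mode = mode, minScore = minScore,
      wordLength = as.integer(wordLength), maxEvalue = maxEvalue,
      minIdentity = minIdentity, threads = as.integer(threads),
      seed = as.integer(seed))
}

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf(
    "PipelineConfig: mode %s, minScore %g, w %d, E <= %g, identity >= %g%%, threads %d\n",
    object@mode, object@minScore, object@wordLength, object@maxEvalue,
    object@minIdentity, object@threads))
})

.stageTimer <- function() {
  t0 <- proc.time()[["elapsed"]]
  function() round(proc.time()[["elapsed"]] - t0, 3)
}

#' Run the full pipeline on one or more samples
#'
#' Per sample: (1) scan reads with the profile HMM and extract 16S
#' fragments (skipped in targeted mode, where the input reads are used
#' directly as fragments); (2) map fragments to the reference database;
#' (3) classify fragments taxonomically. Across samples: (4) build the
#' consensus tree and write the comparison outputs. A JSON manifest
#' records versions, effective parameters and per-stage timings; on a
#' stage failure the manifest is written with status "incomplete" and the
#' error names the stage and offending file.
#'
#' @param config a [PipelineConfig-class].
#' @param samples named character vector of read files (FASTA/FASTQ, `.gz`
#'   accepted); names are sample ids (basenames used when unnamed).
#' @param db reference database FASTA path or [ReferenceIndex-class].
#' @param tax taxonomy TSV path or named character vector.
#' @param hmm profile-HMM file path or [ProfileHMM-class]; required in
#'   shotgun mode.
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly; outputs per sample are
#'   `<sample>.fragments.fasta`, `<sample>.lengths.tsv/.txt`,
#'   `<sample>.hits.tsv`, `<sample>.assignments.tsv`, `<sample>.<rank>.tsv`
#'   and `<sample>.report.txt`, plus `comparison.tree.svg`,
#'   `comparison.tree.nwk`, `comparison.comparison.tsv` and
#'   `manifest.json`.
#' @export
runPipeline <- function(config, samples, db, tax, hmm = NULL, outDir) {
  stopifnot(is(config, "PipelineConfig"), length(samples) >= 1L)
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    names(samples) <- sub("\\.(fa|fasta|fq|fastq)(\\.gz)?$", "",
                          basename(samples))
  if (anyDuplicated(names(samples)))
    stop("duplicate sample id(s)", call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    tool = "MetaSSU", version = as.character(packageVersion("MetaSSU")),
    mode = config@mode,
    parameters = list(minScore = config@minScore,
                      wordLength = config@wordLength,
                      maxEvalue = config@maxEvalue,
                      minIdentity = config@minIdentity,
                      threads = config@threads, seed = config@seed),
    samples = as.list(unname(samples)), status = "incomplete",
    stages = list())
  writeManifest <- function()
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  fail <- function(stage, file, e) {
    manifest$status <<- "incomplete"
    manifest$failedStage <<- stage
    writeManifest()
    stop("pipeline stage '", stage, "' failed on '", file, "': ",
         conditionMessage(e), call. = FALSE)
  }

  stage <- function(name, file, expr) {
    tm <- .stageTimer()
    out <- tryCatch(expr, error = function(e) fail(name, file, e))
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = name, file = file, seconds = tm())
    out
  }

  if (config@mode == "shotgun") {
    if (is.null(hmm)) stop("shotgun mode requires an HMM", call. = FALSE)
    if (is.character(hmm))
      hmm <- stage("load-hmm", hmm, readProfileHMM(hmm))
  }
  if (is.character(db)) {
    refs <- stage("load-db", db, readSequences(db, format = "fasta"))
    index <- stage("index-db", db,
                   buildReferenceIndex(refs, w = config@wordLength))
  } else index <- db
  if (is.character(tax))
    tax <- stage("load-taxonomy", tax, readTaxonomy(tax))
  scheme <- scoringScheme()

  profiles <- list()
  for (sid in names(samples)) {
    sfile <- samples[[sid]]
    prefix <- file.path(outDir, sid)
    reads <- stage("read-input", sfile, readSequences(sfile))
    if (config@mode == "shotgun") {
      hits16 <- stage("extract-scan", sfile,
                      scanReads(reads, hmm, minScore = config@minScore,
                                chunks = config@threads))
      frags <- stage("extract-fragments", sfile,
                     extractFragments(reads, hits16))
      writeSequences(frags, paste0(prefix, ".fragments.fasta"))
      writeLengthDistribution(lengthDistribution(frags), prefix)
    } else {
      frags <- reads  # targeted amplicons are the fragments
    }
    mapHits <- stage("map", sfile,
                     parallelMap(frags, index, scheme,
                                 nChunks = config@threads,
                                 maxEvalue = config@maxEvalue))
    writeTabularHits(mapHits, paste0(prefix, ".hits.tsv"))
    profile <- stage("classify", sfile,
                     assignTaxonomy(frags, mapHits, tax,
                                    minIdentity = config@minIdentity,
                                    sampleId = sid))
    writeClassification(profile, prefix)
    profiles[[sid]] <- profile
  }

  tree <- stage("compare", outDir, buildConsensusTree(profiles))
  writeComparison(tree, file.path(outDir, "comparison"))

  manifest$status <- "complete"
  writeManifest()
  invisible(outDir)
}
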