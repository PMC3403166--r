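# MetaSSU

Taxonomic profiling of shotgun metagenomes through the 16S rRNA gene, as a
self-contained R package. MetaSSU is for microbiome researchers who have
short-read shotgun (or 16S-targeted) libraries and want per-sample
taxonomic profiles plus a multi-sample comparison, without external
binaries or reference downloads: the detection model, the aligner, the
classifier and a ground-truthed synthetic data generator are all inside
the package.

The pipeline has four steps:

1. **Extract** — find 16S fragments in reads with a profile hidden Markov
   model scanned by a local Viterbi algorithm on both strands, and excise
   them in sense orientation. The Viterbi recurrence maximizes the total
   log2-odds score over state paths through match (M), insert (I) and
   delete (D) states, with free entry into and exit from any match state:
   `V_M(i,j) = e_j(x_i) + max{0, V_M(i-1,j-1)+t(M_{j-1},M_j),
   V_I(i-1,j-1)+t(I_{j-1},M_j), V_D(i-1,j-1)+t(D_{j-1},M_j)}`.
2. **Map** — align extracted fragments to an annotated 16S reference
   database with a seed-and-extend aligner (shared 16-mers, X-drop
   ungapped extension, banded affine gapped extension). Scores are
   reported as bit scores and E-values with Karlin–Altschul statistics,
   `S' = (λS − ln K)/ln 2` and `E = K·m·n·e^{−λS}`, with λ and K computed
   for the scoring scheme at uniform background. Mapping is chunk-parallel
   with a deterministic merge: output is byte-identical for every chunk
   count.
3. **Classify** — assign each fragment the Greengenes-style lineage of its
   best hit (identity ≥ 90%), and accumulate counts at the six ranks from
   phylum to species.
4. **Compare** — pool all samples onto one consensus taxonomy tree (at
   most six ranked levels below the root) carrying per-sample counts and
   normalized proportions, rendered as SVG bar-chart tree, Newick and TSV.

A `weightedAverage()` utility summarizes per-input speed-ups weighted by
sequence counts, `S̄ = Σ wᵢSᵢ / Σ wᵢ`, for reporting chunk-level timing
summaries.

## Worked example

Everything below runs from a fresh session with no external files: the
generator builds a 5-taxon reference, its taxonomy and a 400-read sample
whose true composition is uniform (80 planted fragments per taxon).

```r
library(MetaSSU)

ref  <- generateReference(5, 400, seed = 11)   # references + taxonomy + HMM seed
hmm  <- buildProfileHMM(ref$seedAlignment)
hmm
#> ProfileHMM 'ssu16': 400 match states

spec <- communitySpec(ref, nReads = 400, seed = 7)  # 200 planted fragments
smp  <- generateSample(spec)

hits  <- scanReads(smp$reads, hmm, chunks = 4)
nrow(hits)
#> [1] 200
frags <- extractFragments(smp$reads, hits)
lengthDistribution(frags)
#> LengthDistribution: n = 200, min = 59, max = 100, mean = 80.53

idx     <- buildReferenceIndex(ref$references)
mapHits <- parallelMap(frags, idx, scoringScheme(), nChunks = 4)
prof    <- assignTaxonomy(frags, mapHits, ref$taxonomy, sampleId = "demo")
prof
#> SampleProfile 'demo': 200 classified, 0 unclassified

classificationReport(prof)$tables$genus
#>                                        path    name count percent
#> 1 Phylum01;Class01;Order01;Family01;Genus01 Genus01    40      20
#> 2 Phylum01;Class01;Order02;Family02;Genus02 Genus02    40      20
#> 3 Phylum01;Class02;Order03;Family03;Genus03 Genus03    40      20
#> 4 Phylum01;Class02;Order04;Family04;Genus04 Genus04    40      20
#> 5 Phylum02;Class03;Order05;Family05;Genus05 Genus05    40      20

buildConsensusTree(list(prof))
#> ConsensusTree: 25 taxa over 1 sample(s), depth 6
```

All 200 planted fragments were detected (none of the 200 background reads
produced a hit), every fragment classified to its source genus, and the
recovered genus table matches the generating composition exactly — 40
fragments (20%) per genus. The consensus tree holds the 25 taxon nodes of
the 5 full lineages over the 6 ranks.

The same run end-to-end, from files, with the multi-sample comparison:

```r
cfg <- pipelineConfig(mode = "shotgun", threads = 4)
runPipeline(cfg, c(s1 = "s1.fastq", s2 = "s2.fastq"),
            db = "ref.fasta", tax = "ref.tax", hmm = "model.phmm",
            outDir = "out")
```

writes per-sample fragment FASTA, length distributions, hit tables,
assignments and per-rank reports, plus `comparison.tree.svg` /
`comparison.tree.nwk` / `comparison.comparison.tsv` and a JSON run
manifest. In `mode = "targeted16s"` the extraction stage is skipped and
input reads are mapped directly. A thin shell entry point with the same
surface is installed at `inst/scripts/metassu`.

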