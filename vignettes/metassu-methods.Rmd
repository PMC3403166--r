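---
title: "MetaSSU: models, parameters and design notes"
author: "MetaSSU authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MetaSSU: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetaSSU)
```

MetaSSU profiles the taxonomic composition of shotgun metagenomes through
the 16S rRNA gene in four steps: fragment detection by profile-HMM search,
mapping to an annotated reference database by seed-and-extend alignment,
best-hit taxonomic classification, and multi-sample comparison on a
consensus taxonomy tree. This vignette explains the underlying models, the
tunable parameters and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the design choices
made where more than one reasonable option existed.

## The detection model

16S fragments are found with a profile hidden Markov model: one match
state per reference alignment column, plus insert and delete states. Match
and insert emissions are scored as log2-odds in bits against a uniform
0.25 background; transitions as log2 probabilities. The Viterbi scanner
uses local alignment semantics — entry into any match state at any read
position is free, exit after any match state is free, and read residues
outside the aligned interval cost nothing. Every read is scanned on both
strands and the better strand is kept (ties go to plus), because a shotgun
read samples either strand of the rRNA gene with equal probability.

Model construction from an ungapped seed alignment is deliberately simple:
maximum-likelihood column emissions with a +1 pseudocount per base, insert
states at the background distribution, and a global transition prior of
0.9/0.05/0.05 out of every state. The prior is applied identically out of
match, insert and delete states; with only three free parameters per
source state and no training alignments with indels, there is nothing to
estimate them from, and a shared prior keeps the model's behaviour easy to
reason about. Delete states cannot be entered before the first match
column or exited after the last, so a path always begins and ends in a
match state and reported intervals are never empty.

Ambiguity codes (N and the other IUPAC letters) emit at the background
distribution, i.e. contribute 0 bits. This makes an all-N read score
exactly 0 and keeps the kernel free of special cases.

Ties in the Viterbi traceback are broken deterministically: a match
predecessor beats a delete, which beats an insert, and continuing a path
beats opening a fresh local alignment. The best-scoring cell is chosen in
scan order (read position, then model position). Determinism here is not
cosmetic: the pipeline's headline guarantee is byte-identical output for
every chunk count, which requires every kernel to be tie-stable.

### The reporting threshold

`scanReads()` reports hits at or above `minScore = 25` bits. The floor has
to clear the null distribution of the scanner: the maximum local score of
a random read grows with the logarithm of the (model length x read length
x 2 strands) search space, and for the model sizes this package targets
(a few hundred match states against ~100 nt reads) the null maximum
reaches the low twenties — we measured maxima up to 21.6 bits over 2,000
uniform background reads against a 400-state model. A 20-bit floor, a
common reporting convention for database search, therefore admits roughly
one spurious hit per few thousand background reads at this search-space
size, while genuine 16S fragments of 60 nt or more at a few percent
divergence score above 40 bits. 25 bits separates the two regimes with
margin on both sides: in our validation it produced zero false hits on
6,000 background reads across seeds, at planted-fragment recall 1.0. For
substantially longer models or reads the floor should be revisited
upwards (the null maximum grows logarithmically with search space).

## The mapper

Fragment mapping is seed-and-extend against a word index of the reference
database, organized in the three phases that make chunk-parallelism
trivially correct: problem decomposition, per-chunk computation, and
result combination in input order.

* **Decomposition.** Queries are split into at most `nChunks` contiguous
  chunks, greedily balanced by residue count (each chunk closes when its
  load reaches remaining-residues / remaining-chunks). Contiguity is what
  makes the merge deterministic: concatenating per-chunk results in plan
  order restores exactly the serial output, regardless of the order in
  which chunks finish. The balance guarantee (no chunk more than twice the
  load of another) holds whenever queries have comparable lengths and
  chunks hold several queries each; with fewer queries than chunks every
  chunk is a single query and the loads are whatever the query lengths
  are.
* **Seeding.** Shared words of length `w = 16` on either query strand.
  megaBLAST-style word sizes (28) assume near-identical sequences; 16
  retains seeds in ~100 nt fragments at the few-percent divergence this
  pipeline expects between a fragment and its nearest reference, while
  remaining specific (a random 16-mer match has probability 4^-16 per
  position pair). Words containing non-ACGT codes are neither indexed nor
  looked up.
* **Extension.** Co-diagonal seeds are merged, extended ungapped with
  X-drop termination (X = 20 score units), and the best ungapped segment
  per reference is refined by a banded affine local alignment (band 16
  diagonals either side). Band 16 accommodates a net indel drift of 16
  positions, far beyond what substitution-dominated 16S divergence
  produces; against an exhaustive Smith-Waterman oracle the banded score
  matched the true local optimum in 100% of our seeded random-pair trials
  and can never exceed it.
* **Scoring.** Match +1, mismatch -2, gap open -5, gap extend -2 (a gap of
  length L costs 5 + 2L). Raw scores are converted to bit scores and
  E-values with Karlin-Altschul statistics: lambda solves
  $\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1$ by root finding at uniform
  background, and K is computed from the classical partial-sum series for
  lattice score distributions; for +1/-2 this yields lambda = 1.3327,
  K = 0.621, matching the standard ungapped nucleotide values. The same
  parameters are applied to gapped scores, as BLAST does for its default
  nucleotide schemes; since gapped alignments only lower E-values slightly
  at these penalty settings, and hit filtering happens at a generous
  `maxEvalue = 1e-5`, the approximation does not change which hits
  survive. E-values use m = query length and n = total database residues,
  so doubling the database doubles E at fixed score.

Coordinates are 0-based half-open everywhere inside the package and are
converted to the 1-based inclusive tabular convention only at
serialization; minus-strand hits keep ascending query coordinates and
carry descending subject coordinates, the BLAST tabular dialect.

## Classification

Each fragment takes the lineage of its single best hit (highest bit
score; ties broken by E-value, then subject id) when the hit identity
reaches `minIdentity = 90%`; otherwise it is unclassified. The 90% floor
prevents weak, possibly spurious alignments from propagating species-level
calls; at the divergence structure of 16S references, hits below 90%
identity carry little information below the family rank. Classification is
deliberately best-hit, not lowest-common-ancestor: the pipeline's contract
is one assignment per fragment from its mapping result, and an LCA mode is
out of scope.

Lineage strings use the Greengenes dialect — semicolon-delimited,
rank-prefixed (`k__` through `s__`) — with one normalization rule: ranks
must be filled top-down, so a lineage is truncated at its first unfilled
rank. Which reference release or exact file layout a user maps against is
their choice; the dialect is the documented assumption.

Report percentages are computed over classified fragments, with the
unclassified share of all fragments reported separately. Both views are
kept because collapsing them loses information: normalizing over
classified fragments makes samples of very different sequencing depth
comparable, while the unclassified fraction is itself a quality signal.

## Multi-sample comparison

The consensus tree is the union of all observed lineage paths across
samples, one level per rank from phylum to species (at most six levels
below the root; the kingdom is collapsed into the root since essentially
all 16S assignments share it). A node exists iff some sample has a
nonzero count on its path. Per-sample node proportions are counts divided
by that sample's total classified fragments — normalizing per sample makes
bars comparable across libraries whose depths differ by orders of
magnitude. Children are ordered by descending pooled count with
alphabetical tie-breaks, so the tree layout is deterministic and
independent of input order.

The SVG rendering scales bars per node (linear, 0 to the node's maximum
proportion across samples). Per-node scaling was chosen over a global
scale because rare taxa become invisible under a common axis; the
comparison TSV carries the raw proportions for any analysis that needs a
common scale, and the Newick export carries them as bracketed comments.

## The synthetic-data generator

`generateReference()` evolves n taxa from one random ancestor along a
star topology with per-taxon divergences drawn uniformly from 2-15%,
substitution-only, so the taxa double as an ungapped profile-HMM seed
alignment. Each taxon receives a distinct six-rank lineage with shared
higher ranks (phyla in groups of four, classes in pairs), giving the
consensus tree real internal structure. The default reference length of
400 nt is a marker-region scale — comparable to the amplicon windows used
in practice — chosen to keep the model compact; nothing in the code
depends on it.

`generateSample()` emulates a short-read shotgun library: 100 nt reads
(the scale of the Illumina GAIIx libraries this pipeline design targets),
i.i.d. uniform background DNA, and a planted fraction (default 0.5) of
reads carrying a contiguous fragment (60-100 nt) of a reference sequence
at a configurable substitution rate, on either strand. Planted read
counts per taxon follow the community abundances by deterministic
largest-remainder rounding — the simulated sample is a mock community of
*defined* composition, like a laboratory staggered-abundance mix, so
recovery experiments measure pipeline error rather than multinomial
sampling noise. Validation uses 5-taxon communities with uneven
abundances (0.35/0.25/0.20/0.12/0.08), samples of 2,000-4,000 reads, and
substitution rates of 1-5%; these sizes give tight binomial error bars on
recall and composition while keeping the whole suite fast.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: indels and quality-dependent error
profiles; chimeras; conserved/variable region structure within the 16S
gene (real fragments are not uniformly informative); non-uniform,
GC-biased genomic background that can resemble rRNA locally; incomplete
reference databases (every planted taxon has its exact source reference
present); and real phylogenetic covariance between taxa beyond the star
topology. Results on real libraries will be worse than on these fixtures,
mainly through fragments that match no reference within the identity
floor.

## Numerical and degenerate-input conventions

* Viterbi and alignment tie-breaks are fixed (above); all merges happen
  in input order. The package contains no hidden randomness: every
  stochastic routine takes an explicit seed, and the pipeline records its
  seed in the run manifest.
* Emission probabilities must sum to 1 within 1e-9 at model build time;
  after a round-trip through the text format (8 decimal places) validity
  is enforced at 1e-5.
* Empty inputs are values, not errors: an empty FASTA yields an empty
  record set, a read set with no hits yields an empty fragment file and a
  zero-count length distribution, and an empty query set yields a plan
  with zero chunks.
* A query shorter than the word length can never seed and returns no
  hits. Reads whose best strand scores below the floor simply produce
  nothing.
* The E-value cutoff is applied to each hit; best-hit selection happens
  after the cutoff, so a fragment whose only alignments are insignificant
  is unclassified rather than weakly classified.

## Known limitations

One hit per read per strand (multi-domain reads — a read spanning two rRNA
fragments — report only the better interval); no paired-end awareness
(mates are independent reads); no LCA or confidence estimation; banded
extension can in principle undershoot the true optimum when the best
alignment drifts more than 16 diagonals from the seeded one; Karlin-
Altschul parameters come from ungapped theory applied to gapped scores;
and the weighted-average utility summarizes externally measured per-input
speed-ups — the package does not assert anything about wall-clock
performance, which is hardware-dependent.
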