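---
title: "Reconstructing paleo-polyploid karyotypes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing paleo-polyploid karyotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(paleoshuffle)
```

# The problem

Many plant genomes are ancient polyploids. A hexaploidy shared by the core
eudicots (the γ triplication) and later lineage-specific whole-genome
duplications (WGDs) leave a nested signature in an extant genome: every
ancestral chromosome is represented by several homoeologous regions, gene
order within regions is conserved in collinear blocks, duplicated gene
copies are progressively lost (fractionated) with a bias between copies,
and synonymous-site divergence (Ks) between surviving duplicates records
which duplication produced them. On top of the sequence record, duplicated
regions can diverge in chromatin organisation (A/B compartments, TAD-like
domains) and in expression and DNA methylation.

`paleoshuffle` implements the full reconstruction pipeline — collinear
block detection, ancestral-origin painting of extant chromosomes,
Ks-based assignment of duplicate pairs to WGD layers, fusion-junction
counting per layer, intermediate-karyotype reconstruction, rearrangement
detection, fractionation statistics, homoeolog expression-triad
classification, and Hi-C compartment/TAD comparison — together with a
synthetic-genome generator that implants a known history, so that every
stage can be scored against ground truth without any external data.

# The synthetic-genome generator

The generator is first-class, tested code; its defaults define the study
conditions used throughout the test suite.

**Ancestor.** Seven chromosomes of 120 genes each (840 loci), every gene a
random in-frame sequence of 100 sense codons. Genes are spaced 1 kb apart
so gene rank and physical position are interchangeable at I/O boundaries;
all collinearity arithmetic is done on 0-based gene ranks, following the
convention that synteny gaps are counted in genes.

**WGD events.** `applyWGD()` copies every chromosome and evolves each copy
with a synonymous-biased single-base substitution process (synonymous
changes weighted 5:1 over nonsynonymous; stop-creating changes rejected).
The number of mutation rounds is calibrated by bisection against the
package's own NG86 estimator so that the median pairwise Ks between copies
at application time equals the event target within ±0.05. In the packaged
replay the triplication target is 0.8 and the duplication target 0.4:
because every lineage keeps evolving after the second event, the final
observed layer medians separate at roughly 1.2 (γ pairs) and 0.4 (β
pairs), two cleanly resolvable peaks with the older event deeper — the
qualitative structure the dating stage must recover. Substitution
saturation makes Ks sub-additive across events, so the final γ peak is an
emergent property of the process, not a dialled number.

**Karyotype history.** The packaged replay cuts the 21 post-triplication
chromosomes into 34 segments and concatenates them into 8 chromosomes (26
heterologous junctions), duplicates the genome (16 chromosomes), then
applies 4 further whole-chromosome fusions (12 chromosomes). The segment
composition of each fused chromosome is one consistent realization chosen
so that no two segments from the same ancestral chromosome share a fused
chromosome and all 30 junction types are pairwise distinct — this makes
the layer-wise junction counts identifiable. The four post-duplication
fusions combine different chromosome pairs in the two genome copies, as
four independent events in one nucleus would.

**Fractionation.** Per-copy retention probabilities (defaults 0.85, 0.60,
0.55, 0.40, 0.45, 0.30 across the six γ×β copy classes) implement biased
loss, with at least one copy of every locus retained. The mean retained
copy number (≈3.2 of 6) gives heavily fractionated regions in which most
loci survive in a minority of copies, the regime the retention statistics
target. Explicit per-locus implants are also supported and drive the
segment-pair (69/98/112 of 279 loci) and genome-wide (993 of 14,821
high-retention loci) replay scenarios.

**Extant species.** Two species are emitted after shared fractionation:
the primary carries one within-segment inversion; the second carries one
inversion and a reciprocal translocation between non-homoeologous
chromosome tails, cut inside the terminal segments. Homology tables
(species vs ancestor and self) are generated from the true orthology with
percent identity measured from the actual sequences.

**Omics layers.** Expression triads draw a category per gene from seven
archetypes (balanced; leaf/root/stem dominant; leaf/root/stem suppressed)
and sample tissue fractions from a Dirichlet around the archetype
(concentration 50 by default; +0.5 pseudo-count so archetype zeros stay
samplable), scaled by a log-normal magnitude and measured in two
replicates with 10% log-normal noise. Methylation levels are Beta draws
with a hypermethylated distribution inside TAD interiors. Contact matrices
have power-law distance decay `(d+1)^-1`, an optional compartment
checkerboard, within-TAD enrichment, flat inter-chromosomal background
with optional enrichment between regions of shared ancestral origin, and
Poisson counts at a stated depth.

**What the generator does not emulate.** No indels or missing/partial gene
models, no tandem duplications or gene families beyond single-locus
orthology, no translocation of interior (non-terminal) segments, uniform
gene spacing, and noise-free homology tables. Passing tests therefore
demonstrate correctness of the reconstruction logic under a clean but
non-trivial history; they do not certify performance on noisy real
annotations.

# Collinearity and painting

Anchors (homologous gene pairs) are chained per chromosome pair and
orientation by dynamic programming maximizing anchor count under strict
rank monotonicity and a maximum gap of 50 intervening genes on **both**
genomes (the stricter reading; the convention counts gaps in genes).
Chains are extracted greedily by size, ties to the leftmost start; each
anchor joins at most one block; blocks need ≥5 anchors. Pairs touching
gene families larger than 30 members (connected components of the
homology graph) are removed first.

Painting projects each block onto a segment of the extant chromosome.
Two numerical details matter:

* a forward chain can legitimately bridge a short inverted span and even
  capture a stray anchor inside it; overlapping segment spans are
  resolved by splitting the bracketing segment at the intruder's
  boundaries, and end anchors whose ancestral rank jumps by more than 20
  are trimmed;
* merging same-origin neighbours additionally requires the extant and
  ancestral gaps to agree within 10 genes — a large ancestral jump over a
  tiny extant gap is a genuine junction between different copies (e.g.
  after a translocation), not a fractionation hole.

# Copy labels, junction layers and karyotypes

Anchor Ks values from the genome self-comparison are grouped by the
physical pair of painted segments they connect (a single chain can cross
an old fusion boundary where both duplication layers remain collinear, so
block-level medians would mix layers). The segment-pair medians are
fitted with a Gaussian mixture; the lowest-mean component is the youngest
duplication (β). β-layer links group segments into β-pair units; a
segment left without any usable β link (the sparsest copy-class pairs can
share only a couple of retained loci) is paired with the unique
same-origin, span-overlapping unit it has **no** γ link to. Units of each
ancestral chromosome are then clustered into γ copy classes by interval
colouring (span overlap or a γ link means different copies), and sides
within a unit are separated by two-colouring the β links.

A junction is an adjacency between segments of different (ancestor, γ
copy) origin. A junction type observed in both β copies of the genome is
one pre-duplication (post-γ) fusion; a single occurrence is
post-duplication. Junction instances at breakpoints of detected extant
rearrangements are attributed to the extant layer first — without this, a
reciprocal translocation inside one genome copy masquerades as fusion
events, which is why rearrangement detection (a cross-species comparison)
runs before junction counting, exactly as multi-species comparisons
separate these events in practice.

One identifiability caveat is inherent to the problem: when a fission
splits a γ copy before the fusions, no signal can say which of the two
half-segments keeps the copy's *name* — any assignment consistent with
the β pairing and γ conflicts is equally valid. Class *counts*, junction
layer counts and per-locus copy numbers are invariant under this
relabelling; the truth-comparison tests are phrased accordingly.

Karyotype reconstruction reports the extant chromosome complement as-is,
and obtains the pre-duplication complement by splitting chromosomes at
post-duplication junctions and collapsing the pieces pairwise by
orientation-canonical origin composition, with an error if any
composition does not occur exactly twice.

# Ks dating

The Ks/Ka estimator is Nei–Gojobori (1986): per-codon synonymous site
fractions averaged over both sequences (changes to stop codons count as
nonsynonymous); observed differences averaged over all substitution
pathways with pathways through stop codons excluded (if every pathway is
blocked, the average is taken over all pathways with stop-creating steps
as nonsynonymous); Jukes–Cantor correction `Ks = -3/4 log(1 - 4/3 ps)`
with `ps >= 3/4` flagged saturated. The 64×64 pathway-averaged difference
tables are precomputed once, so genome-scale Ks reduces to table lookups.
The estimator is verified exactly against an independent
permutation-enumeration oracle on every pair of sense codons and on
random 2–3-codon alignments.

Mixture fitting is a hand-rolled 1-D Gaussian EM with a variance floor of
1e-6, initialized from the top-k KDE modes plus five seeded random
restarts, with BIC model selection (AIC optional) over k = 1..5 on Ks in
[0.05, 3] (lower bound removes allelic/tandem noise, upper bound removes
saturation). The log-likelihood trace is non-decreasing by construction
and asserted in tests; an independent EM implementation is used as a
cross-check, never as the estimator. Posterior ties in block-to-event
assignment go to the lower-mean component. On the replay the high-Ks
layer's estimator skew occasionally splits into two components; layer
attribution therefore contrasts the lowest-mean component against the
rest, which is insensitive to that split. With a single fitted component
all links are treated as same-layer homoeolog conflicts (a single-WGD
history).

The LTR age formula `age = K/(2r)` with `r = 1.3e-8` per site per year
and the Kimura two-parameter distance are provided as stated.

# Fractionation, triads and methylation

The retention matrix is loci × region classes with one gene per TRUE
cell. The headline statistics are the count/percentage of loci retaining
more than half (>3) of their six copies and, for one duplicated segment
pair, the both/singleton-1/singleton-2 partition with percentages over
present loci.

Triads average replicates, normalize TPM triples to tissue fractions, and
classify by nearest archetype (Euclidean distance in the fraction
simplex; exact ties to Balanced, logged). No "unclassified" band is
introduced because no distance threshold is stated for the convention.
Recovery of implanted categories is ≥99% at Dirichlet concentration 200
and ≥80% at 20. Methylation classes use inclusive thresholds at 0.3
(hypo) and 0.7 (hyper); both are configurable, as no canonical values
exist.

Expression diversity (Dj) and specificity (Sj) have no published
definition for this context, so the package documents its own: Dj is the
mean pairwise Jensen–Shannon divergence (log2, range [0, 1]) of tissue
fraction profiles within a region class; Sj is the mean tau specificity
`sum(1 - x/max(x))/(n_tissues - 1)`. They are substitutes, not
reconstructions.

# Hi-C topology

ICE balancing masks bins below the 2% coverage quantile (with a 1e-3
margin so an already-balanced matrix is a fixed point), iterates row
rescaling to a row-sum CV below 1e-5, and returns a bias vector with the
reconstruction identity `raw = b_i * b_j * balanced`. Masked bins
propagate NA and are never zero-filled, which would bias eigenvectors.

Expected counts per bin distance are lowess-smoothed in log-log space
(power-law decay is linear there, so both the diagonal and the far tail
are fitted faithfully), with plain diagonal means for chromosomes under
10 bins. Compartments are the first eigenvector of the Pearson
correlation of the per-chromosome O/E, sign-oriented so the positive (A)
set has the higher gene density — the positive-is-A convention alone is
basis-dependent. Constant input gives all-NA labels with a warning.

The insulation score is the mean balanced count in a square window
sliding along the diagonal, log2-normalized by the chromosome mean, NA
within a window of chromosome ends. Boundaries are insulation minima
where the delta vector crosses zero downward with amplitude ≥0.1;
near-duplicate minima within half the delta span are collapsed to the
deepest dip. An optional two-state Viterbi smoothing of discretized
scores can refine boundaries and is OFF by default — the reproducible
rule is the delta vector. The window default is 500 kb (the established
convention for mammalian-scale domains); analyses of the simulated
~160–300 kb domains use 100 kb, matching the domain scale, and
compartments and domains are called on separate matrices at their own
scales, as in the underlying protocol.

Region-topology comparison reports mean log2 normalized contact per
region-class pair, a within- vs between-ancestor t test on
inter-chromosomal pairs, and the fraction of region junctions within one
bin of an A/B switch. TAD profiles assign genes to border (boundary bin
±1) or interior zones and report zone means plus a 20-bin rescaled
meta-profile.

# Problem sizes and determinism

The test suite and acceptance script run the full replay (7×120 ancestral
loci, 100 codons/gene, ~2,600 extant genes per species) in a few seconds
per seed; the replay acceptance suite covers ten seeds. The Hi-C checks
use one 500-bin chromosome at 20 kb with 1e6 contacts; the mixture checks
use 500 draws per component; the calibration loop-closure experiment uses
120 loci at 200 codons/gene, where the NG86 estimator's sampling variance
is small enough that its Jukes–Cantor convexity bias at Ks ≈ 1.2 stays
well inside the ±0.05 tolerance. Every random step derives its stream
from a user seed; identical seeds give byte-identical datasets and
pipeline outputs, which is itself asserted in the acceptance suite.

# Known limitations

* Homology input is assumed gene-to-gene; protein alignment and
  alignment-quality filtering are out of scope.
* Copy-class names after fissions are conventional (see above); only
  counts and pairings are identifiable.
* The junction-layer rule assumes the duplication copies both survive
  fractionation at segment scale; a wholly deleted chromosome copy would
  demote its pre-duplication junctions to single occurrences.
* The NG86 estimator saturates near ps = 3/4; anchors beyond Ks ≈ 2.5
  are flagged rather than dated, and the mixture is fitted on [0.05, 3].
* The Hi-C callers operate on moderate bin counts (thousands) with dense
  matrices; genome-scale sparse-matrix support is not a goal.
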