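---
title: "Measuring intragenomic V9 variability and OTU inflation: methods"
author: "v9var"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring intragenomic V9 variability and OTU inflation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(v9var)
```

## The problem

Eukaryotic metabarcoding surveys count diversity in units — OTUs or ASVs —
derived from a short marker, here the V9 hypervariable region of the 18S
rRNA gene (roughly 104–137 nt). Three mechanisms make the number of
distinct V9 sequences recovered from a single organism larger than one:
genuine intragenomic polymorphism among rRNA gene copies, sequencing
errors, and contamination of the sequenced material by other organisms.
How these are handled by the OTU-definition step decides whether an
environmental survey over- or under-counts taxa. `v9var` implements the
full measurement pipeline — reference building, read preparation, V9
extraction and dereplication, two OTU definitions, a divisive denoiser,
identity-based contamination rules, and summary metrics — together with a
synthetic-data generator that produces genomes, amplicon samples, and
truth tables with exactly the structure these stages assume. Every claim
the package makes about its own behavior is tested against that truth.

## Sequence comparison

One identity definition is used everywhere (extraction, clustering,
contamination rules, annotation): optimal global alignment with match
score $+1$, mismatch $-3$, and affine gap penalties (opening 5, extension
2; a gap of length $L$ costs $5 + 2L$), with

$$\mathrm{identity} = \frac{\text{identical columns}}{\text{alignment columns}},$$

gap columns included in the denominator. The aligner is a Gotoh
three-state dynamic program with a deterministic traceback (diagonal, then
up, then left on ties). A banded variant (default half-width 16) is used
in inner loops; whenever the optimal banded path touches the band
boundary, the band is doubled and the alignment recomputed, up to the full
matrix, so banded and full results coincide — the test suite asserts exact
score and identity agreement on a thousand random pairs. For V9
extraction, a "fit" variant consumes the reference end-to-end with free
read overhangs; a hit is accepted only if the reference's first and last
bases are aligned to read bases (the full-span rule) and identity is at
least 0.80. The identity denominator is a genuine design choice — common
alternatives divide by the shorter sequence length — and is applied
uniformly because the 80% extraction rule, the 97% clustering threshold
and the 80%/90% contamination rules must be mutually consistent.

## OTU definitions

**Swarms.** Single-linkage clustering at distance $d = 1$: swarms are the
connected components of the graph joining unique sequences at Levenshtein
distance ≤ 1. Neighbors are found by deletion-signature hashing (each
sequence is keyed by itself and all single-deletion variants; candidate
pairs sharing a key are verified with a banded edit distance), which
scales linearly with the number of sequences; the all-pairs graph is
retained as the test oracle. The fastidious refinement grafts each swarm
with mass (summed read count) below 3 onto the highest-mass heavy swarm
reachable through one virtual intermediate, i.e. by a total distance ≤ 2
link; unreachable light swarms stay standalone. Chain-breaking refinement
is not implemented: it is not applied by the reference single-linkage
protocol at $d = 1$ with default fastidious settings, and none of the
package's statistics depend on it. Output is canonicalized (members and
swarms sorted by count, then sequence), so input order never matters.

**97% centroid clustering.** A single greedy pass in decreasing abundance
order (ties lexicographic): each sequence joins the first established
centroid at identity ≥ 0.97, else founds a new centroid. Size ordering is
assumed (the abundance-sorted dialect); "first centroid" rather than
"best centroid" matches the greedy reference behavior.

## The denoiser

Reads are dereplicated into unique sequences with positionwise mean
qualities (the per-unique aggregate keeps the computation at
unique-sequence rather than per-read granularity; this is a deliberate
approximation that loses within-unique quality variance). Given an error
model, the probability that a partition center $c$ was misread as unique
$u$ is

$$\rho(u \mid c) = \prod_{\text{columns}} p(c_i \to u_i \mid q_i),$$

a product over the banded global alignment's columns of quality-dependent
transition probabilities, with a per-event indel probability ($10^{-5}$
per gap run) for gap columns. With $n_u$ reads of $u$ and $N_c$ reads in
the partition, the expected number of error-derived reads is $\lambda =
\rho N_c$, and the abundance p-value is the conditional Poisson tail

$$p = P(X \ge n_u \mid X \ge 1), \qquad X \sim \mathrm{Poisson}(\lambda),$$

defined as 1 for singletons ($n_u = 1$), so a singleton can never seed a
new partition. The divisive loop starts from one partition centered on
the most abundant unique; while any unique has $p$ below
$\Omega_A = 10^{-40}$ (the published default; exposed in
`denoise_config()` because results are sensitive to it), the most
significant unique is promoted to a new center and every unique is
reassigned to the center maximizing $\rho$. Partition centers with their
aggregated counts are the ASVs.

**Error-model learning** alternates denoising with re-estimation of the
transition matrix from observed (center base → read base, quality)
counts, stopping when the matrix changes by less than $10^{-6}$ in
max-norm or after 10 rounds. Rates are regularized to be monotone
non-increasing in quality by weighted isotonic regression, with a
probability floor of $10^{-7}$; empty quality bins inherit the nearest
observed bin. Isotonic regression was chosen over curve smoothing
because it imposes exactly the shape constraint the model needs without a
smoothing-span parameter. Genome panels are pooled for learning (their
per-genome depth is low); environmental samples can be learned per
sample.

**Bimera removal.** Within a sample, an ASV is flagged when it is exactly
reconstructable as a left prefix of one ≥ 2× more abundant ASV plus a
right suffix of a different one (one breakpoint, zero mismatches per
segment). An ASV is removed when flagged in more than 90% of the samples
where it was testable (at least two candidate parents present). The
zero-mismatch segment rule is stricter than partial-match chimera
scoring; it matches the generator's chimera model (single-breakpoint
concatenation) and keeps the flag decision deterministic.

**Paired 80/80 protocol.** Mates are truncated to 80 nt (after
truncating at the first base below quality 2; reads with any N or
expected errors above 2 are dropped), the two streams are denoised
independently with their own learned models, and each (forward ASV,
reverse ASV) combination is merged by best exact ungapped overlap of at
least 12 identical bases. Combinations that fail to overlap are dropped
and counted. For V9 amplicons (≤ 137 nt) the two 80-nt mates always
overlap; templates longer than 148 nt cannot satisfy the 12-base exact
overlap and are reported as drops rather than merged — a deliberate
failure mode in preference to assembling unsupported sequences.

## Contamination rules

Within a genome/transcriptome, units are ranked by abundance; the most
abundant is `dominant`. At the barcode level, units below 80% identity
to the dominant are classified `foreign_phylum` and removed before any
OTU/ASV inference. At the ASV level the threshold is 90%
(`putative_contaminant`); everything at or above threshold is
`retained_intragenomic`. On simulated data where contaminants are
planted below 0.75 identity and true variants above 0.95, the rules
recover the planted sets with precision and recall 1 — the bands are
separated by more than the rule's resolution, which is what the identity
thresholds implicitly assume about real cross-phylum contamination.

## The generator

`sim_config()` describes a multi-copy rRNA locus: a dominant V9 variant
(default 120 nt) with optional minor variants at an exact substitution
distance, relative copy weights, read depth (default 1000), a
per-position quality profile (default constant q30), quality-dependent
substitution rates (default the Phred-implied $10^{-q/10}$, i.e.
$10^{-3}$ at q30), a per-base indel rate (default $10^{-4}$),
cross-phylum contaminant reads built to a target identity below the 0.80
band, and two-parent single-breakpoint chimeras (breakpoint ≥ 10 nt from
either end, matching the bimera test's model). Indels are applied after
substitutions at uniform positions — an arbitrary but fixed order that
keeps output byte-reproducible under a seed. Configurations whose minor
variants would fall into the contaminant identity band are rejected.
`env_config()` describes a multi-sample community with Zipf
rank-abundance ($p_r \propto r^{-\alpha}$, default $\alpha = 1.7$ over
100 taxa), plus planted prefilter-removable taxa (single-sample
occurrence, or total abundance 2). With the defaults, over half the taxa
fall below a tenth of the mean abundance — a long rare tail. (The mean is
the right yardstick here: no non-negative abundance distribution can put
half its taxa below a tenth of its own median.)

What the generator does *not* emulate: PCR amplification bias,
tag-jumping, platform-specific error motifs, taxonomically structured
sequence similarity between community members (environmental taxa are
independent random sequences), and real rRNA secondary-structure
constraints. Passing tests therefore demonstrate algorithmic
correctness under the stated error model, not performance on any real
dataset; the headline statistics of real surveys (collapse folds,
per-taxon inflation) depend on depth and taxon composition and are only
qualitatively mirrored at this scale.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
per-genome depths of 400–1000 reads, V9 length 120 nt, panels of 6–12
genomes, 12–20 amplicon taxa for the protocol comparison, 20 seeds per
recovery experiment, 100 random instances (≤ 200 unique sequences) for
the clustering oracle and 1000 random pairs for the alignment oracle.
These sizes give the recovery statistics stable values (the binomial
standard error on a 90% recovery criterion at 20 seeds is ~7 points)
while keeping a full run in minutes.

## Known limitations

- E-values are not computed anywhere; best-hit semantics are by identity.
  At V9 scale identity ranking is the operative criterion.
- Primer location allows substitutions only (no indels in the primer
  site), and locates primers per sequence rather than on group
  alignments; for extraction purposes the outcome is equivalent and the
  tool dependency disappears.
- The V9 interval is defined exclusive of both primer footprints
  (configurable in principle by wrapping the extracted interval).
- Merging of read pairs is best-ungapped-overlap with explicit
  parameters, not a reimplementation of any specific merger's scoring.
- `compare_protocols()` takes reads already grouped by taxon; on real
  data the grouping would come from `annotate()` best hits.
- Same-phylum contamination inside the 80%/90% identity bands is
  invisible to the rules, by construction.
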