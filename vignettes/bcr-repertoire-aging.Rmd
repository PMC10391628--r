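---
title: "Methods: BCR repertoire metrics across aging and dietary restriction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BCR repertoire metrics across aging and dietary restriction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcraging)
```

This vignette documents the models, conventions and design choices behind
`bcraging`: what each repertoire statistic assumes, which parameters
matter and why their defaults were chosen, what the synthetic cohort
generator does and does not emulate, and the numerical decisions a reader
would otherwise have to reverse-engineer from the code.

## Clone inference

A clone is the set of sequences descending from one naive B cell. Two
definitions are implemented, and every report records the mode used:

* **Identity mode (default).** Records share a clone iff their (V gene,
  J gene, junction amino-acid sequence) triples are equal. Gene calls are
  compared at gene level: allele suffixes (`*01`) are stripped and, when a
  caller reports multiple comma-separated candidates, the first is used —
  deterministic and the common practice. Clone ids are the triple itself,
  so they are stable across runs without any hashing scheme.
* **Threshold mode.** Within each (V gene, J gene, junction length) group,
  junction nucleotide sequences are clustered by single linkage and cut at
  a normalized Hamming distance threshold. The sample-specific threshold
  is detected from the distance-to-nearest distribution: a Gaussian kernel
  density (`stats::density`, default bandwidth, 512 grid points) is fitted
  and the location of the density minimum between the two largest modes is
  returned. A unimodal or degenerate distribution falls back to a
  configured default of 0.1 — roughly the spacing that separates
  within-clone hypermutation from between-clone junction differences in
  murine heavy chains — and flags the result. Threshold detection requires
  at least 50 finite distances; below that the identity rule is the
  recommended mode.

Records with an empty junction are excluded (with their ids reported), and
clone sizes count distinct records by default. Whether published analyses
weight clones by UMI consensus counts is usually unstated; both weightings
are supported (`by = "consensus_count"`), and the default of counting
records was chosen because consensus counts mix biology with amplification
depth.

## Diversity

Hill numbers unify the common diversity indices: for clone frequencies
$p_i$ and order $q \ge 0$,

$$ {}^qD = \Big( \sum_i p_i^q \Big)^{1/(1-q)}, \qquad
   {}^1D = \exp\Big(-\sum_i p_i \log p_i\Big), $$

with the $q = 1$ case evaluated as the entropy limit whenever
$|q - 1| < 10^{-9}$. Shannon and Simpson diversity are reported on the
Hill scale (effective clone numbers), which makes them comparable across
orders; the raw indices are available via `as_index = TRUE`.

Diversity is never compared at unequal sequencing depth: samples are
subsampled without replacement to a uniform depth (by default the minimum
sample size within each tissue, computed once per run) and the spectrum is
averaged over bootstrap subsamples with a percentile band. The published
depth and bootstrap counts for this kind of analysis are typically not
printed; the defaults here (`depth = min sample size`, `n_boot = 200` for
the standalone function, 100 in the pipeline config) are documented
choices, and both are recorded in every output row.

P20 — the clonal-expansion statistic — is the summed relative frequency of
the 20 largest clones, with rank ties at the boundary broken
deterministically by clone id so that repeated runs agree. A repertoire
with at most 20 clones has P20 = 1 by construction.

## Repertoire dissimilarity (RDI)

The RDI between two repertoires is computed by the five-step procedure:
subsample each repertoire to a common depth, count V/D/J gene-segment
usage over a fixed shared feature space, normalize, take the Euclidean
distance, and average over 100 repeats. Two details are under-specified in
most descriptions and resolved here explicitly:

* **Normalization.** The default normalizes each segment block (V, D, J)
  to proportions separately, so no segment dominates by gene count. The
  log-scale variant of the original RDI implementation
  (`log2(count + 0.5)`, block-centred) is available as
  `normalization = "log"`; the choice is recorded in the output metadata.
* **Missing D calls.** Sequences without an identifiable D segment
  contribute no D feature; the D block is computed over called-D records
  and renormalized, which avoids a spurious "no-D" feature dominating the
  distance.

The matrix routine draws one subsample per sample per repeat and computes
all pairwise distances within the repeat (the scheme of the original RDI
tool); the standalone pair routine subsamples each argument independently
with streams keyed by sample-id order, making it symmetric under a shared
seed. Both estimate the same expectation. Whether published analyses used
V+D+J jointly or V and J only is typically unstated; the feature set is
configurable and defaults to V+D+J.

For correlation analyses a per-sample covariate is needed, while RDI is a
pairwise quantity; the reconstruction used here is the mean RDI of each
sample to all other samples of its diet × age group.

## Somatic hypermutation and class-switch staging

Mutations are counted on the aligned observed/germline pair, excluding the
junction span (junction identity defines clones, and CDR3 properties are
analysed separately). A position is *informative* when both strings carry
an unambiguous base (`A/C/G/T`; gaps `.`/`-` and `N` are excluded) and its
germline codon is fully resolved. Each mismatch is classified by
translating the germline codon with and without the substitution, other
codon positions taken from the germline — the standard single-substitution
approximation; when several mutations hit one codon each changed position
is classified independently against the germline context, a documented
limitation. Substitutions creating a stop codon alter the amino acid and
count as non-synonymous. Frequencies are mutations per informative
position. Both per-sequence means and per-clone aggregates are emitted,
since either could be the published aggregation.

Clones are staged by member isotypes and mutation load: any IgM or IgD
member makes a clone `IgM+IgD+`, split into `SHM−` versus `SHM+` by
whether any member carries at least `shm_min_mutations` mutations
(default 1 — no published threshold exists, and a single observed mutation
is the weakest evidence of hypermutation activity); clones with no naive
isotypes are `IgM−IgD−` (post-antigenic). CDR3 length statistics are a
Gaussian fit to junction amino-acid lengths (sample mean, n−1 standard
deviation, convention recorded), plus the standard deviation of per-mouse
means within each group as the between-replicate variability.

## Morbidity

The macromorbidity index is the neoplasia grade (0 = no tumors, 1 = one
affected organ, 2 = two or more) plus one point per non-neoplastic
macroscopic finding from a closed vocabulary of seven labels (bad
habitus/kyphosis, enlarged spleen, WAT discoloration, knotty/granular
pancreas, uterine cysts, enlarged kidneys, enlarged adrenal glands).
Findings are counted at label level, so bilateral organs (kidneys,
adrenals) count once — the conservative reading of a label-based score.
The vocabulary is a function argument for other study designs.

## Statistical layer

* Per-diet ordinary least squares of each metric on age (two-sided slope
  test), requiring at least three points over two distinct ages.
* Two-way fixed-effects ANOVA with interaction, age and diet as factors,
  per diet pair; empty cells are an error naming the cell.
* Mann-Whitney U per time point and diet pair: exact when both groups have
  at most 8 values — mandatory fidelity for the n = 5 design, where the
  smallest attainable two-sided p is 2/252 ≈ 0.0079 — and the normal
  approximation otherwise.
* Spearman correlation (mid-rank ties, asymptotic p) of every metric
  against macromorbidity, neoplasia grade and non-neoplastic burden
  separately. Constant metrics or outcomes are flagged undefined and
  excluded from the multiple-testing family.

Bonferroni families are a genuine modelling choice with no universal
convention: correlations are corrected within each tissue × outcome panel,
and timepoint tests within each tissue across all metric × age × diet-pair
tests; the scope is a config key and is written into the output. Because
"variance explained" can mean either Spearman ρ² or a regression R², both
are emitted and neither is privileged.

## The synthetic cohort generator

The generator produces AIRR tables, a germline reference, a cohort design
and pathology records with the statistical structure the analysis assumes,
plus the full ground truth (clone partition, clone weights, usage vectors,
planted mutation counts, morbidity drivers). It emulates:

* **Age- and diet-dependent clonal expansion.** Clone weights are
  symmetric-Dirichlet with per-clone concentration
  $\alpha(\mathrm{age}) = \alpha_0 \exp(-E(\mathrm{age}))$, where the
  exposure $E$ accrues per month of life from 3 months at a diet-specific
  rate. A diet switch at 16 months accrues at the AL rate before and the
  DR rate after the switch — attenuation of further skew accrual, the
  simplest mechanistic reading of a mid-life intervention. One parameter
  per diet thus maps directly onto "expansion increases with age, faster
  under AL".
* **Per-mouse usage idiosyncrasy.** Each sample's V/D/J usage vector is
  drawn from a Dirichlet centred on a fixed population vector (geometric
  decay over genes) with precision decaying over age by the same exposure
  construction. Shrinking precision makes individual repertoires drift
  apart with age, producing the within-group RDI growth without bespoke
  machinery. Note that clonal expansion itself also drives usage apart —
  a few large clones dominate the gene counts — which is precisely the
  mechanism the RDI is meant to detect; the dedicated usage test in the
  suite therefore switches expansion off to isolate the idiosyncrasy
  parameter.
* **Tissue-specific isotype composition**, spleen IgM-dominant
  (0.61/0.23/0.13/0.02/0.01 for IgM/IgG/IgA/IgD/IgE) and ileum
  IgA-dominant (0.89 IgA).
* **Planted SHM** outside the junction at isotype-dependent rates
  (defaults: IgM 2, IgD 1, IgG 8, IgE 6, IgA 10 expected mutations per
  sequence — naive-compartment isotypes low, switched isotypes high), each
  substitution recorded as synonymous or non-synonymous against the codon
  table at planting time. Because the junction is never mutated by
  default, the identity clone rule recovers the planted partition exactly
  (Rand index 1), which the suite asserts; a separate junction-mutation
  switch exists to exercise threshold mode.
* **Morbidity coupling.** A latent score,
  coupling × standardized planted expansion + Gaussian noise, is mapped
  monotonically to a tumor-organ count and a finding burden. Zero coupling
  gives null correlations; the coupling sign flips the correlation sign.

Sequences are a concatenation of the full germline V, a clone-specific
in-frame junction (Cys...Trp, 8–24 amino acids), and a germline J; V and J
genes are built from sense codons so germline translation is clean and the
frame offset is 0 throughout. Effect-size defaults are **illustrative, not
estimates**: no quantitative slopes are published for this design, so
$\alpha_0 = 2$ with AL slope 0.25 and DR slope 0.21 per month were chosen
once so that the simulated top-20 clone share at 24 months lands near 0.8
(AL) and 0.6 (DR), the qualitative anchors reported for aging murine
spleen, with usage-precision defaults ($\kappa_0 = 200$, AL 0.15, DR 0.08
per month) chosen analogously for a clear dissimilarity trend.

What the generator does **not** emulate: sequencing error, chimeras, UMI
structure, insertions/deletions or IMGT gap structure in alignments,
lineage trees within clones, biologically realistic V–D–J junction overlap
(the junction is synthesized independently of the D pool), shared clones
across mice, or isotype–clone coherence (isotypes are drawn per sequence).
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated generative assumptions, not robustness to
annotation error or alignment artefacts in real AIRR data.

## Numerical choices and degenerate inputs

* Hill computation drops zero-abundance clones before normalizing; an
  all-zero vector is an error, a single clone gives $^qD = 1$ for all q.
* Rank ties (P20 boundary, threshold-mode component labels) are broken by
  lexicographic clone id / smallest member junction — reproducibility over
  elegance.
* `cutree` at height threshold + 1e-12 guards floating-point equality at
  the single-linkage cut.
* Dirichlet draws at extreme concentration can underflow to an all-zero
  gamma vector; the generator then falls back to a single random atom
  (one-clone repertoire), the correct limit of the model.
* Subsampled usage counts are exactly invariant to record order only at
  full depth; matrices at partial depth are order-sensitive through the
  subsample indices, which is why all randomized stages take explicit
  seeds. The pipeline expands its master seed into per-stage offsets so
  changing one stage's replication count leaves other stages' draws
  untouched.
* Reading rearrangement tables enforces the structural invariants
  (equal-length alignments, consensus count ≥ 1, in-frame junctions for
  productive rows) by dropping offending rows with their line numbers —
  malformed rows in, clean records out. Duplicate-junction collapsing
  exists behind a flag and defaults to off, since whether published
  pipelines collapsed duplicates is unstated.

## Verification problem sizes

The test suite verifies each statistic against independent oracles (brute
force, closed form, enumeration, or Monte-Carlo) on deliberately small
problems: 100–200 sequence samples for clone-assignment oracles, 500-clone
repertoires for sampling-noise checks, 500 replicates for null
calibration, and 100 replicated two-diet cohorts of 1000 sequences over
500 clones per sample (hypermutation off, since the tested signature does
not involve it) for effect-sign recovery. These sizes were chosen as the
smallest at which the planted effects clearly dominate sampling noise; the
end-to-end check runs the default 45-sample × 5000-sequence cohort.
Null-calibration note: the exact Mann-Whitney test at n = 5 versus 5 is
discrete, and its attainable type-I level at α = 0.05 is 8/252 ≈ 0.032 —
conservative by construction, which the calibration check accounts for.

## Known limitations

* No lineage-tree reconstruction within clones and no cross-sample clone
  tracking; no asymptotic richness estimators (rarefied Hill numbers
  only); no selection-strength or mutation-targeting models.
* The single-substitution SHM approximation misclassifies multi-hit codons
  whose joint effect differs from the sum of per-position effects.
* Usage vectors are drawn per sample, not per mouse, so the generator does
  not model within-mouse correlation across tissues.
* The identity clone rule treats allelic variation as noise (alleles are
  stripped); novel-allele discovery is out of scope.
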