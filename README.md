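# bcraging

Analysis toolkit for B-cell-receptor (BCR) heavy-chain repertoires across
aging and dietary-intervention cohorts, with a fully synthetic cohort
generator that makes every stage testable without sequencing data.

## The scientific problem

Aging skews the B cell compartment: a few clones expand, rare clones are
lost, and repertoires of different individuals drift apart. Dietary
restriction (DR) is the classic intervention that slows many aging
phenotypes, and repertoire sequencing of DR versus ad-libitum (AL) fed mice
asks whether it also preserves antibody diversity. Answering that requires
a chain of repertoire statistics, each with small conventions that matter:

- **Clonal inference.** Two sequences belong to the same clone when they
  use the same IghV gene, the same IghJ gene, and have identical CDR3
  amino-acid sequences (identity mode). A distance-based alternative
  performs single-linkage clustering of junction nucleotide sequences
  within V/J/length groups at a sample-specific threshold detected from the
  distance-to-nearest distribution.
- **Hill diversity spectra.** For clone frequencies `p_i`, the Hill number
  of order `q` is `qD = (Σ p_i^q)^(1/(1−q))`, with `q → 1` evaluated as
  `exp(−Σ p_i log p_i)`. `0D` is richness, `1D` exponential Shannon
  entropy (sensitive to rare clones), `2D` inverse Simpson concentration
  (sensitive to large clones). Spectra are computed at uniform subsampling
  depth with a bootstrap band.
- **Clonal expansion (P20).** The summed relative frequency of the 20
  largest clones.
- **Repertoire dissimilarity index (RDI).** Repertoires are subsampled to a
  common depth, V/D/J gene-segment usage is counted over a fixed feature
  space, normalized, and compared pairwise by Euclidean distance; the
  procedure repeats 100 times and reports the mean.
- **Somatic hypermutation (SHM).** Mismatches between each sequence and its
  inferred germline (outside the junction) are classified as synonymous or
  non-synonymous by translating the germline codon with and without the
  substitution.
- **Class-switch staging.** Clones are staged as `IgM+IgD+SHM−` (naive),
  `IgM+IgD+SHM+` (antigen stimulated), or `IgM−IgD−` (post-antigenic).
- **Macromorbidity index.** Per mouse, a neoplasia grade (0 = no tumors,
  1 = one organ affected, 2 = two or more) plus one point per macroscopic
  non-neoplastic finding at necropsy.
- **Cohort statistics.** Per-diet linear regression of each metric over
  age, two-way ANOVA (age × diet) per diet pair, exact Mann-Whitney U
  tests at each time point with Bonferroni correction, and Spearman
  correlation of every metric with the morbidity outcomes.

The package reads and writes AIRR-standard rearrangement TSVs and ships a
synthetic cohort generator (`cohort_spec()`, `generate_cohort()`) whose
planted ground truth — clone partitions, usage vectors, mutation counts,
morbidity coupling — exercises the full pipeline end to end.

## Worked example

```r
library(bcraging)

spec <- cohort_spec(ages = c(16, 20, 24), diets = c("AL", "DR"),
                    tissues = "spleen", seqs_per_sample = 2000,
                    n_clones_base = 800, seed = 42)
cohort <- generate_cohort(spec)
samples <- split_samples(cohort$records[cohort$records$productive, ])

parts <- lapply(samples, assign_clones_identity)
shannon <- sapply(parts, function(p) hill_number(clone_abundances(p), 1))
p20s <- sapply(parts, function(p) p20(p)$p20)

design <- cohort$design
round(tapply(shannon[design$sample_id], paste(design$diet, design$age_months), mean), 1)
#> AL 16 AL 20 AL 24 DR 16 DR 20 DR 24
#>  92.3  41.6  16.1 140.0  63.9  40.9
round(tapply(p20s[design$sample_id], paste(design$diet, design$age_months), mean), 3)
#> AL 16 AL 20 AL 24 DR 16 DR 20 DR 24
#> 0.478 0.720 0.954 0.363 0.589 0.721
```

Shannon diversity (`1D`, in effective clones) declines with age under both
diets but stays higher under DR, while the top-20 clone share (P20) grows
faster under AL — the planted aging signature. The diet contrast at the
final age is an exact Mann-Whitney test, and expansion tracks the planted
morbidity coupling:

```r
old <- design$age_months == 24
timepoint_test(shannon[design$sample_id[old & design$diet == "AL"]],
               shannon[design$sample_id[old & design$diet == "DR"]])$p
#> [1] 0.007936508

morb <- macromorbidity(cohort$pathology)
mm <- morb$macromorbidity[match(design$mouse_id, morb$mouse_id)]
cor(p20s[design$sample_id], mm, method = "spearman")
#> [1] 0.8847521
```

`run_pipeline(run_config(seed = 1), "out/")` runs every stage (clones,
diversity, P20, RDI, SHM/CSR/CDR3, morbidity, statistics) and writes all
report tables plus a manifest; a thin command-line wrapper lives at
`inst/scripts/bcr_pipeline.R`.

## Layout

- `R/` — I/O (`airr-io.R`), generator (`synthetic-cohort.R`), clone
  inference (`clones.R`), diversity (`diversity.R`), RDI (`rdi.R`),
  maturation profiling (`maturation.R`), morbidity (`morbidity.R`),
  statistics (`statistics.R`), orchestration (`pipeline.R`).
- `vignettes/bcr-repertoire-aging.Rmd` — the methods vignette: model
  assumptions, parameter conventions, numerical choices, limitations.
- `tests/testthat/` — unit, property and acceptance suites.
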