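---
title: "Methods: predicting and validating position effects of 22q13 deletions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting and validating position effects of 22q13 deletions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadpose)
```

## The problem

Phelan-McDermid syndrome (PMS) is caused by heterozygous 22q13.3
deletions — most often terminal, spanning anywhere from under 100 kb to
over 8 Mb — or by *SHANK3* variants. Deletion size correlates only
loosely with clinical severity, which motivates the hypothesis that
genes *outside* the deleted segment contribute to the phenotype through
**position effects**: a deletion that removes a gene's enhancers, or
tears through the topologically associating domain (TAD) the gene sits
in, can dysregulate the gene even though both copies remain intact.

`tadpose` implements that analysis as a reusable, tested pipeline with
three validation arms:

1. **Candidate prediction** — rank genes near a deletion by regulatory
   disruption evidence;
2. **qPCR validation** — classify relative expression with the
   2^-ΔΔCt^ statistic;
3. **Metabolic validation** — per-well significance calling on Biolog
   PM-M phenotype-microarray plates against a healthy-control panel.

A seeded synthetic-data generator emulates every input so that the
whole pipeline is testable end to end without patient data.

## Coordinate model

All positions are stored 1-based exactly as printed in clinical tables;
intersection uses half-open `[start, end)` semantics and interval length
is `end - start`. This is a deliberate, load-bearing choice: it is the
convention under which the printed breakpoints reproduce every printed
deletion size exactly (e.g. `51244566 - 42740931 = 8503635` bp =
8.503635 Mb), and it makes adjacent intervals non-overlapping, which in
turn gives clean boundary rules everywhere else (a breakpoint exactly on
a TAD edge disrupts nothing; a gene ending where a deletion starts is
preserved). BED input is converted from its 0-based half-open convention
on read.

A gene is `deleted` when fully contained in the deletion,
`partially_deleted` when it overlaps a breakpoint, `within_window` when
disjoint but within the flanking window, `distal` otherwise. The
`partially_deleted` status exists because the smallest validation
deletion removes only the major part of *SHANK3*; downstream logic
treats it like `deleted` when partitioning candidates, because one
allele is still disrupted.

Deletion size classes (Small/Mid/Large) are an explicitly arbitrary
stratification; the defaults (5 Mb and 8 Mb, upper cutoff inclusive)
reproduce the labels of the five validation deletions and are fully
configurable.

## Candidate prediction

For one patient, every gene that is deleted, breakpoint-overlapping, or
within the flanking window (default 2 Mb on each side of a breakpoint;
terminal deletions have only a proximal flank) receives a feature row:

* `in_disrupted_tad` — the gene overlaps a TAD containing a breakpoint
  strictly in its interior;
* `disrupted_contacts` — how many of the gene's regulatory contacts
  have their element inside the deletion (only counted for preserved
  genes: a deleted gene's contacts are not position-effect evidence);
* `hi_flag` — haploinsufficiency percentage at or below 10. Missing HI
  scores are propagated as missing and never imputed, so a gene without
  a score simply cannot earn this flag;
* `phenotype_percentile` — percentile of the Jaccard overlap between
  the gene's phenotype terms and the patient's clinical terms, computed
  within that patient's search space (the non-distal genes).

Candidate classes follow two rules. A deleted or partially deleted gene
is a **deletion candidate** when it is phenotypically relevant (HI flag,
or phenotype percentile above the 75th-percentile gate) — deletion alone
is not enough, because the point of the gate is to select genes whose
loss plausibly explains the phenotype. A preserved gene is a
**position-effect candidate** when it is within the window *and* has
mechanistic evidence (disrupted TAD or at least one disrupted contact).
Whether the window and TAD criteria combine with AND or OR is not
something the source analysis pins down; AND is the default and OR is
available (`tad_window_rule` in `pe_params()`).

The ranking criteria are published as a list, not a formula, so the
package uses an explicit additive score for reproducibility:

```
rank = w1 * min(contacts, cap)/cap + w2 * [disrupted TAD]
     + w3 * [within window]       + w4 * [HI flag]
     + w5 * [phenotype percentile > gate]
```

with all weights 1 and `cap = 5` by default, everything configurable.
Ties are broken deterministically by distance to the nearest breakpoint,
then symbol, so ranked output is bit-reproducible.

Phenotype overlap is a plain Jaccard index over term sets. The source
analysis organised clinical features as ICD-10 codes without defining an
overlap metric; set overlap is the documented stand-in, and no ontology
traversal or semantic similarity is attempted.

```{r predict-demo}
locus <- gen_locus(n_genes = 30, seed = 1)
cohort <- gen_cohort(1, seed = 2)
terms <- sample(locus$vocab, 8)
head(predict_candidates(cohort[1, ], locus$annotation, locus$tads,
                        locus$contacts, terms), 4)
```

## qPCR relative expression

Ct values are replicate-averaged on the Ct scale (the fold-scale
alternative is exposed as an option), normalised to the housekeeping
gene TBP within each sample, and referenced to the mean ΔCt of the
pooled control samples (two controls pooled by averaging; per-sex
matching is not attempted because nothing describes it). The statistic
is `2^-ΔΔCt`, and categories use the printed inclusive thresholds: fold
≥ 1.5 elevated, ≤ 0.66 decreased. Genes with no blood expression
(*FBLN1*, *SHANK3*, *SCO2* in the fixture panel) carry
`expressed_in_blood = FALSE` and are excluded from the Ct pipeline.

The status-stratified summary reports, per gene, the mean fold over
samples where the gene was not deleted, deleted, and within the window —
the shape of the published summary table. The published "not deleted"
average for one gene (2.71 for *A4GALT*) differs slightly from the mean
of its printed per-patient values; the pipeline computes the arithmetic
mean of its inputs and does not attempt to reproduce that one cell.

No amplification-efficiency correction, standard curves, or
outlier-replicate rejection is performed.

## Biolog PM-M plates

Per well the pipeline computes the endpoint relative absorbance
(A~590~ − A~750~) or, optionally, a kinetic parameter from the 96-point
optical-density series (15-minute sampling over 24 h): maximum sliding
1-hour least-squares slope, final endpoint, or trapezoid area under the
curve. Values are normalised by subtracting the per-well mean of the
empty-plate triplicates, floored at ε = 10⁻⁶ (flooring rather than
dropping keeps all 96 wells in every summary), and log₁₀-transformed
with the same ε offset.

Each well is then tested with a two-sided Mann-Whitney U test of the
focal sample's replicate values against the 50-line control panel,
exact when `min(n) ≤ 8` with no ties, normal approximation with
tie/continuity correction otherwise; significance is `p ≤ 0.05` raw by
default, with optional Benjamini-Hochberg adjustment per plate. The
direction of utilisation is the sign of the median difference on the
normalised scale (medians are rank-consistent with the test).

The unit of replication on the sample side is deliberately strict:
the per-well test requires at least two sample-side replicate values,
and single-replicate input is rejected loudly rather than silently
tested, because the original description never states what constituted
the sample-side observations.

## Synthetic data: what it emulates, and what it does not

* `gen_locus()` — non-overlapping genes over a synthetic chromosome
  arm, TADs partitioning a prefix, contacts within 2 Mb of their gene,
  HI percentages with a configurable ≤ 10% fraction. It emulates the
  *geometry* of a real locus, not real Hi-C contact matrices or real
  DECIPHER score distributions.
* `gen_cohort()` — terminal deletions sharing the chromosome end, with
  sizes spanning 0.1–8.5 Mb by default, the span of the five validation
  deletions.
* `gen_ct_table()` — `Ct = baseline − log2(expression) + N(0, σ)` with
  σ = 0.2 cycles by default; deleted genes at 0.5× (one lost allele, no
  compensation), planted position-effect genes at their true folds, and
  a "compensated" option that reproduces the pattern of an enzyme whose
  remaining allele up-regulates (elevated regardless of deletion).
* `gen_plate_data()` — logistic NADH curves
  `OD(t) = baseline + A/(1 + e^{−k(t−t₀)}) + noise`, 96 points over
  24 h; line-level amplitude noise of SD 0.1, well effects expressed in
  those SD units; empty plates are baseline plus noise in triplicate.

Passing tests on these generators shows the pipeline recovers known
signals under idealised noise models (Gaussian Ct noise, logistic
growth, exchangeable control lines). It does not show robustness to
plate-edge artefacts, batch effects across plates, amplification
efficiency differences, or breakpoint complexity — none of which are
modelled.

`plant_position_effects()` makes planted genes detectable by
construction: it prefers genes inside the disrupted TAD, gives them
five contacts crossing into the deletion, and aligns most of their
phenotype terms with the patient's. That is the intended use — a
positive control with known truth — not a statement about effect sizes
in real cohorts.

## Numerical and design choices

* Exact Mann-Whitney when `min(n) ≤ 8` without ties; the sample-size
  design for the null-calibration tests (5 replicates vs 50 controls)
  was chosen from the exact null distribution, which attains size
  0.0494 at α = 0.05.
* Percentiles use strict-below counting scaled by `n − 1`, so a
  5-score space maps to 0/25/50/75/100 and ties share a value; a
  single-element space is percentile 100.
* Plate percentages recompute as `round(100·k/n, 1)` and print with one
  decimal, except an exact 100 prints as `100%`, matching the published
  rendering style.
* HI ≤ 10% is a ranking feature, never a hard filter: most published
  candidates have HI above 10%.
* Degenerate inputs: zero-length intervals overlap nothing; empty
  annotation yields an empty candidate list; all-tied well values give
  p = 1 and direction `none`; empty summary groups are `NA`, not 0.
* Test and acceptance simulations use 30–50-gene loci, 40–200 seeded
  replicates, and 5,000–10,000 null wells — sizes chosen so the full
  statistical battery runs in a few minutes on one core while keeping
  Monte-Carlo error well inside the asserted margins.

## Known limitations

TADs and contacts are inputs; the package does not call TADs from Hi-C
or re-derive the upstream prediction algorithm's internal scoring. No
liftover between assemblies is provided: coordinates must arrive on one
build. Ring chromosomes and translocations are out of scope (deletions
only, terminal or interstitial). Microarray breakpoints are treated as
exact interval endpoints, though real breakpoints are only bounded by
probe resolution.
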