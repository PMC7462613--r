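---
title: "Scoring and structural inference for binned sort-seq variant screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and structural inference for binned sort-seq variant screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortscreen)
```

## The experiment this package models

In a binned-sort (sort-seq) screen of protein variants, a barcoded
site-saturation library is expressed one-variant-per-cell, cells are sorted
by FACS into four quartile bins on a quantitative fluorescence readout
(steady-state abundance via a GFP fusion, or enzymatic activity via a
reporter), and each bin is deeply sequenced. A variant's distribution across
bins estimates its phenotype. Two control classes anchor the measurement
scale: synonymous variants encode the wild-type protein and behave like it,
while nonsense variants truncate the protein and mark complete loss.

`sortscreen` implements the full desk-side analysis: subassembly consensus
calling that links barcodes to variants, per-bin barcode counting with
quality filtering, scoring, classification, and the downstream structural
analyses (transmembrane-topology profiles, positional clustering,
specific-activity active-site calling, couplings-based secondary-structure
calls). A generative model of the experiment makes every stage testable
without access to raw sequencing data.

## The score model

For variant $v$ in replicate $r$, with read counts $c_{rbv}$ in bins
$b = 1..4$, frequencies are $f_{rbv} = c_{rbv} / \sum_{v'} c_{rbv'}$. Two
filters remove noise-dominated variants: a variant is kept in a replicate if
its total frequency $\sum_b f_{rbv} \ge F_{freq}$ (default $10^{-4}$,
applied to the bin-summed total; the per-variant weighted mean below is
scale-free, so this choice affects only the filter), and kept overall if it
passes in at least $F_{expt}$ replicates (default 2). The replicate-level
statistic is the bin-weighted mean

$$w_{rv} = \frac{\sum_b \omega_b f_{rbv}}{\sum_b f_{rbv}},
  \qquad \omega = (0.25, 0.5, 0.75, 1),$$

which lies in $[0.25, 1]$ and increases whenever count mass moves to a
higher bin (both facts are property-tested). Each replicate is min–max
normalized to its control medians,

$$s_{rv} = \frac{w_{rv} - \tilde{w}^{non}_r}{\tilde{w}^{syn}_r -
  \tilde{w}^{non}_r},$$

so the replicate's nonsense median maps to 0 and its synonymous median to 1
exactly. Final scores average $s_{rv}$ over included replicates; SD uses the
$n-1$ denominator, $SE = SD/\sqrt{n}$, and the 95% interval is
$\bar{s} \pm 1.96\,SE$.

**Final re-anchoring.** Averaging per-replicate-normalized scores leaves the
*aggregate* control medians only approximately at 0 and 1. Because the
published description of the score scale states the anchors exactly (and
downstream thresholds are interpreted on that scale), `score_variants()`
applies one further affine map to the aggregated means so the aggregate
nonsense/synonymous medians are exactly 0 and 1, rescaling SD, SE and CI by
the same factor. `final_normalize = FALSE` disables this and reproduces the
bare average.

## Classification

Thresholds come from the synonymous score distribution: $t_{low}$ and
$t_{high}$ are its 5th and 95th percentiles (linear interpolation). The
five-way call uses both the score and its confidence interval, in order:
*low* (score and CI upper bound below $t_{low}$), *possibly low* (score
below $t_{low}$ only), *high* (score above $t_{high}$ with CI lower bound at
or above $t_{low}$ — deliberately the **lower** threshold, following the
source description literally), *WT-like* (CI lower bound at or above
$t_{low}$), else *possibly WT-like*. Boundary ties resolve toward the
WT-like side (the rules use strict "below"). Thresholds are computed
separately for abundance and activity datasets.

## Topology profiles

Charge is poorly tolerated inside membrane-embedded helices, so a sliding
mean of charged-substitution scores dips sharply over transmembrane
segments while an aliphatic-substitution profile does not.
`windowed_profile()` pools, for center $p$, all qualifying substitution
scores at positions $p-4..p+5$ (width 10, right-heavy centering — the
common rolling-mean convention for even windows; the source states only
"center alignment"). Pooling is variant-level, not a mean of per-position
means. Synonymous rows are excluded even when their unchanged residue
belongs to the class: they are not substitutions, and their WT-like scores
would mask the signal. `call_low_regions()` then reports maximal runs of
centers below a cutoff; the cutoff is an explicit tool parameter (the
figures it emulates identify minima visually), with 0.2 — the nonsense
anchor plus a margin — a sensible default on the normalized scale.

## Positional analyses

`cluster_positions()` clusters positions by their substitution-score
vectors with complete-linkage agglomerative clustering on Euclidean
distances, cut at $k = 4$ groups. Missing scores are handled
pairwise-complete, scaling squared distances by
$n_{total}/n_{shared}$ — the convention of `stats::dist`, verified in the
tests against the explicit formula and against a naive $O(n^3)$
linkage oracle. A position pair sharing no scored substitution has no
defined distance and is reported as an error.

Specific activity asks where variants lose function without losing protein:
abundance and activity scores are each min–max rescaled to $[0,1]$ over
*all* scored variants of the dataset (including controls — this makes the
rescaling sensitive to single extreme variants, which is why it is
documented), and the per-variant ratio rescaled activity / rescaled
abundance is formed, guarded by $\varepsilon = 10^{-6}$ on the denominator
(undefined ratios carry a reason rather than a value; the source is silent
on the variant whose rescaled abundance is exactly 0). Positions are ranked
by their median ratio; those at or below the 12.5th percentile with at
least four activity-scored variants are called functionally constrained.
The quantile is computed before the variant-count filter (matching the
order of the published description); `filter_first = TRUE` gives the
alternative. Here `n_activity_variants` counts variants scored in *both*
assays, since the ratio needs both.

## Secondary structure from couplings

Given a symmetric residue-pair coupling-strength matrix, local helix
propensity at residue $i$ is scored as $C(i,i+3) + C(i,i+4)$ and strand
propensity as $C(i,i+2)$. The offset sets are configurable because the
published cutoffs (1.5 for helices, 0.75 for strands) only have meaning
relative to a stated summation rule, which the source does not spell out;
these offsets are the canonical local-contact separations. Calls require at
least two consecutive residues above the cutoff, are extended by one
residue per side, and must reach length four; segments of one class that
touch after extension are merged so calls stay disjoint. Overlap with a
reference annotation is scored with a hypergeometric upper-tail test
(`P(X ≥ overlap)`), verified in the tests against exhaustive enumeration.

## The generative model

`simulate_sortseq()` emulates the experiment so the pipeline can be tested
end to end:

* **Library.** A random coding reference (no internal stops) over residues
  2–163; per position a configurable number of missense variants (default
  3, ≈550 variants total with 40 synonymous and 25 nonsense controls);
  18-nt barcodes per variant with shifted-Poisson multiplicity (mean 3);
  per-barcode Gamma weights (shape 2) give a Dirichlet-skewed library drawn
  once and shared across replicates.
* **True effects.** Missense abundance comes from a three-component mixture
  — WT-like $N(1, 0.08)$, intermediate $N(0.5, 0.12)$, low $N(0.02, 0.05)$
  — with loop weights (0.60, 0.20, 0.20) and transmembrane weights
  (0.30, 0.35, 0.35), reproducing the trimodal score distribution of a
  membrane protein. Charged and proline substitutions inside a
  transmembrane segment, or within two flanking residues of one (the
  membrane-interface region, where charge is still penalized), fall in the
  low component with probability 0.95. Synonymous truth is $N(1, 0.08)$,
  nonsense $N(0, 0.04)$. Activity tracks abundance ($+N(0, 0.08)$) except
  at designated active-site positions (default eight residues in the large
  lumenal loop), whose missense variants get activity $N(0.05, 0.04)$ with
  abundance drawn normally; these positions are guaranteed at least five
  missense variants so the ≥4-variant rule downstream can operate.
* **Sorting and sequencing.** Per replicate, cells multinomial over the
  library weights; per-cell fluorescence is the true value plus
  $N(0, 0.35)$ noise (fluorescence is modeled directly on the score scale —
  a monotone identity link; the normalization removes assay units anyway);
  gates are that replicate's pooled empirical quartiles, so gates vary
  between replicates like real sorts; reads per bin are multinomial over
  barcodes at depth $10^6$. Optional FASTQ emission (constant Q37,
  configurable per-base error) exercises the counting module; at error
  rate 0 the round trip is exact.

Defaults (4 replicates, $2 \times 10^5$ cells, $10^6$ reads/bin, noise SD
0.35) describe a realistically noisy quartile sort: with them the pipeline
recovers true abundance at Spearman ρ ≥ 0.9, ≥90% of nonsense variants
classify low/possibly-low, and the designated active-site positions are
recovered at ≥80%.

What a green test does **not** establish: the generator has no PCR
jackpotting, no barcode sequencing-error clustering, no optical FACS
artifacts, no mRNA-level effects, and a monotone link between phenotype and
fluorescence — so passing tests certify the arithmetic and the statistical
machinery, not robustness to every real-data pathology. One deliberate
density choice: topology recovery ("four clearly demarcated low regions")
is tested on a simulated near-saturation library (8 missense per position),
because a width-10 window over the ≈500-variant default pools only ~8
charged scores and the threshold crossing then fragments stochastically;
the analyses this emulates likewise rest on a near-saturation dataset.

## Numerical choices and edge cases

* Medians use the midpoint-of-middle-two convention; percentiles linear
  interpolation (R type 7).
* Consensus ties at any base reject the barcode (reproducibility over
  yield); a consensus identical to the reference is rejected as
  uninformative for a mutagenesis library; both are logged distinctly.
* The quality filter applies per-base over the barcode span only (a
  whole-read option exists via `barcode_start`/`barcode_length`); barcode
  matching is exact, with unmapped barcodes reported, never rescued.
* A zero-total bin is an error naming the bin; an all-zero frequency vector
  leaves the weighted mean undefined and excludes the variant for that
  replicate; filtered variants are retained in outputs with explicit
  exclusion reasons.
* All simulator stages set their RNG state from `config$seed` plus a stage
  constant, so every artifact is reproducible bit-for-bit given the
  configuration.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, cells_sorted = 5e4, reads_per_bin = 2e5)
sim <- simulate_sortseq(cfg)
scores <- sim_scores(sim, "abundance")
classes <- classify_variants(scores)
table(classes$mut_class, classes$class)

profile <- windowed_profile(scores, aa_classes()$charged, length = 163)
call_low_regions(profile, cutoff = 0.2)

activity <- sim_scores(sim, "activity")
profiles <- position_profiles(scores, activity)
profiles$position[profiles$constrained]
```

## Known limitations

* No regression-based (log-ratio) scoring mode; only the weighted-average
  estimator.
* No read alignment or barcode-error correction; subassembly reads are
  assumed frame-registered and barcodes exact.
* Reproducing published coupling-score traces exactly requires the original
  coupling model; the summation-rule offsets here are configurable
  precisely because that rule is underdetermined.
* The curated-variant annotator consumes externally curated lists; it does
  no clinical interpretation.
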