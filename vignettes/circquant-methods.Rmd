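---
title: "Quantifying plant circRNAs against a ddPCR anchor: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plant circRNAs against a ddPCR anchor: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circquant)
library(dplyr)
```

## The problem

Circular RNAs (circRNAs) are covalently closed transcripts formed by
back-splicing, in which a downstream splice donor joins an upstream
acceptor. In bulk RNA-seq the only direct evidence for a circRNA is a
*back-spliced read* spanning that non-colinear junction, so circRNA
abundance estimation reduces to normalizing small junction-read counts
across libraries whose composition can differ drastically — in plants,
chloroplast transcripts and residual rRNA can occupy anywhere from a
percent to half of a library depending on the organ sampled. Under those
conditions the habitual total-library-size normalization confounds organ
composition with circRNA abundance.

`circquant` implements a complete comparison workflow around an absolute
anchor: droplet digital PCR (ddPCR) measurements of a panel of circRNAs,
in copies per microgram of total RNA (cp/µg). The anchor serves three
purposes: ranking candidate normalizations by their Pearson concordance
with an absolute method, locating the limit of quantification (LoQ) of the
ddPCR assay itself, and calibrating an RNA-seq detection threshold that
corresponds to that LoQ.

## Normalization models

For raw back-spliced counts $c_{ij}$ (circRNA $i$, library $j$) every
method is a per-sample linear scaling $n_{ij} = c_{ij}\,S/d_j$ with scale
constant $S$ and denominator $d_j$:

| method | $d_j$ |
|---|---|
| `library_size` | total filtered reads $T_j$ |
| `backspliced_sum` | total back-spliced reads $B_j$ |
| `size_factor` | median-of-ratios factor $f_j$ ($S$ ignored) |
| `library_size_excl` | $T_j - R_j - P_j$ (rRNA and chloroplast reads removed) |
| `backspliced_sum_excl` | back-spliced reads excluding organellar circRNAs $B'_j$ |
| `marker_gene` | raw reads on the endogenous marker *ACT2* (AT3G18780), $A_j$ |

Size factors follow the median-of-ratios construction: the reference
pseudo-sample is the per-circRNA geometric mean over samples, and
$f_j = \mathrm{median}_i \, c_{ij}/g_i$ over circRNAs with $g_i > 0$
(no zero in any sample). They are computed on the back-spliced count
matrix itself — the only matrix guaranteed to exist among this package's
inputs — with an explicit error pointing to `backspliced_sum` when the
matrix is too sparse for any row to be eligible.

Because every method is a positive per-sample scaling, three invariants
hold by construction and are enforced by tests: within one sample all six
methods induce the same rank order of circRNAs; zeros are preserved
exactly; and the scale constant $S$ (default $10^6$, the per-million
convention — published normalized values rarely state their multiplier,
and all correlation-, fold-change- and class-based results are invariant
to it) cancels from every downstream comparison.

## ddPCR quantification and the limit of quantification

Droplet digital PCR partitions a reaction into ~15,000–20,000 droplets;
target molecules land in droplets as a Poisson process, so the mean
occupancy is estimated from the negative fraction,
$\hat\lambda = -\ln\big((N - N_+)/N\big)$, and converted to cp/µg through
the droplet volume (default 0.85 nL, the QX200 convention), reaction
volume (20 µL) and RNA mass represented per reaction (default 0.05 µg:
1 µL of a 20 µL reverse-transcription reaction loaded with 1 µg of total
RNA). Both defaults are explicit arguments, since published cp/µg values
rarely pin down the exact loading.

The LoQ rule operationalizes "the replicate scatter is as large as the
signal": a (target, sample type) measurement is unreliable when its
sample standard deviation reaches its mean (CV ≥ 1), and the LoQ is the
smallest mean of any target never flagged in any sample type. At the
default loading, partition sampling alone makes one positive droplet
correspond to ≈31 cp/µg, so replicate CV crosses 1 at roughly 30–50
cp/µg — the LoQ emerges mechanically from the droplet geometry rather
than from a tuned noise parameter. Note that when the rule is applied to
a small published benchmark panel (see `benchmark_table()`), the
recovered threshold reflects only the printed targets; locating the LoQ
properly needs a panel spanning the low range, as in the simulated
five-point panel used by the tests and the acceptance script.

The RNA-seq detection threshold is calibrated by a zero-intercept least
squares fit `normalized reads = k × cp/µg` through the anchor pairs above
the LoQ (a circRNA absent from the RNA must predict zero reads), mapping
the LoQ to `k × LoQ`, rounded up at the resolution of the second
significant figure — conservative, and exact proportionality stays exact:
`k = 0.2` and LoQ 50 give a threshold of exactly 10.

## Filtering and set analyses

The candidate chain applies, in order: a minimum-support rule (total
back-spliced reads within at least one library type ≥ 2, inclusive, with
a per-replicate mode behind a flag), confirmation by a second caller as a
pure id-set intersection at exact coordinates (no fuzzy junction
matching), and the abundance rule (per-organ replicate mean ≥ the
calibrated threshold; a grand-mean mode is available since published
descriptions are ambiguous between the two). Each stage returns a filter
report with retrievable removed ids, and stages commute because both are
row selections. Replicate-reproducibility and organ-overlap analyses
enumerate all exclusive Venn regions; the genome partition recognises
organellar circRNAs by chromosome-name membership in a configurable set
(`chloroplast`, `Pt`, `ChrC`).

## Differential accumulation and classes

Pairwise organ comparisons report
$\log_2\!\big((\bar n_A + 0.5)/(\bar n_B + 0.5)\big)$ with a two-sided
Welch t-test on $\log_2(n + 0.5)$ across replicates. The source studies
rarely name their test; Welch on logs is chosen as robust to unequal
variance at $n = 4$ and exact under log-normal replicate noise, and the
pseudocount keeps fold changes finite and direction-correct at zeros. A
call requires both $|\log_2 FC| \ge 1$ and $p \le 0.05$; no multiplicity
correction is applied by default (matching the plain p ≤ 0.05 convention
of the field), with Benjamini–Hochberg behind `p_adjust = "BH"`. An
organ-specific circRNA is one whose every comparison against the other
sample types is a significant increase.

Discrete abundance classes per organ: `high` is the top
$\lceil 0.05\,n\rceil$ of detected circRNAs, `medium` the values strictly
above the 80th percentile (type-7 quantile; the strict comparison uses a
relative tolerance of $10^{-9}$ so class assignments are invariant to the
scale constant) excluding `high`, `low` the rest, `not_detected` absent
or zero. Ties break by circRNA-id order, making the partition
deterministic. Heatmap row order comes from average-linkage agglomerative
clustering of Euclidean distances on $\log_2(n+1)$.

Circular-versus-linear comparisons join circRNA abundances with their
parent genes' linear-transcript abundances. Pearson correlations
(overall and per organ) are computed on the $\log_2(n+1)$ scale on which
abundance profiles are compared; ratios are defined only where the linear
partner is detected; the enrichment flag marks circRNAs reaching 1.5×
their linear counterpart in at least one sample type; and both matrices
must declare the same normalization method, because the ratios
presuppose comparable units.

## The synthetic-data generator

`sim_config()` describes a four-organ × four-replicate study with paired
R− (rRNA-depleted) and R+ (additionally RNase R-treated) libraries. What
it emulates, and the defaults:

* **Depth and composition.** R− libraries draw 50–70M reads (mean ≈ 60M);
  R+ libraries are scaled by 0.43. rRNA fractions per organ span
  0.5–7.6% (R−) and 0.27–3.2% (R+); chloroplast fractions are large in
  green tissue (up to 40% in seedlings) and small in roots. The marker
  gene takes $5\times10^{-4}$ of informative reads.
* **Two circRNA populations.** A reproducible 5% with persistent
  per-organ concentrations — base law lognormal(log 0.025 cp/µg, sd 2.5),
  calibrated by expectation so the fraction of candidates recovered in
  all four replicates of an organ lands in the observed 1–8% band — and a
  stochastic 95% appearing in exactly one (organ, replicate), the
  simplest mechanism consistent with the tiny four-replicate
  intersections seen in practice.
* **Counts.** $c_{ij} \sim \mathrm{Poisson}(\kappa\, \mathrm{conc}\,
  D_j)$ on the effective (non-rRNA, non-chloroplast) depth $D_j$, with
  $\kappa = 2\times10^{-7}$ reads per cp/µg per read of depth, so
  composition-corrected normalized reads are ≈ 0.2 × cp/µg and the
  10-read threshold corresponds to 50 cp/µg. Poisson is the default
  (back-spliced counts are small and no dispersion estimates exist to
  anchor a negative binomial); replicate-level lognormal noise (sd 0.3,
  ≈30% CV, a standard biological-replicate dispersion) is shared between
  the R− and R+ libraries of a replicate, which derive from the same RNA.
* **RNase R.** Survivors are enriched 10× per molecule; each species
  survives with probability 0.9 (a free parameter — no quantitative loss
  rate is published), and a lost species vanishes from every R+
  replicate, modelling hydrolysis followed by exonucleolytic digestion.
* **ddPCR.** Expected occupancy inverts the cp/µg conversion; positives
  are Binomial over 15,000 droplets with lognormal biological noise
  (sd 0.15). Partition sampling dominates at low concentration, which is
  what creates the LoQ.
* **Linear counterparts.** Bivariate lognormal per organ with log-scale
  correlation `circ_linear_corr` (default 0.46); intergenic circRNAs
  (10%) get no partner.
* **Planted truth.** Organ-specific positives (default 2 per organ,
  8-fold effect, high base abundance) plus a second-caller confirmation
  set (reproducible species confirmed with probability 0.98, stochastic
  with 0.5).

What the generator does **not** emulate: read-level artefacts (no
sequences or alignments), caller-specific false junction calls, fuzzy
junction coordinates, overdispersion beyond Poisson + lognormal, and
trans-splicing reads misclassified as back-splices on the chloroplast
genome. Passing tests on synthetic data therefore demonstrate the
statistical machinery, not robustness to alignment artefacts.

## Numerical and degenerate-input choices

Sample standard deviations use the $n-1$ denominator (small $n = 4$).
Correlations against the ddPCR anchor are computed on raw means — this
reproduces the published per-organ benchmark correlations, which a log
transform would not. Welch tests on constant replicate vectors return
$p = 1$ when the groups are identical (never significant) and $p$ = `NA`
with fewer than two replicates. All-positive droplet wells raise a
saturation error rather than returning infinity. Zero denominators abort
normalization with the offending sample named. Coordinates are 1-based
fully closed everywhere; conversion to BED's 0-based half-open convention
happens only in `write_bed()`.

## Problem sizes used in the tests

The suite exercises the workflow at deliberately modest sizes chosen to
make every check exact or statistically decisive: 1000 random small
matrices for the size-factor oracle, 1000 random vector pairs for the
correlation oracle, 200 droplet round-trip trials at 15,000 droplets,
2000 null circRNAs for type-I calibration, and a 2000-species planted
end-to-end run. The acceptance script (`scripts/acceptance.R`) recomputes
the same quantities from scratch at the same sizes.

## Known limitations

The seedling stratum of the published benchmark correlates worst with
ddPCR under every normalization (≈0.75), consistent with developmentally
mixed tissue; the package reports, but cannot repair, that heterogeneity.
The LoQ rule needs a panel spanning the low range — applied to a panel of
already-abundant targets it returns the smallest reliable mean, not a
true quantification limit. Whether published "all-samples" concordance
was computed on per-replicate points rather than means is not documented;
the package computes means on both sides (3 ddPCR replicates, 4 RNA-seq
replicates), which reproduces the published values. And whether size
factors should come from circRNA or whole-gene counts is likewise
undocumented; circRNA counts are used because they always exist here.
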