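# circquant

Quantification and comparative profiling of plant circular RNAs from
back-spliced junction counts, anchored to droplet digital PCR.

## The problem

Circular RNAs (circRNAs) leave a single footprint in bulk RNA-seq: reads
spanning their back-splice junction. Comparing circRNA accumulation across
plant organs from those few junction reads is dominated by a normalization
problem — organ transcriptomes differ hugely in rRNA carry-over and
chloroplast content, so scaling by total library size confounds library
composition with biology. `circquant` is for transcriptomics researchers
who want to (i) rank candidate normalizations against an absolute
quantification anchor, (ii) derive a principled detection threshold, and
(iii) run the downstream comparative analyses (filtering, overlap sets,
differential accumulation, circular-vs-linear comparison) with a
ground-truth simulator to validate every step.

## What it computes

* **Six normalizations** of back-spliced counts *c<sub>ij</sub>*:
  n<sub>ij</sub> = c<sub>ij</sub>·S/d<sub>j</sub> with d<sub>j</sub> one of
  total reads *T<sub>j</sub>*, back-spliced sum *B<sub>j</sub>*,
  median-of-ratios size factor *f<sub>j</sub>* = median<sub>i</sub>
  c<sub>ij</sub>/g<sub>i</sub> (g<sub>i</sub> the per-circRNA geometric
  mean), composition-corrected *T<sub>j</sub> − R<sub>j</sub> −
  P<sub>j</sub>*, corrected back-spliced sum *B′<sub>j</sub>*, or marker
  gene (*ACT2*) reads *A<sub>j</sub>*.
* **ddPCR quantification**: Poisson occupancy λ = −ln((N − N₊)/N) over
  ~15,000 droplets, converted to copies per µg of input RNA; marker-gene
  normalization; a limit of quantification (LoQ) where replicate CV
  reaches 1.
* **Concordance**: Pearson correlation of normalized means against ddPCR
  means, pooled and per organ, plus calibration of the normalized-read
  threshold corresponding to the ddPCR LoQ through a zero-intercept fit.
* **Filtering & sets**: ≥2-read support, two-caller confirmation,
  abundance threshold, replicate-reproducibility Venn regions, genome
  partition and organ overlaps.
* **Differential accumulation**: Welch t on log₂(n + 0.5), two-fold +
  p ≤ 0.05 calls, percentile abundance classes with clustered ordering,
  and circular:linear transcript comparison.
* **A synthetic study generator** with known truth for every stage
  (organ-structured concentrations, R−/R+ protocol effects, droplet-level
  ddPCR, correlated linear counterparts).

## Worked example

Rank the six normalizations against the packaged eight-circRNA ddPCR
benchmark (32 target × organ pairs):

```r
library(circquant)
library(dplyr)

benchmark_concordance() |> filter(stratum == "all")
#>   method                   r n_pairs
#> 1 backspliced_sum       0.77      32
#> 2 backspliced_sum_excl  0.75      32
#> 3 library_size          0.67      32
#> 4 library_size_excl     0.76      32
#> 5 marker_gene           0.77      32
#> 6 size_factor           0.76      32
```

Library size is clearly the worst anchor-concordant choice (r = 0.67);
every composition-aware alternative reaches 0.75–0.77. Calibrating the
read threshold from anchor pairs above a 50 cp/µg LoQ:

```r
pairs <- tibble(cp_per_ug  = c(60, 80, 120, 300, 900),
                norm_reads = 0.2 * c(60, 80, 120, 300, 900))
calibrate_read_threshold(pairs, loq = 50)
#> Read-threshold calibration (zero-intercept least squares)
#>   slope k      : 0.2 normalized reads per cp/ug
#>   ddPCR LoQ    : 50 cp/ug
#>   read threshold (k x LoQ, rounded up): 10
```

So 50 copies/µg corresponds to 10 normalized reads: circRNAs below that
per-organ replicate mean are below the quantifiable range. An end-to-end
run on simulated data with 40 planted organ-specific circRNAs:

```r
cfg    <- sim_config(seed = 1, n_circ = 2000,
                     n_planted_per_organ = 10, planted_effect = 8)
truth  <- generate_truth(cfg)
sim    <- simulate_rnaseq(truth)
meta   <- filter(sim$samples, protocol == "R-")
counts <- filter(sim$counts, sample_id %in% meta$sample_id)

supported <- filter_min_support(counts, meta, k = 2)
confirmed <- intersect_callers(supported$counts, sim$confirm_ids)
norm      <- normalize_counts(confirmed$counts, sim$stats, "library_size_excl")
analysis  <- abundance_filter(aggregate_replicates(norm, meta), threshold = 10)
diffs     <- all_pairwise_diff(norm, meta, analysis_set = analysis$union)
table(organ_specific_calls(diffs)$organ)
#>   flower     leaf     root seedling
#>        9       10       10       10
```

39 of the 40 planted organ-specific circRNAs are recovered (one was
dropped by the simulated second-caller confirmation) with no false
positives among the 2000 species.

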