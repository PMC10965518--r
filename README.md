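# svsnv

Co-analysis of somatic SNVs and structural variants (SVs) from
whole-genome call sets: are point mutations coupled to SV breakpoints, or
do they accumulate independently of them?

The package is aimed at analysts of somatic mutation data (cell-line
mutation-accumulation experiments, tumour cohorts) who have SNV calls
(VCF) and SV breakpoint calls (BEDPE/BED) and want to quantify, per
condition:

1. **96-channel mutation spectra** — pyrimidine-normalised trinucleotide
   context counts, A–T vs G–C base-pair splits, and Welch tests on the
   extreme channels of a base-pair class between conditions.
2. **SNV enrichment around SV sites** — the observed number of SNVs
   within a range *R* of any SV breakend versus its expectation under
   uniform placement,

   *E(R) = n_SNV / G × n_SV × 2R*,

   reported together with an overlap-corrected expectation
   *n_SNV · L_merged(R) / G* that accounts for neighbourhood overlap and
   chromosome-end clipping.
3. **Decomposition of SNV load** — per-window SNV counts regressed on
   per-window SV counts (OLS over windows tiling the genome; 15/30/60 Mb
   defaults). The slope estimates SV-dependent SNVs per SV; the intercept,
   converted to SNVs/Mb, estimates the SV-independent background. Between
   conditions, slope and intercept-rate ratios come with delta-method
   confidence intervals.
4. **Signature attribution** — non-negative least-squares refitting of
   96-channel spectra against a reference SBS signature matrix
   (COSMIC-style layout), stratified into SNVs within 1 Mb of SV sites
   versus the rest, with a >10-SNV analysability filter per stratum.

A seeded synthetic-data generator (`simulate_dataset()`) produces paired
two-condition SV/SNV call sets with exported ground truth — shared SV
hotspots, per-breakend SNV clusters, a uniform background whose rate
differs between conditions, and per-stratum signature mixtures — so every
stage is validated by parameter recovery without any external data.

## Worked example

Simulate a small two-condition data set and run the main stages:

```r
library(svsnv)

bundle <- simulate_dataset(seed = 7, n_chrom = 3, chrom_length = 4e6,
                           n_sv = 15, b = 15, k = 10, cluster_width = 5e4)
snvs <- bundle$snvs$irradiated
svs  <- bundle$svs$irradiated

fit_b <- fit_decomposition(count_in_windows(snvs, svs, bundle$genome, 5e5))
fit_b
#> decomposition_result (w = 500000 bp, n = 24 windows)
#>   slope      7.814 +/- 0.811 SNVs per SV
#>   intercept  23.565 +/- 1.535 SNVs per window (47.131 SNVs/Mb)
#>   R^2        0.8085
```

The generator placed a 15 SNVs/Mb background plus 42/Mb in the
"irradiated" condition (2.8×) and ~10 clustered SNVs per breakend; at
this toy scale the slope is attenuated slightly by clusters spilling
across window edges, while the intercept rate reflects background plus
the smeared cluster remainder. Comparing conditions:

```r
fit_a <- fit_decomposition(count_in_windows(bundle$snvs$unirradiated,
                                            bundle$svs$unirradiated,
                                            bundle$genome, 5e5))
compare_conditions(fit_a, fit_b)
#> condition_comparison (w = 500000 bp)
#>   slope ratio (B/A)          0.831 [0.638, 1.024]
#>   intercept-rate ratio (B/A) 2.760 [2.030, 3.490]
```

The SV-independent background is recovered as ~2.8-fold higher in the
second condition while the per-SV burden is compatible with unchanged
(ratio CI spans 1). SNVs are strongly clustered near breakends:

```r
observed_vs_expected_curve(snvs, svs, bundle$genome,
                           ranges = c(1e4, 1e5, 1e6))[, 1:4]
#>   range observed expected_naive expected_corrected
#> 1 1e+04      104             40            38.9510
#> 2 1e+05      437            400           251.6553
#> 3 1e+06      791           4000           789.1211
```

At 10 kb the observed count is ~2.7× the expectation (clusters have
half-width 50 kb); at 1 Mb the merged neighbourhoods cover almost the
whole toy genome, the corrected expectation approaches the observed
count, and the naive closed form overshoots because it ignores overlap.
Stratified signature refitting on the near-SV stratum:

```r
sa <- stratified_attribution(snvs, svs, bundle$genome, bundle$sequence,
                             bundle$refs, d = 5e4)
sa$near
#> exposure_vector: 388 SNVs, cosine = 0.9804
#>   sig4          143.4 (37.0%)
#>   sig1          130.7 (33.7%)
#>   sig3           59.0 (15.2%)
#>   sig2           54.9 (14.1%)
```

sig4 is the generator's SV-proximal signature; it dominates the near
stratum and is absent from the far stratum's truth.

A thin command-line wrapper over the same functions is included:

```sh
Rscript inst/scripts/svsnv-pipeline.R simulate --seed 1 --out-dir sim/
Rscript inst/scripts/svsnv-pipeline.R run-all \
    --snv-a sim/snv_unirradiated.vcf --snv-b sim/snv_irradiated.vcf \
    --sv-a sim/sv_unirradiated.bedpe --sv-b sim/sv_irradiated.bedpe \
    --label-a unirradiated --label-b irradiated \
    --chrom-sizes sim/genome.chrom.sizes --fasta sim/genome.fa \
    --signatures sim/signatures.tsv --out-dir out/
```

`run_full_analysis()` writes per-stage tables (96-channel catalog,
expected-random curves, window counts, exposures) and a `summary.json`
stamped with the configuration hash and seed; identical configurations
produce byte-identical summaries.

## Layout

- `R/` — genome/record containers and IO (`variant_io`), spectra
  (`spectrum`), proximity and expected-random model (`proximity`),
  windowed decomposition (`decomposition`), NNLS refitting
  (`signature_fit`), the generator (`synthetic`), orchestration
  (`pipeline`).
- `vignettes/svsnv-methods.Rmd` — model, assumptions, parameter
  defaults, numerical choices, and what the simulator does and does not
  emulate.
- `tests/testthat/` — unit, property, and recovery tests, including
  independent brute-force oracles for every core operation.
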