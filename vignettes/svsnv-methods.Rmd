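---
title: "Decomposing SNV load around structural variants: methods and design"
author: "svsnv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing SNV load around structural variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svsnv)
```

## The question the package addresses

Somatic single nucleotide variants (SNVs) in unstable genomes arise from at
least two regimes: mutations coupled to the repair and replication stress
around structural variant (SV) breakpoints, and a diffuse background that
accumulates genome-wide during ordinary replication — for example the
T-centred substitutions attributed to reactive-oxygen damage after ionising
radiation (COSMIC signatures SBS17a/b and SBS40). Distinguishing the two
matters: an exposure that raises the background without touching the
SV-coupled component has a different mechanism, and a different risk
profile, than one that destabilises the genome.

`svsnv` implements the quantitative machinery for making that distinction
from ordinary call sets (somatic VCF + SV breakends), with four analysis
stages and a simulator that makes each stage testable by parameter
recovery.

## Stage 1: 96-channel mutation spectra

Every SNV is classified by its substitution type and the one flanking base
on each side, with purine-reference records mapped to the
reverse-complement strand so that the reference base is always the
pyrimidine of its pair (`classify_context()`). This collapses 192
strand-specific trinucleotide contexts onto the standard 96 channels, in
the substitution-major channel order of `sbs96_channels()`. Records whose
context is unavailable (position 1 or the chromosome end) or ambiguous
(any non-ACGT base) are counted as unclassifiable rather than dropped
silently, so totals always reconcile.

T-centred channels count mutations at A–T base pairs and C-centred
channels at G–C pairs (`split_by_basepair()`); an irradiation-like
exposure shows up as an A–T excess. `compare_extreme_channels()` ranks the
48 channels of one base-pair class by their mean per-sample count in the
condition of interest, then compares the per-sample summed counts of the
top-*k* and bottom-*k* subsets between conditions with a two-tailed
Welch's t-test. Two design choices deserve note:

* **Ranking basis.** Channels are ranked in the second (treated)
  condition, since the question is which channels that condition induces.
  The ranking condition is a parameter (`rank_condition`).
* **Test unit.** One test per subset, on per-sample sums — not one test
  per channel — because the comparison is of subset burden, and per-sample
  sums are the replicates. Because the subsets are selected on the same
  data, a flat spectrum would make the bottom-*k* selection noise-driven
  and anti-conservative; on realistically structured spectra (strongly
  unequal channel intensities) the ranking is signal-driven and the
  procedure behaves as intended. The test suite simulates that structure
  explicitly.

## Stage 2: the expected-random model around SV sites

To ask whether SNVs cluster near breakpoints, the observed number of SNVs
within a range $R$ of any breakend is compared with its expectation under
uniform placement:

$$E(R) = \frac{n_{\mathrm{SNV}}}{G} \times n_{\mathrm{SV}} \times 2R$$

with $G$ the genome length and $n_{\mathrm{SV}}$ the number of SV sites.
The package implements this closed form verbatim (`expected_random_count()`)
and always reports, alongside it, an overlap-corrected expectation
$n_{\mathrm{SNV}} \cdot L_{\mathrm{merged}}(R) / G$, where
$L_{\mathrm{merged}}$ is the total length of the per-breakend windows
$[\max(1, p-R), \min(L, p+R)]$ after merging overlaps and clipping at
chromosome ends. The naive form ignores overlap and clipping and can
exceed $n_{\mathrm{SNV}}$ at large $R$; the corrected form cannot. Both
are returned by `observed_vs_expected_curve()` over a log-spaced
1 kb–10 Mb grid (half-decade steps by default).

Three conventions are fixed here and surfaced in the documentation:

* **SV sites are breakend points**, not event intervals; both ends of an
  event are lesion positions and both count. Whether "SV number" counts
  breakends or events is genuinely ambiguous in count-based summaries, so
  it is a parameter (`count_sv`, default `"breakends"`) and the choice is
  echoed into every report.
* **The factor 2 is read as the two flanks of each counted SV site.** The
  alternative reading (two breakends per SV event) is equivalent when
  counting breakends with each contributing one flank pair.
* **Inclusive intervals hold $2R + 1$ bp** while the closed form counts
  $2R$; with disjoint unclipped neighbourhoods the two expectations
  therefore differ by exactly $n_{\mathrm{SNV}} n_{\mathrm{SV}} / G$ —
  negligible at any realistic scale, but asserted explicitly in the tests
  rather than hidden.

Internally the observed curve is computed from each SNV's nearest-breakend
distance (one $O(n \log m)$ pass serves every range), which is equivalent
to membership in the merged intervals; the equivalence against both the
interval partition and a per-bp membership oracle is part of the test
suite.

## Stage 3: windowed decomposition into SV-dependent and SV-independent SNVs

SNVs and SV breakends are counted in windows tiling each chromosome from
position 1 in steps of $w$ (defaults 15, 30, and 60 Mb, with 10 Mb
available), and per-window SNV count is regressed on per-window SV count
by ordinary least squares:

$$\mathrm{SNV}_i = \beta_0 + \beta_1 \, \mathrm{SV}_i + \varepsilon_i$$

The slope $\beta_1$ estimates SV-dependent SNVs per SV site; the
intercept $\beta_0$ estimates SV-independent SNVs per window and is also
reported per Mb ($\beta_0 / (w/10^6)$), the natural unit for a background
mutation rate. Design notes:

* **OLS, not Poisson.** Linear regression is the stated method for this
  analysis; a log-link Poisson alternative exists (`family = "poisson"`)
  but is not the default, and its coefficients live on the log scale.
* **Partial windows** at chromosome ends are excluded by default
  (`drop_partial = TRUE`): their shorter territory would bias the
  intercept downward. Including them is a flag for users who prefer
  completeness over bias.
* **Degenerate designs** (all SV counts identical) abort with an explicit
  error rather than returning an undefined slope.
* **Units ambiguity.** A slope of counts on counts is "SNVs per SV", not
  per Mb; descriptions of the slope "per unit genome size" conflate the
  two. The package reports the slope in its natural per-SV unit and
  documents the ambiguity rather than silently rescaling.
* **Pooling.** Windows pool across chromosomes within one sample/condition;
  regression across samples is left to the caller.

`compare_conditions()` forms the B/A ratio of slopes and of intercept
rates with delta-method confidence intervals (independence of the two
fits assumed), flagging ratios whose denominators are non-positive, and
reports Student's and Welch's t-tests on the two fits' window-level
residuals. `chromosome_sv_stats()` supplies the companion per-chromosome
view: SV rates per Mb per chromosome, their Pearson correlation between
conditions (shared hotspot architecture produces high correlation), and
totals normalised by per-chromosome copy counts when the genome
definition carries them (aneuploid lines).

## Stage 4: signature refitting

Attribution of a spectrum to known SBS signatures is computed by
non-negative least squares against a user-supplied 96 × K reference
matrix: minimise $\lVert s - P e \rVert_2$ subject to $e \ge 0$, solved
by a Lawson–Hanson active-set iteration converged to a KKT tolerance of
$10^{-8}$ on the scaled gradient. De novo signature extraction (NMF) is
deliberately out of scope: the analysis questions here are about which
known signatures carry the SNVs of each stratum, which refitting answers
directly against any reference release the user supplies.

Numerical behaviour worth knowing:

* Exposures are reported in SNV counts; since reference columns sum to 1,
  a perfect reconstruction attributes exactly the input total. If the
  unconstrained optimum over-attributes (possible for spectra far outside
  the reference span), exposures are rescaled to the input total so
  attributed counts never exceed the mutations present.
* Duplicated or collinear reference columns are handled through
  rank-revealing least squares inside the active-set loop (aliased
  coefficients treated as zero); the split between identical columns is
  arbitrary but the total attribution and residual are stable.
* Spectra with 10 or fewer classified SNVs are refused — attribution over
  96 channels at that depth is noise. Strata failing the filter are
  reported as "not analysed" by `stratified_attribution()` rather than
  silently skipped.
* Optional backward elimination is deliberately absent by default: all
  supplied columns stay eligible, so results are a pure function of the
  reference set.

`stratified_attribution()` ties stages 2 and 4 together: partition SNVs
at distance `d` (default 1 Mb) from breakends, build per-stratum spectra,
refit each and the whole-genome spectrum.

## The synthetic generator

`simulate_dataset()` generates what the analysis assumes, nothing more:

* a genome of uniform-composition i.i.d. sequence (default 5 chromosomes
  × 30 Mb, sequence optional);
* SV hotspot intervals with gamma-distributed intensities, shared between
  conditions — both conditions draw a configurable fraction
  (`hotspot_weight`, default 0.5) of their 100 events from the same
  hotspot table, the rest uniformly. Hotspot events keep both breakends
  inside the hotspot; uniform events separate breakends by 1–100 kb;
* SNVs as the superposition of a uniform background of Poisson($b \cdot
  G/10^6$) records (default $b = 2$ SNVs/Mb in the first condition,
  $2.8\times$ that in the second — the fold difference the analysis is
  designed to detect) and an SV-proximal component of Poisson($k$)
  records per breakend (default $k = 30$) placed uniformly within
  $\pm c$ of the breakend (default $c = 0.5$ Mb), never on the breakend
  position itself so that distance-0 semantics stay unambiguous;
* per-stratum signature mixtures over a synthetic reference matrix
  (sparse Dirichlet columns; one column confined to T-centred channels so
  the "irradiated" background shows the A–T excess the spectra stage
  looks for).

When sequence is available, each SNV's drawn channel is realised by
rejection sampling: positions are redrawn (cap 1000 rounds) until the
local trinucleotide matches the channel on either strand, then ref/alt
are written strand-consistently. Records that exhaust the cap fall back
to a context-agnostic position and are relabelled from their actual
context; the fallback count is reported, and is zero in practice on
uniform-composition sequence. Uniform-within-$c$ placement is the
documented default decay model; no exponential decay option is
implemented.

All randomness flows from one integer seed per call (restored afterwards,
so the caller's RNG state is untouched); identical seeds give identical
call sets, byte for byte.

**What passing recovery tests does and does not show.** The generator
emulates the statistical structure the analysis assumes — shared
hotspots, a two-component SNV process, per-stratum mixtures — on a
composition-uniform genome with complete detectability. Real genomes
violate several of these: trinucleotide availability varies, centromeres
and repeats hide both SVs and SNVs from calling (inflating the naive
expectation), cluster shapes need not be uniform, and replication timing
structures the background. Parameter recovery here therefore validates
the estimators' correctness under their own model, not their robustness
to those violations.

## Problem sizes used by the test suite

Chosen as the smallest sizes at which the recovery targets are sharp:
regression recovery uses a 20 × 75 Mb coordinate-only genome (100 full
15 Mb windows) over 20 seeds; the uniform-placement Monte-Carlo uses a
100 Mb genome, 1000 SNVs × 1000 replicates; stratified-mixture
separation uses a 2 × 5 Mb sequence genome over 50 replicates; sequence-
dependent unit tests run on 10 kb–10 Mb toys.

## Worked example

```{r example}
bundle <- simulate_dataset(seed = 7, n_chrom = 3, chrom_length = 4e6,
                           n_sv = 15, b = 15, k = 10, cluster_width = 5e4)
snvs <- bundle$snvs$irradiated
svs <- bundle$svs$irradiated

fit <- fit_decomposition(count_in_windows(snvs, svs, bundle$genome, 1e6))
fit

observed_vs_expected_curve(snvs, svs, bundle$genome,
                           ranges = c(1e4, 1e5, 1e6))

sa <- stratified_attribution(snvs, svs, bundle$genome, bundle$sequence,
                             bundle$refs, d = 5e4)
sa$near
```

## Known limitations

* No de novo signature extraction, bootstrap exposure intervals, or
  strand-bias channels; no kataegis/rainfall detection; no per-SV-type
  stratification of enrichment.
* The expected-random model assumes complete detectability; on real WGS
  the naive expectation includes territory where neither SVs nor SNVs are
  callable, and should be read next to the overlap-corrected value.
* The condition comparison treats the two fits as independent; paired
  window designs would need a joint model.
* The simulator does not model sequencing error, clonal evolution, or
  distance-decaying cluster shapes.
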