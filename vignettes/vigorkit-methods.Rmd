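---
title: "vigorkit: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vigorkit: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

vigorkit packages the quantitative stages of a maize seed-vigor locus
study as one tested pipeline: a two-population selection scan with
coalescent and permutation nulls, dissociation-constant fitting of
protein–poly(A) mRNA binding ladders, paired RNA-seq/RNC-seq
translation-efficiency classification, locus-specific methylation
quantification, germination and haplotype statistics, and a protein
neighbor-joining phylogeny. This vignette records the models behind each
stage, the tunable parameters and their defaults, the numerical choices
that make results reproducible, what the synthetic-data generators do and
do not emulate, and the known limitations.

## Selection scan

**Statistics.** For haploid biallelic calls the package uses the
Weir–Cockerham (1984) moment estimator of FST specialized to haploid
data, written in the ANOVA form: per site,
$\mathrm{MSP} = \sum_i n_i (p_i - \bar p)^2 / (r-1)$,
$\mathrm{MSG} = \sum_i n_i p_i (1-p_i) / \sum_i (n_i - 1)$,
$n_c = (\sum n_i - \sum n_i^2 / \sum n_i)/(r-1)$, between-population
component $a = (\mathrm{MSP} - \mathrm{MSG})/n_c$ and denominator
$a + \mathrm{MSG}$. Windows report the ratio of sums
$\sum a / \sum (a + \mathrm{MSG})$ over the segregating sites they
contain. No estimator is canonical for this kind of scan, so the choice
is explicit; a Hudson-type estimator is available behind
`window_scan(..., estimator = "hudson")` for sensitivity checks. Negative
site components are kept in the sums (standard practice); window FST
slightly below 0 is reported as computed. Nucleotide diversity is
$\theta_\pi = \sum_s 2 p_s q_s n_s/(n_s - 1) / L$ with per-site
pairwise-complete sample sizes $n_s$ and $L$ the window span in bp, i.e.
mean pairwise differences per bp.

**Windows.** The default 3000-bp window advanced by 100 bp matches the
scan design the pipeline reproduces. Positions are 1-based; windows are
half-open `[start, start + window)` internally and anchored at the region
start, so coordinates are stable regardless of data content. Windows with
fewer than `min_sites` (default 3) segregating sites keep their
coordinates but carry `NA` FST and diversity ratio rather than being
dropped. Sites missing entirely in one population are excluded from both
statistics; monomorphic sites contribute 0 to diversity and are excluded
from FST sums.

**Null thresholds.** Two nulls are provided. The permutation null
shuffles population labels, rescans, and takes the `1 - alpha` quantile
of the per-shuffle scan maxima — a familywise bound under exchangeable
labels. The neutral null simulates independent windows under a
two-population domestication-bottleneck coalescent and takes marginal
quantiles of window FST and of the teosinte/maize diversity ratio.
Quantiles everywhere use linear interpolation of the empirical CDF
(`type = 4`), chosen so that the 95% point of 1000 simulations is exactly
the 950th order statistic while remaining an interpolating rule at other
sample sizes.

**Coalescent simulator.** No installed R package simulates a
two-population demography with mutations onto haplotypes, so the
structured coalescent is implemented directly: epoch-wise constant sizes
(domesticated lineage at `N_maize_now` until `t_bottleneck_end`, at
`N_maize_bottleneck` until `t_split`, then a merged ancestral population
of size `N_anc`), exponential waiting times with pairwise coalescence
rate $1/(2N)$ per generation, infinite-sites mutations placed on branches
in proportion to branch length with distinct integer positions. Default
parameters are literature-typical for maize domestication — ancestral
and teosinte size 150,000, a bottleneck to 5% of ancestral size lasting
1,000 generations and ending 9,000 generations ago, mutation rate
$3\times10^{-8}$ per bp per generation — and are configuration, not
estimates. Recombination is not simulated (`r = 0`): windows are short
(3 kb) and the null statistics are window-level marginals, which
recombination would narrow rather than shift; this makes both thresholds
mildly conservative. For a single constant-size population the simulator
satisfies $E[\pi] = 4N\mu$, which the tests verify to within 5% over
2,000 replicates.

The genome-wide background values that a full-data analysis would use
(e.g. backgrounds of 0.355 for FST and 4.623 for the diversity ratio)
require population-scale resequencing panels and are intentionally out of
scope; the same scan code applies unchanged when such data are supplied
as VCF plus a population map.

## Binding kinetics

**Model.** The dose–response ladders titrate a protein ligand against a
fixed labelled poly(A) mRNA target near 89 nM, which is not always
negligible against the fitted dissociation constants (down to ~0.1 µM),
so the single-site quadratic depletion isotherm is used throughout:
$\mathrm{FB} = \big((L + T + K_D) - \sqrt{(L + T + K_D)^2 - 4LT}\big)/(2T)$,
reducing to $L/(L+K_D)$ as $T \to 0$. Fluorescence is modelled as
`unbound + (bound - unbound) * FB`; the two levels are profiled out by
linear least squares, leaving a 1-D optimization of $K_D$ on the log
scale, multi-started from 7 log-spaced points spanning
`[min(conc)/10, max(conc) * 10]` with ties broken by lowest residual then
lowest $K_D$.

**Replicates and uncertainty.** With three or more replicate ladders the
reported $K_D$ is the mean of per-replicate fits and the SE is the
standard error of that mean, matching how the source assays report
"mean ± SE (n = 3)"; with fewer replicates the SE falls back to the
curvature of the residual sum of squares at the optimum.
`resample_kd_se()` implements the leave-one-out pairwise resampling of
three replicates (the SE of a pair is $|x - y|/2$), whose three SEs feed
an ANOVA on estimate variability.

**Legitimacy.** Real screening software sometimes declines to report a
constant; the instrument's internal rules are proprietary, so the package
declares its own: an estimate is legitimate only when the fit converged,
the fitted amplitude is at least 3 residual standard deviations, and the
fitted $K_D$ lies strictly inside the search range. Low-amplitude series
(early-timepoint aged protein) therefore return `legitimate = FALSE`
rather than a number, mirroring the "–" entries such tables print.
`qc_series()` flags outlier wells by leave-one-out studentized residuals
from a provisional fit (default threshold 3) and inhomogeneous wells by
initial-fluorescence deviation from the ladder median (default 20%);
series with more than half their wells flagged are unusable.

**Comparisons.** Treatment statistics follow the published layout:
one-way ANOVA within each aging stratum and incubation duration; Scheffé
simultaneous pairwise letters across durations within a treatment; and
Dunnett many-to-one comparisons of each enzyme treatment against the
no-enzyme control. Dunnett critical values and adjusted p-values come
from Monte-Carlo simulation of the max-|t| statistic (default $10^5$
draws, fixed internal seed), which reproduces published table values
(k = 2, df = 6, two-sided 5%: 2.86) without table lookups. Scheffé
letters are built from maximal runs of mutually non-significant groups
along the mean ordering, which is exact for the balanced designs used
here.

## Translatome

Translation efficiency (TE) is RNC/RNA on the normalized scale. Each
gene is tested with a negative-binomial log-linear model with offsets and
a common trended dispersion: the RNA effect is the group coefficient fit
on RNA samples alone, and the TE effect is the group × assay interaction
fit on all samples, both tested by likelihood ratio. The original
analysis's test machinery is not public, so this package defines and
documents its own. Two choices matter in practice:

* **Offsets** are median-of-ratios size factors, not raw column totals.
  When a block of genes shifts strongly in one group, raw totals absorb
  the shift and push every unchanged gene in the opposite direction; in
  planted simulations this inflated false calls on null genes roughly
  eightfold. Size factors restore calibration under the
  majority-unchanged assumption.
* **Dispersion** is estimated by method of moments within each
  (assay, group) cell, pooled per gene, and smoothed against mean
  expression by lowess (floored at $10^{-3}$), giving a common trended
  dispersion in the spirit of count-model packages without per-gene
  shrinkage machinery.

p-values are BH-adjusted in two separate families (RNA, TE) matching the
two volcano plots such studies draw, and genes are classified at FDR
0.05 into Transcription (RNA only), Translation (TE only), Homodirection
(both, same sign), Opposite (both, opposite signs) or Unchanged; genes
with missing q-values are Unclassifiable and excluded from counts. On
simulations with 5,000 genes, 4 replicates and planted |log2FC| = 2
effects, ≥ 90% of planted genes recover their exact category and the
fraction of null genes reaching q < 0.05 stays at or below the nominal
level plus Monte-Carlo margin — structure analogous to, but not a claim
about, the published gene counts, which depend on unavailable sequencing
data.

## Methylation

`call_contexts()` classifies each reference cytosine by its two
downstream bases (CG; CHG; CHH with H ∈ {A, C, T}); trailing cytosines
without two downstream bases are indeterminate and excluded, so every
internal cytosine belongs to exactly one context. `bisulfite_summary()`
treats a clone `C` at a reference cytosine as methylated and `T` as
converted; any other base there is flagged, excluded, and counted — how
partially converted or miscalled clones were handled upstream is not
public, so the exclusion rule is a documented package choice. Clones are
assumed gap-free and pre-aligned (Sanger sequencing of a fixed amplicon)
and to read the converted top strand; bottom-strand amplicons are
reverse-complemented first. Conversion efficiency is not estimated or
corrected, matching assays that report raw percentages.

McrBC scores use `2^(-ddCt)` with the region's digested-minus-undigested
ΔCt referenced to the mean ΔCt of two reference genes; methylation is 1
minus the remaining fraction, clamped to [0, 1] (negative pre-clamp
values are logged as unmethylated-with-noise), with delta-method SEs from
replicate spread.

## Phenotype statistics

Germination curves report per-timepoint replicate mean ± SE of cumulative
percentages; per-timepoint comparisons default to Welch's t (the source
figures say only "Student's t-test", so the equal-variance form sits
behind `var_equal = TRUE`), with stars at 0.05/0.01/0.001. Haplotype
calls are a pure function of amplicon length: within 50 bp of 365 bp is
the short (C7-2-like) haplotype, within 50 bp of 2682 bp the long
(Z58-like) one, anything else `other`; 50 bp is a gel-resolution
default, not a published constant. The expression-GWAS threshold keeps
the 1/m Bonferroni convention (`familywise_alpha = 1`), with 0.05/m one
argument away.

## Phylogeny

`complete_deletion()` removes every column containing a gap or ambiguity
in any row. Distances are Poisson-corrected, $d = -\ln(1 - p)$; a
saturated pair ($p = 1$) is an error rather than an infinity.
Neighbor-joining fixes the details reference implementations leave
unspecified: ties in the Q-criterion break to the lowest index pair, and
a negative branch length is clamped to 0 with the excess moved to its
sister branch so the pair sum is preserved. On additive matrices the
generating tree is recovered exactly (verified against an independent NJ
implementation at 4–8 taxa). Bootstrap supports resample alignment
columns, rebuild the tree per replicate, and score each internal
bipartition of the full-data tree by its replicate frequency; supports
are mapped onto the full-data tree (not a consensus), and collapsing
below 50% happens after mapping — whether the original analysis
collapsed before or after mapping is unstated, so the order here is a
documented choice. Collapsing zeroes the flagged internal edges and
merges them; a genuinely zero-length internal edge with high support
would collapse too, a corner that does not arise in the tested regimes.

## Synthetic data: what it does and does not emulate

The generators produce inputs with the statistical structure each stage
assumes: depletion-isotherm fluorescence with i.i.d. Gaussian well noise;
negative-binomial counts with a single common dispersion and planted
RNA/TE log-fold-changes; bisulfite clones with per-context methylation
probabilities where incomplete conversion appears as false methylation
(C retained); and germination counts from latent logistic germination
times, which makes cumulative counts monotone by construction. Every
generator takes one integer seed and derives fixed-offset substreams per
replicate, so output is byte-identical across calls and replicates differ
only by noise; generator calls restore the caller's RNG state.

They deliberately do not emulate: read-level sequencing error or
alignment artifacts, fluorescence time-traces or plate-reader export
formats, linkage disequilibrium within windows (no recombination),
between-replicate batch effects, or gene-specific dispersion trends
beyond the common model. Passing tests therefore demonstrate that the
estimators are correct and calibrated under their stated models, not that
real data meet those models. Fluorescence noise defaults (1% of
amplitude) are calibrated only to give Table-1-like standard errors
qualitatively; no instrument noise magnitudes are published.

## Problem sizes and runtimes

The test suite runs everything at desk scale, chosen so the full suite
completes in a few minutes: 2,000 coalescent replicates for the
$E[\pi] = 4N\mu$ check (5% tolerance), 50 panmictic datasets × 100
permutations for type-I calibration, 300 windows per arm for the
bottleneck direction checks, 100 simulated plates for KD recovery
(median relative error < 10% at 1% amplitude noise), 5,000-gene
translatome runs, 80-clone bisulfite calibration against exact binomial
CIs, and 1,000 bootstrap replicates on a 10-taxon alignment.

## Known limitations

* No recombination in the coalescent null; thresholds are accordingly
  mildly conservative for multi-window maxima.
* The NB dispersion is a single trend, not per-gene shrinkage; very
  heterogeneous dispersions would miscalibrate extreme genes.
* Scheffé letters use the ordered-run construction, exact for balanced
  groups; badly unbalanced designs could in principle need the general
  insert-absorb algorithm.
* Amplicon haplotype calling is length-only; the "other" class absorbs
  the additional rare polymorphisms such surveys observe.
* Bootstrap supports on weak splits can shift under taxon reordering
  when replicates contain exact distance ties; well-supported splits are
  stable.
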