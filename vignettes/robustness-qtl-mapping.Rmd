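---
title: "Mapping phenotypic-robustness QTL in inbred strain panels"
author: "robustqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping phenotypic-robustness QTL in inbred strain panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robustqtl)
```

## The problem

Most QTL mapping asks where in the genome a marker's genotype associates
with a trait's *mean*.  This package asks where a genotype associates with
a trait's *dispersion* — its robustness.  In a panel of inbred strains,
where every strain is measured in many genetically identical replicate
individuals, two kinds of dispersion can be separated:

* **Environmental robustness (ER).** Replicates of one strain share a
  genome, so their spread reflects sensitivity to micro-environmental
  fluctuation.  A locus at which one genotype class shows systematically
  larger within-strain standard deviations is an ER QTL — a
  gene–environment interaction.
* **Genetic robustness (GR).** Taking the median of each strain's
  replicates suppresses micro-environmental noise; what remains is each
  strain's characteristic value.  A locus at which one genotype class
  shows a wider spread of *strain medians* — with no difference in the
  medians' central value — is a GR QTL: an epistatic interaction in which
  one allele buffers genetic background variation and the other does not.

The defining constraint is that neither scan may be contaminated by
ordinary ("typical") mean-effect QTL, which is enforced by an exclusion
filter described below.

## The GR statistic

GR mapping needs a k-sample test of dispersion on the strain medians,
grouped by marker genotype.  We use the median variant of the
Fligner–Killeen rank test (`fk_test()`):

1. within each genotype group, replace each value by its absolute
   deviation from the group median;
2. pool the deviations from all groups and rank them, assigning midranks
   to ties;
3. transform ranks to half-normal scores
   $a = \Phi^{-1}\!\left(\tfrac12 + \tfrac{r}{2(N+1)}\right)$;
4. compute
   $d = \sum_i n_i (\bar A_i - \bar a)^2 / V^2$,
   where $\bar A_i$ is group $i$'s mean score, $\bar a$ the grand mean
   and $V^2$ the variance of all scores (denominator $N - 1$);
5. refer $d$ to $\chi^2_{k-1}$ for a nominal p-value.

Because it is rank-based the test needs no distributional assumptions and
is robust to outliers; because deviations are taken within groups it is
exactly invariant to group-wise location shifts, so a pure mean effect
contributes nothing.  The test suite verifies the statistic against an
independent step-by-step oracle and against `stats::fligner.test`.

Three numerical properties are worth knowing:

* **Saturation.** $d$ depends only on the ranking of deviations, so it has
  a hard maximum for given group sizes, attained when every deviation in
  one group exceeds every deviation in the other.  With classes of 9 and
  10 strains that maximum is $d \approx 11.79$ (nominal
  $p \approx 6\times10^{-4}$).  A "maximally significant" GR hit therefore
  means complete separation of deviation ranks, not complete variance
  explained, and the default hit flag (`gr_alpha = 1e-3`) marks exactly
  those near-maximal configurations.  Detection curves near the
  saturation point are sensitive to any extra noise in the strain
  medians, which is visible in the interference study below.
* **Tie handling.** Deviations are compared after rounding to 8
  significant digits, so ties that are exact in real arithmetic — the
  structural zero of an odd-sized group, the two equal deviations
  flanking an even group's median — survive floating-point perturbation
  and receive proper midranks.  This is what makes the location-shift and
  scaling invariances hold to machine precision.
* **Conservatism at panel scale.** With 19 strains the $\chi^2$ reference
  is conservative: the true null rejection rate at nominal 0.05 is about
  0.028 (the canonical implementation behaves identically).  Nominal
  p-values are therefore used only for ranking and flagging; genome-wide
  significance always comes from strain-label permutation.
* **Odd-size bias.** An odd-sized group always contains one exact-zero
  deviation, a slight bias against calling that group high-dispersion;
  it shrinks with group size, applies equally to permuted data, and is
  reported by `fk_odd_bias()` as a diagnostic only.

## The ER statistic

ER mapping is a Pearson correlation between per-strain within-strain
standard deviations and the 0/1 genotype — equivalent to a t-test in this
two-class setting.  A pair is a hit when the genotype explains at least
half of the variation in within-strain variability ($r^2 \ge 0.5$), which
at 19 strains corresponds to a two-sided nominal $p \approx 7\times10^{-4}$,
below 0.00085.  A coefficient-of-variation option (`dispersion_metric =
"cv"`, guarded by a mean floor) serves panels whose variability is
reported as CVs.  The macro-ER scan (`macro_er_scan()`) applies the same
machinery to the standard deviation of per-condition strain medians,
measuring sensitivity to defined condition changes rather than
micro-environmental noise; with $k$ conditions each macro dispersion rests
on only $k$ points and is correspondingly noisy.

## Filters

* **Variability floor.** Traits with essentially no variability cannot
  show variability differences; scans keep traits with $\sigma > 0.15$
  (between-strain SD of medians for GR, median within-strain SD for ER).
* **Marker balance.** Dispersion tests have maximal power at balanced
  allele splits; markers are kept when the minor homozygote is carried by
  at least $\lfloor n/2 \rfloor$ strains (9 of 19).
* **Median-QTL exclusion.** Any trait/marker pair whose strain medians
  correlate with genotype at nominal $p < 0.01$ is excluded before
  dispersion testing.  Leaving the threshold uncorrected across millions
  of pairs is deliberately conservative — it can only exclude more pairs.
* **Per-marker exclusions.** Heterozygous or missing strain calls are
  never recoded; the strain is simply ignored for that one marker.
  Markers missing in more than half the strains are dropped by
  `qc_markers()`.

A degenerate case the filter cannot cover: if a hidden mean-effect
variant is carried by *exactly half* of one genotype class's strains (an
even class), the strain medians form a symmetric bimodal whose
correlation with the class genotype converges to $|r| \approx 0.57$ —
nominal $p \approx 0.011$, just above the filter — while the dispersion
statistic saturates.  At that knife edge the marker genuinely tags a
dispersion difference (caused by a linked additive variant rather than a
buffering polymorphism), and no marginal mean test at the marker can
distinguish the two.  Any asymmetric carrier split restores the expected
behaviour, with the mean signal caught far earlier than the dispersion
signal; `simulate_mean_masquerade()` measures both regimes.

## Permutation inference

Scan-wide significance and FDR come from re-pairing strain genotypes with
strain phenotypes under a random bijection (`permute_strain_labels()`),
which preserves all trait–trait and marker–marker correlation.  The
empirical p uses the add-one estimator $(b+1)/(B+1)$ and the FDR is
$\min(1, \overline{\text{permuted}}/\text{observed})$.  When male and
female strata are combined, one bijection is applied to both strata per
permutation — the strata share genotypes, and separate permutations would
overstate the significance of an intersected hit list.  Defaults are
$B = 1000$ for FDR and $10^4$ for headline empirical p-values.

Supporting machinery: percentile bootstrap confidence intervals on
nominal p-values (at least 1000 resamples, degenerate resamples redrawn
and counted); a random-partition test of sex specificity (random halves
of the sex-split sizes versus the true split, compared by z-score); and
split-half power estimation, where samples are split strain-balanced,
both halves are scanned, and the overlap is decomposed into true- and
false-positive overlap using genotype randomizations.  Power is
`(observed overlaps − expected FP overlaps) / (mean estimated true
positives per half)`; the acceptance suite checks it against a direct
planted-marker detection oracle.  Expected-overlap arithmetic
(`expected_overlap()`, `expected_cross_overlap()`, `poisson_zero_prob()`)
turns those estimates into the expected intersection of two hit lists and
the chance of seeing none.

## cis and trans

For expression traits, a hit is *cis* when at least one significant
marker lies within 5 Mb (exactly 5,000,000 bp, inclusive) of the gene's
representative coordinate on the same chromosome, else *trans*; either
side unmapped gives *unknown*.  A point coordinate with an inclusive
window was chosen for determinism; the window is configurable.  The
chance cis count in a list of a given size is estimated two ways —
from permutation-derived hit lists (`expected_cis_null()`) and from
uniform random marker placement (`expected_cis_random()`) — and the cis
fraction among *true positives* subtracts expected false positives from
both numerator and denominator, clamping at zero
(`cis_tp_fraction()`).

## Replication in a two-strain panel

An ER QTL whose genotype differs between two strains predicts which
strain shows the larger within-strain variance.  `test_replication()`
applies, per gene: an eligibility rule of at most one missing value per
strain group; a baseline correction subtracting the mean log2 variance
ratio of unpredicted genes (cancelling any global variability difference
between the strains); a sign-agreement call on the adjusted ratio; and a
one-sided F-test in the predicted direction.  The critical two-sided
ratio at seven samples per strain is about 5.8 at $\alpha = 0.05$
(`critical_variance_ratio()`), the chance expectation of directional
agreements is $n\alpha/2$ per direction, and an excess of agreements is
assessed with an exact binomial upper tail (`confirmation_excess_p()`) —
a deliberate choice of test, since several approximations (Poisson,
normal) give answers differing by small factors at these counts.

## The synthetic panel generator

`simulate_panel()` generates the study design the scans target: 182
individuals from 19 strains, 91 individuals per marker genotype class.
Strains are split into classes first — 10 affected, 9 baseline — and each
class's individuals are balanced round-robin across its strains (9–11
per strain); balancing across all strains before splitting cannot yield
91 per class with 19 strains.  Baseline individuals are drawn
$\mathcal N(0, 1)$.  An ER effect raises the affected class's
within-strain $\sigma$ to 1.5; a GR effect moves affected strain means to
$+2$ for the first half of affected strains and $-2$ for the rest (a
deterministic assignment under the seed), keeping class medians equal; a
combined effect applies both.  Traits whose medians associate with
genotype at $p < 0.01$ are discarded and, by default, regenerated so
class sizes stay exact (a flag disables regeneration; whether discarded
traits should be replaced is an open design point and either choice only
perturbs class sizes by the ~1% discard rate for null and ER traits).

What the generator deliberately does not emulate: microarray noise
structure, probe effects, correlated traits, linkage between markers, or
population structure among strains.  Passing tests on these panels
certify the statistical machinery — filters, statistics, permutation
logic — under idealized noise; they do not certify behaviour under the
correlated, heavy-tailed noise of real expression data, which is exactly
why the diagnostics module exists.

`interference_ratio_study()` asks whether one effect type masks the
other: detection rates among single-effect traits are divided by rates
among combined-effect traits over ten ER thresholds ($r = 0.20$ to
$0.65$ in steps of 0.05) and ten GR thresholds ($\chi^2 = 2$ to $11$ in
steps of 1).  Ratios near one mean joint ER+GR loci are detectable by
both scans.  The package runs 30,000 traits per class by default in its
acceptance computations — ratios stabilise to within about half a
percent at that scale.  One systematic feature appears at the top GR
threshold: $\chi^2 = 11$ sits just below the 9/10-split saturation point
(11.79), where detection requires near-complete rank separation, and the
combined class's larger within-strain $\sigma$ inflates strain-median
noise enough to cost it a few percent of detections there.  The GR-side
ratio at that single threshold is therefore around 1.05 rather than 1.0;
all other thresholds on both sides sit within about 1%.

`make_fixture()` writes a complete miniature study — mixed planted and
null traits, redundant and null markers, maps placing some planted
traits in cis — used by the end-to-end tests; identical seeds give
byte-identical files.

## Diagnostics

`pvalue_inflation_curve()` reports the KS-style maximum deviation of the
scan p-value distribution from uniform (systematic inflation indicates
population structure or batch artifacts; the default warning threshold of
0.05 is meaningful from about $10^4$ p-values).
`cooccurrence_vs_distance()` checks whether closely related strains
co-occur in genotype classes at hit markers more than expected — the
signature of stratification; the distance should be computed over a dense
marker set so the hit markers are a negligible fraction of it.
`paired_group_correlation()` compares trait-profile correlations of
same-strain sample pairs across batch categories (shared cage, shared
shipment, neither).  `flagged_feature_enrichment()` tests hypergeometric
enrichment of technically suspect traits among hits, against both the
full and a restricted background.

## Problem sizes and reproducibility

The test-suite simulations use panels of 19 strains with 3–20 replicates
per strain, tens to hundreds of traits and a handful of markers; the
interference study runs once at 30,000 traits per class; null
calibration uses $10^4$ draws; permutation-uniformity uses 200 replicate
panels at $B = 39$.  These sizes keep Monte-Carlo error well below the
asserted margins while remaining desk-scale.  Every stochastic function
takes an explicit seed; child streams are derived deterministically per
repeat index, so all results in the test suite and the acceptance script
are exactly reproducible.

## Command-line interface

A thin wrapper over the same functions ships at
`system.file("cli", "robustqtl.R", package = "robustqtl")` with
subcommands `simulate`, `scan`, `classify-cis`, `stat fk`, `permute` and
`replicate`; every run writes a JSON manifest (command, options, counts)
next to its output.  Scan thresholds are exposed as flags mirroring
`scan_config()`.

## Known limitations

* Markers are tested marginally; there is no interval mapping, haplotype
  reconstruction, covariate regression or kinship correction (structure
  is *tested for*, not corrected).
* The nominal $\chi^2$ p of the GR statistic is conservative at panel
  scale and saturates at a size-dependent maximum; both properties are
  inherent to the rank statistic and are why inference is
  permutation-based.
* The exact-half hidden-variant configuration described under *Filters*
  is indistinguishable from a genuine GR signature by any marginal test
  at the scanned marker.
* Levene/Brown–Forsythe alternatives to the FK statistic are an
  extension point, not implemented.
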