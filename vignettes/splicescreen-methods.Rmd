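---
title: "Methods: two-stage PCR splicing screens and qBase expression quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage PCR splicing screens and qBase expression quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescreen)
```

# The screening design

`splicescreen` analyses end-point PCR screens of alternative-splicing (AS)
events. Each event is a locus where transcripts differ by inclusion or
exclusion of sequence (most often a cassette exon), so a primer pair
flanking the event amplifies two products — a long and a short isoform —
whose sizes differ by 10 to 450 nt, the range resolvable by microcapillary
electrophoresis. The readout of one PCR lane is a peak table: fragment
sizes in nt with concentrations in arbitrary linear units.

The motivating application is a case-control design in osteoclast biology:
cultures from Paget's disease of bone (PDB) patients and healthy donors
(HD), each genotyped for the recurrent p62/SQSTM1 P392L substitution,
giving four groups (HDwt, HDP392L, PDBwt, PDBP392L). The screen proceeds
in two stages:

1. **Detection screen.** Thousands of candidate events are amplified on
   pooled, pre-amplified RNA (one pool of five subjects per group). An
   event is *active* when both isoforms reach at least 10% of the total
   lane signal in at least one pool; events seen in only one form are
   *monoform*; events with no expected product are *no amplification*.
   Only active events move forward.
2. **Validation screen.** Active events are re-amplified on non-amplified
   RNA from every subject. Each lane yields a percent splicing index
   \(\Psi = c_\mathrm{long} / (c_\mathrm{long} + c_\mathrm{short})\),
   stored as a fraction in [0, 1]. Group differences in \(\Psi\) are tested
   in six fixed contrasts, FDR-corrected, and summarised into
   disease-association and mutation-association calls.

A third component quantifies the expression of the called genes by
efficiency-corrected qPCR normalized to several stable reference genes
(the qBase framework).

# Peak-to-isoform matching and the activity rule

`match_peaks()` assigns each peak to the long isoform if its size is
within `size_tolerance` (default 3 nt) of the expected long amplicon size,
to the short isoform likewise, and otherwise to an `other` bin (primer
dimers, spurious products). Window halves may not overlap
(`2 * tolerance < delta_nt`), multiple peaks per window are summed, and
the three bins conserve total lane signal exactly. The 3 nt default
reflects the sub-nt sizing precision of capillary instruments: under 1 nt
Gaussian size jitter, about 0.27% of peaks drift outside a 3 nt window.

`classify_event()` computes per-pool isoform fractions over the *total*
lane signal, including unmatched peaks — the reading we consider faithful
to a "percent of total signal" rule; a `denominator = "expected"` switch
restricts the denominator to the two expected isoforms for users who
prefer to ignore spurious signal. The 10% boundary is inclusive
(a fraction of exactly 0.10 counts as detectable), and one qualifying pool
suffices. Events whose only signal falls in the `other` bin are classified
`no_amplification`: no expected product amplified.

# The validation screen

## Six contrasts and the t-test

The six contrasts isolate the disease effect and the genotype effect:
all PDB vs all HD; all PDB vs HDwt; PDBwt vs HDwt; PDBwt vs HDP392L;
PDBwt vs PDBP392L; and HDwt vs HDP392L. For each event and contrast we
apply a two-sided Student t-test with pooled variance to the defined
per-subject \(\Psi\) values (undefined entries are dropped pairwise; no
imputation). Welch's form is available by `var_equal = FALSE`. With fewer
than two defined values on either side the result is flagged
`insufficient_n` rather than computed. Two degenerate situations are
resolved explicitly: zero pooled variance with equal means gives
\(t = 0, p = 1\); zero pooled variance with distinct means is reported at
the smallest representable p with a `degenerate` flag, since the evidence
is formally unbounded. A closed-form summary-statistic entry path
(`test_comparison_summary()`) supports re-testing published group
means/SDs/ns.

## FDR correction

q-values are computed per contrast column across events, matching the
layout of published per-event validation tables. The default is
Benjamini–Hochberg: \(q_{(i)} = \min_{j \ge i} p_{(j)} m / j\), capped at
one, which guarantees \(q \ge p\) and monotonicity in the p-value ranks. A
Storey-type variant multiplies by a \(\widehat{\pi}_0\) estimated with the
smoother method (a cubic smoothing spline over a \(\lambda\) grid,
evaluated at the largest \(\lambda\); for fewer than ten p-values the
estimate is unstable and \(\widehat{\pi}_0 = 1\) is used). The packaged
validation table's printed q column is *not* exactly reproducible
rank-by-rank from its printed p column under either plain BH or a single
\(\pi_0\) rescaling — presumably because the printed p-values are rounded
and the original computation used unrounded data — so both methods are
shipped and the BH default is used for all derived quantities.

## Association calling

The headline selection is rule-based, with every decision auditable
through an attached trace. An event is **PDB-associated** when
\(p \le \alpha\) in the three disease contrasts (all PDB vs all HD,
PDBwt vs HDwt, PDBwt vs HDP392L) *and* \(p > \alpha\) in the pure
genotype contrast among healthy donors — i.e. the signal follows disease,
not the mutation. An event is **mutation-associated** when the genotype
contrast is significant in both disease strata (PDBwt vs PDBP392L and
HDwt vs HDP392L). The \(\alpha = 0.05\) boundary is inclusive: a p-value
printed as exactly 0.050 passes, which the packaged table requires for
the selection to reproduce. A missing p fails its check in either
direction: significance cannot be asserted, and neither can its absence.
Applied to the packaged 21-event table these rules select exactly six
PDB-associated events and no mutation-associated event.

## Fisher exact genotype association

`fisher_exact_2x2()` computes the two-sided Fisher exact p by enumerating
the hypergeometric probabilities of all tables with the observed margins
and summing those no more probable than the observed table (with a
\(1 + 10^{-7}\) relative guard against floating-point ties, the standard
convention). The genotype-by-disease table is the implemented
construction (`fisher_mutation_association()`); an alternative reading —
genotype against dichotomized \(\Psi\) — is possible but not the default.

# qBase expression quantification

Threshold cycles follow \(Ct = Ct_0 - \log_E(\text{input})\), so the
per-cycle amplification factor \(E\) is estimated from a dilution-series
standard curve as \(E = 10^{-1/\text{slope}}\) of the OLS fit of Ct on
log10 input; a 10-fold series at perfect efficiency has slope −3.32.
Primer candidates failing the melt-curve single-product check are
discarded and the remaining assay with the lowest Ct on a universal
reference template wins (ties by candidate rank).

Relative quantities are \(RQ_{g,s} = E_g^{Ct^*_g - Ct_{g,s}}\) after
averaging replicate wells (failed wells dropped; a replicate range above
0.5 cycles — a conventional qPCR QC rule of thumb — is logged). The
calibrator \(Ct^*_g\) is the per-gene arithmetic mean Ct across samples,
one of the standard qBase options; any fixed calibrator only rescales a
gene's RQs by a constant, which cancels in normalization and fold
changes, and the tests prove this invariance rather than fixing a
particular convention. The per-sample normalization factor is the
geometric mean of the reference-gene RQs (defaults: SF3A1, PSMC4, PUM1)
and \(CNRQ = RQ / NF\). With a single reference and all efficiencies
exactly 2, CNRQ ratios reduce to the classical \(2^{-\Delta\Delta Ct}\);
group summaries report means ± SEM, Student t p-values, and fold changes
as \(\log_2(\bar{x}_A / \bar{x}_B)\) (antisymmetric under group swap,
undefined and flagged if a group mean is nonpositive). Propagation of
reference-gene error into per-sample CNRQ confidence intervals is out of
scope; group-level SEM and t-tests are what the fold-change analysis
uses.

# The synthetic cohort generator

No subject-level data ship with the package; the generator produces
cohorts with the statistical structure the analysis assumes, so every
stage is testable and calibratable.

- **Cohort.** Defaults: 16 HDwt, 10 HDP392L, 17 PDBwt, 12 PDBP392L
  (55 subjects).
- **True \(\Psi\).** Per event and group, subjects draw from a
  logit-normal distribution moment-matched (by numerical integration and
  Nelder–Mead) to a target mean and SD on the \(\Psi\) scale. The
  logit-normal was preferred over a Beta because it composes exactly with
  the logit-scale measurement noise and pre-amplification distortion;
  only means/SDs are specified, so either family would fit the stated
  moments. Requests with \(\sigma^2\) at the Bernoulli bound
  \(\mu(1-\mu)\) are rejected as infeasible. The default truth table puts
  a disease effect of −0.06 with within-group SD 0.04 — the scale of the
  strongest validated events — on a third of events, and no genotype
  effect anywhere.
- **Lane noise.** Peak concentrations are
  \(\text{total} \cdot (\psi, 1-\psi)\) times independent mean-1
  lognormal factors (CV 0.15), sizes get 1 nt Gaussian jitter, lanes drop
  out with probability 0.05, and a low-level spurious peak appears with
  probability 0.02. Because the concentration noise is multiplicative and
  independent per peak, measured \(\mathrm{logit}(\Psi)\) equals true
  \(\mathrm{logit}(\Psi)\) plus zero-mean Gaussian noise: the measurement
  is ratio-preserving in expectation on the log-odds scale (the
  \(\Psi\)-scale bias at these defaults is below 0.003). The CV, jitter
  and dropout magnitudes are plausible values chosen for this simulator,
  not instrument calibrations, and all are configurable.
- **Pools.** Pooled \(\Psi\) is the equal-weight mean of the members'
  values — equal RNA mass per individual is pooled, so equal weights are
  the faithful default; expression weighting is available via `weights`.
  Pre-amplification bias is modeled as a zero-mean logit-scale Gaussian
  distortion (SD 0.15). Nothing is known about the true bias structure of
  isothermal pre-amplification at specific loci; zero-mean is an
  assumption, flagged here, whose main effect is extra detection-screen
  variance rather than systematic \(\Psi\) shift.
- **Missingness.** Each event × subject measurement is unmeasurable with
  probability 0.36, missing completely at random. The default reproduces
  the effective sample sizes of the motivating cohort (about 19 of 29
  cases and 16 of 26 controls analyzable per event); the true attrition
  mechanism is unknown, so MCAR is the neutral choice.
- **qPCR.** Cts follow the exponential model with efficiency 2.0,
  0.15-cycle Gaussian well noise, triplicates, and a 3-point 10-fold
  dilution series per gene. Reference genes are flat at 1 in every group;
  target genes carry disease/genotype effects on the scale of the
  observed fold changes (e.g. ~1.25× disease up-regulation).

What the generator does **not** emulate: correlation between events or
between genes, batch and culture effects, informative (non-MCAR)
attrition, PCR competition or saturation, heteroscedastic sizing error,
and pre-amplification bias that depends on amplicon properties. Passing
tests therefore demonstrate correctness of the statistical machinery
under the stated model, not robustness to every artifact of real
electrophoresis data.

# Numerical and testing choices

- The logit-normal moment fit requires a squared moment error below
  \(10^{-10}\) and rejects otherwise; fits are cached per distinct
  (mean, SD) pair within a cohort.
- Tabular IO is UTF-8 tab-delimited text with `NA` for missing values;
  doubles are serialized at full precision (`%.17g`) so round trips are
  lossless.
- Determinism: all simulators consume the R RNG; `generate_cohort()`
  seeds it from the configuration, making whole-pipeline runs
  reproducible from a single seed.
- Test problem sizes were chosen to make Monte-Carlo bands tight while
  keeping the suite quick: 10,000 lanes for measurement-bias and
  conservation checks, 2,000 null events for type-I calibration (3
  binomial SEs ≈ ±0.015 around 0.05), 1,000 cohorts for power at the
  published effect size, and exhaustive Fisher enumeration over all 2×2
  tables with row sums ≤ 30.

# Known limitations

- The association rules are conjunctions of per-contrast threshold tests;
  they inherit the multiplicity behaviour of their components and are
  intended to reproduce and audit a published-style selection, not to be
  an optimal detection procedure.
- Storey's \(\widehat{\pi}_0\) is unreliable for small event panels; the
  BH default is recommended below ~50 events.
- CNRQ uncertainty is summarised only at the group level (SEM, t-test);
  no per-sample error bars are propagated through the normalization
  factor.
- The detection screen classifies from point fractions; it does not model
  concentration uncertainty in lanes near the 10% boundary.
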