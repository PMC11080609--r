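---
title: "Quantifying somatic CAG-repeat mosaicism: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying somatic CAG-repeat mosaicism: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagmosaic)
```

## From peak tables to repeat space

Fragment sizing of a PCR across an expanded CAG repeat yields, per sample,
a table of called peaks (size in bp, fluorescence height, optionally area
and scan index). `cagmosaic` starts there — peak *calling* from raw
fluorescence is out of scope — and maps sizes to integer repeat counts with
a linear calibration anchored on one internal-standard sample of known
repeat count, per gene and per plate:

\[ \mathrm{CAG}(s) = \mathrm{CAG}_{\text{anchor}} +
   \mathrm{round}\!\left(\frac{s - s_{\text{anchor}}}{u}\right), \qquad
   u = 3\ \text{bp/repeat by default.} \]

The repeat unit is overridable because observed electrophoretic spacing
can deviate slightly from 3 bp. Fractional repeats are rounded half away
from zero: mobility drift is sub-repeat, and nearest-repeat binning is the
standard practice. Peaks that bin to the same repeat have their heights
summed.

Each trace contains both alleles. The analysis is restricted to the
expanded-allele cluster by an inclusive CAG window whose default lower
bound is the locus' pathological threshold (ATXN1 ≥ 39, ATXN2 ≥ 33,
ATXN3 ≥ 55, ATXN7 ≥ 36). This is the least arbitrary separation rule we
could define; it fails only in the (unobserved) case of a normal allele
inside the pathological range, and the window is fully configurable for
such loci.

## The expansion index

Within the window, the modal repeat is the tallest peak, ties broken
toward the smaller repeat so stutter asymmetry cannot inflate the call.
With \(h_0\) the height at the reference modal \(m\), offsets
\(d_i = \mathrm{CAG}_i - m\):

* peaks with \(d_i < 0\) are PCR stutter and are never counted;
* expanded peaks are retained iff \(h_i \ge \theta h_0\), default
  \(\theta = 0.03\) — a relative threshold calibrated so that low but
  clearly software-distinguishable peaks (as in fetal tissue) survive
  while baseline noise does not;
* with \(S = h_0 + \sum_{\text{ret}} h_i\),
  \(EI = \sum_{\text{ret}} (h_i / S)\, d_i\).

Two normalization readings are possible for "the sum of all peak
heights": over the θ-retained peaks only, or over all candidate expanded
peaks. The retained-only reading is the default (sub-threshold peaks are
"excluded from analysis", which we take to include the denominator); the
alternative is available as `normalize = "all"` and only shrinks EI by
the sub-threshold mass.

Two properties are worth stating precisely:

* **Scale invariance.** EI, the percent profile and the modal call are
  unchanged under any positive rescaling of all heights — fluorescence
  units carry no information.
* **Threshold monotonicity is conditional.** Raising θ removes a retained
  peak at offset \(d\); this lowers EI iff \(d > EI\). For real profiles,
  whose expanded tail decays with offset, retention is lost farthest-first
  and \(EI < d_{\max}\) always, so EI is non-increasing in θ. For
  arbitrary height patterns (e.g. a dominant far peak with a faint near
  peak) monotonicity can fail; the test suite asserts it only on
  decay-shaped tails and checks the general definition against a
  brute-force oracle instead.

For longitudinal series, one fixed reference modal per individual (the
diagnostic repeat when known, else the earliest trace's call) keeps
per-visit EIs comparable even when the blood modal gains repeats across
visits. When a trace's own tallest peak has drifted above the reference,
\(h_0\) is the height *at the reference*, and taller peaks count as
expansion signal — the convention that keeps the longitudinal series well
defined.

The percent-mutant-alleles profile, \(100\, h/S\) over the modal plus
retained peaks, always sums to 100 and is the display form of the same
information; `n_additional_cags` is the largest retained offset.

## Longitudinal models

**Expansion rate.** Per individual with ≥ 2 visits at distinct ages, the
OLS slope of EI on age (EI/year); the intercept extrapolates to a
theoretical EI at birth. Single-visit individuals carry no rate
information and are excluded. All visits are used, not just first/last.

**Mixed-effects model.** `ei ~ age * cag_n * group + (1 | individual)`,
REML via `lme4::lmer`. Age and (CAG)n are mean-centered *by group on
first-visit values* before fitting, and the centering table is stored in
the fit so results are reproducible; per-group slopes then describe the
"mean individual" of each group. The three-way interaction is tested with
a Type II Wald chi-square (`car::Anova`); per-group EI-per-year slopes at
the centered covariates come from `emmeans::emtrends`, and the six
pairwise slope differences use Tukey's single-step adjustment over the
family of four estimates. Degrees of freedom default to Kenward-Roger
(via `pbkrtest`) and fall back — with a logged message — to large-sample
normal, a difference that is immaterial at a hundred-plus individuals.
Simulation loops in the tests use the asymptotic method throughout, a
speed choice with no visible effect at this design size. A singular fit
(zero random-intercept variance) is downgraded to a warning, since the
fixed effects then legitimately equal pooled OLS.

**Residualized comparisons.** To compare premanifest/manifest (or
preataxic/ataxic, SARA 3.5 cutoff) stages within a group without age and
repeat-length confounding, EI at first visit is residualized on age and
(CAG)n, and ER on (CAG)n, by within-group OLS with intercept (residuals
sum to zero per group). A quadratic-age term can be *tested* (nested
model F) but is never auto-selected. Status classes are then compared
with two-sided Wilcoxon rank-sum tests — exact distribution for small
tie-free samples, tie-corrected normal approximation otherwise.
Correlations are Pearson's r with the slope t-test p (identical to the
correlation t-test); severity is SARA divided by disease duration,
undefined at non-positive durations. Descriptive tables report mean and
*sample* SD (n − 1) rounded half away from zero to two decimals — for a
pair of values whose printed SD was computed with an n denominator this
reports the sample-SD value instead, which we consider the correct
summary. Significance is two-sided 0.05 throughout.

## The ddCt expression stage

Relative expression is \(2^{-\Delta\Delta C_t}\) with
\(\Delta C_t = C_t^{\text{target}} - C_t^{\text{reference}}\) per sample
and the same individual's cerebellum as baseline, so each fold change
reads "relative to this person's cerebellum". Technical replicate Cts are
averaged (arithmetic mean, the field convention) before ΔCt.
Amplification-efficiency correction is not modeled. For heatmap display
each gene row is scaled to zero mean and unit sample variance; constant
rows become zeros with a warning; stored fold changes are never clipped.

## What the generators simulate — and what they do not

**Traces.** Modal peak of expected height \(h_0\) (default 10,000
fluorescence units), geometric left stutter (ratio 0.5, 4 peaks),
geometric expansion tail (mean offset 4 repeats, support up to +20 —
chosen so measured tails of 2–10 additional repeats and EIs up to ~3.8
are reachable), and a stable normal-allele cluster below the window so
that allele separation is exercised. Given a target EI, the generator
picks the largest tail support whose feasible EI interval contains the
target (every generated peak is retained at θ by construction) and
inverts the closed-form EI-vs-mass map within that support; the
noise-free EI therefore hits the target to well below 1e-6. The
threshold-filtered map is discontinuous across support changes, so
*some* targets just below a support boundary are unreachable under a
strict geometric shape; the solver reports these explicitly rather than
approximating. Height noise is multiplicative lognormal (mean 1) with CV
0.05 by default — the order of replicate-injection reproducibility of
capillary electrophoresis; fluorescence noise scales with intensity,
which is why the noise is multiplicative. Preset target ranges:
fetal/trophoblast EIs in [0.03, 0.10], adult carrier blood in
[0.40, 1.80].

**Cohorts.** Four groups of 30/50/74/30 individuals; expanded repeats
rounded-normal with means 48.2/39.7/71.5/44.1 and SDs 5/3.5/4/5 (SDs are
our choice; only means are constrained); per-visit
\(EI_{ij} = b_{0i} + s_i\,\mathrm{age}_{ij} + \varepsilon_{ij}\) floored
at 0, with \(s_i = s_g\,(1 + \gamma\,(\mathrm{CAG}_i - \bar c_g))\),
group slopes \(s_g\) = 0.023/0.012/0.008/0.055 EI/year, γ = 0.05/repeat
(sets first-visit EI–CAG correlations in the 0.4–0.8 band),
\(b_{0i} \sim N(0.02, 0.10^2)\) (near-zero EI at birth, per fetal
stability), residual SD 0.15 (these two give slope standard errors of
the ±0.002–0.003 magnitude the design should produce). Baseline age
uniform on [25, 65]; 2–3 visits evenly spaced over a Gamma(4) span with
mean 8.5 years. Clinical course: onset ~ N(35 − 0.8·(CAG − mean), 8²),
SARA accruing at 1.5 points/year after onset, manifest status at onset
and ataxic status at SARA > 3.5 — yielding roughly a fifth to a third
premanifest at first visit. Because the generator couples slope to CAG,
the estimand of a group slope at the *sample*-centered mean individual is
\(s_g(1 + \gamma(\bar c_{\text{sample}} - \bar c_g))\); recovery tests
compare against that quantity.

**Tissue panels** draw per-tissue target EIs from disjoint ranges
(cerebellum [0.35, 0.75] < pons/thalamus < frontal cortex [1.6, 2.6]) and
shift the cerebellar modal one repeat below the diagnostic repeat,
reproducing the cerebellum-low / cortex-high contrast and the −1 cerebellar
modal call. **Ct tables** place a per-gene baseline ΔCt uniformly in
[2, 8] cycles with per-tissue log2 shifts (cerebellum +1, cortex −1) and
0.1-cycle replicate noise.

What the generators do *not* emulate: raw fluorescence signal, dye
spectra and size-standard ladders; inter-plate calibration drift;
repeat-sequence interruptions; informative dropout of late visits;
non-geometric (e.g. bimodal) expansion tails seen in some tissues; and
any coupling between expression and instability. Passing tests therefore
demonstrate correctness of the estimators under the assumed
data-generating process, not fidelity of that process to every real
cohort.

## Numerical choices and degenerate inputs

* Rounding of repeats and of reported descriptives is half-away-from-zero
  with a 1e-9 cushion against binary representation of decimal halves.
* Modal ties break toward the smaller repeat; peaks binning to one repeat
  are summed before calling.
* A missing reference-modal peak (longitudinal reference not present in a
  trace) is an error pointing at `call_modal_peak()`, not a silent 0.
* `expansion_rate` requires two distinct ages; `correlate` requires n ≥ 3
  and errors on zero variance; `residualize` errors on rank-deficient
  designs naming the collinear columns; one-class status comparisons are
  skipped with a warning; zero disease duration flags severity as
  undefined rather than infinite.
* Problem sizes used by the test suite: 100 replicate cohorts at the full
  30/50/74/30 design for slope recovery, 2,000 null simulations for
  Wilcoxon calibration, 400 draws per trace preset, 500 replicates for
  noisy-EI unbiasedness, 100-donor tissue panels.

## Known limitations

The bp→CAG map is linear per plate; strong nonlinearity of mobility
across a wide size range would need a multi-anchor calibration. The
expanded-allele window assumes the normal allele lies below the
pathological threshold. EI normalization ignores peak *area*; height is
used throughout. Left-of-modal (contraction) signal is deliberately
discarded with the stutter, so contraction mosaicism is invisible to this
index. The Wilcoxon exact path is limited to tie-free data; heavily tied
residuals fall back to the corrected normal approximation.
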