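# cagmosaic

Somatic mosaicism of expanded CAG repeats, quantified from fragment-analysis
peak traces, with the longitudinal statistics used to follow it over a
lifetime.

## The problem

In the polyglutamine spinocerebellar ataxias (SCA1, SCA2, SCA3, SCA7 —
caused by CAG expansions in *ATXN1*, *ATXN2*, *ATXN3*, *ATXN7*), the
inherited repeat keeps expanding in somatic tissues during life. A PCR
across the repeat followed by capillary-electrophoresis fragment sizing
shows the expanded allele as a cluster of peaks: a main (modal) peak at the
inherited allele size, PCR stutter to its left, and genuinely expanded
repeat lengths to its right. `cagmosaic` turns such peak tables into
instability metrics and fits the cohort-level models that describe how
instability grows with age, differs between genes and tissues, and relates
to disease status.

## The statistic

For a trace with modal-peak height \(h_0\) at reference repeat \(m\), let
the candidate expanded peaks sit at repeat offsets \(d_i = \mathrm{CAG}_i -
m \ge 1\) with heights \(h_i\). Peaks with \(h_i < \theta h_0\) (relative
threshold, default \(\theta = 0.03\)) are excluded, as is everything left
of the modal peak (stutter). With \(S = h_0 + \sum_{\text{retained}} h_i\),
the **expansion index** is

\[ EI \;=\; \sum_{\text{retained}} \frac{h_i}{S}\, d_i , \]

the position-weighted sum of normalized expanded-peak heights: 0 means no
expansion beyond the inherited allele. The **percent mutant alleles**
profile is \(100\,h/S\) per retained repeat, and the **expansion rate**
(ER) is the per-individual OLS slope of EI on age across visits (EI/year).
Cohort-level change is modeled as
`ei ~ age * cag_n * group + (1 | individual)` (REML; age and (CAG)n
mean-centered by group on first-visit values), with per-group EI-per-year
slopes and Tukey-adjusted slope contrasts estimated from the fit.

A seeded synthetic module generates electropherograms (geometric stutter,
geometric expansion tail solved to hit an exact target EI), longitudinal
cohorts under the mixed-model process, cerebellum-low/cortex-high tissue
panels, and qPCR Ct tables — providing ground truth for every stage.

## Worked example

```r
library(cagmosaic)

traces <- read_peak_table(
  system.file("extdata", "example_peaks.tsv", package = "cagmosaic"),
  sample_sheet = system.file("extdata", "example_samples.tsv",
                             package = "cagmosaic"))
cals <- load_calibrations(system.file("extdata", "example_calibration.yaml",
                                      package = "cagmosaic"))
instability_table(traces, cals)
#>    trace_id individual_id  gene tissue age modal_cag reference_modal        ei
#> 1 P01_blood         IND01 ATXN3  blood  48        70              70 0.5539009
#> 2 P02_blood         IND02 ATXN3  blood  39        67              67 0.2921811
#>   n_additional_cags
#> 1                 4
#> 2                 2

round(percent_mutant_alleles(traces$P01_blood, cal = cals[["ATXN3:plateA"]]), 2)
#>    70    71    72    73    74
#> 65.72 20.72  8.09  3.40  2.07
```

P01's blood trace calls a modal repeat of 70 with four retained expanded
peaks; 65.7% of the mutant-allele signal is still at the inherited length
and the position-weighted excess gives EI = 0.55. The second individual's
trace (modal 67) is less expanded, EI = 0.29.

The expansion rate from four blood EI values at ages 17, 18, 33, 34:

```r
expansion_rate(c(17, 18, 33, 34), c(0.94, 0.79, 1.20, 1.20))
#> <er_result> ER = 0.0206 EI/year, intercept = 0.5081 (n = 4 visits)
```

The numbered scripts under `analysis/` chain the full workflow (simulate a
4-group cohort; compute instability metrics; fit the mixed model, slope
contrasts, correlations and residualized status comparisons; run the ddCt
expression stage) and write their tables under `results/`.

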