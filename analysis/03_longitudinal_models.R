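#!/usr/bin/env Rscript
# Longitudinal statistics on the simulated cohort written by
# 01_simulate_cohort.R: per-individual expansion rates, the mixed-effects
# EI ~ age model with per-group slopes and Tukey contrasts, EI/ER vs
# (CAG)n correlations, and residualized comparisons by disease status.

library(cagmosaic)
dir.create("results", showWarnings = FALSE)
if (!file.exists("results/cohort_visits.tsv"))
  stop("run analysis/01_simulate_cohort.R first")
visits <- read_visit_table("results/cohort_visits.tsv")

## expansion rate per individual ---------------------------------------------
er <- expansion_rates(visits)
write.table(er, "results/expansion_rates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Expansion rate (EI/year), by group:\n")
print(describe_by_group(er$slope, er$group, digits = 3))

## mixed-effects model --------------------------------------------------------
fit <- fit_instability_lmm(visits)
print(fit)
write.table(fit$group_slopes, "results/lmm_group_slopes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(compare_group_slopes(fit), "results/lmm_slope_contrasts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(fit$centering, "results/lmm_centering.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nTukey-adjusted slope contrasts:\n")
print(compare_group_slopes(fit)[, c("contrast", "estimate", "p.value")])

## correlations with the germline repeat -------------------------------------
first <- visits[!duplicated(visits$individual_id), ]
cors <- do.call(rbind, lapply(split(first, first$group), function(d) {
  ce <- correlate(d$cag_n, d$ei)
  data.frame(group = d$group[1], r_ei_cag = ce$r, p_ei_cag = ce$p,
             n = ce$n)
}))
write.table(cors, "results/ei_cag_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nEI vs (CAG)n at first visit:\n"); print(cors, row.names = FALSE)

## residualized status comparisons -------------------------------------------
res_ei <- residualize(first$ei, first[, c("age", "cag_n")], first$group)
cmp_ei <- compare_status(res_ei$residual, first$status_sara, first$group)
erm <- merge(er, first[, c("individual_id", "status_sara")],
             by = "individual_id")
res_er <- residualize(erm$slope, erm[, "cag_n", drop = FALSE], erm$group)
cmp_er <- compare_status(res_er$residual, erm$status_sara, erm$group)
q <- quadratic_age_test(first$ei, first$age,
                        first[, "cag_n", drop = FALSE], first$group)
write.table(cmp_ei, "results/status_compare_residual_ei.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cmp_er, "results/status_compare_residual_er.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nWilcoxon tests, residual EI (first visit) by SARA status:\n")
print(cmp_ei, row.names = FALSE)
cat("\nWilcoxon tests, residual ER by SARA status:\n")
print(cmp_er, row.names = FALSE)
cat("\nQuadratic-age check (reported only, never auto-selected):\n")
print(q, row.names = FALSE)

## severity --------------------------------------------------------------------
manifest <- visits[!is.na(visits$disease_duration) &
                     visits$disease_duration > 0.5, ]
manifest <- manifest[!duplicated(manifest$individual_id), ]
manifest$severity <- severity_score(manifest$sara,
                                    manifest$disease_duration)
cat("\nSeverity (SARA/year) by group:\n")
print(describe_by_group(manifest$severity, manifest$group))
erm$residual_er <- res_er$residual
sev <- merge(erm, manifest[, c("individual_id", "severity")],
             by = "individual_id")
cat("\nResidual ER vs severity, per group:\n")
for (g in sort(unique(sev$group))) {
  d <- sev[sev$group == g, ]
  if (nrow(d) >= 3) {
    ce <- correlate(d$residual_er, d$severity)
    cat(sprintf("  %s: r = %.2f, p = %.3g (n = %d)\n", g, ce$r, ce$p, ce$n))
  }
}
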