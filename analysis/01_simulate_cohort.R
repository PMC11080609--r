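#!/usr/bin/env Rscript
# Simulate the longitudinal study design: four SCA groups (30/50/74/30
# individuals), 2-3 visits spanning 8.5 years on average, gene-specific
# EI-per-year slopes, plus matching electropherogram traces for a handful
# of individuals. Writes the visit table, the generating truth, and an
# example peak table under results/.

library(cagmosaic)
dir.create("results", showWarnings = FALSE)
seed <- 20240101

cfg <- cohort_gen_config()
visits <- generate_cohort(cfg, seed = seed)
truth <- attr(visits, "truth")

write.table(visits, "results/cohort_visits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(truth, "results/cohort_truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Simulated", length(unique(visits$individual_id)), "individuals,",
    nrow(visits), "visits\n")
first <- visits[!duplicated(visits$individual_id), ]
cat("Premanifest at first visit, by group:\n")
print(round(tapply(first$status_clinical == "premanifest", first$group,
                   mean), 2))

# fragment-analysis traces for the first three SCA3 individuals' first two
# visits: target EI taken from the simulated visit values
sca3 <- visits[visits$group == "SCA3" & visits$visit <= 2, ]
sca3 <- sca3[sca3$individual_id %in% unique(sca3$individual_id)[1:3], ]
tcfg <- trace_gen_config(gene = "ATXN3", modal_cag = 70)
set.seed(seed)
sims <- lapply(seq_len(nrow(sca3)), function(i)
  generate_trace(tcfg, max(0.05, sca3$ei[i]),
                 sample_id = sprintf("%s_v%d", sca3$individual_id[i],
                                     sca3$visit[i]),
                 individual_id = sca3$individual_id[i], tissue = "blood"))
write_peak_table(lapply(sims, `[[`, "trace"), "results/example_traces.tsv")
cat("Wrote", length(sims), "simulated traces to results/example_traces.tsv\n")
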