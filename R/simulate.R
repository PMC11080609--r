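# Synthetic-data generators: electropherogram traces with stutter and an
# expansion tail, longitudinal cohorts under the mixed-model data-generating
# process, tissue panels, and qPCR Ct tables. Every generator returns its
# ground truth and is deterministic under a fixed seed.

#' Trace generator configuration
#'
#' Morphology of a synthetic expanded-allele electropherogram: a modal
#' peak, geometric PCR stutter to its left, and a geometric expansion tail
#' to its right whose total mass is solved so the noise-free expansion
#' index hits a requested target. A stable normal-allele cluster (with its
#' own stutter) is included below the expanded window so that window-based
#' allele separation is exercised.
#'
#' @param gene locus (sets bp flank, normal allele and default window).
#' @param modal_cag modal repeat of the expanded allele.
#' @param stutter_decay per-repeat geometric ratio of left stutter in
#'   (0, 1).
#' @param tail_mean mean offset (repeats) of the geometric expansion tail
#'   (>= 1).
#' @param main_height expected fluorescence of the modal peak.
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   peak-height noise (0 = noise free). Default 0.05, the order of
#'   replicate-injection reproducibility of capillary electrophoresis.
#' @param n_stutter number of stutter peaks left of the modal.
#' @param max_delta largest expansion offset with support.
#' @param normal_cag repeat count of the normal allele (NA to omit).
#' @return list of class `trace_gen_config`.
#' @export
trace_gen_config <- function(gene = "ATXN3", modal_cag = 70,
                             stutter_decay = 0.5, tail_mean = 4,
                             main_height = 10000, noise_cv = 0.05,
                             n_stutter = 4, max_delta = 20,
                             normal_cag = c(ATXN1 = 29, ATXN2 = 22,
                                            ATXN3 = 23, ATXN7 = 10)[[gene]]) {
  stopifnot(gene %in% supported_genes(),
            stutter_decay > 0, stutter_decay < 1,
            tail_mean >= 1, main_height > 0, noise_cv >= 0,
            modal_cag >= expanded_window(gene)[1])
  structure(list(gene = gene, modal_cag = as.integer(modal_cag),
                 stutter_decay = stutter_decay, tail_mean = tail_mean,
                 main_height = main_height, noise_cv = noise_cv,
                 n_stutter = as.integer(n_stutter),
                 max_delta = as.integer(max_delta),
                 normal_cag = normal_cag),
            class = "trace_gen_config")
}

# per-gene bp flank so that size_bp = flank + 3 * cag
.gene_flank <- c(ATXN1 = 76, ATXN2 = 94, ATXN3 = 82, ATXN7 = 88)

#' Default calibration for a generator configuration
#'
#' Anchors the linear bp-to-CAG map on the configured modal allele using
#' the generator's own fragment-size model (3 bp per repeat plus a
#' gene-specific flank).
#'
#' @param cfg a [trace_gen_config()].
#' @return a [size_calibration()].
#' @export
sim_calibration <- function(cfg) {
  size_calibration(anchor_bp = .gene_flank[[cfg$gene]] + 3 * cfg$modal_cag,
                   anchor_cag = cfg$modal_cag, gene = cfg$gene)
}

# expansion-tail weights (unnormalized geometric pmf over delta = 1..D)
.tail_weights <- function(cfg) {
  p <- 1 / cfg$tail_mean
  p * (1 - p)^(seq_len(cfg$max_delta) - 1)
}

# noise-free EI for tail mass r over support 1..D (closed form)
.ei_of_mass <- function(r, g, D) {
  d <- seq_len(D)
  sum(r * g[d] * d) / (1 + sum(r * g[d]))
}

# solve support D and mass r so the theta-retained noise-free EI equals
# target; every generated peak is retained by construction
.solve_tail <- function(target, cfg, threshold) {
  g <- .tail_weights(cfg)
  D_all <- seq_len(cfg$max_delta)
  lo <- vapply(D_all, function(D) .ei_of_mass(threshold / g[D], g, D),
               numeric(1))
  hi <- vapply(D_all, function(D) {
    d <- seq_len(D); sum(g[d] * d) / sum(g[d])
  }, numeric(1))
  if (target >= hi[cfg$max_delta])
    stop(sprintf(
      "unreachable target EI %.4f: maximum achievable with this tail is %.4f",
      target, hi[cfg$max_delta]))
  if (target < lo[1])
    stop(sprintf(
      "unreachable target EI %.4f: minimum nonzero EI at threshold %.3g is %.4f (use target 0 for no expansion)",
      target, threshold, lo[1]))
  feas <- which(lo <= target & target < hi)
  if (!length(feas))
    stop(sprintf("target EI %.4f falls in an unreachable gap of the %s",
                 target, "threshold-filtered tail"))
  D <- max(feas)
  d <- seq_len(D)
  A <- sum(g[d] * d); B <- sum(g[d])
  r <- target / (A - target * B)  # exact inverse of .ei_of_mass
  list(D = D, r = r, g = g)
}

#' Generate one synthetic trace with known expansion index
#'
#' Builds noise-free expected heights — modal peak, geometric left
#' stutter, geometric right expansion tail whose mass is solved so that
#' the threshold-retained noise-free EI equals `target_ei` (|error| <
#' 1e-6) — then applies multiplicative lognormal height noise. A
#' normal-allele cluster is added below the expanded window unless
#' disabled in the config.
#'
#' @param cfg a [trace_gen_config()].
#' @param target_ei requested noise-free EI (>= 0). 0 produces no expanded
#'   peaks. Unachievable targets raise a range error stating the
#'   achievable bound.
#' @param threshold relative threshold the EI will be computed with.
#' @param sample_id,individual_id,tissue metadata for the trace.
#' @param seed optional integer seed.
#' @return list of class `sim_trace`: `trace` (a `cag_trace`), `true_ei`
#'   (the exact noise-free EI), `cal` (matching [sim_calibration()]),
#'   `reference_modal`.
#' @export
generate_trace <- function(cfg = trace_gen_config(), target_ei,
                           threshold = 0.03, sample_id = "sim",
                           individual_id = NA_character_,
                           tissue = NA_character_, seed = NULL) {
  stopifnot(inherits(cfg, "trace_gen_config"), target_ei >= 0,
            threshold > 0, threshold < 1)
  if (!is.null(seed)) set.seed(seed)
  h0 <- cfg$main_height
  cag <- cfg$modal_cag
  heights <- c(h0 * cfg$stutter_decay^(cfg$n_stutter:1), h0)
  cags <- c(cag - (cfg$n_stutter:1), cag)
  if (target_ei > 0) {
    sol <- .solve_tail(target_ei, cfg, threshold)
    d <- seq_len(sol$D)
    exp_h <- sol$r * sol$g[d] * h0
    # keep the boundary peak strictly above threshold under exact arithmetic
    exp_h <- pmax(exp_h, threshold * h0 * (1 + 1e-9))
    heights <- c(heights, exp_h)
    cags <- c(cags, cag + d)
  }
  if (!is.na(cfg$normal_cag)) {
    n_h <- c(h0 * cfg$stutter_decay^(2:1), h0)
    n_c <- cfg$normal_cag + (-2:0)
    heights <- c(n_h, heights)
    cags <- c(n_c, cags)
  }
  if (cfg$noise_cv > 0) {
    s <- sqrt(log(1 + cfg$noise_cv^2))
    heights <- heights * stats::rlnorm(length(heights), -s^2 / 2, s)
  }
  cal <- sim_calibration(cfg)
  sizes <- .gene_flank[[cfg$gene]] + 3 * cags
  trace <- new_trace(sample_id, data.frame(size_bp = sizes, height = heights),
                     individual_id = individual_id, gene = cfg$gene,
                     tissue = tissue)
  structure(list(trace = trace, true_ei = target_ei, cal = cal,
                 reference_modal = cfg$modal_cag, config = cfg),
            class = "sim_trace")
}

#' EI ranges emulating fetal and adult-blood presets
#'
#' Fetal central nervous system and trophoblast tissues show near-absent
#' somatic expansion (indexes of roughly 0.04-0.10), while adult blood of
#' mutation carriers shows clear expansion (indexes of roughly 0.4 and
#' above). The presets draw target EIs uniformly from these ranges.
#'
#' @return numeric length-2 range of target EIs.
#' @export
fetal_ei_range <- function() c(0.03, 0.10)

#' @rdname fetal_ei_range
#' @export
adult_blood_ei_range <- function() c(0.40, 1.80)

#' Generate a set of traces with targets drawn from a range
#'
#' @param n number of traces.
#' @param target_range length-2 range; targets are drawn uniformly.
#' @param cfg a [trace_gen_config()].
#' @param threshold relative threshold.
#' @param seed optional seed (fixes both targets and noise).
#' @return list with `sims` (list of `sim_trace`) and `targets`.
#' @export
generate_trace_set <- function(n, target_range, cfg = trace_gen_config(),
                               threshold = 0.03, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  targets <- stats::runif(n, target_range[1], target_range[2])
  sims <- lapply(seq_len(n), function(i)
    generate_trace(cfg, targets[i], threshold,
                   sample_id = sprintf("sim%04d", i)))
  list(sims = sims, targets = targets)
}

#' Cohort generator configuration
#'
#' Defaults encode the longitudinal study design this package analyzes:
#' four disease groups of 30/50/74/30 individuals with mean expanded
#' repeats 48.2/39.7/71.5/44.1, EI-per-year group slopes
#' 0.023/0.012/0.008/0.055, two to three visits spanning 8.5 years on
#' average, and a near-zero EI at birth (fetal repeat stability).
#'
#' @param groups group labels.
#' @param n_individuals individuals per group.
#' @param cag_mean,cag_sd per-group normal distribution of the expanded
#'   repeat (rounded to integers, floored at the locus threshold).
#' @param ei_slope_per_year per-group EI increase per year at the group's
#'   mean repeat.
#' @param ei_at_birth mean of the per-individual EI intercept.
#' @param intercept_sd SD of the per-individual random intercept.
#' @param residual_sd SD of the per-visit residual EI noise.
#' @param cag_slope_coupling relative slope change per repeat above the
#'   group mean (gamma; couples EI to (CAG)n).
#' @param visit_range integer range of visits per individual.
#' @param mean_span mean years between first and last visit.
#' @param baseline_age_range uniform range of the age at first visit.
#' @param onset_mean,onset_sd,onset_cag_shift onset-age model: onset ~
#'   Normal(onset_mean - onset_cag_shift * (cag - cag_mean), onset_sd^2).
#' @param sara_rate SARA points accrued per year after onset.
#' @return list of class `cohort_gen_config`.
#' @export
cohort_gen_config <- function(groups = c("SCA1", "SCA2", "SCA3", "SCA7"),
                              n_individuals = c(30, 50, 74, 30),
                              cag_mean = c(48.2, 39.7, 71.5, 44.1),
                              cag_sd = c(5, 3.5, 4, 5),
                              ei_slope_per_year = c(0.023, 0.012, 0.008, 0.055),
                              ei_at_birth = 0.02,
                              intercept_sd = 0.10,
                              residual_sd = 0.15,
                              cag_slope_coupling = 0.05,
                              visit_range = c(2L, 3L),
                              mean_span = 8.5,
                              baseline_age_range = c(25, 65),
                              onset_mean = 35, onset_sd = 8,
                              onset_cag_shift = 0.8,
                              sara_rate = 1.5) {
  k <- length(groups)
  stopifnot(length(n_individuals) == k, length(cag_mean) == k,
            length(cag_sd) == k, length(ei_slope_per_year) == k,
            all(cag_sd >= 0), all(ei_slope_per_year >= 0),
            intercept_sd >= 0, residual_sd >= 0, mean_span > 0)
  structure(list(groups = groups, n_individuals = n_individuals,
                 cag_mean = cag_mean, cag_sd = cag_sd,
                 ei_slope_per_year = ei_slope_per_year,
                 ei_at_birth = ei_at_birth, intercept_sd = intercept_sd,
                 residual_sd = residual_sd,
                 cag_slope_coupling = cag_slope_coupling,
                 visit_range = as.integer(visit_range),
                 mean_span = mean_span,
                 baseline_age_range = baseline_age_range,
                 onset_mean = onset_mean, onset_sd = onset_sd,
                 onset_cag_shift = onset_cag_shift, sara_rate = sara_rate),
            class = "cohort_gen_config")
}

#' Generate a longitudinal visit table
#'
#' Implements the data-generating process the mixed-effects analysis
#' assumes: per individual, a rounded-normal expanded repeat, a random EI
#' intercept, and per-visit
#' `EI = b0 + slope_g * (1 + gamma * (cag - mean_g)) * age + noise`,
#' floored at zero. Clinical course: onset age shifts earlier with larger
#' repeats; SARA accrues linearly after onset, so disease status follows a
#' SARA trajectory crossing the 3.5 manifest threshold.
#'
#' @param cfg a [cohort_gen_config()].
#' @param seed optional integer seed (same seed, identical output).
#' @return data.frame of visits (`individual_id`, `group`, `gene`,
#'   `visit`, `age`, `cag_n`, `ei`, `sara`, `disease_duration`,
#'   `status_clinical`, `status_sara`) with a `truth` attribute holding
#'   the per-individual generating values (`cag_n`, `slope_true`,
#'   `intercept_true`, `onset_age`).
#' @export
generate_cohort <- function(cfg = cohort_gen_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  visit_rows <- list(); truth_rows <- list()
  for (g in seq_along(cfg$groups)) {
    grp <- cfg$groups[g]
    gene <- if (grp %in% names(.group_gene)) .group_gene[[grp]] else NA_character_
    floor_cag <- if (!is.na(gene)) expanded_window(gene)[1] else 1
    for (i in seq_len(cfg$n_individuals[g])) {
      id <- sprintf("%s_%03d", grp, i)
      cag <- max(floor_cag, round(stats::rnorm(1, cfg$cag_mean[g], cfg$cag_sd[g])))
      slope_i <- max(0, cfg$ei_slope_per_year[g] *
                       (1 + cfg$cag_slope_coupling * (cag - cfg$cag_mean[g])))
      b0 <- stats::rnorm(1, cfg$ei_at_birth, cfg$intercept_sd)
      onset <- stats::rnorm(1, cfg$onset_mean -
                              cfg$onset_cag_shift * (cag - cfg$cag_mean[g]),
                            cfg$onset_sd)
      nv <- sample(seq(cfg$visit_range[1], cfg$visit_range[2]), 1)
      base_age <- stats::runif(1, cfg$baseline_age_range[1],
                               cfg$baseline_age_range[2])
      span <- stats::rgamma(1, shape = 4, rate = 4 / cfg$mean_span)
      ages <- base_age + seq(0, span, length.out = nv)
      ei <- pmax(0, b0 + slope_i * ages +
                   stats::rnorm(nv, 0, cfg$residual_sd))
      sara <- pmin(40, pmax(0, cfg$sara_rate * (ages - onset)))
      visit_rows[[id]] <- data.frame(
        individual_id = id, group = grp, gene = gene, visit = seq_len(nv),
        age = ages, cag_n = cag, ei = ei, sara = sara,
        disease_duration = ifelse(ages > onset, ages - onset, NA_real_),
        status_clinical = ifelse(ages >= onset, "manifest", "premanifest"),
        status_sara = ifelse(sara > 3.5, "ataxic", "preataxic"),
        stringsAsFactors = FALSE)
      truth_rows[[id]] <- data.frame(
        individual_id = id, group = grp, cag_n = cag, slope_true = slope_i,
        intercept_true = b0, onset_age = onset, stringsAsFactors = FALSE)
    }
  }
  visits <- do.call(rbind, visit_rows)
  rownames(visits) <- NULL
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  attr(visits, "truth") <- truth
  visits
}

#' Generate a tissue panel for synthetic brain donors
#'
#' Per donor, one trace per tissue with target EIs drawn from configured
#' ranges. Defaults order cerebellum below brainstem and cortex (the
#' cerebellum is the most repeat-stable brain region, the cortex the most
#' unstable), and the cerebellum preset additionally shifts the modal
#' repeat by -1 relative to the donor's diagnostic repeat.
#'
#' @param n_donors number of donors.
#' @param cfg a [trace_gen_config()] giving the donor's locus and
#'   diagnostic modal repeat.
#' @param tissue_ranges named list of target-EI ranges per tissue.
#' @param cerebellum_shift repeats subtracted from the modal in the
#'   cerebellum (default 1).
#' @param threshold relative threshold.
#' @param seed optional seed.
#' @return list with `sims` (list of `sim_trace`, metadata filled) and
#'   `truth` (data.frame donor x tissue with `target_ei`, `modal_cag`,
#'   `reference_modal`).
#' @export
generate_tissue_panel <- function(n_donors = 1,
                                  cfg = trace_gen_config(),
                                  tissue_ranges = list(
                                    cerebellum = c(0.35, 0.75),
                                    pons = c(1.1, 1.9),
                                    thalamus = c(1.2, 1.8),
                                    frontal_cortex = c(1.6, 2.6)),
                                  cerebellum_shift = 1L,
                                  threshold = 0.03, seed = NULL) {
  stopifnot(length(tissue_ranges) >= 1)
  if (!is.null(seed)) set.seed(seed)
  sims <- list(); truth <- list()
  for (d in seq_len(n_donors)) {
    donor <- sprintf("donor%02d", d)
    for (tis in names(tissue_ranges)) {
      rng <- tissue_ranges[[tis]]
      target <- stats::runif(1, rng[1], rng[2])
      cfg_t <- cfg
      if (tis == "cerebellum")
        cfg_t$modal_cag <- cfg$modal_cag - as.integer(cerebellum_shift)
      sim <- generate_trace(cfg_t, target, threshold,
                            sample_id = paste(donor, tis, sep = "_"),
                            individual_id = donor, tissue = tis)
      sims[[sim$trace$sample_id]] <- sim
      truth[[sim$trace$sample_id]] <- data.frame(
        individual_id = donor, tissue = tis, target_ei = target,
        modal_cag = cfg_t$modal_cag, reference_modal = cfg$modal_cag,
        stringsAsFactors = FALSE)
    }
  }
  tr <- do.call(rbind, truth)
  rownames(tr) <- NULL
  list(sims = sims, truth = tr)
}

#' Generate a synthetic qPCR Ct table
#'
#' Reference-gene Cts around 20 cycles; target dCt per gene drawn once,
#' shifted by a per-tissue log2 expression effect (cerebellum high,
#' cortex low by default, matching the tissue contrast the expression
#' stage displays) plus replicate noise.
#'
#' @param individuals character vector of individual ids.
#' @param tissues tissues per individual (must include the baseline
#'   cerebellum for normalization).
#' @param genes genes of interest.
#' @param tissue_log2 named per-tissue log2 expression shifts.
#' @param n_replicates technical replicates per individual x tissue x gene.
#' @param replicate_sd SD of replicate Ct noise (cycles).
#' @param seed optional seed.
#' @return data.frame with `individual_id`, `tissue`, `gene`,
#'   `replicate`, `ct_target`, `ct_reference` and a `truth` attribute of
#'   per-gene per-tissue true log2 fold changes vs cerebellum.
#' @export
generate_ct_table <- function(individuals = c("i1", "i2"),
                              tissues = c("cerebellum", "frontal_cortex",
                                          "blood"),
                              genes = c("ATXN3", "MSH3", "FAN1", "MLH1"),
                              tissue_log2 = c(cerebellum = 1,
                                              frontal_cortex = -1,
                                              blood = 0),
                              n_replicates = 2, replicate_sd = 0.1,
                              seed = NULL) {
  stopifnot("cerebellum" %in% tissues,
            all(tissues %in% names(tissue_log2)))
  if (!is.null(seed)) set.seed(seed)
  base_dct <- stats::setNames(stats::runif(length(genes), 2, 8), genes)
  rows <- list()
  for (ind in individuals) for (tis in tissues) for (gn in genes) {
    ct_ref <- stats::rnorm(n_replicates, 20, 0.3)
    ct_tgt <- ct_ref + base_dct[[gn]] - tissue_log2[[tis]] +
      stats::rnorm(n_replicates, 0, replicate_sd)
    rows[[paste(ind, tis, gn)]] <- data.frame(
      individual_id = ind, tissue = tis, gene = gn,
      replicate = seq_len(n_replicates),
      ct_target = ct_tgt, ct_reference = ct_ref, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  truth <- expand.grid(gene = genes, tissue = tissues,
                       stringsAsFactors = FALSE)
  truth$true_log2_fc <- tissue_log2[truth$tissue] - tissue_log2[["cerebellum"]]
  attr(out, "truth") <- truth
  out
}
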