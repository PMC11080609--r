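# Per-trace somatic instability metrics: modal CAG call, expansion index,
# percent-mutant-allele profile, count of additional repeats.

#' Expanded-allele window for a locus
#'
#' Traces carry both the normal and the expanded allele. Analysis is
#' restricted to the expanded-allele cluster with a per-gene window whose
#' default lower bound is the locus' pathological repeat threshold
#' (ATXN1 >= 39, ATXN2 >= 33, ATXN3 >= 55, ATXN7 >= 36), upper bound
#' unbounded.
#'
#' @param gene one of [supported_genes()].
#' @return numeric length-2 vector `c(lower, upper)` in repeat units.
#' @export
expanded_window <- function(gene) {
  lo <- c(ATXN1 = 39, ATXN2 = 33, ATXN3 = 55, ATXN7 = 36)
  if (is.na(gene) || !gene %in% names(lo))
    stop("no default expanded window: unknown gene '", gene,
         "'; supply `window` explicitly")
  c(lo[[gene]], Inf)
}

# map a trace's peaks into repeat space, summing heights that bin to the
# same repeat count, restricted to the window
.repeat_bins <- function(trace, cal, window) {
  cag <- bp_to_cag(trace$peaks$size_bp, .cal_for_trace(trace, cal))
  h <- tapply(trace$peaks$height, cag, sum)
  d <- data.frame(cag = as.integer(names(h)), height = as.numeric(h))
  d[d$cag >= window[1] & d$cag <= window[2], , drop = FALSE]
}

#' Call the modal CAG of a trace
#'
#' The repeat count of the maximum-height peak within the expanded-allele
#' window (the main signal of the PCR product cluster, i.e. the diagnostic
#' allele size). Ties are broken toward the smaller repeat so that stutter
#' asymmetry cannot inflate the call.
#'
#' @param trace a `cag_trace`.
#' @param cal calibration (see [write_trace_table()] for list form).
#' @param window inclusive CAG range; default [expanded_window()] of the
#'   trace's gene.
#' @return integer modal repeat count.
#' @export
call_modal_peak <- function(trace, cal, window = expanded_window(trace$gene)) {
  bins <- .repeat_bins(trace, cal, window)
  if (nrow(bins) == 0)
    stop("no peak in the expanded window [", window[1], ", ", window[2],
         "] for trace ", trace$sample_id)
  cands <- bins$cag[bins$height == max(bins$height)]
  as.integer(min(cands))
}

#' Expansion index of one trace
#'
#' Quantifies somatic expansion beyond the inherited allele. With \eqn{h_0}
#' the height at the reference modal repeat, candidate expanded peaks are
#' those at offsets \eqn{d_i \ge 1} inside the window; a peak is retained
#' iff \eqn{h_i \ge \theta h_0} (relative threshold, default 0.03). With
#' \eqn{S = h_0 + \sum h_i} over retained peaks,
#' \deqn{EI = \sum_i (h_i / S) \, d_i,}
#' the sum of normalized heights weighted by peak position. Peaks left of
#' the modal peak are PCR stutter and never counted. EI = 0 means no
#' expansion beyond the inherited allele.
#'
#' For longitudinal data the reference modal is fixed per individual (see
#' [longitudinal_reference_modal()]); when a trace's own tallest peak
#' drifts above the reference, those taller peaks count as expansion
#' signal, which keeps the longitudinal convention well defined.
#'
#' @param trace a `cag_trace`.
#' @param reference_modal integer reference repeat; default the trace's own
#'   modal call.
#' @param threshold relative cutoff \eqn{\theta \in (0, 1)}.
#' @param cal calibration.
#' @param window inclusive CAG range of the expanded-allele cluster.
#' @param normalize `"retained"` (default) normalizes by the modal plus
#'   theta-retained peaks; `"all"` normalizes by all candidate expanded
#'   peaks while still summing only retained ones.
#' @return an `instability_profile`: list with `trace_id`, `gene`,
#'   `tissue`, `modal_cag` (the trace's own call), `reference_modal`,
#'   `threshold`, `ei`, `n_additional_cags` (largest retained offset),
#'   `peaks` (retained expanded peaks with `cag`, `delta`, `height`,
#'   `rel_height`) and `percent_by_cag`.
#' @export
#' @examples
#' cal <- size_calibration(195, 45, gene = "ATXN1")
#' tr <- new_trace("s1", data.frame(size_bp = c(195, 198, 201, 204),
#'                                  height = c(1000, 300, 90, 20)),
#'                 gene = "ATXN1")
#' compute_ei(tr, cal = cal)$ei # (300*1 + 90*2) / 1390 = 0.3453
compute_ei <- function(trace, reference_modal = NULL, threshold = 0.03,
                       cal, window = expanded_window(trace$gene),
                       normalize = c("retained", "all")) {
  normalize <- match.arg(normalize)
  stopifnot(threshold > 0, threshold < 1)
  modal <- call_modal_peak(trace, cal, window)
  reference_modal <- as.integer(reference_modal %||% modal)
  stopifnot(reference_modal >= 1)
  bins <- .repeat_bins(trace, cal, window)
  h0 <- bins$height[match(reference_modal, bins$cag)]
  if (is.na(h0) || h0 == 0)
    stop("missing-modal error: no peak at reference modal ", reference_modal,
         " in trace ", trace$sample_id,
         " (trace modal is ", modal, "); resolve with call_modal_peak()")
  cand <- bins[bins$cag > reference_modal, , drop = FALSE]
  cand$delta <- cand$cag - reference_modal
  retained <- cand[cand$height >= threshold * h0, , drop = FALSE]
  S <- h0 + sum(if (normalize == "retained") retained$height else cand$height)
  ei <- sum(retained$height / S * retained$delta)
  pk <- data.frame(cag = c(reference_modal, retained$cag),
                   delta = c(0L, retained$delta),
                   height = c(h0, retained$height))
  pk$rel_height <- pk$height / h0
  pct <- 100 * pk$height / S
  names(pct) <- pk$cag
  structure(list(trace_id = trace$sample_id, gene = trace$gene,
                 tissue = trace$tissue, modal_cag = modal,
                 reference_modal = reference_modal, threshold = threshold,
                 ei = ei,
                 n_additional_cags = if (nrow(retained)) max(retained$delta) else 0L,
                 peaks = pk, percent_by_cag = pct),
            class = "instability_profile")
}

#' @export
print.instability_profile <- function(x, ...) {
  cat("<instability_profile>", x$trace_id,
      if (!is.na(x$gene)) paste0("[", x$gene, "]"), "\n",
      " modal", x$modal_cag, "| reference", x$reference_modal,
      "| EI", sprintf("%.4f", x$ei),
      "| +", x$n_additional_cags, "CAG\n")
  invisible(x)
}

#' Percent-mutant-allele profile
#'
#' Distribution of the mutant-allele PCR signal over repeat lengths: for
#' the modal peak plus each theta-retained expanded peak,
#' `percent(cag) = 100 * h / S`. Each additional peak corresponds to one
#' additional CAG repeat; values sum to 100.
#'
#' @inheritParams compute_ei
#' @return named numeric vector (names are repeat counts).
#' @export
percent_mutant_alleles <- function(trace, reference_modal = NULL,
                                   threshold = 0.03, cal,
                                   window = expanded_window(trace$gene)) {
  compute_ei(trace, reference_modal, threshold, cal, window)$percent_by_cag
}

#' Fixed per-individual reference modal CAG
#'
#' For longitudinal comparability the same modal CAG is used for all traces
#' from the same individual: the diagnostic repeat count when known,
#' otherwise the modal call of the earliest trace (smallest age at sample,
#' first listed when ages are missing).
#'
#' @param traces list of `cag_trace` from one individual.
#' @param diagnostic_cag optional known diagnostic repeat count.
#' @param cal calibration (unused when `diagnostic_cag` is given).
#' @param window CAG window (default from the first trace's gene).
#' @return integer reference modal.
#' @export
longitudinal_reference_modal <- function(traces, diagnostic_cag = NULL, cal,
                                         window = NULL) {
  stopifnot(length(traces) >= 1)
  if (!is.null(diagnostic_cag)) return(as.integer(diagnostic_cag))
  ages <- vapply(traces, function(tr) tr$age %||% NA_real_, numeric(1))
  first <- if (all(is.na(ages))) 1L else which.min(ages)
  tr <- traces[[first]]
  call_modal_peak(tr, cal, window %||% expanded_window(tr$gene))
}

#' Instability metrics for a set of traces
#'
#' Convenience wrapper: traces are grouped by individual, a fixed
#' per-individual reference modal is derived with
#' [longitudinal_reference_modal()] (or taken from `diagnostic_cag`), and
#' [compute_ei()] is run per trace.
#'
#' @param traces list of `cag_trace`.
#' @param cal calibration object or keyed list.
#' @param threshold relative threshold.
#' @param diagnostic_cag optional named vector of diagnostic repeat counts
#'   keyed by `individual_id`.
#' @return data.frame with one row per trace: `trace_id`, `individual_id`,
#'   `gene`, `tissue`, `age`, `modal_cag`, `reference_modal`, `ei`,
#'   `n_additional_cags`.
#' @export
instability_table <- function(traces, cal, threshold = 0.03,
                              diagnostic_cag = NULL) {
  ids <- vapply(traces, function(tr)
    if (is.na(tr$individual_id)) tr$sample_id else tr$individual_id,
    character(1))
  rows <- lapply(split(seq_along(traces), ids), function(idx) {
    grp <- traces[idx]
    dc <- NULL
    id <- grp[[1]]$individual_id
    if (!is.null(diagnostic_cag) && !is.na(id) && id %in% names(diagnostic_cag))
      dc <- diagnostic_cag[[id]]
    ref <- longitudinal_reference_modal(grp, diagnostic_cag = dc, cal = cal)
    do.call(rbind, lapply(grp, function(tr) {
      p <- compute_ei(tr, reference_modal = ref, threshold = threshold,
                      cal = cal)
      data.frame(trace_id = tr$sample_id, individual_id = tr$individual_id,
                 gene = tr$gene, tissue = tr$tissue, age = tr$age,
                 modal_cag = p$modal_cag, reference_modal = p$reference_modal,
                 ei = p$ei, n_additional_cags = p$n_additional_cags,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
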