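# Relative qPCR expression by the 2^-ddCt method with per-individual
# cerebellum normalization, and row scaling for heatmap display.

#' One qPCR Ct record
#'
#' @param individual_id,tissue,gene identifiers; `gene` is the gene of
#'   interest (an ataxin or DNA-repair gene).
#' @param ct_target cycle threshold of the gene of interest.
#' @param ct_reference cycle threshold of the normalizer gene (PPIA-style
#'   housekeeping control) on the same sample.
#' @return one-row data.frame.
#' @export
ct_record <- function(individual_id, tissue, gene, ct_target, ct_reference) {
  stopifnot(is.finite(ct_target), ct_target > 0,
            is.finite(ct_reference), ct_reference > 0)
  data.frame(individual_id = individual_id, tissue = tissue, gene = gene,
             ct_target = ct_target, ct_reference = ct_reference,
             stringsAsFactors = FALSE)
}

#' Relative expression by 2^-ddCt
#'
#' Per record, dCt = ct_target - ct_reference; ddCt = dCt_sample -
#' dCt_baseline; the fold change is `2^-ddCt`. The baseline is the same
#' individual's cerebellum sample for the same gene of interest.
#'
#' @param sample,baseline one-row data.frames as from [ct_record()].
#' @param baseline_tissue required tissue of the baseline record.
#' @return positive fold change (1 when sample equals baseline).
#' @export
#' @examples
#' b <- ct_record("i1", "cerebellum", "MSH3", 24, 20)
#' s <- ct_record("i1", "frontal_cortex", "MSH3", 25, 20)
#' fold_change_ddct(s, b) # ddCt = 1 -> 0.5
fold_change_ddct <- function(sample, baseline, baseline_tissue = "cerebellum") {
  if (sample$individual_id != baseline$individual_id ||
      sample$gene != baseline$gene)
    stop("pairing error: sample and baseline must share individual_id ",
         "and gene of interest")
  if (!identical(baseline$tissue, baseline_tissue))
    stop("baseline-missing error: baseline record must be the individual's ",
         baseline_tissue, " sample")
  dct_s <- sample$ct_target - sample$ct_reference
  dct_b <- baseline$ct_target - baseline$ct_reference
  2^(-(dct_s - dct_b))
}

#' Fold-change table with per-individual cerebellum normalization
#'
#' Technical replicate Cts (several rows per individual x tissue x gene)
#' are averaged before dCt. Each individual x gene is normalized to that
#' individual's cerebellum.
#'
#' @param ct data.frame with columns `individual_id`, `tissue`, `gene`,
#'   `ct_target`, `ct_reference`.
#' @param baseline_tissue normalizing tissue (default cerebellum).
#' @return data.frame `individual_id`, `tissue`, `gene`, `fold_change`.
#' @export
fold_change_table <- function(ct, baseline_tissue = "cerebellum") {
  need <- c("individual_id", "tissue", "gene", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(ct)))
  agg <- stats::aggregate(cbind(ct_target, ct_reference) ~
                            individual_id + tissue + gene,
                          data = ct, FUN = mean)
  agg$dct <- agg$ct_target - agg$ct_reference
  base <- agg[agg$tissue == baseline_tissue,
              c("individual_id", "gene", "dct")]
  names(base)[3] <- "dct_baseline"
  m <- merge(agg, base, by = c("individual_id", "gene"), all.x = TRUE)
  if (anyNA(m$dct_baseline)) {
    miss <- unique(m$individual_id[is.na(m$dct_baseline)])
    stop("baseline-missing error: no ", baseline_tissue, " record for ",
         paste(miss, collapse = ", "))
  }
  m$fold_change <- 2^(-(m$dct - m$dct_baseline))
  out <- m[order(m$gene, m$individual_id, m$tissue),
           c("individual_id", "tissue", "gene", "fold_change")]
  rownames(out) <- NULL
  out
}

#' Row-standardize a fold-change matrix for heatmap display
#'
#' Each row (gene) is scaled to zero mean and unit sample variance.
#' Constant rows carry no contrast and are set to all zeros with a
#' warning. Scaling is for display only; stored fold changes are never
#' clipped or transformed in place.
#'
#' @param mat numeric matrix, genes in rows, samples in columns.
#' @return matrix of the same shape and dimnames.
#' @export
scale_for_heatmap <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need >= 2 samples (columns) to scale")
  out <- t(apply(mat, 1, function(r) {
    s <- stats::sd(r)
    if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  if (any(apply(mat, 1, stats::sd) == 0))
    warning("constant row(s) scaled to all zeros")
  dimnames(out) <- dimnames(mat)
  out
}
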