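# Reading/writing fragment-analysis peak tables and clinical visit tables,
# and the bp -> CAG size calibration.

#' Column dialect for peak tables
#'
#' Maps the canonical peak-table fields onto the column names used by a
#' particular export. `sample`, `size_bp` and `height` are mandatory in any
#' dialect; `area` and `scan` are optional and tolerated when absent.
#'
#' @param sample,size_bp,height,area,scan column names in the file.
#' @return named character vector of class `peak_dialect`.
#' @seealso [genemapper_dialect()] for the fragment-sizing software export.
#' @export
peak_dialect <- function(sample = "sample_id", size_bp = "size_bp",
                         height = "height", area = "area", scan = "scan") {
  structure(c(sample = sample, size_bp = size_bp, height = height,
              area = area, scan = scan), class = "peak_dialect")
}

#' Dialect matching the GeneMapper sample-plot export
#'
#' Field list of the per-sample data table exported from the fragment-sizing
#' software: sample name, called allele, peak size (bp), peak height, area
#' under the peak, and data point/scan number.
#'
#' @return a `peak_dialect`.
#' @export
genemapper_dialect <- function() {
  peak_dialect(sample = "Sample Name", size_bp = "Size",
               height = "Height", area = "Area", scan = "Data Point")
}

#' Construct a trace
#'
#' A trace is the set of called peaks for one sample (one PCR of one tissue
#' of one individual), plus sample metadata. Peaks are stored sorted by
#' fragment size; duplicated sizes within a trace are rejected.
#'
#' @param sample_id sample name (unique per trace).
#' @param peaks data.frame with numeric columns `size_bp` (> 0) and
#'   `height` (>= 0); optional `area`, `scan`.
#' @param individual_id,gene,tissue,age,plate_id optional metadata. `gene`
#'   must be one of [supported_genes()] when given.
#' @return object of class `cag_trace`.
#' @export
new_trace <- function(sample_id, peaks, individual_id = NA_character_,
                      gene = NA_character_, tissue = NA_character_,
                      age = NA_real_, plate_id = NA_character_) {
  stopifnot(is.data.frame(peaks), all(c("size_bp", "height") %in% names(peaks)))
  if (nrow(peaks) < 1) stop("trace '", sample_id, "' has no peaks")
  if (!all(is.finite(peaks$size_bp)) || any(peaks$size_bp <= 0))
    stop("trace '", sample_id, "': size_bp must be positive and finite")
  if (!all(is.finite(peaks$height)) || any(peaks$height < 0))
    stop("trace '", sample_id, "': height must be non-negative and finite")
  if (!is.na(gene) && !gene %in% supported_genes())
    stop("unsupported gene '", gene, "'; expected one of ",
         paste(supported_genes(), collapse = ", "))
  peaks <- peaks[order(peaks$size_bp), , drop = FALSE]
  if (anyDuplicated(peaks$size_bp))
    stop("trace '", sample_id, "': duplicated peak size_bp")
  rownames(peaks) <- NULL
  structure(list(sample_id = sample_id, individual_id = individual_id,
                 gene = gene, tissue = tissue, age = age,
                 plate_id = plate_id, peaks = peaks),
            class = "cag_trace")
}

#' @export
print.cag_trace <- function(x, ...) {
  cat("<cag_trace>", x$sample_id,
      if (!is.na(x$gene)) paste0("[", x$gene, "]"),
      if (!is.na(x$tissue)) x$tissue,
      "-", nrow(x$peaks), "peaks,",
      sprintf("%.1f-%.1f bp", min(x$peaks$size_bp), max(x$peaks$size_bp)), "\n")
  invisible(x)
}

#' Read a peak table into traces
#'
#' Reads a delimited table with one row per called peak and partitions it
#' into one trace per sample name. Peaks are sorted by fragment size.
#' Sample metadata (individual, gene, tissue, age, plate) can be joined
#' from a sample sheet keyed by `sample_id`.
#'
#' @param path path to the peak table (TSV by default).
#' @param dialect a [peak_dialect()] mapping canonical fields to columns.
#' @param sample_sheet optional data.frame or TSV path with a `sample_id`
#'   column and any of `individual_id`, `gene`, `tissue`, `age`, `plate_id`.
#' @param sep field separator.
#' @return named list of `cag_trace` objects (empty, with a warning, for a
#'   header-only file).
#' @export
read_peak_table <- function(path, dialect = peak_dialect(),
                            sample_sheet = NULL, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  for (field in c("sample", "size_bp", "height")) {
    if (!dialect[[field]] %in% names(raw))
      stop("format error: missing mandatory column '", dialect[[field]],
           "' (", field, ") in ", path)
  }
  if (nrow(raw) == 0) {
    warning("peak table ", path, " has a header but no rows")
    return(structure(list(), names = character(0)))
  }
  num <- function(field) {
    col <- dialect[[field]]
    if (!col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & trimws(raw[[col]]) != "")
    if (length(bad))
      stop("parse error: non-numeric '", col, "' value '",
           raw[[col]][bad[1]], "' at line ", bad[1] + 1L, " of ", path)
    v
  }
  tab <- data.frame(sample_id = as.character(raw[[dialect[["sample"]]]]),
                    size_bp = num("size_bp"), height = num("height"),
                    area = num("area"), scan = num("scan"),
                    stringsAsFactors = FALSE)
  meta <- NULL
  if (!is.null(sample_sheet)) {
    meta <- if (is.character(sample_sheet))
      utils::read.delim(sample_sheet, sep = sep, stringsAsFactors = FALSE)
    else as.data.frame(sample_sheet)
    if (!"sample_id" %in% names(meta))
      stop("sample sheet must have a 'sample_id' column")
  }
  traces <- lapply(split(tab, tab$sample_id), function(d) {
    m <- if (!is.null(meta)) meta[match(d$sample_id[1], meta$sample_id), ] else NULL
    get_meta <- function(col, default) {
      if (!is.null(m) && col %in% names(m) && !is.na(m[[col]])) m[[col]] else default
    }
    new_trace(d$sample_id[1],
              d[c("size_bp", "height", "area", "scan")],
              individual_id = get_meta("individual_id", NA_character_),
              gene = get_meta("gene", NA_character_),
              tissue = get_meta("tissue", NA_character_),
              age = as.numeric(get_meta("age", NA_real_)),
              plate_id = get_meta("plate_id", NA_character_))
  })
  traces[order(names(traces))]
}

#' Write traces back to a peak table
#'
#' Inverse of [read_peak_table()] under the default dialect; full precision
#' is kept so a read-write-read round trip preserves peak fields.
#'
#' @param traces list of `cag_trace`.
#' @param path output TSV path.
#' @export
write_peak_table <- function(traces, path) {
  rows <- do.call(rbind, lapply(traces, function(tr)
    cbind(sample_id = tr$sample_id, tr$peaks)))
  utils::write.table(format(rows, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Size calibration anchored on an internal standard
#'
#' Fragment sizes in bp are mapped to integer CAG counts by a linear map
#' anchored on one internal-standard sample of known repeat count, specific
#' for each gene and plate. CAG is a trinucleotide, so the default is
#' 3 bp per repeat.
#'
#' @param anchor_bp fragment size (bp) of the standard's modal peak.
#' @param anchor_cag known repeat count of the standard (>= 1).
#' @param repeat_unit_bp bp per repeat unit (> 0).
#' @param gene,plate_id optional identifiers for bookkeeping.
#' @return object of class `cag_calibration`.
#' @export
size_calibration <- function(anchor_bp, anchor_cag, repeat_unit_bp = 3,
                             gene = NA_character_, plate_id = NA_character_) {
  stopifnot(is.numeric(anchor_bp), anchor_bp > 0,
            anchor_cag >= 1, anchor_cag == as.integer(anchor_cag),
            repeat_unit_bp > 0)
  structure(list(anchor_bp = anchor_bp, anchor_cag = as.integer(anchor_cag),
                 repeat_unit_bp = repeat_unit_bp, gene = gene,
                 plate_id = plate_id),
            class = "cag_calibration")
}

#' Convert fragment size to repeat count
#'
#' `anchor_cag + round((size_bp - anchor_bp) / repeat_unit_bp)`, rounding
#' half away from zero: sub-repeat electrophoretic mobility drift is binned
#' to the nearest repeat.
#'
#' @param size_bp numeric vector of fragment sizes (bp).
#' @param cal a [size_calibration()].
#' @return integer vector of repeat counts (always >= 1; smaller results
#'   indicate a bad calibration and raise an error).
#' @export
#' @examples
#' cal <- size_calibration(anchor_bp = 250, anchor_cag = 54)
#' bp_to_cag(259, cal) # 57
bp_to_cag <- function(size_bp, cal) {
  stopifnot(inherits(cal, "cag_calibration"))
  k <- round_half_away((size_bp - cal$anchor_bp) / cal$repeat_unit_bp)
  out <- cal$anchor_cag + as.integer(k)
  if (any(out < 1))
    stop("calibration error: size ", size_bp[which(out < 1)[1]],
         " bp maps to repeat count < 1")
  out
}

#' Load calibrations from a YAML config
#'
#' The file holds a list of entries with fields `gene`, `plate_id`
#' (optional), `anchor_bp`, `anchor_cag` and optional `repeat_unit_bp`.
#' Entries are keyed `gene` or `gene:plate_id` when a plate is given.
#'
#' @param path YAML file path.
#' @return named list of `cag_calibration` objects.
#' @export
load_calibrations <- function(path) {
  entries <- yaml::read_yaml(path)
  out <- lapply(entries, function(e)
    size_calibration(anchor_bp = e$anchor_bp, anchor_cag = e$anchor_cag,
                     repeat_unit_bp = e$repeat_unit_bp %||% 3,
                     gene = e$gene %||% NA_character_,
                     plate_id = e$plate_id %||% NA_character_))
  names(out) <- vapply(entries, function(e)
    if (is.null(e$plate_id)) e$gene else paste(e$gene, e$plate_id, sep = ":"),
    character(1))
  out
}

#' Read a clinical visit table
#'
#' One row per individual-visit with `individual_id`, `group` (or `gene`),
#' `age`, `cag_n` and optionally `sara`, `disease_duration`,
#' `status_clinical` and `ei`. The SARA-based status is derived here:
#' ataxic iff SARA > 3.5 (manifest ataxia threshold), preataxic otherwise.
#'
#' @param path TSV path.
#' @return data.frame with a `status_sara` column added when `sara` is
#'   present.
#' @export
read_visit_table <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "age", "cag_n")
  miss <- setdiff(need, names(v))
  if (length(miss))
    stop("format error: visit table missing column(s) ",
         paste(miss, collapse = ", "))
  if (!any(c("group", "gene") %in% names(v)))
    stop("format error: visit table needs a 'group' or 'gene' column")
  if (!"group" %in% names(v))
    v$group <- names(.group_gene)[match(v$gene, .group_gene)]
  if ("sara" %in% names(v)) {
    if (any(v$sara < 0 | v$sara > 40, na.rm = TRUE))
      stop("SARA scores must lie in [0, 40]")
    v$status_sara <- ifelse(is.na(v$sara), NA_character_,
                            ifelse(v$sara > 3.5, "ataxic", "preataxic"))
  }
  v
}

#' Write the normalized per-peak table
#'
#' Long-format output with one row per peak, sizes converted to repeat
#' counts: columns `sample_id`, `individual_id`, `gene`, `tissue`, `cag`,
#' `height`.
#'
#' @param traces list of `cag_trace`.
#' @param cal a single [size_calibration()] or a named list keyed by gene
#'   (or `gene:plate_id`) as returned by [load_calibrations()].
#' @param path output TSV path, or `NULL` to return the data.frame only.
#' @return the normalized data.frame, invisibly when written.
#' @export
write_trace_table <- function(traces, cal, path = NULL) {
  rows <- do.call(rbind, lapply(traces, function(tr) {
    tc <- .cal_for_trace(tr, cal)
    data.frame(sample_id = tr$sample_id, individual_id = tr$individual_id,
               gene = tr$gene, tissue = tr$tissue,
               cag = bp_to_cag(tr$peaks$size_bp, tc),
               height = tr$peaks$height, stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  if (is.null(path)) return(rows)
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}

# resolve a calibration for one trace from a single object or keyed list
.cal_for_trace <- function(trace, cal) {
  if (inherits(cal, "cag_calibration")) return(cal)
  key <- paste(trace$gene, trace$plate_id, sep = ":")
  cal[[key]] %||% cal[[trace$gene]] %||%
    stop("no calibration for gene ", trace$gene, " (plate ",
         trace$plate_id, ")")
}
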