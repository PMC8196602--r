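# Hybridization quality control and quantile normalization.
#
# FFPE-derived RNA is frequently degraded, so arrays are screened before
# analysis: the fraction of probesets detectably expressed (%P) must be
# at least 50%, and the GAPDH 3':5' intensity ratio at most 3 (a high
# ratio means the 5' end of the transcript was lost to degradation).

# ordinary (non-control) probe ids of a matrix, via the annotation
.noncontrol_probes <- function(matrix, annotation) {
  ann <- annotation[match(rownames(matrix), annotation$probe_id), ]
  if (anyNA(ann$probe_id))
    stop("annotation does not cover probe(s): ",
         paste(utils::head(rownames(matrix)[is.na(ann$probe_id)], 3),
               collapse = ", "))
  rownames(matrix)[ann$control_class == "none"]
}

#' Detection calls against negative-control background
#'
#' A probeset is called *present* in a sample when its log2 intensity
#' strictly exceeds the median of the sample's negative-control probes
#' plus `margin`. This is a background-margin rule: the classical
#' detection-call algorithm requires perfect-match/mismatch probe pairs
#' that are not part of the probe-level interface, so the negative
#' controls stand in for the background distribution. Control probes are
#' excluded from the returned call matrix (and hence from the %P
#' denominator).
#'
#' @param matrix an [expr_matrix()].
#' @param annotation probe annotation covering every probe in `matrix`,
#'   with at least one `negative_control` row present in the matrix.
#' @param margin log2 units added to the per-sample control median
#'   (default 1.0).
#' @return logical matrix, non-control probes x samples; `TRUE` = present.
#' @export
detection_call <- function(matrix, annotation, margin = 1.0) {
  ann <- annotation[match(rownames(matrix), annotation$probe_id), ]
  nc <- rownames(matrix)[!is.na(ann$control_class) &
                           ann$control_class == "negative_control"]
  if (!length(nc))
    stop("no negative_control probes found in the matrix; supply ",
         "annotation rows with control_class = 'negative_control'")
  keep <- .noncontrol_probes(matrix, annotation)
  bg <- apply(matrix[nc, , drop = FALSE], 2L, stats::median)
  calls <- sweep(unclass(matrix)[keep, , drop = FALSE], 2L, bg + margin,
                 `>`)
  storage.mode(calls) <- "logical"
  calls
}

#' Percent-present (%P) per sample
#'
#' Fraction of non-control probesets called present by
#' [detection_call()].
#'
#' @inheritParams detection_call
#' @return named numeric vector in `[0, 1]`, one entry per sample.
#' @export
percent_present <- function(matrix, annotation, margin = 1.0) {
  colMeans(detection_call(matrix, annotation, margin))
}

#' GAPDH 3':5' degradation ratio per sample
#'
#' `2^(mean log2 of 3'-end probes - mean log2 of 5'-end probes)` for the
#' housekeeping QC probesets; values near 1 indicate intact transcripts
#' and values above the cutoff (default 3) indicate degradation.
#'
#' @inheritParams detection_call
#' @return named positive numeric vector, one entry per sample.
#' @export
gapdh_ratio <- function(matrix, annotation) {
  ann <- annotation[match(rownames(matrix), annotation$probe_id), ]
  p3 <- rownames(matrix)[!is.na(ann$control_class) &
                           ann$control_class == "qc_3prime"]
  p5 <- rownames(matrix)[!is.na(ann$control_class) &
                           ann$control_class == "qc_5prime"]
  if (!length(p3) || !length(p5))
    stop("annotation must mark at least one qc_3prime and one qc_5prime ",
         "probe present in the matrix")
  m3 <- colMeans(unclass(matrix)[p3, , drop = FALSE])
  m5 <- colMeans(unclass(matrix)[p5, , drop = FALSE])
  2^(m3 - m5)
}

#' Hybridization QC report
#'
#' Combines %P and the GAPDH ratio into per-sample pass/fail calls. A
#' sample passes when `percent_present >= percent_present_cutoff` AND
#' `gapdh_ratio <= gapdh_ratio_cutoff`. Samples whose %P falls in the
#' borderline band (cutoff +/- 0.15) are flagged `borderline` and a
#' warning is emitted, but the operative rule remains the cutoff itself.
#'
#' @inheritParams detection_call
#' @param thresholds a [thresholds()] object.
#' @return data.frame with columns `sample_id`, `percent_present`,
#'   `gapdh_ratio`, `pass_percent_present`, `pass_gapdh`, `pass`,
#'   `borderline`.
#' @export
qc_report <- function(matrix, annotation,
                      thresholds = cnitpipe::thresholds(platform_of(matrix)),
                      margin = 1.0) {
  pp <- percent_present(matrix, annotation, margin)
  gr <- gapdh_ratio(matrix, annotation)
  cut <- thresholds$percent_present_cutoff
  rep <- data.frame(
    sample_id = colnames(matrix),
    percent_present = as.numeric(pp),
    gapdh_ratio = as.numeric(gr),
    pass_percent_present = as.numeric(pp) >= cut,
    pass_gapdh = as.numeric(gr) <= thresholds$gapdh_ratio_cutoff,
    stringsAsFactors = FALSE)
  rep$pass <- rep$pass_percent_present & rep$pass_gapdh
  rep$borderline <- rep$percent_present >= cut - 0.15 &
    rep$percent_present < cut + 0.15
  if (any(rep$borderline))
    warning("sample(s) with borderline %P: ",
            paste(rep$sample_id[rep$borderline], collapse = ", "))
  rep
}

#' Apply a QC report to an expression matrix
#'
#' Drops failing samples, preserving the order (and values) of the
#' survivors.
#'
#' @param matrix an [expr_matrix()].
#' @param report a [qc_report()] data.frame covering every sample of
#'   `matrix`.
#' @param thresholds unused placeholder kept for interface symmetry;
#'   pass/fail is read from `report$pass`.
#' @return list with elements `matrix` (filtered [expr_matrix()]) and
#'   `dropped` (character vector of removed sample ids).
#' @export
apply_qc <- function(matrix, report, thresholds = NULL) {
  missing <- setdiff(colnames(matrix), report$sample_id)
  if (length(missing))
    stop("QC report does not cover sample(s): ",
         paste(missing, collapse = ", "))
  pass <- report$pass[match(colnames(matrix), report$sample_id)]
  if (!any(pass))
    stop("all samples fail hybridization QC; empty cohort")
  dropped <- colnames(matrix)[!pass]
  if (length(dropped))
    message("dropping ", length(dropped), " sample(s) failing QC: ",
            paste(dropped, collapse = ", "))
  list(matrix = matrix[, pass, drop = FALSE], dropped = dropped)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the across-sample mean empirical
#' distribution: the value at each rank becomes the mean, over samples, of
#' the values at that rank. Ties within a column receive the mean of the
#' reference values at the tied ranks. Within-column rank order is
#' preserved and the transform is idempotent.
#'
#' @param matrix an [expr_matrix()] with at least two samples.
#' @return the normalized [expr_matrix()].
#' @export
quantile_normalize <- function(matrix) {
  if (ncol(matrix) < 2L)
    stop("quantile normalization needs at least 2 samples")
  norm <- limma::normalizeQuantiles(unclass(matrix), ties = TRUE)
  dimnames(norm) <- dimnames(matrix)
  expr_matrix(norm, platform_of(matrix))
}
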