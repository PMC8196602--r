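# Domain types and tabular readers/writers shared by all pipeline stages.
# All files are UTF-8, tab-separated, LF newlines. Gene symbols are matched
# case-sensitively and exactly; symbol normalization is the caller's job.

#' Condition labels recognized by the pipeline
#'
#' The four biopsy phenotypes of the study design: calcineurin-inhibitor
#' nephrotoxicity (`CNIT`), histologically normal allograft (`Normal`),
#' acute rejection (`AR`) and interstitial fibrosis / tubular atrophy
#' (`IFTA`).
#' @export
CONDITION_LEVELS <- c("CNIT", "Normal", "AR", "IFTA")

#' Platform labels
#' @export
PLATFORM_LEVELS <- c("mRNA", "miRNA")

#' Probe control classes
#'
#' `none` for ordinary probesets, `negative_control` for background probes
#' used by the detection call, `qc_5prime`/`qc_3prime` for the 5'- and
#' 3'-end probesets of a housekeeping transcript (GAPDH) used for the
#' RNA-degradation ratio.
#' @export
CONTROL_CLASSES <- c("none", "negative_control", "qc_5prime", "qc_3prime")

#' Target-pair evidence classes
#' @export
EVIDENCE_LEVELS <- c("experimentally_observed", "predicted_high",
                     "predicted_moderate")

#' Construct an expression matrix
#'
#' A probes-by-samples matrix of log2 intensities with a platform tag.
#' Probe and sample identifiers must be unique and every value finite.
#'
#' @param values numeric matrix, rows = probes, columns = samples, with
#'   complete `dimnames`. Values are log2-scale intensities.
#' @param platform `"mRNA"` or `"miRNA"`.
#' @return an `expr_matrix`: the numeric matrix with a `platform`
#'   attribute.
#' @export
expr_matrix <- function(values, platform = c("mRNA", "miRNA")) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry probe rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression matrix contains non-finite values")
  structure(values, platform = platform,
            class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d probes x %d samples\n",
              attr(x, "platform"), nrow(x), ncol(x)))
  invisible(x)
}

# keep the platform tag when subsetting columns/rows
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, platform = attr(x, "platform"),
                     class = c("expr_matrix", "matrix", "array"))
  out
}

#' Platform of an expression matrix
#' @param x an `expr_matrix`
#' @return `"mRNA"` or `"miRNA"`
#' @export
platform_of <- function(x) attr(x, "platform")

#' Significance and QC thresholds
#'
#' Platform-specific defaults follow the study protocol: probeset p < 0.001
#' for gene-expression arrays and p < 0.005 for miRNA arrays, BH
#' FDR <= 0.05 for both, and linear fold change >= 1.5 (genes) or >= 2.0
#' (miRNAs). QC cutoffs: percent-present >= 0.50 and GAPDH 3':5'
#' ratio <= 3.
#'
#' @param platform `"mRNA"` or `"miRNA"`; picks the default `p_cutoff` and
#'   `fc_cutoff`.
#' @param p_cutoff strict upper bound on the raw p-value.
#' @param fdr_cutoff non-strict upper bound on the BH q-value.
#' @param fc_cutoff non-strict lower bound on linear |fold change|;
#'   must be >= 1.
#' @param enrichment_p reporting cutoff for enrichment p-values.
#' @param percent_present_cutoff minimum fraction of non-control probesets
#'   called present for a sample to pass hybridization QC.
#' @param gapdh_ratio_cutoff maximum allowed GAPDH 3':5' intensity ratio.
#' @return a `de_thresholds` list.
#' @export
thresholds <- function(platform = c("mRNA", "miRNA"),
                       p_cutoff = NULL,
                       fdr_cutoff = 0.05,
                       fc_cutoff = NULL,
                       enrichment_p = 0.05,
                       percent_present_cutoff = 0.50,
                       gapdh_ratio_cutoff = 3.0) {
  platform <- match.arg(platform)
  if (is.null(p_cutoff))
    p_cutoff <- if (platform == "mRNA") 0.001 else 0.005
  if (is.null(fc_cutoff))
    fc_cutoff <- if (platform == "mRNA") 1.5 else 2.0
  probs <- c(p_cutoff = p_cutoff, fdr_cutoff = fdr_cutoff,
             enrichment_p = enrichment_p,
             percent_present_cutoff = percent_present_cutoff)
  bad <- names(probs)[probs <= 0 | probs >= 1]
  if (length(bad))
    stop("thresholds must lie in (0,1): ", paste(bad, collapse = ", "))
  if (fc_cutoff < 1) stop("`fc_cutoff` must be >= 1 (linear scale)")
  if (gapdh_ratio_cutoff <= 0) stop("`gapdh_ratio_cutoff` must be positive")
  structure(list(platform = platform, p_cutoff = p_cutoff,
                 fdr_cutoff = fdr_cutoff, fc_cutoff = fc_cutoff,
                 enrichment_p = enrichment_p,
                 percent_present_cutoff = percent_present_cutoff,
                 gapdh_ratio_cutoff = gapdh_ratio_cutoff),
            class = "de_thresholds")
}

# split a raw line on tabs without dropping trailing empty fields
.split_tsv <- function(line) strsplit(line, "\t", fixed = TRUE)[[1]]

#' Read a probe-level expression matrix
#'
#' Tab-delimited: a header row of sample ids (first cell is a row-name
#' header and is ignored), then one row per probe, first column the probe
#' id. Every cell must be numeric; duplicate ids, ragged rows and
#' missing/non-numeric cells abort with the offending line number.
#'
#' @param path file to read.
#' @param platform `"mRNA"` or `"miRNA"`.
#' @param input_scale `"log2"` (default; values stored as-is) or
#'   `"linear"`, in which case `log2(x + 1)` is applied on load.
#' @return an [expr_matrix()].
#' @export
read_expression_matrix <- function(path, platform = c("mRNA", "miRNA"),
                                   input_scale = c("log2", "linear")) {
  platform <- match.arg(platform)
  input_scale <- match.arg(input_scale)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L)
    stop("expression file ", path, " has no data rows")
  header <- .split_tsv(lines[1L])
  sample_ids <- header[-1L]
  if (!length(sample_ids)) stop("header row has no sample ids (line 1)")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id in header (line 1): ",
         sample_ids[duplicated(sample_ids)][1L])
  n <- length(sample_ids)
  body <- lines[-1L]
  probe_ids <- character(length(body))
  values <- matrix(NA_real_, nrow = length(body), ncol = n)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(body)) {
    fields <- .split_tsv(body[i])
    lineno <- i + 1L
    if (length(fields) != n + 1L)
      stop(sprintf("ragged row on line %d: expected %d fields, got %d",
                   lineno, n + 1L, length(fields)))
    pid <- fields[1L]
    if (!nzchar(pid)) stop(sprintf("empty probe id on line %d", lineno))
    if (!is.null(seen[[pid]]))
      stop(sprintf("duplicate probe id '%s' on line %d", pid, lineno))
    seen[[pid]] <- TRUE
    vals <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(vals) || !all(is.finite(vals)))
      stop(sprintf("non-numeric or missing value on line %d", lineno))
    probe_ids[i] <- pid
    values[i, ] <- vals
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  if (input_scale == "linear") {
    if (any(values < 0))
      stop("linear-scale input contains negative intensities")
    values <- log2(values + 1)
  }
  expr_matrix(values, platform)
}

#' Write an expression matrix
#'
#' Inverse of [read_expression_matrix()]; row and column order are
#' preserved byte-stably so write-then-read is the identity.
#'
#' @param x an `expr_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(x)), collapse = "\t"), con,
             sep = "\n")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], format(x[i, ], trim = TRUE, digits = 15,
                                   scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(body, con, sep = "\n")
  invisible(path)
}

# shared reader for small headered TSVs with required columns
.read_tsv_table <- function(path, required) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character",
                          fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `condition`, `platform`. Conditions must
#' come from [CONDITION_LEVELS]; sample ids must be unique within each
#' platform.
#'
#' @param path file to read.
#' @return data.frame with the three columns, character-typed.
#' @export
read_sample_table <- function(path) {
  df <- .read_tsv_table(path, c("sample_id", "condition", "platform"))
  bad <- setdiff(unique(df$condition), CONDITION_LEVELS)
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         "; accepted: ", paste(CONDITION_LEVELS, collapse = ", "))
  bad <- setdiff(unique(df$platform), PLATFORM_LEVELS)
  if (length(bad))
    stop("unknown platform label(s): ", paste(bad, collapse = ", "))
  for (pl in unique(df$platform)) {
    ids <- df$sample_id[df$platform == pl]
    if (anyDuplicated(ids))
      stop("duplicate sample id within platform ", pl, ": ",
           ids[duplicated(ids)][1L])
  }
  df[c("sample_id", "condition", "platform")]
}

#' Read a probe annotation table
#'
#' TSV with columns `probe_id`, `gene_symbol`, `control_class`, `qc_gene`.
#' `gene_symbol` may be empty (unmapped probe). `control_class` is one of
#' [CONTROL_CLASSES]; `qc_5prime`/`qc_3prime` rows must name their
#' housekeeping gene in `qc_gene`.
#'
#' @param path file to read.
#' @return data.frame with the four columns.
#' @export
read_probe_annotation <- function(path) {
  df <- .read_tsv_table(path, c("probe_id", "gene_symbol",
                                "control_class", "qc_gene"))
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe id in annotation: ",
         df$probe_id[duplicated(df$probe_id)][1L])
  bad <- setdiff(unique(df$control_class), CONTROL_CLASSES)
  if (length(bad))
    stop("unknown control_class value(s): ", paste(bad, collapse = ", "),
         "; accepted: ", paste(CONTROL_CLASSES, collapse = ", "))
  qc <- df$control_class %in% c("qc_5prime", "qc_3prime")
  if (any(qc & !nzchar(df$qc_gene)))
    stop("qc_5prime/qc_3prime annotation rows must carry a qc_gene symbol")
  df[c("probe_id", "gene_symbol", "control_class", "qc_gene")]
}

#' Write a probe annotation table
#' @param annotation data.frame as returned by [read_probe_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_probe_annotation <- function(annotation, path) {
  utils::write.table(annotation[c("probe_id", "gene_symbol",
                                  "control_class", "qc_gene")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a sample metadata table
#' @param samples data.frame as returned by [read_sample_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples[c("sample_id", "condition", "platform")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a signed gene-set collection (GMT dialect)
#'
#' Standard GMT layout: one set per line, `set-name<TAB>description<TAB>`
#' members. A member token `SYM:+1` or `SYM:-1` carries the direction
#' consistent with activation of the set/regulator; a bare `SYM` is
#' unsigned (0). Curated signed knowledge bases are proprietary, so the
#' sign suffix is this package's open interchange convention.
#'
#' @param path GMT file.
#' @return a `gene_set_collection`: named list of data.frames with columns
#'   `gene_symbol`, `expected_sign`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- .split_tsv(lines[i])
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    name <- fields[1L]
    if (!is.null(sets[[name]]))
      stop(sprintf("duplicate set name '%s' on GMT line %d", name, i))
    tokens <- fields[-(1:2)]
    tokens <- tokens[nzchar(tokens)]
    sign <- rep(0L, length(tokens))
    sym <- tokens
    signed <- grepl(":[+-]1$", tokens)
    sym[signed] <- sub(":[+-]1$", "", tokens[signed])
    sign[signed] <- ifelse(grepl(":\\+1$", tokens[signed]), 1L, -1L)
    if (anyDuplicated(sym))
      stop(sprintf("duplicate member '%s' in set '%s' (GMT line %d)",
                   sym[duplicated(sym)][1L], name, i))
    sets[[name]] <- data.frame(gene_symbol = sym, expected_sign = sign,
                               stringsAsFactors = FALSE)
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a signed gene-set collection
#'
#' Members with `expected_sign != 0` get the `:+1`/`:-1` suffix so that
#' write-then-read is the identity.
#'
#' @param sets a `gene_set_collection`.
#' @param path output GMT file.
#' @param descriptions optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    m <- sets[[i]]
    tok <- ifelse(m$expected_sign == 0L, m$gene_symbol,
                  paste0(m$gene_symbol, ":",
                         ifelse(m$expected_sign > 0, "+1", "-1")))
    paste(c(names(sets)[i], descriptions[i], tok), collapse = "\t")
  }, character(1))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a miRNA target-pair table
#'
#' TSV with columns `mirna_id`, `gene_symbol`, `evidence`, `source`.
#' Evidence must be one of [EVIDENCE_LEVELS]; (miRNA, gene) pairs must be
#' unique.
#'
#' @param path file to read.
#' @return a `target_pair_table` data.frame.
#' @export
read_target_pairs <- function(path) {
  df <- .read_tsv_table(path, c("mirna_id", "gene_symbol", "evidence",
                                "source"))
  target_pair_table(df)
}

#' Construct (and validate) a target-pair table
#' @param df data.frame with columns `mirna_id`, `gene_symbol`,
#'   `evidence`, `source`.
#' @return the validated data.frame, classed `target_pair_table`.
#' @export
target_pair_table <- function(df) {
  req <- c("mirna_id", "gene_symbol", "evidence", "source")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("target-pair table lacks column(s): ",
         paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$evidence), EVIDENCE_LEVELS)
  if (length(bad))
    stop("unknown evidence token(s): ", paste(bad, collapse = ", "),
         "; accepted: ", paste(EVIDENCE_LEVELS, collapse = ", "))
  key <- paste(df$mirna_id, df$gene_symbol, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop(sprintf("duplicated (mirna_id, gene_symbol) pair: (%s, %s)",
                 df$mirna_id[d], df$gene_symbol[d]))
  }
  df <- df[req]
  rownames(df) <- NULL
  class(df) <- c("target_pair_table", "data.frame")
  df
}

#' Write a miRNA target-pair table
#' @param pairs a `target_pair_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_target_pairs <- function(pairs, path) {
  utils::write.table(as.data.frame(pairs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a gene-level differential-expression set
#'
#' A `deg_set` holds the signed gene calls of one contrast: each gene
#' appears once with direction `"up"` or `"down"`, and the passing
#' probeset ids it was collapsed from are retained for traceability.
#'
#' @param contrast_id label such as `"CNIT_vs_Normal"`.
#' @param genes data.frame with columns `gene_symbol`, `direction`.
#' @param probesets character vector of passing probeset ids (may be
#'   empty for fixture-born sets).
#' @param unmapped character vector of passing probesets with no gene
#'   symbol (kept so they are never silently dropped).
#' @return a `deg_set`.
#' @export
deg_set <- function(contrast_id, genes,
                    probesets = character(), unmapped = character()) {
  stopifnot(is.data.frame(genes),
            all(c("gene_symbol", "direction") %in% names(genes)))
  if (anyDuplicated(genes$gene_symbol))
    stop("duplicate gene symbol in DEG set: ",
         genes$gene_symbol[duplicated(genes$gene_symbol)][1L])
  if (!all(genes$direction %in% c("up", "down")))
    stop("directions must be 'up' or 'down'")
  g <- genes[c("gene_symbol", "direction")]
  rownames(g) <- NULL
  structure(list(contrast_id = contrast_id, genes = g,
                 probesets = probesets, unmapped = unmapped),
            class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat(sprintf("deg_set '%s': %d genes (%d up, %d down)\n", x$contrast_id,
              nrow(x$genes), sum(x$genes$direction == "up"),
              sum(x$genes$direction == "down")))
  invisible(x)
}

#' Gene symbols of a DEG set
#' @param x a `deg_set`.
#' @return character vector of member gene symbols.
#' @export
deg_genes <- function(x) x$genes$gene_symbol

#' Named direction lookup of a DEG set
#' @param x a `deg_set`.
#' @return character vector of `"up"`/`"down"`, named by gene symbol.
#' @export
deg_directions <- function(x) {
  stats::setNames(x$genes$direction, x$genes$gene_symbol)
}

#' Write a DEG set as TSV
#' @param x a `deg_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_deg_set <- function(x, path) {
  utils::write.table(x$genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a DEG set from TSV
#' @param path file with columns `gene_symbol`, `direction`.
#' @param contrast_id label to attach.
#' @return a `deg_set`.
#' @export
read_deg_set <- function(path, contrast_id = basename(path)) {
  df <- .read_tsv_table(path, c("gene_symbol", "direction"))
  deg_set(contrast_id, df)
}
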