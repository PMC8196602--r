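# End-to-end orchestration: QC -> normalization -> differential
# expression (three contrasts) -> specificity set algebra -> miRNA-mRNA
# integration -> enrichment -> clustering, with a manifest recording
# every input, parameter and output hash so a run is auditable and
# reproducible.

#' Build and validate a pipeline run configuration
#'
#' All inputs are file paths in the package's tabular formats (see
#' [read_expression_matrix()], [read_sample_table()],
#' [read_probe_annotation()], [read_target_pairs()],
#' [read_gene_sets()]). Validation is pre-flight: missing files or
#' invalid thresholds fail here, before any computation.
#'
#' @param expr_mrna,expr_mirna expression matrix TSVs (miRNA optional:
#'   `NULL` skips the miRNA arm, integration and clustering).
#' @param meta sample metadata TSV covering both platforms.
#' @param annot_mrna,annot_mirna probe annotation TSVs.
#' @param targets miRNA target-pair TSV (optional).
#' @param gene_sets,regulator_sets signed GMT files (optional).
#' @param out_dir output directory (created if absent).
#' @param thresholds_mrna,thresholds_mirna [thresholds()] objects.
#' @param contrasts character vector of case conditions, each tested
#'   against `"Normal"`.
#' @param detection_margin log2 margin of the detection call.
#' @param input_scale `"log2"` or `"linear"`, passed to the readers.
#' @param seed integer seed recorded in the manifest (the pipeline
#'   itself is deterministic; the seed matters when upstream inputs were
#'   generated).
#' @return a validated `run_config` list.
#' @export
run_config <- function(expr_mrna, meta, annot_mrna,
                       expr_mirna = NULL, annot_mirna = NULL,
                       targets = NULL, gene_sets = NULL,
                       regulator_sets = NULL,
                       out_dir = tempfile("cnitpipe_run_"),
                       thresholds_mrna = thresholds("mRNA"),
                       thresholds_mirna = thresholds("miRNA"),
                       contrasts = c("CNIT", "AR", "IFTA"),
                       detection_margin = 1.0,
                       input_scale = "log2",
                       seed = 1L) {
  paths <- list(expr_mrna = expr_mrna, meta = meta,
                annot_mrna = annot_mrna, expr_mirna = expr_mirna,
                annot_mirna = annot_mirna, targets = targets,
                gene_sets = gene_sets, regulator_sets = regulator_sets)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p))
      stop("input `", nm, "` does not exist: ", p)
  }
  if (!is.null(expr_mirna) && is.null(annot_mirna))
    stop("`annot_mirna` is required when `expr_mirna` is given")
  stopifnot(inherits(thresholds_mrna, "de_thresholds"),
            inherits(thresholds_mirna, "de_thresholds"))
  bad <- setdiff(contrasts, setdiff(CONDITION_LEVELS, "Normal"))
  if (length(bad))
    stop("unknown contrast condition(s): ", paste(bad, collapse = ", "))
  structure(c(paths,
              list(out_dir = out_dir,
                   thresholds_mrna = thresholds_mrna,
                   thresholds_mirna = thresholds_mirna,
                   contrasts = contrasts,
                   detection_margin = detection_margin,
                   input_scale = input_scale, seed = as.integer(seed))),
            class = "run_config")
}

.stage <- function(name, code) {
  tryCatch(code, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes the stages in analysis order. The mRNA arm runs QC,
#' normalization and the configured contrasts; with three contrasts the
#' specificity partition and unique-CNIT list are produced, and — given
#' a miRNA matrix and a target table — the miRNA arm (QC, normalization,
#' CNIT-vs-Normal differential expression, supervised clustering on the
#' DE miRNAs) and the integration filter run as well. Gene-set /
#' regulator GMTs trigger enrichment of the unique-CNIT list against
#' the platform's mapped genes as universe. Any stage failure aborts
#' with a stage-named error. All outputs are TSVs under `out_dir`; a
#' `manifest.tsv` records every file with its MD5 plus every threshold
#' actually applied.
#'
#' @param config a [run_config()].
#' @return (invisibly) a `pipeline_run` list with the in-memory results
#'   and the manifest data.frame.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  emit <- function(writer, obj, name, ...) {
    path <- file.path(config$out_dir, name)
    writer(obj, path, ...)
    outputs <<- c(outputs, path)
    path
  }
  results <- list()

  meta <- .stage("read_meta", read_sample_table(config$meta))

  ## ---- mRNA arm -------------------------------------------------------
  expr <- .stage("read_mrna", read_expression_matrix(
    config$expr_mrna, "mRNA", config$input_scale))
  annot <- .stage("read_annot_mrna",
                  read_probe_annotation(config$annot_mrna))
  qcr <- .stage("qc_mrna", suppressWarnings(qc_report(
    expr, annot, config$thresholds_mrna, config$detection_margin)))
  emit(function(x, p) utils::write.table(
         x, p, sep = "\t", quote = FALSE, row.names = FALSE),
       qcr, "qc_report_mRNA.tsv")
  filtered <- .stage("apply_qc_mrna", apply_qc(expr, qcr))
  norm <- .stage("normalize_mrna", quantile_normalize(filtered$matrix))
  emit(write_expression_matrix, norm, "normalized_mRNA.tsv")
  results$qc_mrna <- qcr
  results$dropped_mrna <- filtered$dropped

  meta_m <- meta[meta$platform == "mRNA", , drop = FALSE]
  groups_of <- function(cond, mat)
    intersect(meta_m$sample_id[meta_m$condition == cond], colnames(mat))
  degs <- list()
  for (cond in config$contrasts) {
    cid <- paste0(cond, "_vs_Normal")
    res <- .stage(paste0("de_", cid), {
      r <- probeset_test(norm, groups_of(cond, norm),
                         groups_of("Normal", norm), contrast_id = cid)
      apply_thresholds(r, config$thresholds_mrna)
    })
    emit(write_contrast_result, res, paste0(cid, ".tsv"))
    degs[[cond]] <- .stage(paste0("collapse_", cid),
                           collapse_to_genes(res, annot))
    emit(write_deg_set, degs[[cond]], paste0(cid, "_genes.tsv"))
  }
  results$deg_sets <- degs

  unique_cnit <- NULL
  if (all(c("CNIT", "AR", "IFTA") %in% names(degs))) {
    part <- .stage("specificity", venn_partition(
      degs$CNIT, degs$AR, degs$IFTA))
    emit(function(x, p) utils::write.table(
           venn_summary(x), p, sep = "\t", quote = FALSE,
           row.names = FALSE),
         part, "venn_summary.tsv")
    unique_cnit <- .stage("unique_cnit", unique_genes(part, "CNIT"))
    emit(write_deg_set, unique_cnit, "unique_CNIT_genes.tsv")
    results$venn <- part
    results$unique_cnit <- unique_cnit
  }

  ## ---- miRNA arm ------------------------------------------------------
  de_mirnas <- NULL
  if (!is.null(config$expr_mirna)) {
    expr_mi <- .stage("read_mirna", read_expression_matrix(
      config$expr_mirna, "miRNA", config$input_scale))
    annot_mi <- .stage("read_annot_mirna",
                       read_probe_annotation(config$annot_mirna))
    qcr_mi <- .stage("qc_mirna", suppressWarnings(qc_report(
      expr_mi, annot_mi, config$thresholds_mirna,
      config$detection_margin)))
    emit(function(x, p) utils::write.table(
           x, p, sep = "\t", quote = FALSE, row.names = FALSE),
         qcr_mi, "qc_report_miRNA.tsv")
    filt_mi <- .stage("apply_qc_mirna", apply_qc(expr_mi, qcr_mi))
    norm_mi <- .stage("normalize_mirna",
                      quantile_normalize(filt_mi$matrix))
    meta_mi <- meta[meta$platform == "miRNA", , drop = FALSE]
    g1 <- intersect(meta_mi$sample_id[meta_mi$condition == "CNIT"],
                    colnames(norm_mi))
    g2 <- intersect(meta_mi$sample_id[meta_mi$condition == "Normal"],
                    colnames(norm_mi))
    res_mi <- .stage("de_miRNA", {
      r <- probeset_test(norm_mi, g1, g2,
                         contrast_id = "CNIT_vs_Normal_miRNA")
      apply_thresholds(r, config$thresholds_mirna)
    })
    emit(write_contrast_result, res_mi, "CNIT_vs_Normal_miRNA.tsv")
    de_mirnas <- .stage("collapse_miRNA",
                        collapse_to_genes(res_mi, annot_mi))
    emit(write_deg_set, de_mirnas, "DE_miRNAs.tsv")
    results$de_mirnas <- de_mirnas

    de_probes <- res_mi$probeset_id[which(res_mi$passes)]
    if (length(de_probes) >= 2L) {
      clus <- .stage("clustering", supervised_cluster(
        norm_mi, de_probes, meta_mi))
      emit(function(x, p) utils::write.table(
             data.frame(order = seq_along(x$leaf_order),
                        sample_id = x$leaf_order,
                        cluster = x$cut2[x$leaf_order]),
             p, sep = "\t", quote = FALSE, row.names = FALSE),
           clus, "clustering_leaf_order.tsv")
      results$clustering <- clus
    }
  }

  ## ---- integration ----------------------------------------------------
  if (!is.null(config$targets) && !is.null(de_mirnas) &&
      !is.null(unique_cnit)) {
    targets <- .stage("read_targets", read_target_pairs(config$targets))
    integ <- .stage("integration",
                    integrate_mirna_mrna(de_mirnas, unique_cnit,
                                         targets))
    emit(function(x, p) write_integration_result(
           x, p, file.path(config$out_dir, "integration_audit.tsv")),
         integ, "integration_pairs.tsv")
    outputs <- c(outputs, file.path(config$out_dir,
                                    "integration_audit.tsv"))
    results$integration <- integ
  }

  ## ---- enrichment -----------------------------------------------------
  if (!is.null(config$gene_sets) && !is.null(unique_cnit)) {
    sets <- .stage("read_gene_sets", read_gene_sets(config$gene_sets))
    universe <- unique(annot$gene_symbol[annot$control_class == "none" &
                                           nzchar(annot$gene_symbol)])
    enr <- .stage("enrichment", suppressWarnings(
      fisher_enrichment(unique_cnit, sets, universe)))
    emit(function(x, p) utils::write.table(
           x, p, sep = "\t", quote = FALSE, row.names = FALSE),
         enr, "enrichment.tsv")
    results$enrichment <- enr
    if (!is.null(config$regulator_sets)) {
      regs <- .stage("read_regulators",
                     read_gene_sets(config$regulator_sets))
      ups <- .stage("upstream_regulators", suppressWarnings(
        upstream_regulators(unique_cnit, regs, universe,
                            config$thresholds_mrna$enrichment_p)))
      emit(function(x, p) utils::write.table(
             x, p, sep = "\t", quote = FALSE, row.names = FALSE),
           ups, "upstream_regulators.tsv")
      results$upstream <- ups
    }
  }

  ## ---- manifest -------------------------------------------------------
  inputs <- Filter(Negate(is.null),
                   list(expr_mrna = config$expr_mrna, meta = config$meta,
                        annot_mrna = config$annot_mrna,
                        expr_mirna = config$expr_mirna,
                        annot_mirna = config$annot_mirna,
                        targets = config$targets,
                        gene_sets = config$gene_sets,
                        regulator_sets = config$regulator_sets))
  files <- c(unlist(inputs), outputs)
  roles <- c(rep("input", length(inputs)),
             rep("output", length(outputs)))
  manifest <- data.frame(
    role = roles, file = files,
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE)
  params <- data.frame(
    role = "parameter",
    file = c(paste0("mRNA.", c("p_cutoff", "fdr_cutoff", "fc_cutoff")),
             paste0("miRNA.", c("p_cutoff", "fdr_cutoff", "fc_cutoff")),
             "percent_present_cutoff", "gapdh_ratio_cutoff",
             "detection_margin", "seed"),
    md5 = as.character(c(
      config$thresholds_mrna$p_cutoff,
      config$thresholds_mrna$fdr_cutoff,
      config$thresholds_mrna$fc_cutoff,
      config$thresholds_mirna$p_cutoff,
      config$thresholds_mirna$fdr_cutoff,
      config$thresholds_mirna$fc_cutoff,
      config$thresholds_mrna$percent_present_cutoff,
      config$thresholds_mrna$gapdh_ratio_cutoff,
      config$detection_margin, config$seed)),
    stringsAsFactors = FALSE)
  manifest <- rbind(manifest, params)
  rownames(manifest) <- NULL
  utils::write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  results$manifest <- manifest
  results$out_dir <- config$out_dir
  class(results) <- "pipeline_run"
  invisible(results)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run: outputs in", x$out_dir, "\n")
  cat("  stages:", paste(setdiff(names(x), c("manifest", "out_dir")),
                         collapse = ", "), "\n")
  invisible(x)
}
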