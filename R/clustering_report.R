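# Supervised hierarchical clustering of samples and qPCR delta-Ct group
# comparison.
#
# "Supervised" here means the feature set is preselected (the DE
# probesets of a contrast); the clustering itself is standard
# agglomerative clustering of samples under correlation distance
# (1 - Pearson r) with average linkage, the microarray-heatmap
# convention. Both are configurable.

#' Supervised hierarchical clustering of samples
#'
#' Clusters samples over a preselected feature set, cuts the tree into
#' two clusters, and scores the agreement between cluster labels and the
#' known condition labels under the best label permutation.
#'
#' @param matrix an [expr_matrix()].
#' @param de_features character vector of probeset ids (>= 2) to cluster
#'   on, typically the passing probesets of a contrast.
#' @param meta sample table (columns `sample_id`, `condition`) covering
#'   every sample of `matrix`.
#' @param distance `"correlation"` (1 - Pearson r, default) or
#'   `"euclidean"`.
#' @param linkage linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return a `clustering_result`: list with `features`, `hclust` (the
#'   tree), `merge_heights`, `leaf_order` (sample ids), `cut2`
#'   (two-cluster labels named by sample), `agreement` (best-permutation
#'   agreement in `[0,1]`, `NA` unless exactly two conditions are
#'   present).
#' @export
supervised_cluster <- function(matrix, de_features, meta,
                               distance = c("correlation", "euclidean"),
                               linkage = "average") {
  distance <- match.arg(distance)
  if (length(de_features) < 2L) stop("need at least 2 features")
  if (ncol(matrix) < 3L) stop("need at least 3 samples")
  missing <- setdiff(de_features, rownames(matrix))
  if (length(missing))
    stop("feature(s) not in matrix: ",
         paste(utils::head(missing, 3), collapse = ", "))
  sub <- unclass(matrix)[de_features, , drop = FALSE]
  if (distance == "correlation") {
    sds <- apply(sub, 2L, stats::sd)
    if (any(sds == 0))
      stop("zero-variance sample(s) over the selected features: ",
           paste(colnames(sub)[sds == 0], collapse = ", "))
    d <- stats::as.dist(1 - stats::cor(sub))
  } else {
    d <- stats::dist(t(sub))
  }
  hc <- stats::hclust(d, method = linkage)
  cut2 <- stats::cutree(hc, k = 2)
  cond <- meta$condition[match(colnames(sub), meta$sample_id)]
  if (anyNA(cond))
    stop("meta does not cover sample(s): ",
         paste(colnames(sub)[is.na(cond)], collapse = ", "))
  agreement <- NA_real_
  if (length(unique(cond)) == 2L) {
    lv <- unique(cond)
    match1 <- mean((cut2 == 1L) == (cond == lv[1L]))
    agreement <- max(match1, 1 - match1)
  }
  structure(list(features = de_features, hclust = hc,
                 merge_heights = hc$height,
                 leaf_order = colnames(sub)[hc$order],
                 cut2 = cut2, conditions = cond,
                 agreement = agreement),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: %d samples on %d features; agreement %s\n",
              length(x$leaf_order), length(x$features),
              ifelse(is.na(x$agreement), "NA",
                     format(x$agreement, digits = 3))))
  invisible(x)
}

#' Construct a qPCR table
#'
#' Per-sample cycle thresholds for a target gene and the reference gene
#' (GAPDH); `delta_ct = ct_target - ct_reference` is derived. Lower
#' delta-Ct means higher expression.
#'
#' @param df data.frame with columns `sample_id`, `condition`, `gene`,
#'   `ct_target`, `ct_reference`.
#' @return the validated data.frame with a `delta_ct` column, classed
#'   `qpcr_table`.
#' @export
qpcr_table <- function(df) {
  req <- c("sample_id", "condition", "gene", "ct_target", "ct_reference")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("qPCR table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyNA(df$ct_reference))
    stop("missing reference Ct value(s)")
  if (anyNA(df$ct_target)) stop("missing target Ct value(s)")
  if (any(df$ct_target <= 0) || any(df$ct_reference <= 0))
    stop("Ct values must be positive")
  df$delta_ct <- df$ct_target - df$ct_reference
  class(df) <- c("qpcr_table", "data.frame")
  df
}

#' Compare qPCR delta-Ct between two groups
#'
#' Pooled-variance two-sample t-test on delta-Ct (the same machinery as
#' the probeset test), with per-group means and t-based 95% confidence
#' intervals. Lower delta-Ct = higher expression, so a negative
#' difference (group1 - group2) means the gene is *higher* expressed in
#' group1.
#'
#' @param table a [qpcr_table()].
#' @param gene target gene to compare.
#' @param group1,group2 condition labels (>= 2 samples each for the
#'   gene).
#' @param conf_level confidence level for the group CIs.
#' @return list with `gene`, `groups`, `n`, `mean_delta_ct`, `ci_lower`,
#'   `ci_upper` (per group), `t_statistic`, `p_value`.
#' @export
qpcr_compare <- function(table, gene, group1, group2,
                         conf_level = 0.95) {
  stopifnot(inherits(table, "qpcr_table"))
  rows <- table[table$gene == gene, , drop = FALSE]
  x1 <- rows$delta_ct[rows$condition == group1]
  x2 <- rows$delta_ct[rows$condition == group2]
  if (length(x1) < 2L || length(x2) < 2L)
    stop("need >= 2 samples per group for gene ", gene)
  tt <- .pooled_t(x1, x2)
  ci <- function(x) {
    m <- mean(x)
    half <- stats::qt(1 - (1 - conf_level) / 2, length(x) - 1) *
      stats::sd(x) / sqrt(length(x))
    c(m - half, m + half)
  }
  ci1 <- ci(x1); ci2 <- ci(x2)
  list(gene = gene, groups = c(group1, group2),
       n = c(length(x1), length(x2)),
       mean_delta_ct = c(mean(x1), mean(x2)),
       ci_lower = c(ci1[1], ci2[1]), ci_upper = c(ci1[2], ci2[2]),
       t_statistic = tt$t, p_value = tt$p)
}

# shared pooled-variance two-sample t (scalar case of probeset_test)
.pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
    (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (mean(x1) == mean(x2)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(x1) - mean(x2)) * Inf, p = 0))
  }
  t <- (mean(x1) - mean(x2)) / se
  list(t = t, p = 2 * stats::pt(abs(t), n1 + n2 - 2, lower.tail = FALSE))
}
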