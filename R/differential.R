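# Probeset-level two-group testing, BH FDR, dual thresholds, and
# probeset-to-gene collapse.
#
# The test is the classical pooled-variance (Student) two-sample t on
# log2 intensities, the historical microarray default; Welch is available
# via `var_equal = FALSE`. Fold change is geometric: 2^(difference of
# log2 group means), consistent with testing on the log scale.

#' Probeset-level two-group t-test
#'
#' For every probeset, computes the difference of log2 group means
#' (`group1 - group2`), the two-sample t statistic and its two-sided
#' p-value, BH q-values across all probesets of the contrast, the linear
#' fold change `2^mean_log2_diff`, and the direction (`up` iff
#' `mean_log2_diff > 0`). Degenerate probesets with zero pooled variance
#' get p = 1 when the group means are equal, and p = 0 (with a warning)
#' when they differ.
#'
#' @param matrix an [expr_matrix()] of (normalized) log2 intensities.
#' @param group1,group2 disjoint character vectors of sample ids, each of
#'   length >= 2, all present in `matrix`. `group1` is the case group, so
#'   positive differences mean higher expression in `group1`.
#' @param contrast_id label stored on the result (e.g.
#'   `"CNIT_vs_Normal"`).
#' @param var_equal `TRUE` (default) for the pooled-variance Student
#'   test; `FALSE` for Welch.
#' @return a `contrast_result`: data.frame with columns `probeset_id`,
#'   `mean_log2_diff`, `t_statistic`, `p_value`, `q_value`,
#'   `fold_change`, `direction`, and a `passes` column initialized to
#'   `NA` until [apply_thresholds()] is run.
#' @export
probeset_test <- function(matrix, group1, group2,
                          contrast_id = "group1_vs_group2",
                          var_equal = TRUE) {
  if (length(intersect(group1, group2)))
    stop("groups overlap: ",
         paste(intersect(group1, group2), collapse = ", "))
  if (length(group1) < 2L || length(group2) < 2L)
    stop("each group needs at least 2 samples")
  missing <- setdiff(c(group1, group2), colnames(matrix))
  if (length(missing))
    stop("sample id(s) not in matrix: ", paste(missing, collapse = ", "))
  x1 <- unclass(matrix)[, group1, drop = FALSE]
  x2 <- unclass(matrix)[, group2, drop = FALSE]
  n1 <- length(group1); n2 <- length(group2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  diff <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t_stat <- diff / se
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  degenerate <- se == 0
  if (any(degenerate)) {
    null_deg <- degenerate & diff == 0
    sig_deg <- degenerate & diff != 0
    t_stat[null_deg] <- 0; p[null_deg] <- 1
    if (any(sig_deg)) {
      t_stat[sig_deg] <- sign(diff[sig_deg]) * Inf
      p[sig_deg] <- 0
      warning(sum(sig_deg), " probeset(s) with zero pooled variance but ",
              "unequal means; p set to 0")
    }
  }
  res <- data.frame(
    probeset_id = rownames(matrix),
    mean_log2_diff = as.numeric(diff),
    t_statistic = as.numeric(t_stat),
    p_value = as.numeric(p),
    q_value = bh_fdr(as.numeric(p)),
    fold_change = 2^as.numeric(diff),
    direction = ifelse(diff > 0, "up", "down"),
    passes = NA,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "contrast_id") <- contrast_id
  attr(res, "groups") <- list(group1 = group1, group2 = group2)
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1 and returned in the
#' input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values)) stop("p-values must be numeric")
  if (!length(p_values)) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Apply dual significance thresholds to a contrast
#'
#' A probeset passes iff `p < p_cutoff` (strict), `q <= fdr_cutoff`, and
#' linear `|fold change| = 2^|mean_log2_diff| >= fc_cutoff` — the exact
#' strictness of the study protocol.
#'
#' @param result a `contrast_result` from [probeset_test()].
#' @param thresholds a [thresholds()] object for the matching platform.
#' @return the `contrast_result` with its `passes` column set.
#' @export
apply_thresholds <- function(result, thresholds) {
  stopifnot(inherits(result, "contrast_result"),
            inherits(thresholds, "de_thresholds"))
  result$passes <- result$p_value < thresholds$p_cutoff &
    result$q_value <= thresholds$fdr_cutoff &
    2^abs(result$mean_log2_diff) >= thresholds$fc_cutoff
  attr(result, "thresholds") <- thresholds
  result
}

#' Collapse passing probesets to gene-level calls
#'
#' A gene enters the DEG set when at least one passing probeset maps to
#' it. When several passing probesets map to one gene, the direction is
#' the majority sign; ties are broken by the probeset with the largest
#' `|mean_log2_diff|`. Passing probesets with no gene symbol are
#' reported in the `unmapped` slot, never silently dropped.
#'
#' @param result a thresholded `contrast_result` (`passes` set).
#' @param annotation probe annotation covering every probeset of
#'   `result`.
#' @return a [deg_set()].
#' @export
collapse_to_genes <- function(result, annotation) {
  stopifnot(inherits(result, "contrast_result"))
  if (all(is.na(result$passes)))
    stop("run apply_thresholds() before collapsing to genes")
  ann <- annotation[match(result$probeset_id, annotation$probe_id), ]
  if (anyNA(ann$probe_id))
    stop("annotation does not cover probeset(s): ",
         paste(utils::head(result$probeset_id[is.na(ann$probe_id)], 3),
               collapse = ", "))
  pass <- result[which(result$passes), , drop = FALSE]
  sym <- ann$gene_symbol[match(pass$probeset_id, ann$probe_id)]
  unmapped <- pass$probeset_id[is.na(sym) | !nzchar(sym)]
  if (length(unmapped))
    message(length(unmapped), " passing probeset(s) have no gene symbol")
  mapped <- pass[!is.na(sym) & nzchar(sym), , drop = FALSE]
  sym <- sym[!is.na(sym) & nzchar(sym)]
  if (!nrow(mapped)) {
    genes <- data.frame(gene_symbol = character(),
                        direction = character(),
                        stringsAsFactors = FALSE)
  } else {
    per_gene <- split(seq_len(nrow(mapped)), sym)
    rows <- lapply(names(per_gene), function(g) {
      idx <- per_gene[[g]]
      n_up <- sum(mapped$direction[idx] == "up")
      n_dn <- length(idx) - n_up
      dir <- if (n_up > n_dn) "up"
        else if (n_dn > n_up) "down"
        else mapped$direction[idx][which.max(abs(mapped$mean_log2_diff[idx]))]
      data.frame(gene_symbol = g, direction = dir,
                 stringsAsFactors = FALSE)
    })
    genes <- do.call(rbind, rows)
    genes <- genes[order(genes$gene_symbol), , drop = FALSE]
  }
  deg_set(attr(result, "contrast_id"), genes,
          probesets = pass$probeset_id, unmapped = unmapped)
}

#' Write a contrast result as TSV
#' @param result a `contrast_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contrast_result <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
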