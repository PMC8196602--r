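# Three-contrast marker-specificity set algebra.
#
# Genes differentially expressed in the case contrast (CNIT vs Normal)
# are partitioned against the two positive-control contrasts (AR vs
# Normal, IFTA vs Normal): genes shared with either injury phenotype are
# generic allograft-injury markers, while the "unique" region is the
# candidate disease-specific signature. Membership is by gene symbol
# only — a gene up in one contrast and down in another still counts as
# shared.

#' Three-way Venn partition of DEG sets
#'
#' Exact set algebra on gene symbols over three DEG sets, conventionally
#' A = CNIT, B = AR, C = IFTA. The seven regions are pairwise disjoint
#' and their unions reconstruct each input set exactly.
#'
#' @param cnit,ar,ifta [deg_set()] objects sharing one gene-symbol
#'   namespace.
#' @return a `venn_partition`: list with `regions` (named list of gene
#'   vectors `A`, `B`, `C`, `AB`, `AC`, `BC`, `ABC`, where e.g. `AB` is
#'   the A-and-B-only region), `counts` (named integer vector), `sets`
#'   (the three inputs, for direction lookup), and `labels`.
#' @export
venn_partition <- function(cnit, ar, ifta) {
  a <- deg_genes(cnit); b <- deg_genes(ar); c <- deg_genes(ifta)
  regions <- list(
    A   = setdiff(setdiff(a, b), c),
    B   = setdiff(setdiff(b, a), c),
    C   = setdiff(setdiff(c, a), b),
    AB  = setdiff(intersect(a, b), c),
    AC  = setdiff(intersect(a, c), b),
    BC  = setdiff(intersect(b, c), a),
    ABC = intersect(intersect(a, b), c))
  regions <- lapply(regions, sort)
  structure(list(
    regions = regions,
    counts = vapply(regions, length, integer(1)),
    sets = list(A = cnit, B = ar, C = ifta),
    labels = c(A = cnit$contrast_id, B = ar$contrast_id,
               C = ifta$contrast_id)),
    class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition (A =", x$labels[["A"]], ", B =", x$labels[["B"]],
      ", C =", x$labels[["C"]], ")\n")
  print(x$counts)
  invisible(x)
}

.condition_slot <- c(CNIT = "A", AR = "B", IFTA = "C")

#' Condition-unique genes of a Venn partition
#'
#' Returns the only-in-that-condition region as a [deg_set()], with
#' directions inherited from the source contrast.
#'
#' @param partition a [venn_partition()].
#' @param condition `"CNIT"`, `"AR"` or `"IFTA"` (positional convention
#'   A/B/C of [venn_partition()]).
#' @return a [deg_set()] of the unique genes.
#' @export
unique_genes <- function(partition, condition = c("CNIT", "AR", "IFTA")) {
  condition <- match.arg(condition)
  slot <- .condition_slot[[condition]]
  src <- partition$sets[[slot]]
  members <- partition$regions[[slot]]
  dirs <- deg_directions(src)
  deg_set(paste0("unique_", condition),
          data.frame(gene_symbol = members,
                     direction = unname(dirs[members]),
                     stringsAsFactors = FALSE))
}

#' Region counts and fractions summary
#'
#' One row per region plus the per-set totals and unique fractions
#' (unique / set size), the accounting a specificity analysis reports.
#'
#' @param partition a [venn_partition()].
#' @return data.frame with columns `region`, `count`.
#' @export
venn_summary <- function(partition) {
  cn <- partition$counts
  totals <- c(
    size_A = sum(cn[c("A", "AB", "AC", "ABC")]),
    size_B = sum(cn[c("B", "AB", "BC", "ABC")]),
    size_C = sum(cn[c("C", "AC", "BC", "ABC")]))
  data.frame(region = c(names(cn), names(totals)),
             count = as.integer(c(cn, totals)),
             stringsAsFactors = FALSE)
}
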