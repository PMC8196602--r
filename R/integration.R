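# miRNA-mRNA data integration.
#
# Differentially expressed miRNAs (case vs control) are paired with the
# disease-unique gene list through a curated target table; a candidate
# pair survives only when the interaction is experimentally observed and
# the expression directions oppose (an upregulated miRNA represses its
# target, so the target should be down, and vice versa).

#' Rejection reasons, in evaluation priority order
#' @export
REJECTION_REASONS <- c("not_experimentally_observed", "same_direction",
                       "target_not_in_unique_list", "mirna_not_de")

#' Integrate DE miRNAs with a disease-unique gene list
#'
#' Each candidate edge of the target table is classified exactly once:
#' either retained (evidence `experimentally_observed`, miRNA in the DE
#' set, gene in the unique list, directions strictly opposed) or rejected
#' with the first failing predicate in the fixed order
#' `not_experimentally_observed`, `same_direction`,
#' `target_not_in_unique_list`, `mirna_not_de`. Direction agreement can
#' only be judged for genes present in the unique list, so an
#' out-of-list target is rejected for list membership, not direction.
#'
#' @param de_mirnas a [deg_set()] of differentially expressed miRNAs
#'   (gene_symbol column holds miRNA ids).
#' @param unique_cnit a [deg_set()] of disease-unique genes.
#' @param targets a [target_pair_table()]; must be non-empty.
#' @return an `integration_result`: list with `retained` (data.frame:
#'   `mirna_id`, `mirna_direction`, `gene_symbol`, `gene_direction`,
#'   `evidence`, sorted by miRNA then gene), `rejected` (data.frame:
#'   `mirna_id`, `gene_symbol`, `reason`), and `counts` (named integer
#'   vector `mirnas`, `genes`, `pairs`).
#' @export
integrate_mirna_mrna <- function(de_mirnas, unique_cnit, targets) {
  stopifnot(inherits(de_mirnas, "deg_set"),
            inherits(unique_cnit, "deg_set"))
  if (!nrow(targets))
    stop("empty target table: nothing to integrate (an empty *result* ",
         "is valid, an empty *substrate* is not)")
  mir_dir <- deg_directions(de_mirnas)
  gene_dir <- deg_directions(unique_cnit)

  mirna_de <- targets$mirna_id %in% names(mir_dir)
  in_list <- targets$gene_symbol %in% names(gene_dir)
  observed <- targets$evidence == "experimentally_observed"
  gdir <- unname(gene_dir[targets$gene_symbol])
  mdir <- unname(mir_dir[targets$mirna_id])
  same_dir <- in_list & mirna_de & !is.na(gdir) & !is.na(mdir) &
    gdir == mdir

  reason <- rep(NA_character_, nrow(targets))
  reason[!mirna_de] <- "mirna_not_de"
  reason[!in_list] <- "target_not_in_unique_list"
  reason[same_dir] <- "same_direction"
  reason[!observed] <- "not_experimentally_observed"

  keep <- is.na(reason)
  retained <- data.frame(
    mirna_id = targets$mirna_id[keep],
    mirna_direction = mdir[keep],
    gene_symbol = targets$gene_symbol[keep],
    gene_direction = gdir[keep],
    evidence = targets$evidence[keep],
    stringsAsFactors = FALSE)
  retained <- retained[order(retained$mirna_id, retained$gene_symbol), ,
                       drop = FALSE]
  rownames(retained) <- NULL
  rejected <- data.frame(
    mirna_id = targets$mirna_id[!keep],
    gene_symbol = targets$gene_symbol[!keep],
    reason = reason[!keep],
    stringsAsFactors = FALSE)
  rejected <- rejected[order(rejected$mirna_id, rejected$gene_symbol), ,
                       drop = FALSE]
  rownames(rejected) <- NULL
  structure(list(
    retained = retained,
    rejected = rejected,
    counts = c(mirnas = length(unique(retained$mirna_id)),
               genes = length(unique(retained$gene_symbol)),
               pairs = nrow(retained))),
    class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf(
    "integration_result: %d pairs retained (%d miRNAs, %d genes); %d rejected\n",
    x$counts[["pairs"]], x$counts[["mirnas"]], x$counts[["genes"]],
    nrow(x$rejected)))
  invisible(x)
}

#' Write integration output (pairs + rejection audit)
#' @param result an `integration_result`.
#' @param pairs_path TSV of retained pairs.
#' @param audit_path optional TSV of rejected candidates with reasons.
#' @return `pairs_path`, invisibly.
#' @export
write_integration_result <- function(result, pairs_path,
                                     audit_path = NULL) {
  utils::write.table(result$retained, pairs_path, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(audit_path))
    utils::write.table(result$rejected, audit_path, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  invisible(pairs_path)
}
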