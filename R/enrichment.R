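# Gene-set and upstream-regulator enrichment.
#
# Overlap significance is the one-sided Fisher exact (hypergeometric
# upper-tail) probability of drawing at least the observed number of set
# members in a query of the given size from the universe, BH-adjusted
# across the collection. Directional consistency is summarized by the
# activation z-score z = (N+ - N-)/sqrt(N+ + N-), where N+ counts signed
# set members whose observed direction matches the direction expected
# under activation and N- counts mismatches; z >= 2 is the conventional
# "activated" (z <= -2 "inhibited") reporting threshold.

# hypergeometric upper tail P[X >= k]
.hyper_upper <- function(k, set_size, universe_size, query_size) {
  stats::phyper(k - 1, set_size, universe_size - set_size, query_size,
                lower.tail = FALSE)
}

#' Activation z-score of a signed gene set against a query
#'
#' Unsigned members (expected_sign 0) and members absent from the query
#' are ignored. Undefined (NA, distinct from 0) when no signed member
#' overlaps the query.
#'
#' @param query a [deg_set()] supplying observed directions.
#' @param signed_set data.frame with columns `gene_symbol`,
#'   `expected_sign` (one element of a `gene_set_collection`).
#' @return list with `z`, `n_consistent`, `n_inconsistent`.
#' @export
activation_z <- function(query, signed_set) {
  dirs <- deg_directions(query)
  m <- signed_set[signed_set$expected_sign != 0L &
                    signed_set$gene_symbol %in% names(dirs), ,
                  drop = FALSE]
  if (!nrow(m))
    return(list(z = NA_real_, n_consistent = 0L, n_inconsistent = 0L))
  obs <- ifelse(dirs[m$gene_symbol] == "up", 1L, -1L)
  n_plus <- sum(obs == m$expected_sign)
  n_minus <- nrow(m) - n_plus
  list(z = (n_plus - n_minus) / sqrt(n_plus + n_minus),
       n_consistent = as.integer(n_plus),
       n_inconsistent = as.integer(n_minus))
}

#' Fisher-exact gene-set enrichment
#'
#' Each set is first restricted to the universe; the query is clipped to
#' the universe with a warning if needed. p-values are hypergeometric
#' upper tails `P[X >= k]`; q-values are BH across all sets of the
#' collection. Activation z-scores are computed from signed members.
#'
#' @param query a [deg_set()] (its gene symbols are the query list; its
#'   directions feed the z-score).
#' @param sets a `gene_set_collection` from [read_gene_sets()].
#' @param universe character vector of background gene symbols
#'   (non-empty, typically all genes mapped on the platform).
#' @return data.frame (`enrichment_rows`) with columns `set_name`,
#'   `overlap_k`, `set_size_in_universe`, `query_size`, `universe_size`,
#'   `overlap_fraction` (k / set size in universe), `p_value`, `q_value`,
#'   `n_consistent`, `n_inconsistent`, `activation_z`.
#' @export
fisher_enrichment <- function(query, sets, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  qgenes <- deg_genes(query)
  outside <- setdiff(qgenes, universe)
  if (length(outside)) {
    warning(length(outside),
            " query gene(s) outside the universe were clipped")
    qgenes <- intersect(qgenes, universe)
  }
  n_u <- length(universe)
  n_q <- length(qgenes)
  rows <- lapply(names(sets), function(nm) {
    members <- sets[[nm]]
    in_univ <- members[members$gene_symbol %in% universe, , drop = FALSE]
    k <- sum(in_univ$gene_symbol %in% qgenes)
    az <- activation_z(query, in_univ)
    data.frame(set_name = nm,
               overlap_k = k,
               set_size_in_universe = nrow(in_univ),
               query_size = n_q,
               universe_size = n_u,
               overlap_fraction = if (nrow(in_univ)) k / nrow(in_univ)
                                  else NA_real_,
               p_value = .hyper_upper(k, nrow(in_univ), n_u, n_q),
               n_consistent = az$n_consistent,
               n_inconsistent = az$n_inconsistent,
               activation_z = az$z,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out[c("set_name", "overlap_k", "set_size_in_universe", "query_size",
        "universe_size", "overlap_fraction", "p_value", "q_value",
        "n_consistent", "n_inconsistent", "activation_z")]
}

#' Upstream-regulator analysis
#'
#' Runs the Fisher overlap machinery over regulator target sets and adds
#' the activation call: a regulator is `reported` when its overlap
#' p-value is below `enrichment_p`, and called `activated`/`inhibited`
#' when additionally `|z| >= z_call` (default 2, the conventional
#' cutoff).
#'
#' @param query a [deg_set()].
#' @param regulators a `gene_set_collection` of regulator target sets
#'   (signed where direction-of-regulation is known).
#' @param universe background gene symbols.
#' @param enrichment_p reporting cutoff on the overlap p-value.
#' @param z_call absolute z-score needed for an activation/inhibition
#'   call.
#' @return the [fisher_enrichment()] data.frame plus `reported`
#'   (logical) and `predicted_state` (`"activated"`, `"inhibited"` or
#'   `NA`).
#' @export
upstream_regulators <- function(query, regulators, universe,
                                enrichment_p = 0.05, z_call = 2) {
  out <- fisher_enrichment(query, regulators, universe)
  out$reported <- out$p_value < enrichment_p
  out$predicted_state <- ifelse(
    !is.na(out$activation_z) & out$activation_z >= z_call, "activated",
    ifelse(!is.na(out$activation_z) & out$activation_z <= -z_call,
           "inhibited", NA_character_))
  out
}
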