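# Small in-code fixtures shared across test files.

make_expr <- function(values, platform = "mRNA",
                      probes = sprintf("p%02d", seq_len(nrow(values))),
                      samples = sprintf("s%02d", seq_len(ncol(values)))) {
  dimnames(values) <- list(probes, samples)
  expr_matrix(values, platform)
}

# matrix with explicit negative-control and GAPDH rows, plus annotation
make_qc_matrix <- function(probe_values, control_values,
                           gapdh5 = NULL, gapdh3 = NULL,
                           platform = "mRNA") {
  stopifnot(ncol(probe_values) == ncol(control_values))
  probes <- sprintf("p%02d", seq_len(nrow(probe_values)))
  controls <- sprintf("nc%02d", seq_len(nrow(control_values)))
  rows <- rbind(probe_values, control_values)
  ids <- c(probes, controls)
  classes <- c(rep("none", length(probes)),
               rep("negative_control", length(controls)))
  qc_gene <- rep("", length(ids))
  if (!is.null(gapdh5)) {
    g5 <- sprintf("g5_%d", seq_len(nrow(gapdh5)))
    g3 <- sprintf("g3_%d", seq_len(nrow(gapdh3)))
    rows <- rbind(rows, gapdh5, gapdh3)
    ids <- c(ids, g5, g3)
    classes <- c(classes, rep("qc_5prime", length(g5)),
                 rep("qc_3prime", length(g3)))
    qc_gene <- c(qc_gene, rep("GAPDH", length(g5) + length(g3)))
  }
  dimnames(rows) <- list(ids, sprintf("s%02d", seq_len(ncol(rows))))
  annotation <- data.frame(probe_id = ids,
                           gene_symbol = ifelse(classes == "none", ids,
                                                ""),
                           control_class = classes, qc_gene = qc_gene,
                           stringsAsFactors = FALSE)
  list(matrix = expr_matrix(rows, platform), annotation = annotation)
}

make_deg <- function(symbols, directions = rep("up", length(symbols)),
                     id = "test") {
  deg_set(id, data.frame(gene_symbol = symbols, direction = directions,
                         stringsAsFactors = FALSE))
}

# independent brute-force BH oracle: min over tail thresholds
bh_oracle <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi]
    min(1, min(vapply(cand, function(t) m * t / sum(p <= t),
                      numeric(1))))
  }, numeric(1))
}

# exhaustive hypergeometric tail oracle: enumerate all query draws
hyper_oracle <- function(k, set_size, universe_size, query_size) {
  universe <- seq_len(universe_size)
  set <- seq_len(set_size)
  draws <- utils::combn(universe, query_size)
  mean(apply(draws, 2, function(q) sum(q %in% set) >= k))
}

# independent re-application of the integration predicates, row by row
integration_oracle <- function(de_mirnas, unique_cnit, targets) {
  mdir <- deg_directions(de_mirnas)
  gdir <- deg_directions(unique_cnit)
  out <- lapply(seq_len(nrow(targets)), function(i) {
    r <- targets[i, ]
    if (r$evidence != "experimentally_observed")
      return(c(r$mirna_id, r$gene_symbol, "not_experimentally_observed"))
    in_list <- r$gene_symbol %in% names(gdir)
    is_de <- r$mirna_id %in% names(mdir)
    if (in_list && is_de && gdir[[r$gene_symbol]] == mdir[[r$mirna_id]])
      return(c(r$mirna_id, r$gene_symbol, "same_direction"))
    if (!in_list)
      return(c(r$mirna_id, r$gene_symbol, "target_not_in_unique_list"))
    if (!is_de)
      return(c(r$mirna_id, r$gene_symbol, "mirna_not_de"))
    c(r$mirna_id, r$gene_symbol, "retained")
  })
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("mirna_id", "gene_symbol", "outcome")
  df
}
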