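# Seeded synthetic-data generators.
#
# These emulate the structure of the study cohort — probe-level log2
# intensity matrices with planted group effects, negative-control and
# housekeeping QC probes, a hybridization-failure sample, many-to-one
# probe-to-gene annotation, target tables with decoy edges, and signed
# gene sets — so that every pipeline stage is exercisable and its
# recovery measurable against recorded ground truth, with no external
# downloads. Every generator is a pure function of its config: the same
# seed yields byte-identical output.

# run code under a local RNG state, restoring the caller's state after
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the gene-expression arm of the study design: 38
#' samples (12 CNIT, 12 Normal, 7 AR, 7 IFTA) of which the last CNIT
#' sample is generated under the hybridization-failure model and is
#' expected to fail the %P >= 50% rule. Per-probe baselines are drawn
#' from Normal(8, 1.5) on the log2 scale (a realistic microarray dynamic
#' range), negative-control probes from Normal(4, 0.5), and measurement
#' noise is Normal(0, noise_sd). Planted differentially expressed
#' probesets receive a condition-specific log2 shift versus Normal; the
#' sign split of the shifts follows `effect_up_fraction`.
#'
#' Use [mirna_cohort_config()] for the miRNA arm (10 CNIT + 5 Normal).
#'
#' @param seed integer seed; fully determines the cohort.
#' @param platform `"mRNA"` or `"miRNA"`.
#' @param n_probes number of ordinary (non-control) probesets.
#' @param n_genes number of gene symbols the probes map onto
#'   (many-to-one; must be <= n_probes).
#' @param n_negative_controls number of background probes.
#' @param group_sizes named integer vector of samples per condition.
#' @param n_de named integer vector: planted DE probesets per non-Normal
#'   condition (vs Normal).
#' @param effect_size absolute log2 shift of planted probesets.
#' @param effect_up_fraction fraction of planted shifts that are
#'   positive.
#' @param noise_sd per-measurement noise SD, log2 units.
#' @param baseline_mean,baseline_sd per-probe baseline distribution.
#' @param control_mean,control_sd negative-control distribution.
#' @param gapdh_true_ratio true linear 3':5' ratio of the housekeeping
#'   probes (default 1.5, an intact-RNA value).
#' @param gapdh_noise_sd log2 noise on housekeeping probes.
#' @param qc_failure_sample index (within all samples, column order) of
#'   the hybridization-failure sample, or `NA` for none.
#' @param qc_failure_shift log2 units by which every non-background
#'   probe of the failing sample is depressed toward background.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(seed = 42L,
                          platform = "mRNA",
                          n_probes = 2000L,
                          n_genes = 900L,
                          n_negative_controls = 50L,
                          group_sizes = c(CNIT = 12L, Normal = 12L,
                                          AR = 7L, IFTA = 7L),
                          n_de = c(CNIT = 200L, AR = 100L, IFTA = 60L),
                          effect_size = 1.2,
                          effect_up_fraction = 0.48,
                          noise_sd = 0.3,
                          baseline_mean = 8, baseline_sd = 1.5,
                          control_mean = 4, control_sd = 0.5,
                          gapdh_true_ratio = 1.5,
                          gapdh_noise_sd = 0.1,
                          qc_failure_sample = 12L,
                          qc_failure_shift = 4.0) {
  stopifnot(n_probes > 0, n_genes > 0, n_genes <= n_probes,
            n_negative_controls > 0, all(group_sizes > 0), noise_sd > 0,
            effect_size > 0, effect_up_fraction >= 0,
            effect_up_fraction <= 1)
  if (is.null(names(group_sizes)) ||
      !all(names(group_sizes) %in% CONDITION_LEVELS))
    stop("group_sizes must be named with condition labels")
  if (length(n_de) && (is.null(names(n_de)) ||
      !all(names(n_de) %in% setdiff(names(group_sizes), "Normal"))))
    stop("n_de must be named with non-Normal conditions present in ",
         "group_sizes")
  if (sum(n_de) > n_probes)
    stop("more planted DE probesets than probes")
  structure(list(seed = as.integer(seed), platform = platform,
                 n_probes = as.integer(n_probes),
                 n_genes = as.integer(n_genes),
                 n_negative_controls = as.integer(n_negative_controls),
                 group_sizes = group_sizes, n_de = n_de,
                 effect_size = effect_size,
                 effect_up_fraction = effect_up_fraction,
                 noise_sd = noise_sd,
                 baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 control_mean = control_mean, control_sd = control_sd,
                 gapdh_true_ratio = gapdh_true_ratio,
                 gapdh_noise_sd = gapdh_noise_sd,
                 qc_failure_sample = qc_failure_sample,
                 qc_failure_shift = qc_failure_shift),
            class = "cohort_config")
}

#' miRNA-arm cohort configuration
#'
#' The miRNA profiling arm of the study design: 10 CNIT + 5 Normal
#' samples, no QC failure, larger planted effects (the miRNA platform
#' uses a 2-fold-change threshold), and each probe mapping to its own
#' miRNA id. 72% of planted shifts are upregulated, mirroring the
#' reported up-fraction of differentially expressed miRNAs.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [cohort_config()].
#' @return a `cohort_config`.
#' @export
mirna_cohort_config <- function(seed = 42L, ...) {
  defaults <- list(seed = seed, platform = "miRNA",
                   n_probes = 400L, n_genes = 400L,
                   n_negative_controls = 30L,
                   group_sizes = c(CNIT = 10L, Normal = 5L),
                   n_de = c(CNIT = 40L),
                   effect_size = 1.5,
                   effect_up_fraction = 0.72,
                   noise_sd = 0.4,
                   qc_failure_sample = NA)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

#' Generate a synthetic probe-level cohort
#'
#' Produces an expression matrix, sample table, probe annotation and a
#' truth table of every planted effect, all determined by
#' `config$seed`.
#'
#' Probe ids: ordinary probes `P0001_at` (mRNA) or `mir-sim-0001`
#' (miRNA), negative controls `AFFX-NC-0001`, housekeeping probes
#' `AFFX-GAPDH-5-1`/`AFFX-GAPDH-3-1` (two of each end). Ordinary mRNA
#' probes map many-to-one onto gene symbols `SG0001`...; miRNA probes
#' map to themselves.
#'
#' @param config a [cohort_config()].
#' @return list with `matrix` ([expr_matrix()]), `samples` (sample
#'   table), `annotation` (probe annotation), `truth` (data.frame of
#'   planted effects: `probe_id`, `gene_symbol`, `condition`, `shift`,
#'   `direction`) and `qc_failure_sample` (sample id or `NA`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  .with_seed(config$seed, {
    gs <- config$group_sizes
    conditions <- rep(names(gs), gs)
    sample_ids <- unlist(lapply(names(gs), function(cn)
      sprintf("%s_%02d", cn, seq_len(gs[[cn]]))), use.names = FALSE)

    if (config$platform == "mRNA") {
      probe_ids <- sprintf("P%04d_at", seq_len(config$n_probes))
      # many-to-one map: every gene gets >= 1 probe, remainder spread
      # uniformly at random
      gene_pool <- sprintf("SG%04d", seq_len(config$n_genes))
      gene_of <- c(gene_pool,
                   sample(gene_pool, config$n_probes - config$n_genes,
                          replace = TRUE))
    } else {
      probe_ids <- sprintf("mir-sim-%04d", seq_len(config$n_probes))
      gene_of <- probe_ids
    }
    nc_ids <- sprintf("AFFX-NC-%04d",
                      seq_len(config$n_negative_controls))
    g5_ids <- c("AFFX-GAPDH-5-1", "AFFX-GAPDH-5-2")
    g3_ids <- c("AFFX-GAPDH-3-1", "AFFX-GAPDH-3-2")

    annotation <- data.frame(
      probe_id = c(probe_ids, nc_ids, g5_ids, g3_ids),
      gene_symbol = c(gene_of, rep("", length(nc_ids)),
                      rep("GAPDH", 4L)),
      control_class = c(rep("none", length(probe_ids)),
                        rep("negative_control", length(nc_ids)),
                        rep("qc_5prime", 2L), rep("qc_3prime", 2L)),
      qc_gene = c(rep("", length(probe_ids) + length(nc_ids)),
                  rep("GAPDH", 4L)),
      stringsAsFactors = FALSE)

    n_s <- length(sample_ids)
    baseline <- stats::rnorm(config$n_probes, config$baseline_mean,
                             config$baseline_sd)
    values <- baseline +
      matrix(stats::rnorm(config$n_probes * n_s, 0, config$noise_sd),
             config$n_probes, n_s)

    # plant condition effects on disjoint probe blocks
    truth <- list()
    available <- sample.int(config$n_probes)
    offset <- 0L
    for (cn in names(config$n_de)) {
      k <- config$n_de[[cn]]
      if (k == 0L) next
      idx <- available[(offset + 1L):(offset + k)]
      offset <- offset + k
      n_up <- round(k * config$effect_up_fraction)
      shift <- config$effect_size *
        c(rep(1, n_up), rep(-1, k - n_up))
      cols <- which(conditions == cn)
      values[idx, cols] <- values[idx, cols] + shift
      truth[[cn]] <- data.frame(
        probe_id = probe_ids[idx], gene_symbol = gene_of[idx],
        condition = cn, shift = shift,
        direction = ifelse(shift > 0, "up", "down"),
        stringsAsFactors = FALSE)
    }
    truth <- if (length(truth)) do.call(rbind, truth)
      else data.frame(probe_id = character(), gene_symbol = character(),
                      condition = character(), shift = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
    rownames(truth) <- NULL

    controls <- matrix(stats::rnorm(length(nc_ids) * n_s,
                                    config$control_mean,
                                    config$control_sd),
                       length(nc_ids), n_s)
    g5 <- matrix(stats::rnorm(2L * n_s, 9, config$gapdh_noise_sd),
                 2L, n_s)
    g3 <- g5 + log2(config$gapdh_true_ratio) +
      matrix(stats::rnorm(2L * n_s, 0, config$gapdh_noise_sd), 2L, n_s)

    qc_fail_id <- NA_character_
    if (!is.na(config$qc_failure_sample)) {
      j <- config$qc_failure_sample
      # hybridization failure: target and housekeeping signal collapse
      # toward background; the background probes themselves are
      # unaffected, so the detection threshold stays put and %P drops
      values[, j] <- values[, j] - config$qc_failure_shift
      g5[, j] <- g5[, j] - config$qc_failure_shift
      g3[, j] <- g3[, j] - config$qc_failure_shift
      qc_fail_id <- sample_ids[j]
    }

    full <- rbind(values, controls, g5, g3)
    dimnames(full) <- list(annotation$probe_id, sample_ids)
    list(matrix = expr_matrix(full, config$platform),
         samples = data.frame(sample_id = sample_ids,
                              condition = conditions,
                              platform = config$platform,
                              stringsAsFactors = FALSE),
         annotation = annotation,
         truth = truth,
         qc_failure_sample = qc_fail_id)
  })
}

#' Deterministic three-set accounting fixture
#'
#' Builds three DEG sets over synthetic gene symbols whose seven-region
#' partition has exactly the counts of the study's comparison analysis:
#' unique regions 1245 / 418 / 107 (CNIT / AR / IFTA), pairwise-only
#' overlaps 127 (CNIT-AR), 45 (CNIT-IFTA), 67 (AR-IFTA), and a triple
#' intersection of 66 — giving set sizes 1483, 678 and 285. Directions
#' in the CNIT set are assigned so that exactly 714 of its 1483 genes
#' are up; the AR and IFTA sets carry 60% and 31% up respectively. The
#' construction is fully deterministic (no RNG).
#'
#' @return named list of three [deg_set()]s: `cnit`, `ar`, `ifta`.
#' @export
generate_venn_fixture <- function() {
  region_counts <- c(A = 1245L, B = 418L, C = 107L, AB = 127L,
                     AC = 45L, BC = 67L, ABC = 66L)
  total <- sum(region_counts)
  symbols <- sprintf("VG%04d", seq_len(total))
  idx <- split(symbols,
               rep(names(region_counts), region_counts))

  members <- list(
    A = c(idx$A, idx$AB, idx$AC, idx$ABC),
    B = c(idx$B, idx$AB, idx$BC, idx$ABC),
    C = c(idx$C, idx$AC, idx$BC, idx$ABC))

  make_set <- function(genes, n_up, id) {
    genes <- sort(genes)
    deg_set(id, data.frame(
      gene_symbol = genes,
      direction = c(rep("up", n_up),
                    rep("down", length(genes) - n_up)),
      stringsAsFactors = FALSE))
  }
  list(cnit = make_set(members$A, 714L, "CNIT_vs_Normal"),
       ar = make_set(members$B, round(0.60 * 678), "AR_vs_Normal"),
       ifta = make_set(members$C, round(0.31 * 285), "IFTA_vs_Normal"))
}

#' Integration fixture with decoys
#'
#' Builds a candidate substrate for [integrate_mirna_mrna()]: 20
#' differentially expressed miRNAs of which 13 carry experimentally
#' observed, direction-opposed targets inside the unique-CNIT list
#' (covering exactly 33 distinct genes), and 7 decoys carry only failing
#' pairs. Additional failing pairs are attached to the true miRNAs —
#' one per rejection reason, cycling — and two pairs reference miRNAs
#' absent from the DE set, so every rejection reason is exercised. The
#' names of a handful of true pairs echo well-known mitochondria-related
#' miRNA/gene couples (miR-16-5p with CCND1, SOD2, MYC, ...); the rest
#' are synthetic.
#'
#' @param seed integer seed driving the direction assignments.
#' @return list with `de_mirnas` ([deg_set()] of 20 miRNAs),
#'   `unique_cnit` ([deg_set()] of the unique-gene list, 33 true targets
#'   plus in-list distractors), `targets` ([target_pair_table()]), and
#'   `truth` (data.frame: `mirna_id`, `gene_symbol`,
#'   `expected_outcome`).
#' @export
generate_integration_fixture <- function(seed = 42L) {
  .with_seed(seed, {
    true_mirnas <- c("miR-16-5p", "miR-30a-5p", "miR-26b-5p",
                     "miR-24-3p", sprintf("miR-sim-%02d", 5:13))
    decoy_mirnas <- sprintf("miR-dcy-%02d", 1:7)
    absent_mirnas <- c("miR-abs-01", "miR-abs-02")

    mir_dir <- sample(c("up", "down"), 20L, replace = TRUE,
                      prob = c(0.72, 0.28))
    de_mirnas <- deg_set("CNIT_vs_Normal_miRNA", data.frame(
      gene_symbol = c(true_mirnas, decoy_mirnas),
      direction = mir_dir, stringsAsFactors = FALSE))
    dirs <- deg_directions(de_mirnas)

    # 33 distinct true targets: 7 miRNAs x 3 + 6 x 2
    named_targets <- c("CCND1", "SOD2", "MYC", "APP", "TLR4", "GRB10",
                       "SMAD4", "PNN", "GFPT1", "AGO4")
    true_genes <- c(named_targets, sprintf("UCG%03d", seq_len(23L)))
    n_per <- rep(c(3L, 2L), c(7L, 6L))
    owner <- rep(true_mirnas, n_per)

    flip <- function(d) ifelse(d == "up", "down", "up")
    gene_dir <- flip(dirs[owner])

    # in-list distractor genes used only by failing pairs; their
    # directions are set pair-wise below
    distractors <- sprintf("DST%03d", seq_len(24L))
    out_of_list <- sprintf("XLG%03d", seq_len(12L))

    pairs <- data.frame(mirna_id = owner, gene_symbol = true_genes,
                        evidence = "experimentally_observed",
                        source = "curated", expected = "retained",
                        gene_direction = unname(gene_dir),
                        stringsAsFactors = FALSE)

    # one failing pair per true miRNA, cycling the three in-DE reasons
    reasons <- rep(c("not_experimentally_observed", "same_direction",
                     "target_not_in_unique_list"), length.out = 13L)
    di <- 0L; oi <- 0L
    fail_rows <- lapply(seq_along(true_mirnas), function(i) {
      m <- true_mirnas[i]
      switch(reasons[i],
        not_experimentally_observed = {
          di <<- di + 1L
          data.frame(mirna_id = m, gene_symbol = distractors[di],
                     evidence = "predicted_high", source = "pred",
                     expected = "not_experimentally_observed",
                     gene_direction = flip(dirs[[m]]),
                     stringsAsFactors = FALSE)
        },
        same_direction = {
          di <<- di + 1L
          data.frame(mirna_id = m, gene_symbol = distractors[di],
                     evidence = "experimentally_observed",
                     source = "curated", expected = "same_direction",
                     gene_direction = dirs[[m]],
                     stringsAsFactors = FALSE)
        },
        target_not_in_unique_list = {
          oi <<- oi + 1L
          data.frame(mirna_id = m, gene_symbol = out_of_list[oi],
                     evidence = "experimentally_observed",
                     source = "curated",
                     expected = "target_not_in_unique_list",
                     gene_direction = NA_character_,
                     stringsAsFactors = FALSE)
        })
    })
    # decoys: only failing pairs, cycling reasons
    decoy_reasons <- rep(c("not_experimentally_observed",
                           "same_direction",
                           "target_not_in_unique_list"),
                         length.out = 7L)
    decoy_rows <- lapply(seq_along(decoy_mirnas), function(i) {
      m <- decoy_mirnas[i]
      switch(decoy_reasons[i],
        not_experimentally_observed = {
          di <<- di + 1L
          data.frame(mirna_id = m, gene_symbol = distractors[di],
                     evidence = "predicted_moderate", source = "pred",
                     expected = "not_experimentally_observed",
                     gene_direction = flip(dirs[[m]]),
                     stringsAsFactors = FALSE)
        },
        same_direction = {
          di <<- di + 1L
          data.frame(mirna_id = m, gene_symbol = distractors[di],
                     evidence = "experimentally_observed",
                     source = "curated", expected = "same_direction",
                     gene_direction = dirs[[m]],
                     stringsAsFactors = FALSE)
        },
        target_not_in_unique_list = {
          oi <<- oi + 1L
          data.frame(mirna_id = m, gene_symbol = out_of_list[oi],
                     evidence = "experimentally_observed",
                     source = "curated",
                     expected = "target_not_in_unique_list",
                     gene_direction = NA_character_,
                     stringsAsFactors = FALSE)
        })
    })
    # pairs whose miRNA is not differentially expressed
    di <- di + 1L
    absent_rows <- data.frame(
      mirna_id = absent_mirnas,
      gene_symbol = c(distractors[di], true_genes[1L]),
      evidence = "experimentally_observed", source = "curated",
      expected = "mirna_not_de",
      gene_direction = c("up", NA_character_),
      stringsAsFactors = FALSE)

    all_rows <- rbind(pairs, do.call(rbind, fail_rows),
                      do.call(rbind, decoy_rows), absent_rows)

    # unique-CNIT list: every in-list gene with its designed direction;
    # a gene referenced twice keeps its first designed direction
    in_list <- all_rows[!is.na(all_rows$gene_direction), , drop = FALSE]
    first <- !duplicated(in_list$gene_symbol)
    unique_cnit <- deg_set("unique_CNIT", data.frame(
      gene_symbol = in_list$gene_symbol[first],
      direction = in_list$gene_direction[first],
      stringsAsFactors = FALSE))

    targets <- target_pair_table(
      all_rows[c("mirna_id", "gene_symbol", "evidence", "source")])
    truth <- all_rows[c("mirna_id", "gene_symbol", "expected")]
    names(truth)[3L] <- "expected_outcome"
    rownames(truth) <- NULL
    list(de_mirnas = de_mirnas, unique_cnit = unique_cnit,
         targets = targets, truth = truth)
  })
}

#' Probeset-to-gene collapse fixture at study scale
#'
#' A thresholded contrast of 1837 passing probesets whose annotation
#' maps them many-to-one onto exactly 1483 gene symbols (354 genes carry
#' two passing probesets, the rest one), with directions arranged so
#' that 714 genes collapse as up and 769 as down — the probe/gene
#' multiplicity of the study's case contrast.
#'
#' @param seed integer seed (shuffles which genes get two probes).
#' @return list with `result` (a passing-only `contrast_result`) and
#'   `annotation`.
#' @export
generate_collapse_fixture <- function(seed = 42L) {
  .with_seed(seed, {
    n_genes <- 1483L
    n_double <- 354L                       # 1483 + 354 = 1837 probesets
    genes <- sprintf("CG%04d", seq_len(n_genes))
    gene_dir <- c(rep("up", 714L), rep("down", n_genes - 714L))
    doubled <- sort(sample.int(n_genes, n_double))
    gene_of <- c(genes, genes[doubled])
    dir_of <- c(gene_dir, gene_dir[doubled])
    probe_ids <- sprintf("CP%04d_at", seq_along(gene_of))
    diff <- ifelse(dir_of == "up", 1.0, -1.0) +
      stats::rnorm(length(gene_of), 0, 0.05)
    # keep planted sign: clamp away from zero
    diff <- sign(ifelse(dir_of == "up", 1, -1)) * pmax(abs(diff), 0.6)
    res <- data.frame(
      probeset_id = probe_ids,
      mean_log2_diff = diff,
      t_statistic = diff * 10,
      p_value = rep(1e-6, length(diff)),
      q_value = rep(1e-5, length(diff)),
      fold_change = 2^diff,
      direction = ifelse(diff > 0, "up", "down"),
      passes = TRUE,
      stringsAsFactors = FALSE)
    attr(res, "contrast_id") <- "CNIT_vs_Normal"
    class(res) <- c("contrast_result", "data.frame")
    annotation <- data.frame(
      probe_id = probe_ids, gene_symbol = gene_of,
      control_class = "none", qc_gene = "",
      stringsAsFactors = FALSE)
    list(result = res, annotation = annotation)
  })
}
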