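test_that("cohort generation is a pure function of its config", {
  cfg <- cohort_config(seed = 42, n_probes = 200L, n_genes = 90L,
                       group_sizes = c(CNIT = 4L, Normal = 4L),
                       n_de = c(CNIT = 20L), qc_failure_sample = NA)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(unclass(a$matrix), unclass(b$matrix))
  expect_identical(a$truth, b$truth)
  c3 <- generate_cohort(cohort_config(seed = 43, n_probes = 200L,
                                      n_genes = 90L,
                                      group_sizes = c(CNIT = 4L,
                                                      Normal = 4L),
                                      n_de = c(CNIT = 20L),
                                      qc_failure_sample = NA))
  expect_false(identical(unclass(a$matrix), unclass(c3$matrix)))
  # generation does not disturb the caller's RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(generate_cohort(cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("the default cohort mirrors the study design", {
  co <- generate_cohort(cohort_config(seed = 42))
  expect_equal(ncol(co$matrix), 38L)
  expect_equal(as.integer(table(co$samples$condition)[
    c("CNIT", "Normal", "AR", "IFTA")]), c(12L, 12L, 7L, 7L))
  pp <- percent_present(co$matrix, co$annotation)
  expect_equal(sum(pp < 0.5), 1L)
  expect_equal(names(which(pp < 0.5)), co$qc_failure_sample)
  expect_match(co$qc_failure_sample, "^CNIT_")
  # housekeeping probes are generated near the configured true ratio
  gr <- gapdh_ratio(co$matrix, co$annotation)
  expect_true(all(gr > 1 & gr <= 3))
})

test_that("the miRNA arm uses its own design and identity mapping", {
  co <- generate_cohort(mirna_cohort_config(seed = 3))
  expect_equal(as.integer(table(co$samples$condition)[c("CNIT",
                                                         "Normal")]),
               c(10L, 5L))
  expect_identical(platform_of(co$matrix), "miRNA")
  ann <- co$annotation
  ordinary <- ann[ann$control_class == "none", ]
  expect_identical(ordinary$gene_symbol, ordinary$probe_id)
  # planted up-fraction mirrors the configured 72%
  tr <- co$truth
  expect_equal(mean(tr$direction == "up"), 0.72, tolerance = 0.02)
})

test_that("a null cohort yields (almost) no discoveries", {
  co <- generate_cohort(cohort_config(
    seed = 8, n_probes = 1000L, n_genes = 400L,
    group_sizes = c(CNIT = 8L, Normal = 8L), n_de = c(CNIT = 0L),
    qc_failure_sample = NA))
  g1 <- co$samples$sample_id[co$samples$condition == "CNIT"]
  g2 <- co$samples$sample_id[co$samples$condition == "Normal"]
  norm <- quantile_normalize(co$matrix)
  res <- apply_thresholds(probeset_test(norm, g1, g2),
                          thresholds("mRNA"))
  expect_lte(mean(res$passes), 0.05)
  expect_equal(nrow(co$truth), 0L)
})

test_that("truth tables support exact recovery accounting", {
  co <- generate_cohort(cohort_config(
    seed = 12, n_probes = 800L, n_genes = 300L,
    group_sizes = c(CNIT = 10L, Normal = 10L), n_de = c(CNIT = 80L),
    qc_failure_sample = NA))
  expect_equal(nrow(co$truth), 80L)
  expect_true(all(co$truth$probe_id %in% rownames(co$matrix)))
  g1 <- co$samples$sample_id[co$samples$condition == "CNIT"]
  g2 <- co$samples$sample_id[co$samples$condition == "Normal"]
  res <- apply_thresholds(probeset_test(quantile_normalize(co$matrix),
                                        g1, g2), thresholds("mRNA"))
  sens <- mean(co$truth$probe_id %in%
                 res$probeset_id[which(res$passes)])
  expect_gt(sens, 0.9)
})

test_that("inconsistent configs are rejected up front", {
  expect_error(cohort_config(n_probes = 100L, n_genes = 50L,
                             n_de = c(CNIT = 150L)),
               "more planted")
  expect_error(cohort_config(group_sizes = c(Weird = 5L)),
               "condition labels")
  expect_error(cohort_config(noise_sd = 0))
})

test_that("the accounting fixture reproduces the comparison analysis", {
  vf <- generate_venn_fixture()
  expect_equal(nrow(vf$cnit$genes), 1483L)
  expect_equal(nrow(vf$ar$genes), 678L)
  expect_equal(nrow(vf$ifta$genes), 285L)
  expect_equal(sum(vf$cnit$genes$direction == "up"), 714L)
  expect_identical(generate_venn_fixture(), vf)   # deterministic
})

test_that("the integration fixture exercises every rejection reason", {
  fx <- generate_integration_fixture(seed = 42)
  expect_equal(nrow(fx$de_mirnas$genes), 20L)
  res <- integrate_mirna_mrna(fx$de_mirnas, fx$unique_cnit, fx$targets)
  # classification agrees with the designed truth, pair by pair
  truth <- fx$truth
  got <- rbind(
    data.frame(mirna_id = res$retained$mirna_id,
               gene_symbol = res$retained$gene_symbol,
               outcome = "retained"),
    data.frame(mirna_id = res$rejected$mirna_id,
               gene_symbol = res$rejected$gene_symbol,
               outcome = res$rejected$reason))
  key <- function(d) d[order(d$mirna_id, d$gene_symbol), ]
  expect_equal(key(got)$outcome, key(truth)$expected_outcome)
  expect_setequal(unique(res$rejected$reason), REJECTION_REASONS)
  # same seed, same fixture
  expect_identical(generate_integration_fixture(seed = 42), fx)
})

test_that("the collapse fixture carries the study's probe multiplicity", {
  cf <- generate_collapse_fixture(seed = 42)
  expect_equal(nrow(cf$result), 1837L)
  expect_true(all(cf$result$passes))
  expect_equal(length(unique(cf$annotation$gene_symbol)), 1483L)
  degs <- collapse_to_genes(cf$result, cf$annotation)
  expect_equal(nrow(degs$genes), 1483L)
  expect_equal(sum(degs$genes$direction == "up"), 714L)
  expect_equal(sum(degs$genes$direction == "down"), 769L)
})
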