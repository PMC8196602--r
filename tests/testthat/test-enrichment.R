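make_sets <- function(...) {
  structure(list(...), class = "gene_set_collection")
}
unsigned_members <- function(symbols)
  data.frame(gene_symbol = symbols, expected_sign = 0L)

test_that("Fisher p matches closed forms", {
  universe <- sprintf("u%02d", 1:20)
  sets <- make_sets(hit = unsigned_members(universe[1:5]),
                    miss = unsigned_members(universe[6:10]))
  query <- make_deg(universe[1:5])
  out <- fisher_enrichment(query, sets, universe)
  # full overlap of a 5-set with a 5-query in a 20-universe
  expect_equal(out$p_value[out$set_name == "hit"], 1 / choose(20, 5))
  # zero overlap: P[X >= 0] = 1
  expect_equal(out$p_value[out$set_name == "miss"], 1)
  expect_equal(out$overlap_k[out$set_name == "miss"], 0L)
})

test_that("Fisher p equals exhaustive enumeration on small universes", {
  set.seed(13)
  for (i in 1:20) {
    n_u <- sample(6:12, 1)
    universe <- sprintf("u%02d", seq_len(n_u))
    set_size <- sample(1:(n_u - 1), 1)
    query_size <- sample(2:(n_u - 1), 1)
    query <- make_deg(sample(universe, query_size))
    sets <- make_sets(s = unsigned_members(universe[seq_len(set_size)]))
    out <- fisher_enrichment(query, sets, universe)
    expect_equal(out$p_value,
                 hyper_oracle(out$overlap_k, set_size, n_u, query_size),
                 tolerance = 1e-12)
  }
})

test_that("a larger overlap never raises the p-value", {
  universe <- sprintf("u%02d", 1:40)
  sets <- make_sets(s = unsigned_members(universe[1:10]))
  p_prev <- 1
  for (k in 1:8) {
    query <- make_deg(c(universe[seq_len(k)], universe[31:38]))
    out <- fisher_enrichment(query, sets, universe)
    expect_lte(out$p_value, p_prev + 1e-15)
    p_prev <- out$p_value
  }
})

test_that("activation z matches its closed form and recount oracle", {
  q <- make_deg(c("A", "B", "C", "D"), c("up", "up", "down", "down"))
  all_consistent <- data.frame(gene_symbol = c("A", "B", "C", "D"),
                               expected_sign = c(1L, 1L, -1L, -1L))
  expect_equal(activation_z(q, all_consistent)$z, 2.0)
  half <- data.frame(gene_symbol = c("A", "B", "C", "D"),
                     expected_sign = c(1L, -1L, -1L, 1L))
  expect_equal(activation_z(q, half)$z, 0)
  none <- data.frame(gene_symbol = c("A", "B"), expected_sign = 0L)
  expect_true(is.na(activation_z(q, none)$z))

  set.seed(17)
  pool <- sprintf("g%03d", 1:80)
  for (i in 1:1000) {
    qs <- sample(pool, 30)
    qd <- sample(c("up", "down"), 30, replace = TRUE)
    query <- make_deg(qs, qd)
    members <- data.frame(
      gene_symbol = sample(pool, 20),
      expected_sign = sample(c(-1L, 0L, 1L), 20, replace = TRUE))
    got <- activation_z(query, members)
    # independent recount
    np <- 0L; nm <- 0L
    dirs <- setNames(qd, qs)
    for (j in seq_len(nrow(members))) {
      g <- members$gene_symbol[j]; s <- members$expected_sign[j]
      if (s == 0L || !g %in% qs) next
      obs <- if (dirs[[g]] == "up") 1L else -1L
      if (obs == s) np <- np + 1L else nm <- nm + 1L
    }
    if (np + nm == 0L) {
      expect_true(is.na(got$z))
    } else {
      expect_equal(got$z, (np - nm) / sqrt(np + nm))
      expect_equal(c(got$n_consistent, got$n_inconsistent), c(np, nm))
      expect_lte(abs(got$z), sqrt(np + nm) + 1e-12)
    }
  }
})

test_that("activation z flips sign when all query directions flip", {
  set.seed(18)
  pool <- sprintf("g%03d", 1:40)
  qs <- sample(pool, 20)
  qd <- sample(c("up", "down"), 20, replace = TRUE)
  members <- data.frame(gene_symbol = sample(pool, 15),
                        expected_sign = sample(c(-1L, 1L), 15,
                                               replace = TRUE))
  z1 <- activation_z(make_deg(qs, qd), members)$z
  z2 <- activation_z(make_deg(qs, ifelse(qd == "up", "down", "up")),
                     members)$z
  if (!is.na(z1)) expect_equal(z2, -z1)
})

test_that("collection q-values are the shared BH adjustment", {
  set.seed(19)
  universe <- sprintf("u%03d", 1:100)
  sets <- make_sets(
    a = unsigned_members(sample(universe, 20)),
    b = unsigned_members(sample(universe, 10)),
    c = unsigned_members(sample(universe, 30)),
    d = unsigned_members(sample(universe, 5)))
  query <- make_deg(sample(universe, 25))
  out <- fisher_enrichment(query, sets, universe)
  expect_equal(out$q_value, bh_fdr(out$p_value))
})

test_that("queries outside the universe are clipped with a warning", {
  universe <- sprintf("u%02d", 1:10)
  sets <- make_sets(s = unsigned_members(universe[1:4]))
  query <- make_deg(c(universe[1:3], "alien"))
  expect_warning(out <- fisher_enrichment(query, sets, universe),
                 "clipped")
  expect_equal(out$query_size, 3L)
  expect_error(fisher_enrichment(query, sets, character()),
               "empty universe")
})

test_that("a planted activated regulator is detected", {
  set.seed(11)
  universe <- sprintf("u%03d", 1:100)
  query_genes <- sample(universe, 10)
  # regulator whose 10 signed targets all sit in the query, signs
  # consistent with the observed directions
  qdir <- sample(c("up", "down"), 10, replace = TRUE)
  query <- make_deg(query_genes, qdir)
  regs <- make_sets(
    activated = data.frame(gene_symbol = query_genes,
                           expected_sign = ifelse(qdir == "up", 1L,
                                                  -1L)),
    cold = unsigned_members(setdiff(universe, query_genes)[1:10]))
  out <- upstream_regulators(query, regs, universe)
  act <- out[out$set_name == "activated", ]
  expect_lt(act$p_value, 0.05)
  expect_gt(act$activation_z, 2)
  expect_equal(act$predicted_state, "activated")
  expect_true(act$reported)
  cold <- out[out$set_name == "cold", ]
  expect_equal(cold$p_value, 1)
  expect_true(is.na(cold$activation_z))
})
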