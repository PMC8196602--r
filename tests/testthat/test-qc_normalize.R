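test_that("detection call is a strict background-margin rule", {
  # controls sit at log2 = 4.0 exactly, so threshold = 5.0 at margin 1
  fx <- make_qc_matrix(probe_values = matrix(c(5.5, 5.0, 4.9), 3, 1),
                       control_values = matrix(rep(4, 3), 3, 1))
  calls <- detection_call(fx$matrix, fx$annotation, margin = 1.0)
  expect_identical(as.vector(calls), c(TRUE, FALSE, FALSE))
  # control probes are excluded from the call matrix
  expect_equal(nrow(calls), 3L)
})

test_that("percent present counts planted exceedances exactly", {
  n <- 100
  vals <- matrix(c(rep(6, 60), rep(4.5, 40)), n, 1)
  fx <- make_qc_matrix(vals, matrix(rep(4, 5), 5, 1))
  expect_equal(unname(percent_present(fx$matrix, fx$annotation)), 0.60)
})

test_that("detection call is monotone in the margin", {
  set.seed(11)
  fx <- make_qc_matrix(matrix(rnorm(200, 6, 1.5), 50, 4),
                       matrix(rnorm(40, 4, 0.5), 10, 4))
  prev <- Inf
  for (m in c(0.5, 1, 1.5, 2.5)) {
    cur <- sum(detection_call(fx$matrix, fx$annotation, m))
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("missing negative controls is an instructive error", {
  m <- make_expr(matrix(rnorm(4, 8), 2, 2))
  ann <- data.frame(probe_id = rownames(m), gene_symbol = rownames(m),
                    control_class = "none", qc_gene = "")
  expect_error(detection_call(m, ann), "negative_control")
})

test_that("GAPDH 3':5' ratio matches hand arithmetic", {
  fx <- make_qc_matrix(matrix(8, 1, 1), matrix(4, 1, 1),
                       gapdh5 = matrix(8, 1, 1),
                       gapdh3 = matrix(8, 1, 1))
  expect_equal(unname(gapdh_ratio(fx$matrix, fx$annotation)), 1.0)

  fx <- make_qc_matrix(matrix(8, 1, 1), matrix(4, 1, 1),
                       gapdh5 = matrix(8, 1, 1),
                       gapdh3 = matrix(10, 1, 1))
  expect_equal(unname(gapdh_ratio(fx$matrix, fx$annotation)), 4.0)

  # multiple probes per end: means first, then the power
  fx <- make_qc_matrix(matrix(8, 1, 1), matrix(4, 1, 1),
                       gapdh5 = matrix(c(8, 8.5), 2, 1),
                       gapdh3 = matrix(c(9, 9), 2, 1))
  expect_equal(unname(gapdh_ratio(fx$matrix, fx$annotation)), 2^0.75)
  expect_error(gapdh_ratio(make_qc_matrix(matrix(8, 1, 1),
                                          matrix(4, 1, 1))$matrix,
                           make_qc_matrix(matrix(8, 1, 1),
                                          matrix(4, 1, 1))$annotation),
               "qc_3prime")
})

test_that("qc_report applies the pass rules and flags the borderline band", {
  fx <- make_qc_matrix(
    probe_values = cbind(rep(8, 100),              # high %P
                         c(rep(8, 40), rep(4, 60)),  # 40% -> fail, borderline
                         rep(8, 100)),
    control_values = matrix(4, 5, 3),
    gapdh5 = matrix(8, 1, 3),
    gapdh3 = matrix(c(8.5, 8.5, 10), 1, 3))        # third sample ratio 4
  expect_warning(rep <- qc_report(fx$matrix, fx$annotation,
                                  thresholds("mRNA")),
                 "borderline")
  expect_equal(rep$pass_percent_present, c(TRUE, FALSE, TRUE))
  expect_equal(rep$pass_gapdh, c(TRUE, TRUE, FALSE))
  expect_equal(rep$pass, c(TRUE, FALSE, FALSE))
  expect_equal(rep$borderline, c(FALSE, TRUE, FALSE))
})

test_that("apply_qc drops failing samples without touching survivors", {
  fx <- make_qc_matrix(matrix(rnorm(300, 8), 100, 3),
                       matrix(4, 5, 3))
  rep <- data.frame(sample_id = colnames(fx$matrix),
                    pass = c(TRUE, FALSE, TRUE))
  out <- suppressMessages(apply_qc(fx$matrix, rep))
  expect_identical(out$dropped, "s02")
  expect_identical(colnames(out$matrix), c("s01", "s03"))
  expect_equal(unclass(out$matrix),
               unclass(fx$matrix)[, c(1, 3)], ignore_attr = TRUE)

  all_pass <- data.frame(sample_id = colnames(fx$matrix), pass = TRUE)
  expect_equal(unclass(apply_qc(fx$matrix, all_pass)$matrix),
               unclass(fx$matrix), ignore_attr = TRUE)
  expect_error(apply_qc(fx$matrix, rep[1:2, ]), "does not cover")
  none <- data.frame(sample_id = colnames(fx$matrix), pass = FALSE)
  expect_error(suppressMessages(apply_qc(fx$matrix, none)),
               "empty cohort")
})

test_that("quantile normalization matches the rank-mean definition", {
  m <- make_expr(cbind(c(1, 2, 3), c(4, 5, 6)))
  qn <- quantile_normalize(m)
  expect_equal(unname(unclass(qn)[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(unclass(qn)[, 2]), c(2.5, 3.5, 4.5))

  # works in any row order: rank, not position
  m2 <- make_expr(cbind(c(3, 1, 2), c(4, 6, 5)))
  qn2 <- quantile_normalize(m2)
  expect_equal(unname(unclass(qn2)[, 1]), c(4.5, 2.5, 3.5))
  expect_equal(unname(unclass(qn2)[, 2]), c(2.5, 4.5, 3.5))

  # identical columns are a fixed point
  m3 <- make_expr(cbind(c(1, 5, 9), c(1, 5, 9)))
  expect_equal(unclass(quantile_normalize(m3)), unclass(m3),
               ignore_attr = TRUE)
  expect_error(quantile_normalize(make_expr(matrix(1:3, 3, 1))),
               "at least 2 samples")
})

test_that("quantile normalization is idempotent, rank-preserving, and
           equalizes column marginals", {
  set.seed(5)
  m <- make_expr(matrix(rnorm(400, 8, 2), 100, 4))
  qn <- quantile_normalize(m)
  for (j in 2:4)
    expect_equal(unname(sort(unclass(qn)[, j])),
                 unname(sort(unclass(qn)[, 1])))
  for (j in 1:4)
    expect_identical(order(unclass(qn)[, j]), order(unclass(m)[, j]))
  expect_equal(unclass(quantile_normalize(qn)), unclass(qn),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("ties receive the mean of the reference values at tied ranks", {
  m <- make_expr(cbind(c(1, 1, 3), c(2, 4, 6)))
  qn <- quantile_normalize(m)
  ref <- (sort(c(1, 1, 3)) + sort(c(2, 4, 6))) / 2   # 1.5, 2.5, 4.5
  expect_equal(unname(unclass(qn)[, 1]),
               c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
})
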