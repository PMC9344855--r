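stat_tbl <- function(E, ids = sprintf("S%02d", seq_along(E))) {
  tibble::tibble(subject_id = ids, eqmi_star = E, marker_set = "M1;M2")
}

test_that("linear Wald test recovers an exact linear signal", {
  E <- seq(0, 1, length.out = 20)
  oc <- outcome_spec(sprintf("S%02d", 1:20), 2 * E, type = "continuous")
  # Y = 2E exactly: the fit is perfect, which summary.lm warns about
  res <- suppressWarnings(linear_association(stat_tbl(E), oc))
  expect_equal(res$coefficient, 2, tolerance = 1e-10)
  expect_lt(res$p_value, 1e-12)
  expect_identical(res$test_tag, "wald")
  td <- tidy(res)
  expect_equal(td$estimate, 2, tolerance = 1e-10)
  expect_identical(glance(res)$outcome_type, "continuous")
})

test_that("constant statistics raise a collinearity error", {
  oc <- outcome_spec(sprintf("S%02d", 1:10), rnorm(10), type = "continuous")
  expect_error(linear_association(stat_tbl(rep(0.4, 10)), oc),
               class = "coexmi_collinearity_error")
})

test_that("polynomial terms are tested jointly and adjustment covariates enter", {
  withr::with_seed(21, {
    E <- runif(60)
    C <- cbind(age = rnorm(60))
    y <- 3 * (E - 0.5)^2 + 0.2 * C[, 1] + rnorm(60, 0, 0.05)
    oc <- outcome_spec(sprintf("S%02d", 1:60), y, type = "continuous",
                       covariates = C)
    lin <- linear_association(stat_tbl(E), oc, poly_degree = 1)
    quad <- linear_association(stat_tbl(E), oc, poly_degree = 2)
    # a symmetric quadratic signal is invisible to the linear term alone
    expect_lt(quad$p_value, 1e-6)
    expect_lt(quad$p_value, lin$p_value)
  })
})

test_that("logistic association is calibrated under the null and flags separation", {
  withr::with_seed(22, {
    ok <- replicate(100, {
      E <- runif(40)
      oc <- outcome_spec(sprintf("S%02d", 1:40), rbinom(40, 1, 0.5),
                         type = "binary")
      logistic_association(stat_tbl(E), oc)$p_value > 0.05
    })
    expect_gte(mean(ok), 0.9)
  })
  E <- seq(0, 1, length.out = 20)
  oc <- outcome_spec(sprintf("S%02d", 1:20), as.numeric(E > 0.5),
                     type = "binary")
  expect_warning(res <- logistic_association(stat_tbl(E), oc), "separation")
  expect_identical(res$flag, "separation")
  expect_true(is.na(res$p_value))
  one_class <- outcome_spec(sprintf("S%02d", 1:20), rep(1, 20),
                            type = "binary")
  expect_error(logistic_association(stat_tbl(E), one_class),
               class = "coexmi_precondition_error")
})

test_that("Cox gamma matches a grid-search Breslow partial-likelihood oracle", {
  # tie-free, non-separable: the statistic is not concordant with the event
  # order, so the partial likelihood has an interior maximum
  time <- c(1, 2, 3, 4, 5)
  event <- c(1, 1, 0, 1, 1)
  E <- c(0.2, 0.9, 0.5, 0.8, 0.1)
  oc <- outcome_spec(sprintf("S%02d", 1:5), time, type = "survival",
                     event = event)
  res <- cox_lrt_association(stat_tbl(E), oc, ties = "breslow")
  gamma_ref <- grid_search_gamma(time, event, E)
  expect_equal(res$coefficient, gamma_ref, tolerance = 1e-4)
  expect_equal(res$hazard_ratio, exp(res$coefficient), tolerance = 1e-12)
  expect_identical(res$test_tag, "lrt")
})

test_that("Cox LRT p-values are invariant to affine rescaling of the statistic", {
  withr::with_seed(23, {
    E <- runif(50)
    time <- rexp(50, exp(E))
    event <- rbinom(50, 1, 0.8)
    oc <- outcome_spec(sprintf("S%02d", 1:50), time, type = "survival",
                       event = event)
    p1 <- cox_lrt_association(stat_tbl(E), oc)$p_value
    p2 <- cox_lrt_association(stat_tbl(3.7 * E + 0.2), oc)$p_value
    expect_equal(p1, p2, tolerance = 1e-8)
  })
})

test_that("degenerate survival inputs are refused or flagged", {
  oc0 <- outcome_spec(sprintf("S%02d", 1:5), 1:5, type = "survival",
                      event = c(1, 0, 0, 0, 0))
  expect_error(cox_lrt_association(stat_tbl(runif(5)), oc0),
               class = "coexmi_precondition_error")
  oc <- outcome_spec(sprintf("S%02d", 1:5), 1:5, type = "survival",
                     event = c(1, 1, 0, 1, 1))
  expect_warning(res <- cox_lrt_association(stat_tbl(rep(0.3, 5)), oc),
                 "constant")
  expect_identical(res$flag, "degenerate")
})

test_that("the combination scan enumerates subsets with per-size Bonferroni levels", {
  tbl <- toy_cells(n_per_subject = 30, subjects = sprintf("S%02d", 1:8),
                   seed = 24, p = 4)
  withr::with_seed(24, {
    oc <- outcome_spec(sprintf("S%02d", 1:8), rnorm(8), type = "continuous")
  })
  scan <- suppressWarnings(
    combination_scan(tbl, oc, bw_method = "silverman"))
  expect_equal(nrow(scan), 2^4 - 4 - 1)
  expect_equal(as.vector(table(scan$size)), c(6, 4, 1))
  # within each size, bonferroni_alpha * count == alpha exactly
  by_size <- split(scan, scan$size)
  for (s in by_size) {
    expect_equal(unique(s$bonferroni_alpha) * nrow(s), 0.05)
  }
  # closed-form subset counts for p = 2 (single pair at level alpha)
  tbl2 <- toy_cells(n_per_subject = 30, subjects = sprintf("S%02d", 1:8),
                    seed = 25, p = 2)
  scan2 <- combination_scan(tbl2, oc, bw_method = "silverman")
  expect_equal(nrow(scan2), 1)
  expect_equal(scan2$bonferroni_alpha, 0.05)
  expect_error(combination_scan(toy_cells(p = 2), oc, use_markers = "M1"),
               class = "coexmi_precondition_error")
})
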