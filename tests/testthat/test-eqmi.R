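test_that("the Gaussian kernel matches its closed form", {
  expect_equal(gaussian_kernel(0, 1), 1 / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(gaussian_kernel(0, sqrt(2)), 1 / (sqrt(2 * pi) * sqrt(2)),
               tolerance = 1e-12)
  expect_equal(gaussian_kernel(2, 1), exp(-2) / sqrt(2 * pi),
               tolerance = 1e-12)
  expect_error(gaussian_kernel(1, 0), class = "coexmi_domain_error")
  expect_error(gaussian_kernel(1, -1), class = "coexmi_domain_error")
})

test_that("pairwise kernel matrices carry the sqrt(2)-widened kernel", {
  # single point: G_{sqrt(2)}(0)
  expect_equal(pairwise_kernel_matrix(0.5, 1),
               matrix(1 / (2 * sqrt(pi))), tolerance = 1e-12)
  # identical points: constant matrix equal to the diagonal
  K0 <- pairwise_kernel_matrix(c(0, 0), 0.3)
  expect_true(all(K0 == K0[1, 1]))
  expect_equal(K0[1, 1], 1 / (2 * 0.3 * sqrt(pi)), tolerance = 1e-12)
  # general case: element-wise brute-force evaluation
  x <- c(0, 0.1, 0.3)
  K <- pairwise_kernel_matrix(x, 0.1)
  ref <- outer(x, x, function(a, b) oracle_gauss(a - b, sqrt(2) * 0.1))
  expect_equal(K, ref, tolerance = 1e-14)
  expect_equal(K, t(K))
  expect_error(pairwise_kernel_matrix(c(0, NA), 0.1),
               class = "coexmi_domain_error")
})

test_that("the efficient V-term estimator equals naive triple-loop summation", {
  v <- estimate_v_terms(fixed5(), bw_fixed(0.1, 2))
  ref <- naive_v_terms(fixed5(), c(0.1, 0.1))
  expect_lt(max_rel_err(v, ref), 1e-12)
  # and the derived statistics inherit the agreement
  expect_equal(eqmi_star(v),
               (ref$V_J - 2 * ref$V_C + ref$V_M) / (ref$V_J + ref$V_M),
               tolerance = 1e-12)
  expect_equal(eqmi_raw(v), ref$V_J - 2 * ref$V_C + ref$V_M,
               tolerance = 1e-12)

  # random instances with unequal bandwidths, p in {2, 3}
  withr::with_seed(11, {
    for (rep in 1:10) {
      p <- sample(2:3, 1)
      n <- sample(3:40, 1)
      x <- matrix(runif(n * p), n, p)
      h <- runif(p, 0.02, 0.3)
      expect_lt(max_rel_err(estimate_v_terms(x, bw_fixed(h, p)),
                            naive_v_terms(x, h)), 1e-12)
    }
  })
})

test_that("a single cell degenerates to zero mutual information", {
  h <- c(0.1, 0.2, 0.3)
  v <- estimate_v_terms(matrix(c(0.2, 0.5, 0.7), 1, 3), bw_fixed(h, 3))
  g0 <- prod(1 / (2 * h * sqrt(pi)))
  expect_equal(v$V_J, g0, tolerance = 1e-12)
  expect_equal(v$V_C, g0, tolerance = 1e-12)
  expect_equal(v$V_M, g0, tolerance = 1e-12)
  expect_equal(eqmi_raw(v), 0, tolerance = 1e-20)
  expect_error(estimate_v_terms(matrix(numeric(0), 0, 2), bw_fixed(0.1, 2)),
               class = "coexmi_empty_error")
})

test_that("EQMI*, raw EQMI and CSQMI follow their defining arithmetic", {
  v <- list(V_J = 2, V_C = 0, V_M = 3)
  expect_equal(eqmi_star(v), 1)
  expect_equal(eqmi_raw(v), 5)
  ind <- list(V_J = 0.7, V_C = 0.7, V_M = 0.7)  # f12 = f1 f2
  expect_equal(eqmi_star(ind), 0)
  expect_equal(eqmi_raw(ind), 0)
  expect_equal(csqmi(ind), 0)
  expect_equal(csqmi(list(V_J = 4, V_C = 2, V_M = 4)), log(4))
  expect_warning(inf <- csqmi(v), "infinite")
  expect_identical(inf, Inf)
  expect_error(eqmi_star(list(V_J = 0, V_C = 0, V_M = 0)),
               class = "coexmi_degenerate_error")
})

test_that("the quadrature route agrees with both the estimator and the loop oracle", {
  # exact plug-in identity at tiny n (two independent oracles agree)
  q5 <- vterms_quadrature(fixed5(), bw_fixed(0.1, 2))
  expect_lt(max_rel_err(q5, naive_v_terms(fixed5(), c(0.1, 0.1))), 1e-6)
  expect_gte(q5$V_J - 2 * q5$V_C + q5$V_M, 0)

  withr::with_seed(12, {
    x <- matrix(runif(400), 200, 2)
    bw <- bw_plugin(x)
    expect_lt(max_rel_err(estimate_v_terms(x, bw), vterms_quadrature(x, bw)),
              1e-4)
  })
  expect_error(vterms_quadrature(matrix(runif(30), 10, 3), bw_fixed(0.1, 3)),
               class = "coexmi_precondition_error")
})

test_that("per-subject EQMI* is deterministic, order-invariant and ranks dependence", {
  # two identical subjects, one subject with X2 == X1, one independent
  withr::with_seed(13, {
    xa <- runif(300); ya <- runif(300)
    xd <- runif(500); xi <- runif(500); yi <- runif(500)
  })
  df <- rbind(
    data.frame(subject_id = "dup1", M1 = xa, M2 = ya),
    data.frame(subject_id = "dup2", M1 = xa, M2 = ya),
    data.frame(subject_id = "dep", M1 = xd, M2 = xd),
    data.frame(subject_id = "indep", M1 = xi, M2 = yi))
  tbl <- as_cell_table(df, markers = c("M1", "M2"))
  res <- compute_eqmi(tbl, bw_method = bw_fixed(0.05, 2))
  expect_equal(res$eqmi_star[res$subject_id == "dup1"],
               res$eqmi_star[res$subject_id == "dup2"], tolerance = 1e-15)
  expect_gt(res$eqmi_star[res$subject_id == "dep"],
            res$eqmi_star[res$subject_id == "indep"])

  # permuting cells within a subject leaves the sums unchanged
  perm <- sample(nrow(df))
  res2 <- compute_eqmi(as_cell_table(df[perm, ], markers = c("M1", "M2")),
                       bw_method = bw_fixed(0.05, 2))
  expect_equal(sort(res2$eqmi_star), sort(res$eqmi_star), tolerance = 1e-12)
})

test_that("degenerate subjects are excluded with a warning, not silently", {
  df <- rbind(data.frame(subject_id = "ok", M1 = runif(50), M2 = runif(50)),
              data.frame(subject_id = "flat", M1 = rep(0.5, 50),
                         M2 = runif(50)))
  tbl <- as_cell_table(df, markers = c("M1", "M2"))
  expect_warning(res <- compute_eqmi(tbl, bw_method = "silverman"), "flat")
  expect_equal(res$subject_id, "ok")
  expect_error(suppressWarnings(
    compute_eqmi(as_cell_table(
      data.frame(subject_id = "flat", M1 = rep(0.5, 5), M2 = runif(5)),
      markers = c("M1", "M2")), bw_method = "silverman")),
    class = "coexmi_empty_error")
})

test_that("absolute Pearson correlation behaves as the linear comparator", {
  withr::with_seed(14, {
    x <- runif(100)
    df <- rbind(data.frame(subject_id = "lin", M1 = x, M2 = 3 * x + 1),
                data.frame(subject_id = "par", M1 = runif(5000, 0, 0.1),
                           M2 = NA))
    df$M2[df$subject_id == "par"] <-
      (df$M1[df$subject_id == "par"] - 0.05)^2 +
      runif(5000, 0, 0.0005)
    tbl <- as_cell_table(df, markers = c("M1", "M2"))
    res <- abs_pearson_coexpression(tbl)
    expect_equal(res$abs_pearson[res$subject_id == "lin"], 1,
                 tolerance = 1e-12)
    # parabola symmetric about 0.05: population correlation is 0
    expect_lt(res$abs_pearson[res$subject_id == "par"], 0.05)
  })
  tiny <- as_cell_table(data.frame(subject_id = "t", M1 = c(1, 2),
                                   M2 = c(2, 1)), markers = c("M1", "M2"))
  expect_error(abs_pearson_coexpression(tiny),
               class = "coexmi_precondition_error")
})
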