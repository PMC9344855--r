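#' Define a simulation scenario
#'
#' Configuration for the cell-level intensity generators and the power
#' engine.  Two groups of subjects are simulated — one with high marker
#' co-expression, one with low/none — and a continuous outcome
#' `Y_j = I_j beta + eps_j`, `eps_j ~ N(0, sigma^2)`, is attached to the
#' group indicator so the methods' power to recover the group signal can be
#' compared.
#'
#' @param scenario One of `"copula2"` (bivariate Gaussian copula with Beta
#'   marginals; linear dependence), `"squared"` and `"circular"`
#'   (deterministic nonlinear dependences on \[0, 0.1\]), or
#'   `"copula3_caseA"`, `"copula3_caseB"`, `"copula3_caseC"` (trivariate
#'   copula with progressively fewer correlated pairs).
#' @param N Number of subjects.
#' @param ncells Cells per subject.
#' @param beta Outcome effect size (group mean difference).
#' @param sigma Outcome noise standard deviation (default 1).
#' @param outcome_reps Outcome vectors drawn per intensity dataset
#'   (default 100).
#' @param dataset_repeats Intensity datasets per power estimate
#'   (default 20).
#' @param alpha Test level (default 0.05).
#' @param seed Integer seed; every generator is a deterministic function of
#'   it.
#' @param group_prob Probability that a subject falls in the
#'   high-co-expression group (default 0.5).
#' @param marginal_params List of Beta `(shape1, shape2)` pairs for the
#'   copula marginals; defaults `(1.5, 170)`, `(1.6, 35)`, `(1.6, 35)`,
#'   matching the skewed intensity profiles of functional markers in mIHC
#'   data.
#' @param s_dist For the circular scenario: distribution of the semicircle
#'   sign `s`, `"uniform"` (U(-1, 1), default) or `"rademacher"` (+/-1).
#' @param bw_method Bandwidth selection used when the power engine computes
#'   EQMI* (default `"plugin"`).
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(scenario = c("copula2", "squared", "circular",
                                      "copula3_caseA", "copula3_caseB",
                                      "copula3_caseC"),
                         N = 50, ncells = 1000, beta = 1, sigma = 1,
                         outcome_reps = 100, dataset_repeats = 20,
                         alpha = 0.05, seed = 1, group_prob = 0.5,
                         marginal_params = list(c(1.5, 170), c(1.6, 35),
                                                c(1.6, 35)),
                         s_dist = c("uniform", "rademacher"),
                         bw_method = "plugin") {
  scenario <- match.arg(scenario)
  stopifnot(N >= 4, ncells >= 10, group_prob > 0, group_prob < 1,
            outcome_reps >= 1, dataset_repeats >= 1, sigma >= 0)
  structure(list(scenario = scenario, N = N, ncells = ncells, beta = beta,
                 sigma = sigma, outcome_reps = outcome_reps,
                 dataset_repeats = dataset_repeats, alpha = alpha,
                 seed = as.integer(seed), group_prob = group_prob,
                 marginal_params = marginal_params,
                 s_dist = match.arg(s_dist), bw_method = bw_method),
            class = "sim_scenario")
}

# draw n correlated standard-normal pairs/triples and push them through
# Phi then the Beta quantile function
beta_copula_draw <- function(n, R, shapes) {
  p <- nrow(R)
  L <- chol(R)
  U <- matrix(rnorm(n * p), n, p) %*% L
  X <- matrix(0, n, p)
  for (k in seq_len(p)) {
    X[, k] <- qbeta(pnorm(U[, k]), shapes[[k]][1], shapes[[k]][2])
  }
  X
}

#' Gaussian-copula pair with Beta marginals at a fixed correlation
#'
#' Building block of the copula scenarios, exported so the dependence of
#' EQMI* on the latent correlation can be studied directly.
#'
#' @param n Number of cells.
#' @param rho Latent normal correlation in \[-1, 1\].
#' @param shapes List of two Beta `(shape1, shape2)` pairs.
#' @return n x 2 matrix of intensities in (0, 1).
#' @export
r_copula_pair <- function(n, rho,
                          shapes = list(c(1.5, 170), c(1.6, 35))) {
  beta_copula_draw(n, matrix(c(1, rho, rho, 1), 2), shapes)
}

finish_sim <- function(intensity_rows, groups, mk) {
  cells <- new_cell_tbl(dplyr::bind_rows(intensity_rows), mk)
  list(cells = cells,
       groups = tibble(subject_id = names(groups),
                       group = unname(groups)))
}

#' Simulate two linearly co-expressed markers via a Gaussian copula
#'
#' Group 0 (high co-expression) draws a per-subject latent correlation
#' `rho_j ~ U(0.75, 0.9)`; group 1 draws `rho_j ~ U(0, 0.15)`.  Cell
#' intensities are the Beta-quantile transform of correlated normals, so
#' the marginals match the scenario's Beta parameters exactly.
#'
#' @param scn A [sim_scenario()] with `scenario = "copula2"`.
#' @return List with `cells` (a `cell_tbl`, markers `M1`, `M2`) and
#'   `groups` (tibble `subject_id`, `group`; group 0 = high
#'   co-expression).
#' @export
simulate_copula2 <- function(scn) {
  stopifnot(scn$scenario == "copula2")
  withr::with_seed(scn$seed, {
    ids <- sprintf("S%03d", seq_len(scn$N))
    groups <- setNames(rbinom(scn$N, 1, 1 - scn$group_prob), ids)
    rows <- lapply(ids, function(sj) {
      rho <- if (groups[[sj]] == 0) runif(1, 0.75, 0.9) else runif(1, 0, 0.15)
      X <- r_copula_pair(scn$ncells, rho, scn$marginal_params[1:2])
      tibble(subject_id = sj, M1 = X[, 1], M2 = X[, 2])
    })
    finish_sim(rows, groups, c("M1", "M2"))
  })
}

#' Simulate a squared (parabolic) marker dependence
#'
#' Group 0: `X1 ~ U(0, 0.1)`, `X2 = (X1 - 0.05)^2 + e`,
#' `e ~ U(0, 0.0005)` — a deterministic nonlinear dependence whose
#' population Pearson correlation is zero by symmetry.  Group 1: both
#' markers independent U(0, 0.1).
#'
#' @param scn A [sim_scenario()] with `scenario = "squared"`.
#' @inherit simulate_copula2 return
#' @export
simulate_squared <- function(scn) {
  stopifnot(scn$scenario == "squared")
  withr::with_seed(scn$seed, {
    ids <- sprintf("S%03d", seq_len(scn$N))
    groups <- setNames(rbinom(scn$N, 1, 1 - scn$group_prob), ids)
    rows <- lapply(ids, function(sj) {
      x1 <- runif(scn$ncells, 0, 0.1)
      x2 <- if (groups[[sj]] == 0) {
        (x1 - 0.05)^2 + runif(scn$ncells, 0, 0.0005)
      } else {
        runif(scn$ncells, 0, 0.1)
      }
      tibble(subject_id = sj, M1 = x1, M2 = x2)
    })
    finish_sim(rows, groups, c("M1", "M2"))
  })
}

#' Simulate a circular marker dependence
#'
#' Group 0: `X1 ~ U(0, 0.1)`,
#' `X2 = 0.05 + s * sqrt(0.05^2 - (X1 - 0.05)^2) + e` with
#' `s ~ U(-1, 1)` (or Rademacher +/-1) and `e ~ U(0, 0.0005)`: the cells
#' fall inside/on a circle, again with zero linear correlation.  Group 1:
#' independent U(0, 0.1) pair.
#'
#' @param scn A [sim_scenario()] with `scenario = "circular"`.
#' @inherit simulate_copula2 return
#' @export
simulate_circular <- function(scn) {
  stopifnot(scn$scenario == "circular")
  withr::with_seed(scn$seed, {
    ids <- sprintf("S%03d", seq_len(scn$N))
    groups <- setNames(rbinom(scn$N, 1, 1 - scn$group_prob), ids)
    rows <- lapply(ids, function(sj) {
      x1 <- runif(scn$ncells, 0, 0.1)
      x2 <- if (groups[[sj]] == 0) {
        s <- if (scn$s_dist == "uniform") runif(scn$ncells, -1, 1)
             else sample(c(-1, 1), scn$ncells, replace = TRUE)
        0.05 + s * sqrt(pmax(0.05^2 - (x1 - 0.05)^2, 0)) +
          runif(scn$ncells, 0, 0.0005)
      } else {
        runif(scn$ncells, 0, 0.1)
      }
      tibble(subject_id = sj, M1 = x1, M2 = x2)
    })
    finish_sim(rows, groups, c("M1", "M2"))
  })
}

#' Simulate three markers with case-dependent linear co-expression
#'
#' Trivariate Gaussian copula with Beta marginals.  High-co-expression
#' subjects draw their active latent correlations from U(0.4, 0.6), the
#' rest from U(0.2, 0.4); the cases differ in which pairs are active:
#' case A all three, case B `rho_13 = 0`, case C only `rho_12` nonzero.
#' Correlation matrices failing positive definiteness are redrawn (at most
#' 100 times per subject).
#'
#' @param scn A [sim_scenario()] with a `copula3_*` scenario.
#' @return As [simulate_copula2()], with markers `M1`, `M2`, `M3`.
#' @export
simulate_copula3 <- function(scn) {
  stopifnot(grepl("^copula3_case[ABC]$", scn$scenario))
  case <- sub("copula3_case", "", scn$scenario)
  withr::with_seed(scn$seed, {
    ids <- sprintf("S%03d", seq_len(scn$N))
    groups <- setNames(rbinom(scn$N, 1, 1 - scn$group_prob), ids)
    rows <- lapply(ids, function(sj) {
      lo <- if (groups[[sj]] == 0) 0.4 else 0.2
      hi <- if (groups[[sj]] == 0) 0.6 else 0.4
      R <- NULL
      for (try in seq_len(100)) {
        r12 <- runif(1, lo, hi)
        r23 <- if (case %in% c("A", "B")) runif(1, lo, hi) else 0
        r13 <- if (case == "A") runif(1, lo, hi) else 0
        cand <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3)
        if (min(eigen(cand, symmetric = TRUE,
                      only.values = TRUE)$values) > 1e-8) {
          R <- cand
          break
        }
        inform("coexmi: redrew a non-positive-definite correlation matrix.")
      }
      if (is.null(R)) {
        abort("Could not draw a positive-definite correlation matrix in 100 tries.",
              class = "coexmi_scenario_error")
      }
      X <- beta_copula_draw(scn$ncells, R, scn$marginal_params[1:3])
      tibble(subject_id = sj, M1 = X[, 1], M2 = X[, 2], M3 = X[, 3])
    })
    finish_sim(rows, groups, c("M1", "M2", "M3"))
  })
}

#' Dispatch the generator named by a scenario
#' @param scn A [sim_scenario()].
#' @inherit simulate_copula2 return
#' @export
simulate_scenario <- function(scn) {
  switch(scn$scenario,
         copula2 = simulate_copula2(scn),
         squared = simulate_squared(scn),
         circular = simulate_circular(scn),
         simulate_copula3(scn))
}

#' Draw repeated continuous outcomes for fixed intensity data
#'
#' `Y_j = I_j beta + eps_j`, `eps_j ~ N(0, sigma^2)`; the intensity data
#' stay fixed while the outcome vector is redrawn `outcome_reps` times,
#' which is how empirical power is estimated per intensity dataset.
#'
#' @param groups Tibble `subject_id`, `group` (0 = high co-expression) from
#'   a generator.  The group effect enters as `beta` for group 0, i.e. the
#'   high-co-expression group carries the outcome shift.
#' @param beta Effect size.
#' @param sigma Noise sd.
#' @param outcome_reps Number of outcome vectors.
#' @param seed Integer seed.
#' @return List of [outcome_spec()] objects (`type = "continuous"`).
#' @export
simulate_outcomes <- function(groups, beta, sigma, outcome_reps = 100,
                              seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(outcome_reps), function(r) {
      y <- (groups$group == 0) * beta + rnorm(nrow(groups), 0, sigma)
      outcome_spec(groups$subject_id, y, type = "continuous")
    })
  })
}
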