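#' Empirical power comparison of co-expression methods
#'
#' For each of `dataset_repeats` intensity datasets: generate cells once,
#' compute each method's per-subject statistic once, then for each effect
#' size in `beta_grid` draw `outcome_reps` outcome vectors and record
#' whether the linear Wald test of outcome on statistic rejects at level
#' `alpha`.  Power is the rejection fraction pooled over outcome draws and
#' dataset repeats; its Monte-Carlo standard error is reported.  All
#' methods see identical outcome draws, so method differences are not
#' inflated by outcome noise.
#'
#' Methods: `"eqmi"` (EQMI* per subject), `"corr"` (absolute Pearson
#' correlation; two-marker scenarios only, skipped with a warning
#' otherwise), `"median_threshold"`, `"threshold1"`, `"threshold2"` (the
#' traditional pipeline at pooled quantiles 0.5, 0.95, 0.99: pairwise
#' positivity profiles, Ward clustering at M = 2, cluster label as the
#' tested statistic).  A thresholding repeat whose clustering is degenerate
#' (all profiles identical) contributes non-rejections, mirroring a method
#' failure in practice.
#'
#' @param scn A [sim_scenario()]; `scn$beta` is ignored in favour of
#'   `beta_grid`.
#' @param methods Subset of the method tags above.
#' @param beta_grid Effect sizes to sweep (default `c(0, 0.5, 1, 1.5, 2)`).
#' @return A tibble of class `power_table`: `scenario_tag`, `method_tag`,
#'   `N`, `ncells`, `beta`, `power`, `mc_se`.
#' @export
run_power_study <- function(scn,
                            methods = c("eqmi", "corr", "median_threshold",
                                        "threshold1", "threshold2"),
                            beta_grid = c(0, 0.5, 1, 1.5, 2)) {
  known <- c("eqmi", "corr", "median_threshold", "threshold1", "threshold2")
  bad <- setdiff(methods, known)
  if (length(bad)) {
    abort(paste0("Unknown method tag(s): ", paste(bad, collapse = ", ")),
          class = "coexmi_config_error")
  }
  qs <- c(median_threshold = 0.5, threshold1 = 0.95, threshold2 = 0.99)
  rejections <- list()  # method -> beta -> logical vector

  for (r in seq_len(scn$dataset_repeats)) {
    rep_seed <- scn$seed + 7919L * r
    scn_r <- scn
    scn_r$seed <- rep_seed
    sim <- simulate_scenario(scn_r)
    two_markers <- length(markers(sim$cells)) == 2

    stats_by_method <- list()
    for (m in methods) {
      stats_by_method[[m]] <- if (m == "eqmi") {
        res <- compute_eqmi(sim$cells, bw_method = scn$bw_method)
        tibble(subject_id = res$subject_id, stat = res$eqmi_star)
      } else if (m == "corr") {
        if (!two_markers) {
          warn("coexmi: 'corr' applies to two-marker scenarios only; skipped.")
          NULL
        } else {
          res <- abs_pearson_coexpression(sim$cells)
          tibble(subject_id = res$subject_id, stat = res$abs_pearson)
        }
      } else {
        tryCatch({
          th <- global_quantile_thresholds(sim$cells, qs[[m]])
          prof <- positivity_proportions(sim$cells, th, mode = "pairwise")
          cl <- cluster_subjects(prof, M = 2)
          tibble(subject_id = cl$subject_id, stat = as.numeric(cl$cluster))
        }, error = function(e) {
          warn(sprintf("coexmi: %s failed on repeat %d (%s); counted as non-rejections.",
                       m, r, conditionMessage(e)))
          tibble(subject_id = sim$groups$subject_id, stat = NA_real_)
        })
      }
    }

    outcomes_by_beta <- lapply(beta_grid, function(b) {
      simulate_outcomes(sim$groups, beta = b, sigma = scn$sigma,
                        outcome_reps = scn$outcome_reps,
                        seed = rep_seed + 13L)
    })
    names(outcomes_by_beta) <- as.character(beta_grid)

    for (m in methods) {
      st <- stats_by_method[[m]]
      if (is.null(st)) next
      for (b in as.character(beta_grid)) {
        rej <- vapply(outcomes_by_beta[[b]], function(oc) {
          if (anyNA(st$stat) || sd(st$stat) == 0) return(FALSE)
          res <- tryCatch(
            linear_association(st, oc, value_col = "stat"),
            error = function(e) NULL)
          !is.null(res) && !is.na(res$p_value) && res$p_value < scn$alpha
        }, logical(1))
        rejections[[m]][[b]] <- c(rejections[[m]][[b]], rej)
      }
    }
  }

  rows <- list()
  for (m in names(rejections)) {
    for (b in names(rejections[[m]])) {
      rej <- rejections[[m]][[b]]
      pw <- mean(rej)
      rows[[length(rows) + 1]] <- tibble(
        scenario_tag = scn$scenario, method_tag = m, N = scn$N,
        ncells = scn$ncells, beta = as.numeric(b), power = pw,
        mc_se = sqrt(pw * (1 - pw) / length(rej)))
    }
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$method_tag, .data$beta)
  class(out) <- c("power_table", class(out))
  out
}

#' Plot a power table
#'
#' Power against effect size, one curve per method, faceted by scenario
#' when several are bound together.
#'
#' @param object A `power_table` from [run_power_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$beta, y = .data$power,
                               colour = .data$method_tag)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$power - .data$mc_se, 0),
                                        ymax = pmin(.data$power + .data$mc_se, 1)),
                           width = 0.02) +
    ggplot2::facet_wrap(~ scenario_tag) +
    ggplot2::labs(x = "effect size (beta)", y = "empirical power",
                  colour = "method") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
}

#' @export
plot.power_table <- function(x, ...) print(autoplot(x, ...))
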