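#' Gaussian kernel
#'
#' `G_h(d) = (2*pi)^(-1/2) h^(-1) exp(-d^2 / (2 h^2))`, vectorized over `d`.
#'
#' @param d Numeric difference(s).
#' @param h Positive bandwidth.
#' @return Kernel value(s), non-negative.
#' @export
gaussian_kernel <- function(d, h) {
  if (!is.numeric(h) || length(h) != 1 || !is.finite(h) || h <= 0) {
    abort("`h` must be a single positive finite number.",
          class = "coexmi_domain_error")
  }
  exp(-d^2 / (2 * h^2)) / (h * sqrt(2 * pi))
}

#' Pairwise convolution-kernel matrix for one marker
#'
#' Entry (i, s) is `G_{sqrt(2) h}(x_i - x_s)`: the exact value of
#' `integral G_h(t - x_i) G_h(t - x_s) dt`, i.e. the cross-product of two
#' kernel bumps of the marker's density estimate.  These matrices are the
#' whole computational substrate of the V-term estimators — no
#' p-dimensional grid is ever built.
#'
#' @param x Length-n numeric vector of one marker's intensities.
#' @param h Positive per-marker bandwidth (the KDE bandwidth, before the
#'   `sqrt(2)` convolution widening).
#' @return n x n symmetric matrix with constant diagonal
#'   `1 / (2 h sqrt(pi))`.
#' @export
pairwise_kernel_matrix <- function(x, h) {
  if (!all(is.finite(x))) {
    abort("Marker values must be finite.", class = "coexmi_domain_error")
  }
  gaussian_kernel(outer(x, x, "-"), sqrt(2) * h)
}

#' Estimate the V-terms of quadratic mutual information
#'
#' For one subject's n x p intensity matrix and per-marker bandwidths, the
#' three integrals underlying EQMI/EQMI*/CSQMI are computed in closed form
#' from the per-marker pairwise kernel matrices `K_k`:
#' \itemize{
#'   \item `V_J = n^-2 sum_i sum_s prod_k K_k(i, s)`
#'     (`= integral of fhat_joint^2`),
#'   \item `V_C = n^-1 sum_i prod_k rowmean_k(i)`
#'     (`= integral of fhat_joint * prod fhat_k`),
#'   \item `V_M = prod_k mean(K_k)` (`= prod_k integral of fhat_k^2`),
#' }
#' where `fhat` are Gaussian product-kernel density estimates with marker
#' bandwidths `h_k` (allowed to differ across markers).  Cost is O(n^2 p)
#' time and one n x n matrix of memory at a time.
#'
#' @param x n x p numeric matrix (cells x markers) for one subject.
#' @param bw A `bandwidth_set` (or numeric vector of fixed bandwidths).
#' @return An object of class `vterms`: list with `V_J`, `V_C`, `V_M`.
#' @export
estimate_v_terms <- function(x, bw) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n == 0) abort("No cells supplied.", class = "coexmi_empty_error")
  if (p < 2) abort("Need at least 2 markers.",
                   class = "coexmi_precondition_error")
  if (is.numeric(bw)) bw <- bw_fixed(bw, p)
  h <- rep_len(bw$h, p)

  prod_mat <- NULL      # elementwise product over markers of K_k
  rowmean_prod <- rep(1, n)
  vm <- 1
  for (k in seq_len(p)) {
    K <- pairwise_kernel_matrix(x[, k], h[k])
    prod_mat <- if (is.null(prod_mat)) K else prod_mat * K
    rowmean_prod <- rowmean_prod * rowMeans(K)
    vm <- vm * mean(K)
  }
  structure(list(V_J = mean(prod_mat), V_C = mean(rowmean_prod), V_M = vm),
            class = "vterms")
}

#' @export
print.vterms <- function(x, ...) {
  cat(sprintf("<vterms> V_J = %.6g, V_C = %.6g, V_M = %.6g\n",
              x$V_J, x$V_C, x$V_M))
  invisible(x)
}

#' Quadratic mutual information statistics from V-terms
#'
#' `eqmi_raw()` is the Euclidean quadratic mutual information
#' `V_J - 2 V_C + V_M` (the integrated squared difference between the joint
#' density and the product of marginals; 0 iff the markers are independent).
#' `eqmi_star()` standardizes it by `V_J + V_M`, which bounds it in
#' \[0, 1\] and makes it comparable across subjects.  `csqmi()` is the
#' Cauchy-Schwarz variant `log(V_J V_M / V_C^2)`.
#'
#' @param v A `vterms` object (or a list with `V_J`, `V_C`, `V_M`).
#' @return A single number.
#' @name qmi_statistics
NULL

#' @rdname qmi_statistics
#' @export
eqmi_raw <- function(v) v$V_J - 2 * v$V_C + v$V_M

#' @rdname qmi_statistics
#' @export
eqmi_star <- function(v) {
  denom <- v$V_J + v$V_M
  if (denom <= 0) {
    abort("V_J + V_M must be positive.", class = "coexmi_degenerate_error")
  }
  e <- eqmi_raw(v) / denom
  eps <- 1e-10
  if (e < -eps || e > 1 + eps) {
    abort(sprintf("EQMI* = %g outside [0, 1] beyond numerical slack.", e),
          class = "coexmi_domain_error")
  }
  min(max(e, 0), 1)
}

#' @rdname qmi_statistics
#' @export
csqmi <- function(v) {
  if (v$V_C <= 0) {
    warn("coexmi: V_C = 0; CSQMI is infinite.")
    return(Inf)
  }
  log(v$V_J * v$V_M / v$V_C^2)
}

#' Per-subject EQMI* for a cell table
#'
#' Computes the co-expression statistic of the selected markers for every
#' subject: bandwidths are selected per subject from that subject's own
#' cells (each subject has its own marker densities), then the V-terms and
#' EQMI*, raw EQMI and CSQMI are evaluated.  Subjects that cannot support
#' the computation (fewer than 2 cells, or a constant marker) are excluded
#' with a warning rather than failing the whole run.
#'
#' @param table A `cell_tbl` (values expected in \[0, 1\]; see
#'   [normalize_intensities()]).
#' @param use_markers Markers to include (default: all markers of `table`).
#' @param bw_method `"plugin"` (default), `"silverman"`, a numeric vector of
#'   fixed bandwidths, or a `bandwidth_set` applied to every subject.
#' @return A tibble with one row per retained subject: `subject_id`,
#'   `marker_set` (semicolon-joined), `eqmi_star`, `eqmi_raw`, `csqmi`,
#'   `n_cells`, `h_1` ... `h_p`, `bw_method`.
#' @export
#' @examples
#' tbl <- simulate_squared(sim_scenario("squared", N = 6, ncells = 200,
#'                                      seed = 1))$cells
#' compute_eqmi(tbl, bw_method = "silverman")
compute_eqmi <- function(table, use_markers = NULL, bw_method = "plugin") {
  mk <- use_markers %||% markers(table)
  if (length(mk) < 2) {
    abort("Need at least 2 markers.", class = "coexmi_precondition_error")
  }
  bad <- setdiff(mk, names(table))
  if (length(bad)) {
    abort(paste0("Unknown marker(s): ", paste(bad, collapse = ", ")),
          class = "coexmi_config_error")
  }
  subjects <- unique(table$subject_id)
  rows <- lapply(subjects, function(sj) {
    x <- subject_matrix(table, sj, mk)
    res <- tryCatch({
      bw <- select_bandwidths(x, bw_method)
      v <- estimate_v_terms(x, bw)
      list(v = v, bw = bw)
    }, coexmi_degenerate_marker_error = function(e) e,
       coexmi_precondition_error = function(e) e)
    if (inherits(res, "condition")) {
      warn(sprintf("coexmi: subject '%s' excluded: %s", sj,
                   conditionMessage(res)))
      return(NULL)
    }
    hs <- setNames(as.list(rep_len(res$bw$h, ncol(x))),
                   paste0("h_", seq_len(ncol(x))))
    dplyr::bind_cols(
      tibble(subject_id = sj,
             marker_set = paste(mk, collapse = ";"),
             eqmi_star = eqmi_star(res$v),
             eqmi_raw = eqmi_raw(res$v),
             csqmi = csqmi(res$v),
             n_cells = nrow(x)),
      as_tibble(hs),
      tibble(bw_method = res$bw$method_tag))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    abort("All subjects were excluded.", class = "coexmi_empty_error")
  }
  dplyr::bind_rows(rows)
}

#' Absolute Pearson correlation as a per-subject co-expression statistic
#'
#' The two-marker comparator: `E_j = |cor(X_1, X_2)|` within each subject.
#' Only linear dependence registers, which is exactly the weakness the
#' mutual-information statistic addresses.
#'
#' @param table A `cell_tbl`.
#' @param marker_pair Character vector of exactly two marker names.
#' @return Tibble with `subject_id`, `marker_set`, `abs_pearson`, `n_cells`;
#'   subjects with fewer than 3 cells or a constant marker are excluded with
#'   a warning.
#' @export
abs_pearson_coexpression <- function(table, marker_pair = markers(table)) {
  if (length(marker_pair) != 2) {
    abort("`marker_pair` must name exactly 2 markers.",
          class = "coexmi_precondition_error")
  }
  subjects <- unique(table$subject_id)
  rows <- lapply(subjects, function(sj) {
    x <- subject_matrix(table, sj, marker_pair)
    if (nrow(x) < 3) {
      abort(sprintf("Subject '%s' has fewer than 3 cells.", sj),
            class = "coexmi_precondition_error")
    }
    if (sd(x[, 1]) == 0 || sd(x[, 2]) == 0) {
      warn(sprintf("coexmi: subject '%s' excluded: constant marker.", sj))
      return(NULL)
    }
    tibble(subject_id = sj,
           marker_set = paste(marker_pair, collapse = ";"),
           abs_pearson = abs(cor(x[, 1], x[, 2])),
           n_cells = nrow(x))
  })
  dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
}
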