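#' Brute-force quadrature estimate of the V-terms (two markers)
#'
#' The naive route the efficient estimator exists to avoid: build the joint
#' and marginal Gaussian kernel density estimates on a dense 2-D grid and
#' integrate `fhat_12^2`, `fhat_12 * fhat_1 * fhat_2` and
#' `fhat_1^2 * fhat_2^2` numerically (trapezoid rule).  Kept as an
#' independent cross-check of [estimate_v_terms()]; restricted to p = 2 and
#' modest n because the grid cost is what makes this route infeasible in
#' general.
#'
#' @param x n x 2 numeric matrix.
#' @param bw A `bandwidth_set` or numeric length-2 bandwidths.
#' @param grid_points Grid resolution per axis (default 501, minimum 400).
#' @param padding Grid extension beyond \[0, 1\] in units of the largest
#'   bandwidth (default 6, to keep the truncated kernel tails below the
#'   quadrature tolerance).
#' @return A `vterms` object.
#' @export
vterms_quadrature <- function(x, bw, grid_points = 501, padding = 6) {
  x <- as.matrix(x)
  if (ncol(x) != 2) {
    abort("The quadrature route supports exactly 2 markers.",
          class = "coexmi_precondition_error")
  }
  if (nrow(x) > 2000) {
    abort("Quadrature route limited to n <= 2000.",
          class = "coexmi_precondition_error")
  }
  if (is.numeric(bw)) bw <- bw_fixed(bw, 2)
  h <- rep_len(bw$h, 2)
  pad <- padding * max(h)
  g <- seq(-pad, 1 + pad, length.out = max(grid_points, 400))
  dg <- g[2] - g[1]

  # g x n kernel evaluations per marker; marginal KDE = row mean
  A1 <- gaussian_kernel(outer(g, x[, 1], "-"), h[1])
  A2 <- gaussian_kernel(outer(g, x[, 2], "-"), h[2])
  f1 <- rowMeans(A1)
  f2 <- rowMeans(A2)
  # joint product-kernel KDE on the grid: f12(a,b) = mean_i A1[a,i] A2[b,i]
  f12 <- tcrossprod(A1, A2) / nrow(x)

  tw <- rep(1, length(g)); tw[c(1, length(g))] <- 0.5  # trapezoid weights
  w2 <- (tw %o% tw) * dg^2
  V_J <- sum(f12^2 * w2)
  V_C <- sum(f12 * (f1 %o% f2) * w2)
  V_M <- sum(f1^2 * tw * dg) * sum(f2^2 * tw * dg)
  structure(list(V_J = V_J, V_C = V_C, V_M = V_M), class = "vterms")
}
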