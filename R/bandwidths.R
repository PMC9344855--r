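#' Kernel bandwidth selection for the V-term estimators
#'
#' One bandwidth per marker (a "diagonal" selection: each marker's bandwidth
#' is chosen from its own univariate sample).  `bw_silverman()` applies
#' Silverman's rule of thumb, `h = 0.9 min(sd, IQR/1.34) n^(-1/5)`.
#' `bw_plugin()` applies the two-stage direct plug-in selector
#' ([stats::bw.SJ()] with `method = "dpi"`), falling back to Silverman's rule
#' with a warning if the plug-in computation fails, and switching to
#' Silverman outright when the number of markers exceeds `p_max_plugin`
#' (plug-in selection across many markers is disproportionately expensive).
#'
#' Bandwidths are floored at `1e-6` so near-duplicate intensities cannot
#' produce degenerate kernels.
#'
#' @param x An n x p numeric matrix of one subject's marker intensities.
#' @param p_max_plugin Marker count above which `bw_plugin()` switches to
#'   Silverman's rule (default 6).
#' @return An object of class `bandwidth_set`: a list with `h` (length-p
#'   positive vector) and `method_tag` (`"plugin"`, `"silverman"` or
#'   `"fixed"`).
#' @name bandwidths
NULL

new_bandwidth_set <- function(h, method_tag) {
  h <- pmax(as.numeric(h), 1e-6)
  if (!all(is.finite(h)) || any(h <= 0)) {
    abort("Bandwidths must be positive and finite.",
          class = "coexmi_domain_error")
  }
  structure(list(h = h, method_tag = method_tag), class = "bandwidth_set")
}

#' @export
print.bandwidth_set <- function(x, ...) {
  cat(sprintf("<bandwidth_set [%s]> h = %s\n", x$method_tag,
              paste(signif(x$h, 4), collapse = ", ")))
  invisible(x)
}

#' A fixed bandwidth set
#' @param h Positive bandwidth(s); recycled to length `p` if given.
#' @param p Optional number of markers.
#' @rdname bandwidths
#' @export
bw_fixed <- function(h, p = length(h)) {
  new_bandwidth_set(rep_len(h, p), "fixed")
}

#' @rdname bandwidths
#' @export
bw_silverman <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) {
    abort("Silverman's rule needs at least 2 cells.",
          class = "coexmi_precondition_error")
  }
  h <- vapply(seq_len(ncol(x)), function(k) {
    silverman_1d(x[, k], colnames(x)[k] %||% as.character(k))
  }, numeric(1))
  new_bandwidth_set(h, "silverman")
}

silverman_1d <- function(v, label) {
  s <- sd(v)
  iqr <- diff(quantile(v, c(0.25, 0.75), names = FALSE, type = 7))
  scale <- min(s, iqr / 1.34)
  if (!is.finite(scale) || scale <= 0) {
    # sd==0 (constant) or zero IQR with zero spread
    if (s <= 0) {
      abort(sprintf("Marker '%s' is constant; cannot select a bandwidth.",
                    label),
            class = "coexmi_degenerate_marker_error")
    }
    scale <- s  # heavy ties can zero the IQR while sd > 0
  }
  0.9 * scale * length(v)^(-1 / 5)
}

#' @rdname bandwidths
#' @export
bw_plugin <- function(x, p_max_plugin = 6) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p > p_max_plugin) {
    warn(sprintf(
      "coexmi: %d markers > p_max_plugin = %d; using Silverman's rule instead of plug-in.",
      p, p_max_plugin))
    return(bw_silverman(x))
  }
  if (nrow(x) < 4) {
    abort("Plug-in bandwidth selection needs at least 4 cells per marker.",
          class = "coexmi_precondition_error")
  }
  fell_back <- FALSE
  h <- vapply(seq_len(p), function(k) {
    v <- x[, k]
    label <- colnames(x)[k] %||% as.character(k)
    if (sd(v) <= 0) {
      abort(sprintf("Marker '%s' is constant; cannot select a bandwidth.",
                    label),
            class = "coexmi_degenerate_marker_error")
    }
    tryCatch(bw.SJ(v, method = "dpi"),
             error = function(e) {
               fell_back <<- TRUE
               silverman_1d(v, label)
             })
  }, numeric(1))
  if (fell_back) {
    warn("coexmi: plug-in bandwidth selection failed for >=1 marker; used Silverman's rule there.")
  }
  new_bandwidth_set(h, "plugin")
}

select_bandwidths <- function(x, bw_method, p_max_plugin = 6) {
  if (inherits(bw_method, "bandwidth_set")) {
    return(new_bandwidth_set(rep_len(bw_method$h, ncol(x)),
                             bw_method$method_tag))
  }
  if (is.numeric(bw_method)) return(bw_fixed(bw_method, ncol(x)))
  switch(match.arg(bw_method, c("plugin", "silverman")),
         plugin = bw_plugin(x, p_max_plugin = p_max_plugin),
         silverman = bw_silverman(x))
}
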