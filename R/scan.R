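#' Scan all marker combinations for outcome association
#'
#' For every subset of the chosen markers of size `min_size` or larger
#' (`2^p - p - 1` subsets when `min_size = 2`), computes EQMI* per subject
#' and runs the outcome-appropriate association test.  Because combinations
#' of different sizes answer different questions, multiplicity is corrected
#' within each subset size: `bonferroni_alpha = alpha / (number of subsets
#' of that size)`, and a subset is flagged significant when its raw p-value
#' falls below that size-specific level.
#'
#' @param table A `cell_tbl`.
#' @param outcome An [outcome_spec()].
#' @param use_markers Markers to scan (default all; at most 10 — the scan
#'   is exponential in p, so pre-select a functional-marker panel beyond
#'   that).
#' @param min_size Smallest subset size (default 2).
#' @param alpha Family-wise level before the per-size split (default 0.05).
#' @param bw_method Bandwidth selection, as in [compute_eqmi()].
#' @return A tibble with one row per combination: `marker_set`, `size`,
#'   `coefficient`, `hazard_ratio`, `p_value`, `bonferroni_alpha`,
#'   `significant`, sorted by size then p-value.
#' @export
combination_scan <- function(table, outcome, use_markers = NULL,
                             min_size = 2, alpha = 0.05,
                             bw_method = "plugin") {
  mk <- use_markers %||% markers(table)
  p <- length(mk)
  if (p < 2) abort("Need at least 2 markers.",
                   class = "coexmi_precondition_error")
  if (p > 10) {
    abort(paste0("Scanning ", p, " markers means 2^", p,
                 " subsets; restrict `use_markers` to <= 10 markers."),
          class = "coexmi_config_error")
  }
  if (min_size < 2) abort("`min_size` must be >= 2.",
                          class = "coexmi_config_error")
  sizes <- seq(min_size, p)
  combos <- unlist(lapply(sizes, function(s) {
    asplit(combn(mk, s), 2)
  }), recursive = FALSE)
  n_of_size <- table(vapply(combos, length, integer(1)))

  rows <- purrr::map(combos, function(set) {
    stat <- compute_eqmi(table, use_markers = set, bw_method = bw_method)
    res <- associate(stat, outcome)
    size <- length(set)
    b_alpha <- alpha / n_of_size[[as.character(size)]]
    tibble(marker_set = paste(set, collapse = ";"), size = size,
           coefficient = res$coefficient, hazard_ratio = res$hazard_ratio,
           p_value = res$p_value, bonferroni_alpha = b_alpha,
           significant = !is.na(res$p_value) & res$p_value < b_alpha)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$size, .data$p_value)
}
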