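#' Construct a cell table from a data frame
#'
#' A cell table is the package's tabular container for segmented
#' multiplex-imaging data: one row per cell, one column per marker intensity,
#' plus a subject identifier and optional image / cell-type / tissue-region
#' metadata.  It is an ordinary tibble carrying a `markers` attribute, so it
#' pipes through dplyr verbs; functions that need the marker set re-validate
#' it on entry.
#'
#' @param data A data frame with one row per cell.
#' @param markers Character vector (length >= 2) naming the marker-intensity
#'   columns.  Values must be finite and non-negative.
#' @param subject Name of the subject-identifier column (default
#'   `"subject_id"`).
#' @param image,cell_type,tissue_region Optional names of metadata columns;
#'   `NULL` if absent.
#' @return A tibble of class `cell_tbl` with standardized column names
#'   (`subject_id`, optional `image_id`, `cell_type`, `tissue_region`, then
#'   marker columns) and attribute `markers`.  Rows with a missing marker
#'   value are dropped with a message stating the count.
#' @export
#' @examples
#' df <- data.frame(subject_id = rep(c("a", "b"), each = 3),
#'                  CD3 = runif(6), CK = runif(6))
#' as_cell_table(df, markers = c("CD3", "CK"))
as_cell_table <- function(data, markers, subject = "subject_id",
                          image = NULL, cell_type = NULL,
                          tissue_region = NULL) {
  stopifnot(is.data.frame(data))
  markers <- as.character(markers)
  if (length(markers) < 2 || anyDuplicated(markers)) {
    abort("`markers` must name at least 2 unique intensity columns.",
          class = "coexmi_config_error")
  }
  needed <- c(subject, markers, image, cell_type, tissue_region)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(paste0("Column(s) not found in `data`: ",
                 paste(missing_cols, collapse = ", ")),
          class = "coexmi_config_error")
  }
  out <- tibble(subject_id = data[[subject]])
  if (!is.null(image)) out$image_id <- data[[image]]
  if (!is.null(cell_type)) out$cell_type <- data[[cell_type]]
  if (!is.null(tissue_region)) out$tissue_region <- data[[tissue_region]]
  for (m in markers) out[[m]] <- as.numeric(data[[m]])

  keep <- complete.cases(out[markers])
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    inform(sprintf("Dropped %d cell row(s) with missing marker values.",
                   n_drop))
    out <- out[keep, , drop = FALSE]
  }
  if (nrow(out) == 0) {
    abort("No usable cell rows after dropping missing marker values.",
          class = "coexmi_empty_error")
  }
  X <- as.matrix(out[markers])
  if (!all(is.finite(X))) {
    abort("Marker intensities must be finite.", class = "coexmi_domain_error")
  }
  if (any(X < 0)) {
    abort("Marker intensities must be non-negative.",
          class = "coexmi_domain_error")
  }
  new_cell_tbl(out, markers)
}

new_cell_tbl <- function(data, markers) {
  out <- as_tibble(data)
  attr(out, "markers") <- markers
  class(out) <- c("cell_tbl", class(tibble()))
  out
}

#' Marker names of a cell table
#' @param table A `cell_tbl`.
#' @return Character vector of marker column names.
#' @export
markers <- function(table) {
  m <- attr(table, "markers")
  if (is.null(m)) {
    # attribute lost through a reshaping verb: recover as the numeric
    # non-metadata columns
    meta <- c("subject_id", "image_id", "cell_type", "tissue_region")
    m <- setdiff(names(table)[vapply(table, is.numeric, logical(1))], meta)
  }
  m
}

#' @export
print.cell_tbl <- function(x, ...) {
  cat(sprintf("# Cell table: %d cells, %d subjects, %d markers (%s)\n",
              nrow(x), dplyr::n_distinct(x$subject_id), length(markers(x)),
              paste(markers(x), collapse = ", ")))
  NextMethod()
}

#' Read a cell table from a delimited text file
#'
#' CSV or TSV is auto-detected from the file extension (`.tsv`/`.txt` read as
#' tab-delimited, anything else as comma-delimited).
#'
#' @inheritParams as_cell_table
#' @param path Path to the delimited file; must have a header row.
#' @return A `cell_tbl`; see [as_cell_table()].
#' @export
read_cell_table <- function(path, markers, subject = "subject_id",
                            image = NULL, cell_type = NULL,
                            tissue_region = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "coexmi_config_error")
  }
  reader <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    readr::read_tsv
  } else {
    readr::read_csv
  }
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  as_cell_table(raw, markers = markers, subject = subject, image = image,
                cell_type = cell_type, tissue_region = tissue_region)
}

#' Rescale marker intensities to the unit interval
#'
#' EQMI* treats each marker as a random variable on \[0, 1\], so raw
#' intensities must be mapped there.  `global_minmax` (the default) pools the
#' per-marker min and max over all subjects, keeping subjects on a shared
#' scale; `per_subject_minmax` rescales within each subject;
#' `quantile_cap_minmax` first winsorizes each marker at the pooled
#' `cap_quantile` (robust to hot pixels) and then applies the global min-max
#' map.
#'
#' @param table A `cell_tbl`.
#' @param method One of `"none"`, `"global_minmax"`, `"per_subject_minmax"`,
#'   `"quantile_cap_minmax"`.
#' @param cap_quantile Winsorizing quantile in (0, 1\] used by
#'   `quantile_cap_minmax` (default 0.99).
#' @return A `cell_tbl` with all marker values in \[0, 1\] (unchanged for
#'   `method = "none"`).
#' @export
normalize_intensities <- function(table,
                                  method = c("global_minmax", "none",
                                             "per_subject_minmax",
                                             "quantile_cap_minmax"),
                                  cap_quantile = 0.99) {
  method <- match.arg(method)
  mk <- markers(table)
  if (method == "none") return(table)
  if (method == "quantile_cap_minmax" &&
      !(cap_quantile > 0 && cap_quantile <= 1)) {
    abort("`cap_quantile` must lie in (0, 1].", class = "coexmi_config_error")
  }
  rescale <- function(x, marker, stratum = "all subjects") {
    lo <- min(x); hi <- max(x)
    if (hi <= lo) {
      abort(sprintf("Marker '%s' is constant over %s; cannot min-max scale.",
                    marker, stratum),
            class = "coexmi_degenerate_marker_error")
    }
    (x - lo) / (hi - lo)
  }
  out <- table
  if (method == "per_subject_minmax") {
    for (m in mk) {
      out[[m]] <- as.numeric(unsplit(
        lapply(split(out[[m]], out$subject_id), function(x) {
          rescale(x, m, "a subject")
        }),
        out$subject_id))
    }
  } else {
    for (m in mk) {
      x <- out[[m]]
      if (method == "quantile_cap_minmax") {
        cap <- quantile(x, cap_quantile, names = FALSE, type = 7)
        x <- pmin(x, cap)
      }
      out[[m]] <- rescale(x, m)
    }
  }
  new_cell_tbl(out, mk)
}

#' Subset a cell table by cell type and/or tissue region
#'
#' @param table A `cell_tbl`.
#' @param cell_type_in,tissue_region_in Optional character vectors of levels
#'   to keep; `NULL` leaves the corresponding dimension unfiltered.
#' @return The filtered `cell_tbl`.  Subjects left with zero cells are
#'   removed with a warning.
#' @export
filter_cells <- function(table, cell_type_in = NULL, tissue_region_in = NULL) {
  out <- table
  for (f in list(c("cell_type", "cell_type_in"),
                 c("tissue_region", "tissue_region_in"))) {
    keep_set <- get(f[2])
    if (is.null(keep_set)) next
    if (!f[1] %in% names(out)) {
      abort(sprintf("Filter on '%s' requested but the column is absent.",
                    f[1]),
            class = "coexmi_config_error")
    }
    out <- out[out[[f[1]]] %in% keep_set, , drop = FALSE]
  }
  lost <- setdiff(unique(table$subject_id), unique(out$subject_id))
  if (length(lost)) {
    warn(sprintf("coexmi: %d subject(s) removed by filtering (no cells left): %s",
                 length(lost), paste(head(lost, 5), collapse = ", ")))
  }
  new_cell_tbl(out, markers(table))
}

# intensities of one subject as an n x p matrix (markers in column order)
subject_matrix <- function(table, subject, mk = markers(table)) {
  as.matrix(table[table$subject_id == subject, mk, drop = FALSE])
}
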