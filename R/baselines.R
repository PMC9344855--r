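#' Pooled quantile positivity thresholds
#'
#' The traditional pipeline declares a cell positive for marker k when its
#' intensity strictly exceeds a cutoff `t_k`.  This helper sets `t_k` to the
#' q-quantile of the marker's intensities pooled over all subjects
#' (linear-interpolation / type-7 quantiles).  The three standard
#' comparators are `q = 0.5` (median thresholding), `q = 0.95` and
#' `q = 0.99`.
#'
#' @param table A `cell_tbl`.
#' @param q Quantile in (0, 1).
#' @return An object of class `threshold_set`: list with `t` (named per
#'   marker) and `source_tag` (`"median"`, `"q95"`, `"q99"` or `"user"`).
#' @export
global_quantile_thresholds <- function(table, q) {
  if (!(q > 0 && q < 1)) {
    abort("`q` must lie in (0, 1).", class = "coexmi_config_error")
  }
  if (nrow(table) == 0) abort("Empty cell table.",
                              class = "coexmi_empty_error")
  mk <- markers(table)
  t <- vapply(mk, function(m) {
    quantile(table[[m]], q, names = FALSE, type = 7)
  }, numeric(1))
  tag <- if (q == 0.5) "median" else if (q == 0.95) "q95"
         else if (q == 0.99) "q99" else "user"
  threshold_set(t, source_tag = tag)
}

#' @rdname global_quantile_thresholds
#' @param t Named (per marker) numeric vector of cutoffs.
#' @param source_tag Label recording where the cutoffs came from.
#' @export
threshold_set <- function(t, source_tag = "user") {
  structure(list(t = t, source_tag = source_tag), class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set [%s]> %s\n", x$source_tag,
              paste(names(x$t), signif(x$t, 4), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Per-subject marker positivity proportions
#'
#' Given cutoffs, each cell is positive for marker k iff its intensity
#' strictly exceeds `t_k`.  In `"pairwise"` mode (the traditional feature
#' vector) each unordered marker pair contributes three proportions per
#' subject: both positive, first-only, second-only.  In `"full_pattern"`
#' mode all `2^p - 1` not-all-negative joint patterns are reported.
#'
#' @param table A `cell_tbl`.
#' @param thresholds A `threshold_set` aligned to the table's markers.
#' @param mode `"pairwise"` (default) or `"full_pattern"`.
#' @return A wide tibble: `subject_id`, then one proportion column per
#'   pattern label (e.g. `A+B+`, `A+B-`).
#' @export
positivity_proportions <- function(table, thresholds,
                                   mode = c("pairwise", "full_pattern")) {
  mode <- match.arg(mode)
  mk <- markers(table)
  t <- thresholds$t[mk]
  if (anyNA(t)) {
    abort("Thresholds do not cover all markers.",
          class = "coexmi_config_error")
  }
  pos <- vapply(mk, function(m) table[[m]] > t[[m]],
                logical(nrow(table)))  # cells x p logical
  subjects <- unique(table$subject_id)
  rows <- lapply(subjects, function(sj) {
    P <- pos[table$subject_id == sj, , drop = FALSE]
    n <- nrow(P)
    if (mode == "pairwise") {
      vals <- list()
      for (pr in asplit(combn(mk, 2), 2)) {
        a <- P[, pr[1]]; b <- P[, pr[2]]
        vals[[paste0(pr[1], "+", pr[2], "+")]] <- mean(a & b)
        vals[[paste0(pr[1], "+", pr[2], "-")]] <- mean(a & !b)
        vals[[paste0(pr[1], "-", pr[2], "+")]] <- mean(!a & b)
      }
    } else {
      vals <- list()
      for (s in seq_len(2^length(mk) - 1)) {
        sel <- as.logical(bitwAnd(s, 2^(seq_along(mk) - 1)))
        label <- paste0(mk, ifelse(sel, "+", "-"), collapse = "")
        match_rows <- rep(TRUE, n)
        for (k in seq_along(mk)) {
          match_rows <- match_rows & (P[, k] == sel[k])
        }
        vals[[label]] <- mean(match_rows)
      }
    }
    dplyr::bind_cols(tibble(subject_id = sj), as_tibble(vals))
  })
  dplyr::bind_rows(rows)
}

#' Cluster subjects on their positivity profiles
#'
#' Agglomerative hierarchical clustering of the subjects' proportion
#' vectors (Euclidean distance, Ward linkage by default), cut at M groups —
#' the grouping step of the traditional thresholding pipeline.
#'
#' @param profiles Output of [positivity_proportions()].
#' @param M Number of clusters (default 2).
#' @param linkage Linkage passed to [stats::hclust()] (default
#'   `"ward.D2"`).
#' @return Tibble `subject_id`, `cluster` (integers `0 .. M-1`, relabelled
#'   so cluster 0 contains the lowest-index subject), with attributes
#'   `linkage` and `distance`.
#' @export
cluster_subjects <- function(profiles, M = 2, linkage = "ward.D2") {
  X <- as.matrix(profiles[setdiff(names(profiles), "subject_id")])
  N <- nrow(X)
  if (M < 2 || N < M) {
    abort("Need N >= M >= 2 subjects.", class = "coexmi_precondition_error")
  }
  if (nrow(unique(X)) < M) {
    abort(paste0("Only ", nrow(unique(X)),
                 " distinct profile vectors; reduce M."),
          class = "coexmi_reduce_m_error")
  }
  hc <- hclust(dist(X, method = "euclidean"), method = linkage)
  raw <- cutree(hc, k = M)
  # stable relabel: clusters numbered by first appearance in subject order
  lab <- match(raw, unique(raw)) - 1L
  out <- tibble(subject_id = profiles$subject_id, cluster = lab)
  attr(out, "linkage") <- linkage
  attr(out, "distance") <- "euclidean"
  out
}

#' Association test for threshold-derived cluster labels
#'
#' Encodes the cluster labels as indicator variables Z and delegates to the
#' outcome-appropriate test: a single-coefficient report when M = 2, an
#' (M-1)-df LRT for survival outcomes with M > 2.
#'
#' @param assignment Output of [cluster_subjects()].
#' @param outcome An [outcome_spec()].
#' @return A `coex_assoc` object.
#' @export
threshold_association <- function(assignment, outcome) {
  M <- length(unique(assignment$cluster))
  if (M == 2) {
    stat <- tibble(subject_id = assignment$subject_id,
                   eqmi_star = as.numeric(assignment$cluster),
                   marker_set = "cluster_label")
    return(associate(stat, outcome))
  }
  if (outcome$type != "survival") {
    abort("M > 2 cluster association is implemented for survival outcomes only.",
          class = "coexmi_config_error")
  }
  # (M-1)-df LRT: indicators for clusters 1..M-1
  idx <- match(outcome$subject_id, assignment$subject_id)
  Z <- outer(assignment$cluster[idx], seq_len(M - 1), "==") * 1
  colnames(Z) <- paste0("Z", seq_len(M - 1))
  df <- data.frame(time = outcome$y, event = outcome$event, Z)
  if (!is.null(outcome$covariates)) {
    C <- as.data.frame(outcome$covariates)
    names(C) <- paste0("C", seq_len(ncol(C)))
    df <- cbind(df, C)
  }
  zterms <- paste(colnames(Z), collapse = " + ")
  cterms <- if (!is.null(outcome$covariates))
    paste("+", paste(grep("^C", names(df), value = TRUE), collapse = " + "))
  else ""
  full <- survival::coxph(stats::as.formula(
    paste("survival::Surv(time, event) ~", zterms, cterms)), data = df)
  null <- survival::coxph(stats::as.formula(
    paste("survival::Surv(time, event) ~",
          if (nzchar(cterms)) sub("^\\+ ", "", cterms) else "1")), data = df)
  lrt <- 2 * (full$loglik[length(full$loglik)] -
                if (nzchar(cterms)) null$loglik[length(null$loglik)]
                else full$loglik[1])
  new_assoc(coefficient = NA_real_,
            p_value = pchisq(max(lrt, 0), df = M - 1, lower.tail = FALSE),
            test_tag = "lrt", n_used = nrow(df),
            marker_set = "cluster_label", model = full,
            outcome_type = "survival")
}

#' Run one thresholding comparator end to end
#'
#' Pooled q-quantile cutoffs, pairwise positivity proportions, Ward
#' clustering at M = 2, then the outcome-appropriate association test —
#' the full traditional pipeline as a single call.
#'
#' @param table A `cell_tbl`.
#' @param outcome An [outcome_spec()].
#' @param q Pooled quantile for the cutoffs (0.5, 0.95 or 0.99 for the
#'   standard comparators).
#' @param mode Positivity feature mode, see [positivity_proportions()].
#' @return A `coex_assoc` object.
#' @export
thresholding_pipeline <- function(table, outcome, q,
                                  mode = c("pairwise", "full_pattern")) {
  th <- global_quantile_thresholds(table, q)
  prof <- positivity_proportions(table, th, mode = match.arg(mode))
  cl <- cluster_subjects(prof, M = 2)
  threshold_association(cl, outcome)
}
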