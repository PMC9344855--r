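#' Specify a subject-level outcome
#'
#' Bundles the outcome vector, its type, an optional event indicator
#' (survival only) and an optional covariate matrix, aligned to subjects by
#' identifier so cell tables and outcomes can be joined safely.
#'
#' @param subject_id Length-N subject identifiers (unique).
#' @param y Length-N outcome: a continuous value, a 0/1 class, or the
#'   observed time `min(T, U)` for survival.
#' @param type One of `"continuous"`, `"binary"`, `"survival"`.
#' @param event Length-N 0/1 event indicator (`1` = event observed);
#'   required for survival outcomes.
#' @param covariates Optional N x S numeric matrix or data frame of
#'   subject-level adjustment covariates (no missing values).
#' @return An object of class `outcome_spec`.
#' @export
outcome_spec <- function(subject_id, y,
                         type = c("continuous", "binary", "survival"),
                         event = NULL, covariates = NULL) {
  type <- match.arg(type)
  N <- length(subject_id)
  if (anyDuplicated(subject_id)) {
    abort("`subject_id` must be unique.", class = "coexmi_config_error")
  }
  if (length(y) != N || anyNA(y)) {
    abort("`y` must be length N with no missing values.",
          class = "coexmi_config_error")
  }
  if (type == "survival") {
    if (is.null(event) || length(event) != N || !all(event %in% c(0, 1))) {
      abort("Survival outcomes need a length-N 0/1 `event` vector.",
            class = "coexmi_config_error")
    }
    if (any(y < 0)) {
      abort("Survival times must be non-negative.",
            class = "coexmi_config_error")
    }
  }
  if (type == "binary" && !all(y %in% c(0, 1))) {
    abort("Binary outcomes must be coded 0/1.", class = "coexmi_config_error")
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != N || anyNA(covariates)) {
      abort("`covariates` must be N x S with no missing values.",
            class = "coexmi_config_error")
    }
  }
  structure(list(subject_id = as.character(subject_id), y = as.numeric(y),
                 type = type, event = if (!is.null(event)) as.integer(event),
                 covariates = covariates),
            class = "outcome_spec")
}

#' @export
print.outcome_spec <- function(x, ...) {
  cat(sprintf("<outcome_spec> %s, N = %d%s%s\n", x$type, length(x$y),
              if (x$type == "survival")
                sprintf(", %d events", sum(x$event)) else "",
              if (!is.null(x$covariates))
                sprintf(", %d covariate(s)", ncol(x$covariates)) else ""))
  invisible(x)
}

# align a per-subject statistic tibble (subject_id + value column) with an
# outcome_spec; returns list(E, y, event, C, subject_id)
align_outcome <- function(stat_tbl, outcome, value_col) {
  idx <- match(outcome$subject_id, stat_tbl$subject_id)
  if (anyNA(idx)) {
    abort(paste0("Outcome subjects missing from the statistic table: ",
                 paste(head(outcome$subject_id[is.na(idx)], 5),
                       collapse = ", ")),
          class = "coexmi_config_error")
  }
  list(E = stat_tbl[[value_col]][idx], y = outcome$y, event = outcome$event,
       C = outcome$covariates, subject_id = outcome$subject_id)
}

new_assoc <- function(coefficient, p_value, test_tag, n_used, marker_set,
                      model = NULL, outcome_type, hazard_ratio = NA_real_,
                      flag = NA_character_) {
  structure(list(coefficient = coefficient, hazard_ratio = hazard_ratio,
                 p_value = p_value, test_tag = test_tag, n_used = n_used,
                 marker_set = marker_set, outcome_type = outcome_type,
                 flag = flag, model = model),
            class = "coex_assoc")
}

#' @export
print.coex_assoc <- function(x, ...) {
  cat(sprintf("<coex_assoc> %s outcome, %s test: coef = %.4g%s, p = %.4g (n = %d)%s\n",
              x$outcome_type, x$test_tag, x$coefficient,
              if (!is.na(x$hazard_ratio))
                sprintf(" (HR = %.4g)", x$hazard_ratio) else "",
              x$p_value, x$n_used,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' @export
tidy.coex_assoc <- function(x, ...) {
  tibble(term = "E", estimate = x$coefficient,
         hazard_ratio = x$hazard_ratio, p.value = x$p_value,
         test = x$test_tag)
}

#' @export
glance.coex_assoc <- function(x, ...) {
  tibble(outcome_type = x$outcome_type, test = x$test_tag,
         p.value = x$p_value, n_used = x$n_used,
         marker_set = x$marker_set %||% NA_character_,
         flag = x$flag)
}

#' Test a co-expression vector against a continuous outcome
#'
#' Ordinary least squares of `y` on covariates plus polynomial terms of the
#' per-subject statistic `E`; the null of no E-effect is assessed by a Wald
#' test (the usual single-coefficient t-test when `poly_degree = 1`, a joint
#' chi-square Wald test on all E-terms otherwise).  The reported coefficient
#' is always the linear E term.
#'
#' @param stat_tbl Tibble with `subject_id` and the statistic column.
#' @param outcome An [outcome_spec()] with `type = "continuous"`.
#' @param poly_degree Highest power of E entered (default 1).
#' @param value_col Name of the statistic column (default `"eqmi_star"`).
#' @return A `coex_assoc` object; see [tidy.coex_assoc()].
#' @export
linear_association <- function(stat_tbl, outcome, poly_degree = 1,
                               value_col = "eqmi_star") {
  if (outcome$type != "continuous") {
    abort("`outcome` must be continuous.", class = "coexmi_config_error")
  }
  a <- align_outcome(stat_tbl, outcome, value_col)
  N <- length(a$y)
  S <- if (is.null(a$C)) 0 else ncol(a$C)
  if (N <= S + poly_degree + 1) {
    abort("Too few subjects for the requested design.",
          class = "coexmi_precondition_error")
  }
  Epoly <- vapply(seq_len(poly_degree), function(d) a$E^d,
                  numeric(N))
  colnames(Epoly) <- paste0("E", seq_len(poly_degree))
  X <- if (S > 0) cbind(a$C, Epoly) else Epoly
  df <- data.frame(y = a$y, X)
  fit <- lm(y ~ ., data = df)
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort(paste0("Rank-deficient design; dropped columns: ",
                 paste(names(cf)[is.na(cf)], collapse = ", ")),
          class = "coexmi_collinearity_error")
  }
  eterms <- colnames(Epoly)
  if (poly_degree == 1) {
    sm <- summary(fit)$coefficients
    p <- sm["E1", "Pr(>|t|)"]
  } else {
    g <- cf[eterms]
    V <- vcov(fit)[eterms, eterms, drop = FALSE]
    W <- as.numeric(t(g) %*% solve(V, g))
    p <- pchisq(W, df = poly_degree, lower.tail = FALSE)
  }
  new_assoc(coefficient = unname(cf["E1"]), p_value = unname(p),
            test_tag = "wald", n_used = N,
            marker_set = marker_set_of(stat_tbl),
            model = fit, outcome_type = "continuous")
}

#' Test a co-expression vector against a binary outcome
#'
#' Maximum-likelihood logistic regression of the 0/1 outcome on covariates
#' plus E, with the Wald p-value for the E coefficient.  Complete or
#' quasi-complete separation is flagged (p set to `NA`) rather than reported
#' as a spuriously tiny p-value.
#'
#' @inheritParams linear_association
#' @return A `coex_assoc` object.
#' @export
logistic_association <- function(stat_tbl, outcome,
                                 value_col = "eqmi_star") {
  if (outcome$type != "binary") {
    abort("`outcome` must be binary.", class = "coexmi_config_error")
  }
  a <- align_outcome(stat_tbl, outcome, value_col)
  if (length(unique(a$y)) < 2) {
    abort("Outcome has a single class.", class = "coexmi_precondition_error")
  }
  X <- if (!is.null(a$C)) cbind(a$C, E = a$E) else cbind(E = a$E)
  df <- data.frame(y = a$y, X)
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  sm <- summary(fit)$coefficients
  sep <- !fit$converged ||
    any(fit$fitted.values > 1 - 1e-8) && any(fit$fitted.values < 1e-8) &&
      sm["E", "Std. Error"] > 1e3
  if (sep) {
    warn("coexmi: separation / non-convergence in logistic fit; p-value withheld.")
    return(new_assoc(coefficient = unname(coef(fit)["E"]), p_value = NA_real_,
                     test_tag = "wald", n_used = length(a$y),
                     marker_set = marker_set_of(stat_tbl),
                     model = fit, outcome_type = "binary",
                     flag = "separation"))
  }
  new_assoc(coefficient = unname(coef(fit)["E"]),
            p_value = unname(sm["E", "Pr(>|z|)"]), test_tag = "wald",
            n_used = length(a$y),
            marker_set = marker_set_of(stat_tbl),
            model = fit, outcome_type = "binary")
}

#' Test a co-expression vector against a right-censored outcome
#'
#' Cox proportional-hazards fit
#' `lambda_j(t) = lambda_0(t) exp(C_j' beta + E_j gamma)`; the p-value is a
#' 1-df likelihood-ratio test comparing the partial likelihoods with and
#' without E (covariates retained in both).  Reports `gamma_hat` and the
#' hazard ratio `exp(gamma_hat)`.
#'
#' @inheritParams linear_association
#' @param ties Tie-handling method passed to [survival::coxph()]
#'   (`"efron"` default, `"breslow"` selectable).
#' @return A `coex_assoc` object with `hazard_ratio` filled in.
#' @export
cox_lrt_association <- function(stat_tbl, outcome, value_col = "eqmi_star",
                                ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (outcome$type != "survival") {
    abort("`outcome` must be survival.", class = "coexmi_config_error")
  }
  a <- align_outcome(stat_tbl, outcome, value_col)
  if (sum(a$event) < 2) {
    abort("Need at least 2 observed events.",
          class = "coexmi_precondition_error")
  }
  if (sd(a$E) == 0) {
    warn("coexmi: statistic is constant across subjects; Cox test degenerate.")
    return(new_assoc(coefficient = NA_real_, p_value = NA_real_,
                     test_tag = "lrt", n_used = length(a$y),
                     marker_set = marker_set_of(stat_tbl),
                     outcome_type = "survival", flag = "degenerate"))
  }
  df <- data.frame(time = a$y, event = a$event, E = a$E)
  rhs_cov <- ""
  if (!is.null(a$C)) {
    C <- as.data.frame(a$C)
    names(C) <- paste0("C", seq_len(ncol(C)))
    df <- cbind(df, C)
    rhs_cov <- paste("+", paste(names(C), collapse = " + "))
  }
  full_f <- stats::as.formula(paste("survival::Surv(time, event) ~ E", rhs_cov))
  null_f <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    if (nzchar(rhs_cov)) sub("^\\+ ", "", rhs_cov) else "1"))
  fit <- tryCatch(
    survival::coxph(full_f, data = df, ties = ties),
    warning = function(w) {
      warn(paste0("coexmi: Cox fit warning: ", conditionMessage(w)))
      suppressWarnings(survival::coxph(full_f, data = df, ties = ties))
    })
  null_fit <- suppressWarnings(survival::coxph(null_f, data = df, ties = ties))
  ll_full <- fit$loglik[length(fit$loglik)]
  ll_null <- if (nzchar(rhs_cov)) null_fit$loglik[length(null_fit$loglik)]
             else fit$loglik[1]
  lrt <- 2 * (ll_full - ll_null)
  gamma <- unname(coef(fit)["E"])
  new_assoc(coefficient = gamma,
            p_value = pchisq(max(lrt, 0), df = 1, lower.tail = FALSE),
            test_tag = "lrt", n_used = length(a$y),
            marker_set = marker_set_of(stat_tbl),
            model = fit, outcome_type = "survival",
            hazard_ratio = exp(gamma))
}

#' Dispatch the outcome-appropriate association test
#'
#' @inheritParams linear_association
#' @param ... Passed to the type-specific test.
#' @return A `coex_assoc` object.
#' @export
associate <- function(stat_tbl, outcome, value_col = "eqmi_star", ...) {
  switch(outcome$type,
         continuous = linear_association(stat_tbl, outcome,
                                         value_col = value_col, ...),
         binary = logistic_association(stat_tbl, outcome,
                                       value_col = value_col, ...),
         survival = cox_lrt_association(stat_tbl, outcome,
                                        value_col = value_col, ...))
}

marker_set_of <- function(stat_tbl) {
  if ("marker_set" %in% names(stat_tbl)) stat_tbl$marker_set[1]
  else NA_character_
}
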