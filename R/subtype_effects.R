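## ---------------------------------------------------------------------------
## Case-control odds ratios by intrinsic-like subtype (model "subtype")
## and by grade (model "grade"), via constrained second-stage designs.
## ---------------------------------------------------------------------------

#' Exponentiated Wald confidence interval
#'
#' @param log_or log odds ratio.
#' @param se standard error (> 0).
#' @param level confidence level (default 0.95 -> 1.96 multiplier).
#' @return data.frame(OR, lo, hi), one row per input.
#' @examples
#' or_ci(log(2), 0.1)
#' @export
or_ci <- function(log_or, se, level = 0.95) {
  if (any(se <= 0, na.rm = TRUE)) stop("se must be positive")
  zq <- qnorm(1 - (1 - level) / 2)
  data.frame(OR = exp(log_or), lo = exp(log_or - zq * se),
             hi = exp(log_or + zq * se))
}

ts_or_table <- function(fit, level = 0.95) {
  th <- fit$theta; se <- fit$se_theta
  ok <- is.finite(th) & is.finite(se) & se > 0
  ci <- matrix(NA_real_, length(th), 3,
               dimnames = list(NULL, c("OR", "lo", "hi")))
  if (any(ok)) ci[ok, ] <- as.matrix(or_ci(th[ok], se[ok], level))
  z <- th / se
  data.frame(category = fit$labels, log_or = unname(th), se = unname(se),
             OR = ci[, "OR"], lo = ci[, "lo"], hi = ci[, "hi"],
             z = unname(z), p = unname(2 * pnorm(-abs(z))),
             row.names = NULL)
}

#' Case-control ORs for the five intrinsic-like subtypes
#'
#' Two-stage fit with the subtype-indicator second stage: each of the
#' 24 cells' genotype log OR is constrained to its intrinsic-like
#' subtype's value (5 free parameters), and cases with partially
#' observed markers are handled through the observed-data likelihood
#' (e.g. a luminal HER2-negative case with missing grade contributes to
#' both luminal A-like and luminal B-like/HER2-negative).
#'
#' @inheritParams fit_twostage
#' @param level confidence level for the ORs.
#' @return list of class `subtype_or_fit`: `table`
#'   (category, log_or, se, OR, lo, hi, z, p) and `fit`.
#' @export
fit_model_subtypes <- function(status, g, markers, x = NULL,
                               schema = default_schema(),
                               method = c("direct", "EM"),
                               control = list(), level = 0.95) {
  fit <- fit_twostage(status, g, markers, x,
                      design = "subtype_indicators", schema = schema,
                      method = match.arg(method), control = control)
  if (any(fit$dropped_par))
    warning("subtype(s) with no consistent case mass: ",
            paste(fit$labels[fit$dropped_par], collapse = ", "))
  structure(list(table = ts_or_table(fit, level), fit = fit),
            class = "subtype_or_fit")
}

#' Case-control ORs by tumor grade
#'
#' Two-stage fit with the grade-indicator second stage (3 free genotype
#' parameters, one per grade), intended for variants whose case-case
#' heterogeneity is attributable to grade only.
#'
#' @inheritParams fit_model_subtypes
#' @return list of class `subtype_or_fit` (categories grade1..3).
#' @export
fit_model_grade <- function(status, g, markers, x = NULL,
                            schema = default_schema(),
                            method = c("direct", "EM"),
                            control = list(), level = 0.95) {
  fit <- fit_twostage(status, g, markers, x,
                      design = "grade_indicators", schema = schema,
                      method = match.arg(method), control = control)
  structure(list(table = ts_or_table(fit, level), fit = fit),
            class = "subtype_or_fit")
}

#' @export
print.subtype_or_fit <- function(x, ...) {
  cat("case-control odds ratios:\n")
  print(transform(x$table, OR = round(OR, 3), lo = round(lo, 3),
                  hi = round(hi, 3), p = signif(p, 3))[,
        c("category", "OR", "lo", "hi", "p")])
  invisible(x)
}
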