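#' Validate a survival table
#'
#' Canonical subject-level table for all survival machinery: positive times,
#' binary event indicators (1 = event observed, 0 = censored), an optional
#' group label and arbitrary covariate columns.
#'
#' @param df data.frame with columns `time`, `event`, optionally `id`,
#'   `group` and covariates.
#' @return the validated data.frame, class `survival_table`.
#' @export
as_survival_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (is.null(df$time) || is.null(df$event))
    stop("survival table needs 'time' and 'event' columns")
  if (anyNA(df$time) || any(df$time <= 0))
    stop("times must be positive and non-missing")
  if (!all(df$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (event)")
  class(df) <- unique(c("survival_table", class(df)))
  df
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimator with right censoring (deaths precede censorings at
#' tied times), one curve per group. Groups with zero subjects are dropped.
#'
#' @param st a [as_survival_table()] (or coercible data.frame).
#' @param by column holding the group label; `NULL` fits one pooled curve.
#' @return data.frame `group`, `time`, `n_risk`, `n_event`, `surv` (step
#'   function values at the event/censoring times).
#' @export
km_curve <- function(st, by = "group") {
  st <- as_survival_table(st)
  grp <- if (!is.null(by) && !is.null(st[[by]])) as.character(st[[by]])
         else rep("all", nrow(st))
  fit <- survival::survfit(
    survival::Surv(st$time, st$event) ~ grp, conf.type = "none")
  s <- summary(fit, censored = TRUE)
  group <- if (is.null(s$strata)) rep("all", length(s$time))
           else sub("^grp=", "", as.character(s$strata))
  data.frame(group = group, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, surv = s$surv,
             stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank statistic with a chi-squared df = 1
#' p-value. With zero events the test is undefined and `p = 1` is returned
#' with a warning.
#'
#' @param st a survival table with a group column.
#' @param by column holding the group label (must take exactly two values
#'   among the tested rows).
#' @param groups optional length-2 character vector restricting which two
#'   labels are compared.
#' @return list `chi2`, `p`.
#' @export
logrank <- function(st, by = "group", groups = NULL) {
  st <- as_survival_table(st)
  g <- as.character(st[[by]])
  if (is.null(g)) stop("survival table lacks column '", by, "'")
  if (!is.null(groups)) {
    st <- st[g %in% groups, , drop = FALSE]
    g <- as.character(st[[by]])
  }
  lev <- unique(g)
  if (length(lev) != 2) stop("log-rank needs exactly two non-empty groups")
  if (sum(st$event) == 0) {
    warning("zero events; log-rank undefined, returning p = 1")
    return(list(chi2 = 0, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(st$time, st$event) ~ g)
  chi2 <- sd$chisq
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Cox proportional hazards regression
#'
#' Maximizes the Cox partial likelihood (Efron tie handling) for the given
#' covariates and reports per-covariate hazard ratios with Wald 95%
#' confidence intervals and p-values. Errors on constant covariates, too few
#' events, non-convergence or monotone likelihood (perfect separation),
#' naming the offending covariate.
#'
#' @param st a survival table containing the covariate columns.
#' @param covariates character vector of covariate column names.
#' @param ties tie-handling method passed to [survival::coxph()].
#' @return data.frame `term`, `beta`, `hr`, `ci_lower`, `ci_upper`, `se`,
#'   `p`.
#' @export
cox_fit <- function(st, covariates, ties = "efron") {
  st <- as_survival_table(st)
  miss <- setdiff(covariates, names(st))
  if (length(miss)) stop("covariates absent: ", paste(miss, collapse = ", "))
  for (v in covariates) {
    x <- st[[v]]
    if (!is.numeric(x)) x <- as.numeric(as.factor(x))
    if (stats::sd(x) == 0) stop("constant covariate: ", v)
    st[[v]] <- x
  }
  if (sum(st$event) < length(covariates) + 1)
    stop("need more events than covariates (",
         sum(st$event), " events, ", length(covariates), " covariates)")
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = st, ties = ties,
                         control = survival::coxph.control(
                           eps = 1e-9, iter.max = 100))
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  bad <- !is.finite(beta) | !is.finite(se) | abs(beta) > 15
  if (any(bad))
    stop("Cox fit did not converge (monotone likelihood?) for: ",
         paste(covariates[bad], collapse = ", "))
  z <- beta / se
  data.frame(term = covariates,
             beta = unname(beta),
             hr = unname(exp(beta)),
             ci_lower = unname(exp(beta - 1.96 * se)),
             ci_upper = unname(exp(beta + 1.96 * se)),
             se = unname(se),
             p = unname(2 * stats::pnorm(abs(z), lower.tail = FALSE)),
             row.names = NULL, stringsAsFactors = FALSE)
}
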