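# Survival layer: Kaplan-Meier estimation, log-rank comparison, and Cox
# proportional-hazards modeling with backward Wald elimination. Built on the
# survival package (Efron tie handling).

as_surv_records <- function(records) {
  stopifnot(is.data.frame(records), all(c("time", "event") %in% names(records)))
  if (any(records$time < 0)) stop("survival times must be non-negative")
  if (!all(records$event %in% 0:1)) stop("event must be 0/1")
  records
}

#' Kaplan-Meier estimate with Greenwood standard errors
#'
#' Product-limit estimator of the survival function with Greenwood standard
#' errors; the survival probability at 60 months (5 years) is read from the
#' step function.
#'
#' @param records Data.frame with columns `time` (months) and `event`
#'   (1 = event, 0 = censored).
#' @return Object of class `km_curve`: list with `time`, `survival`, `se`,
#'   `at_risk`, `n`, `survival_at_60_months` (% with its SE in %), and the
#'   underlying `survfit` object.
#' @export
km_estimate <- function(records) {
  records <- as_surv_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records,
                           conf.type = "log")
  sm <- summary(fit, censored = TRUE)
  s60 <- km_survival_at(fit, 60)
  structure(list(time = sm$time, survival = sm$surv, se = sm$std.err,
                 at_risk = sm$n.risk, n = nrow(records),
                 survival_at_60_months = s60, survfit = fit),
            class = "km_curve")
}

# step-function read-out of a survfit curve (and Greenwood SE) at time t
km_survival_at <- function(fit, t) {
  sm <- summary(fit, times = t, extend = TRUE)
  c(surv_pct = 100 * sm$surv, se_pct = 100 * sm$std.err)
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#' @param km A `km_curve`.
#' @param times Numeric vector of times (months).
#' @return Survival probabilities (right-continuous step function).
#' @export
km_at <- function(km, times) {
  sm <- summary(km$survfit, times = times, extend = TRUE)
  sm$surv
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, ", events =",
      sum(x$survfit$n.event), "\n")
  cat(sprintf("  survival at 60 months: %.1f%% +/- %.1f%%\n",
              x$survival_at_60_months["surv_pct"],
              x$survival_at_60_months["se_pct"]))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  plot(x$survfit, xlab = "Months", ylab = "Survival", ...)
  invisible(x)
}

#' Log-rank test between two groups
#'
#' @param records Data.frame with `time` and `event`.
#' @param groups Two-level factor aligned with `records`.
#' @return List with `chisq` (1 df), `p`, and the per-group observed /
#'   expected event counts.
#' @export
logrank_test <- function(records, groups) {
  records <- as_surv_records(records)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L)
    stop("groups must have exactly 2 non-empty levels")
  if (sum(records$event) < 1)
    stop("need at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = cbind(records, g = groups))
  list(chisq = sd$chisq,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Cox proportional-hazards model with backward Wald elimination
#'
#' Fits a Cox model (Efron ties) on all covariates, then repeatedly removes
#' the covariate with the largest Wald p-value at or above `drop_threshold`
#' and refits, until every remaining covariate is significant. Hazard ratios
#' with Wald 95% confidence intervals are reported for retained covariates;
#' eliminated covariates are recorded with the p-value at removal.
#' Covariates with monotone-likelihood/separation symptoms are flagged
#' non-estimable.
#'
#' @param records Data.frame with `time` and `event` (>= 2 events).
#' @param covariates Data.frame of numeric (0/1) covariates, same row order.
#' @param drop_threshold Covariates with Wald p at or above this are dropped
#'   (default 0.05).
#' @return Object of class `cox_fit`: `coefficients` (data.frame `variable`,
#'   `coef`, `se`, `hr`, `ci_low`, `ci_high`, `p`, `estimable`),
#'   `eliminated`, `fit` (the final `coxph`, or NULL if all covariates were
#'   dropped), `drop_threshold`.
#' @export
cox_backward_wald <- function(records, covariates, drop_threshold = 0.05) {
  records <- as_surv_records(records)
  stopifnot(is.data.frame(covariates), nrow(covariates) == nrow(records))
  if (sum(records$event) < 2) stop("need at least 2 events")
  dat <- cbind(records[c("time", "event")], covariates)
  vars <- names(covariates)
  eliminated <- data.frame(variable = character(0), p_removal = numeric(0))
  fit <- NULL
  while (length(vars)) {
    fml <- stats::reformulate(vars, response =
                                quote(survival::Surv(time, event)))
    fit <- survival::coxph(fml, data = dat, ties = "efron")
    sm <- summary(fit)$coefficients
    p <- sm[, "Pr(>|z|)"]
    worst <- which.max(p)
    if (p[worst] < drop_threshold) break
    eliminated <- rbind(eliminated,
                        data.frame(variable = vars[worst],
                                   p_removal = unname(p[worst])))
    vars <- vars[-worst]
    fit <- NULL
  }
  if (length(vars)) {
    sm <- summary(fit)
    co <- sm$coefficients; ci <- sm$conf.int
    coefs <- data.frame(
      variable = rownames(co),
      coef = unname(co[, "coef"]), se = unname(co[, "se(coef)"]),
      hr = unname(co[, "exp(coef)"]),
      ci_low = unname(ci[, "lower .95"]), ci_high = unname(ci[, "upper .95"]),
      p = unname(co[, "Pr(>|z|)"]),
      estimable = unname(abs(co[, "coef"]) < 15 & co[, "se(coef)"] < 50))
  } else {
    coefs <- data.frame(variable = character(0), coef = numeric(0),
                        se = numeric(0), hr = numeric(0), ci_low = numeric(0),
                        ci_high = numeric(0), p = numeric(0),
                        estimable = logical(0))
  }
  structure(list(coefficients = coefs, eliminated = eliminated, fit = fit,
                 drop_threshold = drop_threshold),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat("Cox model (backward Wald elimination, drop at p >=",
      format(x$drop_threshold), ")\n")
  if (!nrow(x$coefficients)) {
    cat("  no covariate retained\n")
  } else {
    tab <- x$coefficients
    tab[2:7] <- lapply(tab[2:7], round, digits)
    print(tab, row.names = FALSE)
  }
  if (nrow(x$eliminated))
    cat("Excluded from the equation (p >=", format(x$drop_threshold), "):",
        paste(x$eliminated$variable, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) {
  stats::setNames(object$coefficients$coef, object$coefficients$variable)
}

#' Point hazard ratio implied by a Wald 95% confidence interval
#'
#' A Wald CI is symmetric on the log-hazard scale, so the point estimate is
#' the geometric mean of the interval bounds: `exp((ln lo + ln hi) / 2)`.
#' Useful as an internal-consistency check of reported hazard ratios.
#'
#' @param ci_low,ci_high Interval bounds, `0 < ci_low <= ci_high`.
#' @return The implied point hazard ratio.
#' @export
hr_from_ci <- function(ci_low, ci_high) {
  if (any(ci_low <= 0) || any(ci_low > ci_high))
    stop("need 0 < ci_low <= ci_high")
  exp((log(ci_low) + log(ci_high)) / 2)
}
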