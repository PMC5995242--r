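# Binary logistic risk model over median-dichotomized morphometric variables
# with backward elimination.

#' Fit a logistic risk model with backward elimination
#'
#' Fits a maximum-likelihood binary logistic regression of a high-risk
#' indicator on dichotomized morphometric features (reference category: the
#' below-median `low` level), then removes, one per step, the term whose
#' likelihood-ratio removal test has the largest p-value at or above
#' `stay_threshold`, until all remaining terms stay. If no term survives an
#' intercept-only model is returned. Terms with unstable estimates
#' (quasi-separation) are flagged non-estimable.
#'
#' @param features Data.frame of factors with levels `low`/`high` (see
#'   [dichotomize_at_median()]) or 0/1 indicators; constant columns are not
#'   allowed.
#' @param risk Binary outcome (0/1, logical, or two-level factor).
#' @param stay_threshold A term is retained while its removal p-value is
#'   below this (default 0.10).
#' @return Object of class `risk_model`: list with `coefficients` (data.frame
#'   `variable`, `B`, `SE`, `Wald`, `p`, `ExpB`, `estimable`), `eliminated`
#'   (variables removed, with their removal p-values), `fit` (the final
#'   `glm`), `stay_threshold`.
#' @export
fit_risk_model <- function(features, risk, stay_threshold = 0.10) {
  stopifnot(is.data.frame(features), nrow(features) > 0)
  y <- risk
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (!all(y %in% 0:1)) stop("risk must be binary")
  if (nrow(features) != length(y))
    stop("features and risk differ in length")
  x <- as.data.frame(lapply(features, function(col) {
    lab <- if (is.numeric(col)) {
      ifelse(col > 0, "high", "low")
    } else as.character(col)
    if (!all(stats::na.omit(lab) %in% c("low", "high")))
      stop("feature levels must be 'low'/'high' (or 0/1)")
    factor(lab, levels = c("low", "high"))
  }))
  const <- vapply(x, function(col) length(unique(stats::na.omit(col))) < 2L,
                  logical(1))
  if (any(const))
    stop("constant feature column(s) after dichotomization: ",
         paste(names(x)[const], collapse = ", "))
  if (nrow(x) <= ncol(x))
    stop("need more observations than features")
  dat <- cbind(x, .risk = y)
  vars <- names(x)
  eliminated <- data.frame(variable = character(0), p_removal = numeric(0))
  repeat {
    fml <- if (length(vars))
      stats::reformulate(vars, response = ".risk") else .risk ~ 1
    fit <- stats::glm(fml, family = stats::binomial(), data = dat)
    if (!length(vars)) break
    lrt <- stats::drop1(fit, test = "LRT")
    pvals <- lrt[["Pr(>Chi)"]][-1]
    names(pvals) <- rownames(lrt)[-1]
    worst <- which.max(pvals)
    if (pvals[worst] < stay_threshold) break
    eliminated <- rbind(eliminated,
                        data.frame(variable = names(pvals)[worst],
                                   p_removal = unname(pvals[worst])))
    vars <- setdiff(vars, names(pvals)[worst])
  }
  sm <- summary(fit)$coefficients
  keep <- rownames(sm) != "(Intercept)"
  B <- sm[keep, "Estimate"]; SE <- sm[keep, "Std. Error"]
  w <- if (any(keep)) wald_statistic(B, SE) else list(statistic = numeric(0),
                                                      p = numeric(0))
  coefs <- data.frame(
    variable = sub("high$", "", rownames(sm)[keep]),
    B = unname(B), SE = unname(SE),
    Wald = unname(w$statistic), p = unname(w$p),
    ExpB = unname(exp(B)),
    estimable = unname(abs(B) < 15 & SE < 50))
  structure(list(coefficients = coefs, eliminated = eliminated, fit = fit,
                 stay_threshold = stay_threshold,
                 intercept = unname(sm["(Intercept)", "Estimate"])),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, digits = 3, ...) {
  cat("Logistic risk model (backward elimination, stay threshold p <",
      format(x$stay_threshold), ")\n")
  if (!nrow(x$coefficients)) {
    cat("  intercept-only model: no feature reached the stay threshold\n")
  } else {
    tab <- x$coefficients
    tab[2:6] <- lapply(tab[2:6], round, digits)
    print(tab, row.names = FALSE)
  }
  if (nrow(x$eliminated))
    cat("Eliminated:", paste(x$eliminated$variable, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.risk_model <- function(object, ...) {
  out <- list(coefficients = object$coefficients,
              eliminated = object$eliminated,
              aic = stats::AIC(object$fit),
              n = length(object$fit$y))
  class(out) <- "summary.risk_model"
  out
}

#' @export
print.summary.risk_model <- function(x, ...) {
  cat("n =", x$n, " AIC =", format(x$aic, digits = 5), "\n")
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' @export
coef.risk_model <- function(object, ...) {
  stats::setNames(object$coefficients$B, object$coefficients$variable)
}

#' @export
predict.risk_model <- function(object, newdata = NULL,
                               type = c("response", "link", "odds_multiplier"),
                               ...) {
  type <- match.arg(type)
  if (type == "odds_multiplier") {
    stopifnot(is.data.frame(newdata))
    return(vapply(seq_len(nrow(newdata)), function(i) {
      ind <- vapply(newdata[i, , drop = FALSE], as.character, character(1))
      risk_odds_product(ind, object)
    }, numeric(1)))
  }
  stats::predict(object$fit, newdata = newdata, type = type)
}
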