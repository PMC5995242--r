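# Inferential layer: median dichotomization, Mann-Whitney contrasts,
# Rice-rule histograms, excess-kurtosis heterogeneity statistics and
# odds-product risk scoring.

#' Dichotomize a numeric variable at its median
#'
#' Labels a value `high` iff it strictly exceeds the median of the finite
#' values; everything else (including values equal to the median, and all
#' values of a constant vector) is `low`. The low group is the reference
#' category downstream.
#'
#' @param values Numeric vector with at least 2 finite values.
#' @return Factor with levels `low`, `high` (NA for non-finite inputs), with
#'   the median as attribute `cutoff`.
#' @export
dichotomize_at_median <- function(values) {
  fin <- is.finite(values)
  if (sum(fin) < 2) stop("need at least 2 finite values")
  med <- stats::median(values[fin])
  lab <- ifelse(values > med, "high", "low")
  lab[!fin] <- NA
  out <- factor(lab, levels = c("low", "high"))
  attr(out, "cutoff") <- med
  out
}

#' Mann-Whitney comparison of a variable between two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test: exact when both groups
#' have at most 8 observations and no ties, otherwise the normal
#' approximation with tie correction and continuity correction. The reported
#' direction is the sign of the median difference (`group` level 2 minus
#' level 1): `"up"`, `"down"` or `"none"`.
#'
#' @param values Numeric vector.
#' @param groups Two-level factor (level 1 = reference, level 2 = adverse
#'   group); both groups must be non-empty.
#' @return List with `p`, `direction`, `statistic` (U of the adverse group),
#'   `n`.
#' @export
compare_groups <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly 2 levels")
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (nlevels(groups) != 2L || any(table(groups) == 0L))
    stop("both groups must be non-empty")
  x <- values[groups == levels(groups)[2]]   # adverse
  y <- values[groups == levels(groups)[1]]   # reference
  exact <- length(x) <= 8 && length(y) <= 8 &&
    !any(duplicated(values))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  dm <- stats::median(x) - stats::median(y)
  list(p = wt$p.value,
       direction = if (dm > 0) "up" else if (dm < 0) "down" else "none",
       statistic = unname(wt$statistic),
       n = c(reference = length(y), adverse = length(x)))
}

#' Contrast every morphometric variable against every binary factor
#'
#' Formatting layer over [compare_groups()]: one row per (variable, factor)
#' pair with the two-sided Mann-Whitney p-value and the direction of the
#' adverse-group shift; an arrow column marks significant contrasts.
#'
#' @param metrics Data.frame of numeric per-sample variables.
#' @param factors Data.frame of binary factors (same row order).
#' @param alpha Significance level for the arrow column.
#' @return Data.frame with columns `variable`, `factor`, `p`, `direction`,
#'   `arrow`.
#' @export
contrast_table <- function(metrics, factors, alpha = 0.05) {
  rows <- list()
  for (v in names(metrics)) for (f in names(factors)) {
    g <- as.factor(factors[[f]])
    res <- tryCatch(compare_groups(metrics[[v]], g), error = function(e) NULL)
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, factor = f, p = res$p, direction = res$direction,
      arrow = if (res$p < alpha)
        switch(res$direction, up = "↑", down = "↓", "-") else "-")
  }
  do.call(rbind, rows)
}

#' Odds ratio from a log-odds coefficient
#' @param B Finite log-odds coefficient.
#' @return `exp(B)`.
#' @export
exp_coefficient <- function(B) {
  if (any(!is.finite(B))) stop("B must be finite")
  exp(B)
}

#' Wald statistic and p-value for a single coefficient
#' @param B Log-odds coefficient.
#' @param SE Standard error (> 0).
#' @return List with `statistic` (`(B/SE)^2`) and `p` (chi-squared, 1 df,
#'   upper tail).
#' @export
wald_statistic <- function(B, SE) {
  if (any(SE <= 0)) stop("SE must be positive")
  w <- (B / SE)^2
  list(statistic = w, p = stats::pchisq(w, df = 1, lower.tail = FALSE))
}

#' Combined odds multiplier from a risk-coefficient table
#'
#' Evaluates the multiplicative risk equation: the product of the odds
#' ratios `Exp(B)` of all variables whose indicator is `high`; variables at
#' their `low` reference level contribute a factor of 1.
#'
#' @param indicators Named character (or factor) vector of `"high"`/`"low"`
#'   states, named by model variable.
#' @param model A [fit_risk_model()] object or a data.frame with columns
#'   `variable` and `ExpB`.
#' @return The odds multiplier (1 when every indicator is low).
#' @export
risk_odds_product <- function(indicators, model) {
  tab <- if (inherits(model, "risk_model")) model$coefficients else model
  stopifnot(all(c("variable", "ExpB") %in% names(tab)))
  if (any(!is.finite(tab$ExpB))) stop("model contains non-finite odds ratios")
  ind <- as.character(indicators)
  names(ind) <- names(indicators)
  bad <- setdiff(names(ind), tab$variable)
  if (length(bad)) stop("unknown model variables: ", paste(bad, collapse = ", "))
  hi <- names(ind)[ind == "high"]
  prod(tab$ExpB[match(hi, tab$variable)])
}

#' Rice's rule for the number of histogram bins
#' @param N Sample size (>= 1).
#' @return `ceiling(2 * N^(1/3))`.
#' @export
rice_bins <- function(N) {
  if (any(N < 1)) stop("N must be at least 1")
  as.integer(ceiling(round(2 * N^(1 / 3), 9)))
}

#' Normalized histogram with Rice-rule binning
#'
#' Builds equal-width bins spanning the data range with the Rice-rule bin
#' count (computed after optional zero discarding, as done for the relative
#' density and relative stained-area variables where zeros mean "no vessels")
#' and normalizes counts to sum to one.
#'
#' @param values Numeric vector.
#' @param discard_zeros Drop exact zeros before binning.
#' @return List of class `histogram_spec`: `n_bins`, `bin_edges`,
#'   `normalized_counts`, `counts`, `n`, `zeros_discarded`.
#' @export
normalized_histogram <- function(values, discard_zeros = FALSE) {
  values <- values[is.finite(values)]
  if (discard_zeros) values <- values[values != 0]
  if (!length(values)) stop("no values left to bin")
  nb <- rice_bins(length(values))
  rng <- range(values)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = nb + 1L)
  counts <- graphics::hist(values, breaks = edges, plot = FALSE,
                           include.lowest = TRUE, right = TRUE)$counts
  structure(list(n_bins = nb, bin_edges = edges,
                 normalized_counts = counts / sum(counts), counts = counts,
                 n = length(values), zeros_discarded = discard_zeros),
            class = "histogram_spec")
}

#' Excess kurtosis with its significance statistic
#'
#' Computes the plain fourth standardized moment minus 3 (population-
#' normalized central moments), its standard error `SEK = sqrt(24 / n)`, and
#' the normality statistic `Zg2 = G2 / SEK`. At 95% significance the
#' distribution is leptokurtic when `Zg2 > 2`, platykurtic when `Zg2 < -2`,
#' and compatible with normality in between.
#'
#' @param values Numeric vector, at least 4 finite values, nonzero variance.
#' @param variable Optional name recorded in the report.
#' @return List of class `kurtosis_report`: `variable`, `n`, `G2`, `SEK`,
#'   `Zg2`, `verdict`.
#' @export
excess_kurtosis <- function(values, variable = deparse(substitute(values))) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4) stop("need at least 4 finite values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("zero variance: kurtosis undefined")
  g2 <- mean((values - m)^4) / m2^2 - 3
  sek <- sqrt(24 / n)
  z <- g2 / sek
  verdict <- if (z > 2) "leptokurtic" else if (z < -2) "platykurtic" else "normal"
  structure(list(variable = variable, n = n, G2 = g2, SEK = sek, Zg2 = z,
                 verdict = verdict),
            class = "kurtosis_report")
}

#' @export
print.kurtosis_report <- function(x, ...) {
  cat(sprintf("%s: n = %d, G2 = %.3f, SEK = %.3f, Zg2 = %.2f (%s)\n",
              x$variable, x$n, x$G2, x$SEK, x$Zg2, x$verdict))
  invisible(x)
}

#' Histogram + kurtosis heterogeneity report over many variables
#'
#' @param metrics Data.frame of numeric variables.
#' @param discard_zero_vars Variable names for which zeros are discarded
#'   (relative density / relative %SA variables by convention).
#' @return Data.frame with one row per variable: `n`, `n_bins`, `G2`, `SEK`,
#'   `Zg2`, `verdict`, `zeros_discarded`.
#' @export
heterogeneity_report <- function(metrics,
                                 discard_zero_vars = grep(
                                   "^rel_", names(metrics), value = TRUE)) {
  rows <- lapply(names(metrics), function(v) {
    dz <- v %in% discard_zero_vars
    vals <- metrics[[v]][is.finite(metrics[[v]])]
    if (dz) vals <- vals[vals != 0]
    if (length(vals) < 4 || stats::var(vals) == 0) return(NULL)
    hs <- normalized_histogram(vals)
    kr <- excess_kurtosis(vals, variable = v)
    data.frame(variable = v, n = kr$n, n_bins = hs$n_bins, G2 = kr$G2,
               SEK = kr$SEK, Zg2 = kr$Zg2, verdict = kr$verdict,
               zeros_discarded = dz)
  })
  do.call(rbind, rows)
}
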