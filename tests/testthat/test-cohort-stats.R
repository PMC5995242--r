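test_that("median dichotomization labels strictly-above-median as high", {
  d <- dichotomize_at_median(c(1, 2, 3, 4))
  expect_equal(as.character(d), c("low", "low", "high", "high"))
  expect_equal(attr(d, "cutoff"), 2.5)
  # degenerate all-equal vector: nothing exceeds the median
  expect_true(all(dichotomize_at_median(rep(7, 5)) == "low"))
  expect_error(dichotomize_at_median(c(1, NA, Inf)), "finite")
})

test_that("median split sizes differ by at most one without ties", {
  set.seed(101)
  for (k in 1:20) {
    x <- rnorm(sample(5:50, 1))
    d <- dichotomize_at_median(x)
    expect_lte(abs(sum(d == "high") - sum(d == "low")), 1)
  }
})

test_that("Mann-Whitney comparison matches exact enumeration", {
  # fully separated groups of 3: 2 of the choose(6,3)=20 equally likely
  # rank assignments are at least as extreme (two-sided exact p = 0.1)
  res <- compare_groups(c(1, 2, 3, 10, 11, 12),
                        factor(rep(c("ref", "adv"), each = 3),
                               levels = c("ref", "adv")))
  expect_equal(res$p, 2 / choose(6, 3))
  expect_equal(res$direction, "up")
  # identical groups: p 1, no direction
  res2 <- compare_groups(rep(c(1, 2, 3), 2), factor(rep(c("a", "b"), each = 3)))
  expect_equal(res2$p, 1)
  expect_equal(res2$direction, "none")
  expect_error(compare_groups(1:4, factor(rep("a", 4))), "2")
})

test_that("Mann-Whitney p is invariant under strictly monotone transforms", {
  set.seed(102)
  x <- rlnorm(30); g <- factor(rep(c("a", "b"), 15))
  p0 <- compare_groups(x, g)$p
  expect_equal(compare_groups(log(x), g)$p, p0)
  expect_equal(compare_groups(x^3, g)$p, p0)
  expect_equal(compare_groups(rank(x), g)$p, p0)
})

test_that("null simulation keeps the Mann-Whitney type-I rate near 5%", {
  set.seed(103)
  rej <- mean(replicate(1000, {
    compare_groups(rnorm(40), factor(rep(c("a", "b"), 20)))$p < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("odds ratios reproduce the published coefficient rows", {
  expect_equal(round(exp_coefficient(0), 3), 1)
  expect_equal(round(exp_coefficient(-2.173), 3), 0.114)
  expect_equal(round(exp_coefficient(-1.706), 3), 0.182)
  w <- wald_statistic(-2.173, 0.810)
  expect_equal(round(w$statistic, 3), 7.197)
  expect_equal(round(w$p, 3), 0.007)
  expect_equal(wald_statistic(0, 1)$statistic, 0)
  expect_equal(wald_statistic(0, 1)$p, 1)
  # the published table prints 4.096 (computed from the unrounded
  # coefficient); the rounded inputs give 4.10
  expect_equal(wald_statistic(-1.310, 0.647)$statistic, 4.10,
               tolerance = 0.005)
  expect_error(wald_statistic(1, 0), "positive")
})

test_that("the odds-product risk score multiplies high-indicator odds ratios", {
  tab <- published_risk_model()
  expect_equal(risk_odds_product(c(), tab), 1)
  expect_equal(
    risk_odds_product(c(rel_sa_pct_intermediate_cap = "high"), tab), 5.916)
  expect_equal(
    risk_odds_product(c(rel_sa_pct_small_cap = "high",
                        branching_total = "high"), tab),
    0.114 * 0.221)
  all_low <- setNames(rep("low", nrow(tab)), tab$variable)
  expect_equal(risk_odds_product(all_low, tab), 1)
  expect_error(risk_odds_product(c(nope = "high"), tab), "unknown")
})

test_that("Rice's rule bin count is the ceiling of 2 N^(1/3)", {
  expect_equal(rice_bins(1000), 20L)
  expect_equal(rice_bins(332), 14L)
  expect_equal(rice_bins(1), 2L)
  expect_equal(rice_bins(8), 4L)
  expect_error(rice_bins(0), "at least 1")
})

test_that("normalized histograms discard zeros and sum to one", {
  h <- normalized_histogram(c(0, 0, 1, 2, 3), discard_zeros = TRUE)
  expect_equal(h$n, 3L)
  expect_equal(h$n_bins, rice_bins(3))
  expect_equal(sum(h$normalized_counts), 1)
  expect_true(h$zeros_discarded)
  # all-equal values collapse to a single occupied bin
  h2 <- normalized_histogram(rep(4, 10))
  expect_equal(max(h2$normalized_counts), 1)
  set.seed(104)
  h3 <- normalized_histogram(rlnorm(500))
  expect_equal(sum(h3$normalized_counts), 1)
  expect_equal(h3$n_bins, rice_bins(500))
})

test_that("excess kurtosis separates normal from heavy-tailed data", {
  expect_equal(round(sqrt(24 / 207), 2), 0.34)
  set.seed(105)
  kn <- excess_kurtosis(rnorm(1e5), "normal")
  expect_equal(kn$G2, 0, tolerance = 0.05)
  expect_equal(kn$SEK, sqrt(24 / 1e5))
  # a perfect normal quantile sample gives a deterministic normal verdict
  kq <- excess_kurtosis(qnorm(ppoints(200)), "normal quantiles")
  expect_equal(kq$verdict, "normal")
  expect_lt(abs(kq$G2), 0.5)
  # standard Laplace has excess kurtosis 3
  lap <- rexp(2e5) * sample(c(-1, 1), 2e5, replace = TRUE)
  kl <- excess_kurtosis(lap, "laplace")
  expect_equal(kl$G2, 3, tolerance = 0.15)
  expect_equal(kl$verdict, "leptokurtic")
  expect_error(excess_kurtosis(rep(2, 10)), "variance")
  expect_error(excess_kurtosis(c(1, 2, 3)), "at least 4")
})

test_that("heterogeneity report flags the heavy-tailed density variables", {
  ch <- default_cohort()
  ev <- ch$samples$vascularized
  rep <- heterogeneity_report(ch$samples[ev, c("density_total",
                                               "rel_density_small_cap")])
  expect_equal(nrow(rep), 2L)
  expect_true(rep$zeros_discarded[rep$variable == "rel_density_small_cap"])
  expect_equal(rep$verdict[rep$variable == "density_total"], "leptokurtic")
})

test_that("backward elimination removes null features and keeps real ones", {
  set.seed(106)
  n <- 500
  x <- data.frame(f1 = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, 0.4)          # outcome independent of f1
  fm <- fit_risk_model(x, y)
  expect_equal(nrow(fm$coefficients), 0L)
  expect_equal(fm$eliminated$variable, "f1")
  # internal consistency of the coefficient table on a real fit
  set.seed(107)
  x2 <- data.frame(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5))
  y2 <- rbinom(n, 1, plogis(-0.3 + 1.2 * x2$a))
  fm2 <- fit_risk_model(x2, y2)
  tab <- fm2$coefficients
  expect_true("a" %in% tab$variable)
  expect_equal(tab$Wald, (tab$B / tab$SE)^2)
  expect_equal(tab$ExpB, exp(tab$B))
  expect_error(fit_risk_model(data.frame(k = rep(1, 10)), rbinom(10, 1, 0.5)),
               "constant")
})

test_that("contrast table mirrors group shifts with direction arrows", {
  set.seed(108)
  n <- 120
  g <- data.frame(grp = rbinom(n, 1, 0.5))
  m <- data.frame(up_var = rnorm(n) + 2 * g$grp,
                  null_var = rnorm(n))
  tab <- contrast_table(m, g)
  row <- tab[tab$variable == "up_var", ]
  expect_lt(row$p, 0.05)
  expect_equal(row$direction, "up")
  expect_equal(row$arrow, "↑")
  expect_equal(tab$arrow[tab$variable == "null_var" & tab$p >= 0.05], "-")
})
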