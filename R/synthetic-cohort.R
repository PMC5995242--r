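# Table-level synthetic patient cohort: per-sample vessel morphometry,
# binary clinical covariates and exponential survival with proportional
# hazards. Vessel descriptors are computed on generated boundary polygons
# (continuous geometry), so the cohort layer is independent of the raster
# segmentation path.

#' Configuration for a synthetic cohort
#'
#' Defaults encode the study conditions the generator emulates: a cohort of
#' 332 tumor samples represented by two 1 mm tissue cylinders each, 37.9% of
#' samples without any stained lymphatic vessel, a heavy-tailed (log-normal)
#' per-sample total vessel density with median 40.6 vessels/mm2 among
#' vascularized samples, 75% of vessels being small capillaries, and
#' exponential event times whose log-hazards mirror the adverse effect of
#' metastatic stage, MYCN amplification, age over 18 months and high total
#' vessel density.
#'
#' @param n_samples Number of samples (>= 2).
#' @param target_median_density Median total density among vascularized
#'   samples, vessels/mm2.
#' @param density_sdlog Log-scale SD of the per-sample density law
#'   (log-normal); 1.1 reproduces a 1-1000 vessels/mm2 range and a strongly
#'   leptokurtic density distribution.
#' @param small_cap_fraction Expected fraction of all vessels in the
#'   small-capillary class; the remaining mass is split 2:2:1 over the
#'   intermediate, large and small-collector classes.
#' @param zero_vessel_fraction Fraction of samples with no stained vessels.
#' @param tissue_area_mm2 Evaluable tissue area per sample (two 1 mm discs
#'   by default).
#' @param open_vessel_fraction Fraction of vessels with broken walls.
#' @param covariate_prevalences Named probabilities of the adverse level of
#'   each binary clinical covariate.
#' @param hazard_log_ratios Named log-hazard increments for the event-time
#'   model; the special name `high_total_density` refers to the
#'   above-median-total-density indicator derived from the generated
#'   morphometry.
#' @param baseline_hazard Events per month at reference levels.
#' @param censoring_rate Target fraction of censored records (independent
#'   exponential censoring; 0 disables censoring).
#' @param seed Integer seed; the generator is fully reproducible.
#' @return Validated config list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 332,
                          target_median_density = 40.6,
                          density_sdlog = 1.1,
                          small_cap_fraction = 0.75,
                          zero_vessel_fraction = 0.379,
                          tissue_area_mm2 = 2 * pi * 0.5^2,
                          open_vessel_fraction = 0.2,
                          covariate_prevalences = c(
                            stage_metastatic = 0.45,
                            age_gt18m = 0.50,
                            unfavorable_histology = 0.85,
                            mycn_amplified = 0.20,
                            del_11q = 0.25,
                            high_risk = 0.45),
                          hazard_log_ratios = c(
                            stage_metastatic = log(4.703),
                            mycn_amplified = log(2.662),
                            age_gt18m = log(3.032),
                            high_total_density = log(2.403)),
                          baseline_hazard = 0.003,
                          censoring_rate = 0.55,
                          seed = 1L) {
  cfg <- list(n_samples = n_samples,
              target_median_density = target_median_density,
              density_sdlog = density_sdlog,
              small_cap_fraction = small_cap_fraction,
              zero_vessel_fraction = zero_vessel_fraction,
              tissue_area_mm2 = tissue_area_mm2,
              open_vessel_fraction = open_vessel_fraction,
              covariate_prevalences = covariate_prevalences,
              hazard_log_ratios = hazard_log_ratios,
              baseline_hazard = baseline_hazard,
              censoring_rate = censoring_rate,
              seed = as.integer(seed))
  probs <- c(cfg$small_cap_fraction, cfg$zero_vessel_fraction,
             cfg$open_vessel_fraction, cfg$covariate_prevalences,
             cfg$censoring_rate)
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (!is.finite(n_samples) || n_samples < 2)
    stop("n_samples must be at least 2")
  if (target_median_density <= 0 || tissue_area_mm2 <= 0 ||
      baseline_hazard <= 0)
    stop("densities, areas and hazards must be positive")
  class(cfg) <- "cohort_config"
  cfg
}

class_probs_from_fraction <- function(small_cap_fraction) {
  rest <- 1 - small_cap_fraction
  c(small_cap_fraction, rest * 0.4, rest * 0.4, rest * 0.2)
}

#' Generate a synthetic patient cohort
#'
#' Draws, per sample: vascularization status, a total vessel density
#' (log-normal among vascularized samples), individual vessel ground truths
#' and their polygon-based morphometry, per-sample quantity aggregates,
#' binary clinical covariates, and event-free / overall survival records from
#' an exponential proportional-hazards model. Identical seeds give identical
#' tables.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort` with `samples` (per-sample
#'   quantity metrics, wide), `vessels` (per-vessel descriptors),
#'   `covariates`, `survival` (sample_id, time, event, endpoint), and the
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    ids <- sprintf("S%04d", seq_len(n))
    vascularized <- stats::runif(n) >= config$zero_vessel_fraction
    density <- ifelse(vascularized,
                      stats::rlnorm(n, log(config$target_median_density),
                                    config$density_sdlog), 0)
    n_vessels <- ifelse(vascularized,
                        pmax(1L, round(density * config$tissue_area_mm2)), 0L)
    cp <- class_probs_from_fraction(config$small_cap_fraction)
    vessel_rows <- vector("list", n)
    sample_rows <- vector("list", n)
    for (i in seq_len(n)) {
      if (n_vessels[i] > 0) {
        tt <- sample_vessel_truths(n_vessels[i], class_probs = cp,
                                   open_vessel_fraction =
                                     config$open_vessel_fraction)
        tt$open_fraction <- 0   # descriptors are measured on closed lumens
        branching <- 2L + stats::rpois(n_vessels[i], 0.3)
        desc <- t(vapply(seq_len(nrow(tt)), function(j) {
          polygon_descriptor_row(
            generate_vessel_shape(tt[j, , drop = FALSE],
                                  n_points = 120L)$xy)
        }, numeric(9)))
        vm <- as.data.frame(desc)
        vm$branching <- branching
        vm$caliber_class <- classify_caliber(vm$length)
        vm$was_closed <- NA
        vm$sample_id <- ids[i]
        vessel_rows[[i]] <- vm
      } else {
        vm <- measure_regions(list())   # empty descriptor frame
      }
      agg <- aggregate_sample(if (n_vessels[i] > 0) vm else vm[0, ],
                              config$tissue_area_mm2)
      q <- agg$quantity
      wide <- stats::setNames(
        as.list(c(q$density, q$sa_pct, q$rel_density, q$rel_sa_pct)),
        c(paste0("density_", q$class), paste0("sa_pct_", q$class),
          paste0("rel_density_", q$class), paste0("rel_sa_pct_", q$class)))
      sample_rows[[i]] <- data.frame(sample_id = ids[i],
                                     vascularized = vascularized[i],
                                     n_vessels = n_vessels[i],
                                     tissue_area_mm2 = config$tissue_area_mm2,
                                     wide)
    }
    samples <- do.call(rbind, sample_rows)
    vessels <- do.call(rbind, vessel_rows[!vapply(vessel_rows, is.null,
                                                  logical(1))])
    if (is.null(vessels)) vessels <- measure_regions(list())
    # binary covariates
    cov <- data.frame(sample_id = ids)
    for (nm in names(config$covariate_prevalences))
      cov[[nm]] <- as.integer(stats::runif(n) <
                                config$covariate_prevalences[[nm]])
    # survival: exponential PH on covariates (+ derived density indicator)
    med_tot <- stats::median(samples$density_total)
    derived <- data.frame(
      high_total_density = as.integer(samples$density_total > med_tot))
    xall <- cbind(cov[-1], derived)
    beta <- config$hazard_log_ratios
    lp <- rep(0, n)
    for (nm in names(beta)) {
      if (!nm %in% names(xall))
        stop("hazard_log_ratios names a missing covariate: ", nm)
      lp <- lp + beta[[nm]] * xall[[nm]]
    }
    surv <- do.call(rbind, lapply(c("EFS", "OS"), function(ep) {
      h0 <- config$baseline_hazard * if (ep == "OS") 0.6 else 1
      rate <- h0 * exp(lp)
      tev <- stats::rexp(n, rate)
      if (config$censoring_rate > 0) {
        crate <- stats::median(rate) * config$censoring_rate /
          (1 - config$censoring_rate)
        cens <- stats::rexp(n, crate)
      } else cens <- rep(Inf, n)
      data.frame(sample_id = ids, time = pmin(tev, cens),
                 event = as.integer(tev <= cens), endpoint = ep)
    }))
    structure(list(samples = samples, vessels = vessels, covariates = cov,
                   survival = surv, config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$samples), "samples,",
      nrow(x$vessels), "vessels;",
      sum(!x$samples$vascularized), "samples without lymphatic vessels\n")
  cat("Median total density (vascularized):",
      format(stats::median(x$samples$density_total[x$samples$vascularized]),
             digits = 4), "vessels/mm2\n")
  invisible(x)
}

#' Write the cohort tables as CSV files
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(samples = file.path(dir, "samples.csv"),
             vessels = file.path(dir, "vessels.csv"),
             covariates = file.path(dir, "covariates.csv"),
             survival = file.path(dir, "survival.csv"))
  utils::write.csv(cohort$samples, paths["samples"], row.names = FALSE)
  utils::write.csv(cohort$vessels, paths["vessels"], row.names = FALSE)
  utils::write.csv(cohort$covariates, paths["covariates"], row.names = FALSE)
  utils::write.csv(cohort$survival, paths["survival"], row.names = FALSE)
  invisible(paths)
}
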