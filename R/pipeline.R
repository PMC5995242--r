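# End-to-end orchestration: synthetic study (or precomputed tables) ->
# morphometry -> inferential battery -> survival, with logged, checksummed,
# reproducible outputs.

#' Published logistic risk-coefficient table
#'
#' The reference logistic-regression coefficient table for pre-treatment
#' high-risk prediction from lymphatic morphometric variables in
#' neuroblastoma (median-dichotomized variables, low half as reference
#' category). Columns: `variable`, `B`, `SE`, `Wald`, `p`, `ExpB`. The table
#' is reproduced as printed in the original report; note that for two rows
#' (`rel_sa_pct_intermediate_cap`, `roundness_large_cap`) the printed
#' `Exp(B)` is not `e^B` of the printed `B` — the printed values are kept
#' verbatim, since the multiplicative risk equation uses them as published.
#'
#' @return Data.frame with one row per retained model variable.
#' @export
published_risk_model <- function() {
  utils::read.csv(system.file("extdata", "published_risk_model.csv",
                              package = "lymphomorph"),
                  stringsAsFactors = FALSE)
}

#' Assemble a pipeline run configuration
#'
#' @param out_dir Output directory for tables, log and checksums.
#' @param seed Integer seed controlling every random draw of the run.
#' @param cohort A [cohort_config()] describing the simulated study (its
#'   `seed` is overridden by `seed`); ignored when precomputed tables are
#'   supplied.
#' @param samples_csv,covariates_csv,survival_csv Optional paths to
#'   precomputed per-sample morphometry, covariate and survival tables
#'   (as written by [write_cohort_csv()]); when given, simulation is skipped.
#' @param image_dir Optional directory of core images (TIFF/PNG) to segment
#'   and measure in addition to the table-level analysis.
#' @param pixel_size Micrometres per pixel for `image_dir` images.
#' @param max_gap Chord-closing tolerance, micrometres.
#' @param n_rendered_cores When simulating, how many cores are additionally
#'   rendered to images and pushed through segmentation (a pipeline
#'   self-check; 0 disables).
#' @param alpha Significance level for contrast arrows and log-rank calls.
#' @param logistic_stay Stay threshold of the logistic backward elimination.
#' @param cox_drop Drop threshold of the Cox backward Wald elimination.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("lymphomorph_run_"),
                       seed = 1L,
                       cohort = cohort_config(),
                       samples_csv = NULL, covariates_csv = NULL,
                       survival_csv = NULL, image_dir = NULL,
                       pixel_size = 0.5, max_gap = 10,
                       n_rendered_cores = 0L,
                       alpha = 0.05, logistic_stay = 0.10, cox_drop = 0.05) {
  stopifnot(max_gap > 0, alpha > 0, alpha < 1)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
              samples_csv = samples_csv, covariates_csv = covariates_csv,
              survival_csv = survival_csv, image_dir = image_dir,
              pixel_size = pixel_size, max_gap = max_gap,
              n_rendered_cores = as.integer(n_rendered_cores),
              alpha = alpha, logistic_stay = logistic_stay,
              cox_drop = cox_drop)
  for (p in c("samples_csv", "covariates_csv", "survival_csv", "image_dir"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("input path does not exist: ", cfg[[p]])
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Every field of [run_config()] may appear in the YAML file; `cohort` is a
#' nested map passed to [cohort_config()].
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort)) y$cohort <- do.call(cohort_config, y$cohort)
  do.call(run_config, y)
}

log_stage <- function(log, stage, msg, t0) {
  line <- sprintf("[%s] %s (%.2fs)", stage, msg,
                  as.numeric(proc.time()[3] - t0))
  c(log, line)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages: (1) obtain per-sample morphometry, covariates
#' and survival records (simulated cohort, or precomputed CSV tables); (2)
#' optionally render and segment synthetic core images as an imaging
#' self-check; (3) inferential battery on vascularized samples — median
#' dichotomization, Mann-Whitney contrast table, backward-elimination
#' logistic risk model, Rice-rule histogram / excess-kurtosis heterogeneity
#' report; (4) survival — Kaplan-Meier with log-rank over the dichotomized
#' total density (samples without lymphatic vascularization carried as their
#' own stratum), and backward-Wald Cox models for each endpoint. All output
#' tables are written as CSV with an MD5 checksum manifest and a stage log;
#' the run is deterministic under a fixed seed. Samples with no stained
#' vessels are excluded from the statistical analysis except for the
#' no-vascularization survival stratum.
#'
#' @param config A [run_config()] (or a YAML path understood by
#'   [read_run_config()]).
#' @return Object of class `pipeline_result` with elements `cohort`,
#'   `contrasts`, `risk_model`, `heterogeneity`, `survival` (per endpoint:
#'   `km`, strata KM curves, `logrank`, `cox`), `files`, `checksums`, `log`,
#'   `evaluable`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[3]
  log <- character(0)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  # stage 1: inputs
  if (!is.null(config$samples_csv)) {
    samples <- utils::read.csv(config$samples_csv)
    covariates <- utils::read.csv(config$covariates_csv)
    survr <- utils::read.csv(config$survival_csv)
    cohort <- list(samples = samples, covariates = covariates,
                   survival = survr)
    log <- log_stage(log, "input", paste("loaded", nrow(samples),
                                         "precomputed samples"), t0)
  } else {
    cc <- config$cohort
    cc$seed <- config$seed
    cohort <- generate_cohort(cc)
    log <- log_stage(log, "simulate",
                     paste("generated", nrow(cohort$samples), "samples,",
                           nrow(cohort$vessels), "vessels"), t0)
  }
  samples <- cohort$samples
  covariates <- cohort$covariates
  survr <- cohort$survival
  # stage 2: imaging self-check / external images
  imaging <- NULL
  if (!is.null(config$image_dir) || config$n_rendered_cores > 0) {
    imaging <- with_seed(config$seed + 1L, {
      imgs <- list()
      if (!is.null(config$image_dir)) {
        paths <- list.files(config$image_dir, "\\.(tif|tiff|png)$",
                            full.names = TRUE, ignore.case = TRUE)
        for (p in paths) imgs[[basename(p)]] <-
            list(image = read_core_image(p), pixel_size = config$pixel_size)
      } else {
        for (k in seq_len(config$n_rendered_cores)) {
          tt <- sample_vessel_truths(30)
          core <- render_core_image(tt, core_diameter = 600,
                                    pixel_size = config$pixel_size)
          imgs[[sprintf("core%02d", k)]] <-
            list(image = core$image, pixel_size = core$pixel_size,
                 truth = core$truth)
        }
      }
      lapply(imgs, function(im) {
        sm <- separate_stain(im$image, im$pixel_size)
        if (!sm$evaluable)
          return(list(evaluable = FALSE, morphometry = NULL))
        rg <- extract_vessel_regions(sm, max_gap = config$max_gap)
        mm <- measure_regions(rg)
        list(evaluable = TRUE, morphometry = mm,
             sample = aggregate_sample(mm, sm$tissue_area_mm2),
             truth = im$truth)
      })
    })
    log <- log_stage(log, "segment",
                     paste("processed", length(imaging), "core images"), t0)
  }
  # stage 3: inferential battery on vascularized samples
  ev <- samples$vascularized
  if (!any(ev)) {
    log <- log_stage(log, "stats", "no evaluable samples - aborting", t0)
    res <- structure(list(evaluable = FALSE, cohort = cohort, log = log,
                          reason = "no sample with lymphatic vascularization"),
                     class = "pipeline_result")
    writeLines(log, file.path(config$out_dir, "run.log"))
    return(res)
  }
  metric_cols <- grep("^(density|sa_pct|rel_density|rel_sa_pct)_",
                      names(samples), value = TRUE)
  metrics <- samples[ev, metric_cols]
  metrics <- metrics[vapply(metrics, function(x) stats::var(x) > 0,
                            logical(1))]
  covs_ev <- covariates[match(samples$sample_id[ev], covariates$sample_id), ]
  inrg <- setdiff(names(covs_ev), c("sample_id", "high_risk"))
  contrasts <- contrast_table(metrics, covs_ev[inrg], alpha = config$alpha)
  feats <- as.data.frame(lapply(metrics, dichotomize_at_median))
  feats <- feats[vapply(feats, function(f) nlevels(droplevels(f)) == 2L,
                        logical(1))]
  rm_fit <- NULL
  if ("high_risk" %in% names(covs_ev) && ncol(feats) &&
      nrow(feats) > ncol(feats) + 5) {
    rm_fit <- fit_risk_model(feats, covs_ev$high_risk,
                             stay_threshold = config$logistic_stay)
  }
  het <- heterogeneity_report(metrics)
  log <- log_stage(log, "stats",
                   paste(nrow(contrasts), "contrasts;",
                         if (is.null(rm_fit)) "no risk model" else
                           paste(nrow(rm_fit$coefficients),
                                 "risk terms retained")), t0)
  # stage 4: survival
  med_tot <- stats::median(samples$density_total[ev])
  stratum <- ifelse(!samples$vascularized, "none",
                    ifelse(samples$density_total > med_tot, "high", "low"))
  surv_res <- lapply(split(survr, survr$endpoint), function(sv) {
    sv <- sv[match(samples$sample_id, sv$sample_id), ]
    km_all <- km_estimate(sv)
    km_strata <- lapply(split(sv, stratum), function(s)
      if (nrow(s) >= 2) km_estimate(s) else NULL)
    lr <- if (all(c("low", "high") %in% stratum)) {
      keep <- stratum %in% c("low", "high")
      logrank_test(sv[keep, ], droplevels(factor(stratum[keep],
                                                 levels = c("low", "high"))))
    }
    covx <- covariates[match(sv$sample_id, covariates$sample_id),
                       setdiff(names(covariates), "sample_id")]
    covx$high_total_density <- as.integer(stratum == "high")
    covx <- covx[vapply(covx, function(x) stats::var(x) > 0, logical(1))]
    cox <- cox_backward_wald(sv, covx, drop_threshold = config$cox_drop)
    list(km = km_all, km_strata = km_strata, logrank = lr, cox = cox)
  })
  log <- log_stage(log, "survival",
                   paste("endpoints:", paste(names(surv_res),
                                             collapse = ", ")), t0)
  # stage 5: outputs
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wr(samples, "samples.csv")
  wr(covariates, "covariates.csv")
  wr(survr, "survival_records.csv")
  wr(contrasts, "contrasts.csv")
  if (!is.null(rm_fit)) wr(rm_fit$coefficients, "risk_model.csv")
  wr(het, "heterogeneity.csv")
  for (ep in names(surv_res)) {
    cx <- surv_res[[ep]]$cox$coefficients
    if (nrow(cx)) wr(cx, paste0("cox_", ep, ".csv"))
    km <- surv_res[[ep]]$km
    wr(data.frame(time = km$time, survival = km$survival, se = km$se,
                  at_risk = km$at_risk), paste0("km_", ep, ".csv"))
  }
  checksums <- tools::md5sum(files)
  utils::write.csv(data.frame(file = basename(names(checksums)),
                              md5 = unname(checksums)),
                   file.path(config$out_dir, "checksums.csv"),
                   row.names = FALSE)
  log <- log_stage(log, "output", paste(length(files), "tables written"), t0)
  writeLines(log, file.path(config$out_dir, "run.log"))
  structure(list(evaluable = TRUE, cohort = cohort, imaging = imaging,
                 contrasts = contrasts, risk_model = rm_fit,
                 heterogeneity = het, survival = surv_res,
                 stratum = stratum, files = files, checksums = checksums,
                 log = log, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:", if (x$evaluable) "complete" else
    paste("non-evaluable -", x$reason), "\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Write a small packaged synthetic study to disk
#'
#' Generates a compact cohort (tables) plus a few rendered core images with
#' their ground truth, sized to run end-to-end quickly: the demo input for
#' [run_pipeline()] and the CLI.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param n_samples Cohort size.
#' @param n_images Number of rendered cores.
#' @return Named list of written paths, invisibly.
#' @export
generate_demo_dataset <- function(seed, out_dir, n_samples = 40L,
                                  n_images = 2L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(cohort_config(n_samples = n_samples,
                                          seed = seed))
  paths <- write_cohort_csv(cohort, out_dir)
  imgs <- character(0)
  truths <- list()
  with_seed(seed + 1L, {
    for (k in seq_len(n_images)) {
      tt <- sample_vessel_truths(25)
      core <- render_core_image(tt, core_diameter = 500, pixel_size = 0.5)
      p <- file.path(out_dir, sprintf("core%02d.png", k))
      write_core_image(core, p)
      core$truth$image <- basename(p)
      truths[[k]] <- core$truth
      imgs <- c(imgs, p)
    }
  })
  if (length(truths)) {
    tp <- file.path(out_dir, "image_ground_truth.csv")
    utils::write.csv(do.call(rbind, truths), tp, row.names = FALSE)
    paths <- c(paths, ground_truth = tp)
  }
  cfg <- list(seed = as.integer(seed), pixel_size = 0.5, max_gap = 10,
              samples_csv = unname(paths[["samples"]]),
              covariates_csv = unname(paths[["covariates"]]),
              survival_csv = unname(paths[["survival"]]))
  yp <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, yp)
  invisible(c(as.list(paths), list(images = imgs, config = yp)))
}
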