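# Per-vessel descriptor suite, caliber classification and per-sample
# aggregation. All sizes are measured on the internal lumen, regardless of
# wall thickness; lengths/areas are in micrometres / square micrometres.

#' Assign a vessel to a caliber class by its longest axis
#'
#' Classes are half-open at the lower edge: small capillaries \[5, 15),
#' intermediate capillaries \[15, 20), large capillaries \[20, 50), small
#' collectors \[50, 200\]. A vessel of exactly 15 micrometres is an
#' intermediate capillary.
#'
#' @param length Longest axis (maximum Feret diameter), micrometres.
#' @return Factor with levels `small_cap`, `intermediate_cap`, `large_cap`,
#'   `small_collector`.
#' @export
classify_caliber <- function(length) {
  if (any(!is.finite(length)) || any(length < 5 | length > 200))
    stop("vessel longest axis outside the considered range [5, 200]")
  cut(length, breaks = CALIBER_BREAKS, labels = CALIBER_LEVELS,
      right = FALSE, include.lowest = TRUE)
}

# descriptors common to the raster and polygon measurement paths
shape_descriptors <- function(area, perimeter, feret_max, feret_min,
                              hull_area, hull_perimeter) {
  data.frame(
    area = area,
    length = feret_max,
    width = feret_min,
    perimeter = perimeter,
    roundness = perimeter^2 / (4 * pi * area),
    aspect = feret_max / pmax(feret_min, .Machine$double.eps),
    perimeter_ratio = pmax(1, perimeter / hull_perimeter),
    deformity = pmin(1, pmax(0, 1 - area / hull_area)),
    shape_factor = feret_max^2 / (4 * area / pi)
  )
}

# fast numeric-vector descriptor row for a closed polygon (cohort generator
# hot path; same formulas as shape_descriptors)
polygon_descriptor_row <- function(xy) {
  area <- polygon_area(xy)
  per <- polygon_perimeter(xy)
  fer <- feret_diameters(xy)
  hull <- convex_hull(xy)
  ha <- polygon_area(hull)
  hp <- polygon_perimeter(hull)
  c(area = area, length = fer[["max"]], width = fer[["min"]],
    perimeter = per,
    roundness = per^2 / (4 * pi * area),
    aspect = fer[["max"]] / max(fer[["min"]], .Machine$double.eps),
    perimeter_ratio = max(1, per / hp),
    deformity = min(1, max(0, 1 - area / ha)),
    shape_factor = fer[["max"]]^2 / (4 * area / pi))
}

# ordered outer boundary of a single-object logical mask (row, col pixels)
mask_contour <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))[[1]]
  # ocontour returns 0-based (x, y) = (row-1, col-1) of the matrix as imaged;
  # only ordered 8-connectivity matters here
  oc
}

#' Measure the descriptor suite on one vessel region
#'
#' Computes lumen-based size descriptors (area; length and width as the
#' maximum / minimum Feret diameter; boundary perimeter with corner-corrected
#' chain weights) and shape descriptors: roundness `P^2 / (4 pi A)`, aspect
#' `length / width`, perimeter ratio (perimeter over convex-hull perimeter),
#' deformity (`1 - A / hull area`), shape factor (`length^2 / (4 A / pi)`),
#' and branching as the endpoint count of the lumen's morphological skeleton
#' (a simple tube scores 2).
#'
#' @param region A vessel region from [extract_vessel_regions()]: a list with
#'   at least `lumen` (cropped logical matrix) and `pixel_size`.
#' @return One-row data.frame of class descriptors plus `caliber_class` and
#'   `was_closed`.
#' @export
measure_vessel <- function(region) {
  mask <- region$lumen
  ps <- region$pixel_size
  npx <- sum(mask)
  if (npx < 1) stop("degenerate region: empty lumen")
  ct <- mask_contour(mask)
  # +0.5 px compensates the half-pixel shrinkage of center-to-center spans
  fer <- (feret_diameters(ct) + 0.5) * ps
  per <- chain_perimeter(ct) * ps
  hull <- convex_hull(ct)
  hull_area <- polygon_area(hull) * ps^2
  hull_per <- polygon_perimeter(hull) * ps
  d <- shape_descriptors(area = npx * ps^2, perimeter = per,
                         feret_max = fer[["max"]], feret_min = fer[["min"]],
                         hull_area = hull_area, hull_perimeter = hull_per)
  skel <- thin_mask(mask)
  d$branching <- max(2L, nrow(skeleton_endpoints(skel)))
  d$caliber_class <- classify_caliber(d$length)
  d$was_closed <- isTRUE(region$was_closed)
  d
}

#' Measure the descriptor suite on a closed polygon
#'
#' Continuous-geometry counterpart of [measure_vessel()] used by the
#' table-level cohort generator (no rasterization involved). Branching is not
#' derivable from a simple polygon and must be supplied.
#'
#' @param xy Closed polygon vertex matrix, micrometres.
#' @param branching Skeleton endpoint count to record (default 2, a simple
#'   tube).
#' @return One-row descriptor data.frame as in [measure_vessel()].
#' @export
polygon_morphometry <- function(xy, branching = 2L) {
  fer <- feret_diameters(xy)
  hull <- convex_hull(xy)
  d <- shape_descriptors(area = polygon_area(xy),
                         perimeter = polygon_perimeter(xy),
                         feret_max = fer[["max"]], feret_min = fer[["min"]],
                         hull_area = polygon_area(hull),
                         hull_perimeter = polygon_perimeter(hull))
  d$branching <- branching
  d$caliber_class <- classify_caliber(d$length)
  d$was_closed <- NA
  d
}

#' Aggregate per-vessel morphometry into per-sample quantity metrics
#'
#' Produces the per-class and total quantity metrics: density (vessels per
#' square millimetre of tissue), percentage of stained area (%SA, lumen area
#' over tissue area), and the relative share of each class in the total
#' density and total %SA. Per-class medians of every size/shape descriptor
#' are attached. A sample with no vessels is flagged
#' `no_vascularization = TRUE` with all-zero quantities.
#'
#' @param vessels Data.frame of per-vessel rows ([measure_vessel()] /
#'   [polygon_morphometry()]); may have zero rows.
#' @param tissue_area_mm2 Evaluable tissue area, square millimetres (> 0).
#' @return Object of class `sample_morphometry`: list with `quantity` (one
#'   row per class plus `total`), `medians`, `n_vessels`,
#'   `no_vascularization`, `tissue_area_mm2`.
#' @export
aggregate_sample <- function(vessels, tissue_area_mm2) {
  if (!is.finite(tissue_area_mm2) || tissue_area_mm2 <= 0)
    stop("tissue_area_mm2 must be positive")
  cls <- factor(character(0), levels = CALIBER_LEVELS)
  if (nrow(vessels)) cls <- factor(vessels$caliber_class, levels = CALIBER_LEVELS)
  n_by <- table(cls)
  area_by <- tapply(vessels$area, cls, sum, default = 0)
  area_by[is.na(area_by)] <- 0
  density <- as.numeric(n_by) / tissue_area_mm2
  sa_pct <- 100 * as.numeric(area_by) / (tissue_area_mm2 * 1e6)
  tot_density <- sum(density)
  tot_sa <- sum(sa_pct)
  rel_density <- if (tot_density > 0) 100 * density / tot_density else rep(0, 4)
  rel_sa <- if (tot_sa > 0) 100 * sa_pct / tot_sa else rep(0, 4)
  quantity <- data.frame(
    class = c(CALIBER_LEVELS, "total"),
    n = c(as.numeric(n_by), sum(n_by)),
    density = c(density, tot_density),
    sa_pct = c(sa_pct, tot_sa),
    rel_density = c(rel_density, if (tot_density > 0) 100 else 0),
    rel_sa_pct = c(rel_sa, if (tot_sa > 0) 100 else 0))
  desc_cols <- c("area", "length", "width", "perimeter", "roundness",
                 "aspect", "perimeter_ratio", "deformity", "shape_factor",
                 "branching")
  med <- lapply(c(as.list(CALIBER_LEVELS), list(CALIBER_LEVELS)), function(lv) {
    sub <- vessels[as.character(cls) %in% lv, desc_cols, drop = FALSE]
    if (!nrow(sub)) return(rep(NA_real_, length(desc_cols)))
    vapply(sub, stats::median, numeric(1))
  })
  medians <- as.data.frame(do.call(rbind, med))
  names(medians) <- desc_cols
  medians <- cbind(class = c(CALIBER_LEVELS, "total"), medians)
  structure(list(quantity = quantity, medians = medians,
                 n_vessels = nrow(vessels),
                 no_vascularization = nrow(vessels) == 0L,
                 tissue_area_mm2 = tissue_area_mm2),
            class = "sample_morphometry")
}

#' @export
print.sample_morphometry <- function(x, ...) {
  cat("Sample morphometry:", x$n_vessels, "vessels in",
      format(x$tissue_area_mm2, digits = 4), "mm2 of tissue\n")
  if (x$no_vascularization) cat("  (no lymphatic vascularization)\n")
  print(x$quantity, row.names = FALSE, digits = 4)
  invisible(x)
}
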