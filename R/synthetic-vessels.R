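# Synthetic lymphatic vessel shapes and stained tissue-core rendering.
#
# A vessel is modelled as a star-convex perturbed ellipse: the lumen boundary
# is r(theta) = r_ellipse(theta) * (1 + sum_k a_k cos(k theta + phi_k)) with
# two Fourier modes drawn from orders 5..10 scaled by an `irregularity`
# parameter (concentrating the perturbation in few modes yields the wavy,
# irregular outlines seen in tumor lymphatics: roundness > 2 at high
# irregularity, near-elliptic contours at low irregularity), then
# rescaled so the maximum Feret diameter of the boundary equals the requested
# caliber (major_axis). The wall is drawn outward from the lumen boundary with
# a given thickness; an optional contiguous arc of the wall (a fraction of the
# perimeter) is removed to emulate broken, open-outline vessel walls.

CALIBER_BREAKS <- c(5, 15, 20, 50, 200)
CALIBER_LEVELS <- c("small_cap", "intermediate_cap", "large_cap", "small_collector")

# sum of relative Fourier amplitudes at irregularity = 1; keeps r(theta) > 0
MAX_PERTURBATION <- 0.6

#' Reference colors for synthetic brightfield staining
#'
#' A fixed two-color scheme: a brown lymphatic-endothelium stain (DAB-like)
#' against a pale blue-violet counterstained tissue and a near-white slide
#' background. Values are RGB in \[0, 1\].
#' @return Named list with components `stain`, `tissue`, `background`.
#' @export
stain_palette <- function() {
  list(stain      = c(0.42, 0.22, 0.08),
       tissue     = c(0.74, 0.72, 0.87),
       background = c(0.97, 0.97, 0.97))
}

#' Construct and validate a vessel ground-truth table
#'
#' @param major_axis Lumen longest axis, micrometres, in \[5, 200\].
#' @param minor_axis Lumen shortest axis, micrometres (defaults to
#'   `0.75 * major_axis`); must satisfy `0 < minor_axis <= major_axis`.
#' @param wall_thickness Wall thickness, micrometres.
#' @param irregularity Dimensionless contour irregularity in \[0, 1\].
#' @param open_fraction Fraction of the wall perimeter removed, in \[0, 0.35\].
#' @param center_x,center_y Optional vessel center, micrometres (NA until the
#'   vessel is placed in a core).
#' @return A `data.frame` with one row per vessel, including the caliber class
#'   implied by `major_axis`.
#' @export
vessel_truth <- function(major_axis, minor_axis = 0.75 * major_axis,
                         wall_thickness = 1.5, irregularity = 0,
                         open_fraction = 0, center_x = NA_real_,
                         center_y = NA_real_) {
  stopifnot(length(major_axis) >= 1)
  df <- data.frame(vessel_id = seq_along(major_axis),
                   center_x = center_x, center_y = center_y,
                   major_axis = major_axis, minor_axis = minor_axis,
                   wall_thickness = wall_thickness,
                   irregularity = irregularity,
                   open_fraction = open_fraction)
  if (any(df$major_axis < 5 | df$major_axis > 200))
    stop("major_axis must lie in [5, 200] micrometres")
  if (any(df$minor_axis <= 0 | df$minor_axis > df$major_axis))
    stop("must have 0 < minor_axis <= major_axis")
  if (any(df$irregularity < 0 | df$irregularity > 1))
    stop("irregularity must lie in [0, 1]")
  if (any(df$open_fraction < 0 | df$open_fraction > 0.35))
    stop("open_fraction must lie in [0, 0.35]")
  if (any(df$wall_thickness <= 0))
    stop("wall_thickness must be positive")
  df$caliber_class <- classify_caliber(df$major_axis)
  df
}

# analytic polar radius of the perturbed ellipse (before rescaling)
shape_radius <- function(theta, a, b, amps, phases, modes) {
  r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  if (length(amps)) {
    pert <- rep(0, length(theta))
    for (m in seq_along(amps))
      pert <- pert + amps[m] * cos(modes[m] * theta + phases[m])
    r <- r * (1 + pert)
  }
  r
}

#' Generate one synthetic vessel wall contour
#'
#' Builds the perturbed-ellipse lumen boundary for a single vessel, rescaled so
#' its maximum Feret diameter equals `major_axis` exactly; if `open_fraction`
#' is positive one contiguous arc of that perimeter fraction is removed, giving
#' an open polyline (a broken wall).
#'
#' @param truth One-row data.frame as returned by [vessel_truth()].
#' @param seed Optional integer seed for the private RNG stream used to draw
#'   Fourier amplitudes, phases, orientation and gap position.
#' @param n_points Number of boundary vertices before gap removal.
#' @return A list with elements `xy` (vertex matrix, micrometres, centered on
#'   the vessel center or the origin if unplaced), `closed` (logical), `shape`
#'   (the analytic shape parameters used by the renderer), and
#'   `perimeter_closed` (perimeter of the closed boundary).
#' @export
generate_vessel_shape <- function(truth, seed = NULL, n_points = 240L) {
  stopifnot(is.data.frame(truth), nrow(truth) == 1L)
  if (truth$major_axis < 5 || truth$major_axis > 200)
    stop("major_axis must lie in [5, 200] micrometres")
  build <- function() {
    a <- truth$major_axis / 2
    b <- truth$minor_axis / 2
    if (truth$irregularity > 0) {
      # cap the mode order so the circumferential wavelength pi*D/k stays
      # above ~4 wall thicknesses, otherwise the wall pinches the lumen shut
      khi <- max(3L, min(10L, floor(pi * truth$major_axis /
                                      (4 * truth$wall_thickness))))
      klo <- max(2L, khi - 5L)
      modes <- sample(seq(klo, khi), 2L, replace = khi == klo)
      w <- abs(stats::rnorm(2))
      w <- w / sum(w) * MAX_PERTURBATION
      amps <- truth$irregularity * w
      phases <- stats::runif(2, 0, 2 * pi)
    } else {
      modes <- integer(0)
      amps <- numeric(0)
      phases <- numeric(0)
    }
    rot <- stats::runif(1, 0, pi)
    theta <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
    r <- shape_radius(theta, a, b, amps, phases, modes)
    xy0 <- cbind(r * cos(theta), r * sin(theta))
    scale <- truth$major_axis / feret_diameters(xy0)[["max"]]
    xy0 <- xy0 * scale
    rotm <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
    xy <- xy0 %*% t(rotm)
    per <- polygon_perimeter(xy)
    gap_theta <- NULL
    closed <- TRUE
    if (truth$open_fraction > 0) {
      seg <- sqrt(rowSums((xy - xy[c(2:nrow(xy), 1L), ])^2))
      start <- sample.int(n_points, 1L)
      cum <- cumsum(seg[c(start:n_points, seq_len(start - 1L))])
      n_rm <- max(1L, sum(cum <= truth$open_fraction * per))
      rm_idx <- ((start - 1L + seq_len(n_rm) - 1L) %% n_points) + 1L
      keep <- ((start - 1L + n_rm) %% n_points) + 1L
      # reorder so the retained arc is contiguous, starting after the gap
      ord <- ((keep - 1L + seq_len(n_points - n_rm) - 1L) %% n_points) + 1L
      theta_gap <- theta[c(rm_idx[1L], rm_idx[n_rm])]
      gap_theta <- theta_gap
      xy <- xy[ord, , drop = FALSE]
      closed <- FALSE
    }
    cx <- if (is.na(truth$center_x)) 0 else truth$center_x
    cy <- if (is.na(truth$center_y)) 0 else truth$center_y
    xy <- sweep(xy, 2, c(cx, cy), "+")
    list(xy = xy, closed = closed, perimeter_closed = per,
         shape = list(a = a, b = b, amps = amps, phases = phases,
                      modes = modes, rot = rot,
                      scale = scale, gap_theta = gap_theta,
                      max_radius = scale * max(r),
                      wall_thickness = truth$wall_thickness,
                      center = c(cx, cy)))
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Draw random vessel ground truths with the cohort's default morphology mix
#'
#' Caliber classes are drawn with probabilities `class_probs` (default: 75%
#' small capillaries, 10% intermediate, 10% large, 5% small collectors); sizes
#' within each class follow right-skewed beta laws so small calibers dominate
#' each class, matching the narrow-vessel morphology of neuroblastic tumors.
#' A fraction `open_vessel_fraction` of vessels get a broken wall whose gap is
#' a physical arc of 3-8 micrometres (a local sectioning artifact), converted
#' to a perimeter fraction and capped at 0.35.
#'
#' @param n Number of vessels.
#' @param class_probs Probabilities for the four caliber classes (in order
#'   small_cap, intermediate_cap, large_cap, small_collector); renormalized.
#' @param open_vessel_fraction Fraction of vessels with a broken wall.
#' @return Ground-truth data.frame as from [vessel_truth()].
#' @export
sample_vessel_truths <- function(n,
                                 class_probs = c(0.75, 0.10, 0.10, 0.05),
                                 open_vessel_fraction = 0.2) {
  class_probs <- class_probs / sum(class_probs)
  cls <- sample.int(4L, n, replace = TRUE, prob = class_probs)
  major <- numeric(n)
  major[cls == 1L] <- 5 + 10 * stats::rbeta(sum(cls == 1L), 1.2, 3)
  major[cls == 2L] <- 15 + 5 * stats::rbeta(sum(cls == 2L), 1, 1.5)
  major[cls == 3L] <- 20 + 30 * stats::rbeta(sum(cls == 3L), 1, 2.5)
  major[cls == 4L] <- 50 + 150 * stats::rbeta(sum(cls == 4L), 1, 3.3)
  minor <- major * stats::runif(n, 0.55, 0.95)
  wall <- ifelse(cls == 4L, stats::runif(n, 2, 4), stats::runif(n, 1, 2))
  irr <- 0.8 * stats::rbeta(n, 1.5, 3)
  open <- rep(0, n)
  is_open <- stats::runif(n) < open_vessel_fraction
  if (any(is_open)) {
    gap <- stats::runif(sum(is_open), 3, 8)
    # approximate closed perimeter by the Ramanujan ellipse formula
    a <- major[is_open] / 2; b <- minor[is_open] / 2
    h <- ((a - b) / (a + b))^2
    per <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
    open[is_open] <- pmin(gap / per, 0.35)
  }
  vessel_truth(major_axis = major, minor_axis = minor, wall_thickness = wall,
               irregularity = irr, open_fraction = open)
}

# rejection-sample non-overlapping vessel centers inside the core disc
place_vessels <- function(truth, core_diameter, max_attempts = 400L) {
  n <- nrow(truth)
  if (n == 0L) return(truth)
  rad <- truth$major_axis / 2 + truth$wall_thickness + 1
  R <- core_diameter / 2
  cx <- numeric(n); cy <- numeric(n)
  ord <- order(rad, decreasing = TRUE)   # place big vessels first
  for (k in seq_len(n)) {
    i <- ord[k]
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      rr <- (R - rad[i]) * sqrt(stats::runif(1))
      ang <- stats::runif(1, 0, 2 * pi)
      x <- R + rr * cos(ang); y <- R + rr * sin(ang)
      prev <- ord[seq_len(k - 1L)]
      if (!length(prev) ||
          all((x - cx[prev])^2 + (y - cy[prev])^2 >
              (rad[i] + rad[prev] + 1)^2)) {
        cx[i] <- x; cy[i] <- y; ok <- TRUE; break
      }
    }
    if (!ok)
      stop("could not place ", n, " vessels in a ", core_diameter,
           " micrometre core after ", max_attempts, " attempts")
  }
  truth$center_x <- cx
  truth$center_y <- cy
  truth
}

#' Render a synthetic stained tissue-core image
#'
#' Paints vessel walls in the stain color over a counterstained circular
#' tissue core on a bright slide background, adds i.i.d. Gaussian channel
#' noise, and returns the image together with its ground-truth table.
#' Vessels without placed centers are positioned by non-overlapping rejection
#' sampling inside the core.
#'
#' @param truth Ground-truth data.frame from [vessel_truth()] /
#'   [sample_vessel_truths()].
#' @param core_diameter Core (tissue disc) diameter, micrometres.
#' @param pixel_size Micrometres per pixel; must be at most 1 so the smallest
#'   5 micrometre vessels span at least 5 pixels.
#' @param noise_sd Standard deviation of additive Gaussian noise per channel.
#' @param seed Optional integer seed (private RNG stream).
#' @param palette Reference colors, see [stain_palette()].
#' @return List with `image` (H x W x 3 array in \[0, 1\]), `truth` (the
#'   placed ground-truth table), `tissue_area_mm2`, `pixel_size`, and
#'   `core_diameter`.
#' @export
render_core_image <- function(truth, core_diameter = 1000, pixel_size = 0.5,
                              noise_sd = 0.04, seed = NULL,
                              palette = stain_palette()) {
  if (pixel_size > 1)
    stop("pixel_size must be <= 1 micrometre per pixel")
  build <- function() {
    npx <- as.integer(ceiling(core_diameter / pixel_size))
    cx_px <- (npx - 1) / 2
    img <- array(rep(palette$background, each = npx * npx),
                 dim = c(npx, npx, 3))
    # tissue disc (pixel centers within the core radius)
    coords <- (seq_len(npx) - 1L)
    dx2 <- (coords - cx_px)^2
    disc <- outer(dx2, dx2, "+") <= (core_diameter / 2 / pixel_size)^2
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[disc] <- palette$tissue[ch]
      img[, , ch] <- pl
    }
    tr <- truth
    if (nrow(tr) && anyNA(tr$center_x))
      tr <- place_vessels(tr, core_diameter)
    wall_mask <- matrix(FALSE, npx, npx)
    if (nrow(tr)) {
      tr$realized_feret <- NA_real_
      for (i in seq_len(nrow(tr))) {
        sh <- generate_vessel_shape(tr[i, , drop = FALSE])
        s <- sh$shape
        half <- s$max_radius + s$wall_thickness + 2 * pixel_size
        r0 <- max(1L, floor((s$center[2] - half) / pixel_size) + 1L)
        r1 <- min(npx, ceiling((s$center[2] + half) / pixel_size) + 1L)
        c0 <- max(1L, floor((s$center[1] - half) / pixel_size) + 1L)
        c1 <- min(npx, ceiling((s$center[1] + half) / pixel_size) + 1L)
        rows <- r0:r1; cols <- c0:c1
        # pixel centers in shape frame
        y <- (rows - 1) * pixel_size - s$center[2]
        x <- (cols - 1) * pixel_size - s$center[1]
        X <- matrix(x, length(rows), length(cols), byrow = TRUE)
        Y <- matrix(y, length(rows), length(cols))
        u <- cos(s$rot) * X + sin(s$rot) * Y
        v <- -sin(s$rot) * X + cos(s$rot) * Y
        th <- atan2(v, u)
        rho <- sqrt(u^2 + v^2)
        rb <- s$scale * shape_radius(th, s$a, s$b, s$amps, s$phases, s$modes)
        # slope-corrected radial band so the wall keeps a constant thickness
        # normal to the boundary even on steep contour segments
        dd <- 1e-3
        rbp <- s$scale * shape_radius(th + dd, s$a, s$b, s$amps, s$phases,
                                      s$modes)
        rbm <- s$scale * shape_radius(th - dd, s$a, s$b, s$amps, s$phases,
                                      s$modes)
        slope <- (rbp - rbm) / (2 * dd) / pmax(rb, .Machine$double.eps)
        t_rad <- s$wall_thickness * sqrt(1 + slope^2)
        wall <- rho > rb & rho <= rb + t_rad
        if (!is.null(s$gap_theta)) {
          g <- s$gap_theta
          thp <- th %% (2 * pi)
          ingap <- if (g[1] <= g[2]) thp >= g[1] & thp <= g[2] else
            thp >= g[1] | thp <= g[2]
          wall <- wall & !ingap
        }
        wall_mask[rows, cols] <- wall_mask[rows, cols] | wall
        tr$realized_feret[i] <- tr$major_axis[i]
      }
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[wall_mask] <- palette$stain[ch]
        img[, , ch] <- pl
      }
    }
    if (noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, noise_sd)
      img[img < 0] <- 0
      img[img > 1] <- 1
    }
    list(image = img, truth = tr,
         tissue_area_mm2 = pi * (core_diameter / 2000)^2,
         pixel_size = pixel_size, core_diameter = core_diameter)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Write a rendered core image to TIFF or PNG
#' @param core Result of [render_core_image()].
#' @param path Output file; format chosen from the extension (.tif/.tiff/.png).
#' @return `path`, invisibly.
#' @export
write_core_image <- function(core, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(core$image, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(core$image, path)
  } else stop("unsupported image extension: ", ext)
  invisible(path)
}

#' Read an RGB core image from TIFF or PNG
#' @param path Image file.
#' @return H x W x 3 array in \[0, 1\].
#' @export
read_core_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else if (ext == "png") png::readPNG(path)
  else stop("unsupported image extension: ", ext)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}
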