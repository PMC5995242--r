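# Stain separation and vessel-region extraction, including chord-closing of
# open-outline vessel walls.

#' Separate the stain channel from a brightfield RGB image
#'
#' Classifies every pixel to the nearest of three reference colors (stain,
#' counterstained tissue, slide background) in RGB space. The stained-pixel
#' mask and the evaluable tissue area (all non-background pixels) are
#' returned; an image with no tissue is flagged non-evaluable.
#'
#' @param image H x W x 3 array in \[0, 1\] (see [read_core_image()]).
#' @param pixel_size Micrometres per pixel.
#' @param palette Reference colors, see [stain_palette()].
#' @return Object of class `stain_mask`: list with `mask` (logical matrix of
#'   stained pixels), `tissue` (logical matrix of tissue pixels, stained
#'   included), `tissue_area_mm2`, `pixel_size`, `evaluable`.
#' @export
separate_stain <- function(image, pixel_size, palette = stain_palette()) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] >= 3L)
  nr <- dim(image)[1]; nc <- dim(image)[2]
  refs <- rbind(palette$stain, palette$tissue, palette$background)
  d <- matrix(0, nr * nc, 3)
  for (k in 1:3) {
    dk <- 0
    for (ch in 1:3) dk <- dk + (as.vector(image[, , ch]) - refs[k, ch])^2
    d[, k] <- dk
  }
  cls <- max.col(-d)
  mask <- matrix(cls == 1L, nr, nc)
  tissue <- matrix(cls != 3L, nr, nc)
  area <- sum(tissue) * pixel_size^2 / 1e6
  structure(list(mask = mask, tissue = tissue, tissue_area_mm2 = area,
                 pixel_size = pixel_size, evaluable = area > 0),
            class = "stain_mask")
}

#' @export
print.stain_mask <- function(x, ...) {
  cat("Stain mask:", sum(x$mask), "stained px,",
      format(x$tissue_area_mm2, digits = 4), "mm2 tissue",
      if (!x$evaluable) "(non-evaluable)" else "", "\n")
  invisible(x)
}

curve_is_closed <- function(xy) {
  isTRUE(attr(xy, "closed")) ||
    (nrow(xy) > 2L && all(xy[1, ] == xy[nrow(xy), ]))
}

#' Close open-outline contours by chord joining
#'
#' Already-closed contours pass through unchanged. Open curves are closed by
#' repeatedly joining the mutually nearest pair of free endpoints whose
#' distance is at most `max_gap` (ties broken by smaller distance, then lower
#' endpoint index): the two ends of one curve are joined by a straight chord,
#' and ends of different curves are concatenated. Curves left open when no
#' join is possible are discarded with a message.
#'
#' @param contours List of n x 2 vertex matrices (micrometres). A contour is
#'   treated as closed if its first and last vertices coincide or it carries
#'   attribute `closed = TRUE`.
#' @param max_gap Maximum endpoint distance to bridge, micrometres.
#' @return List of closed polygon matrices, each with attribute `was_closed`
#'   (`TRUE` if the contour was algorithmically closed) and `closed = TRUE`.
#'   Attribute `n_discarded` on the list counts dropped open contours.
#' @export
close_open_outlines <- function(contours, max_gap) {
  stopifnot(max_gap > 0)
  curves <- lapply(contours, function(xy) {
    cl <- curve_is_closed(xy)
    if (cl && nrow(xy) > 1L && all(xy[1, ] == xy[nrow(xy), ]))
      xy <- xy[-nrow(xy), , drop = FALSE]
    list(xy = xy, closed = cl, joined = FALSE)
  })
  repeat {
    open_idx <- which(!vapply(curves, `[[`, logical(1), "closed"))
    if (!length(open_idx)) break
    pts <- do.call(rbind, lapply(open_idx, function(i) {
      xy <- curves[[i]]$xy
      rbind(xy[1, ], xy[nrow(xy), ])
    }))
    owner <- rep(open_idx, each = 2L)
    end <- rep(c(1L, 2L), length(open_idx))
    pairs <- mutual_nearest_pairs(pts, max_gap)
    if (!nrow(pairs)) break
    i <- pairs[1, "i"]; j <- pairs[1, "j"]
    ci <- owner[i]; cj <- owner[j]
    if (ci == cj) {
      curves[[ci]]$closed <- TRUE
      curves[[ci]]$joined <- TRUE
    } else {
      a <- curves[[ci]]$xy; b <- curves[[cj]]$xy
      if (end[i] == 1L) a <- a[rev(seq_len(nrow(a))), , drop = FALSE]
      if (end[j] == 2L) b <- b[rev(seq_len(nrow(b))), , drop = FALSE]
      curves[[ci]]$xy <- rbind(a, b)   # a's tail now meets b's head
      curves[[ci]]$joined <- TRUE
      curves[[cj]] <- NULL
    }
  }
  closed <- vapply(curves, `[[`, logical(1), "closed")
  if (any(!closed))
    message(sum(!closed), " contour(s) could not be closed within max_gap = ",
            max_gap, " and were discarded")
  out <- lapply(curves[closed], function(cv) {
    xy <- cv$xy
    attr(xy, "closed") <- TRUE
    attr(xy, "was_closed") <- cv$joined
    xy
  })
  attr(out, "n_discarded") <- sum(!closed)
  out
}

# bounding boxes of all labelled components in one pass
component_boxes <- function(lab) {
  idx <- which(lab > 0L)
  vals <- lab[idx]
  nr <- nrow(lab)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  f <- factor(vals)
  data.frame(id = as.integer(levels(f)),
             rmin = as.integer(tapply(rows, f, min)),
             rmax = as.integer(tapply(rows, f, max)),
             cmin = as.integer(tapply(cols, f, min)),
             cmax = as.integer(tapply(cols, f, max)))
}

# crop a labelled component with padding; returns list(mask, r0, c0)
crop_component <- function(lab, id, boxes, pad = 2L) {
  b <- boxes[boxes$id == id, ]
  r0 <- max(1L, b$rmin - pad); r1 <- min(nrow(lab), b$rmax + pad)
  c0 <- max(1L, b$cmin - pad); c1 <- min(ncol(lab), b$cmax + pad)
  list(mask = lab[r0:r1, c0:c1, drop = FALSE] == id, r0 = r0, c0 = c0)
}

# lumen of a cropped wall mask: largest filled cavity, NULL if none
component_lumen <- function(comp_mask, min_px) {
  filled <- EBImage::fillHull(EBImage::Image(comp_mask * 1)) > 0.5
  lumen <- filled & !comp_mask
  if (sum(lumen) < min_px) return(NULL)
  lab <- EBImage::bwlabel(EBImage::Image(lumen * 1))
  sizes <- tabulate(lab[lab > 0])
  if (!length(sizes) || max(sizes) < min_px) return(NULL)
  lumen[] <- lab == which.max(sizes)
  lumen
}

#' Extract closed vessel regions from a stain mask
#'
#' Connected stained-wall components are analysed one by one: a component
#' enclosing a cavity is a closed vessel and its cavity becomes the lumen.
#' Open wall arcs are closed first: their skeleton endpoints are joined by
#' straight chords between mutually nearest endpoints within `max_gap`
#' micrometres (the raster counterpart of [close_open_outlines()]), and
#' regions recovered this way are marked `was_closed`. Regions whose lumen
#' longest axis falls outside \[`min_axis`, `max_axis`\] micrometres are
#' discarded (large collectors above 200 micrometres are not considered).
#'
#' @param sm A `stain_mask` from [separate_stain()].
#' @param max_gap Maximum chord length bridged when closing open walls,
#'   micrometres.
#' @param min_axis,max_axis Retained lumen longest-axis range, micrometres.
#' @param min_component_px Wall components smaller than this many pixels are
#'   treated as noise.
#' @return List of class `vessel_regions`; each element is a region list with
#'   `id`, `lumen` (cropped logical matrix), `offset` (top-left pixel of the
#'   crop), `centroid` (micrometres), `wall_contour` (closed polygon,
#'   micrometres), `was_closed`, `pixel_size`. Attributes `n_discarded_open`
#'   and `n_discarded_size` count dropped candidates.
#' @export
extract_vessel_regions <- function(sm, max_gap = 10, min_axis = 5,
                                   max_axis = 200, min_component_px = 10L) {
  stopifnot(inherits(sm, "stain_mask"), max_gap > 0)
  ps <- sm$pixel_size
  mask <- sm$mask
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  sizes <- tabulate(lab[lab > 0])
  keep_ids <- which(sizes >= min_component_px)
  min_lumen_px <- max(8L, as.integer(floor(pi * 1.5^2 / ps^2)))
  boxes <- component_boxes(lab)
  # pass A: find open components and collect their skeleton endpoints
  ep_list <- list()
  for (id in keep_ids) {
    cc <- crop_component(lab, id, boxes)
    if (!is.null(component_lumen(cc$mask, min_lumen_px))) next
    skel <- thin_mask(cc$mask)
    ep <- skeleton_endpoints(skel)
    if (nrow(ep)) {
      # thinning erodes each arc tip by about half the wall thickness, so
      # skeleton endpoints sit further apart than the true wall gap; record
      # half the estimated thickness as per-endpoint slack
      thick_px <- sum(cc$mask) / max(sum(skel), 1L)
      ep_list[[length(ep_list) + 1L]] <-
        cbind(row = ep[, 1] + cc$r0 - 1L, col = ep[, 2] + cc$c0 - 1L,
              comp = id, slack = thick_px * ps / 2)
    }
  }
  chords <- matrix(FALSE, nrow(mask), ncol(mask))
  if (length(ep_list)) {
    ep <- do.call(rbind, ep_list)
    pts <- cbind((ep[, "col"] - 1) * ps, (ep[, "row"] - 1) * ps)
    pairs <- mutual_nearest_pairs(pts, max_gap, slack = ep[, "slack"])
    if (nrow(pairs)) {
      for (k in seq_len(nrow(pairs))) {
        seg <- raster_segment(ep[pairs[k, 1], "row"], ep[pairs[k, 1], "col"],
                              ep[pairs[k, 2], "row"], ep[pairs[k, 2], "col"])
        chords[seg] <- TRUE
      }
      chords <- EBImage::dilate(EBImage::Image(chords * 1),
                                EBImage::makeBrush(3L, "box")) > 0.5
    }
  }
  mask2 <- mask | chords
  lab2 <- EBImage::bwlabel(EBImage::Image(mask2 * 1))
  lab2 <- matrix(as.integer(lab2), nrow(mask), ncol(mask))
  sizes2 <- tabulate(lab2[lab2 > 0])
  ids2 <- which(sizes2 >= min_component_px)
  boxes2 <- component_boxes(lab2)
  regions <- list()
  n_open <- 0L; n_size <- 0L
  for (id in ids2) {
    cc <- crop_component(lab2, id, boxes2)
    lumen <- component_lumen(cc$mask, min_lumen_px)
    if (is.null(lumen)) { n_open <- n_open + 1L; next }
    ct <- mask_contour(lumen)
    axis <- (feret_diameters(ct)[["max"]] + 0.5) * ps
    if (axis < min_axis || axis > max_axis) { n_size <- n_size + 1L; next }
    idx <- which(lumen, arr.ind = TRUE)
    centroid <- c(x = (mean(idx[, 2]) + cc$c0 - 2) * ps,
                  y = (mean(idx[, 1]) + cc$r0 - 2) * ps)
    filled <- EBImage::fillHull(EBImage::Image(cc$mask * 1)) > 0.5
    wc <- mask_contour(filled)   # 0-based local (row, col)
    wall_contour <- cbind((wc[, 2] + cc$c0 - 1) * ps,
                          (wc[, 1] + cc$r0 - 1) * ps)
    crop_chords <- chords[cc$r0 - 1L + seq_len(nrow(cc$mask)),
                          cc$c0 - 1L + seq_len(ncol(cc$mask)), drop = FALSE]
    was_closed <- any(crop_chords & cc$mask)
    regions[[length(regions) + 1L]] <-
      list(id = length(regions) + 1L, lumen = lumen,
           offset = c(row = cc$r0, col = cc$c0), centroid = centroid,
           wall_contour = wall_contour, was_closed = was_closed,
           pixel_size = ps)
  }
  structure(regions, class = "vessel_regions",
            n_discarded_open = n_open, n_discarded_size = n_size)
}

#' @export
print.vessel_regions <- function(x, ...) {
  cat("Vessel regions:", length(x), "closed regions (",
      sum(vapply(x, `[[`, logical(1), "was_closed")), "algorithmically closed;",
      attr(x, "n_discarded_open"), "unclosable,",
      attr(x, "n_discarded_size"), "out-of-range discarded )\n")
  invisible(x)
}

#' Write a per-region summary CSV (and optional labeled mask)
#'
#' One row per region: `region_id`, centroid (micrometres), lumen longest
#' axis, `was_closed`. Optionally writes a labeled lumen mask as a
#' single-channel TIFF whose pixel value is the region id.
#'
#' @param regions A `vessel_regions` list.
#' @param path Output CSV path.
#' @param mask_path Optional TIFF path for the labeled lumen mask.
#' @param dim Image dimensions (rows, cols), required for `mask_path`.
#' @return `path`, invisibly.
#' @export
write_regions_csv <- function(regions, path, mask_path = NULL, dim = NULL) {
  tab <- data.frame(
    region_id = vapply(regions, `[[`, integer(1), "id"),
    centroid_x = vapply(regions, function(r) r$centroid[["x"]], numeric(1)),
    centroid_y = vapply(regions, function(r) r$centroid[["y"]], numeric(1)),
    longest_axis = vapply(regions, function(r)
      measure_vessel(r)$length, numeric(1)),
    was_closed = vapply(regions, `[[`, logical(1), "was_closed"))
  utils::write.csv(tab, path, row.names = FALSE)
  if (!is.null(mask_path)) {
    stopifnot(!is.null(dim))
    lab <- matrix(0L, dim[1], dim[2])
    for (r in regions) {
      idx <- which(r$lumen, arr.ind = TRUE)
      lab[cbind(idx[, 1] + r$offset[["row"]] - 1L,
                idx[, 2] + r$offset[["col"]] - 1L)] <- r$id
    }
    tiff::writeTIFF(lab / max(1L, max(lab)), mask_path,
                    bits.per.sample = 16L)
  }
  invisible(path)
}

#' Measure all regions of a segmented image
#'
#' Convenience wrapper: applies [measure_vessel()] to every region.
#' @param regions A `vessel_regions` list.
#' @return Data.frame with one row per vessel (possibly zero rows).
#' @export
measure_regions <- function(regions) {
  if (!length(regions)) {
    out <- shape_descriptors(1, 1, 1, 1, 1, 1)[0, ]
    out$branching <- integer(0)
    out$caliber_class <- factor(character(0), levels = CALIBER_LEVELS)
    out$was_closed <- logical(0)
    return(out)
  }
  rows <- lapply(regions, measure_vessel)
  out <- do.call(rbind, rows)
  out$region_id <- vapply(regions, `[[`, integer(1), "id")
  out
}
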