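test_that("stain separation recovers wall pixels with high recall", {
  tt <- with_seed(21, sample_vessel_truths(12))
  clean <- render_core_image(tt, core_diameter = 400, pixel_size = 0.5,
                             noise_sd = 0, seed = 21)
  noisy <- render_core_image(tt, core_diameter = 400, pixel_size = 0.5,
                             noise_sd = 0.04, seed = 21)
  truth_wall <- separate_stain(clean$image, 0.5)$mask
  got <- separate_stain(noisy$image, 0.5)$mask
  recall <- sum(got & truth_wall) / sum(truth_wall)
  expect_gte(recall, 0.95)
})

test_that("an all-background image is non-evaluable", {
  img <- array(rep(stain_palette()$background, each = 50 * 50),
               dim = c(50, 50, 3))
  sm <- separate_stain(img, 0.5)
  expect_false(sm$evaluable)
  expect_equal(sm$tissue_area_mm2, 0)
  expect_equal(sum(sm$mask), 0L)
})

test_that("unstained tissue gives an empty mask but positive tissue area", {
  core <- render_core_image(vessel_truth(10)[0, ], core_diameter = 200,
                            pixel_size = 0.5, seed = 22)
  sm <- separate_stain(core$image, 0.5)
  expect_true(sm$evaluable)
  expect_equal(sum(sm$mask), 0L)
  expect_gt(sm$tissue_area_mm2, 0)
  expect_length(extract_vessel_regions(sm), 0L)
})

make_arc <- function(r, from, to, n = 100) {
  th <- seq(from, to, length.out = n)
  cbind(r * cos(th), r * sin(th))
}

test_that("already-closed contours pass through unchanged", {
  circ <- make_arc(5, 0, 2 * pi)
  circ[nrow(circ), ] <- circ[1, ]   # close exactly
  out <- close_open_outlines(list(circ), max_gap = 5)
  expect_length(out, 1L)
  expect_false(attr(out[[1]], "was_closed"))
  expect_equal(nrow(out[[1]]), nrow(circ) - 1L)  # duplicate vertex dropped
})

test_that("a C-shaped arc within max_gap is closed by a chord", {
  # 3 um endpoint gap on a 10 um radius arc
  half_ang <- asin(1.5 / 10)
  arc <- make_arc(10, half_ang, 2 * pi - half_ang)
  out <- close_open_outlines(list(arc), max_gap = 5)
  expect_length(out, 1L)
  expect_true(attr(out[[1]], "was_closed"))
  # gap beyond max_gap: discarded with a message
  expect_message(out2 <- close_open_outlines(list(make_arc(10, 1, 4)),
                                             max_gap = 5))
  expect_length(out2, 0L)
  expect_equal(attr(out2, "n_discarded"), 1L)
})

test_that("two facing arcs are merged into one closed contour", {
  a1 <- make_arc(10, 0.1, pi - 0.1)
  a2 <- make_arc(10, pi + 0.1, 2 * pi - 0.1)
  out <- close_open_outlines(list(a1, a2), max_gap = 5)
  expect_length(out, 1L)
  expect_true(attr(out[[1]], "was_closed"))
  expect_equal(polygon_perimeter(out[[1]]), 2 * pi * 10, tolerance = 0.05)
})

test_that("closing is idempotent on its own output", {
  half_ang <- asin(1.5 / 10)
  arc <- make_arc(10, half_ang, 2 * pi - half_ang)
  once <- close_open_outlines(list(arc), max_gap = 5)
  twice <- close_open_outlines(once, max_gap = 5)
  expect_equal(unclass(twice[[1]]), unclass(once[[1]]),
               ignore_attr = TRUE)
  expect_false(attr(twice[[1]], "was_closed"))
})

# render a single vessel in a small core and segment it
segment_single <- function(truth, noise_sd = 0.02, max_gap = 10, ...) {
  pad <- max(truth$major_axis) + 20
  truth$center_x <- pad; truth$center_y <- pad
  core <- render_core_image(truth, core_diameter = 2 * pad, pixel_size = 0.5,
                            noise_sd = noise_sd, seed = 33)
  sm <- separate_stain(core$image, core$pixel_size)
  extract_vessel_regions(sm, max_gap = max_gap, ...)
}

test_that("a closed ring yields one region whose lumen is the inner disc", {
  tr <- vessel_truth(30, 30, wall_thickness = 3)
  rg <- segment_single(tr)
  expect_length(rg, 1L)
  expect_false(rg[[1]]$was_closed)
  m <- measure_vessel(rg[[1]])
  expect_equal(m$area, pi * 15^2, tolerance = 0.05)
  expect_equal(m$length, 30, tolerance = 0.05)
})

test_that("vessels beyond 200 um longest axis are not considered", {
  # lumen is drawn at the stated caliber, so use a truth just under the cap
  # and a filter set tighter to prove the size gate
  tr <- vessel_truth(60, 60)
  rg <- segment_single(tr, max_axis = 50)
  expect_length(rg, 0L)
  expect_equal(attr(rg, "n_discarded_size"), 1L)
})

test_that("the per-region CSV and labeled mask round-trip", {
  tr <- vessel_truth(24, 20, wall_thickness = 2)
  tr$center_x <- 30; tr$center_y <- 30
  core <- render_core_image(tr, core_diameter = 60, pixel_size = 0.5,
                            noise_sd = 0.02, seed = 36)
  sm <- separate_stain(core$image, 0.5)
  rg <- extract_vessel_regions(sm)
  p <- withr::local_tempfile(fileext = ".csv")
  mp <- withr::local_tempfile(fileext = ".tiff")
  write_regions_csv(rg, p, mask_path = mp, dim = dim(sm$mask))
  tab <- read.csv(p)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$longest_axis, 24, tolerance = 0.03)
  expect_equal(tab$centroid_x, 30, tolerance = 0.1)
  expect_true(file.exists(mp))
})

test_that("two disjoint rings give two regions with disjoint lumens", {
  tt <- vessel_truth(c(20, 14), c(20, 14))
  tt$center_x <- c(40, 90); tt$center_y <- c(40, 90)
  core <- render_core_image(tt, core_diameter = 130, pixel_size = 0.5,
                            noise_sd = 0.02, seed = 34)
  rg <- extract_vessel_regions(separate_stain(core$image, 0.5))
  expect_length(rg, 2L)
  cents <- t(vapply(rg, `[[`, numeric(2), "centroid"))
  expect_gt(sqrt(sum((cents[1, ] - cents[2, ])^2)), 20)
})

test_that("open-walled vessels are recovered as closed regions", {
  tt <- with_seed(35, sample_vessel_truths(25, open_vessel_fraction = 0.2))
  core <- render_core_image(tt, core_diameter = 800, pixel_size = 0.5,
                            seed = 35)
  rg <- extract_vessel_regions(separate_stain(core$image, 0.5), max_gap = 10)
  expect_gte(recovery_fraction(rg, core$truth), 0.9)
  n_open_truth <- sum(core$truth$open_fraction > 0)
  n_flagged <- sum(vapply(rg, `[[`, logical(1), "was_closed"))
  expect_gte(n_flagged, ceiling(0.6 * n_open_truth))
  # every extracted lumen is within the considered axis range and
  # simply connected
  for (r in rg) {
    m <- measure_vessel(r)
    expect_gte(m$length, 5)
    expect_lte(m$length, 200)
    lab <- EBImage::bwlabel(EBImage::Image(r$lumen * 1))
    expect_equal(max(lab), 1)
    filled <- EBImage::fillHull(EBImage::Image(r$lumen * 1)) > 0.5
    expect_equal(sum(filled), sum(r$lumen))  # no holes
  }
})
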