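test_that("caliber classes use half-open bounds on the longest axis", {
  expect_equal(as.character(classify_caliber(12)), "small_cap")
  expect_equal(as.character(classify_caliber(15)), "intermediate_cap")
  expect_equal(as.character(classify_caliber(19.99)), "intermediate_cap")
  expect_equal(as.character(classify_caliber(20)), "large_cap")
  expect_equal(as.character(classify_caliber(50)), "small_collector")
  expect_equal(as.character(classify_caliber(74.99)), "small_collector")
  expect_equal(as.character(classify_caliber(200)), "small_collector")
  expect_error(classify_caliber(4.5), "range")
  expect_error(classify_caliber(201), "range")
})

test_that("a disc scores roundness 1, aspect 1, deformity 0, branching 2", {
  for (ps in c(0.5, 0.25)) {
    m <- measure_vessel(list(lumen = disc_mask(10, ps), pixel_size = ps))
    expect_equal(m$roundness, 1, tolerance = 0.03)
    expect_equal(m$aspect, 1, tolerance = 0.03)
    expect_lt(m$deformity, 0.03)
    expect_equal(m$branching, 2L)
    expect_equal(m$length, 20, tolerance = 0.03)
    expect_equal(m$area, pi * 100, tolerance = 0.03)
    expect_equal(m$shape_factor, 1, tolerance = 0.06)
  }
})

test_that("a 2:1 ellipse has aspect 2 and the Ramanujan roundness", {
  m <- measure_vessel(list(lumen = ellipse_mask(20, 10, 0.25),
                           pixel_size = 0.25))
  expect_equal(m$aspect, 2, tolerance = 0.03)
  # oracle: Ramanujan perimeter approximation for the 2:1 ellipse
  h <- ((20 - 10) / (20 + 10))^2
  per <- pi * (20 + 10) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  expect_equal(m$roundness, per^2 / (4 * pi * pi * 20 * 10), tolerance = 0.03)
})

test_that("a Y-shaped lumen has branching 3", {
  m <- matrix(FALSE, 61, 61)
  m[31, 1:31] <- TRUE
  for (k in 0:20) {
    m[31 - k, 31 + k] <- TRUE
    m[31 + k, 31 + k] <- TRUE
  }
  thick <- m
  for (dr in -2:2) for (dc in -2:2) thick <- thick | shift_mat(m, dr, dc)
  got <- measure_vessel(list(lumen = thick, pixel_size = 0.5))
  expect_equal(got$branching, 3L)
})

test_that("degenerate empty regions are rejected", {
  expect_error(measure_vessel(list(lumen = matrix(FALSE, 5, 5),
                                   pixel_size = 0.5)), "degenerate")
})

test_that("shape descriptors are invariant under pixel-size rescaling", {
  # same micrometre geometry discretized at two resolutions
  m1 <- measure_vessel(list(lumen = ellipse_mask(15, 9, 0.5), pixel_size = 0.5))
  m2 <- measure_vessel(list(lumen = ellipse_mask(15, 9, 0.25),
                            pixel_size = 0.25))
  for (v in c("roundness", "aspect", "perimeter_ratio", "shape_factor"))
    expect_equal(m1[[v]], m2[[v]], tolerance = 0.04)
  expect_lt(abs(m1$deformity - m2$deformity), 0.03)
  expect_equal(m1$length, m2$length, tolerance = 0.03)
  # scaling the pixel size by k scales lengths by k and areas by k^2 exactly
  mask <- ellipse_mask(15, 9, 0.5)
  a <- measure_vessel(list(lumen = mask, pixel_size = 0.5))
  b <- measure_vessel(list(lumen = mask, pixel_size = 1))
  expect_equal(b$length / a$length, 2)
  expect_equal(b$area / a$area, 4)
  expect_equal(b$roundness, a$roundness)
  expect_equal(b$aspect, a$aspect)
})

test_that("roundness increases along increasingly elongated ellipses", {
  rounds <- vapply(seq(1, 3.5, by = 0.5), function(k) {
    polygon_morphometry(generate_vessel_shape(
      vessel_truth(40, 40 / k), seed = 1)$xy)$roundness
  }, numeric(1))
  expect_true(all(diff(rounds) > 0))
})

test_that("per-sample aggregation computes densities and relative shares", {
  v <- data.frame(area = rep(30, 10), length = 10, width = 6, perimeter = 26,
                  roundness = 1.1, aspect = 1.6, perimeter_ratio = 1,
                  deformity = 0.02, shape_factor = 1.2, branching = 2,
                  caliber_class = factor(rep("small_cap", 10),
                                         levels = CALIBER_LEVELS))
  s <- aggregate_sample(v, 0.5)
  q <- s$quantity
  expect_equal(q$density[q$class == "small_cap"], 20)
  expect_equal(q$rel_density[q$class == "small_cap"], 100)
  expect_equal(q$density[q$class == "total"], 20)
  expect_equal(q$sa_pct[q$class == "total"], 100 * 300 / 5e5)
})

test_that("relative density follows class counts and sums to 100", {
  cls <- rep(CALIBER_LEVELS, c(3, 1, 1, 0))
  v <- data.frame(area = 30, length = c(rep(10, 3), 17, 30), width = 6,
                  perimeter = 26, roundness = 1.1, aspect = 1.6,
                  perimeter_ratio = 1, deformity = 0.02, shape_factor = 1.2,
                  branching = 2,
                  caliber_class = factor(cls, levels = CALIBER_LEVELS))
  s <- aggregate_sample(v, 1)
  q <- s$quantity
  expect_equal(q$rel_density[1:4], c(60, 20, 20, 0))
  expect_equal(sum(q$rel_density[1:4]), 100)
  # class densities partition the total exactly
  expect_equal(sum(q$density[1:4]), q$density[q$class == "total"])
})

test_that("an empty vessel list is flagged as no lymphatic vascularization", {
  s <- aggregate_sample(measure_regions(list()), 1.5)
  expect_true(s$no_vascularization)
  expect_true(all(s$quantity$density == 0))
  expect_error(aggregate_sample(measure_regions(list()), 0), "positive")
})

test_that("about three quarters of default-cohort vessels are small capillaries", {
  ch <- default_cohort()
  expect_equal(mean(ch$vessels$caliber_class == "small_cap"), 0.75,
               tolerance = 0.07)
  # every vessel appears in exactly one class
  expect_false(anyNA(ch$vessels$caliber_class))
})
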