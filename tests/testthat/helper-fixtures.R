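# shared fixtures built in code

# default synthetic cohort at the study conditions, generated once per session
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(cohort_config(seed = 2026L))
    cache
  }
})

# logical disc mask: radius in micrometres at the given pixel size
disc_mask <- function(radius_um, pixel_size, pad = 4L) {
  rpx <- radius_um / pixel_size
  n <- as.integer(ceiling(2 * rpx)) + 2L * pad
  cen <- (n - 1) / 2
  d2 <- (seq_len(n) - 1 - cen)^2
  outer(d2, d2, "+") <= rpx^2
}

# axis-aligned ellipse mask with semi-axes in micrometres
ellipse_mask <- function(a_um, b_um, pixel_size, pad = 4L) {
  apx <- a_um / pixel_size; bpx <- b_um / pixel_size
  n <- as.integer(ceiling(2 * max(apx, bpx))) + 2L * pad
  cen <- (n - 1) / 2
  x <- seq_len(n) - 1 - cen
  outer(x^2 / bpx^2, x^2 / apx^2, "+") <= 1   # rows = y (minor), cols = x
}

# fraction of ground-truth vessels recovered by a segmentation (centroid match)
recovery_fraction <- function(regions, truth) {
  if (!nrow(truth)) return(NA_real_)
  if (!length(regions)) return(0)
  cents <- t(vapply(regions, `[[`, numeric(2), "centroid"))
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    d <- sqrt((cents[, 1] - truth$center_x[i])^2 +
                (cents[, 2] - truth$center_y[i])^2)
    any(d < truth$major_axis[i] / 2 + 5)
  }, logical(1))
  mean(hit)
}
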