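# Independent oracles: nothing here calls the package's own hull or polygon
# primitives.

# convex hull area/perimeter via grDevices::chull + pracma (independent of
# the package's monotone chain)
oracle_hull <- function(pts) {
  h <- pts[grDevices::chull(pts), , drop = FALSE]
  per <- {
    n <- nrow(h)
    d <- h - h[c(2:n, 1), , drop = FALSE]
    sum(sqrt(rowSums(d^2)))
  }
  list(area = abs(pracma::polyarea(h[, 1], h[, 2])), perimeter = per)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# analytic masks built directly (not via the package rasterizer)
mask_disk <- function(r_px, pad = 4) {
  n <- 2 * (r_px + pad) + 1
  cen <- (n + 1) / 2
  xy <- expand.grid(r = 1:n, c = 1:n)
  matrix((xy$c - cen)^2 + (xy$r - cen)^2 <= r_px^2, n, n)
}

mask_square <- function(side_px, pad = 4) {
  n <- side_px + 2 * pad
  m <- matrix(FALSE, n, n)
  m[pad + seq_len(side_px), pad + seq_len(side_px)] <- TRUE
  m
}

rotate90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]

hsb_to_rgb_test <- function(h_deg, s, v) {
  as.numeric(grDevices::col2rgb(grDevices::hsv(h_deg / 360, s, v))) / 255
}

demo_design <- function(reps = 2, seed = 1,
                        lines = c("WT-1", "WT-2", "OE-1")) {
  make_design(design_config(lines = lines, reps = reps,
                            imaging_days = c(21, 25, 28, 31, 34, 38, 42, 45)),
              seed = seed)
}
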