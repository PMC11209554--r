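#' Imaging configuration for the synthetic camera
#'
#' @param size_px image side length in pixels (square frames).
#' @param scale_mm_px millimetres per pixel (> 0).
#' @param soil_hsb mean substrate color as (hue degrees, saturation,
#'   brightness). The mean is converted to RGB once; `soil_noise_sd` and
#'   `sensor_noise_sd` are applied per pixel in RGB space.
#' @param soil_noise_sd per-pixel substrate texture noise (RGB units, 0-1).
#' @param sensor_noise_sd per-pixel sensor noise added to the whole frame.
#' @param fluor_noise_sd per-pixel noise of the fluorescence frames.
#' @param bit_depth quantization depth of the stored images.
#' @return list of class `imaging_config`.
#' @export
imaging_config <- function(size_px = 320,
                           scale_mm_px = 0.25,
                           soil_hsb = c(30, 0.45, 0.40),
                           soil_noise_sd = 0.015,
                           sensor_noise_sd = 0.012,
                           fluor_noise_sd = 0.008,
                           bit_depth = 8) {
  stopifnot(scale_mm_px > 0, size_px >= 8, bit_depth %in% c(8, 16))
  structure(as.list(environment()), class = "imaging_config")
}

hsb_to_rgb <- function(h_deg, s, v) {
  as.numeric(grDevices::col2rgb(grDevices::hsv((h_deg %% 360) / 360, s, v))) / 255
}

quantize <- function(x, bits) {
  mx <- 2^bits - 1
  round(pmin(pmax(x, 0), 1) * mx) / mx
}

# pixel-center coordinates (mm, frame centered on the rosette center)
pixel_axes <- function(cfg) {
  n <- cfg$size_px
  (seq_len(n) - (n + 1) / 2) * cfg$scale_mm_px
}

check_fits <- function(geom, cfg) {
  verts <- geometry_vertices(geom)
  ext <- max(abs(verts))
  half <- cfg$size_px * cfg$scale_mm_px / 2
  if (ext > half - cfg$scale_mm_px) {
    need <- ceiling(2 * (ext + cfg$scale_mm_px) / cfg$scale_mm_px)
    stop("rosette exceeds frame: need at least ", need, " px at ",
         cfg$scale_mm_px, " mm/px (have ", cfg$size_px, ")")
  }
  invisible(TRUE)
}

# logical mask + per-pixel leaf index for one geometry; membership is by
# pixel center (no anti-aliasing), so the true mask is unambiguous
rasterize_membership <- function(geom, cfg) {
  n <- cfg$size_px
  ax <- pixel_axes(cfg)
  leaf_idx <- matrix(0L, n, n)       # rows = y, cols = x
  for (k in seq_along(geom$leaves)) {
    poly <- geom$leaves[[k]]$polygon
    cr <- range(poly[, 1]); rr <- range(poly[, 2])
    ci <- which(ax >= cr[1] - cfg$scale_mm_px & ax <= cr[2] + cfg$scale_mm_px)
    ri <- which(ax >= rr[1] - cfg$scale_mm_px & ax <= rr[2] + cfg$scale_mm_px)
    if (!length(ci) || !length(ri)) next
    gx <- rep(ax[ci], times = length(ri))
    gy <- rep(ax[ri], each = length(ci))
    inside <- pracma::inpolygon(gx, gy, poly[, 1], poly[, 2])
    if (any(inside)) {
      rows <- rep(ri, each = length(ci))[inside]
      cols <- rep(ci, times = length(ri))[inside]
      leaf_idx[cbind(rows, cols)] <- k
    }
  }
  leaf_idx
}

#' Render a rosette scene to an RGB frame
#'
#' Fills each leaf polygon with its HSB color (converted to RGB), the
#' substrate elsewhere, adds per-pixel noise and quantizes to the configured
#' bit depth. Pixel membership is decided by the pixel center, so the
#' ground-truth foreground mask (attached as attribute `mask`) is exact.
#' Deterministic for a fixed seed.
#'
#' @param geom a `rosette_geometry` (leaves may be absent for a pure-soil
#'   frame).
#' @param cfg an [imaging_config()].
#' @param seed integer seed for the noise.
#' @return numeric array `size_px x size_px x 3` in `[0, 1]`, with attributes
#'   `mask` (logical matrix, true foreground), `scale_mm_px` and `seed`.
#' @export
rasterize <- function(geom, cfg = imaging_config(), seed = 1) {
  stopifnot(inherits(cfg, "imaging_config"))
  n <- cfg$size_px
  has_leaves <- inherits(geom, "rosette_geometry") && length(geom$leaves) > 0
  if (has_leaves) check_fits(geom, cfg)

  with_seed(child_seed(seed, 7), {
    soil <- hsb_to_rgb(cfg$soil_hsb[1], cfg$soil_hsb[2], cfg$soil_hsb[3])
    img <- array(0, dim = c(n, n, 3))
    soil_noise <- matrix(stats::rnorm(n * n, 0, cfg$soil_noise_sd), n, n)
    for (ch in 1:3) img[, , ch] <- soil[ch] + soil_noise

    leaf_idx <- if (has_leaves) rasterize_membership(geom, cfg)
                else matrix(0L, n, n)
    if (has_leaves) {
      for (k in seq_along(geom$leaves)) {
        px <- which(leaf_idx == k)
        if (!length(px)) next
        lv <- geom$leaves[[k]]
        col <- hsb_to_rgb(lv$hue_deg %||% 120, lv$sat %||% 0.6,
                          lv$val %||% 0.5)
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[px] <- col[ch]
          img[, , ch] <- plane
        }
      }
    }
    if (cfg$sensor_noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, cfg$sensor_noise_sd),
                         dim = dim(img))
    }
    img <- quantize(img, cfg$bit_depth)
    attr(img, "mask") <- leaf_idx > 0L
    attr(img, "scale_mm_px") <- cfg$scale_mm_px
    attr(img, "seed") <- seed
    img
  })
}

#' Render a dark-adapted fluorescence frame pair (F0, Fm)
#'
#' Plant pixels carry the per-leaf minimal (`f0`) and maximal (`fm`)
#' fluorescence levels plus Gaussian noise; the background is near zero.
#' Frames are quantized to 16 bit.
#'
#' @inheritParams rasterize
#' @return list with matrices `F0` and `Fm` and the ground-truth `mask`.
#' @export
simulate_fluorescence <- function(geom, cfg = imaging_config(), seed = 1) {
  stopifnot(inherits(geom, "rosette_geometry"))
  f0s <- vapply(geom$leaves, function(lv) lv$f0 %||% NA_real_, numeric(1))
  fms <- vapply(geom$leaves, function(lv) lv$fm %||% NA_real_, numeric(1))
  if (anyNA(f0s) || anyNA(fms)) stop("geometry lacks per-leaf F0/Fm levels")
  if (any(fms < f0s) || any(f0s < 0)) {
    stop("invalid fluorescence levels: need Fm >= F0 >= 0 for every leaf")
  }
  check_fits(geom, cfg)
  n <- cfg$size_px

  with_seed(child_seed(seed, 13), {
    leaf_idx <- rasterize_membership(geom, cfg)
    base <- 0.02
    F0 <- matrix(base, n, n)
    Fm <- matrix(base, n, n)
    for (k in seq_along(geom$leaves)) {
      px <- which(leaf_idx == k)
      F0[px] <- f0s[k]
      Fm[px] <- fms[k]
    }
    if (cfg$fluor_noise_sd > 0) {
      F0 <- F0 + matrix(stats::rnorm(n * n, 0, cfg$fluor_noise_sd), n, n)
      Fm <- Fm + matrix(stats::rnorm(n * n, 0, cfg$fluor_noise_sd), n, n)
    }
    F0 <- quantize(F0, 16)
    Fm <- quantize(pmax(Fm, F0), 16)
    list(F0 = F0, Fm = Fm, mask = leaf_idx > 0L)
  })
}

#' Simulate end-point biomass for one plant
#'
#' Fresh weight is proportional to the final projected area (log-normal
#' noise); dry weight follows from the target relative water content
#' `DW = FW * (1 - RWC/100)` with its own noise, constrained to
#' `0 <= DW <= FW`.
#'
#' @param phenotype a [rosette_phenotype()] (used for labeling only).
#' @param treatment treatment label.
#' @param final_geom the plant's last `rosette_geometry`.
#' @param seed integer seed.
#' @param rwc_target target relative water content, percent in `[0, 100]`.
#' @param fw_per_mm2 fresh weight per unit projected area (mg/mm^2).
#' @param fw_sd,rwc_sd noise: log-scale sd of FW, absolute sd (percent
#'   points) of the realized RWC.
#' @return one-row tibble with `plant_id`, `FW_mg`, `DW_mg`.
#' @export
simulate_biomass <- function(phenotype, treatment, final_geom, seed = 1,
                             rwc_target = 80, fw_per_mm2 = 0.9,
                             fw_sd = 0.10, rwc_sd = 2) {
  if (rwc_target < 0 || rwc_target > 100) {
    stop("rwc_target must be in [0, 100], got ", rwc_target)
  }
  stopifnot(inherits(final_geom, "rosette_geometry"))
  with_seed(child_seed(seed, 17), {
    fw <- fw_per_mm2 * final_geom$area_mm2 * exp(stats::rnorm(1, 0, fw_sd))
    rwc_real <- min(max(rwc_target + stats::rnorm(1, 0, rwc_sd), 0), 100)
    dw <- fw * (1 - rwc_real / 100)
    tibble::tibble(
      plant_id = final_geom$plant_id %||% NA_character_,
      genotype_line = phenotype$genotype_label,
      treatment = treatment,
      FW_mg = fw,
      DW_mg = min(max(dw, 0), fw)
    )
  })
}
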