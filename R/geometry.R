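# Vector rosette scenes. Every leaf is a simple polygon confined to its own
# angular sector (half the minimum phyllotactic gap), so the union of leaves
# is exact: union area = sum of petal areas, union boundary = sum of petal
# boundaries, and the hull/extent traits follow analytically from the
# vertices. This is what makes the generator an analytic oracle for the
# raster trait extractor.

GOLDEN_ANGLE_DEG <- 137.5
MAX_LEAVES <- 14L

#' Noise model for the synthetic rosette generator
#'
#' All standard deviations of the generator in one place. Sizes are perturbed
#' multiplicatively (log-normal): `size_sd` once per plant, `leaf_sd` once per
#' leaf per plant, `area_day_sd` per imaging day. Colors and fluorescence are
#' perturbed additively (Gaussian) per leaf.
#'
#' @param size_sd,leaf_sd,area_day_sd log-scale sd of the multiplicative noise.
#' @param hue_sd per-leaf hue jitter, degrees.
#' @param sat_sd,val_sd per-leaf saturation/brightness jitter.
#' @param fvfm_sd,f0_sd per-leaf fluorescence jitter.
#' @return list of class `generator_noise`.
#' @export
generator_noise <- function(size_sd = 0.15, leaf_sd = 0.10,
                            area_day_sd = 0.04, hue_sd = 2,
                            sat_sd = 0.02, val_sd = 0.02,
                            fvfm_sd = 0.01, f0_sd = 0.03) {
  structure(as.list(environment()), class = "generator_noise")
}

#' @rdname generator_noise
#' @export
zero_noise <- function() {
  generator_noise(0, 0, 0, 0, 0, 0, 0, 0)
}

# Unit petal polygon: tip at radial distance 1 from the origin along +x.
# p: petiole fraction; aspect: blade width/length; elev_deg: leaf elevation
# (foreshortens the radial extent of the blade, widening it relative to its
# projected length); gap_half_deg: angular half-width of the sector the petal
# must stay inside.
unit_petal <- function(p, aspect, elev_deg, gap_half_deg, n_arc = 20) {
  cos_e <- cos(elev_deg * pi / 180)
  sa <- (1 - p) / 2                 # projected blade semi-major
  cc <- (1 + p) / 2                 # blade center (radial)
  b <- aspect * sa / cos_e          # blade half-width (not foreshortened)
  wp <- 0.035                       # petiole half-width

  theta <- seq(pi, 0, length.out = n_arc + 1)
  xb <- cc + sa * cos(theta)
  wb <- b * sin(theta)

  x <- c(0.02, p, xb)
  w <- c(wp, wp, wb)
  # hard sector clamp keeps neighboring petals disjoint
  cap <- tan(gap_half_deg * pi / 180) * x * 0.95
  w <- pmin(w, cap)
  w <- pmax(w, 1e-6)
  w[length(w)] <- 0                 # tip

  up <- cbind(x, w)
  lo <- cbind(rev(x[-length(x)]), -rev(w[-length(w)]))
  rbind(c(0, 0), up, lo)
}

rotate_scale <- function(xy, angle_deg, scale) {
  a <- angle_deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  (xy %*% t(R)) * scale
}

circular_gaps_half <- function(angles_deg) {
  n <- length(angles_deg)
  if (n == 1) return(180)
  a <- angles_deg %% 360
  vapply(seq_len(n), function(i) {
    d <- abs(a[-i] - a[i])
    min(pmin(d, 360 - d)) / 2
  }, numeric(1))
}

leaf_count <- function(phen, das) {
  n <- 2L + floor(phen$leaf_init_rate * max(0, das - 7))
  as.integer(min(max(n, 2L), MAX_LEAVES))
}

leaf_ages <- function(phen, das, n) {
  init <- c(5, 5, 7 + (seq_len(MAX_LEAVES - 2L) - 1L) / phen$leaf_init_rate)
  pmax(das - init[seq_len(n)], 0)
}

# Assemble the rosette scene for one plant on one day. `mech` in [0, 1] is
# the drought-architecture intensity: it elongates petioles and raises leaf
# elevation (hyponasty), which pushes blades outward at fixed total area and
# so lowers compactness.
build_rosette <- function(phen, das, area_total, mech = 0,
                          leaf_jitter = rep(1, MAX_LEAVES),
                          rotation = 0, n_arc = 20) {
  stopifnot(area_total > 0)
  n <- leaf_count(phen, das)
  ages <- leaf_ages(phen, das, n)
  wts <- (ages + 2)^1.3 * leaf_jitter[seq_len(n)]
  leaf_areas <- area_total * wts / sum(wts)

  angles <- rotation + (seq_len(n) - 1) * GOLDEN_ANGLE_DEG
  gaps <- circular_gaps_half(angles)

  # drought architecture: petioles elongate, leaves rise (hyponasty) and
  # blades narrow (rolling); all three push blade tips outward at fixed
  # projected area, lowering compactness monotonically in `mech`
  p_t <- min(phen$petiole_fraction + mech * (0.55 - phen$petiole_fraction), 0.6)
  e_t <- min(phen$elevation_angle_deg +
               mech * (60 - phen$elevation_angle_deg), 80)
  aspect_t <- phen$blade_aspect * (1 - 0.6 * mech)

  leaves <- vector("list", n)
  for (k in seq_len(n)) {
    up <- unit_petal(p_t, aspect_t, e_t, gaps[k], n_arc)
    ua <- polygon_area(up)
    len <- sqrt(leaf_areas[k] / ua)
    leaves[[k]] <- list(
      angle_deg = angles[k] %% 360,
      polygon = rotate_scale(up, angles[k], len),
      area_mm2 = leaf_areas[k],
      length_mm = len
    )
  }

  structure(
    list(
      center = c(0, 0),
      das = das,
      leaves = leaves,
      area_mm2 = area_total,
      mechanism = list(
        type = "petiole_elongation+hyponasty",
        intensity = mech,
        petiole_fraction = p_t,
        elevation_deg = e_t
      )
    ),
    class = "rosette_geometry"
  )
}

geometry_vertices <- function(geom) {
  do.call(rbind, lapply(geom$leaves, `[[`, "polygon"))
}

geometry_compactness <- function(geom) {
  hull <- monotone_chain_hull(geometry_vertices(geom))
  geom$area_mm2 / polygon_area(hull)
}

solve_mechanism <- function(phen, das, area_total, target_compactness,
                            leaf_jitter, rotation, n_arc = 20, iters = 14) {
  lo <- 0; hi <- 1
  c_lo <- geometry_compactness(build_rosette(phen, das, area_total, lo,
                                             leaf_jitter, rotation, n_arc))
  if (c_lo <= target_compactness) return(0)
  c_hi <- geometry_compactness(build_rosette(phen, das, area_total, hi,
                                             leaf_jitter, rotation, n_arc))
  if (c_hi >= target_compactness) return(1)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    cm <- geometry_compactness(build_rosette(phen, das, area_total, mid,
                                             leaf_jitter, rotation, n_arc))
    if (cm > target_compactness) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a ground-truthed rosette time series for one plant
#'
#' Produces one vector scene per imaging day. Under control, the total
#' projected area follows `area_at_onset * exp(B_true * (DAS - onset))` with
#' the plant's multiplicative noise; during the withholding window the
#' calendar-time trajectory is quadratic with second-order coefficient
#' `a_true`, and growth resumes exponentially after rewatering. The drought
#' compactness loss (scaled by `1 - compactness_retention`) is imposed by
#' solving the petiole-elongation/hyponasty intensity so that ground-truth
#' compactness matches the phenotype's configured drop; the mechanism used is
#' recorded in each geometry.
#'
#' @param phenotype a [rosette_phenotype()].
#' @param treatment `"control"` or `"drought"`.
#' @param design an [make_design()] result; supplies the schedule, and the
#'   plant's chamber and sowing offset.
#' @param plant_id plant identifier present in `design$plants`.
#' @param seed integer; per-plant randomness is derived from it.
#' @param noise a [generator_noise()].
#' @param n_arc vertices per blade half-arc.
#' @return list of class `rosette_series`: elements `das`, `calendar_day`,
#'   `geometry` (a `rosette_geometry` carrying per-leaf polygons, colors and
#'   fluorescence levels).
#' @export
simulate_rosette_series <- function(phenotype, treatment, design, plant_id,
                                    seed = 1, noise = generator_noise(),
                                    n_arc = 20) {
  stopifnot(inherits(phenotype, "rosette_phenotype"),
            inherits(design, "experiment_design"))
  if (!treatment %in% c("control", "drought")) {
    stop("unknown treatment label: ", treatment)
  }
  row <- design$plants[design$plants$plant_id == plant_id, ]
  if (nrow(row) != 1) stop("plant_id not found in design: ", plant_id)

  sched <- design$schedule
  w_start <- sched$withholding_window[1]
  w_end <- sched$withholding_window[2]
  offset <- row$sowing_offset
  chfac <- if (row$chamber == 1) design$config$chamber_size_factor else 1

  cal_days <- sched$imaging_days
  das_days <- cal_days - offset
  keep <- das_days >= 15
  cal_days <- cal_days[keep]; das_days <- das_days[keep]

  idx <- match(plant_id, design$plants$plant_id)
  out <- with_seed(child_seed(seed, 101, idx), {
    rotation <- stats::runif(1, 0, 360)
    s_p <- exp(stats::rnorm(1, 0, noise$size_sd))
    leaf_jit <- exp(stats::rnorm(MAX_LEAVES, 0, noise$leaf_sd))
    day_noise <- exp(stats::rnorm(length(cal_days), 0, noise$area_day_sd))
    hue_jit <- stats::rnorm(MAX_LEAVES, 0, noise$hue_sd)
    sat_jit <- stats::rnorm(MAX_LEAVES, 0, noise$sat_sd)
    val_jit <- stats::rnorm(MAX_LEAVES, 0, noise$val_sd)
    fvfm_jit <- stats::rnorm(MAX_LEAVES, 0, noise$fvfm_sd)
    f0_jit <- stats::rnorm(MAX_LEAVES, 0, noise$f0_sd)

    das_at_onset <- w_start - offset
    a_ctrl <- function(das) {
      phenotype$area_at_onset * exp(phenotype$B_true * (das - w_start)) *
        s_p * chfac
    }

    series <- vector("list", length(cal_days))
    for (i in seq_along(cal_days)) {
      cal <- cal_days[i]; das <- das_days[i]
      tau <- cal - w_start

      if (treatment == "control" || tau <= 0) {
        area <- a_ctrl(das)
        deficit <- 0
      } else {
        a_on <- a_ctrl(das_at_onset)
        g0 <- phenotype$B_true * a_on
        # the realized decline scales with the plant's multiplicative size
        # factor (plant noise x chamber), so chamber effects stay
        # multiplicative along the whole drought trajectory
        a_pl <- phenotype$a_true * s_p * chfac
        if (cal <= w_end) {
          area <- a_on + g0 * tau + a_pl * tau^2
          ramp <- tau / (w_end - w_start)
        } else {
          tau_w <- w_end - w_start
          a_end <- a_on + g0 * tau_w + a_pl * tau_w^2
          area <- max(a_end, 5) * exp(phenotype$B_true * (cal - w_end))
          ramp <- max(0, 1 - (cal - w_end) / (sched$harvest_das - w_end))
        }
        area <- max(area, 5)
        deficit <- phenotype$drought_compactness_drop *
          (1 - phenotype$compactness_retention) * ramp
      }
      area <- area * day_noise[i]

      mech <- 0
      if (deficit > 0) {
        c0 <- geometry_compactness(
          build_rosette(phenotype, das, area, 0, leaf_jit, rotation, n_arc)
        )
        mech <- solve_mechanism(phenotype, das, area, c0 * (1 - deficit),
                                leaf_jit, rotation, n_arc)
      }
      geom <- build_rosette(phenotype, das, area, mech, leaf_jit, rotation,
                            n_arc)

      # color and fluorescence dynamics
      stress_day <- if (treatment == "drought") max(0, min(tau, w_end - w_start)) else 0
      rewatered <- treatment == "drought" && cal > w_end
      hue <- phenotype$hue_base_deg +
        min(phenotype$hue_age_slope * (das - 21), 25)
      if (stress_day > phenotype$hue_drop_onset_day && !rewatered) {
        hue <- hue - phenotype$hue_drought_drop *
          (stress_day - phenotype$hue_drop_onset_day)
      }
      sat <- phenotype$sat_base + phenotype$sat_age_slope * (das - 21)
      if (stress_day > phenotype$sat_drought_onset_day && !rewatered) {
        sat <- sat + phenotype$sat_drought_slope *
          (stress_day - phenotype$sat_drought_onset_day)
      }
      fvfm <- phenotype$fvfm_control
      if (treatment == "drought" && tau > phenotype$fvfm_drop_onset_day &&
          !rewatered) {
        frac <- (min(tau, w_end - w_start) - phenotype$fvfm_drop_onset_day) /
          (w_end - w_start - phenotype$fvfm_drop_onset_day)
        fvfm <- phenotype$fvfm_control +
          (phenotype$fvfm_drought - phenotype$fvfm_control) * min(frac, 1)
      }

      n <- length(geom$leaves)
      for (k in seq_len(n)) {
        lv <- geom$leaves[[k]]
        lv$hue_deg <- (hue + hue_jit[k]) %% 360
        lv$sat <- min(max(sat + sat_jit[k], 0.05), 1)
        lv$val <- min(max(phenotype$brightness_base + val_jit[k], 0.05), 1)
        fv <- min(max(fvfm + fvfm_jit[k], 0.05), 0.95)
        lv$f0 <- min(max(phenotype$f0_base * (1 + f0_jit[k]), 0.01), 0.5)
        lv$fm <- lv$f0 / (1 - fv)
        geom$leaves[[k]] <- lv
      }
      geom$plant_id <- plant_id
      geom$treatment <- treatment
      geom$calendar_day <- cal

      series[[i]] <- list(das = das, calendar_day = cal, geometry = geom)
    }
    series
  })
  structure(out, class = "rosette_series")
}

#' Rescale a rosette geometry by a spatial factor
#'
#' Utility for scaling studies: multiplies every coordinate by `k`, so areas
#' scale by `k^2`, lengths by `k`, and the dimensionless shape traits are
#' unchanged.
#' @param geom a `rosette_geometry`.
#' @param k positive scale factor.
#' @export
scale_geometry <- function(geom, k) {
  stopifnot(inherits(geom, "rosette_geometry"), k > 0)
  geom$leaves <- lapply(geom$leaves, function(lv) {
    lv$polygon <- lv$polygon * k
    lv$area_mm2 <- lv$area_mm2 * k^2
    lv$length_mm <- lv$length_mm * k
    lv
  })
  geom$area_mm2 <- geom$area_mm2 * k^2
  geom
}

#' Analytic ground-truth traits of a vector rosette scene
#'
#' Computes the full trait set exactly from the leaf polygons: projected area
#' (sum of the disjoint petal areas), plant perimeter (sum of petal boundary
#' lengths), convex hull area and perimeter over all polygon vertices, the
#' area of the circle through the farthest vertex from the rosette center
#' ("area by circumference"), the derived compactness and stockiness ratios,
#' and area-weighted color / fluorescence summaries (hue by circular mean).
#'
#' @param geom a `rosette_geometry`.
#' @param frame_area_mm2 optional imaged-frame area for the surface-coverage
#'   ratio.
#' @return one-row tibble.
#' @export
ground_truth_traits <- function(geom, frame_area_mm2 = NULL) {
  stopifnot(inherits(geom, "rosette_geometry"))
  areas <- vapply(geom$leaves, `[[`, numeric(1), "area_mm2")
  if (length(areas) == 0 || sum(areas) <= 0) {
    stop("degenerate geometry: zero projected area")
  }
  verts <- geometry_vertices(geom)
  hull <- monotone_chain_hull(verts)
  hull_area <- polygon_area(hull)
  hull_per <- polygon_perimeter(hull)
  per <- sum(vapply(geom$leaves, function(lv) polygon_perimeter(lv$polygon),
                    numeric(1)))
  r_max <- sqrt(max(rowSums(sweep(verts, 2, geom$center)^2)))
  abc <- pi * r_max^2
  area <- sum(areas)

  has_col <- !is.null(geom$leaves[[1]]$hue_deg)
  hue <- sat <- val <- f0 <- fm <- fvfm <- NA_real_
  if (has_col) {
    hue <- circular_mean_deg(
      vapply(geom$leaves, `[[`, numeric(1), "hue_deg"), areas)
    sat <- sum(vapply(geom$leaves, `[[`, numeric(1), "sat") * areas) / area
    val <- sum(vapply(geom$leaves, `[[`, numeric(1), "val") * areas) / area
    f0 <- sum(vapply(geom$leaves, `[[`, numeric(1), "f0") * areas) / area
    fm <- sum(vapply(geom$leaves, `[[`, numeric(1), "fm") * areas) / area
    fvfm <- (fm - f0) / fm
  }

  tibble::tibble(
    projected_area = area,
    plant_perimeter = per,
    hull_area = hull_area,
    hull_perimeter = hull_per,
    area_by_circumference = abc,
    compactness = area / hull_area,
    stockiness = area / abc,
    surface_coverage = if (is.null(frame_area_mm2)) NA_real_
                       else area / frame_area_mm2,
    hue_deg = hue, saturation = sat, brightness = val,
    F0 = f0, Fm = fm, FvFm = fvfm
  )
}
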