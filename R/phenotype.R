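#' Define a rosette phenotype
#'
#' A phenotype bundles the ground-truth parameters that drive the synthetic
#' rosette generator: growth (exponential coefficient under control, quadratic
#' decline during water withholding), architecture (leaf initiation, blade
#' aspect, petiole fraction, leaf elevation), the drought compactness response,
#' and the color / chlorophyll-fluorescence dynamics.
#'
#' Growth under control follows `a * exp(B_true * DAS)`; during withholding the
#' projected-area trajectory is quadratic with second-order coefficient
#' `a_true` (mm^2/day^2, <= 0), and growth resumes exponentially after
#' rewatering. `compactness_retention` scales the drought compactness loss:
#' 0 is a wild-type-like plant that loses `drought_compactness_drop` (fraction)
#' of its compactness by the end of withholding through petiole elongation and
#' hyponasty; 1 retains control-like compactness throughout.
#'
#' @param genotype_label character label for the line.
#' @param leaf_init_rate leaves initiated per day.
#' @param B_true exponential growth coefficient under control (1/day).
#' @param area_at_onset expected projected area (mm^2) at the start of the
#'   withholding window for a reference plant; anchors the growth curve.
#' @param blade_aspect blade width/length ratio, in (0, 1).
#' @param petiole_fraction fraction of leaf length that is petiole, in
#'   `[0, 0.6]`.
#' @param elevation_angle_deg leaf elevation from horizontal, in `[0, 80]`.
#' @param a_true quadratic decline coefficient during withholding
#'   (mm^2/day^2, <= 0).
#' @param compactness_retention drought compactness retention, in `[0, 1]`.
#' @param drought_compactness_drop fractional compactness loss at the end of
#'   withholding for a fully non-retaining plant (retention 0).
#' @param hue_base_deg,hue_age_slope,hue_drought_drop hue model: baseline hue
#'   (degrees), increase with age (degrees/day), and decline rate under
#'   drought (degrees/day) once the hue response sets in.
#' @param hue_drop_onset_day days after withholding start before hue declines.
#' @param sat_base,sat_age_slope,sat_drought_slope,sat_drought_onset_day
#'   saturation model: baseline, increase per day under control, decline per
#'   day under drought, and onset (days after withholding start).
#' @param brightness_base mean brightness of plant pixels.
#' @param fvfm_control,fvfm_drought,fvfm_drop_onset_day maximum PSII quantum
#'   efficiency under control, its floor under prolonged drought, and the
#'   stress day on which the decline starts.
#' @param f0_base minimal-fluorescence level (fraction of sensor range).
#'
#' @return an object of class `rosette_phenotype` (a validated list).
#' @examples
#' wt <- rosette_phenotype("WT", compactness_retention = 0)
#' oe <- rosette_phenotype("OE", compactness_retention = 1)
#' @export
rosette_phenotype <- function(genotype_label,
                              leaf_init_rate = 0.4,
                              B_true = 0.15,
                              area_at_onset = 50,
                              blade_aspect = 0.45,
                              petiole_fraction = 0.30,
                              elevation_angle_deg = 20,
                              a_true = -0.4,
                              compactness_retention = 0,
                              drought_compactness_drop = 0.20,
                              hue_base_deg = 110,
                              hue_age_slope = 0.8,
                              hue_drought_drop = 1.5,
                              hue_drop_onset_day = 6,
                              sat_base = 0.55,
                              sat_age_slope = 0.004,
                              sat_drought_slope = -0.012,
                              sat_drought_onset_day = 4,
                              brightness_base = 0.48,
                              fvfm_control = 0.80,
                              fvfm_drought = 0.65,
                              fvfm_drop_onset_day = 7,
                              f0_base = 0.18) {
  stopifnot(
    is.character(genotype_label), length(genotype_label) == 1,
    leaf_init_rate > 0,
    is.finite(B_true),
    area_at_onset > 0,
    blade_aspect > 0, blade_aspect < 1,
    petiole_fraction >= 0, petiole_fraction <= 0.6,
    elevation_angle_deg >= 0, elevation_angle_deg <= 80,
    a_true <= 0,
    compactness_retention >= 0, compactness_retention <= 1,
    drought_compactness_drop >= 0, drought_compactness_drop < 1,
    sat_drought_onset_day >= 0,
    fvfm_control >= 0, fvfm_control < 1,
    fvfm_drought >= 0, fvfm_drought < 1,
    f0_base > 0, f0_base < 1
  )
  structure(
    list(
      genotype_label = genotype_label,
      leaf_init_rate = leaf_init_rate,
      B_true = B_true,
      area_at_onset = area_at_onset,
      blade_aspect = blade_aspect,
      petiole_fraction = petiole_fraction,
      elevation_angle_deg = elevation_angle_deg,
      a_true = a_true,
      compactness_retention = compactness_retention,
      drought_compactness_drop = drought_compactness_drop,
      hue_base_deg = hue_base_deg,
      hue_age_slope = hue_age_slope,
      hue_drought_drop = hue_drought_drop,
      hue_drop_onset_day = hue_drop_onset_day,
      sat_base = sat_base,
      sat_age_slope = sat_age_slope,
      sat_drought_slope = sat_drought_slope,
      sat_drought_onset_day = sat_drought_onset_day,
      brightness_base = brightness_base,
      fvfm_control = fvfm_control,
      fvfm_drought = fvfm_drought,
      fvfm_drop_onset_day = fvfm_drop_onset_day,
      f0_base = f0_base
    ),
    class = "rosette_phenotype"
  )
}

#' Default phenotype roster for the two-genotype drought scenario
#'
#' Wild type loses 20% of its compactness by the end of the withholding
#' window; the overexpressor-like genotype retains control-level compactness.
#' Both share the same growth parameters, so the simulated experiment carries
#' a compactness signal but no projected-area signal between genotypes.
#'
#' @param lines character vector of line names; names containing `"WT"` get
#'   the wild-type phenotype, all others the retaining one.
#' @return named list of [rosette_phenotype()] objects.
#' @export
default_phenotypes <- function(lines = c("WT-1", "WT-2", "OE-1", "OE-2")) {
  out <- lapply(lines, function(ln) {
    if (grepl("WT", ln, fixed = TRUE)) {
      rosette_phenotype(ln, compactness_retention = 0)
    } else {
      rosette_phenotype(ln, compactness_retention = 1)
    }
  })
  names(out) <- lines
  out
}

#' @export
print.rosette_phenotype <- function(x, ...) {
  cat("<rosette_phenotype>", x$genotype_label, "\n")
  cat("  control growth B =", x$B_true, "/day; drought decline a =",
      x$a_true, "mm^2/day^2\n")
  cat("  compactness retention =", x$compactness_retention,
      "(drop", x$drought_compactness_drop, "at retention 0)\n")
  invisible(x)
}
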