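#' Fit an exponential growth curve to a projected-area series
#'
#' Fits `area = a * exp(B * DAS)` by ordinary least squares on the log scale
#' (deterministic, closed form; appropriate for the generator's multiplicative
#' noise). Non-positive areas are dropped with a warning.
#'
#' @param das numeric vector of days after sowing.
#' @param area numeric vector of projected areas (mm^2).
#' @return list of class `growth_fit` with `model = "exponential"`,
#'   `coefficients` (a, B), `window`, `n_points`, `rmse` and `r_squared`
#'   (both on the log scale), and `flagged` (TRUE when the fit is unusable).
#' @export
fit_exponential <- function(das, area) {
  stopifnot(length(das) == length(area))
  ok <- is.finite(das) & is.finite(area) & area > 0
  if (any(is.finite(area) & area <= 0)) {
    warning("dropping ", sum(is.finite(area) & area <= 0),
            " non-positive area value(s) before log-linear fit")
  }
  das <- das[ok]; area <- area[ok]
  if (length(das) < 3 || length(unique(das)) < 2) {
    return(structure(list(model = "exponential",
                          coefficients = c(a = NA_real_, B = NA_real_),
                          window = if (length(das)) range(das) else
                            c(NA_real_, NA_real_),
                          n_points = length(das),
                          rmse = NA_real_, r_squared = NA_real_,
                          flagged = TRUE),
                     class = "growth_fit"))
  }
  fit <- stats::lm(log(area) ~ das)
  co <- stats::coef(fit)
  res <- stats::residuals(fit)
  tss <- sum((log(area) - mean(log(area)))^2)
  structure(list(
    model = "exponential",
    coefficients = c(a = exp(unname(co[1])), B = unname(co[2])),
    window = range(das),
    n_points = length(das),
    rmse = sqrt(mean(res^2)),
    r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
    flagged = FALSE
  ), class = "growth_fit")
}

#' Fit a quadratic growth curve over a window
#'
#' Fits `area = a * DAS^2 + b * DAS + c` by least squares, typically over the
#' water-withholding window; the second-order coefficient `a` quantifies how
#' fast growth declines under stress.
#'
#' @inheritParams fit_exponential
#' @param window optional `c(start, end)` DAS window; points outside are
#'   ignored.
#' @return list of class `growth_fit` with `model = "quadratic"` and
#'   coefficients (a, b, c). Fewer than 4 points or fewer than 4 distinct
#'   days give a flagged fit.
#' @export
fit_quadratic <- function(das, area, window = NULL) {
  stopifnot(length(das) == length(area))
  ok <- is.finite(das) & is.finite(area)
  if (!is.null(window)) ok <- ok & das >= window[1] & das <= window[2]
  das <- das[ok]; area <- area[ok]
  if (length(das) < 4 || length(unique(das)) < 4) {
    return(structure(list(model = "quadratic",
                          coefficients = c(a = NA_real_, b = NA_real_,
                                           c = NA_real_),
                          window = if (length(das)) range(das) else
                            c(NA_real_, NA_real_),
                          n_points = length(das),
                          rmse = NA_real_, r_squared = NA_real_,
                          flagged = TRUE),
                     class = "growth_fit"))
  }
  fit <- stats::lm(area ~ das + I(das^2))
  co <- stats::coef(fit)
  res <- stats::residuals(fit)
  tss <- sum((area - mean(area))^2)
  structure(list(
    model = "quadratic",
    coefficients = c(a = unname(co[3]), b = unname(co[2]), c = unname(co[1])),
    window = range(das),
    n_points = length(das),
    rmse = sqrt(mean(res^2)),
    r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
    flagged = FALSE
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit>", x$model,
      if (x$flagged) "(flagged)" else "", "\n")
  print(round(x$coefficients, 6))
  cat("  window", x$window[1], "-", x$window[2], "DAS; n =", x$n_points,
      "; RMSE =", signif(x$rmse, 4), "\n")
  invisible(x)
}

#' Daily growth rate from a fitted model
#'
#' Analytic derivative of the fitted curve at a given day:
#' `a*B*exp(B*x)` for the exponential model, `2*a*x + b` for the quadratic.
#'
#' @param fit a `growth_fit`.
#' @param das day at which to evaluate the derivative.
#' @return growth rate in mm^2/day (`NA` for flagged fits).
#' @export
growth_rate_per_day <- function(fit, das) {
  stopifnot(inherits(fit, "growth_fit"))
  if (fit$flagged) return(flag_value(NA_real_, "flagged_fit"))
  co <- fit$coefficients
  if (fit$model == "exponential") {
    unname(co["a"] * co["B"] * exp(co["B"] * das))
  } else {
    unname(2 * co["a"] * das + co["b"])
  }
}

#' Drought growth-decline coefficient
#'
#' Returns the second-order coefficient of a quadratic fit over the
#' withholding window -- the single-number summary of how fast growth
#' declined under water deprivation.
#'
#' @param fit a quadratic `growth_fit`.
#' @return coefficient `a` in mm^2/day^2.
#' @export
decline_coefficient <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  if (fit$model != "quadratic") {
    stop("decline_coefficient is defined for quadratic fits, got ",
         fit$model)
  }
  if (fit$flagged) return(flag_value(NA_real_, "flagged_fit"))
  unname(fit$coefficients["a"])
}

#' Stress/recovery growth ratio normalized to control
#'
#' For the drought group, computes the area gain over the stress window
#' divided by the gain over the recovery window (on line-mean trajectories),
#' and normalizes by the same quantity from the line's control plants.
#'
#' @param drought,control data frames with columns `das` and `area`
#'   (individual plants are averaged per day).
#' @param stress_window,recovery_window two-element DAS windows.
#' @return the normalized ratio; `NA` with `flag = "zero_control_recovery"`
#'   when the control recovery gain is zero, `NA` with
#'   `flag = "insufficient_days"` when a window has fewer than 2 imaging days
#'   in either group.
#' @export
stress_recovery_ratio <- function(drought, control,
                                  stress_window, recovery_window) {
  gain <- function(df, w) {
    sub <- df[df$das >= w[1] & df$das <= w[2], ]
    if (length(unique(sub$das)) < 2) return(NULL)
    daymean <- tapply(sub$area, sub$das, mean)
    unname(daymean[length(daymean)] - daymean[1])
  }
  gs_d <- gain(drought, stress_window)
  gr_d <- gain(drought, recovery_window)
  gs_c <- gain(control, stress_window)
  gr_c <- gain(control, recovery_window)
  if (is.null(gs_d) || is.null(gr_d) || is.null(gs_c) || is.null(gr_c)) {
    return(flag_value(NA_real_, "insufficient_days"))
  }
  if (gr_c == 0 || gr_d == 0 || gs_c == 0) {
    return(flag_value(NA_real_, "zero_control_recovery"))
  }
  (gs_d / gr_d) / (gs_c / gr_c)
}

#' Per-plant growth fits over a trait table
#'
#' Fits, for every plant, the exponential model over its control-phase days
#' and (for droughted plants) the quadratic model over the withholding
#' window, returning one tidy row per plant and model.
#'
#' @param traits trait table with columns `plant_id`, `treatment`, `DAS`,
#'   `projected_area`.
#' @param withholding_window two-element calendar DAS window of water
#'   withholding; per-plant windows account for `sowing_offset` when that
#'   column is present.
#' @return tibble with plant metadata, model, coefficients and diagnostics.
#' @export
fit_growth_table <- function(traits, withholding_window = c(25, 38)) {
  stopifnot(all(c("plant_id", "treatment", "DAS", "projected_area") %in%
                  names(traits)))
  split_tab <- split(traits, traits$plant_id)
  rows <- lapply(split_tab, function(tt) {
    tt <- tt[order(tt$DAS), ]
    off <- if ("sowing_offset" %in% names(tt)) tt$sowing_offset[1] else 0
    win <- withholding_window - off
    is_drought <- tt$treatment[1] == "drought"
    exp_days <- if (is_drought) tt$DAS < win[1] | tt$DAS > win[2] else
      rep(TRUE, nrow(tt))
    fe <- fit_exponential(tt$DAS[exp_days], tt$projected_area[exp_days])
    out <- tibble::tibble(
      plant_id = tt$plant_id[1],
      genotype_line = tt$genotype_line[1] %||% NA_character_,
      treatment = tt$treatment[1],
      model = "exponential",
      a = fe$coefficients["a"], B = fe$coefficients["B"],
      b = NA_real_, c = NA_real_,
      window_start = fe$window[1], window_end = fe$window[2],
      n_points = fe$n_points, rmse = fe$rmse, r_squared = fe$r_squared,
      flagged = fe$flagged
    )
    if (is_drought) {
      fq <- fit_quadratic(tt$DAS, tt$projected_area, window = win)
      out <- dplyr::bind_rows(out, tibble::tibble(
        plant_id = tt$plant_id[1],
        genotype_line = tt$genotype_line[1] %||% NA_character_,
        treatment = tt$treatment[1],
        model = "quadratic",
        a = fq$coefficients["a"], B = NA_real_,
        b = fq$coefficients["b"], c = fq$coefficients["c"],
        window_start = fq$window[1], window_end = fq$window[2],
        n_points = fq$n_points, rmse = fq$rmse, r_squared = fq$r_squared,
        flagged = fq$flagged
      ))
    }
    out
  })
  dplyr::bind_rows(rows)
}
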