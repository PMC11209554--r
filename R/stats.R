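DEFAULT_TRAITS <- c("projected_area", "plant_perimeter", "hull_area",
                    "hull_perimeter", "area_by_circumference", "compactness",
                    "stockiness", "surface_coverage", "hue_deg", "saturation",
                    "brightness")

#' Remove a systematic chamber size offset
#'
#' For every trait and treatment, computes the daily ratio of chamber means
#' (designated chamber over the other), averages the daily ratios into a
#' single correction factor, and divides the designated chamber's values by
#' it. Applying the correction twice is a no-op (the second-pass factors are
#' 1). Traits/treatments where a chamber is missing are skipped with a
#' warning.
#'
#' @param table trait table with columns `chamber`, `treatment`, `DAS` and
#'   the trait columns.
#' @param traits character vector of trait columns to correct.
#' @param designated_chamber chamber whose values are rescaled.
#' @param mode `"multiplicative"` (factor of daily mean ratios; default,
#'   size-like traits scale) or `"additive"` (mean of daily mean differences).
#' @return list with `table` (corrected) and `factors` (tibble of per
#'   trait x treatment factors and the number of days used).
#' @export
chamber_correction <- function(table, traits = intersect(DEFAULT_TRAITS,
                                                         names(table)),
                               designated_chamber = 1,
                               mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  stopifnot(all(c("chamber", "treatment", "DAS") %in% names(table)))
  out <- table
  fac_rows <- list()
  for (trt in unique(table$treatment)) {
    sel_t <- table$treatment == trt
    chams <- unique(table$chamber[sel_t])
    if (!all(c(1, 2) %in% chams)) {
      warning("treatment ", trt, ": chamber missing, correction skipped")
      next
    }
    for (tr in traits) {
      v <- table[[tr]]
      des <- sel_t & table$chamber == designated_chamber & is.finite(v)
      oth <- sel_t & table$chamber != designated_chamber & is.finite(v)
      days <- intersect(unique(table$DAS[des]), unique(table$DAS[oth]))
      if (!length(days)) next
      daily <- vapply(days, function(d) {
        m1 <- mean(v[des & table$DAS == d])
        m2 <- mean(v[oth & table$DAS == d])
        if (mode == "multiplicative") {
          if (m2 == 0) NA_real_ else m1 / m2
        } else {
          m1 - m2
        }
      }, numeric(1))
      fac <- mean(daily, na.rm = TRUE)
      if (!is.finite(fac)) next
      if (mode == "multiplicative") {
        out[[tr]][des] <- out[[tr]][des] / fac
      } else {
        out[[tr]][des] <- out[[tr]][des] - fac
      }
      fac_rows[[length(fac_rows) + 1]] <- tibble::tibble(
        trait = tr, treatment = trt, factor = fac, n_days = length(days),
        mode = mode
      )
    }
  }
  list(table = out,
       factors = if (length(fac_rows)) dplyr::bind_rows(fac_rows)
                 else tibble::tibble(trait = character(), treatment = character(),
                                     factor = numeric(), n_days = integer(),
                                     mode = character()))
}

#' Drought-to-control trait normalization per day
#'
#' For each genotype line (or pooled genotype group) and imaging day, divides
#' the drought-group mean of a trait by the control-group mean, propagating
#' the group SEMs into the ratio's standard error. Days without a control
#' mean are missing.
#'
#' @param table trait table with `treatment`, `DAS`, `genotype_line`
#'   (and `is_reference` when `level = "group"`).
#' @param trait trait column name.
#' @param level `"line"` for per-line ratios, `"group"` to pool reference
#'   lines as `"WT"` and the rest as `"transgenic"`.
#' @return tibble with `group`, `DAS`, `ratio`, `sem`, `n_drought`,
#'   `n_control`.
#' @export
normalize_to_control <- function(table, trait, level = c("line", "group")) {
  level <- match.arg(level)
  stopifnot(trait %in% names(table),
            all(c("treatment", "DAS", "genotype_line") %in% names(table)))
  grp <- if (level == "line") {
    table$genotype_line
  } else {
    stopifnot("is_reference" %in% names(table))
    ifelse(table$is_reference, "WT", "transgenic")
  }
  df <- tibble::tibble(group = grp, DAS = table$DAS,
                       treatment = table$treatment, value = table[[trait]])
  df <- df[is.finite(df$value), ]
  agg <- dplyr::summarise(
    dplyr::group_by(df, .data$group, .data$DAS, .data$treatment),
    mean = mean(.data$value),
    sem = stats::sd(.data$value) / sqrt(dplyr::n()),
    n = dplyr::n(), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(agg, names_from = "treatment",
                             values_from = c("mean", "sem", "n"))
  need <- c("mean_control", "mean_drought")
  if (!all(need %in% names(wide))) {
    stop("normalize_to_control needs both control and drought records")
  }
  ratio <- wide$mean_drought / wide$mean_control
  rel <- sqrt((wide$sem_drought / wide$mean_drought)^2 +
                (wide$sem_control / wide$mean_control)^2)
  out <- tibble::tibble(
    group = wide$group, DAS = wide$DAS,
    ratio = ifelse(is.finite(wide$mean_control) & wide$mean_control != 0,
                   ratio, NA_real_),
    sem = abs(ratio) * rel,
    n_drought = wide$n_drought, n_control = wide$n_control
  )
  out[!is.na(out$ratio), ]
}

#' Per-plant control-normalized trait values
#'
#' Divides every drought plant's trait value by its line's control-group mean
#' on the same day, yielding plant-level normalized values (columns
#' `<trait>_norm`) that can be tested across genotypes with [per_day_tests()].
#'
#' @param table trait table with `treatment`, `DAS`, `genotype_line`.
#' @param traits trait columns to normalize.
#' @return the drought rows of `table` with the normalized columns appended;
#'   days without a control mean give `NA`.
#' @export
add_control_normalized <- function(table, traits) {
  stopifnot(all(traits %in% names(table)))
  ctrl <- table[table$treatment == "control", ]
  drt <- table[table$treatment == "drought", ]
  for (tr in traits) {
    key <- paste(ctrl$genotype_line, ctrl$DAS)
    means <- tapply(ctrl[[tr]], key, function(v) mean(v[is.finite(v)]))
    ref <- means[paste(drt$genotype_line, drt$DAS)]
    drt[[paste0(tr, "_norm")]] <- drt[[tr]] / as.numeric(ref)
  }
  drt
}

#' Standardize traits within each imaging day
#'
#' Centers and scales every trait to zero mean and unit variance within each
#' DAS, so that older (bigger) plants do not dominate a pooled decomposition.
#' Trait-day cells with fewer than 2 plants or zero variance are set to `NA`
#' and reported in the `excluded` attribute.
#'
#' @param table trait table with a `DAS` column.
#' @param traits trait columns to standardize.
#' @return the table with the trait columns replaced by their per-day
#'   z-scores; attribute `excluded` lists flagged trait-day cells.
#' @export
standardize_per_day <- function(table, traits = intersect(DEFAULT_TRAITS,
                                                          names(table))) {
  stopifnot("DAS" %in% names(table))
  out <- table
  excluded <- list()
  for (d in unique(table$DAS)) {
    sel <- table$DAS == d
    for (tr in traits) {
      v <- out[[tr]][sel]
      fin <- is.finite(v)
      if (sum(fin) < 2 || stats::sd(v[fin]) == 0) {
        out[[tr]][sel] <- NA_real_
        excluded[[length(excluded) + 1]] <- tibble::tibble(trait = tr, DAS = d)
        next
      }
      v[fin] <- (v[fin] - mean(v[fin])) / stats::sd(v[fin])
      out[[tr]][sel] <- v
    }
  }
  attr(out, "excluded") <- if (length(excluded)) dplyr::bind_rows(excluded)
                           else tibble::tibble(trait = character(),
                                               DAS = numeric())
  out
}

#' Principal component analysis of a standardized trait matrix
#'
#' Thin wrapper around the spectral decomposition of the (already
#' per-day-standardized) trait matrix. Component signs are fixed by making
#' the largest-magnitude entry of each loading vector positive, so results
#' are fully deterministic.
#'
#' @param mat numeric matrix, rows = plant-days, columns = traits; complete
#'   cases only.
#' @param n_components how many components to return (default: all).
#' @return list of class `pca_result`: `scores`, `loadings`,
#'   `variance_fraction` (over all components, summing to 1).
#' @export
run_pca <- function(mat, n_components = NULL) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("run_pca needs a complete-case matrix")
  p <- ncol(mat)
  n_components <- n_components %||% p
  if (n_components > p) {
    stop("more components requested (", n_components, ") than traits (",
         p, ")")
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  var_all <- pc$sdev^2
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2, flip, `*`)
  sco <- sweep(pc$x, 2, flip, `*`)
  structure(list(
    scores = sco[, seq_len(n_components), drop = FALSE],
    loadings = rot[, seq_len(n_components), drop = FALSE],
    variance_fraction = var_all / sum(var_all)
  ), class = "pca_result")
}

pool_reference <- function(table) {
  stopifnot("is_reference" %in% names(table))
  factor(ifelse(table$is_reference, "WT", as.character(table$genotype_line)))
}

#' Per-day ANOVA with comparisons against pooled wild type
#'
#' For every imaging day (within treatment), runs a one-way ANOVA across
#' genotype lines -- with the reference lines pooled into a single `"WT"`
#' group -- followed by family-wise adjusted comparisons of each line against
#' WT, using either Tukey's honest significant difference over all pairs or
#' Dunnett's many-to-one test.
#'
#' @param table trait table with `genotype_line`, `is_reference`, `DAS`,
#'   `treatment`.
#' @param trait trait column to test.
#' @param method `"tukey"` or `"dunnett"`.
#' @param alpha family-wise significance level for the `significant` flag.
#' @return tibble with one row per (treatment, DAS, line): ANOVA p, the
#'   line-vs-WT estimate, adjusted p and significance flag. Days with fewer
#'   than 2 groups of 2 plants are flagged (`degenerate = TRUE`).
#' @export
per_day_tests <- function(table, trait, method = c("tukey", "dunnett"),
                          alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(trait %in% names(table),
            all(c("genotype_line", "is_reference", "DAS", "treatment") %in%
                  names(table)))
  if (!any(table$is_reference)) stop("reference (WT) group absent")
  rows <- list()
  for (trt in unique(table$treatment)) {
    for (d in sort(unique(table$DAS[table$treatment == trt]))) {
      sel <- table$treatment == trt & table$DAS == d &
        is.finite(table[[trait]])
      sub <- table[sel, ]
      if (nrow(sub) == 0) next
      grp <- droplevels(pool_reference(sub))
      sizes <- table(grp)
      if (length(sizes) < 2 || sum(sizes >= 2) < 2 || !"WT" %in% names(sizes)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          trait = trait, treatment = trt, DAS = d, line = NA_character_,
          anova_p = NA_real_, estimate = NA_real_, p_adj = NA_real_,
          significant = NA, degenerate = TRUE
        )
        next
      }
      grp <- stats::relevel(grp, ref = "WT")
      df <- data.frame(value = sub[[trait]], group = grp)
      fit <- stats::aov(value ~ group, data = df)
      anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
      if (method == "tukey") {
        tk <- stats::TukeyHSD(fit)$group
        nm <- rownames(tk)
        is_wt <- grepl("(^WT-)|(-WT$)", nm)
        est <- tk[is_wt, "diff"]
        padj <- tk[is_wt, "p adj"]
        line <- sub("^WT-", "", sub("-WT$", "", nm[is_wt]))
        # orient estimates as line minus WT
        est <- ifelse(grepl("^WT-", nm[is_wt]), -est, est)
      } else {
        gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
        sm <- summary(gl)
        est <- as.numeric(sm$test$coefficients)
        padj <- as.numeric(sm$test$pvalues)
        line <- sub(" - WT$", "", names(sm$test$coefficients))
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        trait = trait, treatment = trt, DAS = d, line = line,
        anova_p = anova_p, estimate = as.numeric(est),
        p_adj = as.numeric(padj),
        significant = as.numeric(padj) < alpha, degenerate = FALSE
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Size-matched trait comparison
#'
#' Bins plants by a size trait (default projected area, with a 50-100 mm^2
#' bin in the default breaks) and summarizes a target trait per bin and
#' genotype group, enabling comparisons of equally sized plants.
#'
#' @param table trait table.
#' @param target_trait trait summarized within bins.
#' @param size_trait binning trait.
#' @param breaks bin breaks for the size trait.
#' @param group_col grouping column (default pools reference lines as WT).
#' @return tibble with `size_bin`, `group`, `n`, `mean`, `sem`; empty bins
#'   are absent.
#' @export
size_matched_curves <- function(table, target_trait,
                                size_trait = "projected_area",
                                breaks = c(0, 25, 50, 100, 200, 400, Inf),
                                group_col = NULL) {
  stopifnot(all(c(target_trait, size_trait) %in% names(table)))
  grp <- if (is.null(group_col)) as.character(pool_reference(table))
         else as.character(table[[group_col]])
  df <- tibble::tibble(
    group = grp,
    size = table[[size_trait]],
    value = table[[target_trait]]
  )
  df <- df[is.finite(df$size) & is.finite(df$value), ]
  df$size_bin <- cut(df$size, breaks = breaks, include.lowest = TRUE)
  dplyr::summarise(
    dplyr::group_by(df, .data$size_bin, .data$group),
    n = dplyr::n(),
    mean = mean(.data$value),
    sem = stats::sd(.data$value) / sqrt(dplyr::n()),
    .groups = "drop"
  )
}

#' Relative water content
#'
#' `RWC = (FW - DW) / FW * 100` (percent).
#'
#' @param FW_mg,DW_mg fresh and dry weight (any common unit); vectors are
#'   accepted.
#' @return RWC in percent.
#' @export
rwc <- function(FW_mg, DW_mg) {
  if (any(FW_mg <= 0)) stop("RWC undefined for FW <= 0")
  if (any(DW_mg > FW_mg)) stop("RWC undefined for DW > FW")
  if (any(DW_mg < 0)) stop("RWC undefined for DW < 0")
  (FW_mg - DW_mg) / FW_mg * 100
}
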