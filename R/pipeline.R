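#' Configuration of a full pipeline run
#'
#' Bundles everything a reproducible run needs: the master seed, the design,
#' the phenotype roster (one [rosette_phenotype()] per genotype line), the
#' imaging and segmentation settings, fit windows and statistics options.
#'
#' @param seed master seed; all stage randomness is derived from it.
#' @param design a [design_config()].
#' @param phenotypes named list of [rosette_phenotype()], one per line in the
#'   design.
#' @param imaging an [imaging_config()].
#' @param thresholds an [hsb_thresholds()].
#' @param min_component_px,closing_radius_px mask cleanup parameters.
#' @param noise a [generator_noise()].
#' @param stat_method `"tukey"` or `"dunnett"`.
#' @param alpha significance level.
#' @param rwc_targets named vector of target relative water content (percent)
#'   per treatment.
#' @param outdir output directory of the run.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       design = design_config(),
                       phenotypes = default_phenotypes(design$lines),
                       imaging = imaging_config(),
                       thresholds = hsb_thresholds(),
                       min_component_px = 10,
                       closing_radius_px = 0,
                       noise = generator_noise(),
                       stat_method = "tukey",
                       alpha = 0.05,
                       rwc_targets = c(control = 82, drought = 78),
                       outdir = tempfile("phenorose_run_")) {
  cfg <- structure(as.list(environment()), class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"),
            inherits(cfg$design, "design_config"),
            inherits(cfg$imaging, "imaging_config"),
            inherits(cfg$thresholds, "hsb_thresholds"))
  missing <- setdiff(cfg$design$lines, names(cfg$phenotypes))
  if (length(missing)) {
    stop("phenotype roster missing line(s): ",
         paste(missing, collapse = ", "))
  }
  if (!all(c("control", "drought") %in% names(cfg$rwc_targets))) {
    stop("rwc_targets must name both treatments")
  }
  invisible(cfg)
}

frame_name <- function(plant_id, cal) sprintf("%s_%02d", plant_id, cal)

#' Ground-truth trait table for a whole experiment
#'
#' Simulates every plant's geometry series and evaluates the analytic trait
#' set on it -- the vector-side twin of the raster pipeline, used as the
#' oracle in benchmarking.
#'
#' @param design an [make_design()] result.
#' @param phenotypes named list of phenotypes covering all design lines.
#' @param seed integer seed.
#' @param noise a [generator_noise()].
#' @return tibble: one row per plant per imaging day with metadata and
#'   ground-truth traits.
#' @export
simulate_trait_table <- function(design, phenotypes, seed = 1,
                                 noise = generator_noise()) {
  stopifnot(inherits(design, "experiment_design"))
  rows <- lapply(seq_len(nrow(design$plants)), function(i) {
    pl <- design$plants[i, ]
    ser <- simulate_rosette_series(phenotypes[[pl$genotype_line]],
                                   pl$treatment, design, pl$plant_id,
                                   seed = seed, noise = noise)
    recs <- lapply(ser, function(e) {
      tt <- ground_truth_traits(e$geometry)
      tt$plant_id <- pl$plant_id
      tt$DAS <- e$das
      tt$calendar_day <- e$calendar_day
      tt
    })
    out <- dplyr::bind_rows(recs)
    out$genotype_line <- pl$genotype_line
    out$chamber <- pl$chamber
    out$treatment <- pl$treatment
    out$sowing_offset <- pl$sowing_offset
    out$is_reference <- pl$is_reference
    out
  })
  dplyr::bind_rows(rows)
}

write_csv_meta <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the simulate-segment-extract-model-test pipeline
#'
#' Executes the full workflow: randomized design, synthetic RGB and
#' fluorescence frames with ground truth, HSB segmentation with cleanup,
#' trait extraction, per-plant growth fits, and the response statistics
#' (chamber correction, control normalization, per-day standardized PCA,
#' per-day comparisons against pooled WT, biomass/RWC). All artifacts are
#' written under `config$outdir` and listed, with checksums, in
#' `manifest.json`. Runs are deterministic for a fixed config and seed.
#'
#' @param config a [run_config()].
#' @param stages which stages to run, in order; default all. Later stages
#'   require the artifacts of earlier ones in `config$outdir`.
#' @param quiet suppress per-stage progress messages.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("design", "simulate", "segment", "traits",
                                    "fit", "stats"),
                         quiet = FALSE) {
  validate_run_config(config)
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  t_start <- Sys.time()

  # run metadata + config hash (seed recorded in the sidecar of every run)
  cfg_json <- file.path(out, "config.json")
  jsonlite::write_json(serialize_config(config), cfg_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(seed = config$seed,
                   config_hash = unname(tools::md5sum(cfg_json)),
                   stages = list())

  design <- NULL
  ensure_design <- function() {
    if (is.null(design)) {
      design <<- make_design(config$design, seed = config$seed)
    }
    design
  }

  for (stage in stages) {
    say("stage: ", stage)
    files <- switch(
      stage,
      design = {
        d <- ensure_design()
        p1 <- write_csv_meta(d$plants, file.path(out, "design.csv"))
        p2 <- file.path(out, "schedule.json")
        jsonlite::write_json(d$schedule, p2, auto_unbox = TRUE, digits = NA)
        c(p1, p2)
      },
      simulate = stage_simulate(config, ensure_design(), out),
      segment = stage_segment(config, out),
      traits = stage_traits(config, ensure_design(), out),
      fit = stage_fit(config, out),
      stats = stage_stats(config, out),
      stop("unknown stage: ", stage)
    )
    manifest$stages[[stage]] <- list(
      files = basename(files),
      md5 = unname(tools::md5sum(files))
    )
  }

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

serialize_config <- function(cfg) {
  list(
    seed = cfg$seed,
    design = unclass(cfg$design),
    phenotypes = lapply(cfg$phenotypes, unclass),
    imaging = unclass(cfg$imaging),
    thresholds = unclass(cfg$thresholds),
    min_component_px = cfg$min_component_px,
    closing_radius_px = cfg$closing_radius_px,
    noise = unclass(cfg$noise),
    stat_method = cfg$stat_method,
    alpha = cfg$alpha,
    rwc_targets = as.list(cfg$rwc_targets)
  )
}

stage_simulate <- function(config, design, out) {
  img_dir <- file.path(out, "images")
  flu_dir <- file.path(out, "fluor")
  tru_dir <- file.path(out, "truth")
  for (d in c(img_dir, flu_dir, tru_dir)) {
    dir.create(d, showWarnings = FALSE)
  }
  truth <- list(); biomass <- list()
  files <- character()
  for (i in seq_len(nrow(design$plants))) {
    pl <- design$plants[i, ]
    phen <- config$phenotypes[[pl$genotype_line]]
    ser <- simulate_rosette_series(phen, pl$treatment, design, pl$plant_id,
                                   seed = config$seed, noise = config$noise)
    for (e in ser) {
      nm <- frame_name(pl$plant_id, e$calendar_day)
      img <- rasterize(e$geometry, config$imaging,
                       seed = child_seed(config$seed, i, e$calendar_day))
      png::writePNG(img, file.path(img_dir, paste0(nm, ".png")))
      if (e$calendar_day %in% design$schedule$fluor_days) {
        fl <- simulate_fluorescence(e$geometry, config$imaging,
                                    seed = child_seed(config$seed, i,
                                                      e$calendar_day, 2))
        tiff::writeTIFF(fl$F0, file.path(flu_dir, paste0(nm, "_F0.tif")),
                        bits.per.sample = 16)
        tiff::writeTIFF(fl$Fm, file.path(flu_dir, paste0(nm, "_Fm.tif")),
                        bits.per.sample = 16)
      }
      tt <- ground_truth_traits(e$geometry)
      tt$plant_id <- pl$plant_id
      tt$DAS <- e$das
      tt$calendar_day <- e$calendar_day
      truth[[length(truth) + 1]] <- tt
    }
    final_geom <- ser[[length(ser)]]$geometry
    biomass[[length(biomass) + 1]] <- simulate_biomass(
      phen, pl$treatment, final_geom,
      seed = child_seed(config$seed, i, 99),
      rwc_target = config$rwc_targets[[pl$treatment]]
    )
  }
  f1 <- write_csv_meta(dplyr::bind_rows(truth),
                       file.path(tru_dir, "ground_truth.csv"))
  f2 <- write_csv_meta(dplyr::bind_rows(biomass),
                       file.path(tru_dir, "biomass.csv"))
  c(f1, f2)
}

stage_segment <- function(config, out) {
  img_dir <- file.path(out, "images")
  msk_dir <- file.path(out, "masks")
  dir.create(msk_dir, showWarnings = FALSE)
  imgs <- list.files(img_dir, pattern = "\\.png$", full.names = TRUE)
  if (!length(imgs)) stop("segment stage: no images found under ", img_dir)
  log_rows <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    img <- png::readPNG(imgs[i])
    mask <- segment_hsb(img, config$thresholds)
    mask <- clean_mask(mask, config$min_component_px,
                       config$closing_radius_px)
    png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                  file.path(msk_dir, basename(imgs[i])))
    log_rows[[i]] <- tibble::tibble(
      image = basename(imgs[i]),
      foreground_px = sum(mask),
      components_kept = attr(mask, "n_components_kept"),
      components_removed = attr(mask, "n_components_removed")
    )
  }
  write_csv_meta(dplyr::bind_rows(log_rows),
                 file.path(out, "segmentation_log.csv"))
}

stage_traits <- function(config, design, out) {
  img_dir <- file.path(out, "images")
  msk_dir <- file.path(out, "masks")
  flu_dir <- file.path(out, "fluor")
  masks <- list.files(msk_dir, pattern = "\\.png$")
  if (!length(masks)) stop("traits stage: no masks found under ", msk_dir)
  plants <- design$plants
  rows <- vector("list", length(masks))
  for (i in seq_along(masks)) {
    nm <- sub("\\.png$", "", masks[i])
    parts <- strsplit(nm, "_")[[1]]
    pid <- parts[1]; cal <- as.integer(parts[2])
    pl <- plants[plants$plant_id == pid, ]
    img <- png::readPNG(file.path(img_dir, masks[i]))
    mask <- png::readPNG(file.path(msk_dir, masks[i])) > 0.5
    f0p <- file.path(flu_dir, paste0(nm, "_F0.tif"))
    fluoro <- NULL
    if (file.exists(f0p)) {
      fluoro <- list(F0 = tiff::readTIFF(f0p),
                     Fm = tiff::readTIFF(sub("_F0", "_Fm", f0p)))
    }
    rec <- extract_all(img, mask, config$imaging$scale_mm_px, fluoro,
                       metadata = list(plant_id = pid,
                                       DAS = cal - pl$sowing_offset,
                                       chamber = pl$chamber,
                                       treatment = pl$treatment,
                                       genotype_line = pl$genotype_line))
    rec$calendar_day <- cal
    rec$sowing_offset <- pl$sowing_offset
    rec$is_reference <- pl$is_reference
    rows[[i]] <- rec
  }
  write_csv_meta(dplyr::bind_rows(rows), file.path(out, "traits.csv"))
}

stage_fit <- function(config, out) {
  tr_path <- file.path(out, "traits.csv")
  if (!file.exists(tr_path)) stop("fit stage: traits.csv not found")
  traits <- utils::read.csv(tr_path)
  fits <- fit_growth_table(traits, config$design$withholding_window)
  write_csv_meta(fits, file.path(out, "fits.csv"))
}

stage_stats <- function(config, out) {
  tr_path <- file.path(out, "traits.csv")
  if (!file.exists(tr_path)) stop("stats stage: traits.csv not found")
  traits <- utils::read.csv(tr_path)
  st_dir <- file.path(out, "stats")
  dir.create(st_dir, showWarnings = FALSE)
  files <- character()

  # statistics group plants by measurement (calendar) day
  tab <- traits
  tab$DAS <- tab$calendar_day

  cc <- chamber_correction(tab)
  files <- c(files,
             write_csv_meta(cc$table, file.path(st_dir, "traits_corrected.csv")),
             write_csv_meta(cc$factors, file.path(st_dir, "chamber_factors.csv")))
  tab <- cc$table

  norm <- dplyr::bind_rows(
    cbind(trait = "compactness",
          normalize_to_control(tab, "compactness", level = "line")),
    cbind(trait = "projected_area",
          normalize_to_control(tab, "projected_area", level = "line"))
  )
  files <- c(files, write_csv_meta(norm, file.path(st_dir, "normalized.csv")))

  tabn <- add_control_normalized(tab, c("compactness", "projected_area"))
  tests <- dplyr::bind_rows(
    per_day_tests(tabn, "compactness_norm", method = config$stat_method,
                  alpha = config$alpha),
    per_day_tests(tabn, "projected_area_norm", method = config$stat_method,
                  alpha = config$alpha),
    per_day_tests(tab[tab$treatment == "drought", ], "compactness",
                  method = config$stat_method, alpha = config$alpha)
  )
  files <- c(files, write_csv_meta(tests, file.path(st_dir, "per_day_tests.csv")))

  # per-day standardized PCA, one decomposition per treatment
  pca_traits <- intersect(DEFAULT_TRAITS, names(tab))
  for (trt in unique(tab$treatment)) {
    sub <- tab[tab$treatment == trt, ]
    std <- standardize_per_day(sub, pca_traits)
    mat <- as.matrix(std[, pca_traits])
    keep_col <- colSums(is.na(mat)) < nrow(mat)
    mat <- mat[, keep_col, drop = FALSE]
    cmp <- stats::complete.cases(mat)
    if (sum(cmp) > ncol(mat)) {
      pca <- run_pca(mat[cmp, , drop = FALSE])
      files <- c(files,
        write_csv_meta(data.frame(component = seq_along(pca$variance_fraction),
                                  variance_fraction = pca$variance_fraction),
                       file.path(st_dir, paste0("pca_variance_", trt, ".csv"))),
        write_csv_meta(data.frame(trait = rownames(pca$loadings),
                                  pca$loadings),
                       file.path(st_dir, paste0("pca_loadings_", trt, ".csv"))))
    }
  }

  # biomass / relative water content
  bio_path <- file.path(out, "truth", "biomass.csv")
  if (file.exists(bio_path)) {
    bio <- utils::read.csv(bio_path)
    bio$RWC <- rwc(bio$FW_mg, bio$DW_mg)
    anova_rows <- lapply(unique(bio$treatment), function(trt) {
      sub <- bio[bio$treatment == trt, ]
      p <- if (length(unique(sub$genotype_line)) > 1) {
        summary(stats::aov(RWC ~ genotype_line, data = sub))[[1]][["Pr(>F)"]][1]
      } else NA_real_
      tibble::tibble(treatment = trt, mean_rwc = mean(sub$RWC),
                     genotype_anova_p = p)
    })
    files <- c(files,
               write_csv_meta(bio, file.path(st_dir, "biomass_rwc.csv")),
               write_csv_meta(dplyr::bind_rows(anova_rows),
                              file.path(st_dir, "rwc_summary.csv")))
  }
  files
}

#' Write analytic and demo fixtures
#'
#' Generates the small deterministic inputs used by the test-suite and
#' examples: analytic shapes with known traits (`disk`, `square`, `cross`)
#' as image + mask + ground-truth CSV, or a miniature experiment
#' (`demo_experiment`).
#'
#' @param preset one of `"disk"`, `"square"`, `"cross"`,
#'   `"demo_experiment"`.
#' @param seed integer seed.
#' @param dir output directory.
#' @return (invisibly) paths of the written files; for the analytic shapes
#'   the return also carries attribute `geometry`.
#' @export
make_fixtures <- function(preset, seed = 1, dir = tempfile("fixtures_")) {
  presets <- c("disk", "square", "cross", "demo_experiment")
  if (!preset %in% presets) {
    stop("unknown preset '", preset, "'; available: ",
         paste(presets, collapse = ", "))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (preset == "demo_experiment") {
    cfg <- run_config(
      seed = seed,
      design = design_config(lines = c("WT-1", "WT-2", "OE-1"),
                             reps = 2,
                             imaging_days = c(21, 25, 30, 34, 38, 45),
                             fluor_days = c(25, 38)),
      imaging = imaging_config(size_px = 160, scale_mm_px = 0.5),
      outdir = dir
    )
    run_pipeline(cfg, quiet = TRUE)
    return(invisible(list.files(dir, recursive = TRUE, full.names = TRUE)))
  }

  geom <- fixture_geometry(preset)
  cfg <- imaging_config(size_px = 256, scale_mm_px = 0.1)
  img <- rasterize(geom, cfg, seed = seed)
  truth <- ground_truth_traits(geom)
  p1 <- file.path(dir, paste0(preset, ".png"))
  p2 <- file.path(dir, paste0(preset, "_mask.png"))
  p3 <- file.path(dir, paste0(preset, "_truth.csv"))
  png::writePNG(img, p1)
  mask <- attr(img, "mask")
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), p2)
  utils::write.csv(truth, p3, row.names = FALSE)
  out <- invisible(c(p1, p2, p3))
  attr(out, "geometry") <- geom
  out
}

# analytic single/multi-leaf scenes with exactly known traits
fixture_geometry <- function(preset) {
  green <- list(hue_deg = 120, sat = 0.9, val = 0.8, f0 = 0.2, fm = 1.0)
  mk_leaf <- function(poly) {
    c(list(polygon = poly, area_mm2 = polygon_area(poly),
           length_mm = sqrt(max(rowSums(poly^2)))), green)
  }
  leaves <- switch(
    preset,
    disk = {
      th <- seq(0, 2 * pi, length.out = 721)[-721]
      list(mk_leaf(cbind(10 * cos(th), 10 * sin(th))))
    },
    square = list(mk_leaf(cbind(c(-5, 5, 5, -5), c(-5, -5, 5, 5)))),
    cross = {
      # arm half-width stays below the 45-degree sector line, so the four
      # arms are disjoint and the union is exactly the sum of the trapezoids
      arm <- cbind(c(0.8, 10, 10, 0.8), c(-0.5, -3, 3, 0.5))
      lapply(c(0, 90, 180, 270), function(a) mk_leaf(rotate_scale(arm, a, 1)))
    }
  )
  structure(list(center = c(0, 0), das = NA_real_, leaves = leaves,
                 area_mm2 = sum(vapply(leaves, `[[`, numeric(1), "area_mm2")),
                 mechanism = list(type = "fixture")),
            class = "rosette_geometry")
}
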