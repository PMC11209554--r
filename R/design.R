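#' Experiment design configuration
#'
#' Captures the layout of a phenotyping run: genotype lines (with at least two
#' wild-type reference lines that are pooled in the statistics), replicate
#' plants per line and treatment, two growth chambers, trays of fixed pot
#' capacity, staggered sowing offsets, and the imaging / watering schedule.
#' Defaults mirror a chamber experiment in which imaging starts at 21 days
#' after sowing (DAS), water is withheld from 25 to 38 DAS (13 days), plants
#' are rewatered and recover until harvest at 45 DAS, RGB imaging is daily
#' during withholding and every 2-3 days otherwise, and fluorescence imaging
#' happens twice per week.
#'
#' @param lines character vector of genotype line names.
#' @param reference_lines lines pooled as the wild-type reference; at least
#'   two are expected by the downstream statistics.
#' @param reps plants per line x treatment cell.
#' @param treatments treatment labels.
#' @param tray_capacity pots per tray.
#' @param n_trays total trays available, or `NULL` to allocate as many as
#'   needed. [make_design()] errors if the plants do not fit.
#' @param sowing_offsets allowed sowing-day offsets (days), cycled over plants.
#' @param chamber_size_factor multiplicative size offset of chamber 1 relative
#'   to chamber 2, applied by the generator.
#' @param imaging_days DAS (offset-0 calendar) on which RGB images are taken.
#' @param fluor_days DAS on which dark-adapted fluorescence pairs are taken.
#' @param withholding_window two-element vector, start and end DAS of water
#'   withholding.
#' @param harvest_das harvest day.
#' @return a list of class `design_config`.
#' @export
design_config <- function(lines = c("WT-1", "WT-2", "OE-1", "OE-2"),
                          reference_lines = grep("WT", lines, value = TRUE),
                          reps = 30,
                          treatments = c("control", "drought"),
                          tray_capacity = 40,
                          n_trays = NULL,
                          sowing_offsets = 0:2,
                          chamber_size_factor = 1.05,
                          imaging_days = c(21, 23, 25, 28:38, 41, 43, 45),
                          fluor_days = c(21, 25, 28, 32, 35, 38, 42, 45),
                          withholding_window = c(25, 38),
                          harvest_das = 45) {
  stopifnot(
    length(lines) >= 1,
    all(reference_lines %in% lines),
    reps >= 1,
    length(treatments) == 2,
    tray_capacity >= 1,
    length(withholding_window) == 2,
    withholding_window[2] > withholding_window[1],
    harvest_das >= withholding_window[2],
    all(imaging_days <= harvest_das)
  )
  structure(
    list(
      lines = lines,
      reference_lines = reference_lines,
      reps = reps,
      treatments = treatments,
      tray_capacity = tray_capacity,
      n_trays = n_trays,
      sowing_offsets = sowing_offsets,
      chamber_size_factor = chamber_size_factor,
      imaging_days = sort(unique(imaging_days)),
      fluor_days = sort(unique(fluor_days)),
      withholding_window = withholding_window,
      harvest_das = harvest_das
    ),
    class = "design_config"
  )
}

#' Randomized experiment design
#'
#' Assigns plants to genotype lines, treatments, chambers, trays, pots and
#' sowing-day offsets under a randomized layout. Chambers are balanced within
#' every line x treatment cell, sowing offsets are spread evenly, and plants
#' are randomized across trays of fixed capacity within a chamber.
#'
#' @param config a [design_config()].
#' @param seed integer seed; the same seed reproduces the same design.
#' @return an object of class `experiment_design`: a list with `plants`
#'   (a tibble with one row per plant) and `schedule` (imaging and watering
#'   days copied from the config).
#' @examples
#' d <- make_design(design_config(reps = 4), seed = 1)
#' nrow(d$plants)  # lines x treatments x reps
#' @export
make_design <- function(config = design_config(), seed = 1) {
  stopifnot(inherits(config, "design_config"))
  cells <- expand.grid(
    genotype_line = config$lines,
    treatment = config$treatments,
    stringsAsFactors = FALSE
  )
  n_total <- nrow(cells) * config$reps
  if (!is.null(config$n_trays) &&
      n_total > config$n_trays * config$tray_capacity) {
    stop("tray capacity exceeded: ", n_total, " plants do not fit in ",
         config$n_trays, " trays of ", config$tray_capacity, " pots")
  }

  plants <- with_seed(child_seed(seed, 11), {
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      # chambers balanced within the cell, and sowing offsets balanced
      # within each chamber (blocked assignment), then shuffled
      chamber <- rep_len(c(1L, 2L), config$reps)
      offset <- integer(config$reps)
      for (ch in c(1L, 2L)) {
        idx <- which(chamber == ch)
        offset[idx] <- rep_len(config$sowing_offsets, length(idx))
      }
      perm <- sample.int(config$reps)
      tibble::tibble(
        genotype_line = cells$genotype_line[i],
        insertion_replicate = seq_len(config$reps),
        treatment = cells$treatment[i],
        chamber = chamber[perm],
        sowing_offset = as.integer(offset[perm])
      )
    })
    tab <- dplyr::bind_rows(rows)
    tab <- tab[sample.int(nrow(tab)), ]
    tab$plant_id <- sprintf("P%04d", seq_len(nrow(tab)))

    # pots/trays per chamber
    tab <- dplyr::group_by(tab, .data$chamber)
    tab <- dplyr::mutate(
      tab,
      pot_index = seq_len(dplyr::n()),
      tray = paste0("C", .data$chamber, "-T",
                    (.data$pot_index - 1L) %/% config$tray_capacity + 1L),
      pot = (.data$pot_index - 1L) %% config$tray_capacity + 1L
    )
    tab <- dplyr::ungroup(tab)
    tab$pot_index <- NULL
    tab$is_reference <- tab$genotype_line %in% config$reference_lines
    tab[, c("plant_id", "genotype_line", "insertion_replicate", "chamber",
            "tray", "pot", "treatment", "sowing_offset", "is_reference")]
  })

  structure(
    list(
      plants = plants,
      schedule = list(
        imaging_days = config$imaging_days,
        fluor_days = config$fluor_days,
        withholding_window = config$withholding_window,
        harvest_das = config$harvest_das
      ),
      config = config,
      seed = seed
    ),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design>", nrow(x$plants), "plants,",
      length(unique(x$plants$genotype_line)), "lines,",
      length(unique(x$plants$tray)), "trays\n")
  cat("  withholding", x$schedule$withholding_window[1], "->",
      x$schedule$withholding_window[2], "DAS; harvest",
      x$schedule$harvest_das, "DAS\n")
  invisible(x)
}
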