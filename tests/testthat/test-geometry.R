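test_that("noiseless control growth is exactly exponential in DAS", {
  d <- demo_design(seed = 1)
  ph <- rosette_phenotype("WT", B_true = 0.15)
  ser <- simulate_rosette_series(ph, "control", d, d$plants$plant_id[1],
                                 seed = 2, noise = zero_noise())
  das <- vapply(ser, `[[`, numeric(1), "das")
  area <- vapply(ser, function(e) e$geometry$area_mm2, numeric(1))
  ratios <- exp(diff(log(area)) / diff(das))
  expect_equal(ratios, rep(exp(0.15), length(ratios)), tolerance = 1e-10)
  # ground-truth trait area equals the trajectory area exactly
  tt <- ground_truth_traits(ser[[3]]$geometry)
  expect_equal(tt$projected_area, area[3], tolerance = 1e-9)
})

test_that("compactness retention 1 reproduces the control trajectory", {
  d <- demo_design(seed = 1)
  pid <- d$plants$plant_id[d$plants$treatment == "drought"][1]
  ph <- rosette_phenotype("OE", compactness_retention = 1)
  sd_ <- simulate_rosette_series(ph, "drought", d, pid, seed = 4,
                                 noise = zero_noise())
  sc_ <- simulate_rosette_series(ph, "control", d, pid, seed = 4,
                                 noise = zero_noise())
  cd <- vapply(sd_, function(e) ground_truth_traits(e$geometry)$compactness,
               numeric(1))
  cc <- vapply(sc_, function(e) ground_truth_traits(e$geometry)$compactness,
               numeric(1))
  expect_equal(cd, cc, tolerance = 1e-9)
})

test_that("retention 0 hits the configured compactness drop at window end", {
  d <- demo_design(seed = 1)
  pid <- d$plants$plant_id[d$plants$treatment == "drought"][1]
  ph <- rosette_phenotype("WT", compactness_retention = 0,
                          drought_compactness_drop = 0.20)
  sd_ <- simulate_rosette_series(ph, "drought", d, pid, seed = 4,
                                 noise = zero_noise())
  sc_ <- simulate_rosette_series(ph, "control", d, pid, seed = 4,
                                 noise = zero_noise())
  cal <- vapply(sd_, `[[`, numeric(1), "calendar_day")
  i_end <- which(cal == 38)
  ratio <- ground_truth_traits(sd_[[i_end]]$geometry)$compactness /
    ground_truth_traits(sc_[[i_end]]$geometry)$compactness
  expect_equal(ratio, 0.80, tolerance = 0.005)
  # monotone decline during withholding
  during <- cal >= 26 & cal <= 38
  rr <- vapply(which(during), function(i) {
    ground_truth_traits(sd_[[i]]$geometry)$compactness /
      ground_truth_traits(sc_[[i]]$geometry)$compactness
  }, numeric(1))
  expect_true(all(diff(rr) < 0.01))
  expect_true(all(rr <= 1 + 1e-9))
  # mechanism is recorded
  expect_match(sd_[[i_end]]$geometry$mechanism$type, "petiole")
  expect_gt(sd_[[i_end]]$geometry$mechanism$intensity, 0)
})

test_that("ground-truth hull agrees with an independent hull oracle", {
  d <- demo_design(seed = 2)
  ph <- rosette_phenotype("WT")
  for (s in 1:5) {
    ser <- simulate_rosette_series(ph, "control", d, d$plants$plant_id[s],
                                   seed = s)
    g <- ser[[sample.int(length(ser), 1)]]$geometry
    verts <- do.call(rbind, lapply(g$leaves, `[[`, "polygon"))
    orc <- oracle_hull(verts)
    tt <- ground_truth_traits(g)
    expect_equal(tt$hull_area, orc$area, tolerance = 1e-9)
    expect_equal(tt$hull_perimeter, orc$perimeter, tolerance = 1e-9)
  }
})

test_that("shape traits are invariant and sizes equivariant under rescaling", {
  d <- demo_design(seed = 3)
  ph <- rosette_phenotype("WT")
  ser <- simulate_rosette_series(ph, "control", d, d$plants$plant_id[2],
                                 seed = 9)
  g <- ser[[5]]$geometry
  k <- 2.7
  t1 <- ground_truth_traits(g)
  t2 <- ground_truth_traits(scale_geometry(g, k))
  expect_equal(t2$projected_area, t1$projected_area * k^2, tolerance = 1e-9)
  expect_equal(t2$hull_area, t1$hull_area * k^2, tolerance = 1e-9)
  expect_equal(t2$plant_perimeter, t1$plant_perimeter * k, tolerance = 1e-9)
  expect_equal(t2$hull_perimeter, t1$hull_perimeter * k, tolerance = 1e-9)
  expect_equal(t2$compactness, t1$compactness, tolerance = 1e-12)
  expect_equal(t2$stockiness, t1$stockiness, tolerance = 1e-12)
})

test_that("ground-truth shape ratios satisfy their bounds across a corpus", {
  d <- demo_design(seed = 4)
  phens <- default_phenotypes(c("WT-1", "WT-2", "OE-1"))
  for (i in 1:6) {
    pl <- d$plants[i, ]
    ser <- simulate_rosette_series(phens[[pl$genotype_line]], pl$treatment,
                                   d, pl$plant_id, seed = 20 + i)
    for (e in ser[c(1, 4, 8)]) {
      tt <- ground_truth_traits(e$geometry)
      expect_gt(tt$compactness, 0)
      expect_lte(tt$compactness, 1 + 1e-9)
      expect_lte(tt$stockiness, tt$compactness + 1e-9)
      expect_lte(tt$projected_area, tt$hull_area + 1e-9)
      expect_lte(tt$hull_area, tt$area_by_circumference + 1e-9)
    }
  }
})

test_that("series generation is deterministic and rejects bad input", {
  d <- demo_design(seed = 5)
  ph <- rosette_phenotype("WT")
  a <- simulate_rosette_series(ph, "control", d, d$plants$plant_id[1], seed = 6)
  b <- simulate_rosette_series(ph, "control", d, d$plants$plant_id[1], seed = 6)
  expect_identical(a, b)
  expect_error(
    simulate_rosette_series(ph, "waterlogged", d, d$plants$plant_id[1]),
    "unknown treatment"
  )
  expect_error(
    simulate_rosette_series(ph, "control", d, "nope"),
    "not found"
  )
  expect_error(ground_truth_traits(structure(list(center = c(0, 0),
                                                  leaves = list()),
                                             class = "rosette_geometry")),
               "degenerate")
})
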