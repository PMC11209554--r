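synthetic_table <- function(n_per = 8, days = c(30, 32, 34), seed = 1,
                            chamber_factor = 1, lines = c("WT-1", "WT-2",
                                                          "OE-1")) {
  set.seed(seed)
  grid <- expand.grid(genotype_line = lines,
                      treatment = c("control", "drought"),
                      rep = seq_len(n_per), DAS = days,
                      stringsAsFactors = FALSE)
  grid$plant_id <- paste0(grid$genotype_line, "_", grid$treatment, "_",
                          grid$rep)
  grid$chamber <- ifelse(grid$rep %% 2 == 0, 1L, 2L)
  grid$is_reference <- grepl("WT", grid$genotype_line)
  grid$projected_area <- exp(rnorm(nrow(grid), log(100), 0.1)) *
    ifelse(grid$chamber == 1, chamber_factor, 1)
  grid$compactness <- pmin(exp(rnorm(nrow(grid), log(0.45), 0.05)), 1) *
    ifelse(grid$chamber == 1, chamber_factor, 1)
  tibble::as_tibble(grid)
}

test_that("a constructed multiplicative chamber offset is removed exactly", {
  tab <- synthetic_table(seed = 2, chamber_factor = 1)
  # impose an exact 5% offset on chamber 1
  sel <- tab$chamber == 1
  tab$projected_area[sel] <- tab$projected_area[sel] * 1.05
  out <- chamber_correction(tab, traits = "projected_area")
  fac <- out$factors$factor
  # second pass: residual averaged chamber ratio is 1 within 1e-9
  again <- chamber_correction(out$table, traits = "projected_area")
  expect_true(all(abs(again$factors$factor - 1) < 1e-9))
  # and the exact offset was estimated up to sampling of the daily means
  expect_gt(mean(fac), 1.0)
})

test_that("identical chambers give unit factors and an unchanged table", {
  tab <- synthetic_table(seed = 3)
  tab$projected_area <- rep(100, nrow(tab))
  out <- chamber_correction(tab, traits = "projected_area")
  expect_true(all(abs(out$factors$factor - 1) < 1e-12))
  expect_equal(out$table$projected_area, tab$projected_area)
})

test_that("chamber correction warns and skips when a chamber is absent", {
  tab <- synthetic_table(seed = 4)
  tab <- tab[!(tab$treatment == "drought" & tab$chamber == 1), ]
  expect_warning(chamber_correction(tab, traits = "projected_area"),
                 "chamber missing")
})

test_that("normalizing a table against itself gives ratio 1 everywhere", {
  tab <- synthetic_table(seed = 5)
  tab$projected_area <- 100   # drought == control by construction
  out <- normalize_to_control(tab, "projected_area", level = "line")
  expect_true(all(abs(out$ratio - 1) < 1e-12))
  # a day with no control measurements disappears, neighbors unaffected
  tab2 <- synthetic_table(seed = 6)
  tab2 <- tab2[!(tab2$treatment == "control" & tab2$DAS == 32), ]
  out2 <- normalize_to_control(tab2, "projected_area", level = "line")
  expect_false(32 %in% out2$DAS)
  expect_setequal(unique(out2$DAS), c(30, 34))
})

test_that("per-plant control normalization divides by the line-day mean", {
  tab <- synthetic_table(seed = 7)
  out <- add_control_normalized(tab, "compactness")
  one <- out[out$genotype_line == "OE-1" & out$DAS == 30, ]
  ctrl_mean <- mean(tab$compactness[tab$genotype_line == "OE-1" &
                                      tab$DAS == 30 &
                                      tab$treatment == "control"])
  expect_equal(one$compactness_norm, one$compactness / ctrl_mean,
               tolerance = 1e-12)
})

test_that("per-day standardization yields zero mean and unit variance", {
  tab <- synthetic_table(seed = 8)
  std <- standardize_per_day(tab, c("projected_area", "compactness"))
  for (d in unique(std$DAS)) {
    v <- std$projected_area[std$DAS == d]
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(stats::sd(v), 1, tolerance = 1e-12)
  }
  # changing a trait's unit does not change the standardized values
  tab2 <- tab; tab2$projected_area <- tab2$projected_area * 1000
  std2 <- standardize_per_day(tab2, "projected_area")
  expect_equal(std2$projected_area, std$projected_area, tolerance = 1e-9)
  # one plant per day -> flagged and excluded
  tiny <- tab[!duplicated(tab$DAS), ]
  std3 <- standardize_per_day(tiny, "projected_area")
  expect_true(all(is.na(std3$projected_area)))
  expect_gt(nrow(attr(std3, "excluded")), 0)
})

test_that("PCA matches a brute-force eigendecomposition of the covariance", {
  set.seed(9)
  mat <- matrix(rnorm(200 * 5), 200, 5) %*%
    matrix(runif(25, -1, 1), 5, 5)
  colnames(mat) <- paste0("t", 1:5)
  pca <- run_pca(mat)
  ev <- eigen(stats::cov(mat), symmetric = TRUE)$values
  expect_equal(pca$variance_fraction, ev / sum(ev), tolerance = 1e-9)
  expect_equal(sum(pca$variance_fraction), 1, tolerance = 1e-9)
  # orthonormal loadings
  expect_equal(crossprod(pca$loadings), diag(5), tolerance = 1e-9,
               ignore_attr = TRUE)
  # sign convention: largest-magnitude entry of each loading positive
  for (j in 1:5) {
    v <- pca$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_error(run_pca(mat, n_components = 6), "more components")
})

test_that("two perfectly correlated traits load equally on their component", {
  set.seed(10)
  z <- rnorm(300)
  mat <- cbind(a = z, b = z, c = rnorm(300), d = rnorm(300))
  pca <- run_pca(scale(mat))
  l1 <- pca$loadings[, 1]
  expect_equal(unname(abs(l1["a"])), unname(abs(l1["b"])), tolerance = 1e-6)
})

test_that("identity-covariance data spreads variance evenly", {
  set.seed(11)
  mat <- matrix(rnorm(4000 * 4), ncol = 4)
  pca <- run_pca(mat)
  expect_equal(unname(pca$variance_fraction), rep(0.25, 4), tolerance = 0.05)
})

test_that("with two groups the Tukey-adjusted p equals the plain ANOVA p", {
  tab <- synthetic_table(seed = 12, lines = c("WT-1", "OE-1"))
  tab$is_reference <- tab$genotype_line == "WT-1"
  res <- per_day_tests(tab, "projected_area", method = "tukey")
  res <- res[!res$degenerate, ]
  expect_true(all(abs(res$p_adj - res$anova_p) < 1e-6))
})

test_that("Tukey and Dunnett both report every line against pooled WT", {
  tab <- synthetic_table(seed = 13)
  for (m in c("tukey", "dunnett")) {
    res <- per_day_tests(tab, "compactness", method = m)
    res <- res[!res$degenerate, ]
    expect_setequal(unique(res$line), "OE-1")
    expect_true(all(res$p_adj >= 0 & res$p_adj <= 1))
  }
  expect_error(per_day_tests(dplyr::mutate(tab, is_reference = FALSE),
                             "compactness"), "reference")
})

test_that("a shifted line is detected with high power", {
  tab <- synthetic_table(n_per = 30, days = 30, seed = 14)
  shift <- tab$genotype_line == "OE-1"
  tab$compactness[shift] <- tab$compactness[shift] +
    3 * stats::sd(tab$compactness[!shift])
  res <- per_day_tests(tab, "compactness")
  expect_true(all(res$significant[res$line == "OE-1"]))
})

test_that("size-matched curves compare equal-size plants", {
  tab <- synthetic_table(n_per = 40, days = 30, seed = 15)
  # identical size-compactness relationship in both groups
  out <- size_matched_curves(tab, "compactness")
  wide <- tidyr::pivot_wider(out, names_from = "group",
                             values_from = c("n", "mean", "sem"))
  diffs <- wide$`mean_OE-1` - wide$mean_WT
  expect_true(all(abs(diffs[is.finite(diffs)]) < 0.05))
  # a configured compactness advantage at matched size shows up per bin
  tab2 <- tab
  oe <- tab2$genotype_line == "OE-1"
  tab2$compactness[oe] <- tab2$compactness[oe] + 0.1
  out2 <- size_matched_curves(tab2, "compactness")
  wide2 <- tidyr::pivot_wider(out2, names_from = "group",
                              values_from = c("n", "mean", "sem"))
  d2 <- wide2$`mean_OE-1` - wide2$mean_WT
  expect_true(all(d2[is.finite(d2)] > 0))
  # single populated bin restricts the output
  tab3 <- tab[tab$projected_area > 50 & tab$projected_area < 100, ]
  out3 <- size_matched_curves(tab3, "compactness")
  expect_equal(length(unique(out3$size_bin)), 1)
})

test_that("relative water content follows (FW - DW)/FW * 100", {
  expect_equal(rwc(100, 20), 80)
  expect_equal(rwc(50, 50), 0)
  expect_error(rwc(0, 0), "FW")
  expect_error(rwc(10, 20), "DW")
})
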