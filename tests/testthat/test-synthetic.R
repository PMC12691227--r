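test_that("config validation enforces the cohort invariants", {
  expect_error(synthetic_cohort_config(censoring_rate = 1), "censoring_rate")
  expect_error(synthetic_cohort_config(grid_height = 8), "too small")
  expect_error(synthetic_cohort_config(category_count = 6), "fixed at 8")
  expect_error(synthetic_cohort_config(
    hazard_coefficients = c(bogus = 1)), "must be among")
  expect_error(synthetic_cohort_config(
    hazard_coefficients = c(N_ratio = Inf)), "finite")
})

test_that("label grids are deterministic and respect the necrosis target", {
  cfg <- synthetic_cohort_config(n_patients = 6L, rng_seed = 11L,
                                 necrosis_target = 0.10)
  g1 <- generate_label_grid(cfg, 2L)
  g2 <- generate_label_grid(cfg, 2L)
  expect_identical(g1$labels, g2$labels)
  expect_identical(g1$mask, g2$mask)
  ## different patients differ
  expect_false(identical(g1$labels, generate_label_grid(cfg, 3L)$labels))
  ## necrosis fraction within +/- 0.02 of the 0.10 target on a 64x64 grid
  for (i in 0:5) {
    g <- generate_label_grid(cfg, i)
    frac <- sum(g$labels[g$mask] == 1L) / sum(g$mask)
    expect_lt(abs(frac - 0.10), 0.02)
  }
  ## zero target -> zero necrosis cells
  cfg0 <- synthetic_cohort_config(n_patients = 2L, rng_seed = 11L,
                                  necrosis_target = 0)
  g0 <- generate_label_grid(cfg0, 0L)
  expect_identical(sum(g0$labels[g0$mask] == 1L), 0L)
  ## background cells are masked out
  expect_true(all(g1$labels[!g1$mask] == category_index("background")))
  expect_error(generate_label_grid(cfg, 99L), "out of range")
})

test_that("tiles are deterministic, correctly shaped, and malignancy-monotone", {
  g <- small_grid(seed = 7L)
  store <- tile_store(g, malignancy = 0.5, rng_seed = 3L, tile_size = 24L)
  cell <- which(g$labels == 0L & g$mask, arr.ind = TRUE)[1, ]
  t1 <- store$get(cell[1], cell[2])
  expect_identical(dim(t1), c(24L, 24L, 3L))
  expect_identical(t1, store$get(cell[1], cell[2]))
  ## masked cell lookup fails
  bad <- which(!g$mask, arr.ind = TRUE)[1, ]
  expect_error(store$get(bad[1], bad[2]), "masked out")
  expect_error(tile_store(g, malignancy = 1.5, rng_seed = 1L), "malignancy")
  ## nuclear staining strictly darker at malignancy 1 than 0, same seed
  lo <- tile_store(g, 0, rng_seed = 9L, tile_size = 24L)
  hi <- tile_store(g, 1, rng_seed = 9L, tile_size = 24L)
  tumor_cells <- which(g$labels == 0L & g$mask, arr.ind = TRUE)
  for (k in 1:5) {
    a <- lo$get(tumor_cells[k, 1], tumor_cells[k, 2])
    b <- hi$get(tumor_cells[k, 1], tumor_cells[k, 2])
    expect_gt(mean(1 - b), mean(1 - a))  # mean staining intensity
  }
})

test_that("survival draws honor censoring settings and the planted hazard", {
  cfg <- synthetic_cohort_config(n_patients = 400L, rng_seed = 13L,
                                 censoring_rate = 0)
  cohort <- generate_cohort(cfg, keep_grids = FALSE)
  expect_true(all(cohort$survival$event == 1L))
  ## calibrated censoring close to its target
  cfg2 <- synthetic_cohort_config(n_patients = 600L, rng_seed = 13L,
                                  censoring_rate = 0.35)
  s2 <- generate_survival(cohort$truth, cfg2)
  expect_lt(abs(mean(1 - s2$event) - 0.35), 0.07)
  ## log-hazard is exactly the planted linear form
  cf <- cfg$hazard_coefficients
  lh <- as.matrix(cohort$truth[names(cf)]) %*% cf
  expect_equal(cohort$truth$log_hazard, drop(lh), tolerance = 1e-12)
  ## higher planted necrosis hazard -> shorter observed times
  cfg3 <- synthetic_cohort_config(n_patients = 500L, rng_seed = 17L,
                                  hazard_coefficients = c(N_ratio = 12))
  c3 <- generate_cohort(cfg3, keep_grids = FALSE)
  rho <- stats::cor(c3$truth$N_ratio, c3$survival$time, method = "spearman")
  expect_lt(rho, -0.1)
})

test_that("null hazard produces exchangeable survival (KM halves agree)", {
  cfg <- synthetic_cohort_config(n_patients = 120L, rng_seed = 1L,
                                 hazard_coefficients = c(N_ratio = 0))
  cohort <- generate_cohort(cfg, keep_grids = FALSE)
  hits <- 0L
  reps <- 100L
  for (s in seq_len(reps)) {
    half <- duxplore:::with_seed(s, sample(120L, 60L))
    grp <- seq_len(120L) %in% half
    p <- logrank_test(cohort$survival$time, cohort$survival$event, grp)$p
    if (p > 0.05) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})

test_that("proportional-hazards recovery of the planted coefficients", {
  cfg <- synthetic_cohort_config(n_patients = 2000L, rng_seed = 19L)
  cohort <- generate_cohort(cfg, keep_grids = FALSE)
  cf <- cfg$hazard_coefficients
  fit <- coxph_fit(as.matrix(cohort$truth[names(cf)]),
                   cohort$survival$time, cohort$survival$event)
  for (nm in names(cf)) {
    expect_equal(sign(fit$coef[[nm]]), sign(cf[[nm]]))
    expect_lt(abs(fit$coef[[nm]] - cf[[nm]]) / abs(cf[[nm]]), 0.30)
  }
})

test_that("cohorts round-trip through the on-disk format", {
  cfg <- synthetic_cohort_config(n_patients = 3L, grid_height = 24L,
                                 grid_width = 24L, rng_seed = 5L)
  cohort <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "survival.csv")))
  g <- read_label_grid(file.path(dir, "grid_0000.tif"))
  expect_identical(g$labels, cohort$grids[[1]]$labels)
  expect_identical(g$mask, cohort$grids[[1]]$mask)
  tab <- utils::read.csv(file.path(dir, "survival.csv"))
  expect_equal(tab$time, cohort$survival$time, tolerance = 1e-6)
  expect_true(all(c("N_ratio", "FIB_center", "FIB_edge") %in% names(tab)))
  ## tiles round-trip through PNG
  g <- cohort$grids[[1]]
  cells <- which(g$mask, arr.ind = TRUE)[1:2, , drop = FALSE]
  tiles <- generate_tiles(g, 0.5, rng_seed = 2L, tile_size = 12L,
                          cells = cells)
  paths <- write_tiles(tiles, file.path(dir, "tiles"))
  expect_length(paths <- list.files(file.path(dir, "tiles"), full.names = TRUE), 2L)
  back <- png::readPNG(paths[1])
  expect_equal(dim(back), c(12, 12, 3))
})
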