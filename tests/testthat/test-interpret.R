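## A linear probe whose risk is a weighted sum of channel totals: occlusion
## deltas are then known in closed form.
linear_channel_model <- function(weights) {
  function(m) sum(vapply(1:8, function(z)
    weights[z] * sum(m$channels[, , z]), numeric(1)))
}

test_that("occlusion map is exact for an analytic channel-sum model", {
  g <- small_grid(seed = 13L, necrosis = 0.12)
  m <- build_mtop(g)
  w <- c(0, 1, 0, 0, 0, 0, 0, 0)  # reads only the necrosis channel total
  probe <- linear_channel_model(w)
  om <- occlusion_map(probe, m, window = 4L, stride = 4L)
  ## delta for a window = number of necrosis cells inside it; averaged over
  ## the single covering window the per-cell value equals the local count
  nec <- (g$labels == 1L & g$mask) * 1
  expected <- matrix(0, nrow(nec), ncol(nec))
  for (r0 in seq(1, nrow(nec) - 3, 4)) for (c0 in seq(1, ncol(nec) - 3, 4)) {
    expected[r0:(r0 + 3), c0:(c0 + 3)] <- sum(nec[r0:(r0 + 3), c0:(c0 + 3)])
  }
  expect_lt(max(abs(om$map - expected)), 1e-5)
  ## positive exactly where a window contains necrosis
  expect_true(all((om$map > 0) == (expected > 0)))
  ## occluding pure background changes nothing
  bg <- which(!g$mask & om$map == 0)
  expect_gt(length(bg), 0)
  expect_error(occlusion_map(probe, m, window = 200L), "larger")
})

test_that("occlusion maps of necrosis-trained models light up necrosis", {
  deltas <- vapply(c(21L, 22L, 23L), function(seed) {
    run <- necrosis_macro_fit(seed)
    idx <- order(run$cohort$truth$N_ratio, decreasing = TRUE)[1]
    m <- run$mtops[[idx]]
    om <- occlusion_map(run$fit$model, m, window = 6L, stride = 3L)
    nec <- m$channels[, , 2] > 0
    nrm <- m$channels[, , 5] > 0
    mean(om$map[nec]) - mean(om$map[nrm])
  }, numeric(1))
  expect_gt(mean(deltas), 0)
  expect_gte(sum(deltas > 0), 2L)
})

test_that("structural parameters quantify the planted regions", {
  ## no fibrosis anywhere
  g0 <- flat_grid(0L)
  sp0 <- structural_params(g0, band_thickness = 4L)
  expect_equal(sp0$FIB_center, 0)
  expect_equal(sp0$FIB_edge, 0)
  ## margin fibrosis of band thickness: FIB_edge >= 0.8, FIB_center <= 0.05
  cfg <- synthetic_cohort_config(n_patients = 4L, rng_seed = 4L,
                                 fib_margin_prob = 1,
                                 fib_thickness_range = c(6L, 6L))
  for (i in 0:3) {
    sp <- structural_params(generate_label_grid(cfg, i), band_thickness = 6L)
    expect_gte(sp$FIB_edge, 0.8)
    expect_lte(sp$FIB_center, 0.05)
  }
  ## necrosis fraction of tissue ~ 0.10
  cfg2 <- synthetic_cohort_config(n_patients = 2L, rng_seed = 6L,
                                  necrosis_target = 0.10)
  sp2 <- structural_params(generate_label_grid(cfg2, 0L), band_thickness = 6L)
  expect_lt(abs(sp2$N_ratio - 0.10), 0.02)
  ## invariance under 90-degree rotation
  g <- generate_label_grid(cfg2, 1L)
  rot <- tissue_label_grid(t(g$labels[nrow(g$labels):1, ]),
                           mask = t(g$mask[nrow(g$mask):1, ]))
  a <- structural_params(g, 6L); b <- structural_params(rot, 6L)
  expect_equal(a$N_ratio, b$N_ratio, tolerance = 1e-12)
  expect_equal(a$FIB_center, b$FIB_center, tolerance = 1e-12)
  expect_equal(a$FIB_edge, b$FIB_edge, tolerance = 1e-12)
  ## regions disjoint
  expect_error(structural_params(flat_grid(4L)), "no tumor")
})

test_that("structural Cox recovers planted signs and matches the reference", {
  skip_if_not(requireNamespace("survival", quietly = TRUE))
  ## planted (+, +, -) pattern at n = 1000
  cfg <- synthetic_cohort_config(n_patients = 1000L, rng_seed = 23L)
  cohort <- generate_cohort(cfg, keep_grids = FALSE)
  tab <- structural_cox(cohort$truth, cohort$survival)
  expect_identical(tab$Covariate, c("N_ratio", "FIB_center", "FIB_edge"))
  expect_gt(tab$HR[1], 1)
  expect_gt(tab$HR[2], 1)
  expect_lt(tab$HR[3], 1)
  expect_true(all(tab$CI_Lower < tab$HR & tab$HR < tab$CI_Upper))
  ## null covariates: each coefficient within 2 SE at the nominal rate
  hits <- 0L
  for (s in 1:20) {
    duxplore:::with_seed(900L + s, {
      n <- 300
      x <- matrix(stats::rnorm(n * 3), n, 3,
                  dimnames = list(NULL, c("N_ratio", "FIB_center", "FIB_edge")))
      surv <- data.frame(time = stats::rexp(n, 0.05),
                         event = stats::rbinom(n, 1, 0.7))
      tb <- structural_cox(as.data.frame(x), surv)
      hits <- hits + sum(abs(tb$Coef) < 2 * tb$Se_Coef)
    })
  }
  expect_gte(hits / 60, 0.9)
  ## single binary covariate agrees with the reference fit
  duxplore:::with_seed(24L, {
    n <- 200
    grp <- rep(c(0, 1), each = n / 2)
    tt <- stats::rexp(n, 0.05 * exp(0.6 * grp))
    ee <- stats::rbinom(n, 1, 0.8)
    f1 <- coxph_fit(cbind(g = grp), tt, pmax(ee, c(1, rep(0, n - 1))))
    f2 <- survival::coxph(survival::Surv(tt, pmax(ee, c(1, rep(0, n - 1)))) ~ grp,
                          ties = "breslow")
    expect_lt(abs(f1$coef - stats::coef(f2)), 1e-4)
  })
})

test_that("risk extremes select the score tails", {
  sc <- 1:100
  ex <- risk_extremes(sc, 0.10)
  expect_identical(ex$low_risk, 1:10)
  expect_identical(ex$high_risk, 91:100)
  halves <- risk_extremes(sc, 0.5)
  expect_identical(halves$low_risk, 1:50)
  expect_error(risk_extremes(1:5, 0.1), "no patients")
  ## monotone scores preserve true-hazard extremes
  duxplore:::with_seed(3L, {
    h <- stats::rnorm(40)
    ex1 <- risk_extremes(h, 0.1)
    ex2 <- risk_extremes(2 * h + 5, 0.1)
    expect_identical(ex1, ex2)
  })
})
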