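test_that("cox loss matches the hand-computed partial likelihood", {
  ## three patients, times (1,2,3), all events, equal scores:
  ## risk sets of sizes 3, 2, 1 -> log 3 + log 2 + log 1
  expect_equal(cox_loss(c(1, 2, 3), c(1, 1, 1), c(0, 0, 0)),
               log(3) + log(2), tolerance = 1e-12)
  ## singleton event: its own risk set
  expect_equal(cox_loss(4.2, 1, 1.7), 0)
  ## shift invariance
  duxplore:::with_seed(2L, {
    tt <- stats::rexp(30); ee <- stats::rbinom(30, 1, 0.6); ss <- stats::rnorm(30)
    ee[1] <- 1L
    expect_lt(abs(cox_loss(tt, ee, ss) - cox_loss(tt, ee, ss + 123.4)), 1e-6)
    ## gradient agrees with finite differences
    lg <- duxplore:::cox_loss_grad(tt, ee, ss)
    for (i in sample(30, 6)) {
      h <- 1e-6
      sp <- ss; sp[i] <- sp[i] + h
      sm <- ss; sm[i] <- sm[i] - h
      num <- (cox_loss(tt, ee, sp) - cox_loss(tt, ee, sm)) / (2 * h)
      expect_lt(abs(num - lg$grad[i]), 1e-6)
    }
  })
  ## zero events: the skip-batch signal, not NaN
  expect_error(cox_loss(c(1, 2), c(0, 0), c(0, 0)), class = "dux_no_events")
})

test_that("concordance equals the brute-force oracle and calibrates on noise", {
  duxplore:::with_seed(33L, {
    for (rep in 1:50) {
      n <- sample(5:100, 1)
      tt <- sample(1:60, n, replace = TRUE)
      ee <- stats::rbinom(n, 1, 0.7)
      if (sum(ee) == 0) ee[1] <- 1L
      rr <- round(stats::rnorm(n), 1)  # induces risk ties
      ok <- tryCatch(concordance_index(tt, ee, rr), error = function(e) NULL)
      if (is.null(ok)) next
      expect_equal(ok, brute_cindex(tt, ee, rr), tolerance = 1e-12)
    }
    ## random scores at n=1000: C-index 0.5 +/- 0.03
    tt <- stats::rexp(1000); ee <- stats::rbinom(1000, 1, 0.7)
    expect_lt(abs(concordance_index(tt, ee, stats::rnorm(1000)) - 0.5), 0.03)
    ## perfect inverse ranking
    tt <- sort(stats::rexp(50))
    expect_equal(concordance_index(tt, rep(1, 50), -tt), 1)
    expect_error(concordance_index(c(1, 1), c(1, 1), c(0, 1)), "comparable")
  })
})

test_that("integrated Brier matches the reference implementation", {
  skip_if_not(requireNamespace("survival", quietly = TRUE))
  withr::defer(if (exists(".dux_brier_df", envir = globalenv()))
    rm(".dux_brier_df", envir = globalenv()))
  duxplore:::with_seed(44L, {
    for (rep in 1:20) {
      n <- 120
      x <- stats::rnorm(n)
      T0 <- stats::rexp(n, 0.1 * exp(0.7 * x))
      C0 <- stats::rexp(n, 0.05)
      tt <- pmin(T0, C0); ee <- as.integer(T0 <= C0)
      if (sum(ee) < 5) next
      ## survival::brier re-evaluates the model call, so the data must be
      ## findable from the global environment
      assign(".dux_brier_df", data.frame(time = tt, ev = ee, x = x),
             envir = globalenv())
      fit <- survival::coxph(survival::Surv(time, ev) ~ x,
                             data = get(".dux_brier_df", envir = globalenv()),
                             ties = "breslow")
      fit$call$data <- as.name(".dux_brier_df")
      et <- sort(unique(tt[ee == 1]))
      grid <- et[et < stats::quantile(tt, 0.85)]
      if (length(grid) < 3) next
      lp <- stats::predict(fit, type = "lp")
      base <- breslow_baseline(tt, ee, lp)
      sm <- predict_survival(base, lp, grid)
      ref <- survival::brier(fit, times = grid, ties = FALSE)$brier
      ours <- vapply(seq_along(grid), function(j)
        integrated_brier(tt, ee, sm[, j, drop = FALSE], grid[j]), numeric(1))
      expect_lt(max(abs(ours - ref)), 1e-6)
    }
    ## constant S(t) = 0.5 without censoring: Brier 0.25 at every time
    tt <- stats::rexp(60); ee <- rep(1L, 60)
    grid <- sort(tt)[10:50]
    expect_equal(integrated_brier(tt, ee, matrix(0.5, 60, length(grid)), grid),
                 0.25, tolerance = 1e-12)
    ## KM prediction at a single time equals the binomial Brier of the KM
    km <- km_estimator(tt, ee)
    t0 <- stats::median(tt)
    s0 <- km_surv(km, t0)
    alive <- tt > t0
    expect_equal(
      integrated_brier(tt, ee, matrix(s0, 60, 1), t0),
      mean(ifelse(alive, (1 - s0)^2, s0^2)), tolerance = 1e-12)
  })
})

test_that("IPCW-MAE reduces to plain normalized MAE without censoring", {
  duxplore:::with_seed(55L, {
    tt <- stats::rexp(40); ee <- rep(1L, 40)
    pred <- tt * stats::runif(40, 0.5, 1.5)
    expect_equal(ipcw_mae(tt, ee, pred), mean(abs(tt - pred)) / max(tt),
                 tolerance = 1e-12)
    expect_equal(ipcw_mae(tt, ee, tt), 0)
    ## hand-rolled weighted sum on a 10-patient cohort with censoring
    tt <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
    ee <- c(1, 0, 1, 1, 0, 1, 0, 1, 1, 0)
    pred <- c(2, 2, 2, 5, 5, 5, 8, 8, 8, 8)
    G <- km_estimator(tt, 1 - ee)
    g <- km_surv(G, tt, left = TRUE)
    w <- 1 / g[ee == 1]
    manual <- sum(w * abs(tt[ee == 1] - pred[ee == 1]) / 10) / sum(w)
    expect_equal(ipcw_mae(tt, ee, pred), manual, tolerance = 1e-12)
  })
})

test_that("log-rank and stratification behave like the reference", {
  skip_if_not(requireNamespace("survival", quietly = TRUE))
  duxplore:::with_seed(66L, {
    for (rep in 1:10) {
      n <- 80
      tt <- round(stats::rexp(n), 1) + 0.1
      ee <- stats::rbinom(n, 1, 0.7)
      g <- stats::rbinom(n, 1, 0.5)
      if (length(unique(g)) < 2 || sum(ee) == 0) next
      ours <- logrank_test(tt, ee, g)
      ref <- survival::survdiff(survival::Surv(tt, ee) ~ g)
      expect_lt(abs(ours$chisq - ref$chisq), 1e-6)
    }
    ## identical survival in both groups: p near 1
    tt <- rep(c(1, 2, 3, 4, 5), 8); ee <- rep(1L, 40)
    g <- rep(c(0, 1), 20)
    expect_gt(logrank_test(tt, ee, g)$p, 0.9)
    ## median split: ties to the low-risk group
    risk <- c(1, 2, 2, 5)  # median 2; only the strict exceeder is high-risk
    st <- stratify_km(stats::rexp(4) + 0.1, rep(1L, 4), risk)
    expect_identical(sum(st$group), 1L)
    expect_error(stratify_km(c(1, 2, 3, 4), rep(1L, 4), rep(2, 4)),
                 "degenerate")
  })
})

test_that("hazard-ratio-3.87 cohorts separate at the planted power", {
  ## two groups with HR 3.87 at n=300: log-rank p < 0.001 nearly always
  hits <- 0L
  reps <- 25L
  for (s in seq_len(reps)) {
    duxplore:::with_seed(700L + s, {
      grp <- rep(c(0L, 1L), each = 150L)
      tt <- stats::rexp(300, 0.03 * 3.87^grp)
      cens <- stats::rexp(300, 0.015)
      ee <- as.integer(tt <= cens)
      obs <- pmin(tt, cens)
      if (logrank_test(obs, ee, grp)$p < 0.001) hits <- hits + 1L
    })
  }
  expect_gte(hits / reps, 0.95)
})

test_that("fold statistics reproduce the t-based protocol", {
  ## hand-checked interval: mean 0.72 +/- 2.776 * SE at df = 4
  x <- c(0.70, 0.71, 0.72, 0.73, 0.74)
  scores <- data.frame(model = "m", fold = 1:5, score = x)
  fs <- fold_statistics(scores)
  se <- stats::sd(x) / sqrt(5)
  expect_equal(fs$summary$mean, 0.72)
  expect_equal(fs$summary$ci_upper, 0.72 + stats::qt(0.975, 4) * se,
               tolerance = 1e-12)
  ## identical fold scores: zero-width interval
  same <- data.frame(model = "m", fold = 1:5, score = rep(0.7, 5))
  expect_equal(fold_statistics(same)$summary$ci_lower, 0.7)
  ## a model against itself: p = 1 (flagged degenerate)
  two <- rbind(data.frame(model = "a", fold = 1:5, score = x),
               data.frame(model = "b", fold = 1:5, score = x))
  expect_equal(fold_statistics(two)$pairwise$p, 1)
  ## three models: repeated-measures ANOVA terms are produced
  three <- rbind(two, data.frame(model = "c", fold = 1:5, score = x + 0.02))
  an <- fold_statistics(three)$anova
  expect_true(is.finite(an$F) && is.finite(an$p))
  expect_error(fold_statistics(data.frame(model = "a", fold = 1, score = 1)),
               "folds")
})

test_that("stratified folds partition patients and preserve event fractions", {
  duxplore:::with_seed(77L, {
    ev <- stats::rbinom(100, 1, 0.6)
    f1 <- make_folds(ev, k = 5L, seed = 9L)
    f2 <- make_folds(ev, k = 5L, seed = 9L)
    expect_identical(f1, f2)
    expect_identical(sort(unique(f1)), 1:5)
    expect_lte(diff(range(table(f1))), 2L)  # balanced within each stratum
    target <- mean(ev)
    for (k in 1:5)
      expect_lte(abs(sum(ev[f1 == k]) - target * sum(f1 == k)), 1.5)
  })
})

test_that("training honors degenerate and capped configurations", {
  mac <- macro_net(encoder_spec("tiny_test", 8L, feature_dim = 4L), seed = 5L)
  duxplore:::with_seed(6L, {
    x <- array(stats::rnorm(12 * 8 * 8 * 8), c(12, 8, 8, 8))
    surv <- data.frame(time = stats::rexp(12) + 0.1,
                       event = rep(c(1L, 0L), 6))
    ## learning rate zero leaves the weights untouched
    fit0 <- train_branch(mac, x, surv,
                         config = train_config(learning_rate = 0,
                                               max_epochs = 3L), seed = 2L)
    expect_equal(duxplore:::model_layerlist(fit0$model)[[1]]$W,
                 mac$layers[[1]]$W)
    ## history never exceeds the epoch cap
    fit <- train_branch(mac, x, surv,
                        config = train_config(learning_rate = 1e-3,
                                              max_epochs = 7L), seed = 2L)
    expect_lte(nrow(fit$history), 7L)
    ## determinism: same seed, same history and weights
    fit2 <- train_branch(mac, x, surv,
                         config = train_config(learning_rate = 1e-3,
                                               max_epochs = 7L), seed = 2L)
    expect_identical(fit$history, fit2$history)
    expect_identical(duxplore:::model_layerlist(fit$model)[[1]]$W,
                     duxplore:::model_layerlist(fit2$model)[[1]]$W)
  })
})

test_that("macro branch learns a necrosis-driven hazard", {
  run <- necrosis_macro_fit(21L)
  expect_gt(run$fit$best_val, 0.65)
  expect_lte(nrow(run$fit$history), 30L)
  ## model risk ranks align with the true log-hazard
  risk <- predict(run$fit$model, run$x)
  rho <- stats::cor(risk, run$cohort$truth$log_hazard, method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("cross-validation partitions patients and shares splits by seed", {
  duxplore:::with_seed(88L, {
    ev <- stats::rbinom(40, 1, 0.7)
    surv <- data.frame(time = stats::rexp(40) + 0.1, event = ev)
    x <- array(stats::rnorm(40 * 8 * 8 * 8), c(40, 8, 8, 8))
    res <- cross_validate(
      x, surv, function() macro_net(
        encoder_spec("tiny_test", 8L, feature_dim = 4L), seed = 3L),
      k = 4L, config = train_config(learning_rate = 1e-3, max_epochs = 2L),
      seed = 5L)
    expect_identical(nrow(res), 4L)
    folds <- attr(res, "folds")
    expect_true(all(table(folds) == 10))
    expect_identical(folds, make_folds(ev, 4L, duxplore:::derive_seed(5L, 7)))
  })
})
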