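test_that("architecture dimension contracts hold", {
  ## macro: 8 channels in, 32-dim embedding out
  mac <- macro_net(encoder_spec("tiny_test", 8L), seed = 1L)
  x <- array(0, dim = c(2, 16, 16, 8))
  out <- macro_forward(mac, x)
  expect_identical(dim(out$embedding), c(2L, 32L))
  expect_true(all(is.finite(out$risk)))       # all-zero input stays finite
  expect_true(all(out$embedding >= 0))        # post-ReLU projection
  ## micro: 81 channels (3 x 27), slot-count guard
  mic <- micro_net(seed = 1L)
  expect_identical(mic$spec$in_channels, 81L)
  xi <- array(stats::rnorm(2 * 8 * 8 * 81), dim = c(2, 8, 8, 81))
  expect_identical(dim(micro_forward(mic, xi)$embedding), c(2L, 32L))
  expect_error(micro_forward(mic, array(0, c(1, 8, 8, 24))), "slots")
  expect_error(macro_net(encoder_spec("tiny_test", 12L)), "8 input channels")
  ## reference encoder emits 2048-dim features
  ref <- macro_net(encoder_spec("reference_large", 8L), seed = 1L)
  expect_identical(ref$spec$feature_dim, 2048L)
  feat <- duxplore:::nn_forward(
    ref$layers[seq_len(ref$encoder_end)],
    array(stats::rnorm(16 * 16 * 8), c(1, 16, 16, 8)))$out
  expect_identical(dim(feat), c(1L, 2048L))
})

test_that("fused model concatenates 64 dims and sees both branches", {
  fm <- duxplore_net(macro_net(seed = 2L), micro_net(seed = 3L), seed = 4L)
  expect_identical(dim(fm$fusion[[1]]$W), c(64L, 32L))
  xm <- array(stats::rnorm(3 * 16 * 16 * 8), c(3, 16, 16, 8))
  xi <- array(stats::rnorm(3 * 8 * 8 * 81), c(3, 8, 8, 81))
  out <- duxplore_forward(fm, xm, xi)
  expect_length(out$risk, 3L)
  expect_identical(dim(out$macro_embedding), c(3L, 32L))
  ## zeroing the micro embedding changes PaTRS (fusion weights nonzero)
  z <- cbind(out$macro_embedding, 0 * out$micro_embedding)
  alt <- as.numeric(duxplore:::nn_forward(fm$fusion, z)$out)
  expect_false(isTRUE(all.equal(alt, out$risk)))
})

test_that("gradients reach every parameterized layer of both branches", {
  fm <- duxplore_net(
    macro_net(encoder_spec("tiny_test", 8L, feature_dim = 4L), seed = 2L),
    micro_net(encoder_spec("tiny_test", 81L, feature_dim = 4L), seed = 3L),
    seed = 4L)
  duxplore:::with_seed(5L, {
    x <- list(macro = array(stats::rnorm(6 * 8 * 8 * 8), c(6, 8, 8, 8)),
              micro = array(stats::rnorm(6 * 6 * 6 * 81), c(6, 6, 6, 81)))
    surv <- data.frame(time = stats::rexp(6) + 0.1, event = c(1, 1, 0, 1, 1, 1))
    before <- duxplore:::model_layerlist(fm)
    fit <- train_branch(fm, x, surv,
                        config = train_config(learning_rate = 1e-2,
                                              max_epochs = 1L,
                                              val_fraction = 0.34),
                        seed = 6L)
    after <- duxplore:::model_layerlist(fit$model)
    for (i in seq_along(before)) {
      for (p in duxplore:::param_names(before[[i]])) {
        if (p %in% c("W", "gamma"))
          expect_gt(max(abs(before[[i]][[p]] - after[[i]][[p]])), 0)
      }
    }
  })
})

test_that("analytic gradient matches finite differences through the stack", {
  model <- macro_net(encoder_spec("tiny_test", 8L, feature_dim = 5L), seed = 9L)
  duxplore:::with_seed(10L, {
    n <- 6
    x <- array(stats::rnorm(n * 8 * 8 * 8), c(n, 8, 8, 8))
    tt <- stats::rexp(n) + 0.1
    ee <- c(1, 0, 1, 1, 0, 1)
    layers <- duxplore:::model_layerlist(model)
    fw <- duxplore:::trainable_forward(model, layers, x, train = TRUE)
    lg <- duxplore:::cox_loss_grad(tt, ee, fw$risk)
    grads <- duxplore:::trainable_backward(model, fw$layers, fw$ctx, lg$grad)
    for (li in seq_along(layers)) {
      for (p in duxplore:::param_names(layers[[li]])) {
        ks <- sample(length(layers[[li]][[p]]), min(3, length(layers[[li]][[p]])))
        for (k in ks) {
          h <- 1e-5
          lp <- layers; lp[[li]][[p]][k] <- lp[[li]][[p]][k] + h
          lm <- layers; lm[[li]][[p]][k] <- lm[[li]][[p]][k] - h
          fp <- duxplore:::trainable_forward(model, lp, x, train = TRUE)$risk
          fmns <- duxplore:::trainable_forward(model, lm, x, train = TRUE)$risk
          num <- (cox_loss(tt, ee, fp) - cox_loss(tt, ee, fmns)) / (2 * h)
          expect_lt(abs(num - grads[[li]][[p]][k]) / max(1, abs(num)), 1e-4)
        }
      }
    }
  })
})

test_that("risk ordering is invariant to affine transforms of the head", {
  mac <- macro_net(seed = 3L)
  duxplore:::with_seed(4L, {
    x <- array(stats::rnorm(20 * 16 * 16 * 8), c(20, 16, 16, 8))
    risk <- predict(mac, x)
    tt <- stats::rexp(20) + 0.1; ee <- stats::rbinom(20, 1, 0.8)
    ee[1] <- 1L
    ci1 <- concordance_index(tt, ee, risk)
    ci2 <- concordance_index(tt, ee, 3.7 * risk + 11)
    expect_equal(ci1, ci2)
  })
})

test_that("tiny micro forward pass is fast enough for interactive use", {
  mic <- micro_net(seed = 1L)
  x <- array(stats::rnorm(16 * 8 * 8 * 81), c(16, 8, 8, 81))
  elapsed <- system.time(micro_forward(mic, x))["elapsed"]
  expect_lt(elapsed, 5)
})

test_that("fused model is at least as good as the better branch on a
           cohort whose hazard needs both scales", {
  scores <- lapply(c(51L, 52L), function(seed) {
    cc <- synthetic_cohort_config(
      n_patients = 80L, rng_seed = seed, tile_size = 12L,
      hazard_coefficients = c(N_ratio = 12, malignancy = 3))
    cohort <- generate_cohort(cc)
    xm <- stack_mtops_helper(lapply(cohort$grids, function(g)
      resize_mtop(build_mtop(g), c(16L, 16L))))
    xi <- duxplore:::build_fst_inputs(cohort, N = 27L, tile_size = 12L,
                                      rng_seed = seed)
    tc <- tiny_train_config(max_epochs = 20L)
    f_ma <- train_branch(macro_net(seed = seed), xm, cohort$survival,
                         config = tc, seed = seed)
    f_mi <- train_branch(micro_net(seed = seed), xi, cohort$survival,
                         config = tc, seed = seed)
    f_fu <- train_branch(duxplore_net(macro_net(seed = seed),
                                      micro_net(seed = seed), seed = seed),
                         list(macro = xm, micro = xi), cohort$survival,
                         config = tc, seed = seed)
    c(macro = f_ma$best_val, micro = f_mi$best_val, fused = f_fu$best_val)
  })
  avg <- colMeans(do.call(rbind, scores))
  expect_gte(avg[["fused"]], max(avg[["macro"]], avg[["micro"]]) - 0.05)
})
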