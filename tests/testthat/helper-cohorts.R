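## Shared fixtures, built in code. Sizes are chosen so the whole suite runs
## in minutes on one CPU; the methods vignette records the scaling choices.

small_grid <- function(seed = 3L, necrosis = NULL, ...) {
  cfg <- synthetic_cohort_config(n_patients = 4L, rng_seed = seed,
                                 necrosis_target = necrosis, ...)
  generate_label_grid(cfg, 0L)
}

## Uniform-label grid for exact-arithmetic checks.
flat_grid <- function(label = 0L, h = 16L, w = 16L) {
  tissue_label_grid(matrix(label, h, w), mask = matrix(TRUE, h, w))
}

## Brute-force O(n^2) concordance oracle (literal double loop).
brute_cindex <- function(time, event, risk) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
    }
  }
  num / den
}

## Exact apportionment oracle: dynamic program minimizing
## sum_z |n_z - r_z * N| subject to sum n_z = N, 0 <= n_z <= avail_z.
## Returns the minimal objective value.
dp_allocate_objective <- function(r, N, avail) {
  q <- r * N
  best <- c(0, rep(Inf, N))          # best[s + 1]: cost using categories so far
  for (z in seq_along(r)) {
    nxt <- rep(Inf, N + 1)
    for (s in 0:N) {
      if (!is.finite(best[s + 1])) next
      for (nz in 0:min(avail[z], N - s)) {
        cost <- best[s + 1] + abs(nz - q[z])
        if (cost < nxt[s + nz + 1]) nxt[s + nz + 1] <- cost
      }
    }
    best <- nxt
  }
  best[N + 1]
}

## Small trained macro fixture shared by model/interpret tests (memoised).
necrosis_fit_cache <- new.env(parent = emptyenv())
necrosis_macro_fit <- function(seed = 21L) {
  key <- as.character(seed)
  if (!is.null(necrosis_fit_cache[[key]])) return(necrosis_fit_cache[[key]])
  cc <- synthetic_cohort_config(n_patients = 120L, rng_seed = seed,
                                hazard_coefficients = c(N_ratio = 20),
                                censoring_rate = 0.3)
  cohort <- generate_cohort(cc)
  mtops <- lapply(cohort$grids, function(g)
    resize_mtop(build_mtop(g), c(16L, 16L)))
  x <- stack_mtops_helper(mtops)
  fit <- train_branch(macro_net(seed = seed), x, cohort$survival,
                      config = tiny_train_config(), seed = seed)
  out <- list(fit = fit, cohort = cohort, mtops = mtops, x = x)
  necrosis_fit_cache[[key]] <- out
  out
}

stack_mtops_helper <- function(mtops) {
  d <- dim(mtops[[1]]$channels)
  x <- array(0, dim = c(length(mtops), d))
  for (i in seq_along(mtops)) x[i, , , ] <- mtops[[i]]$channels
  x
}
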