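#' Slide-level tissue proportions
#'
#' @param grid A [tissue_label_grid()].
#' @return Numeric vector `r` of length 8 (named by category): the fraction
#'   of unmasked cells carrying each category. Sums to 1.
#' @export
compute_proportions <- function(grid) {
  stopifnot(inherits(grid, "tissue_label_grid"))
  lab <- grid$labels[grid$mask]
  if (length(lab) == 0L) stop("empty slide: no unmasked cells")
  r <- tabulate(lab + 1L, nbins = 8L) / length(lab)
  stats::setNames(r, names(duxplore_categories()))
}

#' Apportion the patch budget across tissue categories
#'
#' Turns the tissue proportions into integer per-category patch counts
#' summing exactly to `N`. The target for category *z* is `r_z * N`; the
#' integer allocation minimizes the total absolute deviation from those
#' targets subject to the per-category availability caps. The algorithm
#' starts from the capped floors and assigns the remaining slots greedily by
#' marginal cost, which reduces to floor + largest-remainder (Hamilton
#' apportionment) when availability is ample; when a category cannot supply
#' its share, the shortfall flows to the categories that can, favoring
#' larger `r_z` (then lower index) on ties.
#'
#' @param proportions Length-8 non-negative vector summing to 1.
#' @param N Total patch budget (default 27).
#' @param availability Length-8 integer vector of patches available per
#'   category.
#' @return An object of class `sampling_plan`: list with `n` (length-8
#'   integer allocation), `N`, `targets`.
#' @export
allocate <- function(proportions, N = 27L, availability) {
  r <- as.numeric(proportions)
  stopifnot(length(r) == 8L, length(availability) == 8L)
  if (any(r < 0) || abs(sum(r) - 1) > 1e-9)
    stop("proportions must be non-negative and sum to 1")
  avail <- as.integer(availability)
  if (sum(avail) < N)
    stop(sprintf("insufficient tissue: %d patches available, %d required",
                 sum(avail), as.integer(N)))
  q <- r * N
  n <- pmin(floor(q), avail)
  while (sum(n) < N) {
    open <- which(n < avail)
    cost <- round(abs(n[open] + 1 - q[open]) - abs(n[open] - q[open]), 9)
    pick <- open[order(cost, -r[open], open)[1L]]
    n[pick] <- n[pick] + 1L
  }
  structure(list(n = stats::setNames(as.integer(n),
                                     names(duxplore_categories())),
                 N = as.integer(N), targets = q),
            class = "sampling_plan")
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat(sprintf("<sampling_plan> N = %d\n", x$N))
  print(x$n)
  invisible(x)
}

#' Per-category patch availability of a grid
#'
#' @param grid A [tissue_label_grid()].
#' @return Length-8 integer vector of unmasked cell counts per category.
#' @export
availability <- function(grid) {
  stats::setNames(tabulate(grid$labels[grid$mask] + 1L, nbins = 8L),
                  names(duxplore_categories()))
}

#' Sample patches and assemble the fused structure tensor
#'
#' Three strategies are supported. `category` performs the structure-aware
#' stratified draw: `n_z` cells uniformly without replacement within each
#' category, per the sampling plan. `random` draws the whole budget
#' uniformly from all unmasked cells; `tumor_only` draws it from
#' tumor-labeled cells. Slots are ordered by category index ascending, then
#' draw order, so channel semantics are stable across patients.
#'
#' @param grid A [tissue_label_grid()].
#' @param plan A `sampling_plan` (required for the `category` strategy; for
#'   the others only its `N` is used).
#' @param tiles A `tile_store` for the grid.
#' @param strategy One of `"category"`, `"random"`, `"tumor_only"`.
#' @param rng_seed Integer seed; the draw is deterministic given it.
#' @return An object of class `fst_tensor`: list with `tiles` (array
#'   `L x W x 3 x N`), `slot_category`, `provenance` (slot, category, row,
#'   col), `N`.
#' @export
sample_patches <- function(grid, plan, tiles,
                           strategy = c("category", "random", "tumor_only"),
                           rng_seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(grid, "tissue_label_grid"), inherits(plan, "sampling_plan"))
  H <- nrow(grid$labels)
  cells <- with_seed(derive_seed(rng_seed, 31337), {
    if (strategy == "category") {
      picked <- list()
      for (z in 0:7) {
        nz <- plan$n[z + 1L]
        if (nz == 0L) next
        pool <- which(grid$labels == z & grid$mask)
        if (length(pool) < nz)
          stop(sprintf("category %d has %d cells but the plan needs %d",
                       z, length(pool), nz))
        sel <- if (length(pool) == 1L) pool else sample(pool, nz)
        picked[[length(picked) + 1L]] <- cbind(idx = sel, cat = z)
      }
      do.call(rbind, picked)
    } else {
      pool <- if (strategy == "random") which(grid$mask) else
        which(grid$labels == category_index("tumor") & grid$mask)
      if (strategy == "tumor_only" && length(pool) == 0L)
        stop("tumor_only strategy requires at least one tumor-labeled cell")
      if (length(pool) < plan$N)
        stop(sprintf("insufficient tissue: %d cells available, %d required",
                     length(pool), plan$N))
      sel <- sample(pool, plan$N)
      m <- cbind(idx = sel, cat = grid$labels[sel])
      m[order(m[, "cat"], seq_len(nrow(m))), , drop = FALSE]
    }
  })
  rows <- ((cells[, "idx"] - 1L) %% H) + 1L
  cols <- ((cells[, "idx"] - 1L) %/% H) + 1L
  L <- tiles$tile_size
  arr <- array(0, dim = c(L, L, 3, nrow(cells)))
  for (k in seq_len(nrow(cells))) arr[, , , k] <- tiles$get(rows[k], cols[k])
  structure(list(
    tiles = arr,
    slot_category = as.integer(cells[, "cat"]),
    provenance = data.frame(slot = seq_len(nrow(cells)),
                            category = as.integer(cells[, "cat"]),
                            row = rows, col = cols),
    N = nrow(cells), rng_seed = rng_seed
  ), class = "fst_tensor")
}

#' @export
print.fst_tensor <- function(x, ...) {
  cat(sprintf("<fst_tensor> %d slots of %d x %d tiles (%d channels flattened)\n",
              x$N, dim(x$tiles)[1], dim(x$tiles)[2], 3L * x$N))
  print(table(factor(x$slot_category, levels = 0:7,
                     labels = names(duxplore_categories()))))
  invisible(x)
}

#' Flattened channel view of a fused structure tensor
#'
#' Stacks the N RGB tiles along the channel axis, slot-major (slot 1's three
#' channels, then slot 2's, ...), giving the `3N`-channel image the micro
#' encoder consumes — 81 channels for the default 27-slot tensor.
#'
#' @param fst An `fst_tensor`.
#' @return Array `L x W x 3N`.
#' @export
fst_channels <- function(fst) {
  d <- dim(fst$tiles)
  aperm(fst$tiles, c(1, 2, 3, 4)) |>
    array(dim = c(d[1], d[2], d[3] * d[4]))
}

#' Sampling-strategy / budget sweep
#'
#' Trains and evaluates the micro branch for every (strategy, size) cell
#' under a shared cross-validation protocol, the harness behind the
#' input-strategy comparison. A model factory supplies a fresh micro model
#' per fold.
#'
#' @param cohort A generated cohort (with grids).
#' @param strategies Character vector of sampling strategies.
#' @param sizes Integer vector of patch budgets (default `c(8, 16, 27, 36)`).
#' @param model_factory Function `(n_slots, in_channels) -> dux_branch`.
#' @param config A [train_config()].
#' @param k Number of CV folds.
#' @param tile_size Tile side length used to render patches.
#' @param rng_seed Seed controlling the shared splits and draws.
#' @return Data frame with one row per (strategy, size, fold) and the fold
#'   C-index, plus a `summary` attribute with mean and 95% t-interval.
#' @export
sweep_harness <- function(cohort, strategies = c("category", "random", "tumor_only"),
                          sizes = c(8L, 16L, 27L, 36L),
                          model_factory, config = train_config(),
                          k = 5L, tile_size = 16L, rng_seed = 1L) {
  surv <- cohort$survival
  folds <- make_folds(surv$event, k = k, seed = derive_seed(rng_seed, 5))
  out <- list()
  for (strategy in strategies) {
    for (N in sizes) {
      x <- build_fst_inputs(cohort, N = N, strategy = strategy,
                            tile_size = tile_size, rng_seed = rng_seed)
      for (fold in seq_len(k)) {
        test_idx <- which(folds == fold)
        model <- model_factory(n_slots = N, in_channels = 3L * N)
        fit <- train_branch(model, x[-test_idx, , , , drop = FALSE],
                            surv[-test_idx, ], config = config,
                            seed = derive_seed(rng_seed, fold, N))
        risk <- predict(fit$model, x[test_idx, , , , drop = FALSE])
        ci <- concordance_index(surv$time[test_idx], surv$event[test_idx], risk)
        out[[length(out) + 1L]] <- data.frame(
          strategy = strategy, size = N, fold = fold, c_index = ci)
      }
    }
  }
  res <- do.call(rbind, out)
  agg <- do.call(rbind, lapply(split(res, list(res$strategy, res$size),
                                     drop = TRUE), function(d) {
    ci <- t_interval(d$c_index)
    data.frame(strategy = d$strategy[1], size = d$size[1],
               mean = ci$mean, ci_lower = ci$lower, ci_upper = ci$upper)
  }))
  rownames(agg) <- NULL
  attr(res, "summary") <- agg
  res
}

## Stack per-patient FST channel views into one (n, L, W, 3N) array.
build_fst_inputs <- function(cohort, N = 27L, strategy = "category",
                             tile_size = 16L, rng_seed = 1L) {
  n <- cohort$config$n_patients
  L <- tile_size
  x <- array(0, dim = c(n, L, L, 3L * N))
  for (i in seq_len(n)) {
    g <- cohort$grids[[i]]
    store <- tile_store(g, cohort$truth$malignancy[i],
                        derive_seed(rng_seed, 17, i), tile_size)
    plan <- allocate(compute_proportions(g), N = N,
                     availability = availability(g))
    fst <- sample_patches(g, plan, store, strategy = strategy,
                          rng_seed = derive_seed(rng_seed, 23, i))
    x[i, , , ] <- fst_channels(fst)
  }
  x
}
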