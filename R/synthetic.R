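#' Configuration for a synthetic whole-slide cohort
#'
#' The generator emulates the three things the downstream pipeline needs from
#' a real cohort: spatially coherent tissue-label grids (elliptical tumor
#' core in a normal-liver field, a fibrosis band at the tumor margin or
#' inside the core, necrosis blobs matching a per-patient target fraction),
#' procedural H&E-like tiles whose nuclear texture tracks a latent malignancy
#' level, and survival times drawn from a proportional-hazards model whose
#' log-hazard is a known linear function of the structural parameters.
#'
#' @param n_patients Number of patients.
#' @param grid_height,grid_width Patch-grid dimensions (cells, each >= 16).
#' @param hazard_coefficients Named numeric vector of log-hazard weights on
#'   any of `N_ratio`, `FIB_center`, `FIB_edge`, `malignancy`. The
#'   per-patient true log-hazard is exactly the dot product of these weights
#'   with the true structural parameters.
#' @param censoring_rate Target fraction of censored patients in `[0, 1)`.
#' @param baseline_hazard Baseline event rate (events per month).
#' @param rng_seed Integer seed; all generation is deterministic given it.
#' @param tile_size Tile side length in pixels (224 at slide scale; tests use
#'   smaller tiles).
#' @param necrosis_range Range the per-patient necrosis target fraction (of
#'   tissue cells) is drawn from; or use `necrosis_target` to fix it.
#' @param necrosis_target Optional fixed necrosis fraction for all patients.
#' @param tumor_frac_range Range of the tumor-core fraction of tissue.
#' @param fib_margin_prob Probability a patient's fibrosis band sits at the
#'   tumor margin (otherwise inside the core).
#' @param fib_thickness_range Integer range of fibrosis band thickness, cells.
#' @param band_thickness Margin-band thickness (cells) used for the ground
#'   truth structural parameters; 6 suits the default 64-cell grids where the
#'   tumor radius is around 12 cells.
#' @param weibull_shape Event-time shape; 1 (the default) gives exponential
#'   times with constant baseline hazard.
#' @param category_count Fixed at 8.
#' @return A `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(n_patients = 200L,
                                    grid_height = 64L, grid_width = 64L,
                                    hazard_coefficients = c(N_ratio = 3, FIB_center = 4, FIB_edge = -2),
                                    censoring_rate = 0.3,
                                    baseline_hazard = 0.02,
                                    rng_seed = 1L,
                                    tile_size = 224L,
                                    necrosis_range = c(0.02, 0.30),
                                    necrosis_target = NULL,
                                    tumor_frac_range = c(0.2, 0.4),
                                    fib_margin_prob = 0.5,
                                    fib_thickness_range = c(2L, 4L),
                                    band_thickness = 6L,
                                    weibull_shape = 1,
                                    category_count = 8L) {
  if (category_count != 8L) stop("category_count is fixed at 8")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must lie in [0, 1)")
  if (grid_height < 16L || grid_width < 16L)
    stop("grid too small to place a tumor core: dims must be >= 16 cells")
  known <- c("N_ratio", "FIB_center", "FIB_edge", "malignancy")
  if (length(hazard_coefficients) &&
      !all(names(hazard_coefficients) %in% known))
    stop("hazard_coefficients names must be among: ",
         paste(known, collapse = ", "))
  if (any(!is.finite(hazard_coefficients)))
    stop("hazard_coefficients must be finite")
  structure(list(
    n_patients = as.integer(n_patients),
    grid_height = as.integer(grid_height),
    grid_width = as.integer(grid_width),
    category_count = 8L,
    hazard_coefficients = hazard_coefficients,
    censoring_rate = censoring_rate,
    baseline_hazard = baseline_hazard,
    rng_seed = as.integer(rng_seed),
    tile_size = as.integer(tile_size),
    necrosis_range = necrosis_range,
    necrosis_target = necrosis_target,
    tumor_frac_range = tumor_frac_range,
    fib_margin_prob = fib_margin_prob,
    fib_thickness_range = as.integer(fib_thickness_range),
    band_thickness = as.integer(band_thickness),
    weibull_shape = weibull_shape
  ), class = "synthetic_cohort_config")
}

## Squared elliptical "distance": 1 on the ellipse boundary.
ellipse_d2 <- function(r, c, cy, cx, a, b) {
  ((r - cy) / a)^2 + ((c - cx) / b)^2
}

#' Generate one patient's tissue label grid
#'
#' Deterministic given `(config$rng_seed, patient_index)`. The layout is an
#' elliptical tissue section containing an elliptical tumor core, a fibrosis
#' band placed at the margin or inside the core, necrosis blobs whose total
#' cell count matches the patient's target fraction of tissue, and sparse
#' lymphocyte/hemorrhage/debris specks in the normal field. Cells outside the
#' tissue section are labeled background and masked out.
#'
#' @param config A [synthetic_cohort_config()].
#' @param patient_index 0-based patient index, `< n_patients`.
#' @return A [tissue_label_grid()] carrying a `truth` attribute with the
#'   latent malignancy, the necrosis target, and the fibrosis placement.
#' @export
generate_label_grid <- function(config, patient_index) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  if (patient_index < 0 || patient_index >= config$n_patients)
    stop("patient_index out of range")
  H <- config$grid_height; W <- config$grid_width
  if (min(H, W) < 16L)
    stop("grid too small to place a tumor core")
  cats <- duxplore_categories()
  with_seed(derive_seed(config$rng_seed, 1000003, patient_index), {
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)

    ## tissue section ellipse
    cy <- H / 2 + runif(1, -H / 20, H / 20)
    cx <- W / 2 + runif(1, -W / 20, W / 20)
    a <- H / 2 * runif(1, 0.86, 0.96)
    b <- W / 2 * runif(1, 0.86, 0.96)
    mask <- ellipse_d2(rr, cc, cy, cx, a, b) <= 1
    n_tissue <- sum(mask)

    labels <- matrix(cats[["background"]], H, W)
    labels[mask] <- cats[["normal"]]

    ## necrosis target first: the tumor core must be large enough to host it
    f_n <- config$necrosis_target %||%
      runif(1, config$necrosis_range[1], config$necrosis_range[2])

    ## tumor core ellipse, sized to a target fraction of tissue
    lo <- max(config$tumor_frac_range[1], f_n + 0.12)
    hi <- max(config$tumor_frac_range[2], lo + 0.02)
    frac_t <- runif(1, lo, hi)
    q <- runif(1, 0.75, 1.3)
    at <- min(sqrt(frac_t * n_tissue * q / pi), 0.75 * a)
    bt <- min(at / q, 0.75 * b)
    ct_y <- cy + runif(1, -0.12, 0.12) * H
    ct_x <- cx + runif(1, -0.12, 0.12) * W
    dd <- ellipse_d2(rr, cc, ct_y, ct_x, at, bt)
    tumor <- dd <= 1 & mask
    if (sum(tumor) < 8L) stop("grid too small to place a tumor core")
    labels[tumor] <- cats[["tumor"]]

    ## fibrosis band: straddling the margin, or a ring deep in the core
    at_margin <- runif(1) < config$fib_margin_prob
    t_choices <- seq(config$fib_thickness_range[1],
                     config$fib_thickness_range[2])
    t_f <- t_choices[sample.int(length(t_choices), 1L)]
    w_f <- t_f / min(at, bt)
    sd <- sqrt(dd)
    fib <- if (at_margin) sd > 1 & sd <= 1 + w_f else sd > 0.30 & sd <= 0.30 + w_f
    fib <- fib & mask
    labels[fib] <- cats[["fibrosis"]]

    ## necrosis blobs among remaining tumor cells, hitting the target count
    k <- round(f_n * n_tissue)
    cand <- which(labels == cats[["tumor"]])
    ## keep a viable tumor rim: necrosis never consumes the whole core
    k_max <- floor(0.85 * length(cand))
    if (k > k_max) {
      if ((k - k_max) / n_tissue > 0.03)
        warning("necrosis target exceeds available tumor core; capping")
      k <- k_max
    }
    if (k > 0) {
      deep <- which(labels == cats[["tumor"]] & dd <= 0.5)
      if (!length(deep)) deep <- cand
      m <- 1L + stats::rbinom(1L, 2L, 0.5)
      ctr <- deep[sample.int(length(deep), min(m, length(deep)))]
      di <- matrix(Inf, length(cand), length(ctr))
      for (j in seq_along(ctr)) {
        di[, j] <- sqrt((rr[cand] - rr[ctr[j]])^2 + (cc[cand] - cc[ctr[j]])^2)
      }
      score <- apply(di, 1L, min) + stats::rnorm(length(cand), 0, 0.4)
      labels[cand[order(score)[seq_len(k)]]] <- cats[["necrosis"]]
    }

    ## sparse specks in the normal field
    for (spec in list(c("lymphocyte", 0.03), c("hemorrhage", 0.008),
                      c("debris", 0.008))) {
      pool <- which(labels == cats[["normal"]])
      ns <- round(runif(1, 0, as.numeric(spec[2])) * length(pool))
      if (ns > 0) labels[pool[sample.int(length(pool), ns)]] <- cats[[spec[1]]]
    }

    grid <- tissue_label_grid(labels, mask = mask,
                              patch_size_px = config$tile_size)
    attr(grid, "truth") <- list(
      malignancy = runif(1),
      necrosis_target = f_n,
      fib_at_margin = at_margin,
      fib_thickness = t_f,
      tumor_frac = frac_t
    )
    grid
  })
}

## ---------------------------------------------------------------------------
## Procedural tiles

tile_palette <- function() {
  list(
    tumor      = c(0.80, 0.62, 0.78),
    necrosis   = c(0.93, 0.86, 0.78),
    fibrosis   = c(0.95, 0.72, 0.78),
    lymphocyte = c(0.88, 0.78, 0.86),
    normal     = c(0.92, 0.76, 0.82),
    hemorrhage = c(0.84, 0.42, 0.46),
    debris     = c(0.82, 0.76, 0.70),
    background = c(0.97, 0.97, 0.97)
  )
}

## Nuclei per 32x32-pixel reference tile, by category.
tile_density <- function() {
  c(tumor = 16, necrosis = 2, fibrosis = 5, lymphocyte = 42,
    normal = 9, hemorrhage = 4, debris = 3, background = 0)
}

## Render one tile. All stochastic structure (positions, radii, base
## darkness) is drawn before malignancy is applied, so for a fixed seed the
## tile at malignancy m1 > m0 differs only by monotone transforms: more
## realized nuclei, darker staining, and wider radius dispersion.
render_tile <- function(category, malignancy, seed, tile_size) {
  cats <- duxplore_categories()
  cname <- names(cats)[match(category, cats)]
  pal <- tile_palette()[[cname]]
  S <- tile_size
  with_seed(seed, {
    img <- array(rep(pal, each = S * S), dim = c(S, S, 3))
    img <- img + array(stats::rnorm(S * S, 0, 0.02), dim = c(S, S, 3))
    if (cname == "fibrosis") {
      ph <- stats::runif(1, 0, 2 * pi)
      streak <- 0.05 * sin(outer(seq_len(S), seq_len(S), function(i, j)
        0.6 * i + 0.25 * j) + ph)
      for (ch in 1:3) img[, , ch] <- img[, , ch] + streak
    }
    base <- tile_density()[[cname]]
    if (base > 0) {
      is_tumor <- cname == "tumor"
      scale2 <- (S / 32)^2
      ncap <- max(1L, ceiling(base * 2 * scale2))
      px <- stats::runif(ncap, 1, S)
      py <- stats::runif(ncap, 1, S)
      r0 <- if (cname == "lymphocyte") S / 22 else S / 11
      rad_u <- stats::rnorm(ncap)
      dark_u <- stats::runif(ncap)
      ecc <- stats::runif(ncap, 0, 0.5)
      th <- stats::runif(ncap, 0, pi)
      n_real <- round(base * scale2 * (1 + if (is_tumor) 0.8 * malignancy else 0))
      n_real <- min(max(n_real, 0L), ncap)
      disp <- if (is_tumor) 0.18 * (1 + 1.5 * malignancy) else 0.18
      dark_hi <- if (is_tumor) 0.25 + 0.30 * malignancy else 0.25
      ## chromatin speckle: coarser within-nucleus texture as malignancy rises
      spk <- if (is_tumor) 0.05 + 0.30 * malignancy else 0.05
      for (i in seq_len(n_real)) {
        rad <- max(1, r0 * exp(disp * rad_u[i]))
        dark <- (0.30 + dark_hi * dark_u[i])
        win_r <- ceiling(rad * 1.6)
        rs <- max(1, floor(py[i] - win_r)):min(S, ceiling(py[i] + win_r))
        cs <- max(1, floor(px[i] - win_r)):min(S, ceiling(px[i] + win_r))
        u <- outer(rs - py[i], cs - px[i], function(y, x)
          (cos(th[i]) * x + sin(th[i]) * y)^2 / (rad * (1 + ecc[i]))^2 +
          (-sin(th[i]) * x + cos(th[i]) * y)^2 / rad^2)
        hit <- u <= 1
        dark_px <- pmax(0, dark + spk * stats::rnorm(sum(hit)))
        tint <- c(0.50, 0.58, 0.18)
        for (ch in 1:3) {
          sl <- img[rs, cs, ch]
          sl[hit] <- sl[hit] - tint[ch] * dark_px
          img[rs, cs, ch] <- sl
        }
      }
    }
    clamp01(img)
  })
}

#' Lazy per-cell tile source for a label grid
#'
#' Returns an object whose `$get(row, col)` renders the RGB tile for that
#' grid cell, deterministically given `(rng_seed, row, col)`. Requesting a
#' masked-out cell is an error.
#'
#' @param grid A [tissue_label_grid()].
#' @param malignancy Latent malignancy level in `[0, 1]`; tumor-tile texture
#'   statistics (nuclear density, staining darkness, size dispersion)
#'   increase monotonically with it.
#' @param rng_seed Integer seed.
#' @param tile_size Tile side length in pixels.
#' @return A `tile_store` object with fields `get`, `grid`, `tile_size`.
#' @export
tile_store <- function(grid, malignancy, rng_seed, tile_size = 32L) {
  stopifnot(inherits(grid, "tissue_label_grid"))
  if (malignancy < 0 || malignancy > 1) stop("malignancy must lie in [0, 1]")
  force(rng_seed); force(tile_size)
  get <- function(row, col) {
    if (row < 1 || row > nrow(grid$labels) || col < 1 || col > ncol(grid$labels))
      stop("cell out of range")
    if (!grid$mask[row, col])
      stop(sprintf("cell (%d, %d) is masked out (no tissue)", row, col))
    render_tile(grid$labels[row, col], malignancy,
                derive_seed(rng_seed, row, col), tile_size)
  }
  structure(list(get = get, grid = grid, malignancy = malignancy,
                 tile_size = as.integer(tile_size), rng_seed = rng_seed),
            class = "tile_store")
}

#' Render tiles for a set of grid cells
#'
#' @param grid A [tissue_label_grid()].
#' @param cells Two-column matrix of (row, col) cell coordinates; defaults to
#'   every unmasked cell.
#' @inheritParams tile_store
#' @return Array of shape `(tile_size, tile_size, 3, n_cells)` with the cell
#'   coordinates attached as attribute `cells`.
#' @export
generate_tiles <- function(grid, malignancy, rng_seed, tile_size = 32L,
                           cells = NULL) {
  store <- tile_store(grid, malignancy, rng_seed, tile_size)
  if (is.null(cells)) cells <- which(grid$mask, arr.ind = TRUE)
  out <- array(0, dim = c(tile_size, tile_size, 3, nrow(cells)))
  for (i in seq_len(nrow(cells)))
    out[, , , i] <- store$get(cells[i, 1], cells[i, 2])
  attr(out, "cells") <- cells
  out
}

#' Write rendered tiles as PNG files
#'
#' @param tiles Array `(L, L, 3, n)` from [generate_tiles()] (cell
#'   coordinates are taken from its `cells` attribute when present).
#' @param dir Output directory, created if missing.
#' @return Character vector of written paths, invisibly.
#' @export
write_tiles <- function(tiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- attr(tiles, "cells")
  n <- dim(tiles)[4]
  paths <- character(n)
  for (i in seq_len(n)) {
    nm <- if (is.null(cells)) sprintf("tile_%04d.png", i) else
      sprintf("tile_r%03d_c%03d.png", cells[i, 1], cells[i, 2])
    paths[i] <- file.path(dir, nm)
    png::writePNG(tiles[, , , i], paths[i])
  }
  invisible(paths)
}

## ---------------------------------------------------------------------------
## Survival generation

true_log_hazard <- function(params, coefs) {
  lh <- rep(0, nrow(params))
  for (nm in names(coefs)) {
    if (!nm %in% names(params)) stop("no such structural parameter: ", nm)
    lh <- lh + coefs[[nm]] * params[[nm]]
  }
  lh
}

#' Draw survival outcomes from the planted proportional-hazards model
#'
#' Event times follow a Weibull (default exponential) distribution whose rate
#' is `baseline_hazard * exp(true log-hazard)`. Censoring times are drawn
#' from an independent exponential distribution whose rate is calibrated by
#' a 10,000-sample pilot draw so that the realized censoring fraction
#' approximates `censoring_rate`.
#'
#' @param truth Data frame with the true structural parameters (columns
#'   `N_ratio`, `FIB_center`, `FIB_edge`, `malignancy`) per patient.
#' @param config A [synthetic_cohort_config()].
#' @return Data frame with `patient_id`, `time`, `event`, `log_hazard`.
#' @export
generate_survival <- function(truth, config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  lh <- true_log_hazard(truth, config$hazard_coefficients)
  n <- nrow(truth)
  with_seed(derive_seed(config$rng_seed, 2000003), {
    k <- config$weibull_shape
    e0 <- stats::rexp(n)
    t_event <- (e0 / (config$baseline_hazard * exp(lh)))^(1 / k)
    if (config$censoring_rate <= 0) {
      time <- t_event; event <- rep(1L, n)
    } else {
      np <- 10000L
      lh_p <- sample(lh, np, replace = TRUE)
      e_p <- (stats::rexp(np) / (config$baseline_hazard * exp(lh_p)))^(1 / k)
      u_p <- stats::runif(np)
      f <- function(log_rate) mean(-log(u_p) / exp(log_rate) < e_p) -
        config$censoring_rate
      rate_c <- exp(stats::uniroot(f, c(-25, 25))$root)
      t_cens <- stats::rexp(n, rate_c)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    }
    data.frame(patient_id = truth$patient_id %||% (seq_len(n) - 1L),
               time = pmax(time, 1e-8), event = event, log_hazard = lh)
  })
}

#' Generate a full synthetic cohort with known ground truth
#'
#' Runs the grid generator for every patient, derives the true structural
#' parameters (necrosis ratio, interior and margin fibrosis fractions) from
#' each grid, and draws survival outcomes from the planted hazard model.
#'
#' @param config A [synthetic_cohort_config()].
#' @param keep_grids Keep the per-patient label grids in the result
#'   (needed to build MTOPs/FSTs downstream).
#' @return List with `config`, `truth` (one row per patient: structural
#'   parameters, malignancy, true log-hazard), `survival`, and optionally
#'   `grids`.
#' @export
generate_cohort <- function(config, keep_grids = TRUE) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  n <- config$n_patients
  grids <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- generate_label_grid(config, i - 1L)
    tr <- attr(g, "truth")
    sp <- structural_params(g, band_thickness = config$band_thickness)
    rows[[i]] <- data.frame(patient_id = i - 1L,
                            N_ratio = sp$N_ratio,
                            FIB_center = sp$FIB_center,
                            FIB_edge = sp$FIB_edge,
                            malignancy = tr$malignancy)
    if (keep_grids) grids[[i]] <- g
  }
  truth <- do.call(rbind, rows)
  surv <- generate_survival(truth, config)
  truth$log_hazard <- surv$log_hazard
  out <- list(config = config, truth = truth,
              survival = surv[c("patient_id", "time", "event")])
  if (keep_grids) out$grids <- grids
  out
}

#' Write a synthetic cohort to a directory
#'
#' Label grids are written as integer TIFFs with JSON sidecars, the survival
#' table as CSV (with ground-truth columns when `with_truth`).
#'
#' @param cohort Result of [generate_cohort()] with grids kept.
#' @param dir Output directory, created if missing.
#' @param with_truth Include ground-truth columns in the survival CSV.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, with_truth = TRUE) {
  if (is.null(cohort$grids)) stop("cohort was generated without grids")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$grids)) {
    write_label_grid(cohort$grids[[i]],
                     file.path(dir, sprintf("grid_%04d.tif", i - 1L)),
                     provenance = list(patient_id = i - 1L,
                                       rng_seed = cohort$config$rng_seed))
  }
  tab <- cohort$survival
  if (with_truth) tab <- merge(tab, cohort$truth, by = "patient_id")
  utils::write.csv(tab, file.path(dir, "survival.csv"), row.names = FALSE)
  invisible(dir)
}
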