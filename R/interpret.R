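#' Occlusion sensitivity map over an MTOP
#'
#' Slides a window across the tissue grid, zeroes all 8 channels inside it
#' (zero means "no tissue" in a one-hot map — the natural ablation), and
#' records the change in predicted risk. Map value = risk(original) -
#' risk(occluded): positive where occluding the region *lowers* the risk,
#' i.e. the region contributes risk (rendered red); negative where the
#' region is protective (blue). Overlapping windows are averaged; cells
#' never covered stay zero.
#'
#' @param model A trained `dux_branch` (macro) or `dux_fused` model, or any
#'   plain function mapping an `mtop` to a scalar risk (useful for probing
#'   analytic toy models).
#' @param mtop The patient's `mtop`.
#' @param window Window side, cells.
#' @param stride Stride, cells.
#' @param fst For a fused model: the patient's fixed micro input.
#' @return Object of class `occlusion_map`: list with `map` (matrix aligned
#'   to the MTOP grid), `baseline_risk`, `window`, `stride`.
#' @export
occlusion_map <- function(model, mtop, window = 16L, stride = 8L,
                          fst = NULL) {
  stopifnot(inherits(mtop, "mtop"))
  d <- dim(mtop$channels)
  if (window > min(d[1], d[2]))
    stop("occlusion window larger than the grid")
  risk_of <- function(m) {
    if (is.function(model)) {
      model(m)
    } else if (inherits(model, "dux_fused")) {
      if (is.null(fst)) stop("fused model needs the micro input (fst)")
      duxplore_forward(model, m, fst)$risk
    } else {
      predict(model, m)
    }
  }
  base <- risk_of(mtop)
  starts <- function(extent) unique(c(seq(1L, extent - window + 1L, stride),
                                      extent - window + 1L))
  acc <- matrix(0, d[1], d[2]); cnt <- matrix(0, d[1], d[2])
  for (r0 in starts(d[1])) for (c0 in starts(d[2])) {
    rs <- r0:(r0 + window - 1L); cs <- c0:(c0 + window - 1L)
    occl <- mtop
    occl$channels[rs, cs, ] <- 0
    delta <- base - risk_of(occl)
    acc[rs, cs] <- acc[rs, cs] + delta
    cnt[rs, cs] <- cnt[rs, cs] + 1
  }
  map <- acc
  map[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
  structure(list(map = map, baseline_risk = base,
                 window = as.integer(window), stride = as.integer(stride)),
            class = "occlusion_map")
}

#' @export
print.occlusion_map <- function(x, ...) {
  cat(sprintf("<occlusion_map> %d x %d cells, window %d stride %d, baseline risk %.4f\n",
              nrow(x$map), ncol(x$map), x$window, x$stride, x$baseline_risk))
  invisible(x)
}

#' Plot an occlusion map with a red/blue diverging palette
#'
#' @param x An `occlusion_map`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.occlusion_map <- function(x, ...) {
  lim <- max(abs(x$map), 1e-12)
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
  graphics::image(t(x$map)[, nrow(x$map):1], col = pal,
                  zlim = c(-lim, lim), axes = FALSE, ...)
  invisible(x)
}

#' Structural parameters of a label grid
#'
#' Quantifies the regions the occlusion analysis highlights. The tumor
#' support is the union of tumor- and necrosis-labeled cells after
#' morphological closing and hole filling: necrosis arises inside the tumor
#' mass, so a heavily necrotic core still counts as tumor support, and
#' enclosed intra-tumoral fibrosis is filled into the interior. The margin band is the ring of tissue cells outside
#' the support within `band_thickness` cells of its boundary (distance
#' transform); the interior is the support deeper than `band_thickness / 2`,
#' keeping the two regions disjoint with a buffer between them.
#'
#' * `N_ratio`: necrosis cells / all unmasked cells
#' * `FIB_center`: fibrosis cells in the interior / interior cells
#' * `FIB_edge`: fibrosis cells in the margin band / band cells
#'
#' @param grid A [tissue_label_grid()].
#' @param band_thickness Margin band thickness in grid cells.
#' @return Object of class `structural_params` (a one-row data frame with
#'   the three parameters and the region sizes).
#' @export
structural_params <- function(grid, band_thickness = 10L) {
  stopifnot(inherits(grid, "tissue_label_grid"))
  cats <- duxplore_categories()
  tumor <- grid$labels == cats[["tumor"]] & grid$mask
  if (!any(tumor)) stop("no tumor cells: structural parameters undefined")
  mass <- tumor | (grid$labels == cats[["necrosis"]] & grid$mask)
  supp <- EBImage::fillHull(EBImage::closing(
    EBImage::Image(mass * 1), EBImage::makeBrush(5L, "disc")))
  supp <- matrix(as.numeric(supp) > 0.5, nrow(tumor), ncol(tumor))
  ## distance of support cells to the boundary, and of outside cells to the support
  d_in <- matrix(as.numeric(EBImage::distmap(EBImage::Image(supp * 1))),
                 nrow(supp), ncol(supp))
  d_out <- matrix(as.numeric(EBImage::distmap(EBImage::Image((!supp) * 1))),
                  nrow(supp), ncol(supp))
  band <- !supp & grid$mask & d_out <= band_thickness
  interior <- supp & grid$mask & d_in > band_thickness / 2
  fib <- grid$labels == cats[["fibrosis"]] & grid$mask
  nec <- grid$labels == cats[["necrosis"]] & grid$mask
  out <- data.frame(
    N_ratio = sum(nec) / sum(grid$mask),
    FIB_center = if (any(interior)) sum(fib & interior) / sum(interior) else 0,
    FIB_edge = if (any(band)) sum(fib & band) / sum(band) else 0,
    interior_cells = sum(interior), band_cells = sum(band),
    band_thickness = as.integer(band_thickness))
  class(out) <- c("structural_params", "data.frame")
  out
}

#' Multivariable Cox regression on the structural parameters
#'
#' Fits a three-covariate proportional-hazards model (N-ratio, FIB-center,
#' FIB-edge) by Newton-Raphson and reports the coefficient table in the
#' conventional format: coefficient, standard error, hazard ratio with 95%
#' confidence interval, and Wald p-value per covariate.
#'
#' @param params Data frame with columns `N_ratio`, `FIB_center`,
#'   `FIB_edge` (one row per patient), or any numeric covariate frame.
#' @param surv Data frame with `time`, `event` aligned with `params`.
#' @return Data frame with columns `Covariate`, `Coef`, `Se_Coef`, `HR`,
#'   `CI_Lower`, `CI_Upper`, `p_Value`.
#' @export
structural_cox <- function(params, surv) {
  covars <- intersect(c("N_ratio", "FIB_center", "FIB_edge"), names(params))
  if (!length(covars)) covars <- names(params)[vapply(params, is.numeric,
                                                      logical(1))]
  x <- as.matrix(params[covars])
  if (nrow(x) < 30 || sum(surv$event) < 10)
    warning("fewer than 30 patients (or 10 events); estimates will be unstable")
  fit <- coxph_fit(x, surv$time, surv$event)
  z <- fit$coef / fit$se
  data.frame(
    Covariate = covars,
    Coef = unname(fit$coef),
    Se_Coef = fit$se,
    HR = exp(unname(fit$coef)),
    CI_Lower = exp(unname(fit$coef) - 1.96 * fit$se),
    CI_Upper = exp(unname(fit$coef) + 1.96 * fit$se),
    p_Value = 2 * stats::pnorm(-abs(z)))
}

#' Tile sets from the risk-score extremes
#'
#' Labels the patients in the top and bottom `fraction` of the micro risk
#' score as high- and low-risk, the contrast the nuclear-morphometry
#' analysis compares.
#'
#' @param scores Numeric risk score per patient (for example MiTRS).
#' @param fraction Tail fraction per extreme (default 0.10).
#' @return List with integer index vectors `high_risk` and `low_risk`.
#' @export
risk_extremes <- function(scores, fraction = 0.10) {
  n <- length(scores)
  k <- floor(fraction * n)
  if (k < 1) stop("fraction selects no patients at this cohort size")
  ord <- order(scores)
  list(low_risk = sort(ord[seq_len(k)]),
       high_risk = sort(ord[(n - k + 1L):n]))
}
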