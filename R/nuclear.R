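## Nuclear morphometrics: segmentation, per-nucleus measurements, and the
## dual-criterion (Lasso + Mann-Whitney) feature selection used to explain
## the micro branch.

## Gray-level co-occurrence statistics (symmetric right+down offsets) on a
## region, quantized to `levels` gray levels: variance and angular second
## moment, the two second-order texture measures the analysis relies on.
glcm_stats <- function(gray, mask, levels = 8L, range = c(0, 1)) {
  g <- matrix(NA_integer_, nrow(gray), ncol(gray))
  v <- pmin(pmax(gray[mask], range[1]), range[2])
  ## fixed-scale binning: absolute contrast differences stay visible
  q <- pmin(levels, floor((v - range[1]) / diff(range) * levels) + 1L)
  g[mask] <- q
  P <- matrix(0, levels, levels)
  H <- nrow(g); W <- ncol(g)
  pairs <- rbind(
    cbind(as.vector(g[-H, ]), as.vector(g[-1, ])),   # down
    cbind(as.vector(g[, -W]), as.vector(g[, -1])))   # right
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  if (nrow(pairs) == 0) return(c(glcm_variance = 0, glcm_asm = 1))
  for (k in seq_len(nrow(pairs))) {
    P[pairs[k, 1], pairs[k, 2]] <- P[pairs[k, 1], pairs[k, 2]] + 1
    P[pairs[k, 2], pairs[k, 1]] <- P[pairs[k, 2], pairs[k, 1]] + 1
  }
  P <- P / sum(P)
  mu <- sum(seq_len(levels) * rowSums(P))
  c(glcm_variance = sum(outer(seq_len(levels), seq_len(levels),
                              function(i, j) (i - mu)^2) * P),
    glcm_asm = sum(P^2))
}

#' Extract a nuclear-morphometry feature row from one tile
#'
#' Nuclei are segmented by Otsu thresholding on the grayscale image
#' (staining intensity = 1 - gray, so nuclei are the dark blobs) and split
#' by a distance-transform watershed. Per nucleus: area, perimeter,
#' orientation, eccentricity, extent (area over bounding-box area), maximum
#' and mean staining intensity, and GLCM variance and angular second moment
#' of the nuclear texture. The tile row aggregates each measure's mean,
#' median and standard deviation — covering the discriminative families
#' (staining intensity, GLCM texture, shape variability) plus their
#' standard companions.
#'
#' @param tile RGB array `(H, W, 3)` in `[0, 1]`.
#' @param min_area Minimum nucleus area (pixels) kept.
#' @return One-row data frame of named features; when no nuclei are found
#'   all values are `NA` and the attribute `flagged` is `TRUE` (the row is
#'   meant to be dropped during cleaning).
#' @export
extract_nuclear_features <- function(tile, min_area = 5L) {
  stopifnot(length(dim(tile)) == 3L)
  gray <- (tile[, , 1] + tile[, , 2] + tile[, , 3]) / 3
  intensity <- 1 - gray  # staining intensity: dark = strongly stained
  measures <- c("area", "perimeter", "orientation", "eccentricity", "extent",
                "intensity_max", "intensity_mean", "glcm_variance", "glcm_asm")
  empty_row <- function() {
    nm <- as.vector(outer(measures, c("mean", "median", "sd"), paste,
                          sep = "_"))
    out <- as.data.frame(as.list(stats::setNames(rep(NA_real_, length(nm)),
                                                 nm)))
    attr(out, "flagged") <- TRUE
    attr(out, "n_nuclei") <- 0L
    out
  }
  if (stats::sd(gray) < 1e-8) return(empty_row())
  thr <- EBImage::otsu(EBImage::Image(gray), range = c(0, 1))
  binary <- gray < thr
  if (!any(binary)) return(empty_row())
  dm <- EBImage::distmap(EBImage::Image(binary * 1))
  lab <- EBImage::watershed(dm, tolerance = 1)
  lab <- matrix(as.integer(lab), nrow(gray), ncol(gray))
  ids <- setdiff(unique(as.vector(lab)), 0L)
  sizes <- vapply(ids, function(i) sum(lab == i), numeric(1))
  ids <- ids[sizes >= min_area]
  if (!length(ids)) return(empty_row())
  shp <- EBImage::computeFeatures.shape(EBImage::Image(lab))
  mom <- EBImage::computeFeatures.moment(EBImage::Image(lab),
                                         EBImage::Image(intensity))
  per_nuc <- do.call(rbind, lapply(ids, function(i) {
    m <- lab == i
    coords <- which(m, arr.ind = TRUE)
    bbox <- (diff(range(coords[, 1])) + 1) * (diff(range(coords[, 2])) + 1)
    tex <- glcm_stats(intensity, m)
    data.frame(area = shp[i, "s.area"],
               perimeter = shp[i, "s.perimeter"],
               orientation = mom[i, "m.theta"],
               eccentricity = mom[i, "m.eccentricity"],
               extent = shp[i, "s.area"] / bbox,
               intensity_max = max(intensity[m]),
               intensity_mean = mean(intensity[m]),
               glcm_variance = tex[["glcm_variance"]],
               glcm_asm = tex[["glcm_asm"]])
  }))
  agg <- lapply(measures, function(mn) {
    v <- per_nuc[[mn]]
    stats::setNames(c(mean(v), stats::median(v),
                      if (length(v) > 1) stats::sd(v) else 0),
                    paste(mn, c("mean", "median", "sd"), sep = "_"))
  })
  out <- as.data.frame(as.list(unlist(agg)))
  attr(out, "flagged") <- FALSE
  attr(out, "n_nuclei") <- length(ids)
  out
}

#' Build a feature table from high- and low-risk tile sets
#'
#' @param high,low Lists of RGB tiles.
#' @return Data frame of cleaned (flagged rows dropped), feature columns
#'   plus a `group` factor (`high_risk` / `low_risk`).
#' @export
nuclear_feature_table <- function(high, low) {
  rows <- function(tiles, label) {
    out <- lapply(tiles, extract_nuclear_features)
    keep <- !vapply(out, attr, logical(1), "flagged")
    if (!any(keep)) return(NULL)
    cbind(do.call(rbind, out[keep]), group = label)
  }
  tab <- rbind(rows(high, "high_risk"), rows(low, "low_risk"))
  tab$group <- factor(tab$group, levels = c("low_risk", "high_risk"))
  tab
}

#' Dual-criterion feature selection (Lasso intersection Mann-Whitney)
#'
#' Criterion 1: features with a nonzero Lasso (L1-penalized logistic
#' regression on the group label) coefficient at the cross-validated
#' penalty. Criterion 2: features whose Mann-Whitney U test between groups
#' survives Benjamini-Hochberg adjustment at `alpha`. The selection is the
#' intersection; features are standardized before either criterion.
#'
#' @param table Data frame with numeric feature columns and a two-level
#'   `group` column, or a numeric matrix plus `group` vector.
#' @param group Group labels when `table` is a matrix.
#' @param alpha Adjusted-p threshold for the Mann-Whitney criterion.
#' @param lambda Which cross-validated penalty to use. The default
#'   `"lambda.1se"` (sparsest model within one standard error of the best
#'   cross-validated deviance) keeps the Lasso criterion selective;
#'   `"lambda.min"` admits more candidates and leans on the rank test to
#'   filter them.
#' @param nfolds Cross-validation folds for the penalty path.
#' @param seed Seed for the penalty cross-validation.
#' @return Object of class `dual_selection`: list with `selected` (data
#'   frame: feature, lasso coefficient, adjusted p), `lasso_selected`,
#'   `mw_selected`, `p_adjusted`.
#' @export
dual_criterion_select <- function(table, group = NULL, alpha = 0.05,
                                  lambda = c("lambda.1se", "lambda.min"),
                                  nfolds = 10L, seed = 1L) {
  lambda <- match.arg(lambda)
  if (is.data.frame(table)) {
    if (is.null(group)) group <- table$group
    table <- as.matrix(table[vapply(table, is.numeric, logical(1))])
  }
  y <- factor(group)
  if (nlevels(y) != 2L) stop("group must have exactly two levels")
  if (min(table(y)) < 2L) stop("need at least two tiles per group")
  keep <- apply(table, 2L, function(v) stats::sd(v) > 1e-12)
  x <- scale(table[, keep, drop = FALSE])
  features <- colnames(x)
  cvfit <- with_seed(derive_seed(seed, 99), glmnet::cv.glmnet(
    x, y, family = "binomial", alpha = 1, nfolds = nfolds,
    standardize = FALSE, maxit = 5e5))
  co <- as.matrix(stats::coef(cvfit, s = lambda))[-1, 1]
  lasso_sel <- features[co != 0]
  p_raw <- apply(x, 2L, function(v)
    stats::wilcox.test(v[y == levels(y)[1]], v[y == levels(y)[2]],
                       exact = FALSE)$p.value)
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  mw_sel <- features[p_adj < alpha]
  sel <- intersect(lasso_sel, mw_sel)
  if (!length(lasso_sel))
    warning("the penalized model selected no features; intersection is empty")
  structure(list(
    selected = data.frame(feature = sel,
                          lasso_coef = unname(co[sel]),
                          p_adjusted = unname(p_adj[sel])),
    lasso_selected = lasso_sel, mw_selected = mw_sel,
    p_adjusted = p_adj, lambda = lambda), class = "dual_selection")
}

#' @export
print.dual_selection <- function(x, ...) {
  cat(sprintf("<dual_selection> %d by Lasso, %d by Mann-Whitney, %d in intersection\n",
              length(x$lasso_selected), length(x$mw_selected),
              nrow(x$selected)))
  if (nrow(x$selected)) print(x$selected)
  invisible(x)
}
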