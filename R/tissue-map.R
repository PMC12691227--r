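#' Tissue mask from a slide thumbnail
#'
#' Otsu thresholding on the grayscale channel separates tissue from the
#' bright glass background; connected foreground components smaller than
#' `min_area` pixels are dropped.
#'
#' @param img RGB array `(H, W, 3)` or grayscale matrix, values in `[0, 1]`.
#' @param min_area Minimum connected-component area kept, in pixels.
#' @return Logical matrix, `TRUE` where tissue is present. A fully uniform
#'   image yields an all-`FALSE` mask with a warning.
#' @export
tissue_mask <- function(img, min_area = 8L) {
  if (length(dim(img)) == 3L) {
    gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  } else {
    gray <- as.matrix(img)
  }
  if (length(gray) == 0L) stop("empty image")
  gray <- clamp01(gray)
  if (stats::sd(gray) < 1e-8) {
    warning("image has no contrast; returning an empty tissue mask")
    return(matrix(FALSE, nrow(gray), ncol(gray)))
  }
  thr <- EBImage::otsu(EBImage::Image(gray), range = c(0, 1))
  fg <- gray < thr  # tissue is darker than the glass background
  if (!any(fg)) {
    warning("no foreground below the Otsu threshold; empty tissue mask")
    return(fg)
  }
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= min_area])
  matrix(as.integer(lab) %in% keep, nrow(gray), ncol(gray))
}

#' Per-channel mean/standard-deviation tile normalization
#'
#' The default pre-classification hook: centers and rescales each color
#' channel. Stain-separation normalizers can be plugged in instead via the
#' `normalize` argument of [classify_grid()].
#'
#' @param tile RGB array `(H, W, 3)`.
#' @return Normalized array (zero mean, unit variance per channel).
#' @export
normalize_tile <- function(tile) {
  for (ch in seq_len(dim(tile)[3])) {
    v <- tile[, , ch]
    s <- stats::sd(v)
    tile[, , ch] <- (v - mean(v)) / (if (s > 1e-8) s else 1)
  }
  tile
}

#' Classifier that returns the generator's true category, one-hot
#'
#' A pluggable stand-in for a pre-trained patch classifier, used when the
#' true label grid is known (synthetic cohorts) or to inject label noise.
#'
#' @param grid The true [tissue_label_grid()].
#' @param flip_prob Probability a cell's label is flipped to a random other
#'   category before one-hot encoding.
#' @param rng_seed Seed for the label flips.
#' @return A function `(tile, row, col) -> length-8 probability vector`.
#' @export
oracle_classifier <- function(grid, flip_prob = 0, rng_seed = 1L) {
  flips <- NULL
  if (flip_prob > 0) {
    flips <- with_seed(derive_seed(rng_seed, 777), {
      idx <- which(grid$mask)
      sel <- idx[stats::runif(length(idx)) < flip_prob]
      repl <- sapply(sel, function(i) {
        sample(setdiff(0:7, grid$labels[i]), 1L)
      })
      stats::setNames(repl, sel)
    })
  }
  function(tile, row, col) {
    z <- grid$labels[row, col]
    key <- as.character((col - 1L) * nrow(grid$labels) + row)
    if (!is.null(flips) && key %in% names(flips)) z <- flips[[key]]
    p <- numeric(8); p[z + 1L] <- 1
    p
  }
}

#' Classify every unmasked cell into a tissue label grid
#'
#' Applies the patch classifier to each tile and takes the argmax category,
#' with ties broken toward the lowest category index. Classifier outputs are
#' validated against the interface contract (length 8, non-negative, summing
#' to one within 1e-6).
#'
#' @param tiles A `tile_store` (or any object with `$get(row, col)` and a
#'   `$grid` carrying the mask).
#' @param classifier Function `(tile, row, col) -> probability vector` over
#'   the 8 categories.
#' @param normalize Pre-classification hook applied to each tile; default
#'   [normalize_tile()]. Use `identity` to disable.
#' @return A [tissue_label_grid()] with the classifier probabilities kept in
#'   `$probs` (for soft MTOP mode).
#' @export
classify_grid <- function(tiles, classifier, normalize = normalize_tile) {
  mask <- tiles$grid$mask
  H <- nrow(mask); W <- ncol(mask)
  labels <- matrix(category_index("background"), H, W)
  probs <- array(0, dim = c(H, W, 8))
  for (idx in which(mask)) {
    rc <- arrayInd(idx, dim(mask))
    p <- classifier(normalize(tiles$get(rc[1], rc[2])), rc[1], rc[2])
    if (length(p) != 8L)
      stop("classifier output must have length 8, got ", length(p))
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
      stop("classifier output must be a probability vector over 8 categories")
    labels[rc[1], rc[2]] <- which.max(p) - 1L  # first max = lowest index
    probs[rc[1], rc[2], ] <- p
  }
  tissue_label_grid(labels, mask = mask,
                    patch_size_px = tiles$grid$patch_size_px, probs = probs)
}

#' Build the multi-channel tissue organization map
#'
#' Expands a label grid into an 8-channel spatial indicator tensor: in
#' `one_hot` mode channel *z* is 1 exactly where the cell label is *z*; in
#' `soft` mode the channels carry the classifier's probabilities. Masked
#' cells are all-zero across channels in both modes.
#'
#' @param grid A [tissue_label_grid()] (with `$probs` for `soft` mode).
#' @param mode `"one_hot"` (default) or `"soft"`.
#' @return An object of class `mtop`: list with `channels` (`H x W x 8`),
#'   `mask`, `mode`, and resize metadata (`meta`, identity here).
#' @export
build_mtop <- function(grid, mode = c("one_hot", "soft")) {
  mode <- match.arg(mode)
  H <- nrow(grid$labels); W <- ncol(grid$labels)
  ch <- array(0, dim = c(H, W, 8))
  if (mode == "one_hot") {
    for (z in 0:7) ch[, , z + 1L] <- (grid$labels == z & grid$mask) * 1
  } else {
    if (is.null(grid$probs))
      stop("soft mode requires a grid with classifier probabilities")
    ch <- grid$probs
    ch[array(!grid$mask, dim = dim(ch))] <- 0
  }
  structure(list(channels = ch, mask = grid$mask, mode = mode,
                 meta = list(scale = 1, offset = c(0L, 0L),
                             src_dim = c(H, W))),
            class = "mtop")
}

#' @export
print.mtop <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("<mtop> %d x %d x %d (%s), %d unmasked cells\n",
              d[1], d[2], d[3], x$mode, sum(x$mask)))
  invisible(x)
}

bilinear_resize <- function(mat, nh, nw) {
  H <- nrow(mat); W <- ncol(mat)
  ry <- (seq_len(nh) - 0.5) * H / nh + 0.5
  rx <- (seq_len(nw) - 0.5) * W / nw + 0.5
  y0 <- pmax(1L, pmin(H, floor(ry))); y1 <- pmin(H, y0 + 1L)
  x0 <- pmax(1L, pmin(W, floor(rx))); x1 <- pmin(W, x0 + 1L)
  wy <- pmax(0, pmin(1, ry - y0)); wx <- pmax(0, pmin(1, rx - x0))
  a <- mat[y0, x0, drop = FALSE]; b <- mat[y0, x1, drop = FALSE]
  cc <- mat[y1, x0, drop = FALSE]; d <- mat[y1, x1, drop = FALSE]
  top <- a * (1 - wx)[col(a)] + b * wx[col(b)]
  bot <- cc * (1 - wx)[col(cc)] + d * wx[col(d)]
  top * (1 - wy)[row(top)] + bot * wy[row(bot)]
}

nearest_index <- function(n_new, n_old) {
  pmax(1L, pmin(n_old, floor((seq_len(n_new) - 0.5) * n_old / n_new) + 1L))
}

#' Resize an MTOP to a fixed encoder input size
#'
#' Aspect-preserving rescale followed by zero padding to the target. One-hot
#' maps use nearest-neighbor interpolation (values stay in {0, 1}); soft
#' maps use bilinear. The mapping metadata (scale, padding offsets, source
#' dims) is retained so that spatial attributions computed on the resized
#' map can be projected back onto the original grid.
#'
#' @param mtop An `mtop` object.
#' @param target Target `(height, width)`, each >= 8.
#' @return A resized `mtop`.
#' @export
resize_mtop <- function(mtop, target) {
  stopifnot(inherits(mtop, "mtop"), length(target) == 2L)
  if (any(target < 8L)) stop("target dims must be >= 8")
  H <- dim(mtop$channels)[1]; W <- dim(mtop$channels)[2]
  if (all(c(H, W) == target)) return(mtop)
  s <- min(target[1] / H, target[2] / W)
  nh <- max(1L, round(H * s)); nw <- max(1L, round(W * s))
  off <- c(floor((target[1] - nh) / 2), floor((target[2] - nw) / 2))
  out <- array(0, dim = c(target[1], target[2], 8))
  rows <- off[1] + seq_len(nh); cols <- off[2] + seq_len(nw)
  if (mtop$mode == "one_hot") {
    iy <- nearest_index(nh, H); ix <- nearest_index(nw, W)
    for (z in 1:8) out[rows, cols, z] <- mtop$channels[iy, ix, z]
    msk <- matrix(FALSE, target[1], target[2])
    msk[rows, cols] <- mtop$mask[iy, ix]
  } else {
    for (z in 1:8) out[rows, cols, z] <- bilinear_resize(mtop$channels[, , z], nh, nw)
    msk <- matrix(FALSE, target[1], target[2])
    msk[rows, cols] <- bilinear_resize(mtop$mask * 1, nh, nw) > 0.5
  }
  structure(list(channels = out, mask = msk, mode = mtop$mode,
                 meta = list(scale = s, offset = off, src_dim = c(H, W))),
            class = "mtop")
}

#' Project a spatial map computed on a resized MTOP back to grid coordinates
#'
#' @param map Matrix aligned with the resized MTOP.
#' @param meta The `meta` field of the resized MTOP.
#' @return Matrix aligned with the original label grid.
#' @export
project_back <- function(map, meta) {
  H <- meta$src_dim[1]; W <- meta$src_dim[2]
  nh <- max(1L, round(H * meta$scale)); nw <- max(1L, round(W * meta$scale))
  inner <- map[meta$offset[1] + seq_len(nh), meta$offset[2] + seq_len(nw),
               drop = FALSE]
  iy <- nearest_index(H, nh); ix <- nearest_index(W, nw)
  inner[iy, ix, drop = FALSE]
}
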