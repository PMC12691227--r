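#' Patch-level tissue label grid
#'
#' The compressed representation of a whole-slide image: one cell per
#' non-overlapping patch, holding the 0-based index of the tissue category
#' predicted (or known) for that patch, plus a logical mask marking cells
#' that contain tissue at all. Coordinates are 0-based (row, col), row-major,
#' but stored as ordinary 1-indexed R matrices.
#'
#' @param labels Integer matrix of category indices in `[0, 7]`.
#' @param mask Logical matrix of the same shape; `TRUE` where tissue is
#'   present. Defaults to cells not labeled `background`.
#' @param patch_size_px Side length, in pixels, of the patch each cell
#'   represents (the downsampling factor from slide to grid).
#' @param probs Optional `H x W x 8` array of per-cell classifier
#'   probabilities (kept when the grid came from a soft classifier).
#' @return An object of class `tissue_label_grid`.
#' @export
tissue_label_grid <- function(labels, mask = NULL, patch_size_px = 224L,
                              probs = NULL) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (is.null(mask)) mask <- labels != category_index("background")
  mask <- as.matrix(mask)
  if (!all(dim(labels) == dim(mask)))
    stop("labels and mask must have identical dimensions")
  bad <- mask & (labels < 0L | labels >= N_CATEGORIES)
  if (any(bad)) stop("unmasked cells must carry a label in [0, 7]")
  if (!is.null(probs) && !all(dim(probs)[1:2] == dim(labels)))
    stop("probs must align with the label grid")
  structure(
    list(labels = labels, mask = mask,
         patch_size_px = as.integer(patch_size_px), probs = probs),
    class = "tissue_label_grid")
}

#' @export
print.tissue_label_grid <- function(x, ...) {
  cats <- duxplore_categories()
  tab <- table(factor(x$labels[x$mask], levels = cats,
                      labels = names(cats)))
  cat(sprintf("<tissue_label_grid> %d x %d cells, %d with tissue (patch %d px)\n",
              nrow(x$labels), ncol(x$labels), sum(x$mask), x$patch_size_px))
  print(tab)
  invisible(x)
}

#' @export
dim.tissue_label_grid <- function(x) dim(x$labels)

#' Write / read a tissue label grid
#'
#' The grid is persisted as a single-channel 8-bit TIFF holding the category
#' index per cell, with a JSON sidecar carrying the category vocabulary, the
#' tissue mask, the patch size, and free-form provenance.
#'
#' @param grid A [tissue_label_grid()].
#' @param path Path of the `.tif` file to write (sidecar gets `.json`).
#' @param provenance Optional list stored verbatim in the sidecar.
#' @return `path`, invisibly.
#' @export
write_label_grid <- function(grid, path, provenance = NULL) {
  stopifnot(inherits(grid, "tissue_label_grid"))
  tiff::writeTIFF(grid$labels / 255, path, bits.per.sample = 8L)
  side <- list(
    categories = as.list(duxplore_categories()),
    patch_size_px = grid$patch_size_px,
    mask = apply(grid$mask, 1L, as.integer, simplify = FALSE),
    provenance = provenance
  )
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_label_grid
#' @export
read_label_grid <- function(path) {
  labels <- round(tiff::readTIFF(path) * 255)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  mask <- if (is.matrix(side$mask)) side$mask != 0 else
    do.call(rbind, lapply(side$mask, as.logical))
  tissue_label_grid(labels, mask = mask, patch_size_px = side$patch_size_px)
}

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")
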