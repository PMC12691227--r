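#' Tissue category vocabulary
#'
#' The framework represents a slide as a grid of patches, each assigned one of
#' eight tissue categories. The category *indices* (0-7) are what the model
#' consumes; the names give the indices stable roles. Necrosis, fibrosis and
#' tumor have dedicated roles in the structural parameters; the remaining
#' names cover the usual constituents of an H&E liver section. The vocabulary
#' is configurable but the count is fixed at eight.
#'
#' @return Named integer vector mapping category name to 0-based index.
#' @export
#' @examples
#' duxplore_categories()
duxplore_categories <- function() {
  c(tumor = 0L, necrosis = 1L, fibrosis = 2L, lymphocyte = 3L,
    normal = 4L, hemorrhage = 5L, debris = 6L, background = 7L)
}

N_CATEGORIES <- 8L

category_index <- function(name) {
  cats <- duxplore_categories()
  if (!name %in% names(cats)) stop("unknown tissue category: ", name)
  unname(cats[[name]])
}
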