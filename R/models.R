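#' Encoder backbone specification
#'
#' Two backbones stand behind one interface. `reference_large` is the
#' full-scale configuration: a deeper convolutional stack whose global
#' average pooling emits the standard 2048-dimensional feature vector (the
#' feature width of the ResNet50/ResNeXt50 family the branches are modeled
#' on), with the first layer's channel count set by the branch (8 for the
#' macro MTOP, 81 for the micro FST view). `tiny_test` is a small CNN with
#' the same interface, sized so the whole pipeline trains in seconds on one
#' CPU; the entire test protocol runs on it.
#'
#' @param backbone `"tiny_test"` or `"reference_large"`.
#' @param in_channels First-layer channel count (8 macro / 81 micro).
#' @param feature_dim Encoder output dimension; fixed at 2048 for
#'   `reference_large`, defaults to 16 for `tiny_test`.
#' @return An `encoder_spec` list.
#' @export
encoder_spec <- function(backbone = c("tiny_test", "reference_large"),
                         in_channels, feature_dim = NULL) {
  backbone <- match.arg(backbone)
  feature_dim <- if (backbone == "reference_large") 2048L else
    as.integer(feature_dim %||% 16L)
  structure(list(backbone = backbone, in_channels = as.integer(in_channels),
                 feature_dim = feature_dim),
            class = "encoder_spec")
}

build_encoder <- function(spec) {
  if (spec$backbone == "tiny_test") {
    list(layer_conv(spec$in_channels, spec$feature_dim), layer_relu(),
         layer_gap())
  } else {
    list(layer_conv(spec$in_channels, 32L), layer_relu(), layer_pool2(),
         layer_conv(32L, 64L), layer_relu(), layer_pool2(),
         layer_conv(64L, spec$feature_dim), layer_relu(), layer_gap())
  }
}

## encoder -> FC+BN+ReLU projection to the 32-dim embedding -> linear head
build_branch_layers <- function(spec) {
  enc <- build_encoder(spec)
  proj <- list(layer_fc(spec$feature_dim, 32L), layer_bn(32L), layer_relu())
  head <- list(layer_fc(32L, 1L))
  list(layers = c(enc, proj, head),
       encoder_end = length(enc),
       proj_end = length(enc) + length(proj))
}

#' Construct the macro branch (Macro-Net)
#'
#' Consumes the 8-channel MTOP, encodes it, projects the encoder feature to
#' a 32-dimensional embedding (fully connected + batch norm + ReLU), and
#' emits the macro tumor risk score (MaTRS) through a linear head.
#'
#' @param spec An [encoder_spec()] with `in_channels = 8`.
#' @param seed Seed for weight initialization.
#' @return An object of class `dux_branch`.
#' @export
macro_net <- function(spec = encoder_spec("tiny_test", in_channels = 8L),
                      seed = 1L) {
  if (spec$in_channels != 8L)
    stop("macro branch requires 8 input channels (one per tissue category)")
  built <- with_seed(derive_seed(seed, 101), build_branch_layers(spec))
  structure(c(built, list(spec = spec, branch = "macro")),
            class = "dux_branch")
}

#' Construct the micro branch (Micro-Net)
#'
#' Consumes the flattened channel view of the fused structure tensor
#' (3 channels x `n_slots` tiles; 81 for the default 27-slot tensor) and
#' emits the micro tumor risk score (MiTRS).
#'
#' @param spec An [encoder_spec()]; `in_channels` must equal `3 * n_slots`.
#' @param n_slots Number of tile slots the model accepts (default 27).
#' @param seed Seed for weight initialization.
#' @return An object of class `dux_branch`.
#' @export
micro_net <- function(spec = encoder_spec("tiny_test", in_channels = 81L),
                      n_slots = 27L, seed = 1L) {
  if (spec$in_channels != 3L * n_slots)
    stop("micro branch requires in_channels = 3 * n_slots = ", 3L * n_slots)
  built <- with_seed(derive_seed(seed, 202), build_branch_layers(spec))
  structure(c(built, list(spec = spec, branch = "micro",
                          n_slots = as.integer(n_slots))),
            class = "dux_branch")
}

#' Construct the fused dual-branch network
#'
#' Both branch heads are dropped; the two 32-dimensional embeddings are
#' concatenated (64-dim) and passed through a two-layer perceptron fusion
#' head (64 -> 32 -> 1) to the patient-level tumor risk score (PaTRS).
#' Optionally warm-started from trained branches.
#'
#' @param macro A `dux_branch` from [macro_net()] (trained or fresh).
#' @param micro A `dux_branch` from [micro_net()].
#' @param seed Seed for the fusion head initialization.
#' @return An object of class `dux_fused`.
#' @export
duxplore_net <- function(macro, micro, seed = 1L) {
  stopifnot(inherits(macro, "dux_branch"), inherits(micro, "dux_branch"),
            macro$branch == "macro", micro$branch == "micro")
  fusion <- with_seed(derive_seed(seed, 303), list(
    layer_fc(64L, 32L), layer_relu(), layer_fc(32L, 1L)))
  structure(list(macro = macro, micro = micro, fusion = fusion),
            class = "dux_fused")
}

#' @export
print.dux_branch <- function(x, ...) {
  cat(sprintf("<dux_branch:%s> backbone %s, %d input channels, %d-dim features, 32-dim embedding\n",
              x$branch, x$spec$backbone, x$spec$in_channels,
              x$spec$feature_dim))
  invisible(x)
}

#' @export
print.dux_fused <- function(x, ...) {
  cat("<dux_fused> PaTRS = MLP(64 -> 32 -> 1) on concatenated branch embeddings\n")
  print(x$macro); print(x$micro)
  invisible(x)
}

## ---------------------------------------------------------------------------
## Input coercion

stack_mtops <- function(mtops) {
  d <- dim(mtops[[1]]$channels)
  x <- array(0, dim = c(length(mtops), d))
  for (i in seq_along(mtops)) x[i, , , ] <- mtops[[i]]$channels
  x
}

coerce_branch_input <- function(model, x) {
  if (inherits(x, "mtop")) x <- stack_mtops(list(x))
  else if (inherits(x, "fst_tensor")) {
    ch <- fst_channels(x)
    y <- array(0, dim = c(1L, dim(ch)))
    y[1L, , , ] <- ch
    x <- y
  } else if (is.list(x) && inherits(x[[1]], "mtop")) x <- stack_mtops(x)
  if (length(dim(x)) != 4L) stop("expected a (n, H, W, C) input array")
  C <- dim(x)[4]
  if (C != model$spec$in_channels) {
    if (model$branch == "micro" && !is.null(model$n_slots))
      stop(sprintf("micro branch expects %d slots (%d channels), got %d channels",
                   model$n_slots, model$spec$in_channels, C))
    stop(sprintf("%s branch expects %d channels, got %d",
                 model$branch, model$spec$in_channels, C))
  }
  x
}

## ---------------------------------------------------------------------------
## Forward passes

branch_forward_full <- function(model, x, train = FALSE) {
  fw <- nn_forward(model$layers, x, train = train)
  ## recover the embedding from the projection layer's cached output: run
  ## forward again is wasteful, so read it from the head's input cache
  head_cache <- fw$caches[[model$proj_end + 1L]]
  list(risk = as.numeric(fw$out), embedding = head_cache$x,
       caches = fw$caches, layers = fw$layers)
}

#' Macro branch forward pass
#'
#' @param model A `dux_branch` from [macro_net()].
#' @param mtop An `mtop`, a list of them, or a `(n, H, W, 8)` array.
#' @return List with `embedding` (`n x 32`, non-negative post-ReLU) and
#'   `risk` (MaTRS vector).
#' @export
macro_forward <- function(model, mtop) {
  x <- coerce_branch_input(model, mtop)
  fw <- branch_forward_full(model, x, train = FALSE)
  list(embedding = fw$embedding, risk = fw$risk)
}

#' Micro branch forward pass
#'
#' @param model A `dux_branch` from [micro_net()].
#' @param fst An `fst_tensor` or a `(n, L, W, 3 * n_slots)` array.
#' @return List with `embedding` (`n x 32`) and `risk` (MiTRS vector).
#' @export
micro_forward <- function(model, fst) {
  if (inherits(fst, "fst_tensor") && fst$N != model$n_slots)
    stop(sprintf("fused structure tensor has %d slots; model expects %d",
                 fst$N, model$n_slots))
  x <- coerce_branch_input(model, fst)
  fw <- branch_forward_full(model, x, train = FALSE)
  list(embedding = fw$embedding, risk = fw$risk)
}

#' Fused dual-branch forward pass
#'
#' @param model A `dux_fused` from [duxplore_net()].
#' @param mtop Macro input (see [macro_forward()]).
#' @param fst Micro input (see [micro_forward()]).
#' @return List with `risk` (PaTRS vector), `macro_embedding`,
#'   `micro_embedding`.
#' @export
duxplore_forward <- function(model, mtop, fst) {
  xm <- coerce_branch_input(model$macro, mtop)
  xi <- coerce_branch_input(model$micro, fst)
  ema <- nn_forward(model$macro$layers[seq_len(model$macro$proj_end)], xm)$out
  emi <- nn_forward(model$micro$layers[seq_len(model$micro$proj_end)], xi)$out
  z <- cbind(ema, emi)
  risk <- as.numeric(nn_forward(model$fusion, z)$out)
  list(risk = risk, macro_embedding = ema, micro_embedding = emi)
}

#' Predict risk scores
#'
#' @param object A `dux_branch` or `dux_fused` model.
#' @param newdata For a branch: its input (see [macro_forward()] /
#'   [micro_forward()]). For a fused model: `list(macro = ..., micro = ...)`.
#' @param ... Unused.
#' @return Numeric risk score vector (MaTRS, MiTRS, or PaTRS).
#' @export
predict.dux_branch <- function(object, newdata, ...) {
  x <- coerce_branch_input(object, newdata)
  branch_forward_full(object, x, train = FALSE)$risk
}

#' @rdname predict.dux_branch
#' @export
predict.dux_fused <- function(object, newdata, ...) {
  duxplore_forward(object, newdata$macro, newdata$micro)$risk
}
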