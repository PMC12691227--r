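#' Training configuration
#'
#' Defaults follow the full-scale protocol: Adam with initial learning rate
#' 1e-4, L2 weight decay 1e-5, up to 100 epochs, learning rate cut by a
#' factor of 0.1 when the validation C-index plateaus (no improvement above
#' `plateau_tol` for `patience` epochs). For the `tiny_test` backbone a
#' larger learning rate (1e-2) with mini-batches trains in seconds; see
#' [tiny_train_config()].
#'
#' @param learning_rate Initial Adam learning rate.
#' @param weight_decay L2 coefficient applied to weight matrices.
#' @param max_epochs Epoch cap.
#' @param lr_decay Multiplicative factor applied on plateau.
#' @param patience Plateau length, epochs.
#' @param plateau_tol Minimum validation C-index improvement that resets
#'   the plateau counter.
#' @param batch_size Mini-batch size; `NULL` uses the full cohort per step
#'   (full-cohort risk sets). Mini-batches use batch-local risk sets, a
#'   standard but slightly biased approximation of the full partial
#'   likelihood.
#' @param val_fraction Fraction of the training patients held out for
#'   plateau detection and checkpoint selection (event-stratified).
#' @param min_lr Training stops once the decayed learning rate falls below.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-5,
                         max_epochs = 100L, lr_decay = 0.1, patience = 10L,
                         plateau_tol = 1e-4, batch_size = NULL,
                         val_fraction = 0.25, min_lr = 1e-7) {
  stopifnot(learning_rate >= 0, weight_decay >= 0, max_epochs >= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs), lr_decay = lr_decay,
                 patience = as.integer(patience), plateau_tol = plateau_tol,
                 batch_size = batch_size, val_fraction = val_fraction,
                 min_lr = min_lr),
            class = "train_config")
}

#' @rdname train_config
#' @param ... Overrides passed to [train_config()].
#' @export
tiny_train_config <- function(...) {
  defaults <- list(learning_rate = 1e-2, max_epochs = 30L, batch_size = 32L,
                   patience = 8L)
  args <- utils::modifyList(defaults, list(...))
  do.call(train_config, args)
}

## ---------------------------------------------------------------------------
## A uniform "trainable" view over branch and fused models.

model_layerlist <- function(model) {
  if (inherits(model, "dux_branch")) return(model$layers)
  c(model$macro$layers[seq_len(model$macro$proj_end)],
    model$micro$layers[seq_len(model$micro$proj_end)],
    model$fusion)
}

model_set_layers <- function(model, layers) {
  if (inherits(model, "dux_branch")) {
    model$layers <- layers
    return(model)
  }
  nm <- model$macro$proj_end; ni <- model$micro$proj_end
  model$macro$layers[seq_len(nm)] <- layers[seq_len(nm)]
  model$micro$layers[seq_len(ni)] <- layers[nm + seq_len(ni)]
  model$fusion <- layers[(nm + ni + 1L):length(layers)]
  model
}

slice_input <- function(x, idx) {
  if (is.list(x)) lapply(x, function(a) a[idx, , , , drop = FALSE])
  else x[idx, , , , drop = FALSE]
}

input_n <- function(x) if (is.list(x)) dim(x[[1]])[1] else dim(x)[1]

## Forward in train mode; returns risk, caches and (bn-updated) layers.
trainable_forward <- function(model, layers, xb, train = TRUE) {
  if (inherits(model, "dux_branch")) {
    fw <- nn_forward(layers, xb, train = train)
    return(list(risk = as.numeric(fw$out), layers = fw$layers,
                ctx = list(caches = fw$caches)))
  }
  nm <- model$macro$proj_end; ni <- model$micro$proj_end
  fa <- nn_forward(layers[seq_len(nm)], xb$macro, train = train)
  fb <- nn_forward(layers[nm + seq_len(ni)], xb$micro, train = train)
  z <- cbind(fa$out, fb$out)
  fc_ <- nn_forward(layers[(nm + ni + 1L):length(layers)], z, train = train)
  layers[seq_len(nm)] <- fa$layers
  layers[nm + seq_len(ni)] <- fb$layers
  layers[(nm + ni + 1L):length(layers)] <- fc_$layers
  list(risk = as.numeric(fc_$out), layers = layers,
       ctx = list(ca = fa$caches, cb = fb$caches, cc = fc_$caches))
}

trainable_backward <- function(model, layers, ctx, dscore) {
  dout <- matrix(dscore, ncol = 1L)
  if (inherits(model, "dux_branch")) {
    return(nn_backward(layers, ctx$caches, dout)$grads)
  }
  nm <- model$macro$proj_end; ni <- model$micro$proj_end
  fus_idx <- (nm + ni + 1L):length(layers)
  bf <- nn_backward(layers[fus_idx], ctx$cc, dout)
  dz <- bf$dx
  ba <- nn_backward(layers[seq_len(nm)], ctx$ca, dz[, 1:32, drop = FALSE])
  bb <- nn_backward(layers[nm + seq_len(ni)], ctx$cb,
                    dz[, 33:64, drop = FALSE])
  grads <- vector("list", length(layers))
  grads[seq_len(nm)] <- ba$grads
  grads[nm + seq_len(ni)] <- bb$grads
  grads[fus_idx] <- bf$grads
  grads
}

model_predict_layers <- function(model, layers, x) {
  trainable_forward(model, layers, x, train = FALSE)$risk
}

#' Train a branch (or the fused network) with the Cox objective
#'
#' Optimizes the negative log partial likelihood with Adam, monitors the
#' validation C-index after every epoch, decays the learning rate by
#' `lr_decay` on plateau, and returns the weights of the best-validation
#' epoch. Fully deterministic given `seed`.
#'
#' @param model A `dux_branch` or `dux_fused` model.
#' @param x Input batch array `(n, H, W, C)` for a branch, or
#'   `list(macro = ..., micro = ...)` for the fused model.
#' @param surv Data frame with columns `time`, `event` aligned with `x`.
#' @param config A [train_config()].
#' @param val_idx Optional explicit validation indices; defaults to an
#'   event-stratified draw of `config$val_fraction`.
#' @param seed Integer seed controlling the split and batch shuffles.
#' @return List with `model` (best checkpoint), `history` (per-epoch loss,
#'   learning rate, validation C-index), `best_val`.
#' @export
train_branch <- function(model, x, surv, config = train_config(),
                         val_idx = NULL, seed = 1L) {
  stopifnot(inherits(config, "train_config"))
  n <- input_n(x)
  stopifnot(nrow(surv) == n)
  layers <- model_layerlist(model)
  with_seed(derive_seed(seed, 42), {
    if (is.null(val_idx)) {
      val_idx <- unlist(lapply(unique(surv$event), function(lev) {
        idx <- which(surv$event == lev)
        sample(idx, max(1L, round(config$val_fraction * length(idx))))
      }))
    }
    train_idx <- setdiff(seq_len(n), val_idx)
    if (!length(train_idx) || !length(val_idx))
      stop("training and validation patient sets must be disjoint and non-empty")
    xv <- slice_input(x, val_idx)
    tv <- surv$time[val_idx]; ev <- surv$event[val_idx]

    state <- adam_init(layers)
    lr <- config$learning_rate
    best_val <- -Inf; best_layers <- layers; stall <- 0L; t_step <- 0L
    history <- vector("list", config$max_epochs)
    for (epoch in seq_len(config$max_epochs)) {
      idx <- sample(train_idx)
      bs <- config$batch_size %||% length(idx)
      batches <- split(idx, ceiling(seq_along(idx) / bs))
      losses <- c()
      for (b in batches) {
        if (sum(surv$event[b]) == 0 || length(b) < 2L) next  # skip-batch
        fw <- trainable_forward(model, layers, slice_input(x, b), train = TRUE)
        layers <- fw$layers
        lg <- cox_loss_grad(surv$time[b], surv$event[b], fw$risk)
        if (!is.finite(lg$loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d, lr %.3g",
                       epoch, lr))
        losses <- c(losses, lg$loss / max(1, sum(surv$event[b])))
        grads <- trainable_backward(model, layers, fw$ctx, lg$grad)
        t_step <- t_step + 1L
        upd <- adam_step(layers, grads, state, t_step, lr,
                         weight_decay = config$weight_decay)
        layers <- upd$layers; state <- upd$state
      }
      val_risk <- model_predict_layers(model, layers, xv)
      val_ci <- tryCatch(concordance_index(tv, ev, val_risk),
                         error = function(e) NA_real_)
      improved <- !is.na(val_ci) && val_ci > best_val + config$plateau_tol
      if (improved) {
        best_val <- val_ci; best_layers <- layers; stall <- 0L
      } else {
        stall <- stall + 1L
      }
      history[[epoch]] <- data.frame(
        epoch = epoch, loss = if (length(losses)) mean(losses) else NA_real_,
        lr = lr, val_cindex = val_ci)
      if (stall >= config$patience) {
        lr <- lr * config$lr_decay
        stall <- 0L
        if (lr < config$min_lr) break
      }
    }
    list(model = model_set_layers(model, best_layers),
         history = do.call(rbind, history), best_val = best_val,
         val_idx = sort(val_idx))
  })
}

#' Cross-validated training and evaluation
#'
#' Patient-level event-stratified k-fold protocol: per fold, a fresh model
#' from the factory is trained on the remaining folds (with an inner
#' validation split for checkpointing) and evaluated on the held-out fold
#' with the three survival metrics. Folds are identical across compared
#' models for a fixed seed.
#'
#' @param x Model input (see [train_branch()]).
#' @param surv Data frame with `time`, `event`.
#' @param model_factory Zero-argument function returning a fresh model.
#' @param k Number of folds.
#' @param config A [train_config()].
#' @param seed Integer seed (shared splits across models).
#' @return Data frame of fold results: `fold`, `c_index`, `ibs`,
#'   `ipcw_mae`, with the fold assignment as attribute `folds`.
#' @export
cross_validate <- function(x, surv, model_factory, k = 5L,
                           config = train_config(), seed = 1L) {
  folds <- make_folds(surv$event, k = k, seed = derive_seed(seed, 7))
  rows <- vector("list", k)
  for (fold in seq_len(k)) {
    te <- which(folds == fold); tr <- which(folds != fold)
    fit <- train_branch(model_factory(), slice_input(x, tr), surv[tr, ],
                        config = config, seed = derive_seed(seed, 11, fold))
    risk_tr <- model_predict_layers(fit$model, model_layerlist(fit$model),
                                    slice_input(x, tr))
    risk_te <- model_predict_layers(fit$model, model_layerlist(fit$model),
                                    slice_input(x, te))
    ci <- tryCatch(concordance_index(surv$time[te], surv$event[te], risk_te),
                   error = function(e) NA_real_)
    base <- breslow_baseline(surv$time[tr], surv$event[tr], risk_tr)
    et <- sort(unique(surv$time[tr][surv$event[tr] == 1]))
    grid <- et[et <= stats::quantile(surv$time[te], 0.9)]
    ibs <- mae <- NA_real_
    if (length(grid) >= 2) {
      sm <- predict_survival(base, risk_te, grid)
      ibs <- integrated_brier(surv$time[te], surv$event[te], sm, grid)
      mae <- tryCatch(
        ipcw_mae(surv$time[te], surv$event[te],
                 predicted_median_time(sm, grid)),
        error = function(e) NA_real_)
    }
    rows[[fold]] <- data.frame(fold = fold, c_index = ci, ibs = ibs,
                               ipcw_mae = mae)
  }
  out <- do.call(rbind, rows)
  attr(out, "folds") <- folds
  out
}
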