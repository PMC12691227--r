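#' Cox negative log partial likelihood
#'
#' The training objective: for every event, its risk score is compared
#' against the log-sum-exp of the scores of all patients still at risk at
#' that time (risk set `R(t) = {j : t_j >= t}`). Ties are handled by the
#' Breslow approximation (tied events share the full risk set). The loss is
#' invariant to adding a constant to every score.
#'
#' @param time Observed times (> 0).
#' @param event Event indicators (1 = event, 0 = censored).
#' @param score Predicted risk scores.
#' @return Scalar loss. A batch with zero events raises a classed error
#'   (`dux_no_events`), the skip-batch signal.
#' @export
cox_loss <- function(time, event, score) {
  cox_loss_grad(time, event, score)$loss
}

## Loss and gradient w.r.t. the scores, in one stable pass.
cox_loss_grad <- function(time, event, score) {
  n <- length(time)
  stopifnot(length(event) == n, length(score) == n)
  if (sum(event) == 0)
    stop(structure(class = c("dux_no_events", "error", "condition"),
                   list(message = "batch contains no events; skip it",
                        call = sys.call(-1))))
  s <- score - mean(score)  # shift invariance, exploited for stability
  ord <- order(time)
  st <- s[ord]; tt <- time[ord]; ev <- event[ord]
  ## suffix log-sum-exp of sorted scores
  lse <- numeric(n)
  lse[n] <- st[n]
  if (n > 1) for (i in (n - 1):1) {
    m <- max(st[i], lse[i + 1])
    lse[i] <- m + log(exp(st[i] - m) + exp(lse[i + 1] - m))
  }
  ## group start index per position (ties share the earliest position)
  grp_start <- match(tt, tt)
  loss <- -sum((st - lse[grp_start])[ev == 1])
  ## gradient: dL/ds_k = exp(s_k) * sum_{event groups g with t_g <= t_k} d_g / S_g - delta_k
  ug <- unique(grp_start)
  d_g <- vapply(ug, function(g) sum(ev[grp_start == g]), numeric(1))
  inv_S <- exp(-lse[ug])
  cum <- cumsum(d_g * inv_S)
  gk <- cum[match(grp_start, ug)]
  grad_sorted <- exp(st) * gk - ev
  grad <- numeric(n)
  grad[ord] <- grad_sorted
  list(loss = loss, grad = grad)
}

#' Proportional-hazards fit by Newton-Raphson (Breslow ties)
#'
#' A standard multivariable Cox partial-likelihood fit, implemented
#' in-package so the structural-parameter analysis is self-contained; tests
#' cross-check it against an independent reference fit.
#'
#' @param x Covariate matrix (n x p).
#' @param time,event Survival outcome.
#' @param max_iter,tol Newton-Raphson controls.
#' @return List with `coef`, `se`, `loglik`, `iter`, `converged`, and the
#'   observed information matrix `info`.
#' @export
coxph_fit <- function(x, time, event, max_iter = 25L, tol = 1e-9) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (sum(event) < 1) stop("no events: proportional-hazards fit undefined")
  ord <- order(-time)  # descending: risk sets accumulate as we walk
  xs <- x[ord, , drop = FALSE]; tt <- time[ord]; ev <- event[ord]
  beta <- numeric(p)
  ll_old <- -Inf
  info <- diag(p)
  for (iter in seq_len(max_iter)) {
    eta <- drop(xs %*% beta)
    w <- exp(eta)
    U <- numeric(p); info <- matrix(0, p, p); ll <- 0
    S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
    i <- 1L
    while (i <= n) {
      j <- i
      while (j <= n && tt[j] == tt[i]) j <- j + 1L
      idx <- i:(j - 1L)
      S0 <- S0 + sum(w[idx])
      S1 <- S1 + drop(crossprod(xs[idx, , drop = FALSE], w[idx]))
      xw <- xs[idx, , drop = FALSE] * sqrt(w[idx])
      S2 <- S2 + crossprod(xw)
      di <- idx[ev[idx] == 1]
      d <- length(di)
      if (d > 0) {
        xbar <- S1 / S0
        ll <- ll + sum(eta[di]) - d * log(S0)
        U <- U + colSums(xs[di, , drop = FALSE]) - d * xbar
        info <- info + d * (S2 / S0 - tcrossprod(xbar))
      }
      i <- j
    }
    step <- tryCatch(solve(info, U), error = function(e)
      stop(sprintf("singular information matrix (condition number %.3g)",
                   kappa(info))))
    ## step-halving if the likelihood fails to improve
    h <- 1
    repeat {
      beta_new <- beta + h * step
      ll_new <- cox_partial_loglik(xs, tt, ev, beta_new)
      if (ll_new >= ll - 1e-12 || h < 1e-4) break
      h <- h / 2
    }
    beta <- beta_new
    if (abs(ll_new - ll_old) < tol * (abs(ll_old) + 1)) {
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  se <- sqrt(diag(solve(info)))
  list(coef = stats::setNames(beta, colnames(x)), se = se, loglik = ll_old,
       iter = iter, converged = iter < max_iter, info = info)
}

cox_partial_loglik <- function(xs, tt, ev, beta) {
  ## xs/tt/ev already sorted by descending time
  eta <- drop(xs %*% beta)
  w <- exp(eta)
  n <- length(tt)
  ll <- 0; S0 <- 0; i <- 1L
  while (i <= n) {
    j <- i
    while (j <= n && tt[j] == tt[i]) j <- j + 1L
    idx <- i:(j - 1L)
    S0 <- S0 + sum(w[idx])
    di <- idx[ev[idx] == 1]
    if (length(di) > 0) ll <- ll + sum(eta[di]) - length(di) * log(S0)
    i <- j
  }
  ll
}

#' Breslow baseline cumulative hazard
#'
#' @param time,event Training outcomes.
#' @param score Risk scores of the training patients.
#' @return List with `times` (unique event times, ascending) and `H0`
#'   (cumulative baseline hazard at those times); evaluate with
#'   [predict_survival()].
#' @export
breslow_baseline <- function(time, event, score) {
  ord <- order(time)
  tt <- time[ord]; ev <- event[ord]; w <- exp(score[ord] - mean(score))
  center <- mean(score)
  ## suffix sums of w give the risk-set mass at each event time
  suffix <- rev(cumsum(rev(w)))
  grp_start <- match(tt, tt)
  et <- unique(tt[ev == 1])
  increments <- vapply(et, function(t0) {
    g <- grp_start[match(t0, tt)]
    sum(ev == 1 & tt == t0) / suffix[g]
  }, numeric(1))
  list(times = et, H0 = cumsum(increments), score_center = center)
}

#' Predicted survival curves from a fitted Cox head
#'
#' `S_i(t) = exp(-H0(t) * exp(score_i - center))` with `H0` the Breslow
#' baseline of [breslow_baseline()].
#'
#' @param baseline Result of [breslow_baseline()].
#' @param score Risk scores of the patients to predict.
#' @param times Evaluation time grid.
#' @return Matrix `length(score) x length(times)` of survival probabilities.
#' @export
predict_survival <- function(baseline, score, times) {
  H0 <- stats::stepfun(baseline$times, c(0, baseline$H0))(times)
  outer(exp(score - baseline$score_center), H0, function(a, b) exp(-a * b))
}
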