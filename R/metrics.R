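#' Harrell's concordance index
#'
#' The fraction of comparable patient pairs in which the shorter-lived
#' patient received the higher predicted risk. A pair is comparable when the
#' shorter observed time belongs to a patient with an event; risk ties count
#' one half.
#'
#' @param time,event Observed survival outcome.
#' @param risk Predicted risk scores (higher = worse prognosis).
#' @return C-index in `[0, 1]`.
#' @export
concordance_index <- function(time, event, risk) {
  n <- length(time)
  stopifnot(length(event) == n, length(risk) == n)
  comp <- outer(time, time, "<") & matrix(event == 1, n, n)
  num_pairs <- sum(comp)
  if (num_pairs == 0) stop("no comparable pairs: C-index undefined")
  rd <- outer(risk, risk, "-")
  conc <- sum(comp & rd > 0) + 0.5 * sum(comp & rd == 0)
  conc / num_pairs
}

#' Kaplan-Meier estimator
#'
#' @param time,event Outcome; set `event = 1 - event` to estimate the
#'   censoring distribution.
#' @return List with `times` (unique event times) and `surv`; evaluate with
#'   [km_surv()].
#' @export
km_estimator <- function(time, event) {
  ord <- order(time)
  tt <- time[ord]; ev <- event[ord]
  at_risk <- length(tt) - match(tt, tt) + 1L
  et <- unique(tt[ev == 1])
  s <- 1
  surv <- numeric(length(et))
  for (i in seq_along(et)) {
    g <- match(et[i], tt)
    d <- sum(ev == 1 & tt == et[i])
    s <- s * (1 - d / at_risk[g])
    surv[i] <- s
  }
  list(times = et, surv = surv)
}

#' Evaluate a Kaplan-Meier curve
#'
#' @param km Result of [km_estimator()].
#' @param t Times at which to evaluate.
#' @param left Evaluate the left-continuous version `S(t-)`.
#' @return Survival probabilities.
#' @export
km_surv <- function(km, t, left = FALSE) {
  if (length(km$times) == 0) return(rep(1, length(t)))
  f <- stats::stepfun(km$times, c(1, km$surv), right = left)
  f(t)
}

#' Integrated Brier score with IPCW weighting
#'
#' The time-dependent Brier score compares each predicted survival
#' probability with the observed status, reweighted by the inverse of the
#' Kaplan-Meier estimate of the censoring distribution (patients whose
#' status at `t` is unknowable contribute zero). The score is integrated
#' over the grid by the trapezoid rule and normalized by the grid span.
#'
#' @param time,event Observed outcome of the evaluated patients.
#' @param surv Matrix `n x length(times)` of predicted survival
#'   probabilities (for example from [predict_survival()]).
#' @param times Evaluation grid (two or more times for integration; a single
#'   time returns that time's Brier score).
#' @return Scalar score in `[0, 1]`.
#' @export
integrated_brier <- function(time, event, surv, times) {
  n <- length(time)
  stopifnot(nrow(surv) == n, ncol(surv) == length(times))
  Gkm <- km_estimator(time, 1 - event)
  g_at_T <- km_surv(Gkm, time, left = TRUE)   # G(T_i-)
  g_at_t <- km_surv(Gkm, times)               # G(t)
  if (any(g_at_t <= 0) || any(g_at_T[event == 1 & time <= max(times)] <= 0)) {
    warning("censoring survival reaches zero inside the grid; truncating weights")
    g_at_T <- pmax(g_at_T, min(g_at_t[g_at_t > 0], 1))
    g_at_t <- pmax(g_at_t, min(g_at_t[g_at_t > 0], 1))
  }
  bs <- vapply(seq_along(times), function(j) {
    t0 <- times[j]
    died <- time <= t0 & event == 1
    alive <- time > t0
    contrib <- numeric(n)
    contrib[died] <- surv[died, j]^2 / g_at_T[died]
    contrib[alive] <- (1 - surv[alive, j])^2 / g_at_t[j]
    mean(contrib)
  }, numeric(1))
  if (length(times) == 1L) return(bs)
  span <- max(times) - min(times)
  sum(diff(times) * (utils::head(bs, -1) + utils::tail(bs, -1)) / 2) / span
}

#' IPCW-weighted mean absolute error of predicted survival times
#'
#' Observed and predicted times are first normalized by the cohort's maximum
#' follow-up, then the absolute error is averaged over events with inverse
#' probability of censoring weights `1 / G(T_i-)`.
#'
#' @param time,event Observed outcome.
#' @param pred_time Predicted survival time per patient (for example the
#'   median of the predicted survival curve).
#' @return Scalar error on the normalized time scale.
#' @export
ipcw_mae <- function(time, event, pred_time) {
  stopifnot(length(pred_time) == length(time))
  if (sum(event) == 0) stop("no events: IPCW-MAE undefined")
  tmax <- max(time)
  Gkm <- km_estimator(time, 1 - event)
  g <- km_surv(Gkm, time, left = TRUE)
  idx <- event == 1
  gi <- g[idx]
  if (any(gi <= 0)) {
    warning("censoring survival reaches zero at an event time; truncating weights")
    gi <- pmax(gi, min(gi[gi > 0], 1))
  }
  w <- 1 / gi
  sum(w * abs(time[idx] - pred_time[idx]) / tmax) / sum(w)
}

#' Median survival time of predicted curves
#'
#' @param surv Matrix `n x length(times)` of survival probabilities.
#' @param times Time grid.
#' @return Per-patient first grid time at which the curve drops to 0.5 or
#'   below (the grid maximum if it never does).
#' @export
predicted_median_time <- function(surv, times) {
  apply(surv, 1L, function(s) {
    hit <- which(s <= 0.5)
    if (length(hit)) times[hit[1]] else max(times)
  })
}

#' Two-group log-rank test
#'
#' @param time,event Outcome.
#' @param group Logical or two-level grouping.
#' @return List with `chisq` (1 df) and `p`.
#' @export
logrank_test <- function(time, event, group) {
  g <- as.integer(as.factor(group)) - 1L
  if (length(unique(g)) != 2L) stop("log-rank test requires two groups")
  et <- sort(unique(time[event == 1]))
  obs_minus_exp <- 0; var_sum <- 0
  for (t0 in et) {
    at <- time >= t0
    n_j <- sum(at); n1 <- sum(at & g == 1L)
    d_j <- sum(time == t0 & event == 1)
    d1 <- sum(time == t0 & event == 1 & g == 1L)
    e1 <- d_j * n1 / n_j
    if (n_j > 1)
      var_sum <- var_sum + d_j * (n1 / n_j) * (1 - n1 / n_j) *
        (n_j - d_j) / (n_j - 1)
    obs_minus_exp <- obs_minus_exp + d1 - e1
  }
  chisq <- if (var_sum > 0) obs_minus_exp^2 / var_sum else 0
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Median-split risk stratification with Kaplan-Meier curves
#'
#' Patients at or below the median risk form the low-risk group (ties to
#' low risk); the two groups are compared with a log-rank test.
#'
#' @param time,event Outcome (`n >= 4`).
#' @param risk Risk scores (for example PaTRS).
#' @return Object of class `km_stratification`: list with `group` (logical,
#'   `TRUE` = high risk), the two KM curves, `chisq`, `p`.
#' @export
stratify_km <- function(time, event, risk) {
  n <- length(time)
  if (n < 4L) stop("stratification requires n >= 4")
  high <- risk > stats::median(risk)
  if (!any(high) || all(high))
    stop("degenerate stratification: one group is empty")
  lr <- logrank_test(time, event, high)
  structure(list(group = high,
                 km_high = km_estimator(time[high], event[high]),
                 km_low = km_estimator(time[!high], event[!high]),
                 chisq = lr$chisq, p = lr$p),
            class = "km_stratification")
}

#' @export
print.km_stratification <- function(x, ...) {
  cat(sprintf("<km_stratification> %d high / %d low risk; log-rank chi-square %.3f, p = %.3g\n",
              sum(x$group), sum(!x$group), x$chisq, x$p))
  invisible(x)
}

#' Plot a Kaplan-Meier stratification
#'
#' @param x A `km_stratification`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.km_stratification <- function(x, ...) {
  tmax <- max(c(x$km_high$times, x$km_low$times, 1))
  graphics::plot(NULL, xlim = c(0, tmax), ylim = c(0, 1),
                 xlab = "Time (months)", ylab = "Survival probability", ...)
  graphics::lines(stats::stepfun(x$km_high$times, c(1, x$km_high$surv)),
                  col = "firebrick", do.points = FALSE)
  graphics::lines(stats::stepfun(x$km_low$times, c(1, x$km_low$surv)),
                  col = "steelblue", do.points = FALSE)
  graphics::legend("bottomleft", c("high risk", "low risk"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  graphics::mtext(sprintf("log-rank p = %.3g", x$p), side = 3, adj = 1)
  invisible(x)
}

t_interval <- function(x, level = 0.95) {
  n <- length(x)
  m <- mean(x)
  if (n < 2) return(list(mean = m, lower = m, upper = m, se = 0))
  se <- stats::sd(x) / sqrt(n)
  q <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  list(mean = m, lower = m - q * se, upper = m + q * se, se = se)
}

#' Fold-wise summary statistics across models
#'
#' Per-model mean and 95% t-interval (df = folds - 1), pairwise paired
#' t-tests on fold-wise scores, and a one-way repeated-measures ANOVA
#' across folds when three or more models are compared.
#'
#' @param scores Data frame with columns `model`, `fold`, `score`; every
#'   model must carry the same folds.
#' @return List with `summary`, `pairwise`, and `anova` (`NULL` with fewer
#'   than three models).
#' @export
fold_statistics <- function(scores) {
  stopifnot(all(c("model", "fold", "score") %in% names(scores)))
  counts <- table(scores$model)
  if (any(counts < 2)) stop("fold statistics require at least 2 folds per model")
  if (length(unique(counts)) != 1) stop("models must share the same folds")
  models <- unique(scores$model)
  summ <- do.call(rbind, lapply(models, function(m) {
    ci <- t_interval(scores$score[scores$model == m])
    data.frame(model = m, mean = ci$mean, ci_lower = ci$lower,
               ci_upper = ci$upper, se = ci$se)
  }))
  pairwise <- NULL
  if (length(models) >= 2) {
    combs <- utils::combn(models, 2, simplify = FALSE)
    pairwise <- do.call(rbind, lapply(combs, function(pr) {
      a <- scores[scores$model == pr[1], ]
      b <- scores[scores$model == pr[2], ]
      a <- a[order(a$fold), ]; b <- b[order(b$fold), ]
      d <- a$score - b$score
      if (stats::sd(d) < 1e-12) {
        data.frame(model_a = pr[1], model_b = pr[2],
                   t = NA_real_, p = if (all(d == 0)) 1 else NA_real_,
                   mean_diff = mean(d))
      } else {
        tt <- stats::t.test(a$score, b$score, paired = TRUE)
        data.frame(model_a = pr[1], model_b = pr[2],
                   t = unname(tt$statistic), p = tt$p.value,
                   mean_diff = mean(d))
      }
    }))
  }
  anova_res <- NULL
  if (length(models) >= 3) {
    df <- scores
    df$model <- factor(df$model); df$fold <- factor(df$fold)
    fit <- stats::aov(score ~ model + Error(fold), data = df)
    tab <- summary(fit)[["Error: Within"]][[1]]
    anova_res <- list(F = tab["model", "F value"],
                      p = tab["model", "Pr(>F)"])
  }
  list(summary = summ, pairwise = pairwise, anova = anova_res)
}

#' Stratified cross-validation folds
#'
#' Patient-level splits stratified by event indicator, so every fold's
#' event fraction matches the cohort's within one patient. Identical given
#' the seed, so compared models share the same splits.
#'
#' @param event Event indicator vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold assignment per patient.
#' @export
make_folds <- function(event, k = 5L, seed = 1L) {
  n <- length(event)
  if (n < k) stop("fewer patients than folds")
  folds <- integer(n)
  with_seed(seed, {
    for (lev in unique(event)) {
      idx <- which(event == lev)
      if (length(idx) < k)
        warning("stratum smaller than fold count; assignment is unbalanced")
      folds[idx] <- rep_len(seq_len(k), length(idx))[sample(length(idx))]
    }
  })
  folds
}
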