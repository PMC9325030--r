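# Time-dependent ROC, AIC cut-point, risk groups, Kaplan-Meier and log-rank.

# Kaplan-Meier survival probability at t0 for (time, status).
km_at <- function(time, status, t0) {
  ev <- unique(time[status == 1 & time <= t0])
  if (length(ev) == 0) return(1)
  ev <- sort(ev)
  nr <- vapply(ev, function(u) sum(time >= u), numeric(1))
  d <- vapply(ev, function(u) sum(time == u & status == 1), numeric(1))
  prod(1 - d / nr)
}

align_scores <- function(scores, clinical) {
  if (!is.null(names(scores))) {
    if (!all(clinical$sample_id %in% names(scores)))
      stop_stage("survstats", "scores missing for some clinical samples")
    scores[clinical$sample_id]
  } else {
    if (length(scores) != nrow(clinical))
      stop_stage("survstats", "unnamed scores must match clinical rows")
    scores
  }
}

#' Time-dependent ROC curve and AUC (cumulative/dynamic, KM-weighted)
#'
#' Cumulative-case / dynamic-control ROC at horizon `t`: cases are subjects
#' with an observed event by `t`, controls those still event-free past `t`.
#' Censoring before `t` is handled by the Kaplan-Meier estimator of
#' Heagerty, Lumley and Pepe: with `S` the overall KM survival at `t` and
#' `S_c` the KM survival at `t` within `{score > c}`,
#' `sens(c) = (1 - S_c) P(score > c) / (1 - S)` and
#' `spec(c) = 1 - S_c P(score > c) / S`.  The AUC integrates the curve by
#' the trapezoidal rule over all observed score thresholds.  Without
#' censoring before `t` this reduces exactly to the empirical ROC, whose
#' trapezoidal AUC equals the Mann-Whitney statistic.
#'
#' @param scores per-sample risk scores (named by sample id, or in clinical
#'   row order).
#' @param clinical data.frame with `sample_id`, `futime`, `fustat`.
#' @param t horizon in days (> 0).
#' @return object of class `"td_roc"`: `horizon`, `thresholds` (descending,
#'   ending at `-Inf`), `sens`, `spec`, `auc`, `n_case`, `n_control`.
#' @export
td_roc_auc <- function(scores, clinical, t) {
  if (t <= 0) stop_stage("survstats", "horizon must be > 0")
  sc <- align_scores(scores, clinical)
  time <- clinical$futime; status <- clinical$fustat
  n_case <- sum(time <= t & status == 1)
  n_control <- sum(time > t)
  if (n_case == 0)
    stop_stage("survstats", "no events by t = %s; AUC undefined", format(t))
  S_all <- km_at(time, status, t)
  if (S_all >= 1)
    stop_stage("survstats", "overall KM survival is 1 at t = %s", format(t))

  thr <- c(sort(unique(sc), decreasing = TRUE), -Inf)
  n <- length(sc)
  sens <- spec <- numeric(length(thr))
  for (k in seq_along(thr)) {
    sel <- sc > thr[k]
    px <- mean(sel)
    if (px == 0) { sens[k] <- 0; spec[k] <- 1; next }
    S_c <- km_at(time[sel], status[sel], t)
    sens[k] <- (1 - S_c) * px / (1 - S_all)
    spec[k] <- 1 - S_c * px / S_all
  }
  sens <- pmin(pmax(sens, 0), 1)
  spec <- pmin(pmax(spec, 0), 1)
  # integrate in threshold order (descending), i.e. along the curve from
  # (0,0) to (1,1); re-sorting by FPR would let floating-point jitter on
  # tied FPR values cut staircase corners
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  structure(list(horizon = t, thresholds = thr, sens = sens, spec = spec,
                 auc = auc, n_case = n_case, n_control = n_control),
            class = "td_roc")
}

#' @export
print.td_roc <- function(x, ...) {
  cat("Time-dependent ROC at t =", x$horizon, "days: AUC =",
      round(x$auc, 4), "(", x$n_case, "cases /", x$n_control, "controls )\n")
  invisible(x)
}

#' @export
plot.td_roc <- function(x, ...) {
  graphics::plot(1 - x$spec, x$sens, type = "l", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "1 - specificity",
                 ylab = "sensitivity",
                 main = sprintf("t = %s days, AUC = %.3f", x$horizon, x$auc),
                 ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' AIC-optimal risk-score cut-point on the time-dependent ROC
#'
#' Evaluates every point of the horizon-`t` ROC curve as a dichotomisation:
#' for each candidate threshold `c` (midpoints of consecutive sorted unique
#' scores), horizon status (case: event by `t`; control: event-free past
#' `t`; censored-before-`t` excluded) is modelled by a binomial fit on the
#' indicator `score > c`, and `AIC = 2k - 2 logLik` with `k = 2` parameters.
#' The returned cut-point minimises the AIC; ties take the smaller
#' threshold.  `method = "youden"` instead maximises Youden's J
#' (sensitivity + specificity - 1) over the same candidates.
#'
#' @param scores per-sample risk scores (named or in clinical row order).
#' @param clinical data.frame with `sample_id`, `futime`, `fustat`.
#' @param t horizon in days (default 1825 = 5 years).
#' @param method `"aic"` (default) or `"youden"`.
#' @return object of class `"cutoff_result"`: `cutoff`, `method`, `horizon`,
#'   and the per-threshold `table` (`threshold`, `aic`, `youden`).
#' @export
aic_cutoff <- function(scores, clinical, t = 1825,
                       method = c("aic", "youden")) {
  method <- match.arg(method)
  sc <- align_scores(scores, clinical)
  time <- clinical$futime; status <- clinical$fustat
  case <- time <= t & status == 1
  control <- time > t
  keep <- case | control
  if (sum(case) == 0 || sum(control) == 0)
    stop_stage("survstats", "need at least one case and one control at t = %s",
               format(t))
  s <- sc[keep]; is_case <- case[keep]
  u <- sort(unique(s))
  if (length(u) < 2)
    stop_stage("survstats", "all scores identical; no cut-point exists")
  cand <- (u[-1] + u[-length(u)]) / 2

  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  tab <- t(vapply(cand, function(cc) {
    hi <- s > cc
    a <- sum(is_case & hi); b <- sum(is_case & !hi)
    cc_ <- sum(!is_case & hi); d <- sum(!is_case & !hi)
    # binomial log-likelihood of a 2-group (above/below) dichotomisation
    ll <- xlogx(a) + xlogx(cc_) - xlogx(a + cc_) +
          xlogx(b) + xlogx(d) - xlogx(b + d)
    j <- a / (a + b) + d / (cc_ + d) - 1
    c(aic = 4 - 2 * ll, youden = j)
  }, c(aic = 0, youden = 0)))
  idx <- if (method == "aic") which.min(tab[, "aic"])
         else which.max(tab[, "youden"])
  structure(list(cutoff = cand[idx], method = method, horizon = t,
                 table = data.frame(threshold = cand, aic = tab[, "aic"],
                                    youden = tab[, "youden"])),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat("Risk-score cut-point (", x$method, ", t = ", x$horizon, " days): ",
      format(x$cutoff), "\n", sep = "")
  invisible(x)
}

#' Assign high/low risk groups at a cut-point
#'
#' @param scores named per-sample risk scores.
#' @param cutoff finite cut-point; a sample is `high` iff `score > cutoff`.
#' @return data.frame of class `"risk_profile"` with `sample_id`, `score`,
#'   `group` (factor low/high); the cut-point is stored as attribute
#'   `"cutoff"`.
#' @export
assign_risk_groups <- function(scores, cutoff) {
  if (inherits(cutoff, "cutoff_result")) cutoff <- cutoff$cutoff
  if (!is.finite(cutoff)) stop_stage("survstats", "cutoff must be finite")
  grp <- factor(ifelse(scores > cutoff, "high", "low"),
                levels = c("low", "high"))
  out <- data.frame(sample_id = names(scores) %||%
                      paste0("s", seq_along(scores)),
                    score = unname(scores), group = grp,
                    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("risk_profile", "data.frame")
  out
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate for one sample set; a thin wrapper around
#' [survival::survfit()] returning the step function as a table with the
#' `S(0) = 1` origin included.
#'
#' @param clinical data.frame with `futime`, `fustat`.
#' @return data.frame of class `"km_curve"` (`time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`), with the `survfit` object as attribute `"fit"`.
#' @export
km_curve <- function(clinical) {
  if (nrow(clinical) == 0) stop_stage("survstats", "empty clinical subset")
  fit <- survival::survfit(
    survival::Surv(futime, fustat) ~ 1,
    data = clinical[, c("futime", "fustat"), drop = FALSE])
  out <- data.frame(time = c(0, fit$time),
                    n_risk = c(fit$n, fit$n.risk),
                    n_event = c(0, fit$n.event),
                    n_censor = c(0, fit$n.censor),
                    surv = c(1, fit$surv))
  attr(out, "fit") <- fit
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of survival between groups (chi-square with
#' `#groups - 1` df), wrapping [survival::survdiff()].
#'
#' @param clinical data.frame with `futime`, `fustat`.
#' @param groups group labels aligned to `clinical` rows (or named by
#'   `sample_id`).
#' @return list of class `"logrank_test"`: `statistic`, `df`, `p`,
#'   `n`, `obs`, `exp`.
#' @export
logrank_test <- function(clinical, groups) {
  if (!is.null(names(groups))) {
    if (!all(clinical$sample_id %in% names(groups)))
      stop_stage("survstats", "groups missing for some samples")
    groups <- groups[clinical$sample_id]
  }
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2)
    stop_stage("survstats", "log-rank needs >= 2 non-empty groups")
  if (sum(clinical$fustat) == 0)
    stop_stage("survstats", "log-rank needs >= 1 event")
  dat <- data.frame(futime = clinical$futime, fustat = clinical$fustat,
                    g = groups)
  sd_ <- survival::survdiff(survival::Surv(futime, fustat) ~ g, data = dat)
  df <- nlevels(groups) - 1L
  structure(list(statistic = sd_$chisq, df = df,
                 p = pchisq(sd_$chisq, df, lower.tail = FALSE),
                 n = as.numeric(sd_$n), obs = sd_$obs, exp = sd_$exp),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Log-rank test: chi-square =", round(x$statistic, 4), "on", x$df,
      "df, p =", format.pval(x$p, digits = 4), "\n")
  invisible(x)
}
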