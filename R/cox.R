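# Cox proportional-hazards fitting and screening.  survival::coxph (Efron
# ties, Newton-Raphson) does the estimation; this layer standardises feature
# alignment, convergence reporting and the summary surface used downstream.

# Accept features as samples x features (rownames = sample ids) or
# features x samples (e.g. a pair matrix); return samples x features aligned
# to clinical$sample_id.
align_features <- function(features, clinical) {
  if (is.null(dim(features)))
    features <- matrix(features, ncol = 1,
                       dimnames = list(names(features), "x"))
  ids <- clinical$sample_id
  if (!is.null(rownames(features)) && all(ids %in% rownames(features)))
    return(features[ids, , drop = FALSE])
  if (!is.null(colnames(features)) && all(ids %in% colnames(features)))
    return(t(features[, ids, drop = FALSE]))
  if (nrow(features) == length(ids)) return(features)
  if (ncol(features) == length(ids)) return(t(features))
  stop_stage("signature", "cannot align features to clinical samples")
}

.cox_warn_patterns <- paste(
  c("did not converge", "infinite", "converged before variable",
    "out of iterations", "beta may be infinite"), collapse = "|")

#' Fit a Cox proportional hazards model
#'
#' Maximises the partial likelihood with Efron tie handling.  Monotone
#' likelihood (perfect separation) and other convergence failures are
#' reported through the `converged` flag rather than silently returning huge
#' coefficients; constant features yield `NA` coefficients.
#'
#' @param features numeric vector, samples x features matrix (rownames =
#'   sample ids) or features x samples matrix (e.g. a pair matrix).
#' @param clinical data.frame with `sample_id`, `futime`, `fustat`.
#' @return object of class `"cox_fit"`: named `coefficients`, `hr`,
#'   `ci_lower`/`ci_upper` (95%), `se`, `p` (Wald), `loglik`
#'   (null, fitted), `n`, `nevent`, `converged`, and the underlying `fit`.
#' @examples
#' cl <- data.frame(sample_id = paste0("s", 1:60),
#'                  futime = rexp(60, 0.01 * exp(0.7 * rep(0:1, 30))),
#'                  fustat = 1)
#' f <- setNames(rep(0:1, 30), cl$sample_id)
#' fit_cox(f, cl)
#' @export
fit_cox <- function(features, clinical) {
  x <- align_features(features, clinical)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (sum(clinical$fustat) == 0)
    stop_stage("signature", "zero events; cannot fit Cox model")
  dat <- data.frame(futime = clinical$futime, fustat = clinical$fustat,
                    x, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(futime, fustat) ~",
    paste(sprintf("`%s`", colnames(x)), collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl(.cox_warn_patterns, conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  beta <- stats::coef(fit)
  names(beta) <- colnames(x)
  se <- sqrt(diag(fit$var))
  if (length(se) < length(beta)) {     # NA coefficients drop out of var
    full_se <- rep(NA_real_, length(beta))
    full_se[!is.na(beta)] <- se
    se <- full_se
  }
  z <- beta / se
  structure(list(
    coefficients = beta,
    hr = exp(beta),
    ci_lower = exp(beta - 1.96 * se),
    ci_upper = exp(beta + 1.96 * se),
    se = se,
    p = 2 * pnorm(abs(z), lower.tail = FALSE),
    loglik = fit$loglik,
    n = fit$n, nevent = fit$nevent,
    converged = converged && is.null(fit$fail),
    fit = fit), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 4, ...) {
  cat("Cox proportional hazards fit (Efron ties): n =", x$n,
      ", events =", x$nevent, "\n")
  tab <- data.frame(beta = x$coefficients, HR = x$hr,
                    `CI95.lo` = x$ci_lower, `CI95.hi` = x$ci_upper,
                    p = x$p, check.names = FALSE)
  print(round(tab, digits))
  if (!x$converged)
    cat("warning: fit did not converge (possible monotone likelihood)\n")
  invisible(x)
}

#' Univariate Cox screen over candidate pairs
#'
#' Fits one single-feature Cox model per pair and keeps pairs whose Wald
#' p-value is below `p_max`.  Non-convergent fits (monotone likelihood) are
#' dropped with a message, as are constant pairs.
#'
#' @param pm pair matrix (pairs x samples).
#' @param clinical clinical table covering the pair-matrix samples.
#' @param p_max Wald p-value threshold (default 0.05, strict).
#' @return list with `ids` (retained pair identifiers, in pair-matrix order)
#'   and `table` (pair_id, beta, hr, p, converged).
#' @export
univariate_cox_screen <- function(pm, clinical, p_max = 0.05) {
  if (nrow(pm) == 0)
    return(list(ids = character(0),
                table = data.frame(pair_id = character(0), beta = numeric(0),
                                   hr = numeric(0), p = numeric(0),
                                   converged = logical(0))))
  clinical <- clinical[clinical$sample_id %in% colnames(pm), , drop = FALSE]
  x <- align_features(pm, clinical)
  y <- survival::Surv(clinical$futime, clinical$fustat)
  res <- lapply(colnames(x), function(pid) {
    v <- x[, pid]
    if (stats::sd(v) == 0)
      return(data.frame(pair_id = pid, beta = NA_real_, hr = NA_real_,
                        p = NA_real_, converged = FALSE))
    converged <- TRUE
    fit <- withCallingHandlers(
      survival::coxph(y ~ v, ties = "efron"),
      warning = function(w) {
        if (grepl(.cox_warn_patterns, conditionMessage(w))) {
          converged <<- FALSE
          invokeRestart("muffleWarning")
        }
      })
    b <- unname(stats::coef(fit))
    se <- sqrt(diag(fit$var))[1]
    data.frame(pair_id = pid, beta = b, hr = exp(b),
               p = 2 * pnorm(abs(b / se), lower.tail = FALSE),
               converged = converged)
  })
  tab <- do.call(rbind, res)
  n_bad <- sum(!tab$converged)
  if (n_bad > 0)
    message("univariate_cox_screen: dropped ", n_bad,
            " non-convergent/constant pair(s)")
  keep <- tab$converged & !is.na(tab$p) & tab$p < p_max
  list(ids = tab$pair_id[keep], table = tab)
}
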