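#' Repeated cross-validated LASSO-Cox selection with frequency counting
#'
#' Runs `n_repeats` cycles of `folds`-fold cross-validated L1-penalised Cox
#' regression (glmnet).  Each cycle draws a fresh random fold partition,
#' picks the penalty minimising the mean cross-validated partial-likelihood
#' deviance (`lambda.min`; `lambda_rule = "1se"` for the one-standard-error
#' rule), and records which pairs carry a non-zero coefficient there.  Pairs
#' selected in strictly more than `min_count` cycles form the stable set;
#' by default `min_count` is 10% of `n_repeats`, the proportion behind the
#' "frequency above 100 of 1000 cycles" rule.
#'
#' Binary 0/1 indicators share a scale already, so features are not
#' standardised before penalisation (`standardize = FALSE` by default).
#'
#' @param pm pair matrix (pairs x samples), restricted to the univariate
#'   survivors.
#' @param clinical clinical table covering the pair-matrix samples.
#' @param n_repeats number of LASSO cycles (default 1000).
#' @param folds cross-validation folds per cycle (default 10).
#' @param min_count selection-count threshold (strict); default
#'   `round(min_count_fraction * n_repeats)`.
#' @param min_count_fraction fraction of repeats behind the default
#'   `min_count` (default 0.1).
#' @param seed integer seed governing every fold partition.
#' @param nlambda penalty-path length per fit (default 50; frequency counting
#'   only needs a coarse grid).
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @param standardize standardise features inside glmnet (default FALSE).
#' @return object of class `"lasso_selection"`: named `counts`, `selected`
#'   (pair ids with `count > min_count`), `lambda` per repeat, plus the
#'   settings used.
#' @export
repeated_lasso_selection <- function(pm, clinical, n_repeats = 1000,
                                     folds = 10, min_count = NULL,
                                     min_count_fraction = 0.1, seed = 1,
                                     nlambda = 50,
                                     lambda_rule = c("min", "1se"),
                                     standardize = FALSE) {
  lambda_rule <- match.arg(lambda_rule)
  if (nrow(pm) == 0)
    stop_stage("signature", "candidate pair set is empty")
  if (is.null(min_count)) min_count <- round(min_count_fraction * n_repeats)
  clinical <- clinical[clinical$sample_id %in% colnames(pm), , drop = FALSE]
  x <- align_features(pm, clinical)
  n_event <- sum(clinical$fustat)
  if (n_event < folds)
    stop_stage("signature",
               "need >= %d samples with events for %d-fold CV (have %d)",
               folds, folds, n_event)
  y <- survival::Surv(clinical$futime, clinical$fustat)
  counts <- setNames(integer(ncol(x)), colnames(x))
  lambdas <- numeric(n_repeats)

  if (ncol(x) == 1L) {
    # glmnet needs >= 2 columns; a single candidate is trivially stable
    counts[] <- n_repeats
    lambdas[] <- NA_real_
  } else {
    set.seed(stream_seed(seed, "lasso"))
    s_name <- paste0("lambda.", lambda_rule)
    for (i in seq_len(n_repeats)) {
      foldid <- sample(rep_len(seq_len(folds), nrow(x)))
      cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                              nlambda = nlambda, standardize = standardize)
      b <- as.numeric(stats::coef(cv, s = cv[[s_name]]))
      counts <- counts + (b != 0)
      lambdas[i] <- cv[[s_name]]
    }
  }
  structure(list(counts = counts,
                 selected = names(counts)[counts > min_count],
                 n_repeats = n_repeats, folds = folds,
                 min_count = min_count, lambda = lambdas,
                 lambda_rule = lambda_rule, seed = seed),
            class = "lasso_selection")
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat("Repeated LASSO-Cox selection:", x$n_repeats, "cycles,", x$folds,
      "folds, lambda.", x$lambda_rule, "\n", sep = "")
  cat("  stable pairs (count > ", x$min_count, "): ",
      length(x$selected), " of ", length(x$counts), "\n", sep = "")
  top <- sort(x$counts, decreasing = TRUE)
  print(head(top, 10))
  invisible(x)
}

#' Greedy AUC-guided Cox model search
#'
#' Builds the final signature by greedy forward selection: starting from the
#' empty model, each step adds the pair whose refitted multivariate Cox model
#' maximises the `horizon` time-dependent AUC of the in-sample risk scores
#' ([td_roc_auc()]); the search stops when no addition increases the AUC.
#' Ties prefer the smaller model, then the lexicographically smaller pair.
#' `search = "all"` instead fits one Cox model on all candidates.
#'
#' @param pm pair matrix containing the candidate pairs.
#' @param clinical clinical table covering the pair-matrix samples.
#' @param candidates candidate pair identifiers (default: all rows of `pm`).
#' @param horizon ROC horizon in days (default 1825 = 5 years).
#' @param search `"greedy"` (default) or `"all"`.
#' @return object of class `"pair_signature"`; see [fit_pair_signature()].
#' @export
forward_auc_search <- function(pm, clinical, candidates = rownames(pm),
                               horizon = 1825, search = c("greedy", "all")) {
  search <- match.arg(search)
  if (length(candidates) == 0)
    stop_stage("signature", "no candidate pairs for model search")
  missing <- setdiff(candidates, rownames(pm))
  if (length(missing) > 0)
    stop_stage("signature", "candidates absent from pair matrix: %s",
               paste(missing, collapse = ", "))
  clinical <- clinical[clinical$sample_id %in% colnames(pm), , drop = FALSE]
  candidates <- sort(candidates)

  model_auc <- function(ids) {
    fit <- tryCatch(fit_cox(pm[ids, , drop = FALSE], clinical),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged || anyNA(fit$coefficients))
      return(list(auc = -Inf, fit = NULL))
    sc <- risk_score(list(pair_ids = ids, beta = fit$coefficients), pm)
    auc <- tryCatch(td_roc_auc(sc, clinical, horizon)$auc,
                    error = function(e) -Inf)
    list(auc = auc, fit = fit)
  }

  if (search == "all") {
    chosen <- candidates
    best <- model_auc(chosen)
    history <- data.frame(step = 1L, added = paste(chosen, collapse = ","),
                          auc = best$auc)
  } else {
    chosen <- character(0)
    best <- list(auc = -Inf, fit = NULL)
    history <- data.frame(step = integer(0), added = character(0),
                          auc = numeric(0))
    repeat {
      remaining <- setdiff(candidates, chosen)
      if (length(remaining) == 0) break
      step_best <- list(auc = -Inf, fit = NULL); step_pair <- NULL
      for (pid in remaining) {      # lexicographic order; strict > keeps first
        cand <- model_auc(c(chosen, pid))
        if (cand$auc > step_best$auc) {
          step_best <- cand
          step_pair <- pid
        }
      }
      if (is.null(step_pair) || step_best$auc <= best$auc) break
      chosen <- c(chosen, step_pair)
      best <- step_best
      history <- rbind(history, data.frame(step = length(chosen),
                                           added = step_pair,
                                           auc = best$auc))
    }
  }
  if (length(chosen) == 0 || is.null(best$fit))
    stop_stage("signature", "model search found no fittable pair model")

  structure(list(pair_ids = chosen,
                 beta = best$fit$coefficients[chosen],
                 cox = best$fit, auc = best$auc, horizon = horizon,
                 search = search, history = history),
            class = "pair_signature")
}

#' Fit an expression-level-independent pair signature
#'
#' The headline fitting function: runs the full selection cascade on a binary
#' pair matrix and survival data -
#' \enumerate{
#'   \item univariate Cox screen at `uni_p` ([univariate_cox_screen]);
#'   \item `n_repeats` cycles of 10-fold cross-validated LASSO-Cox with
#'     selection-frequency thresholding ([repeated_lasso_selection]);
#'   \item greedy forward Cox search maximising the `horizon` time-dependent
#'     AUC ([forward_auc_search]).
#' }
#' The fitted object holds the signature pairs, their Cox coefficients
#' (the beta of `RiskScore = sum(beta_i * S_i)`), hazard ratios with 95% CIs,
#' and the training AUC.
#'
#' @param pm pair matrix (pairs x samples) from [build_pair_matrix()] +
#'   [filter_valid_pairs()].
#' @param clinical clinical table (`sample_id`, `futime`, `fustat`); samples
#'   are intersected with the pair-matrix columns.
#' @param uni_p univariate Wald p threshold (default 0.05).
#' @param n_repeats,folds,min_count,min_count_fraction,nlambda,lambda_rule
#'   passed to [repeated_lasso_selection()].
#' @param horizon ROC horizon in days (default 1825 = 5 years).
#' @param search `"greedy"` or `"all"`; see [forward_auc_search()].
#' @param seed integer seed for the LASSO fold partitions.
#' @param quiet suppress progress messages.
#' @return object of class `"pair_signature"` with components `pair_ids`,
#'   `beta`, `cox` (a [fit_cox()] result), `auc`, `horizon`, `history` and
#'   `selection` (funnel: univariate table, selection counts, settings).
#' @seealso [predict.pair_signature()], [risk_score()]
#' @export
fit_pair_signature <- function(pm, clinical, uni_p = 0.05,
                               n_repeats = 1000, folds = 10,
                               min_count = NULL, min_count_fraction = 0.1,
                               horizon = 1825, search = "greedy",
                               seed = 1, nlambda = 50,
                               lambda_rule = "min", quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  clinical <- clinical[clinical$sample_id %in% colnames(pm), , drop = FALSE]
  if (nrow(clinical) == 0)
    stop_stage("signature", "no overlap between pair matrix and clinical samples")

  uni <- univariate_cox_screen(pm, clinical, p_max = uni_p)
  say("fit_pair_signature: ", length(uni$ids), " of ", nrow(pm),
      " pairs pass univariate screen (p < ", uni_p, ")")
  if (length(uni$ids) == 0)
    stop_stage("signature", "no pairs pass the univariate screen")

  las <- repeated_lasso_selection(pm[uni$ids, , drop = FALSE], clinical,
                                  n_repeats = n_repeats, folds = folds,
                                  min_count = min_count,
                                  min_count_fraction = min_count_fraction,
                                  seed = seed, nlambda = nlambda,
                                  lambda_rule = lambda_rule)
  say("fit_pair_signature: ", length(las$selected),
      " pairs selected in > ", las$min_count, " of ", n_repeats, " cycles")
  if (length(las$selected) == 0)
    stop_stage("signature", "no pairs pass the selection-frequency threshold")

  sig <- forward_auc_search(pm, clinical, candidates = las$selected,
                            horizon = horizon, search = search)
  say("fit_pair_signature: final model has ", length(sig$pair_ids),
      " pair(s), ", horizon, "-day AUC = ", round(sig$auc, 3))
  sig$selection <- list(univariate = uni$table, n_univariate = length(uni$ids),
                        lasso = las, seed = seed, uni_p = uni_p)
  sig
}

#' Risk score of the pair signature
#'
#' `RiskScore(sample) = sum_i beta_i * S_i(sample)` over the signature's pair
#' indicators.
#'
#' @param model a `pair_signature` (or any list with `pair_ids` and `beta`).
#' @param pm pair matrix containing every signature pair.
#' @return named numeric vector of per-sample risk scores.
#' @export
risk_score <- function(model, pm) {
  missing <- setdiff(model$pair_ids, rownames(pm))
  if (length(missing) > 0)
    stop_stage("signature", "pair(s) missing from pair matrix: %s",
               paste(missing, collapse = ", "))
  beta <- model$beta[model$pair_ids]
  colSums(pm[model$pair_ids, , drop = FALSE] * beta)
}

#' @export
print.pair_signature <- function(x, digits = 4, ...) {
  cat("Pair signature:", length(x$pair_ids), "lncRNA pair(s), ",
      x$horizon, "-day training AUC =", round(x$auc, digits), "\n")
  print(round(x$beta, digits))
  invisible(x)
}

#' @rdname print.pair_signature
#' @param object,x a `pair_signature`.
#' @param digits significant digits for printing.
#' @param ... unused.
#' @export
summary.pair_signature <- function(object, ...) {
  cox <- object$cox
  tab <- data.frame(pair_id = object$pair_ids,
                    beta = cox$coefficients[object$pair_ids],
                    hr = cox$hr[object$pair_ids],
                    ci_lower = cox$ci_lower[object$pair_ids],
                    ci_upper = cox$ci_upper[object$pair_ids],
                    p = cox$p[object$pair_ids],
                    row.names = NULL)
  structure(list(table = tab, auc = object$auc, horizon = object$horizon,
                 n = cox$n, nevent = cox$nevent),
            class = "summary.pair_signature")
}

#' @export
print.summary.pair_signature <- function(x, digits = 4, ...) {
  cat("Pair signature (", nrow(x$table), " pairs): n = ", x$n,
      ", events = ", x$nevent, ", ", x$horizon, "-day AUC = ",
      round(x$auc, digits), "\n", sep = "")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) signif(v, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pair_signature <- function(object, ...) object$beta

#' Predict from a pair signature
#'
#' @param object a fitted `pair_signature`.
#' @param pm pair matrix for the samples to score.
#' @param type `"score"` (risk score, default) or `"group"` (high/low given
#'   `cutoff`).
#' @param cutoff risk-score cut-point, required for `type = "group"`;
#'   typically from [aic_cutoff()].
#' @param ... unused.
#' @return named numeric scores, or a factor of `"low"`/`"high"` groups.
#' @export
predict.pair_signature <- function(object, pm, type = c("score", "group"),
                                   cutoff = NULL, ...) {
  type <- match.arg(type)
  sc <- risk_score(object, pm)
  if (type == "score") return(sc)
  if (is.null(cutoff))
    stop_stage("signature", "type = 'group' needs a cutoff")
  assign_risk_groups(sc, cutoff)$group
}
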