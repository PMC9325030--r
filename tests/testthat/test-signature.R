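test_that("Cox fit recovers a known log hazard ratio and its null", {
  # rate ratio 2 between exponential groups: beta ~ ln 2; independent oracle
  # is the exponential MLE log(rate1/rate0)
  d <- sim_exp_surv(2000, beta = log(2), seed = 101)
  fit <- fit_cox(setNames(d$x, d$clin$sample_id), d$clin)
  mle <- log((sum(d$x == 1) / sum(d$clin$futime[d$x == 1])) /
             (sum(d$x == 0) / sum(d$clin$futime[d$x == 0])))
  expect_lt(abs(fit$coefficients - log(2)), 0.1)
  expect_lt(abs(fit$coefficients - mle), 0.05)
  expect_true(fit$converged)
  # feature independent of survival: beta ~ 0
  d0 <- sim_exp_surv(2000, beta = 0, seed = 102)
  fit0 <- fit_cox(setNames(d0$x, d0$clin$sample_id), d0$clin)
  expect_lt(abs(fit0$coefficients), 0.05)
})

test_that("Cox fit reports degenerate inputs instead of silently failing", {
  clin <- make_clin(c(1, 2), c(1, 1))
  fit <- suppressWarnings(fit_cox(setNames(c(1, 0), clin$sample_id), clin))
  expect_false(fit$converged)                      # monotone likelihood
  expect_error(fit_cox(setNames(c(1, 0), c("s1", "s2")),
                       make_clin(c(1, 2), c(0, 0))), "zero events")
  # constant feature -> undefined coefficient
  d <- sim_exp_surv(50, beta = 0, seed = 5)
  fitc <- suppressWarnings(
    fit_cox(matrix(1, 50, 1, dimnames = list(d$clin$sample_id, "const")),
            d$clin))
  expect_true(is.na(fitc$coefficients))
})

test_that("Cox estimates are translation-invariant and scale-equivariant", {
  d <- sim_exp_surv(400, beta = 0.7, seed = 7)
  x <- setNames(d$x, d$clin$sample_id)
  b0 <- fit_cox(x, d$clin)$coefficients
  expect_equal(fit_cox(x + 5, d$clin)$coefficients, b0,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fit_cox(x * 3, d$clin)$coefficients, b0 / 3,
               tolerance = 1e-6, ignore_attr = TRUE)
  # partial likelihood at the MLE is no worse than at beta = 0
  fit <- fit_cox(x, d$clin)
  expect_gte(fit$loglik[2], fit$loglik[1])
})

test_that("univariate screen keeps informative pairs at ~nominal type I error", {
  # planted pair with beta = 1 at n = 400 is retained
  set.seed(20)
  pm <- matrix(rbinom(30 * 400, 1, 0.5), 30, 400,
               dimnames = list(sprintf("p%02d|q%02d", 1:30, 1:30),
                               paste0("s", 1:400)))
  lp <- pm[1, ] * 1.0
  tt <- rexp(400, 0.002 * exp(lp))
  clin <- make_clin(tt, rep(1L, 400), paste0("s", 1:400))
  scr <- univariate_cox_screen(pm, clin)
  expect_true(rownames(pm)[1] %in% scr$ids)
  # null pairs retained at roughly the nominal 5% rate across seeds
  rates <- vapply(1:25, function(s) {
    set.seed(300 + s)
    pmn <- matrix(rbinom(40 * 150, 1, 0.5), 40, 150,
                  dimnames = list(sprintf("n%02d|m%02d", 1:40, 1:40),
                                  paste0("s", 1:150)))
    cln <- make_clin(rexp(150, 0.002), rep(1L, 150), paste0("s", 1:150))
    length(univariate_cox_screen(pmn, cln)$ids) / 40
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.02)
  # empty pair matrix -> empty candidate set
  empty <- matrix(integer(0), 0, 10,
                  dimnames = list(character(0), paste0("s", 1:10)))
  expect_length(univariate_cox_screen(empty, make_clin(1:10, rep(1, 10)))$ids,
                0)
})

test_that("risk score is the linear pair-indicator combination", {
  pm <- rbind("a|b" = c(1L, 0L, 1L), "c|d" = c(1L, 1L, 0L))
  colnames(pm) <- paste0("s", 1:3)
  model <- list(pair_ids = c("a|b", "c|d"), beta = c("a|b" = 0.5, "c|d" = -0.2))
  expect_equal(risk_score(model, pm), c(s1 = 0.3, s2 = -0.2, s3 = 0.5))
  # all-zero indicators score 0
  pm0 <- pm; pm0[] <- 0L
  expect_equal(unname(risk_score(model, pm0)), c(0, 0, 0))
  # linearity: splitting a beta across a duplicated pair changes nothing
  pm2 <- rbind(pm, "a|b2" = pm["a|b", ])
  model2 <- list(pair_ids = c("a|b", "a|b2", "c|d"),
                 beta = c("a|b" = 0.25, "a|b2" = 0.25, "c|d" = -0.2))
  expect_equal(unname(risk_score(model2, pm2)), unname(risk_score(model, pm)))
  # missing pair is an explicit error naming the pair
  expect_error(risk_score(model, pm[1, , drop = FALSE]), "c\\|d")
})

test_that("repeated LASSO selection is deterministic and threshold-faithful", {
  coh <- small_cohort()
  pm <- coh$pair_matrix
  s1 <- repeated_lasso_selection(pm, coh$clinical, n_repeats = 10, seed = 4)
  s2 <- repeated_lasso_selection(pm, coh$clinical, n_repeats = 10, seed = 4)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$selected, s2$selected)
  # impossible threshold empties the selection
  s3 <- repeated_lasso_selection(pm, coh$clinical, n_repeats = 5,
                                 min_count = 5, seed = 4)
  expect_length(s3$selected, 0)
  # counts never exceed the number of repeats
  expect_true(all(s1$counts >= 0 & s1$counts <= 10))
  expect_error(repeated_lasso_selection(pm[0, , drop = FALSE], coh$clinical),
               "empty")
})

test_that("greedy AUC search matches exhaustive subset search on few candidates", {
  coh <- small_cohort()
  pm <- coh$pair_matrix
  clin <- coh$clinical
  cands <- unique(c(coh$truth$true_pair_ids, rownames(pm)[1:6]))[1:6]
  sig <- forward_auc_search(pm, clin, candidates = cands, horizon = 1825)

  # exhaustive oracle over all non-empty subsets
  best_auc <- -Inf
  subsets <- unlist(lapply(seq_along(cands), function(k)
    combn(cands, k, simplify = FALSE)), recursive = FALSE)
  for (ss in subsets) {
    fit <- tryCatch(suppressWarnings(fit_cox(pm[ss, , drop = FALSE], clin)),
                    error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients) || !fit$converged) next
    sc <- risk_score(list(pair_ids = ss, beta = fit$coefficients), pm)
    auc <- td_roc_auc(sc, clin, 1825)$auc
    if (auc > best_auc) best_auc <- auc
  }
  expect_gte(sig$auc, best_auc - 0.02)
  # single candidate: model is that pair at its univariate AUC
  sig1 <- forward_auc_search(pm, clin, candidates = cands[1], horizon = 1825)
  expect_equal(sig1$pair_ids, cands[1])
  fit1 <- fit_cox(pm[cands[1], , drop = FALSE], clin)
  sc1 <- risk_score(list(pair_ids = cands[1], beta = fit1$coefficients), pm)
  expect_equal(sig1$auc, td_roc_auc(sc1, clin, 1825)$auc)
})

test_that("pair signature methods expose coefficients, summary and predictions", {
  coh <- small_cohort()
  sig <- suppressMessages(
    fit_pair_signature(coh$pair_matrix, coh$clinical, n_repeats = 20,
                       min_count_fraction = 0.1, seed = 2))
  expect_s3_class(sig, "pair_signature")
  expect_named(coef(sig), sig$pair_ids)
  sm <- summary(sig)
  expect_true(all(sm$table$ci_lower <= sm$table$hr &
                  sm$table$hr <= sm$table$ci_upper))
  sc <- predict(sig, coh$pair_matrix)
  expect_equal(sc, risk_score(sig, coh$pair_matrix))
  grp <- predict(sig, coh$pair_matrix, type = "group", cutoff = median(sc))
  expect_s3_class(grp, "factor")
  expect_setequal(levels(grp), c("low", "high"))
  expect_output(print(sig), "Pair signature")
  expect_output(print(sm), "pairs")
})

test_that("risk scores inherit the pairing monotone-transform invariance", {
  coh <- small_cohort()
  de_genes <- c(coh$truth$de_up, coh$truth$de_down)
  tumor <- names(coh$sample_class)[coh$sample_class == "tumor"]
  ex <- coh$expression[de_genes, tumor]
  model <- list(pair_ids = coh$truth$true_pair_ids,
                beta = setNames(coh$truth$true_betas,
                                coh$truth$true_pair_ids))
  sc <- risk_score(model, build_pair_matrix(ex))
  expect_equal(risk_score(model, build_pair_matrix(ex^2)), sc)
  expect_equal(risk_score(model, build_pair_matrix(log2(ex + 1))), sc)
})
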