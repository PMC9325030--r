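# Shared fixtures, built in code at test time.

# quick clinical table
make_clin <- function(time, status, ids = NULL) {
  ids <- ids %||% paste0("s", seq_along(time))
  data.frame(sample_id = ids, futime = time, fustat = status,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# a small cohort reused across tests (memoised per session)
.small_cohort_env <- new.env()
small_cohort <- function() {
  if (is.null(.small_cohort_env$coh)) {
    cfg <- sim_config(n_tumor = 80, n_normal = 30, n_lnc = 100,
                      n_immune_genes = 30, n_de_up = 10, n_de_down = 4,
                      coexpr_block_size = 14, seed = 42)
    .small_cohort_env$coh <- simulate_cohort(cfg)
  }
  .small_cohort_env$coh
}

# naive O(n^2) Mann-Whitney AUC between case and control score sets
mw_auc <- function(case_scores, control_scores) {
  s <- 0
  for (a in case_scores) for (b in control_scores)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(case_scores) * length(control_scores))
}

# two-group exponential survival with rate ratio exp(beta) on x in {0,1}
sim_exp_surv <- function(n, beta, base_rate = 0.01, censor = FALSE,
                         seed = 1) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, base_rate * exp(beta * x))
  if (censor) {
    cc <- runif(n, 0, quantile(tt, 0.9) * 2)
    list(x = x, clin = make_clin(pmin(tt, cc), as.integer(tt <= cc)))
  } else {
    list(x = x, clin = make_clin(tt, rep(1L, n)))
  }
}
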