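test_that("sim_config validates fields by name", {
  expect_error(sim_config(n_tumor = 0), "n_tumor")
  expect_error(sim_config(censor_rate = 1.2), "censor_rate")
  expect_error(sim_config(n_de_up = 150, n_de_down = 100, n_lnc = 200),
               "n_de_up")
  expect_error(sim_config(coexpr_r = 0), "coexpr_r")
  expect_error(sim_config(true_betas = c(1, 2)), "true_betas")
  expect_error(sim_config(coexpr_block_size = 500), "coexpr_block_size")
})

test_that("expression generator is deterministic and non-negative", {
  cfg <- sim_config(n_tumor = 25, n_normal = 10, n_lnc = 40,
                    n_immune_genes = 12, coexpr_block_size = 8,
                    n_de_up = 4, n_de_down = 2, seed = 11)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a, b)
  expect_true(all(a$expr >= 0))
  expect_equal(dim(a$expr), c(52, 35))
  # different seed changes the matrix
  c2 <- simulate_expression(sim_config(n_tumor = 25, n_normal = 10,
                                       n_lnc = 40, n_immune_genes = 12,
                                       coexpr_block_size = 8, n_de_up = 4,
                                       n_de_down = 2, seed = 12))
  expect_false(identical(a$expr, c2$expr))
})

test_that("noiseless unit-correlation block gives Pearson r = 1 exactly", {
  cfg <- sim_config(n_tumor = 30, n_normal = 12, n_lnc = 20,
                    n_immune_genes = 6, coexpr_block_size = 4,
                    n_de_up = 0, n_de_down = 0, n_true_pairs = 0,
                    true_betas = numeric(0), coexpr_r = 1, noise_sd = 0,
                    seed = 5)
  ex <- simulate_expression(cfg)
  for (i in 1:4) {
    lnc <- log2(ex$expr[ex$genes$symbol[i], ] + 1)
    imm <- log2(ex$expr[ex$genes$partner[i], ] + 1)
    expect_equal(unname(cor(lnc, imm)), 1, tolerance = 1e-12)
  }
})

test_that("block correlation approximates the configured coexpr_r", {
  cfg <- sim_config(n_tumor = 400, n_normal = 100, n_lnc = 30,
                    n_immune_genes = 10, coexpr_block_size = 6,
                    n_de_up = 0, n_de_down = 0, n_true_pairs = 0,
                    true_betas = numeric(0), coexpr_r = 0.8, seed = 3)
  ex <- simulate_expression(cfg)
  rs <- vapply(1:6, function(i)
    cor(log2(ex$expr[ex$genes$symbol[i], ] + 1),
        log2(ex$expr[ex$genes$partner[i], ] + 1)), numeric(1))
  expect_true(all(abs(rs - 0.8) < 0.08))
})

test_that("planted DE lncRNAs carry the configured log2 shift", {
  cfg <- sim_config(n_tumor = 200, n_normal = 100, n_lnc = 50,
                    n_immune_genes = 15, coexpr_block_size = 10,
                    n_de_up = 5, n_de_down = 3, de_log2fc = 3,
                    n_true_pairs = 0, true_betas = numeric(0), seed = 8)
  ex <- simulate_expression(cfg)
  y <- log2(ex$expr + 1)
  tum <- ex$sample_class == "tumor"
  for (g in ex$genes$symbol[ex$genes$de == "up"])
    expect_equal(mean(y[g, tum]) - mean(y[g, !tum]), 3, tolerance = 0.5)
  for (g in ex$genes$symbol[ex$genes$de == "down"])
    expect_equal(mean(y[g, tum]) - mean(y[g, !tum]), -3, tolerance = 0.5)
})

test_that("survival generator honours censoring settings", {
  coh0 <- simulate_cohort(sim_config(n_tumor = 60, n_normal = 20,
                                     n_lnc = 60, n_immune_genes = 20,
                                     coexpr_block_size = 10, n_de_up = 6,
                                     n_de_down = 2, censor_rate = 0,
                                     seed = 21))
  expect_true(all(coh0$clinical$fustat == 1))
  expect_true(all(coh0$clinical$futime > 0))

  # censoring calibration within +/- 5 percentage points at n = 1000
  coh <- simulate_cohort(sim_config(n_tumor = 1000, n_normal = 20,
                                    n_lnc = 60, n_immune_genes = 20,
                                    coexpr_block_size = 10, n_de_up = 6,
                                    n_de_down = 2, censor_rate = 0.3,
                                    seed = 22))
  expect_lt(abs(mean(coh$clinical$fustat == 0) - 0.3), 0.05)
})

test_that("ground truth is stable, consistent and JSON round-trippable", {
  cfg <- sim_config(n_tumor = 50, n_normal = 20, n_lnc = 60,
                    n_immune_genes = 20, coexpr_block_size = 10,
                    n_de_up = 6, n_de_down = 2, seed = 33)
  coh <- simulate_cohort(cfg)
  truth <- coh$truth
  expect_identical(make_ground_truth(cfg), truth)
  expect_true(all(truth$true_pair_ids %in% rownames(coh$pair_matrix)))
  # linear predictor recomputes exactly from pairs and betas
  lp <- colSums(coh$pair_matrix[truth$true_pair_ids, , drop = FALSE] *
                  truth$true_betas)
  expect_equal(unname(truth$linear_predictor), unname(lp))

  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(truth, tmp, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$true_pair_ids, truth$true_pair_ids)
  expect_equal(back$true_betas, truth$true_betas)
  expect_equal(unname(unlist(back$linear_predictor)),
               unname(truth$linear_predictor))

  # no planted pairs -> zero linear predictor
  cfg0 <- sim_config(n_tumor = 30, n_normal = 10, n_lnc = 40,
                     n_immune_genes = 12, coexpr_block_size = 8,
                     n_de_up = 4, n_de_down = 2, n_true_pairs = 0,
                     true_betas = numeric(0), seed = 2)
  t0 <- make_ground_truth(cfg0)
  expect_length(t0$true_pair_ids, 0)
  expect_true(all(t0$linear_predictor == 0))
})

test_that("null expression design yields no DE calls at screen thresholds", {
  cfg <- sim_config(n_tumor = 40, n_normal = 40, n_lnc = 300,
                    n_immune_genes = 10, coexpr_block_size = 0,
                    n_de_up = 0, n_de_down = 0, n_true_pairs = 0,
                    true_betas = numeric(0), seed = 9)
  ex <- simulate_expression(cfg)
  lnc <- ex$expr[ex$genes$role == "lnc", ]
  de <- moderated_t_de(lnc, ex$sample_class)
  sel <- select_deirlncrna(de)
  expect_length(c(sel$up, sel$down), 0)
})

test_that("planted effects are recovered by the DE screen across seeds", {
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(n_tumor = 50, n_normal = 50, n_lnc = 60,
                      n_immune_genes = 10, coexpr_block_size = 0,
                      n_de_up = 5, n_de_down = 3, de_log2fc = 3,
                      noise_sd = 0.5, n_true_pairs = 0,
                      true_betas = numeric(0), seed = 100 + s)
    ex <- simulate_expression(cfg)
    lnc <- ex$expr[ex$genes$role == "lnc", ]
    sel <- select_deirlncrna(moderated_t_de(lnc, ex$sample_class))
    planted <- ex$genes$symbol[ex$genes$de != "none"]
    mean(planted %in% c(sel$up, sel$down))
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})
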