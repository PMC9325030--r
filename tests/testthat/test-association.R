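test_that("chi-square association applies Yates correction on 2x2 tables", {
  g <- rep(c("high", "low"), each = 10)
  f <- rep(c("a", "b"), each = 10)               # perfect association
  res <- chisq_association(g, f, variable = "demo")
  # hand oracle: all E = 5, statistic = 4 * (|10-5| - 0.5)^2 / 5 = 16.2
  expect_equal(res$statistic, 16.2, tolerance = 1e-12)
  expect_equal(res$df, 1)
  # perfectly balanced table: statistic 0, p = 1
  f2 <- rep(c("a", "b"), 10)
  res2 <- chisq_association(g, f2)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p, 1)
  # degenerate factor
  expect_error(chisq_association(g, rep("a", 20)), "levels")
})

test_that("rank-sum comparisons are exact for small tie-free samples", {
  sc <- c(1, 2, 3, 4, 5, 6)
  f <- rep(c("lo", "hi"), each = 3)
  res <- ranksum_by_factor(sc, f, variable = "demo")
  # enumeration oracle: most extreme of C(6,3)=20 arrangements, two-sided
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  expect_equal(res$direction, -1)   # "lo" level sorts after "hi" (levels)
  # identical multiset split across groups: exact p = 1
  res2 <- ranksum_by_factor(c(1, 2, 3, 1, 2, 3), f)
  expect_equal(res2$p, 1)
  # p decreases monotonically with the shift between groups
  set.seed(5)
  base <- rnorm(60)
  ps <- vapply(c(0.2, 0.6, 1.2, 2.0), function(d)
    ranksum_by_factor(c(base, base + d),
                      rep(c("a", "b"), each = 60))$p, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(ranksum_by_factor(1:3, rep("a", 3)), "levels")
})

test_that("multi-level factors use the configured binary contrast", {
  sc <- c(10, 11, 1, 2, 20, 21)
  grades <- c("G1", "G1", "G2", "G2", "G3", "G3")
  r_def <- ranksum_by_factor(sc, grades, variable = "grade")
  expect_match(r_def$contrast, "G1 vs G2/G3")
  r_cus <- ranksum_by_factor(sc, grades,
                             contrast = list(a = c("G1", "G2"), b = "G3"))
  expect_match(r_cus$contrast, "G1/G2 vs G3")
  expect_equal(r_cus$direction, 1)
})

test_that("forest table recovers a score-driven hazard and flags collinearity", {
  coh <- small_cohort()
  truth_lp <- coh$truth$linear_predictor
  for_tab <- suppressMessages(
    multivariable_forest(coh$clinical, truth_lp))
  multi <- for_tab[for_tab$analysis == "multivariate", ]
  rs <- multi[multi$term == "risk_score", ]
  expect_gt(rs$hr, 1)
  expect_gt(rs$ci_lower, 1)             # independent prognostic factor
  expect_true(all(for_tab$ci_lower <= for_tab$hr + 1e-12 &
                  for_tab$hr <= for_tab$ci_upper + 1e-12))
  expect_setequal(unique(for_tab$analysis), c("univariate", "multivariate"))
  # duplicated covariate is dropped from the joint fit with a message
  cl2 <- coh$clinical
  cl2$age2 <- cl2$age
  expect_message(
    multivariable_forest(cl2, truth_lp, covariates = c("age", "age2")),
    "collinear")
})

test_that("null covariate CIs cover 1 at roughly the nominal rate", {
  cover <- vapply(1:40, function(s) {
    set.seed(700 + s)
    n <- 120
    cl <- data.frame(sample_id = paste0("s", 1:n),
                     futime = rexp(n, 0.01), fustat = 1L,
                     age = round(rnorm(n, 60, 10)))
    sc <- setNames(rnorm(n), cl$sample_id)
    ft <- multivariable_forest(cl, sc, covariates = "age")
    m <- ft[ft$analysis == "multivariate" & ft$term == "age", ]
    m$ci_lower <= 1 && 1 <= m$ci_upper
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("Spearman infiltration correlations match the rank formula", {
  sc <- setNames(c(1, 2, 3), c("s1", "s2", "s3"))
  infil <- data.frame(sample = rep(c("s1", "s2", "s3"), 3),
                      cell_type = rep(c("selfcell", "permcell", "flatcell"),
                                      each = 3),
                      method = "toolA",
                      score = c(1, 2, 3,      # identical ranks: rho = 1
                                3, 1, 2,      # d^2 sum 6: rho = -0.5
                                5, 5, 5))     # constant: skipped
  res <- suppressMessages(spearman_infiltration(sc, infil))
  expect_equal(nrow(res), 2)
  expect_equal(res$rho[res$cell_type == "selfcell"], 1)
  # oracle: 1 - 6*sum(d^2)/(n(n^2-1)) = 1 - 36/24 = -0.5
  expect_equal(res$rho[res$cell_type == "permcell"], -0.5)
  expect_true(all(diff(res$rho) <= 0))     # sorted by decreasing rho
  # invariance under monotone transform of the score
  res2 <- suppressMessages(spearman_infiltration(exp(sc), infil))
  expect_equal(res2$rho, res$rho)
  # insufficient overlap
  expect_error(spearman_infiltration(sc[1:2],
                                     infil[infil$cell_type == "selfcell", ]),
               "overlapping")
})

test_that("per-column group comparisons rank and adjust sensibly", {
  set.seed(8)
  n <- 40
  grp <- setNames(rep(c("high", "low"), each = n / 2), paste0("s", 1:n))
  vals <- cbind(identical = rep(1:4, n / 4),
                score_like = ifelse(grp == "high", 1, 0) + rnorm(n, 0, 0.01),
                noise = rnorm(n))
  rownames(vals) <- names(grp)
  res <- group_compare_table(vals, grp)
  expect_equal(res$p[res$variable == "identical"], 1, tolerance = 1e-9)
  expect_equal(which.min(res$p), match("score_like", res$variable))
  expect_equal(res$direction[res$variable == "score_like"], 1)
  expect_equal(res$p_adj, p.adjust(res$p, "BH"))
  # 3v3 fixture against exact enumeration: p = 2/20
  vals2 <- matrix(c(1, 2, 3, 4, 5, 6), 6, 1,
                  dimnames = list(paste0("t", 1:6), "v"))
  grp2 <- setNames(rep(c("low", "high"), each = 3), rownames(vals2))
  expect_equal(group_compare_table(vals2, grp2)$p, 0.1, tolerance = 1e-12)
  expect_error(group_compare_table(vals2, setNames(rep("high", 6),
                                                   rownames(vals2))),
               "both risk groups")
})

test_that("association tests are invariant to sample order", {
  set.seed(13)
  n <- 50
  grp <- rep(c("high", "low"), each = n / 2)
  f <- sample(c("a", "b"), n, replace = TRUE)
  sc <- rnorm(n)
  perm <- sample(n)
  expect_equal(chisq_association(grp, f)$statistic,
               chisq_association(grp[perm], f[perm])$statistic)
  expect_equal(ranksum_by_factor(sc, grp)$p,
               ranksum_by_factor(sc[perm], grp[perm])$p)
})
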