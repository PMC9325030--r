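# Downstream association statistics: risk group vs clinical factors, Cox
# forest tables, immune-infiltration correlation, and per-column group
# comparisons (checkpoint genes, drug IC50).

#' Chi-square association between risk group and a categorical factor
#'
#' Pearson chi-square on the groups x factor contingency table; Yates
#' continuity correction is applied for 2x2 tables.  Pairs with a missing
#' factor value are dropped.
#'
#' @param groups group labels per sample (e.g. the `group` column of a
#'   [assign_risk_groups()] profile).
#' @param factor_values categorical variable aligned to `groups`.
#' @param variable variable name for the output row.
#' @return one-row data.frame: `variable`, `test`, `statistic`, `df`, `p`,
#'   `n`.
#' @export
chisq_association <- function(groups, factor_values, variable = "factor") {
  keep <- !is.na(groups) & !is.na(factor_values)
  g <- droplevels(factor(groups[keep]))
  f <- droplevels(factor(factor_values[keep]))
  if (nlevels(g) < 2 || nlevels(f) < 2)
    stop_stage("association",
               "chi-square needs >= 2 levels per variable ('%s')", variable)
  tab <- table(g, f)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  data.frame(variable = variable, test = "chi_square",
             statistic = unname(ct$statistic), df = unname(ct$parameter),
             p = ct$p.value, n = sum(tab), stringsAsFactors = FALSE)
}

# Choose exact vs normal-approximation rank-sum p the way the spec'd
# two-sample comparisons are reported: exact when small and tie-free.
.ranksum <- function(a, b) {
  exact <- (length(a) + length(b) <= 20) && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Rank-sum comparison of risk scores across a clinical factor
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test of the scores between two
#' factor levels (or a binary contrast of a multi-level factor).  The exact
#' distribution is used when the combined n is at most 20 and tie-free,
#' otherwise the normal approximation with tie correction.
#'
#' @param scores numeric per-sample values (risk scores).
#' @param factor_values categorical variable aligned to `scores`.
#' @param contrast for factors with more than 2 levels: a list
#'   `list(a = levels, b = levels)` defining the binary contrast.  Default:
#'   first half of the sorted levels vs the rest (e.g. G1-G2 vs G3-G4).
#' @param variable variable name for the output row.
#' @return one-row data.frame: `variable`, `contrast`, `test`, `statistic`
#'   (Mann-Whitney W), `p`, `direction` (sign of median difference, b minus
#'   a), `n_a`, `n_b`.
#' @export
ranksum_by_factor <- function(scores, factor_values, contrast = NULL,
                              variable = "factor") {
  keep <- !is.na(scores) & !is.na(factor_values)
  s <- scores[keep]
  f <- droplevels(factor(factor_values[keep]))
  lev <- levels(f)
  if (length(lev) < 2)
    stop_stage("association", "rank-sum needs >= 2 levels ('%s')", variable)
  if (is.null(contrast)) {
    k <- length(lev)
    contrast <- list(a = lev[seq_len(floor(k / 2))],
                     b = lev[(floor(k / 2) + 1):k])
  }
  a <- s[f %in% contrast$a]; b <- s[f %in% contrast$b]
  if (length(a) == 0 || length(b) == 0)
    stop_stage("association", "empty contrast level for '%s'", variable)
  rs <- .ranksum(a, b)
  data.frame(variable = variable,
             contrast = paste(paste(contrast$a, collapse = "/"), "vs",
                              paste(contrast$b, collapse = "/")),
             test = "wilcoxon_rank_sum", statistic = rs$statistic,
             p = rs$p, direction = sign(median(b) - median(a)),
             n_a = length(a), n_b = length(b), stringsAsFactors = FALSE)
}

# Ordinal coding of TCGA-style clinical categories; unknown codes (GX, MX,
# blank) become NA.
encode_ordinal <- function(x, prefix) {
  v <- toupper(trimws(as.character(x)))
  v[v %in% c("", "GX", "TX", "NX", "MX", "NA", "UNKNOWN")] <- NA
  if (prefix == "stage") {
    roman <- c("I" = 1, "II" = 2, "III" = 3, "IV" = 4)
    v <- sub("^STAGE\\s*", "", v)
    return(unname(roman[v]))
  }
  as.numeric(sub(paste0("^", toupper(prefix)), "", v))
}

#' Univariate and multivariate Cox forest table
#'
#' Fits one univariate Cox model per covariate plus one joint multivariate
#' model of the risk score and the clinical covariates.  Grade, stage and
#' T/N/M are ordinal-coded (G1-G4, I-IV, T1-T4, N0/N1, M0/M1 as numbers;
#' GX/MX/blank as missing); age and the risk score enter as continuous.
#' Covariates that are constant or collinear in the joint fit are dropped
#' with a message.
#'
#' @param clinical clinical table with `sample_id`, `futime`, `fustat` and
#'   covariate columns.
#' @param scores named per-sample risk scores.
#' @param covariates clinical columns to include (default: those of `age`,
#'   `grade`, `stage` present).
#' @return data.frame of class `"forest_table"`: `term`, `analysis`
#'   (`univariate`/`multivariate`), `hr`, `ci_lower`, `ci_upper`, `p`.
#' @export
multivariable_forest <- function(clinical, scores,
                                 covariates = intersect(
                                   c("age", "grade", "stage"),
                                   names(clinical))) {
  cl <- clinical[clinical$sample_id %in% names(scores), , drop = FALSE]
  X <- data.frame(risk_score = unname(scores[cl$sample_id]))
  for (cv in covariates) {
    X[[cv]] <- switch(cv,
      age = as.numeric(cl$age),
      grade = encode_ordinal(cl$grade, "G"),
      stage = encode_ordinal(cl$stage, "stage"),
      T = encode_ordinal(cl$T, "T"),
      N = encode_ordinal(cl$N, "N"),
      M = encode_ordinal(cl$M, "M"),
      as.numeric(cl[[cv]]))
  }
  ok <- complete.cases(X)
  cl <- cl[ok, , drop = FALSE]; X <- X[ok, , drop = FALSE]

  one_rows <- function(fit, terms, analysis) {
    data.frame(term = terms, analysis = analysis,
               hr = fit$hr[terms], ci_lower = fit$ci_lower[terms],
               ci_upper = fit$ci_upper[terms], p = fit$p[terms],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  uni <- do.call(rbind, lapply(names(X), function(tm) {
    fit <- fit_cox(setNames(data.frame(X[[tm]]), tm), cl)
    one_rows(fit, tm, "univariate")
  }))

  # joint fit; drop constant/collinear covariates flagged by NA coefficients
  keep <- names(X)[vapply(X, function(v) stats::sd(v) > 0, logical(1))]
  if (length(keep) < ncol(X))
    message("multivariable_forest: dropped constant covariate(s): ",
            paste(setdiff(names(X), keep), collapse = ", "))
  fit <- fit_cox(X[, keep, drop = FALSE], cl)
  if (anyNA(fit$coefficients)) {
    bad <- names(fit$coefficients)[is.na(fit$coefficients)]
    message("multivariable_forest: dropped collinear covariate(s): ",
            paste(bad, collapse = ", "))
    keep <- setdiff(keep, bad)
    fit <- fit_cox(X[, keep, drop = FALSE], cl)
  }
  multi <- one_rows(fit, keep, "multivariate")
  out <- rbind(uni, multi)
  class(out) <- c("forest_table", "data.frame")
  out
}

#' Spearman correlation of risk score with immune-infiltration estimates
#'
#' One Spearman correlation per (cell type, method) row of a long-format
#' infiltration table, with average ranks for ties and a two-sided p from
#' the t transform; rows are returned sorted by decreasing rho.  Rows with a
#' constant infiltration score are skipped with a message.
#'
#' @param scores named per-sample risk scores.
#' @param infiltration long data.frame with columns `sample`, `cell_type`,
#'   `method`, `score` (per-sample infiltration estimate).
#' @return data.frame: `cell_type`, `method`, `rho`, `p`, `n`.
#' @export
spearman_infiltration <- function(scores, infiltration) {
  req <- c("sample", "cell_type", "method", "score")
  if (!all(req %in% names(infiltration)))
    stop_stage("association", "infiltration table needs columns: %s",
               paste(req, collapse = ", "))
  keys <- unique(infiltration[, c("cell_type", "method")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- infiltration[infiltration$cell_type == keys$cell_type[i] &
                        infiltration$method == keys$method[i], ]
    common <- intersect(names(scores), sub$sample)
    if (length(common) < 3)
      stop_stage("association",
                 "fewer than 3 overlapping samples for %s (%s)",
                 keys$cell_type[i], keys$method[i])
    y <- sub$score[match(common, sub$sample)]
    if (stats::sd(y) == 0) {
      message("spearman_infiltration: skipped constant row ",
              keys$cell_type[i], " (", keys$method[i], ")")
      return(NULL)
    }
    ct <- suppressWarnings(
      stats::cor.test(scores[common], y, method = "spearman",
                      exact = FALSE))
    data.frame(cell_type = keys$cell_type[i], method = keys$method[i],
               rho = unname(ct$estimate), p = ct$p.value,
               n = length(common), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out[order(-out$rho), , drop = FALSE]
}

#' Per-column rank-sum comparison between risk groups
#'
#' For a samples x variables table (immune-checkpoint gene expression, drug
#' IC50, ...), tests each column between the high- and low-risk groups with
#' the two-sided Mann-Whitney rank-sum test, reports the direction as the
#' sign of the high-minus-low median difference, and adjusts p-values across
#' columns by Benjamini-Hochberg.
#'
#' @param values numeric matrix or data.frame, samples (rownames) x
#'   variables.
#' @param groups named `"low"`/`"high"` labels (e.g. from
#'   [assign_risk_groups()]).
#' @return data.frame: `variable`, `statistic`, `p`, `p_adj`, `direction`,
#'   `n_high`, `n_low`.
#' @export
group_compare_table <- function(values, groups) {
  values <- as.matrix(values)
  common <- intersect(rownames(values), names(groups))
  if (length(common) == 0)
    stop_stage("association", "no overlap between values and groups")
  g <- groups[common]
  if (!all(c("low", "high") %in% g))
    stop_stage("association", "both risk groups must be present")
  hi <- common[g == "high"]; lo <- common[g == "low"]
  rows <- lapply(colnames(values), function(v) {
    rs <- .ranksum(values[hi, v], values[lo, v])
    data.frame(variable = v, statistic = rs$statistic, p = rs$p,
               direction = sign(median(values[hi, v]) - median(values[lo, v])),
               n_high = length(hi), n_low = length(lo),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out[, c("variable", "statistic", "p", "p_adj", "direction",
          "n_high", "n_low")]
}
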