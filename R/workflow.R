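# End-to-end pipeline: ingest -> immune screen -> DE -> pairing -> signature
# selection -> risk stratification -> association statistics.

#' Pipeline configuration
#'
#' Collects input paths and every analysis threshold, with defaults equal to
#' the published screening rules: co-expression r > 0.7 at p < 0.001, DE at
#' |log2 FC| > 2 and FDR < 0.001, pair validity band (0.2, 0.8), univariate
#' Cox p < 0.05, 1000 LASSO cycles with 10 folds and a 10% selection-
#' frequency threshold, ROC horizons 1, 3 and 5 years with the cut-point on
#' the 5-year curve.
#'
#' @param file optional YAML file with any of the settings; values in `...`
#'   override it.
#' @param ... named overrides, e.g. `n_repeats = 100`,
#'   `paths = list(expression = "expr.tsv", ...)`.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(file = NULL, ...) {
  cfg <- list(
    paths = list(expression = NULL, gtf = NULL, immune = NULL,
                 clinical = NULL, sample_class = NULL,
                 infiltration = NULL, ic50 = NULL),
    r_min = 0.7, p_max = 0.001,
    lfc_min = 2.0, fdr_max = 0.001,
    valid_low = 0.2, valid_high = 0.8,
    uni_p = 0.05,
    n_repeats = 1000, folds = 10, min_count_fraction = 0.1,
    nlambda = 50, lambda_rule = "min", search = "greedy",
    horizons_years = c(1, 3, 5), cutpoint_horizon_years = 5,
    days_per_year = 365,
    seed = 1, outdir = NULL)
  if (!is.null(file)) {
    over <- yaml::read_yaml(file)
    cfg <- modifyList(cfg, over)
  }
  dots <- list(...)
  if (length(dots) > 0) cfg <- modifyList(cfg, dots)
  for (f in c("r_min", "p_max", "lfc_min", "fdr_max", "uni_p",
              "min_count_fraction"))
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L)
      stop_stage("config", "'%s' must be a single number", f)
  if (!(cfg$valid_low < cfg$valid_high))
    stop_stage("config", "validity band must satisfy valid_low < valid_high")
  if (any(cfg$horizons_years <= 0) || cfg$cutpoint_horizon_years <= 0)
    stop_stage("config", "horizons must be > 0")
  structure(cfg, class = "pipeline_config")
}

load_pipeline_inputs <- function(config, data = NULL) {
  if (inherits(data, "sim_cohort")) {
    return(list(expr = data$expression,
                annotation = data$genes[, c("gene_id", "symbol", "biotype")],
                immune_symbols = data$immune_symbols,
                sample_class = data$sample_class,
                clinical = clean_clinical(data$clinical)))
  }
  if (!is.null(data)) {
    need <- c("expr", "annotation", "immune_symbols", "clinical")
    miss <- setdiff(need, names(data))
    if (length(miss) > 0)
      stop_stage("ingest", "in-memory data lacks: %s",
                 paste(miss, collapse = ", "))
    data$sample_class <- data$sample_class %||%
      classify_samples(colnames(data$expr))
    data$clinical <- clean_clinical(data$clinical)
    return(data)
  }
  p <- config$paths
  for (f in c("expression", "gtf", "immune", "clinical"))
    if (is.null(p[[f]]))
      stop_stage("ingest", "config path '%s' is not set", f)
  expr <- read_expression_matrix(p$expression)
  list(expr = expr,
       annotation = read_gene_annotation(p$gtf),
       immune_symbols = read_gene_list(p$immune),
       sample_class = classify_samples(colnames(expr),
                                       class = p$sample_class),
       clinical = read_clinical(p$clinical))
}

#' Run the full pair-signature pipeline
#'
#' Executes the complete analysis from a [pipeline_config()]: ingest and
#' validation, biotype partition, immune co-expression screen, moderated-t
#' differential expression, pair matrix construction and validity filtering,
#' signature selection ([fit_pair_signature()]), risk scoring with the
#' AIC cut-point on the 5-year ROC, Kaplan-Meier / log-rank risk-group
#' comparison, chi-square and rank-sum clinical associations and the
#' univariate/multivariate Cox forest, plus optional immune-infiltration and
#' drug-IC50 associations when those tables are supplied.  All randomness
#' derives from `config$seed`.  Any stage failure aborts with the stage name
#' in the error message.
#'
#' @param config a [pipeline_config()].
#' @param data optional in-memory inputs instead of files: a
#'   [simulate_cohort()] result, or a list with `expr`, `annotation`,
#'   `immune_symbols`, `clinical` (and optionally `sample_class`,
#'   `infiltration`, `ic50`).
#' @param quiet suppress progress messages.
#' @return object of class `"irlnc_pipeline"`: `manifest` (stage counts and
#'   settings), `screen` (co-expression + DE results), `pair_matrix`,
#'   `signature`, `risk` (scores, cut-point, groups), `roc` (per horizon),
#'   `km`, `logrank`, `associations`.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("run_pipeline: ", ...)
  msg_wrap <- function(expr) if (quiet) suppressMessages(expr) else expr

  ## ingest -----------------------------------------------------------------
  inp <- msg_wrap(load_pipeline_inputs(config, data))
  expr <- inp$expr
  sample_class <- inp$sample_class[colnames(expr)]
  if (anyNA(sample_class))
    stop_stage("ingest", "sample classes missing for some expression columns")
  parts <- msg_wrap(partition_by_biotype(expr, inp$annotation))
  immune_expr <- parts$coding[rownames(parts$coding) %in% inp$immune_symbols,
                              , drop = FALSE]
  if (nrow(immune_expr) == 0)
    stop_stage("ingest", "no immune genes found in the expression matrix")
  clinical <- inp$clinical
  tumor <- names(sample_class)[sample_class == "tumor"]
  model_samples <- intersect(tumor, clinical$sample_id)
  if (length(model_samples) == 0)
    stop_stage("ingest", "no tumour samples with clinical data")
  clinical <- clinical[match(model_samples, clinical$sample_id), ,
                       drop = FALSE]
  say(length(tumor), " tumour / ", sum(sample_class == "normal"),
      " normal samples; ", length(model_samples), " with clinical data")

  ## immune screen + DE -----------------------------------------------------
  co <- coexpression_filter(parts$lnc, immune_expr,
                            r_min = config$r_min, p_max = config$p_max)
  say(length(co$ids), " immune-related lncRNAs (r > ", config$r_min,
      ", p < ", config$p_max, ")")
  if (length(co$ids) == 0)
    stop_stage("screen", "0 immune-related lncRNAs")
  de <- moderated_t_de(parts$lnc[co$ids, , drop = FALSE], sample_class)
  sel <- select_deirlncrna(de, lfc_min = config$lfc_min,
                           fdr_max = config$fdr_max)
  de_genes <- c(sel$up, sel$down)
  say(length(de_genes), " DEirlncRNAs (", length(sel$up), " up, ",
      length(sel$down), " down)")
  if (length(de_genes) == 0)
    stop_stage("screen", "0 DEirlncRNAs at |logFC| > %s, FDR < %s",
               config$lfc_min, config$fdr_max)
  if (length(de_genes) < 2)
    stop_stage("pairing", "fewer than 2 DEirlncRNAs; cannot build pairs")

  ## pairing ----------------------------------------------------------------
  pm_all <- build_pair_matrix(expr[de_genes, model_samples, drop = FALSE])
  pm <- msg_wrap(filter_valid_pairs(pm_all, low = config$valid_low,
                                    high = config$valid_high))
  say(nrow(pm), " of ", nrow(pm_all), " pairs in the validity band (",
      config$valid_low, ", ", config$valid_high, ")")
  if (nrow(pm) == 0)
    stop_stage("pairing", "no valid pairs after filtering")

  ## signature --------------------------------------------------------------
  horizon <- config$cutpoint_horizon_years * config$days_per_year
  sig <- msg_wrap(fit_pair_signature(
    pm, clinical, uni_p = config$uni_p, n_repeats = config$n_repeats,
    folds = config$folds, min_count_fraction = config$min_count_fraction,
    horizon = horizon, search = config$search, seed = config$seed,
    nlambda = config$nlambda, lambda_rule = config$lambda_rule))
  say("signature: ", length(sig$pair_ids), " pairs, ",
      config$cutpoint_horizon_years, "-year AUC = ", round(sig$auc, 3))

  ## risk stratification ----------------------------------------------------
  scores <- risk_score(sig, pm)
  roc <- lapply(config$horizons_years, function(h)
    td_roc_auc(scores, clinical, h * config$days_per_year))
  names(roc) <- paste0("year", config$horizons_years)
  cut <- aic_cutoff(scores, clinical, t = horizon)
  risk <- assign_risk_groups(scores, cut)
  grp <- setNames(as.character(risk$group), risk$sample_id)
  km <- lapply(split(clinical, grp[clinical$sample_id]), km_curve)
  lr <- logrank_test(clinical, grp)
  say("cut-point ", round(cut$cutoff, 4), ": ",
      sum(risk$group == "high"), " high / ", sum(risk$group == "low"),
      " low; log-rank p = ", format.pval(lr$p, digits = 3))

  ## associations -----------------------------------------------------------
  assoc <- list()
  cat_vars <- intersect(c("gender", "grade", "stage", "T", "N", "M"),
                        names(clinical))
  if (length(cat_vars) > 0) {
    assoc$chisq <- do.call(rbind, lapply(cat_vars, function(v)
      chisq_association(grp[clinical$sample_id], clinical[[v]], variable = v)))
    assoc$ranksum <- do.call(rbind, lapply(cat_vars, function(v)
      ranksum_by_factor(scores[clinical$sample_id], clinical[[v]],
                        variable = v)))
  }
  assoc$forest <- msg_wrap(multivariable_forest(clinical, scores))
  infil <- if (!is.null(data) && !is.null(data$infiltration)) data$infiltration
           else if (!is.null(config$paths$infiltration))
             read.delim(config$paths$infiltration, stringsAsFactors = FALSE)
           else NULL
  if (!is.null(infil))
    assoc$infiltration <- msg_wrap(spearman_infiltration(scores, infil))
  ic50 <- if (!is.null(data) && !is.null(data$ic50)) data$ic50
          else if (!is.null(config$paths$ic50))
            read.delim(config$paths$ic50, row.names = 1,
                       check.names = FALSE, stringsAsFactors = FALSE)
          else NULL
  if (!is.null(ic50))
    assoc$ic50 <- group_compare_table(ic50, grp)

  manifest <- list(
    seed = config$seed,
    thresholds = config[setdiff(names(config), c("paths", "outdir"))],
    counts = c(n_samples_tumor = length(tumor),
               n_samples_normal = sum(sample_class == "normal"),
               n_samples_model = length(model_samples),
               n_lnc = nrow(parts$lnc),
               n_immune_genes = nrow(immune_expr),
               n_irlnc = length(co$ids),
               n_deirlnc = length(de_genes),
               n_de_up = length(sel$up), n_de_down = length(sel$down),
               n_pairs_candidate = nrow(pm_all),
               n_pairs_valid = nrow(pm),
               n_univariate = sig$selection$n_univariate,
               n_freq_selected = length(sig$selection$lasso$selected),
               n_signature = length(sig$pair_ids),
               n_high = sum(risk$group == "high"),
               n_low = sum(risk$group == "low")))

  out <- structure(list(manifest = manifest,
                        screen = list(irlnc_ids = co$ids, de = sel$table,
                                      up = sel$up, down = sel$down),
                        pair_matrix = pm, signature = sig,
                        risk = risk, cutoff = cut, roc = roc,
                        km = km, logrank = lr,
                        associations = assoc, clinical = clinical),
                   class = "irlnc_pipeline")
  if (!is.null(config$outdir)) write_pipeline_outputs(out, config$outdir)
  out
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) write.table(x, file.path(outdir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(res$screen$de, "de_table.tsv")
  wt(pair_meta(res$pair_matrix), "pair_meta.tsv")
  wt(data.frame(pair_id = names(res$signature$selection$lasso$counts),
                count = res$signature$selection$lasso$counts),
     "selection_frequency.tsv")
  wt(as.data.frame(res$risk), "risk_profile.tsv")
  roc5 <- res$roc[[length(res$roc)]]
  wt(data.frame(threshold = roc5$thresholds, sens = roc5$sens,
                spec = roc5$spec), "roc_table.tsv")
  wt(res$associations$forest, "forest.tsv")
  jsonlite::write_json(
    list(pair_ids = res$signature$pair_ids,
         beta = as.list(res$signature$beta),
         auc = res$signature$auc, horizon = res$signature$horizon,
         cutoff = res$cutoff$cutoff,
         manifest = res$manifest),
    file.path(outdir, "signature.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.irlnc_pipeline <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("Immune-related lncRNA pair signature pipeline\n")
  cat(sprintf("  samples: %d tumour / %d normal (%d modelled)\n",
              cnt[["n_samples_tumor"]], cnt[["n_samples_normal"]],
              cnt[["n_samples_model"]]))
  cat(sprintf("  funnel: %d lncRNAs -> %d immune-related -> %d DE -> %d valid pairs\n",
              cnt[["n_lnc"]], cnt[["n_irlnc"]], cnt[["n_deirlnc"]],
              cnt[["n_pairs_valid"]]))
  cat(sprintf("          -> %d univariate -> %d frequency-selected -> %d in signature\n",
              cnt[["n_univariate"]], cnt[["n_freq_selected"]],
              cnt[["n_signature"]]))
  cat(sprintf("  risk groups: %d high / %d low at cut-point %.4f; log-rank p = %s\n",
              cnt[["n_high"]], cnt[["n_low"]], x$cutoff$cutoff,
              format.pval(x$logrank$p, digits = 3)))
  cat(sprintf("  AUC: %s\n",
              paste(sprintf("%s = %.3f", names(x$roc),
                            vapply(x$roc, `[[`, 0, "auc")), collapse = ", ")))
  invisible(x)
}
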