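#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of the synthetic tumour/normal cohort:
#' group sizes, number of lncRNAs and immune genes, the differential
#' expression design, the immune co-expression block, the planted prognostic
#' pair effects, the survival model and the censoring level.
#'
#' The defaults describe the cohort regime the package's own tests and
#' examples run on: 150 tumour / 50 normal samples, 200 lncRNAs of which a
#' 30-gene block is co-expressed with immune genes at Pearson r = 0.8 on the
#' log2 scale, 18 up- and 6 down-regulated lncRNAs at |log2 FC| = 3, three
#' planted prognostic pairs with log-hazard ratios 0.8 / 1.0 / 1.2 on an
#' exponential baseline of 1.5e-4 events/day (median survival about 12.7
#' years for a zero linear predictor, so a realistic fraction of patients
#' remains event-free past five years), and 30% uniform censoring.
#'
#' @param n_tumor,n_normal tumour and normal sample counts.
#' @param n_lnc,n_immune_genes number of lncRNAs and immune genes.
#' @param n_de_up,n_de_down number of lncRNAs up-/down-regulated in tumour.
#' @param de_log2fc planted tumour-vs-normal difference, log2 units.
#' @param n_true_pairs number of planted prognostic pair indicators.
#' @param true_betas log-hazard coefficient per planted pair
#'   (length `n_true_pairs`).
#' @param baseline_hazard exponential baseline hazard, events per day.
#' @param censor_rate target expected censored fraction, in \[0, 1\].
#' @param coexpr_block_size number of lncRNAs sharing a latent factor with an
#'   immune gene (at most `min(n_lnc, n_immune_genes)`).
#' @param coexpr_r target Pearson correlation, on log2(x+1), between each
#'   block lncRNA and its immune partner; in (0, 1\].
#' @param noise_sd per-gene log2-scale noise standard deviation for genes
#'   outside the co-expression block.
#' @param seed integer seed; all generator randomness derives from it.
#' @return A validated list of class `"sim_config"`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_tumor = 150, n_normal = 50,
                       n_lnc = 200, n_immune_genes = 60,
                       n_de_up = 18, n_de_down = 6, de_log2fc = 3,
                       n_true_pairs = 3, true_betas = c(0.8, 1.0, 1.2),
                       baseline_hazard = 1.5e-4, censor_rate = 0.3,
                       coexpr_block_size = 30, coexpr_r = 0.8,
                       noise_sd = 0.5, seed = 1) {
  cfg <- list(n_tumor = n_tumor, n_normal = n_normal, n_lnc = n_lnc,
              n_immune_genes = n_immune_genes, n_de_up = n_de_up,
              n_de_down = n_de_down, de_log2fc = de_log2fc,
              n_true_pairs = n_true_pairs, true_betas = true_betas,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              coexpr_block_size = coexpr_block_size, coexpr_r = coexpr_r,
              noise_sd = noise_sd, seed = seed)

  chk_count <- function(field, min = 0) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < min ||
        v != round(v))
      stop(sprintf("sim_config: '%s' must be an integer >= %d", field, min),
           call. = FALSE)
  }
  for (f in c("n_tumor", "n_normal")) chk_count(f, min = 1)
  for (f in c("n_lnc", "n_immune_genes", "n_de_up", "n_de_down",
              "n_true_pairs", "coexpr_block_size")) chk_count(f)
  if (n_de_up + n_de_down > n_lnc)
    stop("sim_config: 'n_de_up' + 'n_de_down' exceeds 'n_lnc'", call. = FALSE)
  if (coexpr_block_size > min(n_lnc, n_immune_genes))
    stop("sim_config: 'coexpr_block_size' exceeds min(n_lnc, n_immune_genes)",
         call. = FALSE)
  if (!is.numeric(true_betas) || length(true_betas) != n_true_pairs)
    stop("sim_config: 'true_betas' must have length 'n_true_pairs'",
         call. = FALSE)
  if (!is.numeric(censor_rate) || censor_rate < 0 || censor_rate > 1)
    stop("sim_config: 'censor_rate' must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(coexpr_r) || coexpr_r <= 0 || coexpr_r > 1)
    stop("sim_config: 'coexpr_r' must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(baseline_hazard) || baseline_hazard <= 0)
    stop("sim_config: 'baseline_hazard' must be > 0", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("sim_config: 'noise_sd' must be >= 0", call. = FALSE)
  if (!is.numeric(de_log2fc) || de_log2fc < 0)
    stop("sim_config: 'de_log2fc' must be >= 0", call. = FALSE)
  chk_count("seed")
  structure(cfg, class = "sim_config")
}

#' Simulate a tumour/normal expression matrix with planted structure
#'
#' Generates FPKM-like abundances on a latent log2 scale: every gene is
#' log-normal, a designated block of lncRNAs shares a standard-normal latent
#' factor with one immune gene each (giving Pearson correlation
#' `coexpr_r` on log2(x+1) by construction), and the planted differentially
#' expressed lncRNAs (together with their immune partners, mimicking immune
#' activation in tumours) receive a +/- `de_log2fc` mean shift in tumour
#' samples.  Abundances are `2^z - 1` truncated at zero, so `log2(x + 1)`
#' recovers the latent scale exactly wherever `z >= 0`.
#'
#' Sample names follow the TCGA barcode convention (`-01A` tumour, `-11A`
#' normal) so that [classify_samples()] works on simulated data unchanged.
#'
#' @param config a [sim_config()].
#' @return list with components
#'   \item{expr}{numeric matrix, genes (symbols) x samples;}
#'   \item{genes}{data.frame with `gene_id`, `symbol`, `biotype`, `role`
#'     (`"lnc"`/`"immune"`), `de` (`"up"`/`"down"`/`"none"`) and `partner`
#'     (immune partner symbol, or `NA`);}
#'   \item{sample_class}{named character vector, `"tumor"`/`"normal"`.}
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, "expression"))
  n_s <- config$n_tumor + config$n_normal
  tumor <- sprintf("TCGA-SY-%04d-01A", seq_len(config$n_tumor))
  normal <- sprintf("TCGA-SY-%04d-11A", config$n_tumor + seq_len(config$n_normal))
  samples <- c(tumor, normal)
  is_tumor <- c(rep(TRUE, config$n_tumor), rep(FALSE, config$n_normal))

  lnc_sym <- sprintf("LNC%04d", seq_len(config$n_lnc))
  imm_sym <- sprintf("IMM%03d", seq_len(config$n_immune_genes))
  syms <- c(lnc_sym, imm_sym)
  genes <- data.frame(
    gene_id = sprintf("ENSGS%08d", seq_along(syms)),
    symbol = syms,
    biotype = c(rep("lncRNA", config$n_lnc),
                rep("protein_coding", config$n_immune_genes)),
    role = c(rep("lnc", config$n_lnc), rep("immune", config$n_immune_genes)),
    de = "none", partner = NA_character_,
    stringsAsFactors = FALSE
  )

  B <- config$coexpr_block_size
  n_de <- config$n_de_up + config$n_de_down
  # DE genes sit inside the co-expression block first (so they survive the
  # immune screen), spilling over to unlinked lncRNAs only if the block is
  # too small.
  de_idx <- seq_len(n_de)
  if (config$n_de_up > 0)
    genes$de[de_idx[seq_len(config$n_de_up)]] <- "up"
  if (config$n_de_down > 0)
    genes$de[de_idx[config$n_de_up + seq_len(config$n_de_down)]] <- "down"
  if (B > 0)
    genes$partner[seq_len(B)] <- imm_sym[seq_len(B)]

  # baseline log2 means; DE genes get means clear of the zero floor so the
  # tumour-side shift stays on the exactly-recoverable part of the scale
  mu <- runif(length(syms), 2, 8)
  if (n_de > 0)
    mu[de_idx] <- runif(n_de, config$de_log2fc + 2, config$de_log2fc + 6)

  z <- matrix(0, nrow = length(syms), ncol = n_s,
              dimnames = list(syms, samples))
  r <- config$coexpr_r
  for (g in seq_along(syms)) {
    if (g <= B) next           # filled below together with the partner
    z[g, ] <- mu[g] + config$noise_sd * rnorm(n_s)
  }
  if (B > 0) {
    for (i in seq_len(B)) {
      f <- rnorm(n_s)
      imm_row <- config$n_lnc + i
      z[imm_row, ] <- mu[imm_row] + f
      z[i, ] <- mu[i] + r * f + sqrt(1 - r^2) * rnorm(n_s)
    }
  }
  # tumour-vs-normal shifts (lncRNA and, when linked, its immune partner)
  if (n_de > 0) {
    for (g in de_idx) {
      shift <- if (genes$de[g] == "up") config$de_log2fc else -config$de_log2fc
      z[g, is_tumor] <- z[g, is_tumor] + shift
      if (!is.na(genes$partner[g]))
        z[genes$partner[g], is_tumor] <- z[genes$partner[g], is_tumor] + shift
    }
  }

  expr <- pmax(2^z - 1, 0)
  sample_class <- setNames(ifelse(is_tumor, "tumor", "normal"), samples)
  list(expr = expr, genes = genes, sample_class = sample_class)
}

#' Simulate survival driven by planted pair indicators
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(sum(beta_j * S_j))`, where `S_j` are the planted
#' pair indicators.  Censoring is independent uniform on `[0, c]`, with `c`
#' solved numerically so the expected censored fraction equals
#' `censor_rate`; `censor_rate = 0` disables censoring.  Times are rounded up
#' to whole days, so follow-up is always at least one day.  Clinical
#' covariates (age, gender, grade, stage, T/N/M) are generated with grade and
#' stage weakly tied to the true linear predictor.
#'
#' @param pairs binary pair indicator matrix (pairs x samples) containing all
#'   planted pairs; see [build_pair_matrix()].
#' @param truth ground-truth record from [make_ground_truth()] /
#'   [simulate_cohort()].
#' @param config the [sim_config()] used to generate `truth`.
#' @return A clinical `data.frame` with `sample_id`, `futime` (days),
#'   `fustat` (1 = event), `age`, `gender`, `grade`, `stage`, `T`, `N`, `M`.
#' @export
simulate_survival <- function(pairs, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  missing_pairs <- setdiff(truth$true_pair_ids, rownames(pairs))
  if (length(missing_pairs) > 0)
    stop("simulate_survival: planted pairs missing from pair matrix: ",
         paste(missing_pairs, collapse = ", "), call. = FALSE)
  n <- ncol(pairs)
  lp <- if (length(truth$true_pair_ids) > 0) {
    colSums(pairs[truth$true_pair_ids, , drop = FALSE] * truth$true_betas)
  } else rep(0, n)

  set.seed(stream_seed(config$seed, "survival"))
  rate <- config$baseline_hazard * exp(lp)
  t_event <- rexp(n, rate)
  if (config$censor_rate > 0) {
    # P(censored | rate) for C ~ U(0, cmax) is (1 - exp(-rate*cmax))/(rate*cmax)
    pcens <- function(cmax) mean((1 - exp(-rate * cmax)) / (rate * cmax))
    cmax <- uniroot(function(cc) pcens(cc) - config$censor_rate,
                    lower = 1e-6, upper = 1e6 / config$baseline_hazard,
                    extendInt = "downX", tol = 1e-8)$root
    cens <- runif(n, 0, cmax)
  } else {
    cens <- rep(Inf, n)
  }
  fustat <- as.integer(t_event <= cens)
  futime <- ceiling(pmin(t_event, cens))

  set.seed(stream_seed(config$seed, "covariates"))
  lp_std <- if (stats::sd(lp) > 0) as.numeric(scale(lp)) else rep(0, n)
  age <- pmin(pmax(round(rnorm(n, 60, 10)), 30), 90)
  gender <- sample(c("male", "female"), n, replace = TRUE)
  g_lat <- 0.8 * lp_std + rnorm(n)
  s_lat <- 0.8 * lp_std + rnorm(n)
  grade <- paste0("G", findInterval(g_lat, quantile(g_lat, c(.3, .6, .85))) + 1L)
  stage_num <- findInterval(s_lat, quantile(s_lat, c(.35, .65, .85))) + 1L
  stage <- c("I", "II", "III", "IV")[stage_num]
  tstage <- paste0("T", pmin(stage_num + (runif(n) < 0.2), 4L))
  nstage <- ifelse(stage_num >= 3 & runif(n) < 0.5, "N1", "N0")
  mstage <- ifelse(stage_num == 4 & runif(n) < 0.6, "M1", "M0")

  data.frame(sample_id = colnames(pairs), futime = futime, fustat = fustat,
             age = age, gender = gender, grade = grade, stage = stage,
             T = tstage, N = nstage, M = mstage,
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Ground truth of a simulated cohort
#'
#' Returns the planted identities and coefficients for the cohort implied by
#' `config`: which lncRNAs are differentially expressed, which are
#' immune-linked, the planted pair indicators with their log-hazard
#' coefficients, and the per-sample linear predictor.  Stable across calls
#' with the same config.
#'
#' @param config a [sim_config()].
#' @return list with `de_up`, `de_down`, `immune_linked_lnc`,
#'   `true_pair_ids`, `true_betas` and named `linear_predictor`.
#' @export
make_ground_truth <- function(config) {
  simulate_cohort(config)$truth
}

#' Generate a complete synthetic cohort with ground truth
#'
#' Runs the whole generator: expression with planted co-expression and
#' differential expression ([simulate_expression()]), the tumour-side binary
#' pair matrix over the planted DE lncRNAs ([build_pair_matrix()] +
#' [filter_valid_pairs()], so planted pairs survive the validity filter by
#' construction), planted prognostic pairs chosen among valid pairs with
#' indicator frequency closest to 1/2 (preferring gene-disjoint pairs), and
#' proportional-hazards survival ([simulate_survival()]).
#'
#' @param config a [sim_config()].
#' @return list of class `"sim_cohort"` with `expression`, `genes`,
#'   `immune_symbols`, `sample_class`, `pair_matrix` (valid pairs x tumour
#'   samples), `clinical`, `truth` and `config`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_tumor = 40, n_normal = 15, seed = 7))
#' dim(coh$expression)
#' coh$truth$true_pair_ids
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ex <- simulate_expression(config)
  tumor <- names(ex$sample_class)[ex$sample_class == "tumor"]
  de_syms <- ex$genes$symbol[ex$genes$de != "none"]

  if (length(de_syms) >= 2) {
    pm <- build_pair_matrix(ex$expr[de_syms, tumor, drop = FALSE])
    pm <- filter_valid_pairs(pm, quiet = TRUE)
  } else {
    pm <- matrix(integer(0), nrow = 0, ncol = length(tumor),
                 dimnames = list(character(0), tumor))
  }

  true_ids <- character(0)
  if (config$n_true_pairs > 0) {
    if (nrow(pm) < config$n_true_pairs)
      stop("simulate_cohort: only ", nrow(pm), " valid pairs available but ",
           config$n_true_pairs, " planted pairs requested", call. = FALSE)
    frac <- rowMeans(pm)
    ord <- rownames(pm)[order(abs(frac - 0.5), rownames(pm))]
    used_genes <- character(0)
    for (pid in ord) {              # prefer gene-disjoint planted pairs
      gs <- strsplit(pid, "|", fixed = TRUE)[[1]]
      if (!any(gs %in% used_genes)) {
        true_ids <- c(true_ids, pid)
        used_genes <- c(used_genes, gs)
      }
      if (length(true_ids) == config$n_true_pairs) break
    }
    if (length(true_ids) < config$n_true_pairs)
      true_ids <- ord[seq_len(config$n_true_pairs)]
  }

  lp <- if (length(true_ids) > 0) {
    setNames(colSums(pm[true_ids, , drop = FALSE] * config$true_betas), tumor)
  } else setNames(rep(0, length(tumor)), tumor)

  truth <- list(
    de_up = ex$genes$symbol[ex$genes$de == "up"],
    de_down = ex$genes$symbol[ex$genes$de == "down"],
    immune_linked_lnc = ex$genes$symbol[!is.na(ex$genes$partner)],
    true_pair_ids = true_ids,
    true_betas = config$true_betas,
    linear_predictor = lp
  )
  clinical <- simulate_survival(pm, truth, config)

  structure(list(expression = ex$expr, genes = ex$genes,
                 immune_symbols = ex$genes$symbol[ex$genes$role == "immune"],
                 sample_class = ex$sample_class, pair_matrix = pm,
                 clinical = clinical, truth = truth, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic cohort:", sum(x$sample_class == "tumor"), "tumour /",
      sum(x$sample_class == "normal"), "normal samples;",
      nrow(x$expression), "genes\n")
  cat("  planted DE lncRNAs:", length(x$truth$de_up), "up,",
      length(x$truth$de_down), "down\n")
  cat("  valid pairs over DE lncRNAs:", nrow(x$pair_matrix), "\n")
  cat("  planted prognostic pairs:",
      paste(x$truth$true_pair_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic cohort to the on-disk formats the readers ingest
#'
#' Writes `expression.tsv`, `clinical.tsv`, `immune_genes.txt`, a minimal
#' Ensembl-style `genes.gtf`, `sample_class.tsv` and `truth.json` under
#' `dir`, in exactly the formats [read_expression_matrix()],
#' [read_clinical()], [read_gene_list()], [read_gene_annotation()] and
#' [classify_samples()] accept.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory, created if needed.
#' @return invisibly, a named character vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             immune = file.path(dir, "immune_genes.txt"),
             gtf = file.path(dir, "genes.gtf"),
             sample_class = file.path(dir, "sample_class.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression_matrix(cohort$expression, paths[["expression"]])
  write.table(cohort$clinical, paths[["clinical"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(c("Symbol", cohort$immune_symbols), paths[["immune"]])
  g <- cohort$genes
  pos <- cumsum(rep(2000L, nrow(g)))
  gtf <- sprintf(
    'chr1\tsynthetic\tgene\t%d\t%d\t.\t+\t.\tgene_id "%s"; gene_name "%s"; gene_biotype "%s";',
    pos - 1999L, pos, g$gene_id, g$symbol, g$biotype)
  writeLines(gtf, paths[["gtf"]])
  write.table(data.frame(sample_id = names(cohort$sample_class),
                         class = unname(cohort$sample_class)),
              paths[["sample_class"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
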