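#' Screen immune-related lncRNAs by co-expression
#'
#' A lncRNA is called immune-related if it is strongly co-expressed with at
#' least one gene of the immune panel: correlation `r > r_min` with two-sided
#' p-value `p < p_max`, computed on `log2(x + 1)` values across all samples.
#' The default rule is *signed* (r must exceed the threshold, not |r|);
#' `use_abs = TRUE` switches to |r|.  Zero-variance genes are skipped - they
#' can never be matched but raise no error.
#'
#' @param lnc,immune expression matrices (genes x samples) over identical,
#'   identically ordered samples.
#' @param r_min correlation threshold (default 0.7, strict inequality).
#' @param p_max p-value threshold (default 0.001, strict inequality).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param use_abs threshold on |r| instead of signed r.
#' @param log2 transform inputs with `log2(x + 1)` first (default TRUE).
#' @return list with `ids` (retained lncRNA identifiers), `r` and `p`
#'   (lnc x immune matrices), and `skipped` (zero-variance genes).
#' @export
coexpression_filter <- function(lnc, immune, r_min = 0.7, p_max = 0.001,
                                method = c("pearson", "spearman"),
                                use_abs = FALSE, log2 = TRUE) {
  method <- match.arg(method)
  if (ncol(lnc) != ncol(immune) ||
      !identical(colnames(lnc), colnames(immune)))
    stop_stage("screen", "lncRNA and immune matrices must share identical sample order")
  n <- ncol(lnc)
  if (n < 3) stop_stage("screen", "need at least 3 samples for correlation")
  la <- if (log2) log2p1(lnc) else lnc
  im <- if (log2) log2p1(immune) else immune
  if (method == "spearman") {
    la <- t(apply(la, 1, rank))
    im <- t(apply(im, 1, rank))
  }
  sd_l <- apply(la, 1, stats::sd)
  sd_i <- apply(im, 1, stats::sd)
  skipped <- c(rownames(la)[sd_l == 0], rownames(im)[sd_i == 0])
  r <- matrix(NA_real_, nrow = nrow(la), ncol = nrow(im),
              dimnames = list(rownames(la), rownames(im)))
  ok_l <- sd_l > 0; ok_i <- sd_i > 0
  if (any(ok_l) && any(ok_i))
    r[ok_l, ok_i] <- cor(t(la[ok_l, , drop = FALSE]),
                         t(im[ok_i, , drop = FALSE]))
  # two-sided p via the t transform; |r| = 1 maps to p = 0
  rc <- pmin(pmax(r, -1), 1)
  tt <- abs(rc) * sqrt((n - 2) / pmax(1 - rc^2, .Machine$double.eps))
  p <- 2 * pt(tt, df = n - 2, lower.tail = FALSE)
  p[abs(rc) >= 1] <- 0

  rr <- if (use_abs) abs(r) else r
  hit <- (rr > r_min) & (p < p_max)
  hit[is.na(hit)] <- FALSE
  ids <- rownames(la)[rowSums(hit) > 0]
  list(ids = ids, r = r, p = p, skipped = unique(skipped))
}

# Solve trigamma(x) = y by Newton iteration (monotone decreasing trigamma).
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (i in 1:60) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Moderated-t differential expression between tumour and normal
#'
#' Per-gene two-group comparison on `log2(x + 1)` with empirical-Bayes
#' variance moderation: the pooled within-group variance `s^2` (d residual
#' df) is shrunk towards a prior `s0^2` with prior df `d0`,
#' `s2_post = (d0*s0^2 + d*s^2) / (d0 + d)`, and the moderated t uses
#' `d0 + d` degrees of freedom.  The prior `(d0, s0^2)` is estimated by
#' moment matching on `log(s^2)` using the scaled-F distribution of sample
#' variances (digamma/trigamma moments); an estimated `d0` above 1e6 is
#' treated as effectively infinite.
#'
#' @param expr expression matrix, genes x samples (FPKM-like, untransformed
#'   unless `log2 = FALSE`).
#' @param sample_class named `"tumor"`/`"normal"` vector covering the
#'   columns, e.g. from [classify_samples()].
#' @param log2 transform with `log2(x + 1)` first (default TRUE).
#' @param d0 override the prior df: `NULL` (estimate, default), `0` (ordinary
#'   two-sample t) or `Inf` (fully pooled).
#' @return data.frame of class `"de_table"`, one row per gene:
#'   `gene`, `logFC` (tumour minus normal), `t`, `p`, `fdr` (Benjamini-
#'   Hochberg), plus attributes `d0` and `s0_2`.
#' @export
moderated_t_de <- function(expr, sample_class, log2 = TRUE, d0 = NULL) {
  cls <- sample_class[colnames(expr)]
  if (anyNA(cls))
    stop_stage("screen", "sample_class does not cover all expression columns")
  n1 <- sum(cls == "tumor"); n0 <- sum(cls == "normal")
  if (n1 < 2 || n0 < 2)
    stop_stage("screen", "need >= 2 samples per class (tumor %d, normal %d)",
               n1, n0)
  y <- if (log2) log2p1(expr) else expr
  y1 <- y[, cls == "tumor", drop = FALSE]
  y0 <- y[, cls == "normal", drop = FALSE]
  m1 <- rowMeans(y1); m0 <- rowMeans(y0)
  logfc <- m1 - m0
  d <- n1 + n0 - 2
  s2 <- (rowSums((y1 - m1)^2) + rowSums((y0 - m0)^2)) / d

  if (is.null(d0)) {
    z <- log(s2[s2 > 0])
    if (length(z) >= 2) {
      evar <- var(z) - trigamma(d / 2)
      if (is.finite(evar) && evar > 0) {
        d0 <- 2 * trigamma_inverse(evar)
        s0_2 <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                      digamma(d0 / 2) - log(d0 / 2))
      } else {
        d0 <- Inf
        s0_2 <- exp(mean(z) - digamma(d / 2) + log(d / 2))
      }
    } else {
      d0 <- 0; s0_2 <- 0
    }
  } else if (d0 == 0) {
    s0_2 <- 0
  } else {
    s0_2 <- exp(mean(log(s2[s2 > 0])) - digamma(d / 2) + log(d / 2))
  }
  if (is.finite(d0) && d0 > 1e6) d0 <- 1e6   # "effectively infinite"

  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2))
             else (d0 * s0_2 + d * s2) / (d0 + d)
  df_total <- if (is.infinite(d0)) 1e6 else d0 + d
  se <- sqrt(s2_post * (1 / n1 + 1 / n0))
  tstat <- ifelse(se > 0, logfc / se, ifelse(logfc == 0, 0, Inf * sign(logfc)))
  p <- 2 * pt(abs(tstat), df = df_total, lower.tail = FALSE)
  fdr <- p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(expr), logFC = logfc, t = tstat,
                    p = p, fdr = fdr, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  attr(out, "df_residual") <- d
  class(out) <- c("de_table", "data.frame")
  out
}

#' Select differentially expressed immune-related lncRNAs
#'
#' Applies the fold-change / FDR thresholds to a [moderated_t_de()] table:
#' up-regulated means `logFC > lfc_min` and `fdr < fdr_max`, down-regulated
#' `logFC < -lfc_min` and `fdr < fdr_max` (both strict).
#'
#' @param de a `de_table` from [moderated_t_de()].
#' @param lfc_min log2 fold-change threshold (default 2).
#' @param fdr_max FDR threshold (default 0.001).
#' @return list with `up`, `down` (character vectors) and `table` (the input
#'   with a `direction` column in `{"up","down","ns"}`).
#' @export
select_deirlncrna <- function(de, lfc_min = 2.0, fdr_max = 0.001) {
  stopifnot(is.data.frame(de), all(c("gene", "logFC", "fdr") %in% names(de)))
  up <- de$logFC > lfc_min & de$fdr < fdr_max
  down <- de$logFC < -lfc_min & de$fdr < fdr_max
  de$direction <- ifelse(up, "up", ifelse(down, "down", "ns"))
  list(up = de$gene[up], down = de$gene[down], table = de)
}
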