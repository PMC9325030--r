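---
title: "Methods: expression-level-independent prognostic signatures from immune-related lncRNA pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-level-independent prognostic signatures from immune-related lncRNA pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

Most transcriptomic prognostic signatures score a patient as a weighted sum
of absolute expression values.  That makes them fragile: the score changes
under renormalisation, platform shifts, or any monotone distortion of the
measurement scale.  `lncPairRisk` implements the alternative that has become
popular for immune-related lncRNA (irlncRNA) signatures: the features are
*within-sample pair order indicators*.  For a pair of lncRNAs $(A, B)$ and a
sample $s$,

$$ S_{A|B}(s) \;=\; \mathbf{1}\{x_A(s) > x_B(s)\}, $$

i.e. the indicator that $A$ is expressed above $B$ in that sample.  This is
the "divide A by B, call it 1 if the ratio exceeds 1" rule, extended to the
boundary cases the ratio cannot express (see *Numerical choices*).  Because
$S$ depends only on the ordering of two genes inside one sample, the whole
downstream model is invariant to any strictly increasing transform of the
expression matrix and to per-sample rescaling — properties the test suite
checks explicitly.

The fitted model is a Cox proportional-hazards model on $k$ selected pair
indicators, with risk score

$$ \mathrm{RiskScore}(s) \;=\; \sum_{i=1}^{k} \beta_i S_i(s), $$

and a dichotomising cut-point derived from the 5-year time-dependent ROC
curve.

# The screening funnel

1. **Immune-related lncRNAs.**  A lncRNA is *immune-related* if its
   Pearson correlation (on $\log_2(x+1)$, across all tumour and normal
   samples) with at least one immune-panel gene exceeds 0.7 with a two-sided
   $p < 0.001$.  The rule is signed by default — `use_abs = TRUE` switches
   to $|r|$ — and a flag switches to Spearman.  We adopt the strict
   inequality reading of "greater than 0.7".
2. **Differential expression.**  Tumour-vs-normal moderated-$t$ on
   $\log_2(x+1)$: per gene, the pooled within-group variance $s^2$ (with $d$
   residual df) is shrunk towards an empirical-Bayes prior,
   $\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, and the statistic is
   referred to a $t$ distribution on $d_0 + d$ df.  $(d_0, s_0^2)$ are
   estimated by moment matching on $\log s^2$ using the scaled-$F$
   distribution of sample variances (digamma/trigamma moments); an estimate
   of $d_0$ above $10^6$ is treated as effectively infinite.  The test suite
   verifies this implementation against limma's `eBayes` on the same data
   and against the textbook two-sample $t$ in the $d_0 = 0$ limit.
   Genes with $\log_2\mathrm{FC} > 2$ and Benjamini–Hochberg FDR $< 0.001$
   (both strict) are the DEirlncRNAs.
3. **Pairing and validity.**  All $\binom{n}{2}$ unordered pairs of
   DEirlncRNAs are formed ("A|B" with A lexicographically first).  A pair is
   *valid* when its indicator frequency lies strictly inside $(0.2, 0.8)$:
   a near-constant indicator cannot rank patients.  The published rule is
   stated only as "more than 20%"; its own rationale (pairs "without a
   certain rank" are uninformative) applies symmetrically at the top, so we
   mirror the bound at 80%.  Both bounds are configurable.
4. **Signature selection.**
   - univariate Cox screen, Wald $p < 0.05$;
   - `n_repeats = 1000` cycles of 10-fold cross-validated LASSO–Cox
     (`glmnet`), each with a fresh random fold partition, penalty chosen at
     the minimum mean CV partial-likelihood deviance (`lambda.min`; the
     1-SE rule is available), recording which pairs have non-zero
     coefficients; pairs selected in strictly more than
     `min_count_fraction * n_repeats` cycles (default 10%, i.e. the
     100-of-1000 rule) are kept.  The threshold is expressed as a fraction
     so scaled-down analyses keep the same proportion.
   - a final Cox model chosen by greedy forward search maximising the
     5-year time-dependent AUC, refitting the multivariate Cox model at
     every step and stopping when no addition improves the AUC.  The
     published description ("stop when the curve reaches its highest
     point") names no search strategy; greedy forward selection with a full
     refit per step is our reading, with `search = "all"` (one Cox fit on
     all frequency-selected pairs) as the alternative.  Ties prefer the
     smaller model, then the lexicographically smaller pair id.  An
     exhaustive-subset oracle in the test suite confirms the greedy search
     attains the best subset AUC within 0.02 on small candidate sets.

# Survival statistics

**Time-dependent ROC.**  Cumulative-case / dynamic-control at horizon $t$:
cases have an observed event by $t$, controls are event-free past $t$.
Censoring before $t$ is handled with the Kaplan–Meier weighting of
Heagerty, Lumley and Pepe (the estimator of the `survivalROC` tradition,
implemented here directly): with $\hat S$ the overall KM survival at $t$ and
$\hat S_c$ the KM survival within $\{ \mathrm{score} > c \}$,

$$ \widehat{\mathrm{sens}}(c) = \frac{(1-\hat S_c)\,\hat P(X>c)}{1-\hat S},
\qquad
\widehat{\mathrm{spec}}(c) = 1 - \frac{\hat S_c\,\hat P(X>c)}{\hat S}. $$

The AUC integrates the curve by the trapezoidal rule *in threshold order*
(descending).  Re-sorting points by FPR first looks equivalent, but
floating-point jitter on tied FPR values can swap points and cut staircase
corners; threshold order avoids that and makes the no-censoring case agree
with the Mann–Whitney statistic to machine precision, which the tests
assert at $10^{-12}$.

**AIC cut-point.**  "Evaluate the AIC of every point of the 5-year ROC
curve" has no published formula, so the package defines it operationally:
every candidate threshold $c$ (midpoints of consecutive sorted unique
scores) dichotomises the cohort, horizon status (case vs control, censored
before $t$ excluded) is modelled as binomial with one probability per side,
and $\mathrm{AIC}(c) = 2k - 2\ell(c)$ with $k = 2$.  The returned cut-point
minimises the AIC; ties take the smaller threshold.  Youden's $J$ is a
selectable alternative (`method = "youden"`).  The binomial log-likelihood
is evaluated in closed form from the 2×2 table; the tests verify it against
`stats::glm` + `AIC()` by exhaustive scan.  Excluding
censored-before-horizon subjects from this fit is a deliberate
simplification; the ROC itself handles them by KM weighting.

**Groups.**  A sample is high-risk iff its score is strictly above the
cut-point.  Kaplan–Meier curves (`survival::survfit`) and the log-rank test
(`survival::survdiff`) compare the groups.

# Association statistics

Risk group vs clinicopathological factor uses Pearson chi-square with Yates
correction on 2×2 tables.  Score-by-factor comparisons use the two-sample
Mann–Whitney rank-sum test: the published description says "Wilcoxon
signed-rank", but a signed-rank test requires paired data and every
comparison shown is between independent groups, so the rank-sum test is
what those comparisons can mean; exact p-values are used for combined
$n \le 20$ without ties, otherwise the normal approximation with tie
correction.  Multi-level factors are contrasted through a configurable
binary split (default: first half of the sorted levels vs the rest, e.g.
G1–G2 vs G3–G4).  Ordinal clinical codes map G1–G4, stage I–IV, T1–T4,
N0/N1, M0/M1 to integers, with GX/MX/blank treated as missing.
Immune-infiltration tables are consumed as long-format per-sample scores
(deconvolution itself is out of scope) and correlated with the risk score
by Spearman's rho; drug-IC50 tables are compared between groups per column
with BH adjustment across columns.

# The synthetic cohort generator

`simulate_cohort()` generates cohorts with exactly the structure the
analysis assumes, plus a ground-truth record, so every stage is testable
without downloads:

- **Expression**: genes are log-normal on a latent $\log_2$ scale
  (abundances $2^z - 1$ truncated at zero, so $\log_2(x+1)$ recovers the
  latent scale wherever $z \ge 0$).  A block of `coexpr_block_size` lncRNAs
  shares a standard-normal latent factor with one immune gene each, giving
  population Pearson correlation `coexpr_r` on the log scale by
  construction; the linked pairs use unit-scale factor structure while
  unlinked genes have `noise_sd` log2-scale noise.  DE lncRNAs (and their
  immune partners, mimicking immune activation in tumours — this keeps the
  pooled-sample correlation of DE block genes above the screen threshold)
  get a $\pm$`de_log2fc` tumour shift; their baseline means are drawn clear
  of the zero floor so the planted shift is exact on the analysis scale.
- **Pairs and survival**: planted prognostic pairs are chosen among *valid*
  pairs of the DE genes (indicator frequency nearest 1/2, preferring
  gene-disjoint pairs), so they survive the validity filter by
  construction.  Event times are exponential with hazard
  $\lambda_0 \exp(\sum_j \beta_j S_j)$; censoring is independent uniform on
  $[0, c]$ with $c$ solved numerically so the expected censored fraction
  equals `censor_rate`; times are rounded up to whole days (no 0-day
  follow-up).  Sample names follow the TCGA barcode convention so the
  barcode classifier runs unchanged on simulated data.
- **Determinism**: one seed governs fixed stream offsets (expression,
  survival, covariates, LASSO folds), so stages can be regenerated
  independently and identical configs give byte-identical cohorts.

Default conditions (chosen once as a realistic desk-scale cohort): 150
tumour / 50 normal samples; 200 lncRNAs and 60 immune genes; a 30-gene
co-expression block at $r = 0.8$; 18 up- and 6 down-regulated lncRNAs at
$|\log_2 \mathrm{FC}| = 3$ with `noise_sd = 0.5` (roughly the published
3–5:1 up:down imbalance); three planted pairs with $\beta = 0.8, 1.0, 1.2$;
baseline hazard $1.5\times10^{-4}$ events/day (median survival about 12.7
years at linear predictor 0, so a realistic fraction of the cohort is
event-free at the 5-year horizon); 30% censoring.  Clinical grade and stage
are weakly tied to the true linear predictor so the association stage has
signal to find; age and gender are independent.

What the generator does *not* emulate: batch effects, library-size or
GC biases, count noise (values are smooth log-normals), copy-number or
mutation structure, correlated censoring, or multi-modal patient
subgroups.  Passing tests therefore demonstrate correctness of the
*method* under its own assumptions, not robustness to real TCGA
artefacts.

# Numerical choices

- **Ties and zeros in the indicator**: $S = 1$ iff $a > b$ strictly; ties
  (including $0/0$) give 0, and $a > 0, b = 0$ gives 1.  The ratio form is
  undefined at $b = 0$; the order rule is its evident intent.
- **$p$-value of a correlation**: $t = r\sqrt{(n-2)/(1-r^2)}$, two-sided;
  $|r| = 1$ maps to $p = 0$.  Zero-variance genes are skipped, never
  matched and never an error.
- **Duplicate gene rows** collapse by elementwise mean (deterministic and
  symmetric).
- **LASSO path**: 50 penalty values per fit (glmnet's default is 100);
  selection-frequency counting needs only a coarse grid, and this halves
  the cost of the 1000-cycle loop.  Binary indicators are not standardised
  before penalisation (they share a scale already); both are configurable.
- **Horizons**: years are converted at 365 days/year; the cut-point uses
  the 5-year (1825-day) curve.
- **Cox fitting**: `survival::coxph` with Efron ties.  Monotone likelihood
  is surfaced as `converged = FALSE` (detected from the fitter's warnings);
  constant features yield `NA` coefficients.  Pairs that fail to converge
  are dropped from the univariate screen with a message.
- **Degenerate inputs** raise stage-named errors: no events, all scores
  identical, no cases or no controls at the horizon, empty candidate sets,
  empty lncRNA partitions.

# Problem sizes in the shipped checks

The test-suite and acceptance-script runs use desk-scale versions of the
analysis chosen to exercise every stage meaningfully: the default cohort
above for the end-to-end run (1000 LASSO cycles, as published); selection
recovery at $n = 500$ with ~100 candidate pairs, 100 cycles and the 10%
frequency threshold over 20 seeds; estimator checks at $n = 2000$
(Cox recovery, null AUC) and 10,000 genes (moderated-$t$ calibration).

# Known limitations

- The validity band's upper bound (80%) and the AIC cut-point definition
  are reconstructions of under-specified published rules; both are
  configurable and documented above.
- The forward AUC search is greedy; it is not guaranteed to find the
  globally best subset (the tests bound its gap on small candidate sets).
- The KM-weighted ROC estimator is not guaranteed monotone under heavy
  censoring; the AUC integrates the curve as estimated.
- Deconvolution (TIMER/CIBERSORT/…) and drug-response imputation are out
  of scope by design: their outputs are consumed as tables.
- p-values in the downstream association battery are reported raw plus
  BH-adjusted where multiple columns are tested; no cross-analysis
  correction is attempted.
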