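# lncPairRisk

Prognostic modelling from **immune-related lncRNA pairs** whose features are
rank-based 0/1 indicators rather than expression levels — for survival
analysts and computational biologists who want a tumour risk score that does
not depend on normalisation, platform, or any monotone distortion of the
expression scale.

## The method

For a pair of lncRNAs (A, B) and a sample *s*, the feature is the
within-sample order indicator

```
S_{A|B}(s) = 1  if  x_A(s) > x_B(s),  else 0
```

and the fitted model is a Cox proportional-hazards model on *k* selected
pairs, with risk score

```
RiskScore(s) = Σ_{i=1..k} β_i · S_i(s)
```

dichotomised at a cut-point that minimises the AIC over every point of the
5-year time-dependent ROC curve.  The selection funnel:

1. **immune screen** — lncRNAs co-expressed with an immune gene panel
   (Pearson r > 0.7, p < 0.001 on log2(x+1));
2. **differential expression** — empirical-Bayes moderated-t, keeping genes
   with |log2 FC| > 2 and BH FDR < 0.001;
3. **pairing** — all unordered pairs of the DE genes, keeping pairs whose
   indicator frequency lies strictly in (0.2, 0.8) (a near-constant
   indicator cannot rank patients);
4. **selection** — univariate Cox screen (p < 0.05), then 1000 cycles of
   10-fold cross-validated LASSO–Cox with a selection-frequency threshold
   (> 10% of cycles), then a greedy forward Cox search maximising the
   5-year AUC (cumulative/dynamic, Kaplan–Meier-weighted);
5. **evaluation** — risk groups at the AIC cut-point, Kaplan–Meier +
   log-rank, chi-square / rank-sum clinical associations, a
   univariate/multivariate Cox forest, and optional immune-infiltration
   (Spearman) and drug-IC50 (rank-sum) associations.

A synthetic cohort generator (`simulate_cohort()`) plants known
co-expression, differential expression and pair-driven hazards with a
ground-truth record, so the whole pipeline is testable end to end without
external data.

## Worked example

```r
library(lncPairRisk)

coh <- simulate_cohort(sim_config(seed = 1))      # 150 tumour / 50 normal
res <- run_pipeline(pipeline_config(seed = 1), data = coh, quiet = TRUE)
print(res)
```

```
Immune-related lncRNA pair signature pipeline
  samples: 150 tumour / 50 normal (150 modelled)
  funnel: 200 lncRNAs -> 30 immune-related -> 24 DE -> 93 valid pairs
          -> 19 univariate -> 13 frequency-selected -> 9 in signature
  risk groups: 62 high / 88 low at cut-point 1.7090; log-rank p = <2e-16
  AUC: year1 = 0.785, year3 = 0.858, year5 = 0.848
```

The funnel line traces the screening cascade: of 200 simulated lncRNAs, 30
pass the immune co-expression screen, 24 are differentially expressed, their
276 pairs reduce to 93 with informative indicators, and the selection
cascade retains a 9-pair signature.  The risk-group line shows the AIC
cut-point on the 5-year ROC and the resulting survival separation.

```r
summary(res$signature)
```

```
Pair signature (9 pairs): n = 150, events = 104, 1825-day AUC = 0.8479
         pair_id     beta     hr ci_lower ci_upper         p
 LNC0004|LNC0006  1.27300 3.5730   2.1230   6.0140 1.634e-06
 LNC0012|LNC0015  0.20350 1.2260   0.7998   1.8780 3.502e-01
 LNC0002|LNC0011  0.82650 2.2850   1.3690   3.8160 1.575e-03
 ...
```

Each row is one pair indicator with its Cox log-hazard coefficient (the β of
the risk-score formula), hazard ratio and 95% CI.  The cohort's three
planted pairs (`coh$truth$true_pair_ids`) are recovered among the top
coefficients.  The multivariate forest confirms the score is an independent
predictor next to age, grade and stage:

```r
subset(res$associations$forest, term == "risk_score")
```

```
        term     analysis       hr ci_lower ci_upper            p
1 risk_score   univariate 2.718282 2.180837 3.388174 5.721469e-19
5 risk_score multivariate 2.632342 2.019079 3.431873 8.530807e-13
```

i.e. each unit of risk score multiplies the hazard by ~2.6 after adjusting
for the clinical covariates.  `predict(res$signature, pm)` scores new
samples from their pair matrix; because the features are order indicators,
`build_pair_matrix(expr)` and `build_pair_matrix(log2(expr + 1))` give
identical scores.

Real data enter through the same interface: `pipeline_config(paths =
list(expression = ..., gtf = ..., immune = ..., clinical = ...))` with a
genes × samples FPKM TSV, an Ensembl GTF, an ImmPort-style gene list and a
clinical TSV (`sample_id`, `futime` in days, `fustat`, covariates).

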