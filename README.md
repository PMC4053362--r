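# mlcp — conformal region prediction for multi-label clinical data

`mlcp` is an R package for *reliable* multi-label classification of binary
clinical records, built around conformal prediction. The motivating task is
syndrome differentiation of chronic fatigue in traditional Chinese medicine:
a patient is described by binary symptoms (M = 95 in the motivating study)
and diagnosed with a **set** of syndrome factors ('spleen deficiency',
'heart deficiency', 'liver depression', 'qi deficiency'). Point predictions
are not enough in this setting — the clinician needs a label set *and* a
confidence level at which that set can be trusted.

## The method

1. **PT5 transformation.** Each training case with label set
   $Y_i$ is replicated $|Y_i|$ times, once per label, giving
   $n' = \sum_i |Y_i|$ single-label examples.
2. **Nonconformity via random-forest proximity.** A forest of un-pruned
   trees (`ntree`, `mtry = ⌊√M⌋`) is grown on the expanded examples. The
   proximity of two examples is the fraction of trees in which they share a
   terminal node. An example evaluated under label $y$ gets

   $$\alpha \;=\; \frac{\sum_{k=1}^{K}\text{k-th largest proximity to rows labelled} \ne y}
                       {\sum_{k=1}^{K}\text{k-th largest proximity to rows labelled} = y},$$

   small when the example sits inside class $y$. KNN-distance and
   naive-Bayes-posterior scorers are included for comparison, as is the
   ML-KNN baseline.
3. **Conformal p-values and regions.** For each candidate label,
   $p_y = (\#\{j:\alpha_j \ge \alpha_{\text{test}}(y)\} + 1)/(n'+1)$, and the
   region at confidence $1-\varepsilon$ is $\{y : p_y > \varepsilon\}$.
   Under exchangeability the online error rate at significance
   $\varepsilon$ is at most $\varepsilon$ — the calibration property that
   makes the output a trustworthy diagnostic aid.

Evaluation follows the multi-label conventions: subset accuracy, hamming
loss, one-error, coverage, ranking loss and average precision, computed by a
leave-one-out harness with threshold sweeps and empirical calibration
curves. A synthetic generator produces chronic-fatigue-like datasets
(binary signatures per syndrome factor, controllable prevalence,
co-occurrence and noise) so the whole pipeline is testable without any
clinical data.

## Worked example

```r
library(mlcp)

train <- simulate_cf_dataset(60, seed = 7)   # 60 cases, 95 binary symptoms
test  <- simulate_cf_dataset(3,  seed = 8)

model <- cp_fit(train, method = "rf", ntree = 500, seed = 7)
pred  <- cp_predict(model, test, confidence = 0.9)
```

`pred` holds one conformal p-value per syndrome factor and the region they
imply at 90% confidence:

```
  case_id spleen deficiency heart deficiency liver depression qi deficiency
1       1           0.75439          0.00877          0.75439       0.00877
2       2           0.00877          0.00877          0.00877       0.80702
3       3           0.00877          0.75439          0.00877       0.75439

 case 1 : spleen deficiency + liver depression   | truth: spleen deficiency + liver depression
 case 2 : qi deficiency                          | truth: qi deficiency
 case 3 : heart deficiency + qi deficiency       | truth: heart deficiency + qi deficiency
```

Read row 1 as: with the candidate label 'spleen deficiency' the test case
conforms to the training data (p = 0.75), with 'heart deficiency' it does
not (p = 0.0088, the minimum possible value 1/(n'+1)); at significance
0.1 the region keeps exactly the two conforming factors, which here equal
the true label set. Each p-value is the fraction of training examples at
least as nonconforming as the test case under that label, so small p-values
are evidence *against* a label.

A full study runs through the harness:

```r
d <- simulate_cf_dataset(200, seed = 1)
report <- loocv_evaluate(d, method = "cp-rf", ntree = 200,
                         thresholds = seq(0.8, 0.99, 0.01), seed = 1)
glance(report)        # six metrics at the top threshold
autoplot(report)      # metric curves across thresholds
autoplot(report$calibration)  # accuracy vs confidence + diagonal
```

On this synthetic study CP-RF's subset accuracy rises from 0.970 at
confidence 0.80 to 0.985 at 0.99, while the ML-KNN baseline (whose regions
shrink with its posterior threshold) collapses from 0.955 to 0.320 over the
same sweep — the qualitative behaviour that makes conformal regions
attractive when high confidence is required.

A thin command-line front end mirroring these functions (subcommands
`generate`, `evaluate`, `predict`, `calibrate`) ships at
`inst/cli/mlcp.R`; after installation:
`Rscript $(Rscript -e 'cat(system.file("cli", "mlcp.R", package = "mlcp"))') generate --n 100 --out d.csv`.

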