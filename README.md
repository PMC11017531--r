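# prevcal

Prevalence-calibrated performance metrics for binary classifier
validation.

## The problem

Validating a binary classifier — a QSAR toxicity model, a diagnostic
screen — produces a 2×2 confusion matrix per test set, and from it the
usual metrics: accuracy, MCC, predictivities, Cohen's kappa, F1. All of
them except sensitivity and specificity depend on the test set's
**positive prevalence** `Pre = (TP+FN)/N` as well as on the model. When
two test sets differ in prevalence (internal vs external validation,
applicability-domain filtering, cluster splits, data streams), comparing
raw metric values can invert the correct conclusion: a model that
improved can show a *falling* MCC, and vice versa.

`prevcal` fixes this with the **derived confusion matrix**. Any confusion
matrix is exactly

    TP = Sen·Pre·N    FN = (1−Sen)·Pre·N
    FP = (1−Spe)(1−Pre)·N    TN = Spe·(1−Pre)·N

so `(Sen, Spe, Pre, N)` fully characterises it. Holding `(Sen, Spe)`
fixed and rebuilding the matrix at a reference prevalence *calibrates*
any metric; at `Pre = 0.5` this yields the **balanced** metrics, e.g.

    Bal.Acc = (Sen + Spe)/2
    Bal.MCC = (Sen + Spe − 1) / sqrt(1 − (Sen − Spe)²)

which are prevalence-free and safe to compare across test sets.

## Worked example: a tale of two MCCs

An applicability-domain (AD) filter discards 1000 of 2000 test instances
(coverage 50%). Sensitivity rises 0.680 → 0.710 and specificity
0.850 → 0.890 — the model genuinely predicts better in-domain — but the
filter also shifts prevalence 0.600 → 0.900.

```r
library(prevcal)

full <- performance_profile(sen = 0.680, spe = 0.850, pre = 0.600, n = 2000)
derive_matrix(full)
#> <confusion_matrix>  N = 2000
#>                 pred_positive pred_negative
#> actual_positive           816           384
#> actual_negative           120           680
#> prevalence 0.6   sensitivity 0.68   specificity 0.85

compare_runs(scenario("ad_split"))
#> <comparison_report>  full vs in_domain
#>   N              2000     1000
#>   prevalence      0.6      0.9
#>   sen            0.68     0.71  +
#>   spe            0.85     0.89  +
#> raw metrics (each run's own prevalence):
#>   accuracy              0.748    0.728  -
#>   balanced_accuracy     0.765      0.8  +
#>   mcc                    0.52    0.377  -
#>   balanced_mcc          0.538     0.61  +
#>   ...
#> verdict: better    flags: prevalence_shift, raw_metric_contradiction
```

Reading the raw MCC alone (0.520 → 0.377) one would wrongly conclude the
AD filter hurt the model. The balanced MCC (0.538 → 0.610) agrees with
the sensitivity/specificity improvements, and the report flags both the
prevalence shift and the raw-metric contradiction. The same mechanism
calibrates every catalogue metric (`calibrated_metric()`), and
`prevalence_sweep()` traces any metric across the whole prevalence range
— a straight line with slope `Sen − Spe` for accuracy, the umbrella curve
vanishing at both prevalence endpoints for MCC.

A thin command-line wrapper ships in `inst/cli/prevcal`
(`compute`, `compare`, `sweep`, `fixtures`, `plot`; `compare` exits 2
when the contradiction flag fires, usable as a CI gate for model
validation).

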