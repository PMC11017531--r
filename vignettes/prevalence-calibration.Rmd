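---
title: "Prevalence-calibrated metrics for binary classifier validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prevalence-calibrated metrics for binary classifier validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevcal)
```

## The problem

When a binary classifier — a QSAR toxicity model, a diagnostic screen, any
hard yes/no predictor — is validated against several test sets, almost all
of the usual summary metrics depend not only on the model but also on the
*positive prevalence* of each test set, the fraction of instances whose
actual class is positive. Accuracy, positive and negative predictivity,
Cohen's kappa, F1 and, less obviously, the Matthews correlation
coefficient (MCC) all move when the class balance moves, even for a fixed
model. Comparing their raw values across test sets with different
prevalence — internal vs external validation, applicability-domain
filtering, cluster splits, temporal data streams — can therefore invert
the correct conclusion: a model that genuinely improved can appear to get
worse, and vice versa.

Only sensitivity, specificity (and functions of them alone, such as
balanced accuracy and Youden's informedness) are prevalence-free. This
package turns that observation into a general calibration mechanism.

## The derived confusion matrix

A confusion matrix with counts TP, FN, FP, TN and total
$N = TP+FN+FP+TN$ defines

$$Pre = \frac{TP+FN}{N}, \qquad
  Sen = \frac{TP}{TP+FN}, \qquad
  Spe = \frac{TN}{FP+TN}.$$

These can be inverted: every confusion matrix is exactly

$$TP = Sen \cdot Pre \cdot N, \quad
  FN = (1-Sen) \cdot Pre \cdot N, \quad
  FP = (1-Spe)(1-Pre) \cdot N, \quad
  TN = Spe \cdot (1-Pre) \cdot N,$$

so $(Sen, Spe, Pre, N)$ fully characterises the validation result:
$(Sen, Spe)$ describe the model, $(Pre, N)$ describe the test set. In the
package this round trip is `as_profile()` / `derive_matrix()`, and it is
tested to be exact (1e-9 relative per cell on random integer matrices;
the class totals $Pre \cdot N$ and $(1-Pre) \cdot N$ are conserved to
double precision).

**Calibration** keeps $(Sen, Spe)$ fixed and rebuilds the matrix at a
chosen reference prevalence (`calibrate_matrix()`); any count-based metric
evaluated on that matrix is the *calibrated* metric, and $N$ cancels out
of every metric in the catalogue, so the result depends only on
$(Sen, Spe, Pre_{target})$. Calibrating to $Pre = 0.5$ gives the
*balanced* metric.

## Closed forms

Substituting the derived counts into the metric definitions gives
closed forms used as the public fast path (the generic matrix route is
retained and the two are tested to agree to 1e-12 over $10^4$ random
profiles):

* accuracy: $Acc^{Pre} = Sen \cdot Pre + Spe \cdot (1-Pre)
  = (Sen-Spe) \cdot Pre + Spe$ — affine in prevalence, slope $Sen-Spe$,
  intercept $Spe$; at 0.5 it is balanced accuracy $(Sen+Spe)/2$;
* MCC:
  $$MCC^{Pre} = \frac{Sen+Spe-1}
  {\sqrt{\left[Sen+(1-Spe)\frac{1-Pre}{Pre}\right]
         \left[Spe+(1-Sen)\frac{Pre}{1-Pre}\right]}}$$
  — the umbrella-shaped curve over prevalence, vanishing toward both
  endpoints for interior $Sen, Spe$;
* balanced MCC: $MCC^{0.5} = \dfrac{Sen+Spe-1}{\sqrt{1-(Sen-Spe)^2}}$,
  whose numerator is informedness $Sen+Spe-1$ (balanced accuracy rescaled
  from $[0,1]$ to $[-1,1]$), and which equals that rescaled balanced
  accuracy exactly when $Sen = Spe$;
* balanced kappa reduces to $Sen+Spe-1$, balanced PPV to
  $Sen/(Sen+1-Spe)$, balanced NPV to $Spe/(Spe+1-Sen)$ — all re-derived
  here and verified against the generic mechanism rather than quoted.

## Parameters that matter

* `target_prevalence` (default **0.5**): the reference prevalence for
  calibrated metrics. 0.5 is the natural convention — it removes the
  imbalance term and reproduces the well-known balanced accuracy — but any
  domain-specific reference can be passed explicitly.
* `shift_threshold` (default **0.02** absolute prevalence difference): when
  two compared runs differ by more than this, the report raises
  `prevalence_shift`. Any nonzero shift technically matters; the threshold
  only suppresses noise on near-identical sets and is configurable.
* `tol` (default **1e-9**): metric differences below this count as
  "constant" when classifying variations, so floating-point noise cannot
  produce a spurious increase/decrease.
* sweep grid (default **199 points**, `epsilon = 0.005`): sweeps evaluate
  on $[\epsilon, 1-\epsilon]$ because the MCC closed form divides by $Pre$
  and $1-Pre$; the exact endpoints are analytic limits (0 at both ends for
  interior sensitivity/specificity), reported as such, never evaluated.
  199 points render the umbrella smoothly at negligible cost.

## Numerical and degenerate-input choices

* **Fractional counts.** Calibrated matrices keep real-valued cells; the
  algebra above is continuous and rounding would break the metric
  identities. Integer realisation is a separate, explicit step
  (`realise_counts()`, largest-remainder rounding that preserves $N$
  exactly, ties broken in cell order TP, FN, FP, TN) used only when label
  files or integer fixtures are needed.
* **Undefined statistics.** A sensitivity with no actual positives (or
  specificity with no negatives) is `NA_real_`, an explicit undefined
  marker — never a silent 0 or 1. Operations that *consume* an undefined
  value raise a classed condition (`prevcal_undefined_error`), and the
  comparison report withholds its verdict rather than guessing.
* **MCC conventions.** From counts, MCC is defined as 0 whenever a
  marginal sum vanishes — a convention consistent with the closed form's
  endpoint anchors, documented as such. In the closed form, prevalence 0
  or 1 returns the anchor value 0 flagged `degenerate_point`, except when
  sensitivity or specificity is itself exactly 0 or 1, where the limit
  genuinely depends on the approach path and a
  `prevcal_undefined_limit_error` is raised instead. Likewise
  `balanced_mcc()` at $|Sen-Spe| = 1$ is a 0/0 form and returns a flagged
  0. `calibrated_metric()` refuses endpoint targets outright: the generic
  matrix route is ill-defined there and endpoint behaviour belongs to the
  closed forms.
* **Tolerances.** Closed-form identities are asserted at 1e-12 absolute;
  matrix round trips at 1e-9 relative — comfortable double-precision
  headroom without masking real defects.
* **CSV orientation.** A 2×2 CSV is accepted only with explicit
  `actual_*` / `pred_*` headers, in either orientation; silent positional
  transposition is the classic confusion-matrix bug and is rejected as
  ambiguous.

## The comparison report

`compare_runs()` compares validation runs (pairwise against the first when
more than two are given). The verdict uses only sensitivity and
specificity, the prevalence-free pair: `better` iff both increase,
`worse` iff both decrease, `trade_off` otherwise — the subjective mixed
case is reported, not resolved. Raw metrics computed at each run's own
prevalence and calibrated metrics at the common reference are tabulated
with qualitative variations, and two flags protect against
misinterpretation: `prevalence_shift` and `raw_metric_contradiction` (some
raw metric moved against the verdict). The command-line `compare` exits
with status 2 when the contradiction fires, so it can gate a validation
pipeline. Swapping the run order maps better to worse and back and leaves
`trade_off` fixed; this antisymmetry is tested.

## What the synthetic scenarios emulate — and what they do not

The package ships four scenarios (`scenario()`), defined purely at the
confusion-matrix level:

* `ad_split` is the applicability-domain use case: full set (Sen 0.680, Spe 0.850, Pre
  0.600, N 2000, raw MCC 0.520) vs in-domain half (Sen 0.710, Spe 0.890,
  Pre 0.900, N 1000, raw MCC 0.377), coverage 50%. The model improves,
  raw MCC drops, balanced MCC rises 0.538 → 0.610.
* `same_prevalence` / `shifted_prevalence` emulate internal-vs-external
  validation at constant (0.900/0.900) and shifted (0.900/0.600)
  prevalence, with N 2000/1000. The sensitivity/specificity pairs
  (0.700/0.950 internal, 0.680/0.900 external) were chosen once to be
  integer-realisable at the stated prevalences and to produce the
  instructive qualitative pattern — both statistics fall externally, yet
  under the shift the raw MCC (0.405 → 0.571), accuracy and kappa rise.
* `stream_drift` illustrates a nonstationary data stream: ten windows of
  N 500, prevalence drifting linearly 0.3 → 0.9 at fixed Sen 0.75 /
  Spe 0.85. These illustrative window parameters are not all exactly
  integer-realisable, which is precisely what the largest-remainder
  policy is for.

Because all scenarios live at the confusion-matrix level, passing tests
demonstrate the *arithmetic* claims — calibration removes prevalence
dependence, raw metrics can contradict the model's true direction — for
any classifier whose validation reduces to a 2×2 table. They say nothing
about chemistry: no molecular descriptors, applicability-domain algorithm
or model training is simulated, sampling variability in sensitivity and
specificity is not modelled (profiles are treated as exact), and
real-world prevalence shifts are rarely as clean as a single number.

## Problem sizes used in the test suite

Property-style tests run on generated cases under fixed seeds: $10^4$
random profiles for the closed-form vs count-based agreement check, 200–
2000 cases for the other identities, 500 random integer matrices for
round-trip and range checks. These sizes give dense coverage of the unit
cube of $(Sen, Spe, Pre)$ while keeping the whole suite fast; the
identities are exact, so larger samples would only re-confirm them.

## Known limitations

* Binary, hard-label classification only: no multi-class matrices, no
  probabilistic scores or thresholding, and no rank-based metrics (AUROC
  cannot be computed from a single confusion matrix, hence cannot be
  calibrated by this mechanism).
* No confidence intervals: the framework treats (Sen, Spe) as exact;
  quantifying their sampling error under calibration is out of scope.
* The `better`/`worse` verdict is deliberately conservative; when
  sensitivity and specificity move in opposite directions the trade-off
  is use-case specific and the package does not rank it.
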