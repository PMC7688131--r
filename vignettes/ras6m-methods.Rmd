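---
title: "Methods: 6M dose-response fitting and expression-based sensitivity biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 6M dose-response fitting and expression-based sensitivity biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models, the defaults and why they are what they are, the numerical choices,
and what the synthetic-data validation does and does not establish.

## The 6M dose-response model

Cytotoxicity data are percent-growth observations
`100 * (treated - blank) / (untreated - blank)` at positive arithmetic
doses (µM). The working curve is the four-parameter logistic

$$\hat Y(X) = d + \frac{a - d}{1 + (X/c)^b}$$

with $a$ the zero-dose asymptote (% growth), $d$ the infinite-dose
asymptote, $c$ the dose at the midpoint $(a+d)/2$, and $b$ the Hill slope.
Six constrained variants are fitted — `3P`, `3P-Top100`, `3P-Bottom0`
(slope fixed at 1; `Top100` pins $a = 100$, `Bottom0` pins $d = 0$) and
`4P`, `4P-Top100`, `4P-Bottom0` (free slope) — and the winner minimises the
residual standard error $\sqrt{RSS/(n-p)}$ with $p$ the number of free
parameters. Fixing the slope is implemented as $b = 1$: that is the only
reading under which $c$ keeps its midpoint interpretation.

Constraining a parameter can *lower* the RSE even though it raises the RSS,
because $p$ shrinks the denominator; the test suite therefore asserts
optimality on RSE and nesting on RSS (the free 4P fit never has higher RSS
than a constrained variant on the same data), but deliberately not
`rse(4P) <= rse(3P)`.

### Optimisation

Each variant is a bounded Levenberg–Marquardt least-squares problem
(`minpack.lm::nls.lm`), with $c$ and $b$ estimated on the log scale.
Bounds: $a, d \in [-100, 300]$ (normalized growth can exceed 100 or fall
below 0), $c \in (0, 10^3 \times$ max dose$]$, $b \in [0.05, 20]$. Starts:
$a_0 = \max Y$, $d_0 = \min Y$, $c_0$ = geometric mean dose, $b_0 = 1$,
plus four deterministic restarts scaling $c_0$ by 1/4 and 4 and $b_0$ by
1/2 and 2. The schedule is fixed — no RNG — so fits are reproducible by
construction. Convergence tolerances are `ftol = ptol = 1e-12` with at most
200 iterations; a fit that exhausts all starts without an acceptable
termination code is flagged `converged = FALSE` and excluded from
selection. RSE ties within `1e-9` resolve toward fewer free parameters,
then catalogue order — this is what makes noise-free data reproducibly pick
the most parsimonious variant that fits exactly.

Replicates enter as individual points (an `average_replicates` switch
collapses them first); degenerate inputs (a single distinct dose, or
constant growth for slope-estimating variants) error, and a fully flat
response errors unless `allow_flat = TRUE` returns a flagged
non-informative fit.

### Derived metrics

ICxx solves $\hat Y(X) = t$ in closed form,
$X = c\,((a-t)/(t-d))^{1/b}$, returning `NA` ("not reached") when $t$ lies
outside the open interval between the asymptotes; the closed form is
cross-checked against bisection to 1e-8 relative. Two deliberate
conventions:

* **Targets are percent growth**, literally: IC90 is the dose at 90%
  *growth*, not 90% inhibition. This inverts the common convention but is
  the definition the 6M workflow uses; `convention = "inhibition"`
  retargets to growth 50/10/5.
* **EC50 is the midpoint dose**, i.e. $c$. A literal "dose where
  $\hat Y = a + d$" is unattainable on the curve (the curve lives strictly
  between $a$ and $d$), so the midpoint — the standard EC50 — is the only
  defensible reading; the choice is stated here rather than silently
  applied.

Amax is exactly $a - d$. Activity Area is the plain sum of $\hat Y$ over
the inclusive arithmetic grid `dose_min, dose_min + 0.01, ..., dose_max`
(defaults: the tested range, 0.1–20 µM), i.e. a Riemann sum not scaled by
the step; it is validated against an independently coded loop to 1e-6.
IC50s are reported in µM and consumed untransformed downstream; a natural
log is a caller-side choice since screening databases differ on this.

## Expression filtering and correlation

The probe filter passes a probe when variance ≥ 0.8, mean ≥ 5.5 and
max−min > 3 (log2 units; inclusive, inclusive, strict — the boundary cases
are pinned in tests). Variance uses the sample (n−1) denominator by
default, with a population option, since either reading is defensible; the
filter takes an explicit sample subset so the cohort over which variability
is judged is always a visible argument. Probeset collapse keeps, per gene,
the probe with the highest mean expression across samples (the common
collapse rule; a highest-single-sample option exists), ties broken by
probe id so results are deterministic. Per-probe association with IC50 is
Pearson's r with the two-sided p from the t distribution on n−2 df; no
multiple-testing correction is applied at this screening stage by design
(the workflow treats it as a ranking device, not an inference), and a
Benjamini–Hochberg adjustment can be applied by the caller.

## Regression and validation

Models are OLS fits `y = a + Σ nᵢ xᵢ` of IC50 on gene expression. The
best-subsets search enumerates all $2^m - 1$ non-empty subsets (guarded at
m ≤ 20) and ranks by adjusted R² — the stated selection criterion, rather
than Mallows' Cp — with ties to the smaller model. The enumeration is
checked bit-for-bit against an independent bitmask brute force. Validation
follows two routes:

* **Repeated random splits**: ten seeded 12/5 discovery/test partitions;
  the figure of merit is the mean *discovery-fit* adjusted R² (the
  held-out R² and Sy.x are reported alongside, since "average R² across
  splits" is ambiguous between the two readings and both are informative).
* **Range-spanning split**: a deterministic stand-in for a manual
  "cover the sensitivity range" partition — samples are ranked by IC50 and
  evenly spaced interior ranks form the test group, keeping both extremes
  in discovery. Documented as an approximation of an intrinsically manual
  choice.

Sy.x is `sqrt(Σ(obs − pred)²/(n − 2))`, the residual standard deviation
used as the goodness-of-fit measure for test-group predictions.

## LRMC survival scanning

For a gene and cohort (time in days, event 1 = death), every distinct
expression value is a candidate cutoff; Low is strictly below, High at or
above (tie placement is a convention and is pinned in tests). Each
admissible split — at least `min_group_size = 3` per side, because the
log-rank statistic is degenerate at size 1; a literal every-sample scan is
available with size 1 — gets a Mantel–Haenszel log-rank p and the O/E
hazard ratio $(O_H/E_H)/(O_L/E_L)$, reported High vs Low. The selected
cutoff minimises p; exact ties resolve to the cutoff nearest the median
(central cutoffs are the interpretable ones), then the lower value.

Scanning many correlated cutoffs and keeping the minimum p inflates type-I
error substantially: on null cohorts (no true effect, n = 163) the selected
cutoff is "significant" at 0.05 in roughly half the simulations — an
order of magnitude above nominal. The scan object therefore always carries
a "selected by minimum p over K candidate cutoffs" annotation and applies
no correction by default, matching how the scan is used descriptively; the
acceptance suite measures the inflation rather than hiding it.

The binary Cox model is a single-coefficient partial likelihood maximised
by Newton–Raphson with Breslow tie handling (tied days are common once
times are rounded to days); monotone likelihoods are flagged as
non-converged rather than reported at the boundary. Kaplan–Meier medians
are the smallest time with $S(t) \le 0.5$. Whether published per-cutoff
HRs come from Cox or from the log-rank O/E ratio is often unstated, so
both are computed; on well-separated cohorts they agree within ~15% and a
test asserts that.

The combined classifier labels a patient Good iff IGF2R is High, CTSA is
High and ATP6AP2 is Low at their per-gene cutoffs (the shipped defaults
`ras_prognostic_cutoffs` are the LRMC cutoffs 7.077/11.247/11.773 derived
on the GSE12417 AML training cohort); everyone else is Bad.

## qRT-PCR bridge

ddCT with efficiency fixed at 2: replicates average on the Ct scale,
`dCt = Ct_target − Ct_GAPDH`, `RQ = 2^(−(dCt − dCt_calibrator))`. The
calibrator defaults to the cohort mean dCt (no natural single calibrator
exists in a cell-line panel), which makes `log2_rq` mean-centred and the
RQs multiply to 1. To feed RQ values into regression formulas trained on
log2 microarray intensities, use `log2_rq` — the bridge between the two
scales is this package's stated convention, since PCR and array units are
not otherwise commensurable.

## Synthetic study conditions

The generators emulate the statistical structure of the three real inputs
and their defaults are fixed study conditions, chosen once:

* **Screen**: 17 cell lines, doses 20/10/2/1/0.2/0.1 µM in triplicate,
  growth noise sd 5% (a typical luminescence-assay replicate scatter);
  curves drawn with a = 100, d ~ U[0, 30], c log-uniform over the dose
  range, b ~ U[0.5, 3].
* **Expression cohort**: nine probesets (two mapping to the same gene, as
  in the motivating panel), means uniform on log2 5.5–11, sd 1.2; IC50 =
  12 − 1.5·IGF2R_1 + 1.2·ATP6AP2 − 0.8·CTSA + N(0, 0.3) — a strong,
  sign-realistic signal in which high IGF2R/CTSA mark sensitivity and high
  ATP6AP2 resistance.
* **Survival cohort**: 163 patients, driver expression N(10, 1.5²),
  hazard ratio 3 at the 40th percentile, exponential baseline
  log(2)/365 per day (one-year median survival in the low-risk group,
  plausible for adult AML), censoring uniform on (0, τ) with τ solved so
  the expected censored fraction is 20%; times rounded up to whole days,
  which also exercises tie handling.

What passing tests show: the estimators recover known truths under
Gaussian noise, exponential hazards and exact linear signals at realistic
sizes. What they do not show: robustness to batch effects, heavy-tailed or
heteroscedastic assay noise, correlated gene expression, non-proportional
hazards, or informative censoring — none of which the generators emulate.
Conclusions about real cohorts need the real accessions.

Problem sizes in the test and acceptance runs — 100 curves for recovery,
50 brute-force regression instances, 100 support-recovery cohorts, 50
cutoff-recovery and 60 null survival cohorts — were chosen to make the
Monte-Carlo rates stable at the asserted margins while keeping a full run
in the minutes range on a single core.

## Known limitations

* The 6M selection compares RSE across differently-constrained models fit
  to the same points; it is a heuristic, not a formal model-selection
  criterion, and with few points the 2-parameter variants win ties by
  construction.
* Activity Area depends on the dose grid; values are only comparable
  between curves integrated over the same range.
* The LRMC minimum-p cutoff is optimistically biased (measured, annotated,
  uncorrected by default).
* Best-subsets at n = 12, m = 9 can overfit; the cross-validation output,
  not the discovery R², is the honest summary of predictive value.
* `read_expression_matrix` expects a rectangular numeric TSV after
  dropping `!` metadata lines; it is not a general GEO parser.
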