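# ras6m

Drug-sensitivity biomarker analysis for cell-line screens, built around the
**6-model (6M)** approach to dose–response fitting, with the downstream
statistics needed to turn gene expression into chemosensitivity predictors
and prognostic classifiers: variance-based probe filtering, exhaustive
best-subsets regression of IC50 on expression, log-rank-with-multiple-cutoffs
(LRMC) survival stratification, and ddCT quantification of qRT-PCR data.
The package targets the setting where a cytotoxicity screen (e.g. AML cell
lines under Doxorubicin or Etoposide), a log2-normalized expression matrix
and a survival cohort are analysed together.

## The model

Percent growth *Y* at arithmetic dose *X* follows the four-parameter
logistic (4PL)

    Ŷ(X) = d + (a − d) / (1 + (X/c)^b)

with *a* the percent growth of untreated cells, *d* the percent growth at
infinite dose, *c* the dose at the midpoint between *a* and *d*, and *b*
the Hill slope. The 6M procedure fits six constrained variants — `3P`,
`3P-Top100` (*a* = 100), `3P-Bottom0` (*d* = 0), each without a free slope
(*b* = 1), and their `4P` counterparts with a free slope — and selects the
fit with the lowest residual standard error `sqrt(RSS/(n − p))`, *p* the
number of free parameters. From the selected curve the package derives
IC50/IC90/IC95 (dose at predicted growth 50/90/95%; an inhibition-convention
switch is available), EC50 (the midpoint dose *c*), Amax (*a* − *d*) and
Activity Area (the sum of predicted growth over an arithmetic 0.01 µM dose
grid).

Downstream, per-gene Pearson correlations and OLS models
`y = a + Σ nᵢ·xᵢ` link expression to IC50; the best predictor subset is
found by exhaustive enumeration ranked by adjusted R², validated by
repeated random 12/5 discovery/test splits and the Sy.x residual standard
deviation. For survival cohorts, every observed expression value is scanned
as a Low/High cutoff with a Mantel–Haenszel log-rank test and O/E hazard
ratio (the LRMC scan; the minimal-p cutoff is selected and flagged for its
multiplicity optimism), complemented by Kaplan–Meier estimates and a
binary-covariate Cox model. A combined three-gene rule (IGF2R High ∧ CTSA
High ∧ ATP6AP2 Low ⇒ "Good", else "Bad") classifies patients.

## Worked example

```r
library(ras6m)

# a seeded synthetic screen: 17 cell lines, six doses in triplicate, 5% noise
sc  <- sim_config(seed = 3)
dr  <- simulate_dose_response(sc)
one <- dplyr::filter(dr$data, cell_line == "CL009")
fit <- fit_6m(one)
glance(fit)
#> # A tibble: 1 × 9
#>   variant        a     d     c     b n_free   rss   rse converged
#>   <chr>      <dbl> <dbl> <dbl> <dbl>  <int> <dbl> <dbl> <lgl>
#> 1 3P-Bottom0  96.6     0  11.1     1      2  398.  4.99 TRUE

response_metrics(fit)
#> # A tibble: 1 × 9
#>    ic50  ic90  ic95  ec50  amax activity_area dose_min dose_max convention
#>   <dbl> <dbl> <dbl> <dbl> <dbl>         <dbl>    <dbl>    <dbl> <chr>
#> 1  10.3 0.808 0.184  11.1  96.6       109375.      0.1       20 growth
```

Of the six variants, the slope-free curve with the bottom pinned at 0 wins
on residual standard error (4.99% growth over 18 points with 2 free
parameters). Its IC50 — the dose at 50% predicted growth — is 10.3 µM; the
truth table for this simulated line records 10.4 µM. IC90/IC95 here are the
doses at 90%/95% *growth* (the literal convention; sub-micromolar because
the curve passes those growth levels at low dose), EC50 equals the fitted
midpoint `c`, and Amax is the full effect span `a − d`.

An LRMC scan on a simulated 163-patient cohort whose hazard triples at the
40th expression percentile:

```r
sv   <- simulate_survival_cohort(sc)
coh  <- dplyr::inner_join(sv$survival, sv$expression, by = "sample_id")
scan <- lrmc_scan(coh, "IGF2R", time = "time_days", event = "event")
scan
#> <lrmc_scan> IGF2R: 163 patients, 158 admissible cutoffs
#>   selected cutoff 9.757: p = 2.52e-09, HR (High vs Low) = 2.76, n_low/n_high = 70/93
#>   note: selected by minimum p over 158 candidate cutoffs; no multiplicity correction applied
sv$truth$cutoff
#> [1] 9.537673
```

The scan recovers a cutoff at the 43rd percentile against a true 40th, with
an O/E hazard ratio of 2.8 against a true 3. `autoplot(scan)` draws the
−log10 p profile; `classify_prognosis()` then combines three such cutoffs
into the Good/Bad call, and `run_pipeline(pipeline_config(...))` sequences
the whole analysis with TSV/JSON artifacts and a hash manifest.

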