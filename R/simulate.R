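# Seeded synthetic-data generators emulating the statistical structure of
# the three real inputs: a cytotoxicity screen (4PL-shaped viability at six
# doses with replicate noise), an expression cohort in which a small gene
# subset linearly determines IC50, and a survival cohort whose hazard jumps
# at a thresholded expression value. Each generator is a pure function of
# its config: the seed is applied with withr::with_seed, so reruns are
# byte-identical and the caller's RNG state is untouched.

#' Simulation configuration
#'
#' Bundles every knob of the three synthetic-data generators with the
#' default study conditions: 17 cell lines measured at the six standard
#' doses (20, 10, 2, 1, 0.2, 0.1 uM) in triplicate with 5% growth noise;
#' nine candidate probesets of which three (the prognostic trio) linearly
#' determine IC50; and a 163-patient survival cohort whose hazard triples
#' at the 40th expression percentile, with 20% censoring and a baseline
#' hazard giving one-year median survival in the low-risk group.
#'
#' @param seed Integer seed used by every generator call.
#' @param n_cell_lines Cell lines in the screen and expression cohort.
#' @param drug Drug label written into the tables.
#' @param concentrations Dose grid, uM.
#' @param replicates Replicates per dose.
#' @param viability_noise_sd Gaussian noise sd on percent growth.
#' @param d_range,b_range Ranges for the infinite-dose asymptote and Hill
#'   slope of the generating curves (zero-dose asymptote is 100, midpoint
#'   log-uniform over the dose range).
#' @param genes Candidate probeset/gene identifiers.
#' @param true_predictors Subset of `genes` that determine IC50.
#' @param coefficients Named coefficients for `true_predictors`.
#' @param intercept Regression intercept.
#' @param expression_mean_range Per-gene means drawn uniformly here (log2).
#' @param expression_sd Per-gene expression sd (log2).
#' @param ic50_noise_sd Gaussian noise sd on simulated IC50.
#' @param n_patients Survival-cohort size.
#' @param surv_genes Gene columns in the survival cohort; the first drives
#'   the hazard, any others are independent noise genes.
#' @param cutoff_percentile Percentile of driver expression at which the
#'   hazard jumps.
#' @param hazard_ratio Hazard ratio at/above the cutoff.
#' @param baseline_hazard Exponential event rate below the cutoff, per day.
#' @param censoring_fraction Target fraction censored (independent uniform
#'   censoring), in \[0, 1).
#' @param surv_expression_mean,surv_expression_sd Driver/noise gene
#'   expression distribution (log2).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_cell_lines = 17,
                       drug = "Doxorubicin",
                       concentrations = c(20, 10, 2, 1, 0.2, 0.1),
                       replicates = 3,
                       viability_noise_sd = 5,
                       d_range = c(0, 30),
                       b_range = c(0.5, 3),
                       genes = c("CTSG", "CPA3", "AGT", "ANPEP", "IGF2R_1",
                                 "IGF2R_2", "RNPEP", "ATP6AP2", "CTSA"),
                       true_predictors = c("IGF2R_1", "ATP6AP2", "CTSA"),
                       coefficients = c(IGF2R_1 = -1.5, ATP6AP2 = 1.2, CTSA = -0.8),
                       intercept = 12,
                       expression_mean_range = c(5.5, 11),
                       expression_sd = 1.2,
                       ic50_noise_sd = 0.3,
                       n_patients = 163,
                       surv_genes = c("IGF2R", "CTSA", "ATP6AP2"),
                       cutoff_percentile = 0.4,
                       hazard_ratio = 3,
                       baseline_hazard = log(2) / 365,
                       censoring_fraction = 0.2,
                       surv_expression_mean = 10,
                       surv_expression_sd = 1.5) {
  cfg <- as.list(environment())
  stopifnot(
    length(seed) == 1, is.finite(seed),
    n_cell_lines >= 1, replicates >= 1, n_patients >= 2,
    all(concentrations > 0), viability_noise_sd >= 0,
    d_range[1] <= d_range[2], b_range[1] > 0,
    length(coefficients) == length(true_predictors),
    all(true_predictors %in% genes),
    cutoff_percentile > 0, cutoff_percentile < 1,
    hazard_ratio > 0, baseline_hazard > 0,
    censoring_fraction >= 0, censoring_fraction < 1,
    expression_sd > 0, surv_expression_sd > 0, ic50_noise_sd >= 0
  )
  names(cfg$coefficients) <- cfg$true_predictors
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %s | %d cell lines x %d doses x %d reps (noise sd %g%%)\n",
              format(x$seed), x$n_cell_lines, length(x$concentrations),
              x$replicates, x$viability_noise_sd))
  cat(sprintf("  %d genes, %d true predictors | %d patients, HR %g at %gth pct, %g%% censoring\n",
              length(x$genes), length(x$true_predictors), x$n_patients,
              x$hazard_ratio, 100 * x$cutoff_percentile,
              100 * x$censoring_fraction))
  invisible(x)
}

#' Simulate a cytotoxicity screen
#'
#' Each cell line gets a 4PL curve with `a = 100`, `d` uniform over
#' `d_range`, midpoint `c` log-uniform over the dose range and slope `b`
#' uniform over `b_range`; observed percent growth is the curve plus
#' Gaussian replicate noise.
#'
#' @param config A [sim_config()].
#' @return List: `data` (tibble `cell_line`, `drug`, `concentration_uM`,
#'   `replicate`, `percent_growth`) and `truth` (per-line generating
#'   parameters with the closed-form true IC50).
#' @export
simulate_dose_response <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_cell_lines
    lines <- sprintf("CL%03d", seq_len(n))
    a <- rep(100, n)
    d <- runif(n, config$d_range[1], config$d_range[2])
    cc <- exp(runif(n, log(min(config$concentrations)),
                    log(max(config$concentrations))))
    b <- runif(n, config$b_range[1], config$b_range[2])
    truth <- tibble::tibble(
      cell_line = lines, a = a, d = d, c = cc, b = b,
      ic50_true = cc * ((a - 50) / (50 - d))^(1 / b)
    )
    data <- tidyr::expand_grid(
      cell_line = lines,
      concentration_uM = config$concentrations,
      replicate = seq_len(config$replicates)
    ) |>
      dplyr::left_join(truth, by = "cell_line") |>
      dplyr::mutate(
        percent_growth = fourpl(.data$concentration_uM, .data$a, .data$d,
                                .data$c, .data$b) +
          rnorm(dplyr::n(), 0, config$viability_noise_sd),
        drug = config$drug
      ) |>
      dplyr::select("cell_line", "drug", "concentration_uM", "replicate",
                    "percent_growth")
    list(data = data, truth = truth)
  })
}

#' Simulate an expression cohort with a linear IC50 signal
#'
#' Per-gene expression is Gaussian (means drawn uniformly over
#' `expression_mean_range`, common sd); IC50 is
#' `intercept + sum(coef_i * expr_i)` over the true predictors plus
#' Gaussian noise.
#'
#' @param config A [sim_config()].
#' @return List: `expression` (wide tibble `probe_id` x samples), `ic50`
#'   (tibble `cell_line`, `drug`, `ic50`) and `truth` (tibble `term`,
#'   `coefficient` with the intercept first, plus attribute-free `support`
#'   column flag).
#' @export
simulate_expression_ic50 <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    genes <- config$genes
    n <- config$n_cell_lines
    lines <- sprintf("CL%03d", seq_len(n))
    means <- runif(length(genes), config$expression_mean_range[1],
                   config$expression_mean_range[2])
    mat <- matrix(rnorm(length(genes) * n, mean = rep(means, n),
                        sd = config$expression_sd),
                  nrow = length(genes), dimnames = list(genes, lines))
    ic50 <- config$intercept +
      drop(crossprod(mat[config$true_predictors, , drop = FALSE],
                     config$coefficients)) +
      rnorm(n, 0, config$ic50_noise_sd)
    expression <- dplyr::bind_cols(tibble::tibble(probe_id = genes),
                                   tibble::as_tibble(mat))
    truth <- tibble::tibble(
      term = c("(Intercept)", config$true_predictors),
      coefficient = c(config$intercept, unname(config$coefficients)),
      support = c(FALSE, rep(TRUE, length(config$true_predictors)))
    )
    list(expression = expression,
         ic50 = tibble::tibble(cell_line = lines, drug = config$drug,
                               ic50 = unname(ic50)),
         truth = truth)
  })
}

# solve for the uniform-censoring horizon giving the target censored fraction:
# with C ~ U(0, tau) and T ~ Exp(rate_i), P(censored_i) = (1 - exp(-r tau))/(r tau)
censoring_horizon <- function(rates, fraction) {
  if (fraction <= 0) return(Inf)
  f <- function(tau) mean((1 - exp(-rates * tau)) / (rates * tau)) - fraction
  uniroot(f, lower = 1e-6, upper = 1e9, tol = 1e-10)$root
}

#' Simulate a survival cohort with a thresholded-expression hazard
#'
#' The driver gene's expression is Gaussian; patients at or above its
#' `cutoff_percentile` quantile have their exponential event rate
#' multiplied by `hazard_ratio`. Censoring is independent and uniform on
#' `(0, tau)` with `tau` solved so the expected censored fraction matches
#' `censoring_fraction`. Times are rounded up to whole days. Additional
#' `surv_genes` beyond the first are independent noise genes.
#'
#' @param config A [sim_config()].
#' @return List: `survival` (tibble `sample_id`, `time_days`, `event`),
#'   `expression` (tibble `sample_id` + one column per gene in
#'   `surv_genes`) and `truth` (driver gene, true cutoff, percentile,
#'   hazard ratio, baseline hazard, target censoring).
#' @export
simulate_survival_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_patients
    ids <- sprintf("P%04d", seq_len(n))
    genes <- config$surv_genes
    expr <- matrix(rnorm(n * length(genes), config$surv_expression_mean,
                         config$surv_expression_sd),
                   nrow = n, dimnames = list(ids, genes))
    driver <- expr[, 1]
    cutoff <- unname(quantile(driver, config$cutoff_percentile))
    high <- driver >= cutoff
    rates <- config$baseline_hazard * ifelse(high, config$hazard_ratio, 1)
    t_event <- rexp(n, rates)
    tau <- censoring_horizon(rates, config$censoring_fraction)
    t_cens <- if (is.finite(tau)) runif(n, 0, tau) else rep(Inf, n)
    time <- ceiling(pmin(t_event, t_cens))
    event <- as.integer(t_event <= t_cens)
    list(
      survival = tibble::tibble(sample_id = ids, time_days = as.numeric(time),
                                event = event),
      expression = dplyr::bind_cols(tibble::tibble(sample_id = ids),
                                    tibble::as_tibble(expr)),
      truth = tibble::tibble(
        gene = genes[1], cutoff = cutoff,
        cutoff_percentile = config$cutoff_percentile,
        hazard_ratio = config$hazard_ratio,
        baseline_hazard = config$baseline_hazard,
        target_censoring = config$censoring_fraction
      )
    )
  })
}
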