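# 6-model (6M) dose-response fitting.
#
# The working model is the four-parameter logistic (4PL)
#   Y(X) = d + (a - d) / (1 + (X / c)^b)
# with a = percent growth at zero dose, d = percent growth at infinite dose,
# c = dose at the midpoint between a and d, b = Hill slope. The 6M procedure
# fits six constrained variants (with/without a free slope, top fixed at 100,
# bottom fixed at 0) and keeps the one with the lowest residual standard
# error sqrt(RSS / (n - p)).

#' The six 4PL model variants fitted by the 6M procedure
#'
#' Returns the catalogue of constrained four-parameter-logistic variants:
#' `3P` variants fix the Hill slope at 1, `Top100` variants pin the zero-dose
#' asymptote `a` at 100% growth, `Bottom0` variants pin the infinite-dose
#' asymptote `d` at 0. `n_free` is the number of parameters estimated from
#' the data; it enters the residual-standard-error denominator and breaks
#' ties during model selection.
#'
#' @return A tibble with columns `variant`, `fixed_a`, `fixed_d`,
#'   `fit_slope`, `n_free`, in the order used for tie-breaking.
#' @export
#' @examples
#' model_variants()
model_variants <- function() {
  tibble::tibble(
    variant = c("3P", "3P-Top100", "3P-Bottom0", "4P", "4P-Top100", "4P-Bottom0"),
    fixed_a = c(NA, 100, NA, NA, 100, NA),
    fixed_d = c(NA, NA, 0, NA, NA, 0),
    fit_slope = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    n_free = c(3L, 2L, 2L, 4L, 3L, 3L)
  )
}

# the 4PL curve itself; x = 0 gives a for b > 0 since (0/c)^b = 0
fourpl <- function(x, a, d, c, b) d + (a - d) / (1 + (x / c)^b)

#' Convert raw viability signal to percent growth
#'
#' Percent growth is the treated signal relative to the untreated control,
#' both blank-corrected: `100 * (treated - blank) / (untreated - blank)`.
#' Values above 100 (growth stimulation) or below 0 (signal under blank)
#' are legitimate and preserved.
#'
#' @param treated Signal (e.g. luminescence) of the treated well(s).
#' @param untreated Signal of the matched untreated control.
#' @param blank Background signal; defaults to 0.
#' @return Percent growth, same length as `treated`.
#' @export
#' @examples
#' normalize_growth(450, 600) # 75
normalize_growth <- function(treated, untreated, blank = 0) {
  denom <- untreated - blank
  if (any(!is.finite(denom)) || any(denom <= 0)) {
    abort("unusable control well: `untreated - blank` must be positive and finite")
  }
  100 * (treated - blank) / denom
}

# accept a fourpl_fit, a sixm_fit (its best fit), or a plain list/vector
fit_params <- function(fit) {
  if (inherits(fit, "sixm_fit")) fit <- fit$best
  if (inherits(fit, "fourpl_fit")) {
    return(c(a = fit$a, d = fit$d, c = fit$c, b = fit$b))
  }
  fit <- as.list(fit)
  need <- c("a", "d", "c", "b")
  if (!all(need %in% names(fit))) {
    abort("`fit` must be a fourpl_fit/sixm_fit or carry named elements a, d, c, b")
  }
  vapply(fit[need], as.numeric, numeric(1))
}

#' Predicted percent growth at a dose
#'
#' Evaluates the fitted 4PL curve \eqn{\hat Y = d + (a-d)/(1+(X/c)^b)}.
#'
#' @param fit A `fourpl_fit`, a `sixm_fit`, or a list with elements
#'   `a`, `d`, `c`, `b`.
#' @param concentration Dose(s), in the same units as the fitted data
#'   (micromolar throughout the package); must be non-negative.
#' @return Predicted percent growth, vectorized over `concentration`.
#' @export
#' @examples
#' predict_growth(list(a = 100, d = 0, c = 5, b = 1), c(0, 5, 50))
predict_growth <- function(fit, concentration) {
  p <- fit_params(fit)
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    abort("`concentration` must be finite and non-negative")
  }
  if (p[["c"]] <= 0) abort("midpoint dose `c` must be positive")
  fourpl(concentration, p[["a"]], p[["d"]], p[["c"]], p[["b"]])
}

check_dr_data <- function(data, average_replicates = FALSE) {
  if (!is.data.frame(data)) abort("`data` must be a data frame")
  # tolerate the raw-CSV column names
  nm <- names(data)
  if (!"concentration" %in% nm && "concentration_uM" %in% nm) {
    data$concentration <- data$concentration_uM
  }
  if (!"growth" %in% nm && "percent_growth" %in% nm) {
    data$growth <- data$percent_growth
  }
  if (!all(c("concentration", "growth") %in% names(data))) {
    abort("`data` needs columns `concentration` (or `concentration_uM`) and `growth` (or `percent_growth`)")
  }
  x <- data$concentration
  y <- data$growth
  if (any(!is.finite(x)) || any(x <= 0)) abort("concentrations must be finite and > 0")
  if (any(!is.finite(y))) abort("growth values must be finite")
  out <- tibble::tibble(concentration = x, growth = y)
  if (average_replicates) {
    out <- out |>
      dplyr::group_by(.data$concentration) |>
      dplyr::summarise(growth = mean(.data$growth), .groups = "drop")
  }
  out
}

# deterministic multi-start schedule: base start plus 4 jittered restarts
# (scales on c and b; no RNG involved, so fits are reproducible by construction)
start_schedule <- function() {
  list(
    c(c_fac = 1,    b_fac = 1),
    c(c_fac = 0.25, b_fac = 1),
    c(c_fac = 4,    b_fac = 1),
    c(c_fac = 1,    b_fac = 0.5),
    c(c_fac = 1,    b_fac = 2)
  )
}

#' Fit one constrained 4PL variant
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nls.lm()]) for a single model variant, honouring its fixed
#' parameters exactly. `c` and (when free) `b` are estimated on the log
#' scale; bounds are `a, d` in \[-100, 300\], `c` in (0, 1000 x max dose\],
#' `b` in \[0.05, 20\]. A fixed five-point multi-start schedule (base start
#' `a = max Y`, `d = min Y`, `c` = geometric mean dose, `b = 1`, plus four
#' deterministic jitters of `c` and `b`) guards against local minima.
#'
#' @param data Data frame with columns `concentration` (>0, micromolar) and
#'   `growth` (percent growth; `concentration_uM`/`percent_growth` also
#'   accepted). Replicates are fitted as individual points unless
#'   `average_replicates = TRUE`.
#' @param variant One of `model_variants()$variant`.
#' @param average_replicates Average growth within each concentration first?
#' @return A `fourpl_fit`: parameters `a`, `d`, `c`, `b`, the residual
#'   standard error `rse = sqrt(RSS/(n - p))`, `rss`, `n_points`, `n_free`,
#'   and a `converged` flag.
#' @export
#' @examples
#' pts <- tibble::tibble(
#'   concentration = c(20, 10, 2, 1, 0.2, 0.1),
#'   growth = predict_growth(list(a = 100, d = 0, c = 2, b = 1), c(20, 10, 2, 1, 0.2, 0.1))
#' )
#' fit_variant(pts, "4P")
fit_variant <- function(data, variant = "4P", average_replicates = FALSE) {
  vt <- model_variants()
  if (!is.character(variant) || length(variant) != 1 || !variant %in% vt$variant) {
    abort(paste0("`variant` must be one of: ", paste(vt$variant, collapse = ", ")))
  }
  v <- vt[vt$variant == variant, ]
  data <- check_dr_data(data, average_replicates)
  x <- data$concentration
  y <- data$growth
  n <- length(y)
  p <- v$n_free
  if (n < p + 1) {
    abort(sprintf("variant %s estimates %d parameters and needs at least %d points (got %d)",
                  variant, p, p + 1, n))
  }
  if (length(unique(x)) < 2) abort("need at least 2 distinct concentrations")
  if (sd(y) == 0 && v$fit_slope) {
    abort(sprintf("degenerate fit: growth is constant, slope of variant %s is not identifiable", variant))
  }

  free_a <- is.na(v$fixed_a)
  free_d <- is.na(v$fixed_d)
  free_b <- v$fit_slope
  a_fix <- if (free_a) NA_real_ else v$fixed_a
  d_fix <- if (free_d) NA_real_ else v$fixed_d

  unpack <- function(theta) {
    c(a = if (free_a) theta[["a"]] else a_fix,
      d = if (free_d) theta[["d"]] else d_fix,
      c = exp(theta[["logc"]]),
      b = if (free_b) exp(theta[["logb"]]) else 1)
  }
  resid_fn <- function(theta) {
    q <- unpack(theta)
    y - fourpl(x, q[["a"]], q[["d"]], q[["c"]], q[["b"]])
  }

  c_lo <- min(x) / 1000
  c_hi <- max(x) * 1000
  lower <- c(a = -100, d = -100, logc = log(c_lo), logb = log(0.05))
  upper <- c(a = 300, d = 300, logc = log(c_hi), logb = log(20))
  keep <- c(a = free_a, d = free_d, logc = TRUE, logb = free_b)

  base_start <- c(a = max(y), d = min(y), logc = mean(log(x)), logb = 0)
  best <- NULL
  for (jit in start_schedule()) {
    st <- base_start
    st[["logc"]] <- base_start[["logc"]] + log(jit[["c_fac"]])
    st[["logb"]] <- base_start[["logb"]] + log(jit[["b_fac"]])
    st <- pmin(pmax(st, lower), upper)
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = st[keep], lower = lower[keep], upper = upper[keep],
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12, ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    ok <- res$info %in% 1:4
    dev <- res$deviance
    if (is.null(best) || (ok && !best$ok) || (ok == best$ok && dev < best$dev)) {
      best <- list(par = res$par, dev = dev, ok = ok)
    }
  }
  if (is.null(best)) {
    abort(sprintf("optimizer failed for variant %s on all starts", variant))
  }
  q <- unpack(best$par)
  rss <- best$dev
  structure(
    list(
      variant = variant,
      a = unname(q[["a"]]), d = unname(q[["d"]]),
      c = unname(q[["c"]]), b = unname(q[["b"]]),
      n_free = p, n_points = n,
      rss = rss, rse = sqrt(rss / (n - p)),
      converged = best$ok,
      data = data
    ),
    class = "fourpl_fit"
  )
}

#' Fit all six 4PL variants and select the lowest-RSE model (6M)
#'
#' Fits every variant in [model_variants()] and returns the converged fit
#' with the smallest residual standard error. Fits whose RSE is within
#' `1e-9` of the minimum are treated as tied; ties resolve toward fewer free
#' parameters, then toward the catalogue order.
#'
#' @inheritParams fit_variant
#' @param allow_flat With constant growth at every dose no curve is
#'   informative; by default this errors. `allow_flat = TRUE` instead
#'   returns a flat fit flagged `flat = TRUE`.
#' @return A `sixm_fit`: `best` (the selected `fourpl_fit`), `fits` (all
#'   attempts, named by variant), and `summary` (per-variant tibble with
#'   parameters, RSS, RSE, convergence, failure reason and the selection
#'   flag). `tidy()` returns the summary, `glance()` the selected fit.
#' @export
#' @examples
#' x <- c(20, 10, 2, 1, 0.2, 0.1)
#' pts <- tibble::tibble(concentration = rep(x, 2),
#'                       growth = predict_growth(list(a = 100, d = 0, c = 2, b = 1), rep(x, 2)))
#' fit_6m(pts)$best$variant
fit_6m <- function(data, average_replicates = FALSE, allow_flat = FALSE) {
  data <- check_dr_data(data, average_replicates)
  if (sd(data$growth) == 0) {
    if (!allow_flat) {
      abort("non-informative dose-response: growth is identical at every dose (use `allow_flat = TRUE` to get a flagged flat fit)")
    }
    flat <- structure(
      list(variant = "3P", a = data$growth[1], d = data$growth[1],
           c = exp(mean(log(data$concentration))), b = 1,
           n_free = 3L, n_points = nrow(data), rss = 0, rse = 0,
           converged = TRUE, flat = TRUE, data = data),
      class = "fourpl_fit"
    )
    warn("flat (non-informative) dose-response; returning degenerate fit")
    return(structure(
      list(best = flat, fits = list(`3P` = flat),
           summary = tidy_fit_row(flat) |> dplyr::mutate(selected = TRUE, reason = "flat")),
      class = "sixm_fit"
    ))
  }

  vt <- model_variants()
  fits <- vector("list", nrow(vt))
  names(fits) <- vt$variant
  reasons <- rep(NA_character_, nrow(vt))
  for (i in seq_len(nrow(vt))) {
    fits[[i]] <- tryCatch(
      fit_variant(data, vt$variant[i]),
      error = function(e) {
        reasons[i] <<- conditionMessage(e)
        NULL
      }
    )
  }
  conv <- vapply(fits, function(f) !is.null(f) && isTRUE(f$converged), logical(1))
  if (!any(conv)) {
    abort(paste0(
      "no 4PL variant converged:\n",
      paste(sprintf("  %s: %s", vt$variant,
                    ifelse(is.na(reasons), "did not converge", reasons)),
            collapse = "\n")
    ))
  }
  rse <- vapply(fits, function(f) if (is.null(f)) Inf else f$rse, numeric(1))
  rse[!conv] <- Inf
  rmin <- min(rse)
  tied <- which(rse <= rmin + 1e-9)
  sel <- tied[order(vt$n_free[tied], tied)][1]

  summ <- purrr::map_dfr(seq_along(fits), function(i) {
    if (is.null(fits[[i]])) {
      tibble::tibble(variant = vt$variant[i], a = NA_real_, d = NA_real_,
                     c = NA_real_, b = NA_real_, n_free = vt$n_free[i],
                     rss = NA_real_, rse = NA_real_, converged = FALSE,
                     reason = reasons[i])
    } else {
      tidy_fit_row(fits[[i]]) |>
        dplyr::mutate(reason = if (conv[i]) NA_character_ else "did not converge")
    }
  }) |>
    dplyr::mutate(selected = dplyr::row_number() == sel)

  structure(list(best = fits[[sel]], fits = fits, summary = summ),
            class = "sixm_fit")
}

tidy_fit_row <- function(f) {
  tibble::tibble(variant = f$variant, a = f$a, d = f$d, c = f$c, b = f$b,
                 n_free = f$n_free, rss = f$rss, rse = f$rse,
                 converged = f$converged)
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("<fourpl_fit> variant %s (%d points, %d free parameters)\n",
              x$variant, x$n_points, x$n_free))
  cat(sprintf("  a = %.4g  d = %.4g  c = %.4g  b = %.4g\n", x$a, x$d, x$c, x$b))
  cat(sprintf("  rse = %.4g  converged = %s\n", x$rse, x$converged))
  invisible(x)
}

#' @export
print.sixm_fit <- function(x, ...) {
  cat(sprintf("<sixm_fit> selected variant: %s (rse = %.4g)\n",
              x$best$variant, x$best$rse))
  print(x$summary, ...)
  invisible(x)
}

#' @method tidy fourpl_fit
#' @export
tidy.fourpl_fit <- function(x, ...) tidy_fit_row(x)

#' @method glance fourpl_fit
#' @export
glance.fourpl_fit <- function(x, ...) tidy_fit_row(x)

#' @method tidy sixm_fit
#' @export
tidy.sixm_fit <- function(x, ...) x$summary

#' @method glance sixm_fit
#' @export
glance.sixm_fit <- function(x, ...) tidy_fit_row(x$best)

#' Derived drug-response parameters from a fitted curve
#'
#' Computes the six response metrics of the 6M workflow, in closed form from
#' the fitted parameters:
#' * `icXX`: the dose where predicted percent growth equals the target,
#'   `X = c * ((a - t)/(t - d))^(1/b)`; `NA` ("not reached") when the target
#'   lies outside the open interval between the asymptotes. Targets are the
#'   literal growth percentages 50/90/95; `convention = "inhibition"`
#'   instead targets 50/90/95 percent inhibition (growth 50/10/5).
#' * `ec50`: the dose at the curve midpoint \eqn{(a+d)/2}, i.e. `c`.
#' * `amax`: the effect span `a - d`.
#' * `activity_area`: the sum of predicted growth over the arithmetic dose
#'   grid `dose_min, dose_min + 0.01, ..., dose_max` (a Riemann sum, not
#'   scaled by the step).
#'
#' @param fit A `fourpl_fit`, `sixm_fit`, or list with `a`, `d`, `c`, `b`.
#' @param dose_min,dose_max Grid limits in micromolar; default to the tested
#'   concentration range when `fit` carries its data.
#' @param convention `"growth"` (default, literal growth targets) or
#'   `"inhibition"`.
#' @param grid_step Grid increment for the activity area (default 0.01).
#' @return One-row tibble with `ic50`, `ic90`, `ic95`, `ec50`, `amax`,
#'   `activity_area`, plus the grid limits and convention used.
#' @export
#' @examples
#' response_metrics(list(a = 100, d = 0, c = 5, b = 1), 0.1, 20)
response_metrics <- function(fit, dose_min = NULL, dose_max = NULL,
                             convention = c("growth", "inhibition"),
                             grid_step = 0.01) {
  convention <- match.arg(convention)
  p <- fit_params(fit)
  a <- p[["a"]]; d <- p[["d"]]; cc <- p[["c"]]; b <- p[["b"]]
  if (b == 0) abort("ICxx undefined: Hill slope is zero")
  f <- if (inherits(fit, "sixm_fit")) fit$best else fit
  if (is.null(dose_min) || is.null(dose_max)) {
    if (inherits(f, "fourpl_fit") && !is.null(f$data)) {
      dose_min <- dose_min %||% min(f$data$concentration)
      dose_max <- dose_max %||% max(f$data$concentration)
    } else {
      abort("supply `dose_min` and `dose_max` (fit carries no data)")
    }
  }
  if (!(dose_min > 0 && dose_max > dose_min)) {
    abort("need 0 < dose_min < dose_max")
  }

  ic_at <- function(target) {
    lo <- min(a, d); hi <- max(a, d)
    if (!(target > lo && target < hi)) return(NA_real_)
    cc * ((a - target) / (target - d))^(1 / b)
  }
  targets <- if (convention == "growth") c(50, 90, 95) else c(50, 10, 5)

  n_steps <- floor((dose_max - dose_min) / grid_step + 1e-9)
  grid <- dose_min + grid_step * seq(0, n_steps)
  tibble::tibble(
    ic50 = ic_at(targets[1]),
    ic90 = ic_at(targets[2]),
    ic95 = ic_at(targets[3]),
    ec50 = cc,
    amax = a - d,
    activity_area = sum(fourpl(grid, a, d, cc, b)),
    dose_min = dose_min, dose_max = dose_max,
    convention = convention
  )
}

#' Fit the 6M model per cell line and drug
#'
#' Convenience wrapper for screening tables: groups by `cell_line` and
#' `drug`, runs [fit_6m()] on each group and appends [response_metrics()].
#'
#' @param data Tibble with columns `cell_line`, `drug`,
#'   `concentration_uM` (or `concentration`) and `percent_growth`
#'   (or `growth`).
#' @param drug Optional drug name to restrict to.
#' @inheritParams fit_variant
#' @inheritParams response_metrics
#' @return Tibble with one row per (cell line, drug): selected variant,
#'   parameters, RSE, the response metrics, and the full `sixm_fit` in the
#'   list-column `fit`.
#' @export
fit_drug_response <- function(data, drug = NULL, average_replicates = FALSE,
                              convention = c("growth", "inhibition")) {
  convention <- match.arg(convention)
  if (!all(c("cell_line", "drug") %in% names(data))) {
    abort("`data` needs `cell_line` and `drug` columns")
  }
  if (!is.null(drug)) {
    data <- data[data$drug %in% drug, , drop = FALSE]
    if (nrow(data) == 0) abort(sprintf("drug '%s' not found in the input", drug))
  }
  data |>
    dplyr::group_by(.data$cell_line, .data$drug) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::mutate(
      fit = purrr::map(.data$data, fit_6m, average_replicates = average_replicates),
      row = purrr::map2(.data$fit, .data$data, function(f, d) {
        dplyr::bind_cols(
          tidy_fit_row(f$best),
          response_metrics(f, convention = convention)
        )
      })
    ) |>
    dplyr::select(-"data") |>
    tidyr::unnest("row") |>
    dplyr::relocate("fit", .after = dplyr::last_col())
}

#' Diagnostic plot of a 6M fit
#'
#' Observed percent growth against dose (log10 axis) with the selected
#' curve overlaid.
#'
#' @param object A `sixm_fit` or `fourpl_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sixm_fit
#' @export
autoplot.sixm_fit <- function(object, ...) autoplot(object$best, ...)

#' @rdname autoplot.sixm_fit
#' @method autoplot fourpl_fit
#' @export
autoplot.fourpl_fit <- function(object, ...) {
  dat <- object$data
  grid <- exp(seq(log(min(dat$concentration)), log(max(dat$concentration)),
                  length.out = 200))
  curve <- tibble::tibble(concentration = grid,
                          growth = predict_growth(object, grid))
  ggplot2::ggplot(dat, ggplot2::aes(.data$concentration, .data$growth)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (µM)", y = "percent growth",
                  title = sprintf("%s fit (rse = %.3g)", object$variant, object$rse))
}
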