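# Expression -> IC50 linear modelling: OLS fits, exhaustive best-subsets
# selection by adjusted R^2, prediction from the stored formula, Sy.x
# goodness of fit, and repeated random discovery/test splitting.

# core OLS on a predictor matrix (no intercept column); returns NULL-free list
ols_fit <- function(X, y) {
  n <- length(y)
  k <- ncol(X)
  Xi <- cbind(`(Intercept)` = 1, X)
  ft <- lm.fit(Xi, y)
  aliased <- names(ft$coefficients)[is.na(ft$coefficients)]
  if (length(aliased)) {
    return(list(ok = FALSE, aliased = aliased))
  }
  res <- ft$residuals
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) abort("response is constant: R^2 undefined")
  r2 <- 1 - rss / tss
  list(
    ok = TRUE,
    coef = ft$coefficients,
    fitted = ft$fitted.values,
    residuals = res,
    rss = rss,
    r2 = r2,
    r2_adj = 1 - (1 - r2) * (n - 1) / (n - k - 1),
    sigma = sqrt(rss / (n - k - 1)),
    n = n, k = k
  )
}

get_xy <- function(data, response, predictors) {
  missing <- setdiff(c(response, predictors), names(data))
  if (length(missing)) {
    abort(paste0("columns not in `data`: ", paste(missing, collapse = ", ")))
  }
  y <- as.numeric(data[[response]])
  X <- as.matrix(data[predictors])
  if (!is.numeric(X)) abort("predictors must be numeric")
  if (any(!is.finite(X)) || any(!is.finite(y))) abort("predictors and response must be finite")
  list(X = X, y = y)
}

#' Ordinary least squares regression of IC50 on gene expression
#'
#' Fits `response = a + sum(n_i * x_i)` by OLS and reports the coefficient
#' of determination and its adjusted form
#' `r2_adj = 1 - (1 - r2) (n - 1)/(n - k - 1)`.
#'
#' @param data Tibble with one row per sample.
#' @param response Name of the response column (IC50).
#' @param predictors Character vector of predictor column names (gene
#'   expression); defaults to every other numeric column.
#' @return A `ras_lm`: intercept, named `coefficients`, `r2`, `r2_adj`,
#'   `sigma`, `n`, `k`, fitted values and residuals. `tidy()` gives the
#'   term/estimate table, `glance()` the fit statistics.
#' @export
fit_linear <- function(data, response, predictors = NULL) {
  if (is.null(predictors)) {
    predictors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], response)
  }
  xy <- get_xy(data, response, predictors)
  n <- length(xy$y)
  k <- length(predictors)
  if (n <= k + 1) {
    abort(sprintf("need n > k + 1 samples (n = %d, k = %d)", n, k))
  }
  ft <- ols_fit(xy$X, xy$y)
  if (!ft$ok) {
    abort(paste0("rank-deficient design; collinear predictor(s): ",
                 paste(ft$aliased, collapse = ", ")))
  }
  structure(
    list(response = response, predictors = predictors,
         intercept = unname(ft$coef[1]),
         coefficients = setNames(unname(ft$coef[-1]), predictors),
         r2 = ft$r2, r2_adj = ft$r2_adj, sigma = ft$sigma,
         n = n, k = k,
         fitted = unname(ft$fitted), residuals = unname(ft$residuals)),
    class = "ras_lm"
  )
}

#' @export
print.ras_lm <- function(x, ...) {
  terms <- sprintf("[%.4g x %s]", x$coefficients, names(x$coefficients))
  cat(sprintf("<ras_lm> %s = %.4g + %s\n", x$response, x$intercept,
              paste(terms, collapse = " + ")))
  cat(sprintf("  n = %d, k = %d, R2 = %.4f, adj R2 = %.4f\n",
              x$n, x$k, x$r2, x$r2_adj))
  invisible(x)
}

#' @method tidy ras_lm
#' @export
tidy.ras_lm <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' @method glance ras_lm
#' @export
glance.ras_lm <- function(x, ...) {
  tibble::tibble(r2 = x$r2, r2_adj = x$r2_adj, sigma = x$sigma,
                 n = x$n, k = x$k)
}

#' Exhaustive best-subsets regression
#'
#' Enumerates every non-empty subset of the candidate predictors
#' (`2^m - 1` models), fits each by OLS, and selects the subset with the
#' highest adjusted R^2 (ties go to the smaller subset, then enumeration
#' order). Rank-deficient subsets and subsets with too few residual degrees
#' of freedom are skipped with a warning.
#'
#' @inheritParams fit_linear
#' @param max_predictors Combinatorial guard; more candidates than this is
#'   refused (default 20).
#' @return A `best_subsets` object: `subsets` (tibble of every fitted
#'   subset: `size`, `predictors`, `terms` list-column, `r2`, `r2_adj`),
#'   `best_by_size`, `best_model` (the winning subset refitted as a
#'   `ras_lm`), and `n_enumerated`. `tidy()` gives `subsets`, `glance()`
#'   the winner.
#' @export
best_subsets <- function(data, response, predictors = NULL, max_predictors = 20) {
  if (is.null(predictors)) {
    predictors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], response)
  }
  m <- length(predictors)
  if (m < 1) abort("need at least one candidate predictor")
  if (m > max_predictors) {
    abort(sprintf("%d candidate predictors exceed the guard of %d (raise `max_predictors` deliberately)",
                  m, max_predictors))
  }
  xy <- get_xy(data, response, predictors)
  n <- length(xy$y)

  rows <- vector("list", 2^m - 1)
  skipped <- character(0)
  idx <- 0L
  for (size in seq_len(m)) {
    for (cols in combn(m, size, simplify = FALSE)) {
      idx <- idx + 1L
      terms <- predictors[cols]
      label <- paste(terms, collapse = "+")
      if (n <= size + 1) {
        skipped <- c(skipped, label)
        next
      }
      ft <- ols_fit(xy$X[, cols, drop = FALSE], xy$y)
      if (!ft$ok) {
        skipped <- c(skipped, label)
        next
      }
      rows[[idx]] <- tibble::tibble(
        id = idx, size = size, predictors = label, terms = list(terms),
        r2 = ft$r2, r2_adj = ft$r2_adj
      )
    }
  }
  subsets <- dplyr::bind_rows(rows)
  if (length(skipped)) {
    warn(paste0("skipped ", length(skipped), " unfittable subset(s): ",
                paste(head(skipped, 5), collapse = "; "),
                if (length(skipped) > 5) " ..." else ""))
  }
  if (nrow(subsets) == 0) abort("no fittable subset")
  ord <- order(-subsets$r2_adj, subsets$size, subsets$id)
  winner <- subsets[ord[1], ]
  best_by_size <- subsets |>
    dplyr::arrange(.data$size, dplyr::desc(.data$r2_adj), .data$id) |>
    dplyr::distinct(.data$size, .keep_all = TRUE)
  best_model <- fit_linear(data, response, winner$terms[[1]])
  structure(
    list(subsets = subsets, best_by_size = best_by_size,
         best_model = best_model, response = response,
         candidates = predictors, n_enumerated = idx,
         n_fitted = nrow(subsets)),
    class = "best_subsets"
  )
}

#' @export
print.best_subsets <- function(x, ...) {
  cat(sprintf("<best_subsets> %d/%d subsets of %d candidates fitted\n",
              x$n_fitted, x$n_enumerated, length(x$candidates)))
  cat("winner by adjusted R2:\n")
  print(x$best_model)
  invisible(x)
}

#' @method tidy best_subsets
#' @export
tidy.best_subsets <- function(x, ...) x$subsets

#' @method glance best_subsets
#' @export
glance.best_subsets <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(predictors = paste(x$best_model$predictors, collapse = "+")),
    glance(x$best_model)
  )
}

#' Predict IC50 from a stored regression formula
#'
#' Applies `y = a + sum(n_i * x_i)` to new samples.
#'
#' @param model A `ras_lm` or `best_subsets` (its winning model is used).
#' @param newdata Data frame providing every predictor column.
#' @return Numeric vector of predictions.
#' @export
predict_from_model <- function(model, newdata) {
  if (inherits(model, "best_subsets")) model <- model$best_model
  if (!inherits(model, "ras_lm")) abort("`model` must be a ras_lm or best_subsets")
  missing <- setdiff(model$predictors, names(newdata))
  if (length(missing)) {
    abort(paste0("missing predictor(s): ", paste(missing, collapse = ", ")))
  }
  X <- as.matrix(newdata[model$predictors])
  unname(drop(model$intercept + X %*% model$coefficients))
}

#' @export
predict.ras_lm <- function(object, newdata, ...) predict_from_model(object, newdata)

#' Goodness of fit between observed and predicted response
#'
#' `sy_x = sqrt(sum((obs - pred)^2) / (n - 2))`, the standard deviation of
#' the residuals, and `r_sq`, the squared Pearson correlation between
#' observed and predicted values.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 3).
#' @return One-row tibble: `r_sq`, `sy_x`, `n`.
#' @export
goodness_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted)) abort("length mismatch")
  n <- length(observed)
  if (n < 3) abort("need at least 3 pairs")
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) abort("values must be finite")
  if (sd(observed) == 0 || sd(predicted) == 0) {
    abort("constant observed or predicted values: r_sq undefined")
  }
  tibble::tibble(
    r_sq = cor(observed, predicted)^2,
    sy_x = sqrt(sum((observed - predicted)^2) / (n - 2)),
    n = n
  )
}

#' Range-spanning discovery/test split
#'
#' Deterministic alternative to a random split: samples are ranked by the
#' response and evenly spaced interior ranks go to the test group, so both
#' groups cover the response range (the extremes stay in the discovery
#' group).
#'
#' @param data Tibble, one row per sample.
#' @param response Response column name.
#' @param test_n Test-group size (default 5).
#' @return List with integer row indices `discovery` and `test`.
#' @export
range_spanning_split <- function(data, response, test_n = 5) {
  n <- nrow(data)
  if (n < test_n + 2) abort("cohort too small for a range-spanning split")
  ord <- order(data[[response]])
  pos <- unique(round(seq(2, n - 1, length.out = test_n)))
  test <- sort(ord[pos])
  list(discovery = setdiff(seq_len(n), test), test = test)
}

#' Repeated random discovery/test cross-validation
#'
#' Randomly splits the cohort into discovery and test groups `n_repeats`
#' times (seeded, without replacement), fits the full predictor set on each
#' discovery group, records the discovery-fit adjusted R^2 (the headline
#' figure of merit) and the held-out goodness of fit of the formula applied
#' to the test group.
#'
#' @inheritParams fit_linear
#' @param n_repeats Number of random splits (default 10).
#' @param discovery_n,test_n Group sizes; must sum to `nrow(data)`
#'   (defaults 12 and 5).
#' @param seed Integer seed; the same seed reproduces the splits exactly.
#' @return A `cv_result`: `results` (per-repeat tibble with `r2_adj`,
#'   held-out `test_r_sq`, `test_sy_x` and the split indices),
#'   `mean_r2_adj`, `mean_test_r_sq`. `tidy()` gives `results`, `glance()`
#'   the means.
#' @export
cross_validate <- function(data, response, predictors = NULL, n_repeats = 10,
                           discovery_n = 12, test_n = 5, seed = 1) {
  n <- nrow(data)
  if (n != discovery_n + test_n) {
    abort(sprintf("cohort has %d samples but discovery_n + test_n = %d",
                  n, discovery_n + test_n))
  }
  if (is.null(predictors)) {
    predictors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], response)
  }
  splits <- withr::with_seed(seed, {
    purrr::map(seq_len(n_repeats), function(i) sort(sample.int(n, test_n)))
  })
  results <- purrr::imap_dfr(splits, function(test_idx, i) {
    disc_idx <- setdiff(seq_len(n), test_idx)
    fit <- fit_linear(data[disc_idx, , drop = FALSE], response, predictors)
    pred <- predict_from_model(fit, data[test_idx, , drop = FALSE])
    gof <- goodness_of_fit(as.numeric(data[[response]][test_idx]), pred)
    tibble::tibble(
      repeat_id = i, r2 = fit$r2, r2_adj = fit$r2_adj,
      test_r_sq = gof$r_sq, test_sy_x = gof$sy_x,
      discovery = list(disc_idx), test = list(test_idx)
    )
  })
  structure(
    list(results = results,
         mean_r2_adj = mean(results$r2_adj),
         mean_test_r_sq = mean(results$test_r_sq),
         n_repeats = n_repeats, seed = seed,
         response = response, predictors = predictors),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d random %d/%d splits (seed %s)\n",
              x$n_repeats,
              length(x$results$discovery[[1]]), length(x$results$test[[1]]),
              format(x$seed)))
  cat(sprintf("  mean discovery adj R2 = %.4f, mean held-out R sq. = %.4f\n",
              x$mean_r2_adj, x$mean_test_r_sq))
  invisible(x)
}

#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$results

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(mean_r2_adj = x$mean_r2_adj,
                 mean_test_r_sq = x$mean_test_r_sq,
                 n_repeats = x$n_repeats, seed = x$seed)
}
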