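# 4PL curve evaluation, per-variant fitting and 6M model selection.

test_that("percent-growth normalization follows the blank-corrected ratio", {
  expect_equal(normalize_growth(600, 600), 100)
  expect_equal(normalize_growth(50, 600, blank = 50), 0)
  expect_equal(normalize_growth(450, 600), 75)
  expect_equal(normalize_growth(c(450, 300), c(600, 600)), c(75, 50))
  expect_error(normalize_growth(10, 5, blank = 5), "control")
  expect_error(normalize_growth(10, 4, blank = 5), "control")
})

test_that("predicted growth honours the 4PL limits and midpoint", {
  f <- list(a = 100, d = 0, c = 5, b = 1)
  expect_equal(predict_growth(f, 5), 50)
  expect_equal(predict_growth(f, 0), 100)
  expect_equal(predict_growth(list(a = 100, d = 0, c = 5, b = 2), 10), 20)
  # midpoint is (a+d)/2 for any asymptotes
  expect_equal(predict_growth(list(a = 120, d = 20, c = 3, b = 1.7), 3), 70)
  expect_error(predict_growth(f, -1), "non-negative")
})

test_that("4PL prediction is strictly decreasing for b > 0, a > d", {
  withr::with_seed(7, {
    for (i in 1:20) {
      f <- list(a = runif(1, 80, 120), d = runif(1, -10, 40),
                c = exp(runif(1, log(0.1), log(20))), b = runif(1, 0.2, 5))
      x <- sort(exp(runif(50, log(0.01), log(100))))
      y <- predict_growth(f, x)
      expect_true(all(diff(y) < 0))
    }
  })
})

test_that("noise-free curves are recovered exactly by the matching variant", {
  pts <- make_curve_points(100, 0, 2, 1)
  f <- fit_variant(pts, "4P")
  expect_true(f$converged)
  expect_equal(c(f$a, f$d, f$c, f$b), c(100, 0, 2, 1), tolerance = 1e-4)
  expect_lt(f$rse, 1e-6)

  f100 <- fit_variant(pts, "4P-Top100")
  expect_identical(f100$a, 100)         # constraint honoured exactly
  f0 <- fit_variant(pts, "4P-Bottom0")
  expect_identical(f0$d, 0)
  f3 <- fit_variant(pts, "3P")
  expect_identical(f3$b, 1)             # 3P variants never estimate the slope
})

test_that("fitting refuses under-determined or degenerate inputs", {
  pts <- make_curve_points(100, 0, 2, 1, reps = 1)
  expect_error(fit_variant(pts[1:4, ], "4P"), "at least 5 points")
  expect_error(fit_variant(pts[1:2, ], "3P"), "at least 4 points")
  one_dose <- tibble::tibble(concentration = rep(2, 6), growth = rnorm(6, 50))
  expect_error(fit_variant(one_dose, "4P"), "distinct concentrations")
  flat <- tibble::tibble(concentration = rep(six_doses, 2), growth = rep(100, 12))
  expect_error(fit_variant(flat, "4P"), "degenerate")
  expect_error(fit_6m(flat), "non-informative")
  expect_warning(res <- fit_6m(flat, allow_flat = TRUE), "flat")
  expect_true(isTRUE(res$best$flat))
})

test_that("noisy 4P fit is at least as good as a coarse grid-search oracle", {
  withr::with_seed(11, {
    pts <- make_curve_points(100, 5, 1.5, 1.2, noise_sd = 5)
  })
  fit <- fit_variant(pts, "4P")
  # independent coarse oracle: exhaustive RSS over a parameter grid
  grid <- expand.grid(a = seq(80, 120, by = 2.5), d = seq(-10, 30, by = 2.5),
                      c = exp(seq(log(0.1), log(20), length.out = 25)),
                      b = seq(0.3, 3, by = 0.15))
  rss_grid <- vapply(seq_len(nrow(grid)), function(i) {
    with(grid[i, ], sum((pts$growth - (d + (a - d) / (1 + (pts$concentration / c)^b)))^2))
  }, numeric(1))
  expect_lte(fit$rss, min(rss_grid) + 1e-8)
  # and the optimum sits in the same region as the oracle's best cell
  best <- grid[which.min(rss_grid), ]
  expect_lt(abs(log(fit$c / best$c)), log(4))
})

test_that("6M selects the minimal-RSE converged variant and reproduces exact data", {
  # noise-free data from each variant archetype is reproduced to < 1e-4
  cases <- list(c(a = 100, d = 0, c = 2, b = 1),    # 3P-Bottom0/Top100 territory
                c(a = 100, d = 20, c = 5, b = 1),   # Top100, unit slope
                c(a = 90, d = 10, c = 0.5, b = 2),  # full 4P
                c(a = 95, d = 0, c = 3, b = 0.8))   # 4P-Bottom0
  for (p in cases) {
    pts <- make_curve_points(p["a"], p["d"], p["c"], p["b"], reps = 2)
    res <- fit_6m(pts)
    grid <- exp(seq(log(0.1), log(20), length.out = 100))
    truth <- p["d"] + (p["a"] - p["d"]) / (1 + (grid / p["c"])^p["b"])
    expect_lt(max(abs(predict_growth(res, grid) - truth)), 1e-4)
  }
})

test_that("6M selection is optimal and free fits never lose on RSS", {
  withr::with_seed(23, {
    for (i in 1:30) {
      a <- runif(1, 90, 110); d <- runif(1, 0, 30)
      cc <- exp(runif(1, log(0.2), log(10))); b <- runif(1, 0.5, 3)
      pts <- make_curve_points(a, d, cc, b, noise_sd = 5)
      res <- fit_6m(pts)
      conv <- dplyr::filter(res$summary, converged)
      # winner has minimal rse among all converged variants
      expect_lte(res$best$rse, min(conv$rse) + 1e-9)
      # nesting on RSS (not RSE): the free 4P fit beats every constrained fit
      if ("4P" %in% conv$variant) {
        rss_4p <- conv$rss[conv$variant == "4P"]
        expect_true(all(rss_4p <= conv$rss + 1e-8 * pmax(1, conv$rss)))
      }
    }
  })
})

test_that("replicates are fitted as points unless averaging is requested", {
  withr::with_seed(31, {
    pts <- make_curve_points(100, 0, 2, 1, reps = 3, noise_sd = 5)
  })
  f_all <- fit_variant(pts, "4P")
  f_avg <- fit_variant(pts, "4P", average_replicates = TRUE)
  expect_identical(f_all$n_points, nrow(pts))
  expect_identical(f_avg$n_points, length(six_doses))
})

test_that("fit_drug_response maps the 6M fit over cell line x drug groups", {
  sc <- sim_config(seed = 5, n_cell_lines = 3, viability_noise_sd = 0)
  dr <- simulate_dose_response(sc)
  out <- fit_drug_response(dr$data)
  expect_identical(nrow(out), 3L)
  expect_true(all(c("variant", "rse", "ic50", "activity_area", "fit") %in% names(out)))
  joined <- dplyr::inner_join(out, dr$truth, by = "cell_line")
  expect_equal(joined$ic50, joined$ic50_true, tolerance = 1e-3)
  expect_error(fit_drug_response(dr$data, drug = "nonexistent"), "not found")
})
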