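# OLS fitting, exhaustive best-subsets selection, prediction, Sy.x and
# repeated discovery/test cross-validation.

test_that("OLS recovers exact linear relationships and matches normal equations", {
  d <- tibble::tibble(x = 1:8, y = 2 * (1:8) + 1)
  f <- fit_linear(d, "y", "x")
  expect_equal(f$intercept, 1)
  expect_equal(unname(f$coefficients), 2)
  expect_equal(f$r2_adj, 1)

  withr::with_seed(21, {
    X <- matrix(rnorm(12 * 3), 12, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
    y <- rnorm(12)
  })
  d2 <- dplyr::bind_cols(tibble::as_tibble(X), y = y)
  f2 <- fit_linear(d2, "y", c("g1", "g2", "g3"))
  # oracle: solve the normal equations directly
  Xi <- cbind(1, X)
  beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  expect_equal(c(f2$intercept, unname(f2$coefficients)), unname(drop(beta)), tolerance = 1e-10)
  # adjusted R^2 closed form
  expect_equal(f2$r2_adj, 1 - (1 - f2$r2) * (12 - 1) / (12 - 3 - 1), tolerance = 1e-12)
})

test_that("OLS guards: pure noise stays finite, rank deficiency is named", {
  withr::with_seed(22, {
    d <- tibble::tibble(x = rnorm(12), y = rnorm(12))
  })
  f <- fit_linear(d, "y", "x")
  expect_lte(f$r2_adj, f$r2)   # may be negative; must not error
  d$x2 <- 2 * d$x
  expect_error(fit_linear(d, "y", c("x", "x2")), "x2")
  expect_error(fit_linear(d[1:3, ], "y", c("x", "x2")), "n > k")
})

test_that("best subsets enumerates 2^m - 1 models and matches brute force", {
  withr::with_seed(33, {
    n_agree <- 0
    for (rep in 1:50) {
      X <- matrix(rnorm(12 * 9), 12, 9, dimnames = list(NULL, sprintf("g%d", 1:9)))
      y <- rnorm(12)
      d <- dplyr::bind_cols(tibble::as_tibble(X), y = y)
      bs <- best_subsets(d, "y", sprintf("g%d", 1:9))
      expect_identical(bs$n_enumerated, 511L)
      expect_identical(nrow(bs$subsets), 511L)
      # independent brute force: bitmask enumeration with stats::lm
      best_r2a <- -Inf; best_mask <- NULL
      for (mask in 1:511) {
        cols <- which(bitwAnd(mask, 2^(0:8)) > 0)
        ft <- stats::lm(y ~ ., data = data.frame(y = y, X[, cols, drop = FALSE]))
        r2a <- summary(ft)$adj.r.squared
        if (r2a > best_r2a + 1e-12) {
          best_r2a <- r2a
          best_mask <- cols
        }
      }
      expect_identical(sort(bs$best_model$predictors),
                       sort(sprintf("g%d", best_mask)))
      expect_equal(bs$best_model$r2_adj, best_r2a, tolerance = 1e-10)
      n_agree <- n_agree + 1
    }
    expect_identical(n_agree, 50)
  })
})

test_that("R^2 is monotone under subset nesting", {
  withr::with_seed(35, {
    X <- matrix(rnorm(15 * 5), 15, 5, dimnames = list(NULL, sprintf("g%d", 1:5)))
    y <- rnorm(15)
  })
  d <- dplyr::bind_cols(tibble::as_tibble(X), y = y)
  bs <- best_subsets(d, "y", sprintf("g%d", 1:5))
  subs <- bs$subsets
  for (i in seq_len(nrow(subs))) {
    for (j in seq_len(nrow(subs))) {
      if (i != j && all(subs$terms[[i]] %in% subs$terms[[j]])) {
        expect_lte(subs$r2[i], subs$r2[j] + 1e-10)
      }
    }
  }
})

test_that("the combinatorial guard refuses oversized candidate sets", {
  d <- tibble::as_tibble(matrix(rnorm(30 * 25), 30, 25,
                                dimnames = list(NULL, sprintf("g%d", 1:25))))
  d$y <- rnorm(30)
  expect_error(best_subsets(d, "y", sprintf("g%d", 1:25)), "guard")
})

test_that("prediction applies the stored formula and reproduces fitted values", {
  m <- structure(list(response = "y", predictors = c("x1", "x2"),
                      intercept = 1, coefficients = c(x1 = 2, x2 = -0.5)),
                 class = "ras_lm")
  expect_equal(predict_from_model(m, tibble::tibble(x1 = 3, x2 = 4)), 5)
  m0 <- structure(list(response = "y", predictors = "x1",
                       intercept = 7, coefficients = c(x1 = 0)), class = "ras_lm")
  expect_equal(predict_from_model(m0, tibble::tibble(x1 = c(-5, 100))), c(7, 7))
  expect_error(predict_from_model(m, tibble::tibble(x1 = 1)), "x2")

  withr::with_seed(41, {
    d <- tibble::tibble(x1 = rnorm(10), x2 = rnorm(10))
    d$y <- 1 + d$x1 - 2 * d$x2 + rnorm(10, 0, 0.5)
  })
  f <- fit_linear(d, "y", c("x1", "x2"))
  expect_equal(predict_from_model(f, d), f$fitted, tolerance = 1e-10)
  expect_equal(mean(d$y - predict_from_model(f, d)), 0, tolerance = 1e-12)
})

test_that("Sy.x and R sq. follow their closed forms", {
  expect_equal(goodness_of_fit(c(1, 2, 3), c(1, 2, 3))$sy_x, 0)
  expect_equal(goodness_of_fit(c(1, 2, 3), c(1, 2, 3))$r_sq, 1)
  pred <- c(1, 3, 2, 5, 4)
  obs <- pred + c(1, -1, 1, -1, 0)
  g <- goodness_of_fit(obs, pred)
  expect_equal(g$sy_x, sqrt(4 / 3))
  expect_error(goodness_of_fit(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(goodness_of_fit(1:2, 1:2), "3 pairs")
})

test_that("cross-validation is seeded, sized and reproducible", {
  sc <- sim_config(seed = 8)
  ex <- simulate_expression_ic50(sc)
  cohort <- expr_to_cohort(ex$expression)
  cohort$ic50 <- ex$ic50$ic50
  cv1 <- cross_validate(cohort, "ic50", sc$genes, seed = 99)
  cv2 <- cross_validate(cohort, "ic50", sc$genes, seed = 99)
  expect_identical(tidy(cv1), tidy(cv2))
  expect_identical(nrow(tidy(cv1)), 10L)
  expect_true(all(purrr::map2_lgl(cv1$results$discovery, cv1$results$test,
                                  ~ length(intersect(.x, .y)) == 0 &&
                                    length(union(.x, .y)) == 17)))
  cv3 <- cross_validate(cohort, "ic50", sc$genes, seed = 100)
  expect_false(identical(cv1$results$test, cv3$results$test))
  expect_error(cross_validate(cohort[1:10, ], "ic50", sc$genes), "discovery_n")
  # strong synthetic signal: the full-model discovery fits explain IC50 well
  expect_gt(cv1$mean_r2_adj, 0.8)
})

test_that("the range-spanning split keeps the extremes in discovery", {
  d <- tibble::tibble(ic50 = c(10, 1, 5, 7, 2, 9, 3, 8, 4, 6, 0.5, 11,
                               12, 2.5, 6.5, 3.5, 9.5))
  sp <- range_spanning_split(d, "ic50", test_n = 5)
  expect_identical(length(sp$test), 5L)
  expect_identical(sort(c(sp$discovery, sp$test)), 1:17)
  expect_true(which.min(d$ic50) %in% sp$discovery)
  expect_true(which.max(d$ic50) %in% sp$discovery)
  # test group spans the range: covers more than half of it
  expect_gt(diff(range(d$ic50[sp$test])), 0.5 * diff(range(d$ic50)))
})
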