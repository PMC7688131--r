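# Log-rank test, Kaplan-Meier, binary Cox, LRMC scan and the combined
# prognostic classifier. The survival package serves as the independent
# reference implementation.

test_that("log-rank matches the hand-computed O/E table on the toy cohort", {
  lr <- logrank_test(toy_surv)
  # frozen from the hand-built O/E table (E_a = 17/7, E_b = 25/7, V = 61/49...)
  expect_equal(lr$statistic, 0.262295081967213, tolerance = 1e-10)
  expect_equal(lr$p_value, 0.608547769107773, tolerance = 1e-10)
  expect_equal(lr$obs_b, 3)
  expect_equal(lr$exp_a, 2.428571428571429, tolerance = 1e-12)
  expect_equal(lr$hr, 0.68, tolerance = 1e-12)
})

test_that("log-rank agrees with survival::survdiff on random cohorts", {
  skip_if_not_installed("survival")
  withr::with_seed(19, {
    for (i in 1:10) {
      n <- sample(20:60, 1)
      d <- tibble::tibble(
        time = ceiling(rexp(n, 0.01)),
        event = rbinom(n, 1, 0.8),
        group = sample(c("a", "b"), n, replace = TRUE)
      )
      if (length(unique(d$group)) < 2 || sum(d$event) == 0) next
      sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
      lr <- logrank_test(d)
      expect_equal(lr$statistic, sd$chisq, tolerance = 1e-8)
      expect_equal(c(lr$exp_a, lr$exp_b), unname(sd$exp), tolerance = 1e-8)
    }
  })
})

test_that("log-rank symmetry: identical groups give null, swapping inverts HR", {
  dup <- tibble::tibble(time = rep(c(3, 6, 9, 12), 2),
                        event = rep(c(1, 1, 0, 1), 2),
                        group = rep(c("a", "b"), each = 4))
  lr <- logrank_test(dup)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)
  expect_equal(lr$hr, 1)

  sw <- toy_surv
  sw$group <- ifelse(sw$group == "a", "b", "a")
  lr_sw <- logrank_test(sw)
  lr0 <- logrank_test(toy_surv)
  expect_equal(lr_sw$p_value, lr0$p_value, tolerance = 1e-12)
  expect_equal(lr_sw$hr, 1 / lr0$hr, tolerance = 1e-12)

  allc <- tibble::tibble(time = 1:4, event = 0, group = c("a", "a", "b", "b"))
  expect_error(logrank_test(allc), "event")
})

test_that("Kaplan-Meier reproduces the empirical curve and reference values", {
  # no censoring: product-limit = empirical survival; median of 1..5 is 3
  d <- tibble::tibble(time = 1:5, event = 1)
  km <- km_estimate(d)
  expect_equal(km$survival, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km_median(km), 3)

  # all censored: flat at 1, median undefined
  dc <- tibble::tibble(time = c(2, 4, 6), event = 0)
  kmc <- km_estimate(dc)
  expect_true(all(kmc$survival == 1))
  expect_true(is.na(km_median(kmc)))

  # mixed censoring: frozen from the reference product-limit computation
  km2 <- km_estimate(toy_km)
  expect_equal(km2$survival[km2$time %in% c(2, 3, 5, 8, 11)],
               c(0.875, 0.75, 0.6, 0.4, 0), tolerance = 1e-12)
  # censoring-only times leave the curve unchanged
  expect_equal(km2$survival[km2$time == 6], 0.6, tolerance = 1e-12)
  expect_equal(km_median(km2), 8)
})

test_that("KM agrees with survival::survfit pointwise", {
  skip_if_not_installed("survival")
  withr::with_seed(29, {
    d <- tibble::tibble(time = ceiling(rexp(40, 0.02)), event = rbinom(40, 1, 0.7))
  })
  km <- km_estimate(d)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  expect_equal(km$survival[match(sf$time, km$time)], sf$surv, tolerance = 1e-12)
})

test_that("binary Cox matches the reference implementation and is symmetric", {
  skip_if_not_installed("survival")
  cx <- cox_hr_binary(toy_surv)
  expect_true(cx$converged)
  # frozen from the Breslow partial-likelihood reference fit
  expect_equal(cx$beta, -0.464153607993206, tolerance = 1e-6)
  expect_equal(cx$se, 0.914365414255167, tolerance = 1e-6)

  withr::with_seed(61, {
    d <- tibble::tibble(
      time = ceiling(rexp(80, 0.01)),
      event = rbinom(80, 1, 0.8),
      group = sample(c("lo", "hi"), 80, replace = TRUE)
    )
  })
  ref <- survival::coxph(survival::Surv(time, event) ~ I(group == "lo"),
                         data = d, ties = "breslow")
  cx2 <- cox_hr_binary(d) # levels: hi (ref), lo (comparison)
  expect_equal(cx2$beta, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(cx2$se, sqrt(unname(stats::vcov(ref)[1, 1])), tolerance = 1e-6)

  dup <- tibble::tibble(time = rep(c(3, 6, 9, 12), 2),
                        event = rep(c(1, 1, 0, 1), 2),
                        group = rep(c("a", "b"), each = 4))
  expect_equal(cox_hr_binary(dup)$hr, 1, tolerance = 1e-8)
})

test_that("Cox recovers a known hazard ratio on a simulated cohort", {
  sc <- sim_config(seed = 71, n_patients = 500, hazard_ratio = 2,
                   cutoff_percentile = 0.5)
  sv <- simulate_survival_cohort(sc)
  d <- dplyr::inner_join(sv$survival, sv$expression, by = "sample_id")
  d$group <- factor(ifelse(d$IGF2R >= sv$truth$cutoff, "High", "Low"),
                    levels = c("Low", "High"))
  cx <- cox_hr_binary(d, time = "time_days", group = "group")
  expect_gt(cx$hr, 1.7)
  expect_lt(cx$hr, 2.3)
  # log-rank O/E hazard ratio tells the same story
  lr <- logrank_test(d, time = "time_days", group = "group")
  expect_lt(abs(log(cx$hr / lr$hr)), log(1.15))
})

test_that("monotone likelihood is flagged rather than reported as converged", {
  d <- tibble::tibble(time = c(1, 2, 3, 10, 11, 12),
                      event = 1,
                      group = rep(c("early", "late"), each = 3))
  cx <- cox_hr_binary(d)
  expect_false(cx$converged)
})

test_that("the LRMC scan equals brute-force log-rank at every admissible cutoff", {
  sc <- sim_config(seed = 83, n_patients = 60)
  sv <- simulate_survival_cohort(sc)
  d <- dplyr::inner_join(sv$survival, sv$expression, by = "sample_id")
  scan <- lrmc_scan(d, "IGF2R", time = "time_days", event = "event")
  tab <- tidy(scan)
  expect_identical(nrow(tab), length(unique(d$IGF2R)))
  adm <- tab[tab$admissible, ]
  expect_true(all(adm$n_low >= 3 & adm$n_high >= 3))
  expect_true(all(adm$n_low + adm$n_high == nrow(d)))
  for (i in seq_len(nrow(adm))) {
    d$grp <- factor(ifelse(d$IGF2R >= adm$cutoff[i], "High", "Low"),
                    levels = c("Low", "High"))
    lr <- logrank_test(d, time = "time_days", group = "grp")
    expect_identical(adm$p_value[i], lr$p_value)
    expect_identical(adm$hr[i], lr$hr)
  }
  # selected cutoff attains the maximum of -log10 p
  expect_equal(scan$selected$neg_log10_p, max(adm$neg_log10_p))
  expect_match(scan$note, "minimum p over")
})

test_that("LRMC selection depends only on the expression ordering", {
  sc <- sim_config(seed = 89, n_patients = 80)
  sv <- simulate_survival_cohort(sc)
  d <- dplyr::inner_join(sv$survival, sv$expression, by = "sample_id")
  base <- lrmc_scan(d, "IGF2R", time = "time_days", event = "event")
  d$warped <- exp(d$IGF2R / 3) # strictly monotone relabelling
  warped <- lrmc_scan(d, "warped", time = "time_days", event = "event")
  expect_identical(which(tidy(base)$cutoff == base$selected_cutoff),
                   which(tidy(warped)$cutoff == warped$selected_cutoff))
  expect_identical(tidy(base)$p_value, tidy(warped)$p_value)
})

test_that("LRMC guards: censored cohorts and min group size", {
  d <- tibble::tibble(time_days = c(10, 20, 30, 40, 50, 60),
                      event = 0, expression = 1:6)
  expect_error(lrmc_scan(d, time = "time_days"), "censored")
  d$event <- c(1, 1, 0, 1, 0, 1)
  scan <- lrmc_scan(d, time = "time_days", min_group_size = 1)
  # n distinct values give n - 1 admissible splits at min size 1
  expect_lte(sum(tidy(scan)$admissible), 5)
  expect_error(lrmc_scan(d, time = "time_days", min_group_size = 4),
               "admissible")
})

test_that("the Good/Bad classifier applies the High/Low boundary rule", {
  pats <- tibble::tibble(
    sample_id = c("good", "boundary_bad", "all_low"),
    IGF2R = c(8.0, 8.0, 5.0),
    CTSA = c(12.0, 12.0, 10.0),
    ATP6AP2 = c(10.0, 11.773, 10.0)
  )
  calls <- classify_prognosis(pats)
  expect_identical(as.character(calls$prognosis), c("Good", "Bad", "Bad"))
  # ties sit in High by convention
  expect_identical(as.character(calls$ATP6AP2_call),
                   c("Low", "High", "Low"))
  expect_identical(as.character(calls$IGF2R_call[3]), "Low")
  expect_error(classify_prognosis(pats[, -2]), "IGF2R")
})
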