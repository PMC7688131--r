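# Survival machinery: Mantel-Haenszel log-rank test with O/E hazard ratio,
# Kaplan-Meier product-limit estimation, binary-covariate Cox regression
# (Newton-Raphson, Breslow ties), the LRMC all-cutoffs scan, and the
# combined three-gene prognostic classifier.

check_surv_cols <- function(data, time, event) {
  missing <- setdiff(c(time, event), names(data))
  if (length(missing)) {
    abort(paste0("columns not in `data`: ", paste(missing, collapse = ", ")))
  }
  t <- as.numeric(data[[time]])
  e <- as.numeric(data[[event]])
  if (any(!is.finite(t)) || any(t <= 0)) abort("survival times must be finite and > 0")
  if (!all(e %in% c(0, 1))) abort("event indicator must be 0 (censored) or 1 (death)")
  list(time = t, event = e)
}

# Mantel-Haenszel log-rank over two groups; g = TRUE marks group b
logrank_core <- function(time, event, g) {
  ut <- sort(unique(time[event == 1]))
  o2 <- e2 <- v <- d_tot <- 0
  for (t in ut) {
    at <- time >= t
    n <- sum(at)
    n2 <- sum(at & g)
    n1 <- n - n2
    d <- sum(event == 1 & time == t)
    d2 <- sum(event == 1 & time == t & g)
    o2 <- o2 + d2
    e2 <- e2 + d * n2 / n
    d_tot <- d_tot + d
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  o1 <- d_tot - o2
  e1 <- d_tot - e2
  chisq <- if (v > 0) (o2 - e2)^2 / v else 0
  p <- if (v > 0) pchisq(chisq, df = 1, lower.tail = FALSE) else 1
  hr <- if (e1 > 0 && e2 > 0 && o1 > 0) (o2 / e2) / (o1 / e1) else NA_real_
  list(chisq = chisq, p = p, hr = hr,
       obs = c(o1, o2), exp = c(e1, e2), var = v, n_events = d_tot)
}

#' Two-group log-rank test with O/E hazard ratio
#'
#' Mantel-Haenszel log-rank test (1 df). The hazard ratio is the
#' observed/expected ratio of the second group over the first,
#' `HR = (O_b/E_b)/(O_a/E_a)`; it is `NA` when a group has zero expected
#' (or the reference group zero observed) events, in which case the p-value
#' is still returned.
#'
#' @param data Data frame with time, event and group columns.
#' @param time,event,group Column names (defaults `"time"`, `"event"`,
#'   `"group"`). `event` is 1 = death observed, 0 = censored. `group` must
#'   have exactly two levels; the first level (factor order, else sort
#'   order) is the reference.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `hr`
#'   (second vs first level), per-group `n`, observed and expected events.
#' @export
logrank_test <- function(data, time = "time", event = "event", group = "group") {
  te <- check_surv_cols(data, time, event)
  if (!group %in% names(data)) abort(sprintf("column '%s' not in `data`", group))
  g <- data[[group]]
  if (!is.factor(g)) g <- factor(g)
  lv <- levels(droplevels(g))
  if (length(lv) != 2) abort("`group` must have exactly two non-empty levels")
  gb <- droplevels(g) == lv[2]
  if (sum(te$event) < 1) abort("need at least one observed event")
  lr <- logrank_core(te$time, te$event, gb)
  tibble::tibble(
    statistic = lr$chisq, df = 1L, p_value = lr$p, hr = lr$hr,
    reference = lv[1], comparison = lv[2],
    n_a = sum(!gb), n_b = sum(gb),
    obs_a = lr$obs[1], obs_b = lr$obs[2],
    exp_a = lr$exp[1], exp_b = lr$exp[2]
  )
}

#' Kaplan-Meier product-limit estimate
#'
#' @param data Data frame with time and event columns.
#' @param time,event Column names (defaults `"time"`, `"event"`).
#' @return Tibble with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival` (the estimate just after
#'   that time); attributes `median` (smallest time with S <= 0.5, `NA` if
#'   never reached) and `n`. See [km_median()].
#' @export
km_estimate <- function(data, time = "time", event = "event") {
  te <- check_surv_cols(data, time, event)
  if (length(te$time) == 0) abort("empty group")
  ut <- sort(unique(te$time))
  n_risk <- vapply(ut, function(t) sum(te$time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(te$time == t & te$event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(te$time == t & te$event == 0), numeric(1))
  s <- cumprod(1 - n_event / n_risk)
  out <- tibble::tibble(time = ut, n_risk = n_risk, n_event = n_event,
                        n_censor = n_censor, survival = s)
  med <- if (any(s <= 0.5)) ut[which(s <= 0.5)[1]] else NA_real_
  attr(out, "median") <- med
  attr(out, "n") <- length(te$time)
  out
}

#' Median survival from a Kaplan-Meier estimate
#'
#' @param km Output of [km_estimate()].
#' @return Smallest time at which the survival estimate drops to 0.5 or
#'   below; `NA` if never reached.
#' @export
km_median <- function(km) attr(km, "median")

#' Cox proportional-hazards regression on a binary group
#'
#' Single-coefficient Cox model maximised by Newton-Raphson with Breslow
#' handling of tied event times. Reports `HR = exp(beta)`, the Wald 95%
#' confidence interval and p-value. A monotone partial likelihood (all
#' events in one group preceding the other's) drives beta to infinity; this
#' is flagged via `converged = FALSE`.
#'
#' @inheritParams logrank_test
#' @return One-row tibble: `hr` (second vs first level), `conf_low`,
#'   `conf_high`, `beta`, `se`, `p_value`, `n`, `n_events`, `converged`.
#' @export
cox_hr_binary <- function(data, time = "time", event = "event", group = "group") {
  te <- check_surv_cols(data, time, event)
  g <- data[[group]]
  if (!is.factor(g)) g <- factor(g)
  lv <- levels(droplevels(g))
  if (length(lv) != 2) abort("`group` must have exactly two non-empty levels")
  x <- as.integer(droplevels(g) == lv[2])
  if (sum(te$event[x == 0]) < 1 || sum(te$event[x == 1]) < 1) {
    abort("both groups need at least one observed event")
  }
  # per distinct event time: events d, events in group 1 s, risk-set sizes
  ut <- sort(unique(te$time[te$event == 1]))
  d <- vapply(ut, function(t) sum(te$event == 1 & te$time == t), numeric(1))
  s <- vapply(ut, function(t) sum(te$event == 1 & te$time == t & x == 1), numeric(1))
  r1 <- vapply(ut, function(t) sum(te$time >= t & x == 1), numeric(1))
  r0 <- vapply(ut, function(t) sum(te$time >= t & x == 0), numeric(1))

  beta <- 0
  converged <- FALSE
  info <- NA_real_
  for (it in seq_len(50)) {
    eb <- exp(beta)
    denom <- r0 + r1 * eb
    mu <- r1 * eb / denom
    score <- sum(s - d * mu)
    info <- sum(d * mu * (1 - mu))
    if (info < 1e-12 || abs(beta) > 15) break
    step <- score / info
    beta <- beta + step
    if (abs(step) < 1e-10) {
      converged <- TRUE
      break
    }
  }
  se <- if (is.finite(info) && info > 0) 1 / sqrt(info) else NA_real_
  z <- beta / se
  tibble::tibble(
    hr = exp(beta),
    conf_low = exp(beta - qnorm(0.975) * se),
    conf_high = exp(beta + qnorm(0.975) * se),
    beta = beta, se = se,
    p_value = 2 * pnorm(-abs(z)),
    n = length(x), n_events = sum(te$event),
    reference = lv[1], comparison = lv[2],
    converged = converged
  )
}

#' Log-rank scan over all expression cutoffs (LRMC)
#'
#' Scans every distinct expression value as a candidate cutoff, splits the
#' cohort into Low (expression strictly below the cutoff) and High (at or
#' above), and records the log-rank p-value and High-vs-Low hazard ratio
#' for each admissible split (both sides at least `min_group_size`; set it
#' to 1 for the literal every-sample scan). The selected cutoff minimises
#' the p-value; exact ties resolve to the cutoff closest to the median
#' expression, then to the lower cutoff.
#'
#' Because the minimum is taken over many correlated tests, the selected
#' p-value is optimistically biased; the scan therefore always carries a
#' multiplicity note and applies no correction (matching common practice
#' for this scan), so treat the selected p as descriptive.
#'
#' @param data Data frame with expression, time and event columns.
#' @param expression Expression column name (default `"expression"`).
#' @param time,event Column names (defaults `"time"`, `"event"`).
#' @param min_group_size Minimum patients on each side of an admissible
#'   cutoff (default 3).
#' @return An `lrmc_scan`: `scan` (per-cutoff tibble: `cutoff`, `n_low`,
#'   `n_high`, `statistic`, `p_value`, `neg_log10_p`, `hr`, `admissible`),
#'   `selected_cutoff`, `selected` (its scan row), `n`, `n_admissible` and
#'   `note`. `tidy()` gives the scan, `glance()` the selected row;
#'   `autoplot()` draws the -log10 p profile.
#' @export
lrmc_scan <- function(data, expression = "expression", time = "time",
                      event = "event", min_group_size = 3) {
  te <- check_surv_cols(data, time, event)
  if (!expression %in% names(data)) {
    abort(sprintf("column '%s' not in `data`", expression))
  }
  expr <- as.numeric(data[[expression]])
  if (any(!is.finite(expr))) abort("expression values must be finite")
  if (sum(te$event) == 0) abort("all-censored cohort: log-rank undefined")
  n <- length(expr)
  cuts <- sort(unique(expr))
  scan <- purrr::map_dfr(cuts, function(cut) {
    high <- expr >= cut
    n_high <- sum(high)
    n_low <- n - n_high
    if (n_low < min_group_size || n_high < min_group_size) {
      return(tibble::tibble(cutoff = cut, n_low = n_low, n_high = n_high,
                            statistic = NA_real_, p_value = NA_real_,
                            neg_log10_p = NA_real_, hr = NA_real_,
                            admissible = FALSE))
    }
    lr <- logrank_core(te$time, te$event, high)
    tibble::tibble(cutoff = cut, n_low = n_low, n_high = n_high,
                   statistic = lr$chisq, p_value = lr$p,
                   neg_log10_p = -log10(lr$p), hr = lr$hr,
                   admissible = TRUE)
  })
  adm <- which(scan$admissible)
  if (length(adm) == 0) {
    abort(sprintf("no admissible cutoff with at least %d patients per side", min_group_size))
  }
  pmin_val <- min(scan$p_value[adm])
  cand <- adm[scan$p_value[adm] <= pmin_val * (1 + 1e-12)]
  med <- median(expr)
  cand <- cand[order(abs(scan$cutoff[cand] - med), scan$cutoff[cand])]
  sel <- cand[1]
  structure(
    list(scan = scan,
         selected_cutoff = scan$cutoff[sel],
         selected = scan[sel, ],
         gene = expression, n = n,
         n_admissible = length(adm),
         min_group_size = min_group_size,
         note = sprintf(
           "selected by minimum p over %d candidate cutoffs; no multiplicity correction applied",
           length(adm))),
    class = "lrmc_scan"
  )
}

#' @export
print.lrmc_scan <- function(x, ...) {
  cat(sprintf("<lrmc_scan> %s: %d patients, %d admissible cutoffs\n",
              x$gene, x$n, x$n_admissible))
  cat(sprintf("  selected cutoff %.4g: p = %.3g, HR (High vs Low) = %.3g, n_low/n_high = %d/%d\n",
              x$selected_cutoff, x$selected$p_value, x$selected$hr,
              x$selected$n_low, x$selected$n_high))
  cat("  note:", x$note, "\n")
  invisible(x)
}

#' @method tidy lrmc_scan
#' @export
tidy.lrmc_scan <- function(x, ...) x$scan

#' @method glance lrmc_scan
#' @export
glance.lrmc_scan <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(gene = x$gene), x$selected,
                   tibble::tibble(n = x$n, n_admissible = x$n_admissible,
                                  note = x$note))
}

#' LRMC scan profile plot
#'
#' -log10 log-rank p against cutoff, coloured by hazard-ratio direction
#' (High vs Low), with the 25th/50th/75th expression percentiles (dotted
#' verticals), the 0.05 significance line and the selected cutoff circled.
#'
#' @param object An `lrmc_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lrmc_scan
#' @export
autoplot.lrmc_scan <- function(object, ...) {
  sc <- object$scan[object$scan$admissible, ]
  qs <- quantile(rep(sc$cutoff, 1), c(0.25, 0.5, 0.75))
  ggplot2::ggplot(sc, ggplot2::aes(.data$cutoff, .data$neg_log10_p,
                                   colour = .data$hr > 1)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = unname(qs), linetype = "dotted") +
    ggplot2::annotate("point", x = object$selected_cutoff,
                      y = object$selected$neg_log10_p,
                      shape = 1, size = 4, colour = "red") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "blue"),
                                 name = "HR > 1") +
    ggplot2::labs(x = sprintf("%s expression cutoff", object$gene),
                  y = "-log10(log-rank p)",
                  subtitle = object$note)
}

#' Kaplan-Meier step plot
#'
#' @param data Data frame with time, event and (optionally) group columns.
#' @param time,event,group Column names; `group = NULL` plots one curve.
#' @return A ggplot object.
#' @export
plot_km <- function(data, time = "time", event = "event", group = NULL) {
  if (is.null(group)) {
    data$..group <- "all"
    group <- "..group"
  }
  km <- data |>
    dplyr::group_by(.data[[group]]) |>
    dplyr::group_modify(function(d, key) km_estimate(d, time, event)) |>
    dplyr::ungroup()
  start <- km |>
    dplyr::distinct(.data[[group]]) |>
    dplyr::mutate(time = 0, survival = 1)
  km <- dplyr::bind_rows(start, km) |> dplyr::arrange(.data[[group]], .data$time)
  ggplot2::ggplot(km, ggplot2::aes(.data$time, .data$survival,
                                   colour = .data[[group]])) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "overall survival (days)", y = "survival probability")
}

#' LRMC-derived prognostic cutoffs for the AML reference cohort
#'
#' Log2 expression cutoffs for IGF2R, CTSA and ATP6AP2 selected by the LRMC
#' scan on the 163-patient GSE12417 AML training cohort; used as defaults
#' by [classify_prognosis()].
#'
#' @format Named numeric vector of length 3.
#' @export
ras_prognostic_cutoffs <- c(IGF2R = 7.077, CTSA = 11.247, ATP6AP2 = 11.773)

#' Combined three-gene Good/Bad prognostic classification
#'
#' Calls each gene High (expression at or above its cutoff) or Low
#' (strictly below), then labels a patient `Good` when every gene in
#' `high_good` is High and every gene in `low_good` is Low — by default
#' IGF2R High, CTSA High and ATP6AP2 Low; everyone else is `Bad`.
#'
#' @param data Data frame with one numeric expression column per gene named
#'   in `cutoffs`.
#' @param cutoffs Named numeric vector of per-gene cutoffs (default
#'   [ras_prognostic_cutoffs]).
#' @param high_good,low_good Gene names whose High (resp. Low) call defines
#'   the Good group.
#' @return `data` with an added `<gene>_call` factor column per gene and a
#'   `prognosis` factor (`Good`/`Bad`).
#' @export
classify_prognosis <- function(data, cutoffs = ras_prognostic_cutoffs,
                               high_good = c("IGF2R", "CTSA"),
                               low_good = "ATP6AP2") {
  genes <- names(cutoffs)
  if (is.null(genes) || !all(nzchar(genes))) abort("`cutoffs` must be named by gene")
  missing <- setdiff(genes, names(data))
  if (length(missing)) {
    abort(paste0("missing gene column(s): ", paste(missing, collapse = ", ")))
  }
  if (!all(c(high_good, low_good) %in% genes)) {
    abort("`high_good`/`low_good` genes must appear in `cutoffs`")
  }
  calls <- purrr::map(genes, function(g) {
    factor(ifelse(data[[g]] >= cutoffs[[g]], "High", "Low"),
           levels = c("Low", "High"))
  })
  names(calls) <- paste0(genes, "_call")
  good <- Reduce(`&`, c(
    purrr::map(high_good, function(g) calls[[paste0(g, "_call")]] == "High"),
    purrr::map(low_good, function(g) calls[[paste0(g, "_call")]] == "Low")
  ))
  dplyr::bind_cols(
    tibble::as_tibble(data),
    tibble::as_tibble(calls),
    tibble::tibble(prognosis = factor(ifelse(good, "Good", "Bad"),
                                      levels = c("Good", "Bad")))
  )
}
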