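# End-to-end orchestration: simulate (or read) inputs, filter probes, fit
# the 6M curves, correlate expression with IC50, select the best predictor
# subset, predict the held-out group, scan survival cutoffs, classify
# prognosis, and write every intermediate as TSV/JSON plus a manifest with
# seeds, thresholds and file hashes. Rerunning with the same config
# reproduces identical bytes.

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Seed forwarded to the generators and the random split.
#' @param simulate Generate inputs with the synthetic-data module
#'   (default); set `FALSE` and supply `inputs` paths to use real files.
#' @param sim Named list of [sim_config()] overrides.
#' @param inputs Named list of file paths (`dose_response`, `expression`,
#'   `ic50`, `survival`, `survival_expression`) used when
#'   `simulate = FALSE`.
#' @param drug Drug to analyse.
#' @param filter List of [variance_filter()] thresholds.
#' @param split List: `mode` (`"random"` or `"range"`), `n_repeats`,
#'   `discovery_n`, `test_n`.
#' @param lrmc List: `min_group_size`.
#' @param icxx_convention Passed to [response_metrics()].
#' @return Config list for [run_pipeline()].
#' @export
pipeline_config <- function(out_dir = tempfile("ras6m-run-"),
                            seed = 1,
                            simulate = TRUE,
                            sim = list(),
                            inputs = list(),
                            drug = "Doxorubicin",
                            filter = list(var_min = 0.8, mean_min = 5.5, range_min = 3),
                            split = list(mode = "range", n_repeats = 10,
                                         discovery_n = 12, test_n = 5),
                            lrmc = list(min_group_size = 3),
                            icxx_convention = "growth") {
  as.list(environment())
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

write_tsv_out <- function(x, dir, file) {
  path <- file.path(dir, file)
  readr::write_tsv(x, path)
  path
}

#' Run the full biomarker-discovery pipeline
#'
#' Sequences the package end to end on one drug: probe filtering, per-line
#' 6M curve fitting with response metrics, per-gene Pearson correlation
#' with IC50, best-subsets regression on the discovery group with
#' prediction and goodness of fit on the test group, repeated random
#' cross-validation, LRMC cutoff scans for the survival genes, and the
#' combined Good/Bad classification with its log-rank comparison. Every
#' intermediate is written as TSV/JSON under `config$out_dir` together
#' with a `manifest.json` recording the configuration, package version and
#' MD5 hash of each output file.
#'
#' @param config A [pipeline_config()] list, or the path to a YAML file of
#'   overrides.
#' @return Invisibly, a list with the in-memory results of each stage, the
#'   output directory and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config) && length(config) == 1) {
    config <- utils::modifyList(pipeline_config(), yaml::read_yaml(config))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- config$out_dir
  files <- character(0)
  results <- list()

  # --- inputs -------------------------------------------------------------
  inputs <- run_stage("inputs", {
    if (isTRUE(config$simulate)) {
      sc <- do.call(sim_config, utils::modifyList(list(seed = config$seed),
                                                  config$sim))
      dr <- simulate_dose_response(sc)
      ex <- simulate_expression_ic50(sc)
      sv <- simulate_survival_cohort(sc)
      indir <- file.path(out, "inputs")
      dir.create(indir, showWarnings = FALSE)
      readr::write_csv(dr$data, file.path(indir, "dose_response.csv"))
      readr::write_tsv(ex$expression, file.path(indir, "expression.tsv"))
      readr::write_tsv(ex$ic50, file.path(indir, "ic50.tsv"))
      readr::write_tsv(sv$survival, file.path(indir, "survival.tsv"))
      readr::write_tsv(sv$expression, file.path(indir, "survival_expression.tsv"))
      readr::write_tsv(dr$truth, file.path(indir, "truth_dose_response.tsv"))
      readr::write_tsv(ex$truth, file.path(indir, "truth_regression.tsv"))
      readr::write_tsv(sv$truth, file.path(indir, "truth_survival.tsv"))
      files <- c(files, list.files(indir, full.names = TRUE))
      # round-trip through the package readers: no hidden in-memory state
      list(
        dose_response = read_dose_response(file.path(indir, "dose_response.csv")),
        expression = read_expression_matrix(file.path(indir, "expression.tsv")),
        ic50 = readr::read_tsv(file.path(indir, "ic50.tsv"), show_col_types = FALSE),
        survival = read_survival(file.path(indir, "survival.tsv")),
        survival_expression = readr::read_tsv(
          file.path(indir, "survival_expression.tsv"), show_col_types = FALSE)
      )
    } else {
      req <- c("dose_response", "expression", "ic50", "survival",
               "survival_expression")
      missing <- setdiff(req, names(config$inputs))
      if (length(missing)) {
        abort(paste0("missing input path(s): ", paste(missing, collapse = ", ")))
      }
      list(
        dose_response = read_dose_response(config$inputs$dose_response),
        expression = read_expression_matrix(config$inputs$expression),
        ic50 = readr::read_tsv(config$inputs$ic50, show_col_types = FALSE),
        survival = read_survival(config$inputs$survival),
        survival_expression = readr::read_tsv(config$inputs$survival_expression,
                                              show_col_types = FALSE)
      )
    }
  })

  # --- 6M dose-response fits ----------------------------------------------
  results$fits <- run_stage("fit_dose_response", {
    fits <- fit_drug_response(inputs$dose_response, drug = config$drug,
                              convention = config$icxx_convention)
    all_variants <- fits |>
      dplyr::mutate(variants = purrr::map(.data$fit, tidy)) |>
      dplyr::select("cell_line", "drug", "variants") |>
      tidyr::unnest("variants")
    files <- c(files,
               write_tsv_out(dplyr::select(fits, -"fit"), out, "dose_response_fits.tsv"),
               write_tsv_out(all_variants, out, "dose_response_variants.tsv"))
    
    fits
  })

  # --- probe filter --------------------------------------------------------
  results$filter <- run_stage("filter", {
    rep <- variance_filter(inputs$expression,
                           var_min = config$filter$var_min,
                           mean_min = config$filter$mean_min,
                           range_min = config$filter$range_min)
    files <- c(files, write_tsv_out(rep, out, "filter_report.tsv"))
    rep
  })
  expr_kept <- apply_probe_filter(inputs$expression, results$filter)
  if (nrow(expr_kept) == 0) abort("pipeline stage 'filter' failed: no probe passed")

  # --- correlation screen --------------------------------------------------
  ic50_vec <- setNames(inputs$ic50$ic50, inputs$ic50$cell_line)
  results$correlations <- run_stage("correlate", {
    co <- correlate_with_response(expr_kept, ic50_vec)
    files <- c(files, write_tsv_out(co, out, "correlations.tsv"))
    co
  })

  # --- regression: split, best subsets, prediction, CV ---------------------
  results$regression <- run_stage("regress", {
    em <- as_expr_matrix(expr_kept)
    cohort <- dplyr::bind_cols(
      tibble::tibble(cell_line = colnames(em$mat)),
      tibble::as_tibble(t(em$mat))
    ) |>
      dplyr::inner_join(inputs$ic50[c("cell_line", "ic50")], by = "cell_line")
    predictors <- em$probe_id
    split <- if (identical(config$split$mode, "range")) {
      range_spanning_split(cohort, "ic50", test_n = config$split$test_n)
    } else {
      withr::with_seed(config$seed, {
        test <- sort(sample.int(nrow(cohort), config$split$test_n))
        list(discovery = setdiff(seq_len(nrow(cohort)), test), test = test)
      })
    }
    bs <- best_subsets(cohort[split$discovery, ], "ic50", predictors)
    pred <- predict_from_model(bs, cohort[split$test, ])
    gof <- goodness_of_fit(cohort$ic50[split$test], pred)
    cv <- cross_validate(cohort, "ic50", predictors,
                         n_repeats = config$split$n_repeats,
                         discovery_n = config$split$discovery_n,
                         test_n = config$split$test_n,
                         seed = config$seed)
    model_json <- list(
      drug = config$drug,
      intercept = bs$best_model$intercept,
      coefficients = as.list(bs$best_model$coefficients),
      r2_adj = bs$best_model$r2_adj,
      test_goodness_of_fit = as.list(gof)
    )
    jsonlite::write_json(model_json, file.path(out, "best_model.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    preds <- tibble::tibble(cell_line = cohort$cell_line[split$test],
                            observed_ic50 = cohort$ic50[split$test],
                            predicted_ic50 = pred)
    files <- c(files,
                write_tsv_out(dplyr::select(tidy(bs), -"terms"), out, "best_subsets.tsv"),
                write_tsv_out(preds, out, "test_predictions.tsv"),
                write_tsv_out(tidy(cv) |> dplyr::select(-"discovery", -"test"),
                              out, "cross_validation.tsv"),
                file.path(out, "best_model.json"))
    list(cohort = cohort, split = split, best_subsets = bs,
         predictions = preds, gof = gof, cv = cv)
  })

  # --- LRMC scans ----------------------------------------------------------
  results$lrmc <- run_stage("lrmc", {
    surv <- dplyr::inner_join(inputs$survival, inputs$survival_expression,
                              by = "sample_id")
    genes <- setdiff(names(inputs$survival_expression), "sample_id")
    scans <- purrr::map(genes, function(g) {
      lrmc_scan(surv, expression = g, time = "time_days", event = "event",
                min_group_size = config$lrmc$min_group_size)
    })
    names(scans) <- genes
    for (g in genes) {
      files <- c(files, write_tsv_out(tidy(scans[[g]]), out,
                                       sprintf("lrmc_%s.tsv", g)))
    }
    selected <- purrr::map_dfr(scans, glance)
    files <- c(files, write_tsv_out(dplyr::select(selected, -"note"),
                                     out, "lrmc_selected.tsv"))
    list(scans = scans, selected = selected, data = surv)
  })

  # --- combined prognostic classification ----------------------------------
  results$prognosis <- run_stage("classify", {
    genes <- names(results$lrmc$scans)
    cutoffs <- setNames(results$lrmc$selected$cutoff, results$lrmc$selected$gene)
    high_good <- intersect(c("IGF2R", "CTSA"), genes)
    low_good <- intersect("ATP6AP2", genes)
    if (length(high_good) == 0) { # generic cohorts: driver gene high = good/bad by HR
      high_good <- genes[1]
      low_good <- character(0)
    }
    calls <- classify_prognosis(results$lrmc$data, cutoffs,
                                high_good = high_good, low_good = low_good)
    lr <- logrank_test(calls, time = "time_days", event = "event",
                       group = "prognosis")
    medians <- calls |>
      dplyr::group_by(.data$prognosis) |>
      dplyr::group_modify(function(d, key) {
        tibble::tibble(n = nrow(d),
                       median_survival_days = km_median(
                         km_estimate(d, "time_days", "event")))
      }) |>
      dplyr::ungroup()
    jsonlite::write_json(
      list(logrank = as.list(lr), groups = medians),
      file.path(out, "prognosis_logrank.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
    files <- c(files,
                write_tsv_out(calls, out, "prognosis_calls.tsv"),
                file.path(out, "prognosis_logrank.json"))
    list(calls = calls, logrank = lr, medians = medians)
  })

  # --- manifest ------------------------------------------------------------
  manifest <- run_stage("manifest", {
    files <- sort(unique(files))
    m <- list(
      package = "ras6m",
      version = as.character(utils::packageVersion("ras6m")),
      seed = config$seed,
      drug = config$drug,
      filter = config$filter,
      split = config$split,
      lrmc = config$lrmc,
      icxx_convention = config$icxx_convention,
      files = lapply(setNames(nm = basename(files)), function(b) {
        unname(tools::md5sum(files[basename(files) == b][1]))
      })
    )
    jsonlite::write_json(m, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    m
  })

  invisible(list(out_dir = out, files = sort(unique(files)),
                 manifest = manifest, results = results, config = config))
}
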