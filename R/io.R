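# Readers for the plain-text interchange formats: cytotoxicity CSV,
# tab-delimited expression matrices (GEO series-matrix metadata lines
# skipped), probe->gene maps, survival TSV and qRT-PCR Ct CSV.

#' Read a cytotoxicity screening CSV
#'
#' Expects columns `cell_line`, `drug`, `concentration_uM`, `replicate`,
#' and either `percent_growth` (pre-normalized) or `signal` together with
#' `untreated_signal` (and optionally `blank_signal`), in which case
#' [normalize_growth()] is applied.
#'
#' @param path CSV file path.
#' @return Tibble with a `percent_growth` column.
#' @export
read_dose_response <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("cell_line", "drug", "concentration_uM", "replicate")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(paste0("dose-response CSV is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"percent_growth" %in% names(x)) {
    if (!all(c("signal", "untreated_signal") %in% names(x))) {
      abort("need `percent_growth`, or `signal` plus `untreated_signal` (optional `blank_signal`)")
    }
    blank <- if ("blank_signal" %in% names(x)) x$blank_signal else 0
    x$percent_growth <- normalize_growth(x$signal, x$untreated_signal, blank)
  }
  x
}

#' Read a tab-delimited expression matrix
#'
#' First column is the probe identifier, header row carries sample ids.
#' GEO series-matrix files are accepted: lines starting with `!` are
#' skipped.
#'
#' @param path TSV file path.
#' @return Tibble with first column `probe_id` and numeric sample columns.
#' @export
read_expression_matrix <- function(path) {
  x <- readr::read_tsv(path, comment = "!", show_col_types = FALSE)
  names(x)[1] <- "probe_id"
  x$probe_id <- as.character(x$probe_id)
  as_expr_matrix(x) # validates: duplicates, finiteness, numeric
  x
}

#' Read a two-column probe-to-gene map
#'
#' @param path TSV file path: probe id, gene symbol.
#' @return Tibble `probe_id`, `gene`.
#' @export
read_probe_map <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(x) < 2) abort("probe map needs two columns: probe id, gene")
  tibble::tibble(probe_id = as.character(x[[1]]), gene = as.character(x[[2]]))
}

#' Read a survival TSV
#'
#' @param path TSV file path with columns `sample_id`, `time_days`
#'   (overall survival in days, > 0) and `event` (1 = death, 0 = censored).
#' @return Validated tibble.
#' @export
read_survival <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  missing <- setdiff(c("sample_id", "time_days", "event"), names(x))
  if (length(missing)) {
    abort(paste0("survival TSV is missing column(s): ", paste(missing, collapse = ", ")))
  }
  check_surv_cols(x, "time_days", "event")
  x
}

#' Read a qRT-PCR Ct CSV
#'
#' @param path CSV file path with columns `sample`, `gene`, `ct` and
#'   optionally `replicate`.
#' @return Tibble.
#' @export
read_ct_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(c("sample", "gene", "ct"), names(x))
  if (length(missing)) {
    abort(paste0("Ct CSV is missing column(s): ", paste(missing, collapse = ", ")))
  }
  x
}
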