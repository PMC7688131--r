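# Expression-matrix handling: variance/mean/range probe filtering,
# probeset-to-gene collapsing, and per-probe correlation with drug response.
# Matrices are tibbles: first column = probe (or gene) identifier, remaining
# columns = samples, values already log2-normalized.

as_expr_matrix <- function(data, id_col = NULL) {
  if (is.matrix(data)) {
    if (is.null(rownames(data))) abort("expression matrix needs rownames (probe ids)")
    return(list(probe_id = rownames(data), mat = data))
  }
  if (!is.data.frame(data)) abort("`data` must be a data frame or matrix")
  id_col <- id_col %||% names(data)[1]
  ids <- as.character(data[[id_col]])
  if (anyDuplicated(ids)) abort("duplicate probe ids in expression matrix")
  mat <- as.matrix(data[setdiff(names(data), id_col)])
  if (!is.numeric(mat)) abort("expression values must be numeric")
  if (any(!is.finite(mat))) abort("expression values must all be finite")
  rownames(mat) <- ids
  list(probe_id = ids, mat = mat)
}

#' Variance/mean/range probe filter
#'
#' Flags probes whose expression across samples is variable enough to be
#' useful downstream (e.g. detectable by qRT-PCR): a probe passes when its
#' variance is at least `var_min`, its mean is at least `mean_min`, and its
#' max-min difference exceeds `range_min` (log2 units; note the strict
#' inequality on the range, inclusive on the other two).
#'
#' @param data Expression tibble (first column probe id, remaining columns
#'   samples) or numeric matrix with probe rownames.
#' @param var_min,mean_min,range_min Thresholds; defaults 0.8, 5.5 and 3.
#' @param samples Optional character vector restricting the computation to a
#'   sample subset (the analysis cohort).
#' @param var_denominator `"sample"` (n-1, default) or `"population"` (n).
#' @return Tibble with one row per probe: `probe_id`, `variance`, `mean`,
#'   `range`, `pass`.
#' @export
variance_filter <- function(data, var_min = 0.8, mean_min = 5.5, range_min = 3,
                            samples = NULL,
                            var_denominator = c("sample", "population")) {
  var_denominator <- match.arg(var_denominator)
  em <- as_expr_matrix(data)
  mat <- em$mat
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(mat))
    if (length(missing)) {
      abort(paste0("samples not in matrix: ", paste(missing, collapse = ", ")))
    }
    mat <- mat[, samples, drop = FALSE]
  }
  n <- ncol(mat)
  if (n < 2) abort("variance undefined: need at least 2 samples")
  mu <- rowMeans(mat)
  ss <- rowSums((mat - mu)^2)
  v <- ss / (if (var_denominator == "sample") n - 1 else n)
  rng <- apply(mat, 1, max) - apply(mat, 1, min)
  tibble::tibble(
    probe_id = em$probe_id,
    variance = unname(v),
    mean = unname(mu),
    range = unname(rng),
    pass = unname(v >= var_min & mu >= mean_min & rng > range_min)
  )
}

#' Keep only probes that pass a filter report
#'
#' @param data Expression tibble (first column probe id).
#' @param report Output of [variance_filter()].
#' @return The expression tibble restricted to passing probes.
#' @export
apply_probe_filter <- function(data, report) {
  keep <- report$probe_id[report$pass]
  id_col <- names(data)[1]
  data[data[[id_col]] %in% keep, , drop = FALSE]
}

#' Collapse probesets to one row per gene
#'
#' For genes measured by several probesets, keeps the probeset with the
#' highest expression: by default the highest mean across samples (the usual
#' collapse rule for enrichment analyses); `rule = "max-sample"` instead
#' uses the highest single-sample value. Ties are broken toward the
#' lexicographically smallest probe id. Probes absent from `probe_map` are
#' dropped with a warning.
#'
#' @param data Expression tibble (first column probe id).
#' @param probe_map Two-column data frame: probe id, gene symbol.
#' @param rule `"mean-expression"` (default) or `"max-sample"`.
#' @return Gene-level expression tibble (first column `gene`); the chosen
#'   probe per gene is recorded in the `"selection"` attribute.
#' @export
collapse_probesets <- function(data, probe_map,
                               rule = c("mean-expression", "max-sample")) {
  rule <- match.arg(rule)
  if (!is.data.frame(probe_map) || ncol(probe_map) < 2 || nrow(probe_map) == 0) {
    abort("`probe_map` must be a non-empty data frame: probe id, gene")
  }
  map <- tibble::tibble(probe_id = as.character(probe_map[[1]]),
                        gene = as.character(probe_map[[2]]))
  em <- as_expr_matrix(data)
  id_col <- names(data)[1]
  unmapped <- setdiff(em$probe_id, map$probe_id)
  if (length(unmapped)) {
    warn(sprintf("%d probe(s) without a gene mapping dropped", length(unmapped)))
  }
  score <- if (rule == "mean-expression") rowMeans(em$mat) else apply(em$mat, 1, max)
  sel <- tibble::tibble(probe_id = em$probe_id, score = unname(score)) |>
    dplyr::inner_join(map, by = "probe_id") |>
    dplyr::arrange(.data$gene, dplyr::desc(.data$score), .data$probe_id) |>
    dplyr::distinct(.data$gene, .keep_all = TRUE)
  out <- tibble::tibble(gene = sel$gene) |>
    dplyr::bind_cols(tibble::as_tibble(em$mat[sel$probe_id, , drop = FALSE]))
  attr(out, "selection") <- sel[c("gene", "probe_id", "score")]
  out
}

#' Pearson correlation of each probe with a per-sample response
#'
#' Correlates every probe's expression with a numeric response (typically
#' IC50) over the shared samples, returning Pearson's r and the two-sided
#' p-value from the t distribution with n-2 degrees of freedom. Probes with
#' zero variance over the shared samples get `NA` with a warning.
#'
#' @param data Expression tibble (first column probe id).
#' @param response Named numeric vector (names = sample ids) or a
#'   data frame whose first two columns are sample id and value.
#' @return Tibble: `probe_id`, `n`, `r`, `p_value`.
#' @export
correlate_with_response <- function(data, response) {
  if (is.data.frame(response)) {
    response <- setNames(as.numeric(response[[2]]), as.character(response[[1]]))
  }
  if (is.null(names(response))) abort("`response` must carry sample names")
  em <- as_expr_matrix(data)
  shared <- intersect(colnames(em$mat), names(response))
  if (length(shared) < 3) abort("need at least 3 paired samples")
  y <- response[shared]
  if (any(!is.finite(y))) abort("response values must be finite")
  if (sd(y) == 0) abort("response has zero variance: correlation undefined")
  mat <- em$mat[, shared, drop = FALSE]
  n <- length(shared)
  res <- purrr::map_dfr(seq_len(nrow(mat)), function(i) {
    xi <- mat[i, ]
    if (sd(xi) == 0) {
      return(tibble::tibble(n = n, r = NA_real_, p_value = NA_real_))
    }
    r <- cor(xi, y)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    tibble::tibble(n = n, r = r, p_value = 2 * pt(-abs(tt), n - 2))
  })
  if (anyNA(res$r)) {
    warn(sprintf("%d probe(s) with zero variance: correlation undefined (NA)", sum(is.na(res$r))))
  }
  dplyr::bind_cols(tibble::tibble(probe_id = em$probe_id), res)
}
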