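# ddCT relative quantification of qRT-PCR threshold cycles.

#' Relative expression by the delta-delta-Ct method
#'
#' Classic ddCT with amplification efficiency fixed at 2. Technical
#' replicates are averaged on the Ct scale, then
#' `dCt = Ct_target - Ct_reference` per sample,
#' `ddCt = dCt_sample - dCt_calibrator`, and `RQ = 2^(-ddCt)`. With
#' `calibrator = "mean"` the cohort mean dCt is the calibrator, so the RQs
#' multiply to 1 (equivalently, `log2_rq` is mean-centred).
#'
#' `log2_rq` (= -ddCt) is the scale on which RQ values should enter
#' regression formulas trained on log2 microarray expression.
#'
#' @param data Ct table: columns `sample`, `gene`, `ct`, optional
#'   `replicate`. Ct values must be finite and positive.
#' @param target_gene Gene to quantify.
#' @param reference_gene Endogenous control gene (default `"GAPDH"`).
#' @param calibrator `"mean"` (default) or a sample id whose dCt defines
#'   ddCt = 0.
#' @return Tibble per sample: `sample`, `gene`, `ct_target`,
#'   `ct_reference`, `dct`, `ddct`, `rq`, `log2_rq`.
#' @export
#' @examples
#' ct <- tibble::tibble(
#'   sample = rep(c("s1", "s2"), each = 2),
#'   gene = rep(c("IGF2R", "GAPDH"), 2),
#'   ct = c(24, 18, 23, 18)
#' )
#' relative_expression_ddct(ct, "IGF2R", calibrator = "s1")
relative_expression_ddct <- function(data, target_gene,
                                     reference_gene = "GAPDH",
                                     calibrator = "mean") {
  need <- c("sample", "gene", "ct")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(paste0("Ct table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  ct <- as.numeric(data$ct)
  if (any(!is.finite(ct)) || any(ct <= 0)) abort("Ct values must be finite and > 0")

  avg <- tibble::tibble(sample = as.character(data$sample),
                        gene = as.character(data$gene), ct = ct) |>
    dplyr::filter(.data$gene %in% c(target_gene, reference_gene)) |>
    dplyr::group_by(.data$sample, .data$gene) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")

  wide <- tidyr::pivot_wider(avg, names_from = "gene", values_from = "ct")
  for (g in c(target_gene, reference_gene)) {
    if (!g %in% names(wide)) wide[[g]] <- NA_real_
  }
  bad <- wide$sample[is.na(wide[[target_gene]]) | is.na(wide[[reference_gene]])]
  if (length(bad)) {
    abort(paste0("missing Ct for target or reference gene in sample(s): ",
                 paste(bad, collapse = ", ")))
  }

  dct <- wide[[target_gene]] - wide[[reference_gene]]
  if (identical(calibrator, "mean")) {
    dct_cal <- mean(dct)
  } else {
    hit <- which(wide$sample == calibrator)
    if (length(hit) != 1) abort(sprintf("calibrator sample '%s' not found", calibrator))
    dct_cal <- dct[hit]
  }
  ddct <- dct - dct_cal
  tibble::tibble(
    sample = wide$sample, gene = target_gene,
    ct_target = wide[[target_gene]], ct_reference = wide[[reference_gene]],
    dct = dct, ddct = ddct, rq = 2^(-ddct), log2_rq = -ddct
  )
}
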