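# Shared fixtures, built in code.

six_doses <- c(20, 10, 2, 1, 0.2, 0.1)

# noise-free 4PL points at the six standard doses, n replicates
make_curve_points <- function(a, d, c, b, reps = 3, noise_sd = 0, doses = six_doses) {
  x <- rep(doses, reps)
  y <- d + (a - d) / (1 + (x / c)^b)
  if (noise_sd > 0) y <- y + rnorm(length(x), 0, noise_sd)
  tibble::tibble(concentration = x, growth = y)
}

# 8-patient two-group survival table with a tie (at t = 5) and censoring;
# frozen expectations were hand-derived from the O/E table and match
# survival::survdiff
toy_surv <- tibble::tibble(
  time  = c(1, 3, 5, 7, 2, 4, 5, 8),
  event = c(1, 1, 0, 1, 1, 0, 1, 1),
  group = rep(c("a", "b"), each = 4)
)

# mixed-censoring one-group table for Kaplan-Meier pointwise checks
toy_km <- tibble::tibble(
  time  = c(2, 3, 3, 5, 6, 8, 9, 11),
  event = c(1, 1, 0, 1, 0, 1, 0, 1)
)

# small expression cohort: samples in columns, one response per sample
make_expr_cohort <- function(n_genes = 9, n_samples = 17, seed = 42, sd = 1.2) {
  withr::with_seed(seed, {
    genes <- sprintf("g%02d", seq_len(n_genes))
    samples <- sprintf("s%02d", seq_len(n_samples))
    mat <- matrix(rnorm(n_genes * n_samples, 8, sd), n_genes,
                  dimnames = list(genes, samples))
    dplyr::bind_cols(tibble::tibble(probe_id = genes), tibble::as_tibble(mat))
  })
}

expr_to_cohort <- function(expr) {
  m <- as.matrix(expr[-1])
  rownames(m) <- expr$probe_id
  dplyr::bind_cols(tibble::tibble(sample_id = colnames(m)),
                   tibble::as_tibble(t(m)))
}
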