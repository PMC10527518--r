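# Fixture builders and independent oracles shared across the suite.

# minimal valid cohort with hand-chosen values
make_tiny_cohort <- function(n_malignant = 2, n_benign = 2, p = 2, seed = 7) {
  n <- n_malignant + n_benign
  withr::with_seed(seed, {
    df <- tibble::tibble(
      patient_id = sprintf("T%02d", seq_len(n)),
      label = c(rep(1L, n_malignant), rep(0L, n_benign)),
      histotype = c(rep("clear_cell", n_malignant), rep("oncocytoma", n_benign)),
      scanner_model = rep(c("S1", "S2"), length.out = n),
      convolution_kernel = rep(c("K1", "K2"), length.out = n),
      pixel_spacing_mm = runif(n, 0.61, 0.98),
      slice_thickness_mm = runif(n, 1.5, 2.5),
      tube_voltage_kvp = runif(n, 100, 130)
    )
    for (j in seq_len(p)) df[[sprintf("rf%03d", j)]] <- rnorm(n)
    radsig::as_cohort(df)
  })
}

# brute-force Mann-Whitney U by pair counting (ties count 1/2)
brute_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
  u
}

# brute-force ROC-AUC: P(score_pos > score_neg) + 0.5 P(equal)
brute_auc <- function(scores, labels) {
  brute_u(scores[labels == 1], scores[labels == 0]) /
    (sum(labels == 1) * sum(labels == 0))
}

# mid-ranks computed by hand (average rank of tied values)
mid_ranks <- function(v) {
  out <- numeric(length(v))
  for (i in seq_along(v)) {
    out[i] <- sum(v < v[i]) + (1 + sum(v == v[i])) / 2
  }
  out
}

# brute-force kNN malignancy scores via all-pairs distances
brute_knn <- function(ref, ref_labels, queries, k) {
  vapply(seq_len(nrow(queries)), function(i) {
    d <- sqrt(rowSums((ref - matrix(queries[i, ], nrow(ref), ncol(ref),
                                    byrow = TRUE))^2))
    mean(ref_labels[order(d)[seq_len(k)]])
  }, numeric(1))
}
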