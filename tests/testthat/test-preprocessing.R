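# Redundancy elimination, standardization transfer, and RWO oversampling.

test_that("an exact affine copy is dropped with r = 1 recorded", {
  withr::with_seed(1, {
    df <- tibble::tibble(fa = rnorm(20))
    df$fb <- 2 * df$fa + 5
    df$fc <- rnorm(20)
  })
  res <- eliminate_redundant(df, threshold = 0.99, features = c("fa", "fb", "fc"))
  expect_setequal(res$kept, c("fa", "fc"))
  expect_equal(res$report$feature, "fb")
  expect_equal(res$report$partner, "fa")
  expect_equal(res$report$r, 1, tolerance = 1e-12)
})

test_that("independent features are retained and zero-variance flagged", {
  withr::with_seed(2, df <- tibble::tibble(fa = rnorm(85), fb = rnorm(85),
                                           fz = rep(3, 85)))
  res <- eliminate_redundant(df, features = names(df))
  expect_setequal(res$kept, c("fa", "fb"))
  expect_equal(res$report$reason, "zero_variance")
  expect_true(is.na(res$report$r))
})

test_that("a generator block of 3 redundant features keeps exactly 1 survivor,
          matching the rule applied by hand", {
  cfg <- generator_config(n_features = 6, n_informative = 0,
                          n_redundant_blocks = 1, block_size = 3,
                          redundancy_noise_sd = 0.01, n_batch_affected = 0)
  co <- generate_cohort(cfg, seed = 4)
  gt <- ground_truth(co)
  block <- sort(gt$feature[grepl("redundant", gt$role)])
  res <- eliminate_redundant(co, threshold = 0.99)
  expect_length(intersect(res$kept, block), 1)
  # hand application: lexicographically first block member survives,
  # because all pairwise |r| > 0.99 (verified by brute force)
  cm <- abs(cor(as.matrix(co[block])))
  expect_true(all(cm[upper.tri(cm)] > 0.99))
  expect_true(block[1] %in% res$kept)
})

test_that("no surviving pair exceeds the threshold (recomputed)", {
  withr::with_seed(6, {
    base <- matrix(rnorm(60 * 4), 60, 4)
    m <- cbind(base, base[, 1] + rnorm(60, 0, 0.05),
               base[, 2] + rnorm(60, 0, 0.02))
    colnames(m) <- sprintf("f%02d", 1:6)
    df <- tibble::as_tibble(m)
  })
  res <- eliminate_redundant(df, threshold = 0.99, features = names(df))
  cm <- abs(cor(as.matrix(df[res$kept])))
  diag(cm) <- 0
  expect_lte(max(cm), 0.99)
})

test_that("standardizer stores sample moments and applies them exactly", {
  df <- tibble::tibble(f = c(1, 2, 3))
  std <- fit_standardizer(df, features = "f")
  expect_equal(tidy(std)$mean, 2)
  expect_equal(tidy(std)$sd, 1)
  z <- apply_standardizer(std, df)
  expect_equal(mean(z$f), 0)
  expect_equal(sd(z$f), 1)
  # empty new data passes through
  expect_equal(nrow(apply_standardizer(std, df[0, , drop = FALSE])), 0)
})

test_that("standardization transfers without refitting: a shifted copy is
          not recentred", {
  withr::with_seed(11, df <- tibble::tibble(f = rnorm(40, 5, 2)))
  std <- fit_standardizer(df, features = "f")
  shifted <- dplyr::mutate(df, f = f + 10)
  z <- apply_standardizer(std, shifted)
  expect_equal(mean(z$f), 10 / tidy(std)$sd, tolerance = 1e-10)
  expect_error(apply_standardizer(std, tibble::tibble(g = 1:3)), "lacks")
  expect_error(fit_standardizer(tibble::tibble(f = rep(1, 5)), features = "f"),
               "zero-variance")
})

test_that("RWO degenerate cases: zero rows requested, zero-variance feature", {
  x <- tibble::tibble(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_equal(nrow(rwo_oversample(x, 0)), 0)
  synth <- rwo_oversample(x, 50, seed = 3)
  expect_true(all(synth$b == 5))  # zero step when sigma_j = 0
  expect_error(rwo_oversample(x[1, ], 5), "at least 2")
})

test_that("RWO preserves the minority mean and has the closed-form variance", {
  m <- 50
  withr::with_seed(21, x <- tibble::tibble(f = rnorm(m, 3, 2)))
  synth <- rwo_oversample(x, 5000, seed = 22)
  sig_hat <- sqrt(mean((x$f - mean(x$f))^2))
  walk_sd <- sqrt(sig_hat^2 * (1 + 1 / m))
  expect_lt(abs(mean(synth$f) - 3), 3 * walk_sd / sqrt(5000) + abs(mean(x$f) - 3))
  expect_lt(abs(sd(synth$f) - walk_sd) / walk_sd, 0.05)
})

test_that("balancing appends flagged synthetic minority rows to parity", {
  co <- generate_cohort(seed = 13)
  sp <- stratified_split(co, 0.2, seed = 14)
  expect_equal(table(sp$train$label)[["1"]], 41)
  expect_equal(table(sp$train$label)[["0"]], 27)
  bal <- balance_classes(sp$train, seed = 15)
  expect_equal(sum(bal$label == 0), sum(bal$label == 1))
  expect_equal(sum(bal$.synthetic), 14)
  expect_true(all(bal$.synthetic[bal$label == 1] == FALSE))
  # already balanced input is unchanged
  even <- make_tiny_cohort(3, 3)
  expect_equal(nrow(balance_classes(even)), 6)
})
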