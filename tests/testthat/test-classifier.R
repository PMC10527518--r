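# Dimensionality reduction, kNN scoring, metrics and the training MCCV.

test_that("PCA recovers an exact low-rank embedding", {
  withr::with_seed(71, {
    basis <- qr.Q(qr(matrix(rnorm(20), 10, 2)))
    scores <- matrix(rnorm(80), 40, 2) %*% diag(c(3, 1))
    x <- scores %*% t(basis)  # lies exactly in a 2-D plane of 10-D space
  })
  red <- fit_reduction(x, model_config("pca", d = 2))
  proj <- predict(red, x)
  recon <- sweep(proj %*% t(red$rotation), 2, red$center, `+`)
  expect_lt(max(abs(recon - x)), 1e-10)
})

test_that("PCA component variances equal the covariance eigenvalues", {
  withr::with_seed(72, x <- matrix(rnorm(200 * 5), 200, 5))
  red <- fit_reduction(x, model_config("pca", d = 3))
  ev <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(red$variances, ev[1:3], tolerance = 1e-10)
  expect_equal(unname(apply(predict(red, x), 2, var)), ev[1:3],
               tolerance = 1e-10)
  # sign convention: each component's largest-magnitude loading is positive
  for (j in 1:3) expect_gt(red$rotation[which.max(abs(red$rotation[, j])), j], 0)
})

test_that("ICA is deterministic under a seed and spans the whitened space", {
  withr::with_seed(73, {
    s <- cbind(runif(300, -2, 2), sign(rnorm(300)) * rexp(300))
    x <- s %*% matrix(c(1, 0.5, -0.3, 1), 2, 2)
    x <- cbind(x, rnorm(300, sd = 0.1))
  })
  a <- fit_reduction(x, model_config("ica", d = 2), seed = 5)
  b <- fit_reduction(x, model_config("ica", d = 2), seed = 5)
  expect_identical(a$rotation, b$rotation)
  proj <- predict(a, x)
  # recovered sources are uncorrelated with unit variance
  expect_equal(unname(cov(proj)), diag(2), tolerance = 0.05)
  expect_error(fit_reduction(matrix(rnorm(6), 3, 2), model_config("pca", 3)),
               "rows|rank")
})

test_that("rank-deficient data refuses a too-large d", {
  x <- cbind(1:10, (1:10) * 2)  # rank 1
  expect_error(fit_reduction(x, model_config("pca", d = 2)), "rank")
})

test_that("kNN scores match a brute-force all-pairs oracle", {
  withr::with_seed(74, {
    tr <- make_tiny_cohort(12, 10, p = 4)
    qu <- make_tiny_cohort(5, 4, p = 4, seed = 75)
  })
  sig <- feature_names(tr)
  model <- train_model(tr, sig, model_config("pca", 2, 5), seed = 76)
  got <- knn_score(model, qu)
  z <- apply_standardizer(model$standardizer, qu)
  q <- predict(model$reduction, z[sig])
  oracle <- brute_knn(model$ref, model$ref_labels, q, 5)
  expect_equal(got$score, oracle)
  expect_equal(got$predicted, as.integer(oracle > 0.5))
  # independent cross-check on tie-free continuous data
  ref_class <- class::knn(model$ref, q, factor(model$ref_labels), k = 5)
  expect_equal(got$predicted, as.integer(as.character(ref_class)))
  expect_error(knn_score(model, qu, k = 999), "exceeds")
})

test_that("kNN degenerate geometries behave as stated", {
  # query identical to a reference with k = 1 returns that label;
  # a center query equidistant from a balanced reference set scores 0.5
  ref <- tibble::tibble(label = c(1L, 1L, 0L, 0L),
                        patient_id = letters[1:4],
                        f1 = c(1, -1, 0, 0), f2 = c(0, 0, 1, -1))
  model <- structure(list(
    standardizer = structure(list(params = tibble::tibble(
      feature = c("f1", "f2"), mean = c(0, 0), sd = c(1, 1))),
      class = "standardizer"),
    signature = c("f1", "f2"),
    reduction = structure(list(type = "pca", d = 2, center = c(f1 = 0, f2 = 0),
                               rotation = diag(2), variances = c(1, 1),
                               features = c("f1", "f2")), class = "reduction"),
    ref = as.matrix(ref[, c("f1", "f2")]),
    ref_labels = ref$label,
    config = model_config("pca", 2, 3)), class = "knn_model")
  at_ref <- knn_score(model, tibble::tibble(f1 = 1, f2 = 0), k = 1)
  expect_equal(at_ref$score, 1)
  center <- knn_score(model, tibble::tibble(f1 = 0, f2 = 0), k = 4)
  expect_equal(center$score, 0.5)
})

test_that("metrics match their definitions and the AUC-U identity", {
  perfect <- evaluate_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(unlist(perfect), c(auc = 1, accuracy = 1, sensitivity = 1,
                                  specificity = 1, ppv = 1, npv = 1,
                                  f1_minority = 1))
  flipped <- evaluate_metrics(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  expect_equal(flipped$auc, 0)
  withr::with_seed(77, {
    for (i in 1:25) {
      sc <- round(runif(8), 1)  # ties likely
      lb <- c(1, 1, 1, sample(0:1, 4, replace = TRUE), 0)
      m <- evaluate_metrics(sc, lb)
      expect_equal(m$auc, brute_auc(sc, lb))
      # PPV from sensitivity/specificity/prevalence (Bayes identity)
      pi1 <- mean(lb)
      denom <- m$sensitivity * pi1 + (1 - m$specificity) * (1 - pi1)
      if (!is.na(m$ppv) && denom > 0) {
        expect_equal(m$ppv, m$sensitivity * pi1 / denom, tolerance = 1e-12)
      }
    }
  })
  expect_error(evaluate_metrics(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("training MCCV returns bounded per-round metrics and flags a
          single-round summary", {
  cfg <- generator_config(n_features = 12, n_informative = 4, effect_size = 2,
                          n_redundant_blocks = 0, n_batch_affected = 0)
  co <- generate_cohort(cfg, seed = 80)
  sp <- stratified_split(co, 0.2, seed = 81)
  sig <- paste0("rf00", 1:4)
  pm <- run_training_mccv(sp$train, sp$test, sig, model_config(), rounds = 5,
                          base_seed = 82)
  tt <- tidy(pm)
  expect_equal(nrow(tt), 10)  # 5 rounds x validation/test
  mets <- unlist(tt[, c("auc", "accuracy", "sensitivity", "specificity",
                        "f1_minority")])
  expect_true(all(mets >= 0 & mets <= 1))
  one <- run_training_mccv(sp$train, sp$test, sig, model_config(), rounds = 1,
                           base_seed = 83)
  expect_true(one$degenerate)
  expect_true(all(one$summary$sd == 0))
})

test_that("tuning returns the single config of a singleton grid and is
          reproducible", {
  cfg <- generator_config(n_features = 10, n_informative = 3, effect_size = 1.5,
                          n_redundant_blocks = 0, n_batch_affected = 0)
  tr <- stratified_split(generate_cohort(cfg, seed = 84), 0.2, seed = 85)$train
  sig <- paste0("rf00", 1:3)
  single <- tune_model(tr, sig, reductions = "pca", d_values = 2, k_values = 7,
                       rounds = 3, base_seed = 86)
  expect_equal(unclass(single$best_config),
               unclass(model_config("pca", 2, 7)))
  a <- tune_model(tr, sig, rounds = 3, base_seed = 87)
  b <- tune_model(tr, sig, rounds = 3, base_seed = 87)
  expect_identical(a$curve, b$curve)
  expect_true(a$best_config$d %in% c(2, 3))
  # the curve covers every grid point
  expect_equal(nrow(a$curve), 2 * 2 * 7)
})
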