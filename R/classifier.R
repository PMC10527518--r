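# Second MCCV: dimensionality reduction (PCA or ICA) + kNN on a fixed
# signature, hyperparameter tuning by mean validation F1 (minority class),
# and per-round evaluation on the untouched test set.

#' Classifier configuration
#'
#' The tuned default - PCA with two components and k = 7 neighbours - is
#' the configuration that maximized mean validation F1 in the renal-mass
#' study this package implements.
#'
#' @param reduction `"pca"` or `"ica"`.
#' @param d Number of components, 2 or 3 (kept low for explainability and
#'   to avoid the curse of dimensionality).
#' @param k Number of neighbours; odd and >= 3 so majority votes cannot
#'   tie.
#' @return A `model_config` list.
#' @export
model_config <- function(reduction = c("pca", "ica"), d = 2, k = 7) {
  reduction <- match.arg(reduction)
  abort_if(!d %in% c(2, 3), "d must be 2 or 3")
  abort_if(k < 3 || k %% 2 == 0, "k must be an odd integer >= 3")
  structure(list(reduction = reduction, d = as.integer(d), k = as.integer(k)),
            class = "model_config")
}

fix_component_signs <- function(w) {
  for (j in seq_len(ncol(w))) {
    i <- which.max(abs(w[, j]))
    if (w[i, j] < 0) w[, j] <- -w[, j]
  }
  w
}

sym_decorrelate <- function(w) {
  e <- eigen(w %*% t(w), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(e$values), nrow = length(e$values)) %*%
    t(e$vectors) %*% w
}

# Symmetric fixed-point FastICA with the tanh (logcosh) nonlinearity on
# pre-whitened data; deterministic given the RNG state at entry.
fastica_unmix <- function(z, max_iter = 200, tol = 1e-6) {
  d <- ncol(z)
  n <- nrow(z)
  w <- sym_decorrelate(matrix(rnorm(d * d), d, d))
  for (it in seq_len(max_iter)) {
    s <- z %*% t(w)
    g <- tanh(s)
    w_new <- crossprod(g, z) / n - diag(colMeans(1 - g^2), nrow = d) %*% w
    w_new <- sym_decorrelate(w_new)
    delta <- max(abs(abs(diag(w_new %*% t(w))) - 1))
    w <- w_new
    if (delta < tol) break
  }
  w
}

#' Fit a dimensionality reduction on (standardized) training features
#'
#' PCA takes the top-`d` eigenvectors of the sample covariance, components
#' ordered by decreasing variance. ICA whitens to `d` principal components
#' and runs symmetric fixed-point FastICA (logcosh nonlinearity) under the
#' supplied seed; its components are re-ordered by decreasing explained
#' variance. For both, each component's sign is fixed so that its
#' largest-magnitude loading is positive, making the transform
#' deterministic.
#'
#' @param x Data frame or matrix of standardized training features.
#' @param config A [model_config()].
#' @param seed Optional seed for the ICA initialisation; `NULL` uses the
#'   current RNG stream.
#' @return A `reduction` object usable with [predict()].
#' @export
fit_reduction <- function(x, config = model_config(), seed = NULL) {
  xm <- as.matrix(x)
  d <- config$d
  abort_if(nrow(xm) <= d, "need more rows than components")
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  ev <- eigen(cov(xc), symmetric = TRUE)
  pos <- sum(ev$values > max(ev$values) * 1e-10)
  abort_if(pos < d,
           paste0("data rank (", pos, ") is below the requested d = ", d))
  if (config$reduction == "pca") {
    rotation <- fix_component_signs(ev$vectors[, seq_len(d), drop = FALSE])
    variances <- ev$values[seq_len(d)]
  } else {
    rotation <- with_seed(seed, {
      k_whiten <- ev$vectors[, seq_len(d), drop = FALSE] %*%
        diag(1 / sqrt(ev$values[seq_len(d)]), nrow = d)
      w <- fastica_unmix(xc %*% k_whiten)
      k_whiten %*% t(w)
    })
    # explained variance of component i = ||cov(x, s_i)||^2 (sources have
    # unit variance), used to order the components
    a <- crossprod(xc, xc %*% rotation) / (nrow(xc) - 1)
    variances <- colSums(a^2)
    ord <- order(variances, decreasing = TRUE)
    rotation <- fix_component_signs(rotation[, ord, drop = FALSE])
    variances <- variances[ord]
  }
  colnames(rotation) <- paste0("C", seq_len(d))
  structure(list(type = config$reduction, d = d, center = mu,
                 rotation = rotation, variances = variances,
                 features = colnames(xm)),
            class = "reduction")
}

#' Project new data with a fitted reduction
#'
#' @param object A `reduction` from [fit_reduction()].
#' @param newdata Data frame or matrix containing the fitted feature
#'   columns.
#' @param ... Unused.
#' @return Matrix of component scores (rows x d).
#' @export
predict.reduction <- function(object, newdata, ...) {
  nd <- if (is.null(object$features)) {
    as.matrix(newdata)  # unnamed training matrix: positional columns
  } else {
    as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  }
  sweep(nd, 2, object$center) %*% object$rotation
}

#' Train a reduced-space kNN model on a training subset
#'
#' Fits, on the given subset only: the z-score standardizer for the
#' signature features, RWO class balancing, and the dimensionality
#' reduction; the balanced, projected rows become the kNN reference set.
#' Nothing is ever refitted on data scored later, so validation and test
#' rows see the training subset's parameters unchanged.
#'
#' @param train_subset Cohort subset with `label` and the signature
#'   features.
#' @param signature Character vector of feature names to use.
#' @param config A [model_config()].
#' @param seed Optional seed driving balancing (and ICA, if used).
#' @return A `knn_model` object.
#' @export
train_model <- function(train_subset, signature, config = model_config(),
                        seed = NULL) {
  missing_cols <- setdiff(signature, names(train_subset))
  abort_if(length(missing_cols) > 0,
           paste0("signature feature(s) absent: ",
                  paste(missing_cols, collapse = ", ")))
  with_seed(seed, {
    std <- fit_standardizer(train_subset, features = signature)
    z <- apply_standardizer(std, train_subset)
    bal <- balance_classes(z[, c("patient_id", "label", signature)])
    red <- fit_reduction(bal[signature], config)
    refs <- predict(red, bal[signature])
    structure(list(standardizer = std, signature = signature,
                   reduction = red, ref = refs,
                   ref_labels = bal$label, config = config),
              class = "knn_model")
  })
}

#' Score new patients with a trained kNN model
#'
#' Each query row is standardized with the model's stored parameters,
#' projected into component space, and scored as the fraction of its `k`
#' Euclidean-nearest reference points labelled malignant; the predicted
#' label is malignant when the score exceeds 0.5 (odd `k` means votes
#' cannot tie). Exact distance ties are broken by reference insertion
#' order.
#'
#' @param model A `knn_model` from [train_model()].
#' @param newdata Cohort subset containing the signature features on their
#'   original scale.
#' @param k Number of neighbours; defaults to the model's configured `k`.
#' @return A tibble with `score` (malignancy score in \[0, 1\]) and
#'   `predicted` (0/1).
#' @export
knn_score <- function(model, newdata, k = NULL) {
  stopifnot(inherits(model, "knn_model"))
  k <- k %||% model$config$k
  abort_if(k > nrow(model$ref),
           paste0("k = ", k, " exceeds the ", nrow(model$ref),
                  " reference points"))
  z <- apply_standardizer(model$standardizer, newdata)
  q <- predict(model$reduction, z[model$signature])
  score <- vapply(seq_len(nrow(q)), function(i) {
    d2 <- colSums((t(model$ref) - q[i, ])^2)
    nn <- order(d2)[seq_len(k)]  # radix order is stable: ties by insertion
    mean(model$ref_labels[nn])
  }, numeric(1))
  tibble::tibble(score = score, predicted = as.integer(score > 0.5))
}

#' Classification metrics for malignancy scores
#'
#' Sensitivity, specificity, PPV and NPV use malignant as the positive
#' class; the F1 score uses the benign (minority) class as positive, the
#' convention of the renal-mass signature study. ROC-AUC is computed as
#' the normalized Mann-Whitney U of the scores (ties count 1/2), which
#' equals the area under the empirical ROC curve.
#'
#' @param scores Malignancy scores in \[0, 1\].
#' @param labels True labels (1 = malignant, 0 = benign); both classes
#'   must be present.
#' @param threshold Decision threshold on the score; default 0.5.
#' @return One-row tibble with `auc`, `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `f1_minority`. PPV/NPV are `NA` when no
#'   patient is predicted in the respective class.
#' @export
evaluate_metrics <- function(scores, labels, threshold = 0.5) {
  abort_if(length(scores) != length(labels), "scores/labels length mismatch")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  abort_if(n1 == 0 || n0 == 0, "both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    auc = auc,
    accuracy = (tp + tn) / length(labels),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    # benign as positive class: TP_b = tn, FP_b = fn, FN_b = fp
    f1_minority = 2 * tn / (2 * tn + fn + fp)
  )
}

#' Monte Carlo cross-validated training and evaluation
#'
#' Per round (round `r` runs under `base_seed + r`): draw a stratified
#' 80/20 subset of the training set, train the model on the 80% part, and
#' evaluate on the untouched 20% validation subset and on the fixed test
#' set. Model hyperparameters stay fixed across rounds; means and standard
#' deviations over rounds summarize stability.
#'
#' @param training Training-set cohort.
#' @param test Held-out test-set cohort (never used for fitting).
#' @param signature Feature names the model may use.
#' @param config A [model_config()].
#' @param rounds Number of MCCV rounds; default 100.
#' @param base_seed Base seed.
#' @param subset_fraction Per-round training share; default 0.8.
#' @return An `mccv_performance` object; `tidy()` gives per-round metrics,
#'   `summary()`/`glance()` the mean +/- sd table.
#' @export
run_training_mccv <- function(training, test, signature,
                              config = model_config(), rounds = 100,
                              base_seed = 0, subset_fraction = 0.8) {
  abort_if(rounds < 1, "rounds must be >= 1")
  rows <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    rows[[r]] <- with_seed(base_seed + r, {
      sp <- stratified_split(training, test_fraction = 1 - subset_fraction)
      model <- train_model(sp$train, signature, config)
      val <- evaluate_metrics(knn_score(model, sp$test)$score, sp$test$label)
      tst <- evaluate_metrics(knn_score(model, test)$score, test$label)
      dplyr::bind_rows(
        dplyr::mutate(val, round = r, subset = "validation", .before = 1),
        dplyr::mutate(tst, round = r, subset = "test", .before = 1)
      )
    })
  }
  per_round <- dplyr::bind_rows(rows)
  metric_cols <- c("auc", "accuracy", "sensitivity", "specificity",
                   "ppv", "npv", "f1_minority")
  summ <- per_round |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric") |>
    dplyr::group_by(.data$subset, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(sd = ifelse(is.na(.data$sd), 0, .data$sd),
                  metric = factor(.data$metric, levels = metric_cols)) |>
    dplyr::arrange(.data$subset, .data$metric) |>
    dplyr::mutate(metric = as.character(.data$metric))
  structure(list(per_round = per_round, summary = summ, config = config,
                 rounds = rounds, base_seed = base_seed,
                 degenerate = rounds == 1),
            class = "mccv_performance")
}

#' @export
tidy.mccv_performance <- function(x, ...) x$per_round

#' @export
glance.mccv_performance <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = c("subset", "metric"),
                             values_from = c("mean", "sd"))
  dplyr::bind_cols(tibble::tibble(rounds = x$rounds), wide)
}

#' @export
summary.mccv_performance <- function(object, ...) {
  tidyr::pivot_wider(object$summary, names_from = "subset",
                     values_from = c("mean", "sd"))
}

#' @export
print.mccv_performance <- function(x, ...) {
  cat("MCCV performance over", x$rounds, "rounds (",
      toupper(x$config$reduction), " d =", x$config$d, ", k =", x$config$k,
      ")\n", sep = " ")
  if (x$degenerate) cat("note: single round; standard deviations are 0 by convention\n")
  s <- x$summary
  for (sub in unique(s$subset)) {
    cat("\n", sub, " set:\n", sep = "")
    ss <- s[s$subset == sub, ]
    for (i in seq_len(nrow(ss))) {
      cat(sprintf("  %-12s %.2f +/- %.2f\n", ss$metric[i], ss$mean[i], ss$sd[i]))
    }
  }
  invisible(x)
}

#' Tune the classifier by paired Monte Carlo cross-validation
#'
#' Evaluates every combination of reduction technique, number of
#' components `d` and neighbour count `k` with common per-round seeds (the
#' per-round subsets are identical across the grid, a paired comparison)
#' and returns the configuration maximizing mean validation F1 of the
#' minority (benign) class. Ties are broken by smaller `d`, then smaller
#' `k`, then PCA over ICA. Test-set performance is deliberately not
#' consulted here; extract it for the chosen configuration with
#' [run_training_mccv()].
#'
#' @param training Training-set cohort.
#' @param signature Feature names the model may use.
#' @param reductions,d_values,k_values Grid axes; defaults `pca`/`ica`,
#'   `d = 2, 3`, odd `k` from 3 to 15.
#' @param rounds MCCV rounds per grid point; default 100.
#' @param base_seed Base seed shared across the grid.
#' @param subset_fraction Per-round training share; default 0.8.
#' @return A `tuning_result` with `best_config` and the tuning `curve`
#'   (mean/sd validation F1 per grid point).
#' @export
tune_model <- function(training, signature, reductions = c("pca", "ica"),
                       d_values = c(2, 3), k_values = c(3, 5, 7, 9, 11, 13, 15),
                       rounds = 100, base_seed = 0, subset_fraction = 0.8) {
  abort_if(length(reductions) == 0 || length(d_values) == 0 ||
             length(k_values) == 0, "tuning grid is empty")
  curve_rows <- list()
  for (red in reductions) {
    for (d in d_values) {
      f1 <- matrix(NA_real_, nrow = rounds, ncol = length(k_values))
      for (r in seq_len(rounds)) {
        with_seed(base_seed + r, {
          sp <- stratified_split(training, test_fraction = 1 - subset_fraction)
          model <- train_model(sp$train, signature,
                               model_config(red, d, k = min(k_values)))
          for (ki in seq_along(k_values)) {
            sc <- knn_score(model, sp$test, k = k_values[ki])
            f1[r, ki] <- evaluate_metrics(sc$score, sp$test$label)$f1_minority
          }
        })
      }
      curve_rows[[length(curve_rows) + 1]] <- tibble::tibble(
        reduction = red, d = d, k = k_values,
        mean_f1 = colMeans(f1), sd_f1 = apply(f1, 2, stats::sd))
    }
  }
  curve <- dplyr::bind_rows(curve_rows)
  best <- curve |>
    dplyr::mutate(red_pref = match(.data$reduction, c("pca", "ica"))) |>
    dplyr::arrange(dplyr::desc(.data$mean_f1), .data$d, .data$k,
                   .data$red_pref) |>
    dplyr::slice(1)
  structure(list(curve = curve,
                 best_config = model_config(best$reduction, best$d, best$k),
                 rounds = rounds, base_seed = base_seed),
            class = "tuning_result")
}

#' @export
tidy.tuning_result <- function(x, ...) x$curve

#' @export
print.tuning_result <- function(x, ...) {
  b <- x$best_config
  cat("Tuned configuration:", toupper(b$reduction), "with d =", b$d,
      "and k =", b$k, "\n")
  cat("(argmax of mean validation F1, minority class, over", x$rounds,
      "paired MCCV rounds)\n")
  invisible(x)
}
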