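# Preprocessing: redundancy elimination, z-score standardization with
# train-to-unseen transfer, and random walk oversampling of the minority
# class.

features_of <- function(x, features = NULL) {
  features <- features %||% feature_names(x)
  abort_if(length(setdiff(features, names(x))) > 0,
           paste0("unknown feature(s): ",
                  paste(setdiff(features, names(x)), collapse = ", ")))
  x[features]
}

#' Drop redundant (near-duplicate) features
#'
#' Computes the Pearson cross-correlation matrix of the feature columns and
#' removes one member of every pair with `|r|` above `threshold`. Features
#' are scanned in lexicographic name order and the later-named member of a
#' redundant pair is dropped, so the result is deterministic and invariant
#' to row order. Zero-variance features are removed first with a distinct
#' report entry (their correlation is undefined).
#'
#' @param x A data frame whose non-reserved columns are features, or a
#'   plain feature table.
#' @param threshold Redundancy threshold on `|r|`; default 0.99.
#' @param features Optional subset of feature columns to consider.
#' @return A list with `kept` (surviving feature names) and `report`, a
#'   tibble of drops with columns `feature`, `partner`, `r`, `reason`.
#' @export
eliminate_redundant <- function(x, threshold = 0.99, features = NULL) {
  abort_if(threshold <= 0 || threshold >= 1, "threshold must be in (0, 1)")
  feats <- features %||% feature_names(x)
  fx <- features_of(x, feats)
  abort_if(nrow(fx) < 2, "need at least 2 rows")
  ord <- sort(feats)
  sds <- vapply(fx[ord], stats::sd, numeric(1))
  zero_var <- ord[sds == 0]
  report <- tibble::tibble(feature = zero_var,
                           partner = NA_character_,
                           r = NA_real_,
                           reason = rep("zero_variance", length(zero_var)))
  ord <- setdiff(ord, zero_var)
  if (length(ord) >= 2) {
    cm <- stats::cor(as.matrix(fx[ord]))
    dropped <- character(0)
    for (i in seq_len(length(ord) - 1)) {
      fi <- ord[i]
      if (fi %in% dropped) next
      for (j in seq((i + 1), length(ord))) {
        fj <- ord[j]
        if (fj %in% dropped) next
        if (abs(cm[fi, fj]) > threshold) {
          dropped <- c(dropped, fj)
          report <- dplyr::bind_rows(report, tibble::tibble(
            feature = fj, partner = fi, r = cm[fi, fj], reason = "redundant"))
        }
      }
    }
    ord <- setdiff(ord, dropped)
  }
  list(kept = ord, report = report)
}

#' Fit per-feature z-score standardization parameters
#'
#' Stores the per-feature sample mean and sample standard deviation (n - 1
#' denominator) of a training table, for transfer to unseen data with
#' [apply_standardizer()]: preprocessing is fitted once on the training
#' subset and never refitted downstream.
#'
#' @param x Training data frame (feature columns used).
#' @param features Optional subset of feature columns.
#' @param fitted_on Optional identifier of the training subset, kept for
#'   audit.
#' @return A `standardizer` object.
#' @export
fit_standardizer <- function(x, features = NULL, fitted_on = NULL) {
  fx <- features_of(x, features)
  abort_if(nrow(fx) < 2, "need at least 2 rows to fit a standardizer")
  mu <- vapply(fx, mean, numeric(1))
  sig <- vapply(fx, stats::sd, numeric(1))
  bad <- names(sig)[sig == 0]
  abort_if(length(bad) > 0,
           paste0("zero-variance feature(s): ", paste(bad, collapse = ", "),
                  "; remove them with eliminate_redundant() first"))
  structure(list(params = tibble::tibble(feature = names(mu), mean = unname(mu),
                                         sd = unname(sig)),
                 fitted_on = fitted_on),
            class = "standardizer")
}

#' @export
tidy.standardizer <- function(x, ...) x$params

#' Apply stored standardization parameters to new data
#'
#' Computes `(x - mean) / sd` with the parameters stored at fit time; the
#' parameters are never refitted, so columns of unseen data are not
#' mean-0/sd-1 in general.
#'
#' @param params A `standardizer` from [fit_standardizer()].
#' @param x Data frame containing the fitted feature columns (other columns
#'   are passed through unchanged).
#' @return `x` with the fitted feature columns standardized.
#' @export
apply_standardizer <- function(params, x) {
  stopifnot(inherits(params, "standardizer"))
  missing_cols <- setdiff(params$params$feature, names(x))
  abort_if(length(missing_cols) > 0,
           paste0("data lacks fitted feature(s): ",
                  paste(missing_cols, collapse = ", ")))
  x <- tibble::as_tibble(x)
  for (i in seq_len(nrow(params$params))) {
    f <- params$params$feature[i]
    x[[f]] <- (x[[f]] - params$params$mean[i]) / params$params$sd[i]
  }
  x
}

#' Random walk oversampling (RWO) of a minority class
#'
#' Generates synthetic minority rows designed to preserve the minority
#' class mean and variance: each synthetic row starts from a uniformly
#' chosen real minority row `x` and takes a Gaussian step per feature,
#' `x'_j = x_j - (sigma_j / sqrt(m)) * r_j`, where `m` is the number of
#' minority rows, `sigma_j` the minority standard deviation of feature `j`
#' (population form, denominator `m`), and `r_j` i.i.d. standard normal.
#' The per-feature variance of the walk is `sigma_j^2 * (1 + 1/m)`.
#'
#' @param x Data frame or matrix of minority-class feature rows, `m >= 2`.
#' @param n_synthetic Number of synthetic rows to draw.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return A tibble of `n_synthetic` synthetic rows with the same columns.
#' @export
rwo_oversample <- function(x, n_synthetic, seed = NULL) {
  x <- as.matrix(x)
  m <- nrow(x)
  abort_if(m < 2, "need at least 2 minority rows (sd undefined otherwise)")
  abort_if(n_synthetic < 0, "n_synthetic must be >= 0")
  if (n_synthetic == 0) {
    return(tibble::as_tibble(x[0, , drop = FALSE]))
  }
  with_seed(seed, {
    sig <- sqrt(colMeans(sweep(x, 2, colMeans(x))^2))  # population sd
    src <- sample.int(m, n_synthetic, replace = TRUE)
    steps <- matrix(rnorm(n_synthetic * ncol(x)), nrow = n_synthetic)
    synth <- x[src, , drop = FALSE] - sweep(steps, 2, sig / sqrt(m), `*`)
    tibble::as_tibble(synth)
  })
}

#' Balance a training subset by oversampling the minority class
#'
#' Appends RWO-synthesized minority rows until both outcome classes have
#' equal counts. Synthetic rows are flagged in a `.synthetic` column (real
#' rows get `.synthetic = FALSE`) and carry no acquisition metadata, so
#' downstream acquisition-reproducibility tests can exclude them. Balancing
#' is meant for training subsets only and must never touch validation or
#' test data.
#'
#' @param x A cohort subset with a `label` column and feature columns.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return `x` with synthetic minority rows appended and `.synthetic`
#'   flags.
#' @export
balance_classes <- function(x, seed = NULL) {
  abort_if(!all(c(0L, 1L) %in% x$label), "both classes must be present")
  x <- tibble::as_tibble(x)
  if (!".synthetic" %in% names(x)) x$.synthetic <- FALSE
  counts <- table(factor(x$label, levels = c(0L, 1L)))
  deficit <- abs(counts[["1"]] - counts[["0"]])
  if (deficit == 0) return(x)
  minority <- if (counts[["0"]] < counts[["1"]]) 0L else 1L
  feats <- feature_names(x)
  synth <- rwo_oversample(x[x$label == minority, feats, drop = FALSE],
                          deficit, seed = seed)
  synth$label <- minority
  synth$patient_id <- sprintf("SYN%03d", seq_len(deficit))
  synth$.synthetic <- TRUE
  dplyr::bind_rows(x, synth)
}
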