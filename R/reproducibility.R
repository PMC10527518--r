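# Acquisition-parameter reproducibility screening: an ordered chain of five
# tests (scanner model, convolution kernel, pixel spacing, slice thickness,
# tube voltage) removing features associated with how the images were
# acquired or reconstructed rather than with the lesion.

#' Kruskal-Wallis rank test of a feature against a categorical parameter
#'
#' Thin wrapper around [stats::kruskal.test()] returning the tie-corrected
#' H statistic and its chi-square p-value on `nlevels - 1` degrees of
#' freedom. When every observation is tied (no rank variation) H is 0 and
#' p is 1.
#'
#' @param values Numeric vector of feature values.
#' @param groups Categorical parameter (factor or character).
#' @return A one-row tibble with `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  res <- kw_stat(values, droplevels(as.factor(groups)))
  tibble::tibble(statistic = res$statistic, df = res$df, p_value = res$p_value)
}

# list-returning core, shared with the screening loop
kw_stat <- function(values, groups) {
  abort_if(nlevels(groups) < 2, "need at least 2 groups")
  kt <- suppressWarnings(kruskal.test(values, groups))
  h <- unname(kt$statistic)
  p <- kt$p.value
  if (!is.finite(h)) {  # all observations tied: no rank variation
    h <- 0
    p <- 1
  }
  list(statistic = h, df = unname(kt$parameter), p_value = p)
}

#' Spearman rank correlation of a feature against a continuous parameter
#'
#' Tie-aware Spearman rho (Pearson correlation of mid-ranks). A constant
#' covariate (or constant feature) leaves rho undefined; it is reported as
#' 0 with `undefined = TRUE`.
#'
#' @param values Numeric vector of feature values.
#' @param covariate Numeric acquisition parameter of the same length.
#' @return A one-row tibble with `rho` and `undefined`.
#' @export
spearman_rho <- function(values, covariate) {
  abort_if(length(values) != length(covariate), "inputs must have equal length")
  abort_if(length(values) < 3, "need at least 3 observations")
  res <- rho_stat(values, rank(covariate))
  tibble::tibble(rho = res$rho, undefined = res$undefined)
}

# Spearman rho against a pre-ranked covariate; Pearson on mid-ranks
rho_stat <- function(values, cov_ranks) {
  if (stats::var(cov_ranks) == 0 || stats::var(values) == 0) {
    return(list(rho = 0, undefined = TRUE))
  }
  list(rho = stats::cor(rank(values), cov_ranks), undefined = FALSE)
}

repro_tests <- function() {
  tibble::tibble(
    test = c("scanner_model", "convolution_kernel", "pixel_spacing",
             "slice_thickness", "tube_voltage"),
    column = c("scanner_model", "convolution_kernel", "pixel_spacing_mm",
               "slice_thickness_mm", "tube_voltage_kvp"),
    kind = c("categorical", "categorical", "continuous", "continuous",
             "continuous")
  )
}

#' Screen features against acquisition parameters (reproducibility chain)
#'
#' Applies, per feature and in fixed order, five tests: Kruskal-Wallis
#' against scanner model (n.1) and convolution kernel (n.2), then Spearman
#' correlation against pixel spacing (n.3), slice thickness (n.4) and tube
#' voltage (n.5). A feature is removed at the first failing test -
#' KW p < `alpha` for the categorical tests, `|rho| > rho_threshold` for the
#' continuous ones - and is not tested further, so removals are attributed
#' to the earliest offending parameter. Synthetic (oversampled) rows carry
#' no acquisition metadata and are excluded. No multiple-testing correction
#' is applied: the raw per-test thresholds are the screening rule.
#'
#' @param x A cohort subset with metadata columns and feature columns.
#' @param alpha Significance level of the categorical tests; default 0.05.
#' @param rho_threshold Absolute Spearman correlation above which a feature
#'   is non-reproducible; default 0.75.
#' @param features Optional subset of features to screen.
#' @return A `repro_report` list with `kept` (surviving feature names),
#'   `report` (per-feature tibble: `feature`, `kept`, `removed_by`,
#'   `statistic`, `value`) and `skipped` (tests skipped because a
#'   categorical parameter had a single level in the subset).
#' @export
reproducibility_chain <- function(x, alpha = 0.05, rho_threshold = 0.75,
                                  features = NULL) {
  feats <- features %||% feature_names(x)
  if (".synthetic" %in% names(x)) x <- x[!x$.synthetic, , drop = FALSE]
  missing_meta <- setdiff(metadata_columns(), names(x))
  abort_if(length(missing_meta) > 0,
           paste0("missing metadata column(s): ",
                  paste(missing_meta, collapse = ", ")))
  tests <- repro_tests()
  skipped <- character(0)
  for (i in which(tests$kind == "categorical")) {
    if (length(unique(x[[tests$column[i]]])) < 2) {
      skipped <- c(skipped, tests$test[i])
    }
  }
  if (length(skipped) > 0) {
    warning("reproducibility test(s) skipped (single level in subset): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  # prepare grouping factors / covariate ranks once; the per-feature loop
  # only ranks the feature values
  prepared <- lapply(seq_len(nrow(tests)), function(ti) {
    if (tests$kind[ti] == "categorical") {
      droplevels(as.factor(x[[tests$column[ti]]]))
    } else {
      rank(x[[tests$column[ti]]])
    }
  })
  n <- length(feats)
  removed_by <- rep("none", n)
  statistic <- rep(NA_real_, n)
  value <- rep(NA_real_, n)
  for (fi in seq_len(n)) {
    v <- x[[feats[fi]]]
    for (ti in seq_len(nrow(tests))) {
      if (tests$test[ti] %in% skipped) next
      if (tests$kind[ti] == "categorical") {
        res <- kw_stat(v, prepared[[ti]])
        if (res$p_value < alpha) {
          removed_by[fi] <- tests$test[ti]
          statistic[fi] <- res$statistic
          value[fi] <- res$p_value
          break
        }
      } else {
        res <- rho_stat(v, prepared[[ti]])
        if (!res$undefined && abs(res$rho) > rho_threshold) {
          removed_by[fi] <- tests$test[ti]
          statistic[fi] <- res$rho
          value[fi] <- res$rho
          break
        }
      }
    }
  }
  report <- tibble::tibble(feature = feats, kept = removed_by == "none",
                           removed_by = removed_by, statistic = statistic,
                           value = value)
  structure(list(kept = feats[removed_by == "none"], report = report,
                 skipped = skipped, alpha = alpha,
                 rho_threshold = rho_threshold),
            class = "repro_report")
}

#' @export
tidy.repro_report <- function(x, ...) x$report

#' @export
summary.repro_report <- function(object, ...) {
  tests <- c(repro_tests()$test, "none")
  counts <- vapply(tests, function(t) sum(object$report$removed_by == t),
                   integer(1))
  tibble::tibble(test = tests, n_removed = counts,
                 fraction = counts / nrow(object$report))
}
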