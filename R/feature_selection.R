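# First MCCV: per-round preprocessing + Mann-Whitney univariable filter,
# cumulative feature scoring, and top-K signature selection.

#' Mann-Whitney U test
#'
#' `U` counts, over all cross pairs, the times an `x` value exceeds a `y`
#' value (ties count 1/2); equivalently `U = R_x - n_x(n_x + 1)/2` with
#' `R_x` the rank sum of `x` in the pooled sample. The two-sided p-value
#' uses exact enumeration when the pooled sample has at most 20
#' observations and no ties, and the tie-corrected normal approximation
#' otherwise.
#'
#' @param x,y Non-empty numeric vectors.
#' @return A one-row tibble with `u` (the U statistic of `x`) and
#'   `p_value`.
#' @export
mann_whitney <- function(x, y) {
  res <- mw_core(x, y)
  tibble::tibble(u = res$u, p_value = res$p_value)
}

mw_core <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  abort_if(n1 == 0 || n2 == 0, "both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  if (n <= 20 && !has_ties) {
    if (u > n1 * n2 / 2) {
      p <- 2 * (1 - pwilcox(u - 1, n1, n2))
    } else {
      p <- 2 * pwilcox(u, n1, n2)
    }
    p <- min(1, p)
  } else {
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1  # every observation tied
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  list(u = u, p_value = p)
}

#' One feature-selection round
#'
#' Draws a stratified 80/20 subset of the training set and, on the 80%
#' part, runs the full preprocessing cascade followed by the univariable
#' filter: redundant-feature elimination, z-score standardization, minority
#' class balancing by RWO, the acquisition-reproducibility chain (on real
#' rows only - synthetic rows carry no acquisition metadata), and a
#' Mann-Whitney test of each surviving feature against the outcome at
#' `alpha`. By default the Mann-Whitney filter sees the balanced
#' (oversampled) rows, matching the preprocessing order; set
#' `mw_on_balanced = FALSE` to test on real rows only as a sensitivity
#' analysis.
#'
#' @param training A cohort tibble (the training set).
#' @param seed Optional round seed.
#' @param alpha Mann-Whitney significance level; default 0.05.
#' @param redundancy_threshold Passed to [eliminate_redundant()].
#' @param rho_threshold Passed to [reproducibility_chain()].
#' @param subset_fraction Fraction of the training set used by the round;
#'   default 0.8.
#' @param mw_on_balanced Apply the Mann-Whitney filter to the balanced
#'   subset (default) or to the real rows only.
#' @return A list with `selected` (significant surviving features),
#'   `p_values` (named, for every feature that reached the filter) and
#'   `filter_stats` (one-row tibble of per-stage removal counts).
#' @export
fs_round <- function(training, seed = NULL, alpha = 0.05,
                     redundancy_threshold = 0.99, rho_threshold = 0.75,
                     subset_fraction = 0.8, mw_on_balanced = TRUE) {
  with_seed(seed, {
    sub <- stratified_split(training, test_fraction = 1 - subset_fraction)$train
    feats <- feature_names(sub)
    red <- eliminate_redundant(sub, threshold = redundancy_threshold,
                               features = feats)
    std <- fit_standardizer(sub, features = red$kept)
    subz <- apply_standardizer(std, sub)
    bal <- balance_classes(subz)
    chain <- reproducibility_chain(subz, alpha = alpha,
                                   rho_threshold = rho_threshold,
                                   features = red$kept)
    mw_data <- if (mw_on_balanced) bal else subz
    is_mal <- mw_data$label == 1
    p_values <- vapply(chain$kept, function(f) {
      mw_core(mw_data[[f]][is_mal], mw_data[[f]][!is_mal])$p_value
    }, numeric(1))
    removed <- summary(chain)
    filter_stats <- tibble::tibble(
      n_features = length(feats),
      n_zero_variance = sum(red$report$reason == "zero_variance"),
      n_redundant = sum(red$report$reason == "redundant"),
      n_removed_scanner_model = removed$n_removed[removed$test == "scanner_model"],
      n_removed_convolution_kernel = removed$n_removed[removed$test == "convolution_kernel"],
      n_removed_pixel_spacing = removed$n_removed[removed$test == "pixel_spacing"],
      n_removed_slice_thickness = removed$n_removed[removed$test == "slice_thickness"],
      n_removed_tube_voltage = removed$n_removed[removed$test == "tube_voltage"],
      n_to_selection = length(chain$kept),
      n_selected = sum(p_values < alpha)
    )
    list(selected = names(p_values)[p_values < alpha],
         p_values = p_values,
         filter_stats = filter_stats)
  })
}

#' Monte Carlo cross-validated feature scoring
#'
#' Repeats [fs_round()] over `rounds` stratified resamples (round `r` uses
#' seed `base_seed + r`) and accumulates, per feature, the number of rounds
#' in which it both survived preprocessing and passed the Mann-Whitney
#' filter. Features removed by preprocessing in a round score 0 for that
#' round. The mean Mann-Whitney p-value over the rounds in which a feature
#' was tested is kept as the tie-break key for signature selection.
#'
#' @param training A cohort tibble.
#' @param rounds Number of MCCV rounds; default 100.
#' @param base_seed Base seed; round `r` runs under `base_seed + r`.
#' @param ... Passed to [fs_round()].
#' @return A `scoreboard` object; see [tidy()] for the per-feature table
#'   and [select_signature()] for the top-K cut.
#' @export
run_fs_mccv <- function(training, rounds = 100, base_seed = 0, ...) {
  abort_if(rounds < 1, "rounds must be >= 1")
  feats <- feature_names(training)
  score <- stats::setNames(integer(length(feats)), feats)
  p_sum <- stats::setNames(numeric(length(feats)), feats)
  p_n <- stats::setNames(integer(length(feats)), feats)
  selections <- vector("list", rounds)
  stats_rows <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    res <- fs_round(training, seed = base_seed + r, ...)
    score[res$selected] <- score[res$selected] + 1L
    p_sum[names(res$p_values)] <- p_sum[names(res$p_values)] + res$p_values
    p_n[names(res$p_values)] <- p_n[names(res$p_values)] + 1L
    selections[[r]] <- res$selected
    stats_rows[[r]] <- res$filter_stats
  }
  board <- tibble::tibble(
    feature = feats,
    score = unname(score),
    rounds = rounds,
    mean_p = ifelse(p_n > 0, p_sum / p_n, NA_real_),
    n_tested = unname(p_n)
  )
  structure(list(board = board, rounds = rounds, base_seed = base_seed,
                 selections = selections,
                 filter_stats = dplyr::bind_rows(stats_rows, .id = "round")),
            class = "scoreboard")
}

#' @export
tidy.scoreboard <- function(x, ...) {
  dplyr::arrange(x$board, dplyr::desc(.data$score), .data$mean_p, .data$feature)
}

#' @export
glance.scoreboard <- function(x, ...) {
  fs <- x$filter_stats
  tibble::tibble(
    rounds = x$rounds,
    n_features = nrow(x$board),
    mean_redundant = mean(fs$n_redundant + fs$n_zero_variance),
    mean_removed_scanner_model = mean(fs$n_removed_scanner_model),
    mean_removed_convolution_kernel = mean(fs$n_removed_convolution_kernel),
    mean_to_selection = mean(fs$n_to_selection),
    sd_to_selection = stats::sd(fs$n_to_selection),
    max_score = max(x$board$score)
  )
}

#' @export
print.scoreboard <- function(x, ...) {
  cat("Feature scoreboard:", nrow(x$board), "features over", x$rounds,
      "MCCV rounds\n")
  print(head(tidy(x), 10))
  invisible(x)
}

#' Select the top-K radiomic signature from a scoreboard
#'
#' Returns the `k` features with the highest cumulative scores; ties are
#' broken by ascending mean Mann-Whitney p-value, then by feature name.
#'
#' @param board A `scoreboard` from [run_fs_mccv()] (or its tidied tibble).
#' @param k Signature size; default 10.
#' @return Character vector of `k` feature names, best first.
#' @export
select_signature <- function(board, k = 10) {
  b <- if (inherits(board, "scoreboard")) tidy(board) else
    dplyr::arrange(tibble::as_tibble(board), dplyr::desc(.data$score),
                   .data$mean_p, .data$feature)
  abort_if(nrow(b) < k,
           paste0("scoreboard has ", nrow(b), " features; cannot select ", k))
  b$feature[seq_len(k)]
}
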