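# Mann-Whitney filter, MCCV scoring and signature selection.

test_that("Mann-Whitney U agrees with brute-force pair counting", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$u, 0)
  withr::with_seed(51, {
    for (i in 1:50) {
      x <- sample(1:8, sample(2:9, 1), replace = TRUE)  # ties likely
      y <- sample(1:8, sample(2:9, 1), replace = TRUE)
      expect_equal(mann_whitney(x, y)$u, brute_u(x, y))
      # pair-counting identity
      expect_equal(mann_whitney(x, y)$u + mann_whitney(y, x)$u,
                   length(x) * length(y))
    }
  })
})

test_that("Mann-Whitney p-values: identical samples, exact and approximate", {
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # tie-free small samples use the exact distribution: cross-check wilcox.test
  withr::with_seed(52, {
    for (i in 1:20) {
      x <- rnorm(6)
      y <- rnorm(7)
      expect_equal(mann_whitney(x, y)$p_value,
                   wilcox.test(x, y, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
    # large samples: normal approximation close to wilcox.test's
    x <- rnorm(40)
    y <- rnorm(35, 0.5)
    expect_equal(mann_whitney(x, y)$p_value,
                 wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value,
                 tolerance = 1e-10)
  })
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("fs_round is deterministic and respects preprocessing", {
  co <- generate_cohort(seed = 53)
  tr <- stratified_split(co, 0.2, seed = 54)$train
  a <- fs_round(tr, seed = 99)
  b <- fs_round(tr, seed = 99)
  expect_identical(a$selected, b$selected)
  expect_identical(a$p_values, b$p_values)
  # redundancy elimination ran: block members never reach the filter
  gt <- ground_truth(co)
  members <- gt$feature[gt$role == "redundant_member"]
  expect_length(intersect(names(a$p_values), members), 0)
})

test_that("scoreboard scores are bounded and additive over seed blocks", {
  cfg <- generator_config(n_features = 20, n_informative = 2,
                          n_redundant_blocks = 1, n_batch_affected = 3)
  tr <- stratified_split(generate_cohort(cfg, seed = 55), 0.2, seed = 56)$train
  whole <- run_fs_mccv(tr, rounds = 8, base_seed = 200)
  first <- run_fs_mccv(tr, rounds = 5, base_seed = 200)
  second <- run_fs_mccv(tr, rounds = 3, base_seed = 205)
  expect_true(all(whole$board$score >= 0 & whole$board$score <= 8))
  expect_equal(whole$board$score, first$board$score + second$board$score)
})

test_that("a single round reduces to that round's indicator", {
  cfg <- generator_config(n_features = 15, n_informative = 2,
                          n_redundant_blocks = 0, n_batch_affected = 2)
  tr <- stratified_split(generate_cohort(cfg, seed = 57), 0.2, seed = 58)$train
  sb <- run_fs_mccv(tr, rounds = 1, base_seed = 300)
  single <- fs_round(tr, seed = 301)
  expect_setequal(sb$board$feature[sb$board$score == 1], single$selected)
})

test_that("signature selection takes the top K with the stated tie-breaks", {
  board <- tibble::tibble(
    feature = sprintf("f%02d", 1:12),
    score = c(10, 10, 9, 9, 8, 7, 6, 5, 4, 3, 2, 1),
    mean_p = c(0.02, 0.01, 0.03, 0.005, NA, 0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1),
    n_tested = 10
  )
  sig <- select_signature(board, k = 10)
  expect_length(sig, 10)
  expect_equal(sig[1:2], c("f02", "f01"))   # equal score, smaller mean p first
  expect_equal(sig[3:4], c("f04", "f03"))
  expect_error(select_signature(board[1:5, ], k = 10), "cannot select")
})

test_that("informative cohorts outscore null cohorts", {
  cfg_sig <- generator_config(n_features = 20, n_informative = 3,
                              effect_size = 1.5, n_redundant_blocks = 0,
                              n_batch_affected = 0)
  cfg_null <- generator_config(n_features = 20, n_informative = 0,
                               effect_size = 0, n_redundant_blocks = 0,
                               n_batch_affected = 0)
  tr_sig <- stratified_split(generate_cohort(cfg_sig, seed = 60), 0.2,
                             seed = 61)$train
  tr_null <- stratified_split(generate_cohort(cfg_null, seed = 60), 0.2,
                              seed = 61)$train
  sb_sig <- run_fs_mccv(tr_sig, rounds = 10, base_seed = 400)
  sb_null <- run_fs_mccv(tr_null, rounds = 10, base_seed = 400)
  expect_gt(sum(sb_sig$board$score), sum(sb_null$board$score))
  top <- select_signature(sb_sig, k = 10)
  expect_true(all(c("rf001", "rf002", "rf003") %in% top))
})
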