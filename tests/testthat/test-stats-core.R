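test_that("Spearman correlation matches the no-ties closed form and handles edge cases", {
  expect_equal(spearman_correlation(c(1, 2, 3), c(2, 4, 6))$rho, 1)
  expect_equal(spearman_correlation(c(1, 2, 3), c(6, 4, 2))$rho, -1)
  # 1 - 6*sum(d^2)/(n(n^2-1)) with sum(d^2) = 4
  expect_equal(spearman_correlation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$rho, 0.8)

  # invariance under strictly monotone transforms of either input
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(15)
    y <- rnorm(15)
    base <- spearman_correlation(x, y)
    expect_equal(spearman_correlation(exp(x), y)$rho, base$rho)
    expect_equal(spearman_correlation(x, y^3)$p_value, base$p_value)
  }

  # missing pairs dropped before ranking
  x <- c(1, 2, NA, 4, 5)
  y <- c(2, 1, 3, NA, 5)
  expect_equal(spearman_correlation(x, y)$n, 3)

  expect_error(spearman_correlation(1:3, 1:4), "equal length")
  expect_error(spearman_correlation(c(1, NA, 3), c(1, 2, 3)), "at least 3")
  expect_error(spearman_correlation(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  # |rho| = 1 reports the smallest representable tail, not a zero p
  expect_gt(spearman_correlation(1:5, 1:5)$p_value, 0)
})

test_that("rank-sum test agrees with enumeration, is symmetric, and handles ties", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3))$p_value,
               wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value)
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5))$p_value, 1)

  set.seed(7)
  for (i in 1:25) {
    na <- sample(2:5, 1)
    nb <- sample(2:5, 1)
    vals <- sample(100, na + nb)   # tie-free
    a <- vals[seq_len(na)]
    b <- vals[-seq_len(na)]
    expect_equal(wilcoxon_rank_sum(a, b)$p_value, oracle_wilcoxon_p(a, b),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("BH adjustment equals the step-up brute force and keeps its invariants", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04, 0.05)),
               rep(0.05, 5))
  expect_equal(benjamini_hochberg(0.5), 0.5)
  expect_equal(benjamini_hochberg(c(0.005, 0.5)), c(0.01, 0.5))

  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    perm <- sample(length(p))
    expect_equal(benjamini_hochberg(p[perm]), adj[perm])
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("ROC AUC equals pair counting and the curve is a valid path", {
  expect_equal(roc_auc(c(3, 2, 1, 0), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(1, 1), c(1, 0))$auc, 0.5)
  expect_equal(roc_auc(c(2, 0, 1, 1), c(1, 1, 0, 0))$auc, 0.5)

  set.seed(5)
  for (i in 1:30) {
    n_pos <- sample(2:8, 1)
    n_neg <- sample(2:8, 1)
    scores <- c(sample(10, n_pos, TRUE), sample(10, n_neg, TRUE))
    labels <- rep(1:0, c(n_pos, n_neg))
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, oracle_auc(scores[labels == 1], scores[labels == 0]))
    expect_equal(r$curve$fpr[1], 0)
    expect_equal(r$curve$tpr[1], 0)
    expect_equal(r$curve$fpr[nrow(r$curve)], 1)
    expect_equal(r$curve$tpr[nrow(r$curve)], 1)
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
  }

  # agreement with the reference ROC implementation
  skip_if_not_installed("pROC")
  set.seed(8)
  sc <- rnorm(30)
  lb <- rbinom(30, 1, 0.5)
  lb[1:2] <- c(0, 1)
  ref <- suppressMessages(pROC::auc(pROC::roc(lb, sc, direction = "<")))
  expect_equal(roc_auc(sc, lb)$auc, as.numeric(ref))

  # complementary labels give 1 - AUC for tie-free scores
  set.seed(6)
  scores <- sample(100, 12)
  labels <- rep(c(1, 0), 6)
  expect_equal(roc_auc(scores, labels)$auc + roc_auc(scores, 1 - labels)$auc, 1)
  # flip flag mirrors the score axis
  expect_equal(roc_auc(scores, labels, flip = TRUE)$auc,
               1 - roc_auc(scores, labels)$auc)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("hypergeometric over-representation gives the exact upper tail", {
  universe <- sprintf("u%02d", 1:10)
  annotation <- universe[1:5]
  query <- universe[1:4]
  expect_equal(hypergeometric_ora(query, universe, annotation)$p_value,
               5 / 210)
  # zero overlap is the certain event
  expect_equal(
    hypergeometric_ora(universe[6:9], universe, annotation[1:2])$p_value, 1)
  # query = universe forces the overlap
  res <- hypergeometric_ora(universe, universe, annotation)
  expect_equal(res$k, 5)
  expect_equal(res$p_value, 1)
  expect_error(hypergeometric_ora(c("x"), universe, annotation), "contained")
  expect_error(hypergeometric_ora("a", character(0), "a"), "empty universe")
})

test_that("significance tiers follow the reporting convention", {
  expect_equal(p_tier(c(0.0005, 0.005, 0.03, 0.07, 0.5)),
               c("***", "**", "*", "#", "ns"))
})
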