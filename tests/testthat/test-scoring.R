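small_ds <- function(X) {
  expression_dataset(X, tibble::tibble(sample_id = colnames(X)))
}

test_that("ssGSEA equals the running-sum oracle on small instances", {
  # the single-sample worked example: 4 features, set = {feature 1}
  X <- matrix(c(8, 6, 4, 2), 4, 1, dimnames = list(sprintf("f%d", 1:4), "s1"))
  ds <- small_ds(X)
  got <- ssgsea_score(ds, "f1")
  expect_equal(unname(got),
               oracle_ssgsea(stats::setNames(X[, 1], rownames(X)),
                             c(TRUE, FALSE, FALSE, FALSE)))

  set.seed(17)
  for (i in 1:25) {
    p <- sample(4:10, 1)
    m <- sample(1:(p - 1), 1)
    X <- matrix(rnorm(p * 3, 7), p, 3,
                dimnames = list(sprintf("f%02d", 1:p), sprintf("s%d", 1:3)))
    ds <- small_ds(X)
    set <- sample(rownames(X), m)
    got <- ssgsea_score(ds, set)
    for (j in 1:3) {
      expect_equal(unname(got[j]),
                   oracle_ssgsea(stats::setNames(X[, j], rownames(X)),
                                 rownames(X) %in% set),
                   tolerance = 1e-12)
    }
  }
})

test_that("ssGSEA is rank-invariant and per-sample shift-invariant", {
  set.seed(23)
  X <- matrix(rnorm(60, 7), 20, 3,
              dimnames = list(sprintf("f%02d", 1:20), c("a", "b", "c")))
  X[, 2] <- X[, 1]                         # identical samples
  ds <- small_ds(X)
  set <- sprintf("f%02d", c(2, 5, 9))
  s <- ssgsea_score(ds, set)
  expect_equal(s[["a"]], s[["b"]])

  expd <- small_ds(exp(X))                 # strictly monotone transform
  expect_equal(ssgsea_score(expd, set), s)

  shifted <- X
  shifted[, 3] <- shifted[, 3] + 5         # constant shift of one sample
  expect_equal(ssgsea_score(small_ds(shifted), set)[["c"]], s[["c"]])

  expect_error(ssgsea_score(ds, "nope"), "no set member")
  expect_error(ssgsea_score(ds, rownames(X)), "covers all")
  expect_warning(ssgsea_score(ds, c(set, "ghost")), "absent")
})

test_that("signature scores use the strict mean-split grouping", {
  # mean split on a known score vector: (1,2,3,4) -> high = {3,4}
  sc <- c(1, 2, 3, 4)
  expect_equal(ifelse(sc > mean(sc), "high", "low"),
               c("low", "low", "high", "high"))

  cohort <- generate_cohort(simulation_design(
    subtype_counts = c(MTC = 20, normal = 20), n_genes = 800, n_mirnas = 60
  ), seed = 5)
  sets <- export_gene_sets(cohort)
  scores <- signature_scores(cohort$mrna, cohort$mirna,
                             sets$tf_set, sets$hub_set, sets$mirna_set)
  expect_equal(nrow(scores), 40)
  for (col in c("tf_group", "hub_group", "mirna_group")) {
    expect_setequal(unique(scores[[col]]), c("high", "low"))
  }
  # all-equal scores are all labelled low (strictly-greater convention)
  expect_true(all(ifelse(rep(2, 4) > 2, "high", "low") == "low"))

  # partial miRNA set: scoring proceeds on the remaining members
  expect_warning(
    partial <- signature_scores(cohort$mrna, cohort$mirna, sets$tf_set,
                                sets$hub_set,
                                c(sets$mirna_set, "mir_absent_1",
                                  "mir_absent_2")),
    "absent")
  expect_equal(nrow(partial), 40)
})

test_that("combined score is the stromal+immune sum and purity follows the cosine", {
  cohort <- generate_cohort(simulation_design(
    subtype_counts = c(MTC = 15, normal = 15), n_genes = 800, n_mirnas = 60
  ), seed = 8)
  sets <- export_gene_sets(cohort)
  est <- estimate_scores(cohort$mrna, sets$stromal, sets$immune)
  expect_equal(est$estimate_score, est$stromal_score + est$immune_score)
  expect_equal(est$tumor_purity,
               cos(0.6049872018 + 0.0001467884 * est$estimate_score))
  # purity decreases with the combined score while the argument is in (0, pi)
  ord <- order(est$estimate_score)
  args <- 0.6049872018 + 0.0001467884 * est$estimate_score[ord]
  if (all(args > 0 & args < pi)) {
    expect_true(all(diff(est$tumor_purity[ord]) <= 0))
  }
})

test_that("immune associations report direction, tier, and degenerate cases", {
  scores <- tibble::tibble(
    sample_id = sprintf("s%d", 1:12),
    hub_score = c(1:6 / 10 + 1, 1:6 / 10), tf_score = runif(12),
    mirna_score = runif(12),
    hub_group = rep(c("high", "low"), each = 6),
    tf_group = rep(c("high", "low"), 6),
    mirna_group = rep(c("low", "high"), 6)
  )
  # identical values in both groups: p = 1, no direction
  same <- immune_associations(scores, rep(3, 12), "hub", "wilcoxon")
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, 0L)

  # clearly separated values
  sep <- immune_associations(scores, c(rep(10, 6), rep(1, 6)), "hub", "wilcoxon")
  expect_lt(sep$p_value, 0.01)
  expect_equal(sep$direction, 1L)

  cor_res <- immune_associations(scores, scores$hub_score, "hub", "spearman")
  expect_equal(cor_res$statistic, 1)
  expect_equal(cor_res$direction, 1L)
})
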