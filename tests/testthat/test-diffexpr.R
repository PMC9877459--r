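test_that("moderated t matches the closed-form posterior with an injected prior", {
  # printed 3-vs-3 toy matrix
  X <- matrix(c(5, 6, 7, 9, 10, 11,
                4, 4, 4, 4, 4, 4,
                8, 7, 9, 6, 7, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), sprintf("s%d", 1:6)))
  ann <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                        subtype = rep(c("T", "N"), each = 3))
  ds <- expression_dataset(X, ann)

  de <- moderated_de(ds, "T", "N", d0 = 4, s02 = 1)
  # independent evaluation of the posterior-variance formula per feature
  for (g in rownames(X)) {
    a <- X[g, 1:3]; b <- X[g, 4:6]
    s2 <- (2 * var(a) + 2 * var(b)) / 4
    s2_post <- (4 * 1 + 4 * s2) / (4 + 4)
    t_expect <- (mean(a) - mean(b)) / sqrt(s2_post * (1 / 3 + 1 / 3))
    expect_equal(de$t_mod[de$feature == g], t_expect, tolerance = 1e-12)
    expect_equal(de$p_value[de$feature == g],
                 2 * pt(-abs(t_expect), df = 8), tolerance = 1e-12)
  }
  # identical values in both groups: no signal
  expect_equal(de$log2FC[de$feature == "gB"], 0)
  expect_equal(de$t_mod[de$feature == "gB"], 0)

  # d0 = 0 is the ordinary pooled-variance t
  de0 <- moderated_de(ds, "T", "N", d0 = 0, s02 = 1)
  for (g in c("gA", "gC")) {
    tt <- t.test(X[g, 1:3], X[g, 4:6], var.equal = TRUE)
    expect_equal(de0$t_mod[de0$feature == g], unname(tt$statistic),
                 tolerance = 1e-10)
  }
})

test_that("moderated DE is reorder-invariant and antisymmetric in the groups", {
  ds <- toy_dataset()
  de <- moderated_de(ds, "MTC", "normal")
  perm <- sample(ncol(ds$values))
  ds_perm <- expression_dataset(ds$values[, perm], ds$annotations[perm, ])
  de_perm <- moderated_de(ds_perm, "MTC", "normal")
  expect_equal(de$log2FC, de_perm$log2FC)
  expect_equal(de$p_value, de_perm$p_value)

  de_swap <- moderated_de(ds, "normal", "MTC")
  expect_equal(de_swap$log2FC, -de$log2FC)
  expect_equal(de_swap$t_mod, -de$t_mod)
})

test_that("moderated t tracks the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  ds <- toy_dataset(seed = 9)
  de <- moderated_de(ds, "MTC", "normal")
  keep <- ds$annotations$subtype %in% c("MTC", "normal")
  design <- model.matrix(~ ds$annotations$subtype[keep] == "MTC")
  fit <- limma::eBayes(limma::lmFit(ds$values[, keep], design))
  expect_gt(cor(de$t_mod, fit$t[, 2]), 0.999)
  expect_equal(attr(de, "d0"), fit$df.prior, tolerance = 0.01)
})

test_that("DEG calls use strict p and inclusive fold-change boundaries", {
  de <- tibble::tibble(
    feature = c("a", "b", "c"),
    log2FC = c(1.0, 3, -0.99),
    adj_p = c(0.049, 0.05, 0.01)
  )
  calls <- call_degs(de, p_cut = 0.05, lfc_cut = 1)
  expect_equal(calls$up, "a")          # 0.049 < 0.05 and 1.0 >= 1
  expect_false("b" %in% calls$up)      # 0.05 is not < 0.05
  expect_false("c" %in% calls$down)    # |-0.99| < 1
  calls58 <- call_degs(de, p_cut = 0.05, lfc_cut = 0.58)
  expect_true("c" %in% calls58$down)

  expect_equal(call_degs(de, p_cut = 0), list(up = character(0), down = character(0)))
  all_calls <- call_degs(de, p_cut = 1, lfc_cut = 0)
  expect_setequal(c(all_calls$up, all_calls$down), de$feature)
})

test_that("exclusivity algebra subtracts comparators direction-agnostically", {
  calls <- list(
    MTC = list(up = c("a", "b", "c"), down = c("d")),
    ATC = list(up = c("b"), down = character(0))
  )
  res <- exclusive_degs(calls, "MTC")
  expect_setequal(res$exclusive_up, c("a", "c"))
  expect_equal(res$exclusive_down, "d")

  res2 <- exclusive_degs(calls, "MTC", second_cohort_degs = c("a", "d"))
  expect_equal(res2$post_exclusion_up, "c")
  expect_length(res2$post_exclusion_down, 0)

  # gene up in target but down in a comparator is disqualified
  calls3 <- list(
    MTC = list(up = c("x", "y"), down = character(0)),
    PTC = list(up = character(0), down = c("x"))
  )
  res3 <- exclusive_degs(calls3, "MTC")
  expect_false("x" %in% res3$exclusive_up)
  expect_equal(res3$exclusive_up, "y")

  # merge plan unions member DEG sets
  calls4 <- list(
    MTC = list(up = c("a", "b"), down = character(0)),
    PTC = list(up = "a", down = character(0)),
    FTC = list(up = character(0), down = "b")
  )
  res4 <- exclusive_degs(calls4, "MTC",
                         merge_plan = list(WDTC = c("PTC", "FTC")))
  expect_length(res4$exclusive_up, 0)
  expect_error(
    exclusive_degs(calls4, "MTC", merge_plan = list(WDTC = c("MTC", "PTC"))),
    "own comparator")
})

test_that("planted DE structure in the toy dataset is called correctly", {
  ds <- toy_dataset()
  de <- moderated_de(ds, "MTC", "normal")
  calls <- call_degs(de)
  expect_setequal(calls$up, sprintf("g%03d", c(1:5, 9:10)))
  expect_setequal(calls$down, sprintf("g%03d", 6:8))
  atc <- call_degs(moderated_de(ds, "ATC", "normal"))
  res <- exclusive_degs(list(MTC = calls, ATC = atc), "MTC")
  expect_setequal(res$exclusive_up, sprintf("g%03d", 1:5))
})
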