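# small matched datasets with known correlation signs across 20 samples
regnet_fixture <- function(seed = 21) {
  set.seed(seed)
  n <- 20
  ids <- sprintf("s%02d", 1:n)
  z <- rnorm(n)
  mk <- function(loading, noise = 0.3) 7 + loading * z + rnorm(n, 0, noise)
  X <- rbind(TF1 = mk(-1), gene1 = mk(1), gene2 = mk(1), gene3 = rnorm(n, 7))
  colnames(X) <- ids
  M <- rbind(mir1 = mk(-1), mir2 = rnorm(n, 7))
  colnames(M) <- ids
  ann <- tibble::tibble(sample_id = ids, subtype = "MTC")
  list(mrna = expression_dataset(X, ann), mirna = expression_dataset(M, ann))
}

test_that("prediction filters apply their exact boundary rules", {
  tf_pairs <- tibble::tibble(tf = "TF1", target = c("gene1", "gene2", "gene3"),
                             nes = c(5.0, 5.1, 9))
  kept <- filter_tf_candidates(tf_pairs, allowed_targets = c("gene1", "gene2"))
  expect_equal(kept$target, "gene2")      # NES 5.0 dropped (strict), gene3 not allowed

  mir_pairs <- tibble::tibble(mirna = c("mir1", "mir1", "mir2"),
                              target = c("gene1", "gene2", "gene1"),
                              tool_count = c(2L, 1L, 5L))
  kept2 <- filter_mirna_candidates(mir_pairs, de_down_mirnas = "mir1",
                                   allowed_targets = c("gene1", "gene2"))
  expect_equal(nrow(kept2), 1)            # tool_count 2 inclusive; 1 dropped;
  expect_equal(kept2$target, "gene1")     # mir2 not DE-down

  expect_equal(nrow(filter_tf_candidates(tf_pairs[0, ], allowed_targets = "g")), 0)
})

test_that("correlation validation retains pairs by layer-specific sign rules", {
  fx <- regnet_fixture()
  # miRNA layer keeps only significant negative pairs
  mg <- validate_edges(tibble::tibble(mirna = c("mir1", "mir1", "mir2"),
                                      target = c("gene1", "gene3", "gene1")),
                       fx$mrna, fx$mirna, layer = "mirna_mrna")
  expect_true(all(mg$rho < 0 & mg$p_value < 0.05))
  expect_true("gene1" %in% mg$target)     # strong planted repression
  expect_false("gene3" %in% mg$target)    # pure noise target

  # positively correlated miRNA pair is rejected regardless of p
  flipped_vals <- fx$mirna$values
  flipped_vals["mir1", ] <- 14 - flipped_vals["mir1", ]
  flipped <- expression_dataset(flipped_vals, fx$mirna$annotations)
  pos <- validate_edges(tibble::tibble(mirna = "mir1", target = "gene1"),
                        fx$mrna, flipped, layer = "mirna_mrna")
  expect_equal(nrow(pos), 0)

  # TF layer keeps either sign, records it
  tg <- validate_edges(tibble::tibble(tf = "TF1", target = c("gene1", "gene2")),
                       fx$mrna, layer = "tf_mrna")
  expect_equal(nrow(tg), 2)
  expect_true(all(tg$sign == -1))
  # TF-miRNA layer keeps positives
  tm <- validate_edges(tibble::tibble(tf = "TF1", mirna = c("mir1", "mir2")),
                       fx$mrna, fx$mirna, layer = "tf_mirna")
  expect_equal(tm$target, "mir1")
  expect_equal(tm$sign, 1L)

  # an absent pair member is skipped with a message, not an error
  expect_message(
    skipped <- validate_edges(tibble::tibble(mirna = "ghost", target = "gene1"),
                              fx$mrna, fx$mirna, layer = "mirna_mrna"),
    "skipped")
  expect_equal(nrow(skipped), 0)
})

test_that("network assembly flags non-linear genes and builds chains", {
  mk_edges <- function(src, tgt, layer, sign) {
    tibble::tibble(source = src, target = tgt, layer = layer,
                   rho = sign * 0.8, p_value = 0.001, sign = as.integer(sign),
                   tier = "***")
  }
  tf_e <- mk_edges("TF1", c("g1", "g2"), "tf_mrna", -1)
  mir_e <- mk_edges("m1", "g1", "mirna_mrna", -1)
  net <- assemble_network(tf_e, mir_e)
  expect_equal(nrow(net$chains), 1)
  expect_equal(net$chains$gene, "g1")
  expect_true(net$nodes$linear[net$nodes$id == "g1"])
  expect_false(net$nodes$linear[net$nodes$id == "g2"])   # TF edge only

  empty <- assemble_network(tf_e[0, ], mir_e[0, ])
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(find_ffls(empty)), 0)
})

test_that("FFL classification equals the sign-product rule on all 8 patterns", {
  for (s_tg in c(-1L, 1L)) for (s_tm in c(-1L, 1L)) for (s_mg in c(-1L, 1L)) {
    e <- dplyr::bind_rows(
      tibble::tibble(source = "T", target = "g", layer = "tf_mrna",
                     rho = s_tg * 0.5, p_value = 0.01, sign = s_tg, tier = "*"),
      tibble::tibble(source = "T", target = "m", layer = "tf_mirna",
                     rho = s_tm * 0.5, p_value = 0.01, sign = s_tm, tier = "*"),
      tibble::tibble(source = "m", target = "g", layer = "mirna_mrna",
                     rho = s_mg * 0.5, p_value = 0.01, sign = s_mg, tier = "*")
    )
    net <- list(edges = e)
    ffl <- find_ffls(net)
    expect_equal(nrow(ffl), 1)
    expect_equal(ffl$classification,
                 ifelse(s_tg == s_tm * s_mg, "coherent", "incoherent"))
  }
  # the repressor pattern (-1, +1, -1) is coherent
  expect_equal((-1L) == 1L * -1L, TRUE)
})

test_that("filter order does not change the final edge set", {
  fx <- regnet_fixture()
  tf_pairs <- tibble::tibble(tf = "TF1", target = c("gene1", "gene2", "gene3"),
                             nes = c(8, 7, 3))
  allowed <- c("gene1", "gene2", "gene3")
  # filter then validate
  a <- validate_edges(filter_tf_candidates(tf_pairs, 5, allowed)[, 1:2],
                      fx$mrna, layer = "tf_mrna")
  # validate then filter (on the candidate ids retained)
  b_all <- validate_edges(tf_pairs[, 1:2], fx$mrna, layer = "tf_mrna")
  keep <- filter_tf_candidates(tf_pairs, 5, allowed)
  b <- b_all[paste(b_all$source, b_all$target) %in%
               paste(keep$tf, keep$target), ]
  expect_equal(a$target, b$target)
  expect_equal(a$rho, b$rho)
})
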