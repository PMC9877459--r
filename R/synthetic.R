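#' Simulation design for a synthetic matched mRNA/miRNA cohort
#'
#' Encodes the study conditions the generator emulates: a 362-sample
#' multi-subtype thyroid cohort (ATC 24, MTC 54, PTC 142, FTC 22, OTC 8,
#' FTA 27, OTA 16, normal 69) with MTC-exclusive planted DEGs, a
#' co-expressed hub block driven by a latent factor, a repressor TF
#' (negative loading on the hub factor, positive on the miRNA factor),
#' regulator miRNAs anti-correlated with their targets and positively
#' correlated with the TF, an immune latent factor anti-correlated with the
#' hub factor, and exponential survival linked to hub (protective) and
#' miRNA (adverse) scores.
#'
#' @param ... Named overrides for any design field (see the returned list).
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(...) {
  design <- list(
    subtype_counts = c(ATC = 24, MTC = 54, PTC = 142, FTC = 22, OTC = 8,
                       FTA = 27, OTA = 16, normal = 69),
    n_genes = 2000L,
    n_mirnas = 300L,
    n_up = 80L, n_down = 20L,
    effect_range = c(1.2, 2.5),
    shared_de = list(n_per_subtype = 60L, effect_range = c(1.5, 2.5),
                     prop_up = 0.7, n_overlap = 10L),
    hub_block = list(size = 15L, loading = 1.5, effect_range = c(2, 3)),
    tf_spec = list(loading_hub = -1.3, loading_mir = 0.8, mtc_shift = -1.5),
    mirna_spec = list(n = 13L, loading_target = -1.5, loading_tf = 0.6,
                      mtc_shift = -1.5, targets_per_mirna = 2L,
                      n_network_genes = 9L),
    immune_spec = list(hub_corr = -0.8, loading = 1.5, n_stromal = 30L,
                       n_immune = 30L, n_til_sets = 28L, til_set_size = 8L,
                       n_icg = 14L),
    noise_sd = 0.7,
    baseline_mean = 7, baseline_sd = 1,
    survival_spec = list(beta_hub = -0.7, beta_mir = 0.7,
                         baseline_rate = 0.02, censor_max = 120)
  )
  over <- list(...)
  for (nm in names(over)) {
    design[[nm]] <- if (is.list(design[[nm]]) && is.list(over[[nm]])) {
      utils::modifyList(design[[nm]], over[[nm]])
    } else {
      over[[nm]]
    }
  }
  stopifnot(all(design$subtype_counts > 0),
            design$mirna_spec$n < design$n_mirnas,
            abs(design$immune_spec$hub_corr) < 1,
            design$hub_block$size <= design$n_up)
  n_other <- length(setdiff(names(design$subtype_counts), c("MTC", "normal")))
  needed <- design$n_up + design$n_down + 1 + design$shared_de$n_overlap +
    n_other * design$shared_de$n_per_subtype +
    design$immune_spec$n_stromal + design$immune_spec$n_immune +
    design$immune_spec$n_til_sets * design$immune_spec$til_set_size +
    design$immune_spec$n_icg
  if (needed > design$n_genes) {
    stop(sprintf("planted feature sets need %d genes but n_genes = %d",
                 needed, design$n_genes), call. = FALSE)
  }
  structure(design, class = "simulation_design")
}

#' Generate a synthetic matched mRNA/miRNA cohort
#'
#' Baseline expression is Normal(mean 7, sd 1) per feature on the log2
#' scale plus Gaussian noise (sd `noise_sd`).  Planted structure:
#' * MTC-exclusive DEGs shifted only in MTC samples (effects uniform in
#'   `effect_range`, sign by direction);
#' * per-comparator-subtype DEGs, plus a small overlap block DE in both MTC
#'   and ATC (exercises the exclusivity subtraction);
#' * a hub block `loading * latent_hub + noise` (pairwise positive
#'   correlation), the first `hub_block$size` planted up-genes;
#' * a repressor TF `= mtc_shift * I(MTC) - |loading_hub| * latent_hub +
#'   loading_mir * latent_mir + noise`;
#' * regulator miRNAs shifted down in MTC with the same two-factor
#'   structure (anti-correlated with hub targets, positively correlated
#'   with the TF);
#' * immune-program genes (stromal/immune/TIL/ICG sets) loaded on a latent
#'   immune factor with `corr(latent_immune, latent_hub) =
#'   immune_spec$hub_corr`;
#' * survival times from an exponential hazard with linear predictor
#'   `beta_hub * z(hub proxy) + beta_mir * z(miRNA proxy)`, independent
#'   uniform censoring, times rounded up to whole months.
#'
#' Identical `design` and `seed` give byte-identical cohorts.
#'
#' @param design A [simulation_design()].
#' @param seed Integer random seed.
#' @return A list of class `synthetic_cohort` with elements `mrna` and
#'   `mirna` (both [expression_dataset()] over identical samples) and
#'   `truth` (planted identities, effects, regulatory edges, latent factor
#'   values, survival coefficients).
#' @export
generate_cohort <- function(design = simulation_design(), seed = 1L) {
  set.seed(seed)
  counts <- design$subtype_counts
  subtype <- rep(names(counts), counts)
  n_s <- length(subtype)
  sample_id <- sprintf("S%03d", seq_len(n_s))
  is_mtc <- subtype == "MTC"

  gene_ids <- sprintf("g%04d", seq_len(design$n_genes))
  mir_ids <- sprintf("mir%03d", seq_len(design$n_mirnas))

  # ---- planted feature identities (disjoint pools) ----
  pool <- gene_ids
  take <- function(n) {
    picked <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    picked
  }
  up_genes <- take(design$n_up)
  down_genes <- take(design$n_down)
  tf_gene <- take(1L)
  overlap_genes <- take(design$shared_de$n_overlap)   # DE in MTC and ATC
  other_subtypes <- setdiff(names(counts), c("MTC", "normal"))
  shared <- lapply(other_subtypes, function(s) take(design$shared_de$n_per_subtype))
  names(shared) <- other_subtypes
  imm <- design$immune_spec
  stromal_set <- take(imm$n_stromal)
  immune_set <- take(imm$n_immune)
  til_sets <- lapply(seq_len(imm$n_til_sets), function(i) take(imm$til_set_size))
  names(til_sets) <- sprintf("til_%02d", seq_len(imm$n_til_sets))
  icg_set <- take(imm$n_icg)

  hub_genes <- up_genes[seq_len(design$hub_block$size)]
  reg_mirnas <- mir_ids[seq_len(design$mirna_spec$n)]

  # ---- latent factors ----
  # Centered within each subtype: the latents encode within-group program
  # covariation only, so the planted shifts are the sole source of
  # between-group mean differences.
  latent_hub <- stats::rnorm(n_s)
  latent_mir <- stats::rnorm(n_s)
  r <- imm$hub_corr
  latent_immune <- r * latent_hub + sqrt(1 - r^2) * stats::rnorm(n_s)
  for (s in names(counts)) {
    idx <- subtype == s
    latent_hub[idx] <- latent_hub[idx] - mean(latent_hub[idx])
    latent_mir[idx] <- latent_mir[idx] - mean(latent_mir[idx])
    latent_immune[idx] <- latent_immune[idx] - mean(latent_immune[idx])
  }

  # ---- mRNA matrix ----
  mu_g <- stats::rnorm(design$n_genes, design$baseline_mean, design$baseline_sd)
  X <- matrix(stats::rnorm(design$n_genes * n_s, 0, design$noise_sd),
              design$n_genes, n_s, dimnames = list(gene_ids, sample_id))
  X <- X + mu_g

  eff_up <- stats::runif(design$n_up, design$effect_range[1], design$effect_range[2])
  # hub-block genes are the cohort's strongest exclusive markers
  eff_up[seq_len(design$hub_block$size)] <-
    stats::runif(design$hub_block$size, design$hub_block$effect_range[1],
                 design$hub_block$effect_range[2])
  eff_down <- -stats::runif(design$n_down, design$effect_range[1], design$effect_range[2])
  X[up_genes, is_mtc] <- X[up_genes, is_mtc] + eff_up
  X[down_genes, is_mtc] <- X[down_genes, is_mtc] + eff_down
  X[tf_gene, is_mtc] <- X[tf_gene, is_mtc] + design$tf_spec$mtc_shift

  eff_overlap <- stats::runif(design$shared_de$n_overlap,
                              design$shared_de$effect_range[1],
                              design$shared_de$effect_range[2])
  X[overlap_genes, is_mtc] <- X[overlap_genes, is_mtc] + eff_overlap
  X[overlap_genes, subtype == "ATC"] <- X[overlap_genes, subtype == "ATC"] + eff_overlap

  shared_empty <- tibble::tibble(subtype = character(), feature = character(),
                                 effect = numeric(), direction = character())
  shared_tab <- purrr::map2_dfr(shared, names(shared), function(genes, s) {
    sgn <- ifelse(stats::runif(length(genes)) < design$shared_de$prop_up, 1, -1)
    eff <- sgn * stats::runif(length(genes), design$shared_de$effect_range[1],
                              design$shared_de$effect_range[2])
    X[genes, subtype == s] <<- X[genes, subtype == s] + eff
    tibble::tibble(subtype = s, feature = genes, effect = eff,
                   direction = ifelse(eff > 0, "up", "down"))
  })
  if (nrow(shared_tab) == 0) shared_tab <- shared_empty

  X[hub_genes, ] <- X[hub_genes, ] +
    matrix(design$hub_block$loading * latent_hub, design$hub_block$size, n_s,
           byrow = TRUE)
  X[tf_gene, ] <- X[tf_gene, ] +
    design$tf_spec$loading_hub * latent_hub +
    design$tf_spec$loading_mir * latent_mir
  for (set in c(list(stromal_set, immune_set, icg_set), til_sets)) {
    X[set, ] <- X[set, ] +
      matrix(imm$loading * latent_immune, length(set), n_s, byrow = TRUE)
  }

  # ---- miRNA matrix ----
  mu_m <- stats::rnorm(design$n_mirnas, design$baseline_mean, design$baseline_sd)
  M <- matrix(stats::rnorm(design$n_mirnas * n_s, 0, design$noise_sd),
              design$n_mirnas, n_s, dimnames = list(mir_ids, sample_id))
  M <- M + mu_m
  ms <- design$mirna_spec
  M[reg_mirnas, is_mtc] <- M[reg_mirnas, is_mtc] + ms$mtc_shift
  M[reg_mirnas, ] <- M[reg_mirnas, ] +
    matrix(ms$loading_target * latent_hub + ms$loading_tf * latent_mir,
           ms$n, n_s, byrow = TRUE)

  # ---- planted regulatory edges ----
  network_genes <- hub_genes[seq_len(ms$n_network_genes)]
  target_map <- lapply(seq_len(ms$n), function(j) {
    idx <- ((j - 1) * ms$targets_per_mirna + seq_len(ms$targets_per_mirna) - 1) %%
      ms$n_network_genes + 1
    network_genes[unique(idx)]
  })
  names(target_map) <- reg_mirnas
  edges <- dplyr::bind_rows(
    tibble::tibble(source = tf_gene, target = hub_genes,
                   layer = "tf_mrna", sign = -1L),
    tibble::tibble(source = tf_gene, target = reg_mirnas,
                   layer = "tf_mirna", sign = 1L),
    purrr::map2_dfr(names(target_map), target_map, function(m, tg) {
      tibble::tibble(source = m, target = tg, layer = "mirna_mrna", sign = -1L)
    })
  )

  # ---- survival from hub (protective) and miRNA (adverse) proxies ----
  sv <- design$survival_spec
  hub_proxy <- as.numeric(scale(colMeans(X[hub_genes, , drop = FALSE])))
  mir_proxy <- as.numeric(scale(colMeans(M[reg_mirnas, , drop = FALSE])))
  lp <- sv$beta_hub * hub_proxy + sv$beta_mir * mir_proxy
  t_true <- stats::rexp(n_s, rate = sv$baseline_rate * exp(lp))
  cens <- stats::runif(n_s, 0, sv$censor_max)
  time <- ceiling(pmin(t_true, cens))
  event <- as.integer(t_true <= cens)

  mutation <- rep(NA_integer_, n_s)
  mutation[is_mtc] <- stats::rbinom(sum(is_mtc), 1, stats::plogis(-hub_proxy[is_mtc]))

  ann <- tibble::tibble(sample_id = sample_id, subtype = subtype,
                        time = time, event = event, mutation = mutation)

  second_cohort_degs <- unique(c(
    shared_tab$feature[shared_tab$subtype == "PTC"],
    sample(setdiff(gene_ids, c(up_genes, down_genes, tf_gene, overlap_genes)), 20)
  ))

  truth <- list(
    design = design,
    degs = dplyr::bind_rows(
      tibble::tibble(feature = up_genes, direction = "up", effect = eff_up),
      tibble::tibble(feature = down_genes, direction = "down", effect = eff_down),
      tibble::tibble(feature = tf_gene, direction = "down",
                     effect = design$tf_spec$mtc_shift)
    ),
    overlap_degs = tibble::tibble(feature = overlap_genes, effect = eff_overlap),
    shared_degs = shared_tab,
    hub_genes = hub_genes,
    network_genes = network_genes,
    tf = tf_gene,
    mirnas = reg_mirnas,
    target_map = target_map,
    edges = edges,
    gene_sets = c(list(tf_set = tf_gene, hub_set = hub_genes,
                       mirna_set = reg_mirnas, stromal = stromal_set,
                       immune = immune_set, icg = icg_set), til_sets),
    latent = tibble::tibble(sample_id = sample_id, hub = latent_hub,
                            mir = latent_mir, immune = latent_immune),
    survival = list(beta_hub = sv$beta_hub, beta_mir = sv$beta_mir,
                    hub_proxy = hub_proxy, mir_proxy = mir_proxy),
    second_cohort_degs = second_cohort_degs
  )

  structure(
    list(mrna = expression_dataset(X, ann),
         mirna = expression_dataset(M, ann),
         truth = truth),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d genes, %d miRNAs, %d samples\n",
              nrow(x$mrna$values), nrow(x$mirna$values), ncol(x$mrna$values)))
  cat(sprintf("planted: %d MTC DEGs, %d hub genes, TF %s, %d regulator miRNAs, %d edges\n",
              nrow(x$truth$degs), length(x$truth$hub_genes), x$truth$tf,
              length(x$truth$mirnas), nrow(x$truth$edges)))
  invisible(x)
}

#' Export TF and miRNA regulatory priors with decoys
#'
#' True TF->target pairs are emitted with NES drawn uniform in `[5.5, 9]`
#' and true miRNA->target pairs with tool counts in `{2..6}`; decoy
#' (non-regulating) pairs are added at `decoy_fraction` times the true
#' count with NES in `[2, 5]` and tool count 1, so the standard prediction
#' filters (NES > 5, >= 2 tools) separate them.
#'
#' @param cohort A [generate_cohort()] result.
#' @param decoy_fraction Decoy pairs per true pair, in `[0, 5]`.
#' @param seed Integer seed for the prior draws.
#' @return A list with tibbles `tf_prior` (`tf`, `target`, `nes`) and
#'   `mirna_prior` (`mirna`, `target`, `tool_count`).
#' @export
export_priors <- function(cohort, decoy_fraction = 1, seed = 1L) {
  if (decoy_fraction < 0 || decoy_fraction > 5) {
    stop("decoy_fraction must lie in [0, 5]", call. = FALSE)
  }
  set.seed(seed)
  tr <- cohort$truth
  genes <- feature_ids(cohort$mrna)
  mirs <- feature_ids(cohort$mirna)

  true_tf <- tibble::tibble(
    tf = tr$tf, target = tr$hub_genes,
    nes = stats::runif(length(tr$hub_genes), 5.5, 9)
  )
  true_mir <- purrr::map2_dfr(names(tr$target_map), tr$target_map,
    function(m, tg) tibble::tibble(mirna = m, target = tg))
  true_mir$tool_count <- sample(2:6, nrow(true_mir), replace = TRUE)

  n_tf_decoy <- round(decoy_fraction * nrow(true_tf))
  n_mir_decoy <- round(decoy_fraction * nrow(true_mir))
  decoy_tf <- tibble::tibble(
    tf = tr$tf,
    target = sample(setdiff(genes, c(tr$hub_genes, tr$tf)), n_tf_decoy),
    nes = stats::runif(n_tf_decoy, 2, 5)
  )
  decoy_mir <- tibble::tibble(
    mirna = sample(mirs, n_mir_decoy, replace = TRUE),
    target = sample(genes, n_mir_decoy, replace = TRUE),
    tool_count = 1L
  )
  decoy_mir <- dplyr::anti_join(decoy_mir, true_mir, by = c("mirna", "target"))

  list(
    tf_prior = validate_edge_list(dplyr::bind_rows(true_tf, decoy_tf), "tf_prior"),
    mirna_prior = validate_edge_list(dplyr::bind_rows(true_mir, decoy_mir),
                                     "mirna_prior")
  )
}

#' Export a confidence-scored PPI edge list for the planted DEGs
#'
#' The hub block is wired as a dense (complete) subgraph with confidence
#' scores in `[0.6, 0.95]`; the remaining planted DEGs receive sparse
#' random background edges with scores in `[0.2, 0.9]`, straddling the 0.4
#' retention threshold.
#'
#' @param cohort A [generate_cohort()] result.
#' @param background_degree Average background edges per non-hub DEG.
#' @param seed Integer seed.
#' @return A tibble of `node_a`, `node_b`, `score` records.
#' @export
export_ppi <- function(cohort, background_degree = 2, seed = 1L) {
  set.seed(seed)
  tr <- cohort$truth
  hubs <- tr$hub_genes
  others <- setdiff(tr$degs$feature, hubs)
  hub_pairs <- t(utils::combn(hubs, 2))
  hub_edges <- tibble::tibble(
    node_a = hub_pairs[, 1], node_b = hub_pairs[, 2],
    score = stats::runif(nrow(hub_pairs), 0.6, 0.95)
  )
  n_bg <- round(background_degree * length(others))
  bg_edges <- tibble::tibble(
    node_a = sample(others, n_bg, replace = TRUE),
    node_b = sample(others, n_bg, replace = TRUE),
    score = stats::runif(n_bg, 0.2, 0.9)
  )
  bg_edges <- bg_edges[bg_edges$node_a != bg_edges$node_b, ]
  suppressMessages(
    validate_edge_list(dplyr::bind_rows(hub_edges, bg_edges), "ppi")
  )
}

#' Export the cohort's gene-set collection (GMT-ready)
#'
#' TF / hub / miRNA signature sets plus the stromal, immune, 28 TIL and
#' ICG sets planted by the generator.
#'
#' @param cohort A [generate_cohort()] result.
#' @return A named list of character vectors (class `gene_set_collection`).
#' @export
export_gene_sets <- function(cohort) {
  structure(cohort$truth$gene_sets, class = "gene_set_collection")
}

#' Simulate single-covariate exponential survival data
#'
#' Survival times follow an exponential hazard `rate = baseline_rate *
#' exp(beta * x)` with a standard-normal covariate `x` and independent
#' uniform censoring; used for proportional-hazards parameter-recovery
#' checks.
#'
#' @param n Number of subjects.
#' @param beta True log-hazard coefficient.
#' @param baseline_rate Baseline event rate per month.
#' @param censor_max Upper bound of the uniform censoring distribution
#'   (months); the defaults give roughly 30% censoring.
#' @param seed Integer seed.
#' @return A tibble with columns `time`, `event`, `x`.
#' @export
simulate_survival <- function(n = 500, beta = 0.7, baseline_rate = 0.02,
                              censor_max = 150, seed = 1L) {
  set.seed(seed)
  x <- stats::rnorm(n)
  t_true <- stats::rexp(n, rate = baseline_rate * exp(beta * x))
  cens <- stats::runif(n, 0, censor_max)
  tibble::tibble(
    time = pmin(t_true, cens),
    event = as.integer(t_true <= cens),
    x = x
  )
}
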