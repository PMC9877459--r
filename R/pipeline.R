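#' Run the full inference pipeline on a synthetic cohort
#'
#' Orchestrates every stage end-to-end: cohort simulation, differential
#' expression with subtype-exclusivity algebra, PPI hub ranking (MCC) and
#' dense-module detection (MCODE), prior filtering and correlation
#' validation of the TF-mRNA-miRNA network, feed-forward loop
#' classification, signature / immune scoring, and survival
#' characterization.  With `out_dir` set, each stage writes its result
#' tables as TSV; repeated runs with the same config and seed produce
#' byte-identical outputs.
#'
#' @param config A [default_config()] run configuration.
#' @param design A [simulation_design()].
#' @param out_dir Optional output directory for stage TSVs.
#' @param quiet Suppress stage log messages.
#' @param with_scoring,with_survival Toggle the immune-scoring and
#'   survival stages (the network stages never depend on them).
#' @return A list with the results of every stage (see Details in the
#'   package vignette).
#' @export
run_pipeline <- function(config = default_config(),
                         design = simulation_design(),
                         out_dir = NULL, quiet = FALSE,
                         with_scoring = TRUE, with_survival = TRUE) {
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed

  # -- simulate -------------------------------------------------------
  cohort <- generate_cohort(design, seed = seed)
  priors <- export_priors(cohort, decoy_fraction = config$decoy_fraction,
                          seed = seed)
  ppi <- export_ppi(cohort, seed = seed)
  sets <- export_gene_sets(cohort)
  log_msg("simulate: %d samples, %d genes, %d miRNAs",
          ncol(cohort$mrna$values), nrow(cohort$mrna$values),
          nrow(cohort$mirna$values))

  # -- degs -----------------------------------------------------------
  tumor_subtypes <- setdiff(unique(cohort$mrna$annotations$subtype), "normal")
  de_tables <- lapply(tumor_subtypes, function(s) {
    moderated_de(cohort$mrna, s, "normal",
                 p_cut = config$mrna_p_cut, lfc_cut = config$mrna_lfc_cut)
  })
  names(de_tables) <- tumor_subtypes
  calls <- lapply(de_tables, call_degs,
                  p_cut = config$mrna_p_cut, lfc_cut = config$mrna_lfc_cut)
  exclusivity <- exclusive_degs(
    calls, target = "MTC",
    merge_plan = list(WDTC = intersect(c("PTC", "FTC", "OTC"), tumor_subtypes),
                      TA = intersect(c("FTA", "OTA"), tumor_subtypes)),
    second_cohort_degs = cohort$truth$second_cohort_degs
  )
  exclusive <- c(exclusivity$post_exclusion_up, exclusivity$post_exclusion_down)
  de_mirna <- moderated_de(cohort$mirna, "MTC", "normal",
                           p_cut = config$mirna_p_cut,
                           lfc_cut = config$mirna_lfc_cut)
  mirna_down <- call_degs(de_mirna, config$mirna_p_cut,
                          config$mirna_lfc_cut)$down
  log_msg("degs: %d exclusive (p<%.2g, |lfc|>=%.2g), %d miRNAs down",
          length(exclusive), config$mrna_p_cut, config$mrna_lfc_cut,
          length(mirna_down))

  # -- network (PPI -> hubs, modules) ---------------------------------
  graph <- build_ppi(ppi, min_score = config$ppi_min_score,
                     restrict_to = exclusive)
  hubs <- mcc_ranking(graph, top_k = config$top_k_hubs)
  hub_set <- hubs$node[hubs$is_hub]
  modules <- mcode_modules(graph)
  log_msg("network: %d nodes, %d edges; %d modules; top hub %s",
          igraph::vcount(graph), igraph::ecount(graph), nrow(modules),
          hubs$node[1])

  # -- ffl (regulatory network) ---------------------------------------
  mtc_samples <- cohort$mrna$annotations$sample_id[
    cohort$mrna$annotations$subtype == "MTC"]
  tf_cand <- filter_tf_candidates(priors$tf_prior, config$nes_min, hub_set)
  mir_cand <- filter_mirna_candidates(priors$mirna_prior, config$min_tools,
                                      mirna_down, hub_set)
  tf_edges <- validate_edges(tf_cand[, c("tf", "target")], cohort$mrna,
                             layer = "tf_mrna", alpha = config$cor_alpha,
                             samples = mtc_samples)
  mir_edges <- validate_edges(mir_cand[, c("mirna", "target")], cohort$mrna,
                              cohort$mirna, layer = "mirna_mrna",
                              alpha = config$cor_alpha, samples = mtc_samples)
  tfmir_cand <- tidyr::expand_grid(tf = unique(tf_edges$source),
                                   mirna = unique(mir_edges$source))
  tfmir_edges <- if (nrow(tfmir_cand) > 0) {
    validate_edges(tfmir_cand, cohort$mrna, cohort$mirna,
                   layer = "tf_mirna", alpha = config$cor_alpha,
                   samples = mtc_samples)
  } else NULL
  network <- assemble_network(tf_edges, mir_edges, tfmir_edges)
  ffls <- find_ffls(network)
  log_msg("ffl: %d edges, %d chains, %d loops (%d coherent)",
          nrow(network$edges), nrow(network$chains), nrow(ffls),
          sum(ffls$classification == "coherent"))

  # -- score (signatures + immune, tumor samples) ---------------------
  scores <- est <- associations <- NULL
  surv_data <- surv_report <- NULL
  net_tfs <- network$nodes$id[network$nodes$type == "TF"]
  net_mirnas <- network$nodes$id[network$nodes$type == "miRNA"]
  if (with_scoring) {
  scores <- signature_scores(cohort$mrna, cohort$mirna,
                             tf_set = if (length(net_tfs)) net_tfs else sets$tf_set,
                             hub_set = hub_set,
                             mirna_set = if (length(net_mirnas)) net_mirnas else sets$mirna_set,
                             alpha = config$ssgsea_alpha,
                             samples = mtc_samples)
  mtc_mrna <- subset_samples(cohort$mrna, mtc_samples)
  est <- estimate_scores(mtc_mrna, sets$stromal, sets$immune,
                         alpha = config$ssgsea_alpha)
  til_names <- grep("^til_", names(sets), value = TRUE)
  til_scores <- vapply(til_names, function(nm) {
    ssgsea_score(mtc_mrna, sets[[nm]], config$ssgsea_alpha, normalize = TRUE)
  }, numeric(length(mtc_samples)))
  icg_expr <- t(mtc_mrna$values[intersect(sets$icg, feature_ids(mtc_mrna)), ,
                                drop = FALSE])
  immune_quantities <- cbind(
    stromal_score = est$stromal_score, immune_score = est$immune_score,
    estimate_score = est$estimate_score, tumor_purity = est$tumor_purity,
    til_scores, icg_expr
  )
  associations <- purrr::map_dfr(c("hub", "tf", "mirna"), function(sig) {
    purrr::map_dfr(colnames(immune_quantities), function(q) {
      dplyr::mutate(
        immune_associations(scores, immune_quantities[, q], sig, "wilcoxon"),
        quantity = q, .before = 1)
    })
  })
  log_msg("score: %d MTC samples, %d immune quantities", length(mtc_samples),
          ncol(immune_quantities))
  }

  # -- survive (whole cohort) -----------------------------------------
  if (with_survival) {
  all_scores <- signature_scores(cohort$mrna, cohort$mirna,
                                 sets$tf_set, hub_set, sets$mirna_set,
                                 alpha = config$ssgsea_alpha)
  all_est <- estimate_scores(cohort$mrna, sets$stromal, sets$immune,
                             alpha = config$ssgsea_alpha)
  surv_data <- cohort$mrna$annotations |>
    dplyr::select("sample_id", "time", "event") |>
    dplyr::left_join(all_scores, by = "sample_id") |>
    dplyr::left_join(all_est, by = "sample_id")
  surv_report <- survival_report(surv_data,
                                 c("hub_score", "tf_score", "mirna_score"),
                                 endpoint = "OS",
                                 minprop = config$cutpoint_minprop)
  log_msg("survive: %d subjects, %d events", nrow(surv_data),
          sum(surv_data$event))
  }

  results <- list(
    config = config, cohort = cohort, priors = priors, ppi = ppi,
    gene_sets = sets, de_tables = de_tables, de_mirna = de_mirna,
    exclusivity = exclusivity, exclusive_degs = exclusive,
    mirna_down = mirna_down, graph = graph, hubs = hubs, modules = modules,
    network = network, ffls = ffls, scores = scores, estimate = est,
    associations = associations, survival_data = surv_data,
    survival_report = surv_report
  )
  if (!is.null(out_dir)) write_pipeline_results(results, out_dir)
  results
}

#' Write pipeline stage tables to a directory
#'
#' @param results A [run_pipeline()] result list.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) readr::write_tsv(tibble::as_tibble(x),
                                          file.path(out_dir, name),
                                          progress = FALSE)
  write_expression(results$cohort$mrna, file.path(out_dir, "mrna.tsv"),
                   file.path(out_dir, "annotations.tsv"))
  write_expression(results$cohort$mirna, file.path(out_dir, "mirna.tsv"))
  write_gmt(results$gene_sets, file.path(out_dir, "gene_sets.gmt"))
  w(results$ppi, "ppi_edges.tsv")
  w(results$priors$tf_prior, "tf_prior.tsv")
  w(results$priors$mirna_prior, "mirna_prior.tsv")
  for (nm in names(results$de_tables)) {
    w(results$de_tables[[nm]], sprintf("de_%s_vs_normal.tsv", nm))
  }
  w(results$de_mirna, "de_mirna_MTC_vs_normal.tsv")
  w(results$exclusivity$report, "exclusivity_report.tsv")
  w(tibble::tibble(feature = results$exclusive_degs), "exclusive_degs.tsv")
  w(results$hubs, "hub_ranking.tsv")
  w(dplyr::mutate(results$modules,
                  members = vapply(.data$members, paste, "", collapse = ",")),
    "mcode_modules.tsv")
  w(results$network$edges, "network_edges.tsv")
  w(results$network$chains, "network_chains.tsv")
  w(results$ffls, "ffl_table.tsv")
  if (!is.null(results$scores)) {
    w(results$scores, "score_table.tsv")
    w(results$estimate, "estimate_scores.tsv")
    w(results$associations, "immune_associations.tsv")
  }
  if (!is.null(results$survival_report)) w(results$survival_report, "survival_report.tsv")
  invisible(out_dir)
}
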