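#' Filter TF->target candidate pairs by enrichment score
#'
#' Keeps predicted pairs with NES strictly greater than `nes_min`
#' (default 5.0) whose target belongs to the hub-gene set.
#'
#' @param pairs A `tf_prior` tibble (`tf`, `target`, `nes`).
#' @param nes_min NES threshold (strict `>`).
#' @param allowed_targets Character vector of allowed target genes.
#' @return The filtered tibble.
#' @export
filter_tf_candidates <- function(pairs, nes_min = 5.0, allowed_targets) {
  pairs <- validate_edge_list(pairs, "tf_prior")
  pairs[pairs$nes > nes_min & pairs$target %in% allowed_targets, , drop = FALSE]
}

#' Filter miRNA->target candidate pairs
#'
#' Keeps pairs supported by at least `min_tools` prediction tools
#' (inclusive), whose miRNA is in the DE-downregulated miRNA set and whose
#' target is in the hub-gene set.
#'
#' @param pairs A `mirna_prior` tibble (`mirna`, `target`, `tool_count`).
#' @param min_tools Minimum supporting tool count (inclusive `>=`).
#' @param de_down_mirnas Character vector of downregulated miRNAs.
#' @param allowed_targets Character vector of allowed target genes.
#' @return The filtered tibble.
#' @export
filter_mirna_candidates <- function(pairs, min_tools = 2,
                                    de_down_mirnas, allowed_targets) {
  pairs <- validate_edge_list(pairs, "mirna_prior")
  pairs[pairs$tool_count >= min_tools &
          pairs$mirna %in% de_down_mirnas &
          pairs$target %in% allowed_targets, , drop = FALSE]
}

#' Validate candidate regulatory pairs by expression correlation
#'
#' Spearman correlation per pair on the common samples, with layer-specific
#' retention: `mirna_mrna` keeps significantly negative pairs (repression),
#' `tf_mirna` keeps significantly positive pairs, and `tf_mrna` keeps
#' significant pairs of either sign, the sign recorded and carried into the
#' network (repressor vs activator).  By default correlations are computed
#' on tumor samples only (the `tumor_subtype` argument); pass
#' `samples = sample_ids(...)` to include all samples.
#'
#' @param pairs A two-column source/target pair table (first column the
#'   regulator, second the target), e.g. the output of the filter
#'   functions.
#' @param mrna mRNA [expression_dataset()].
#' @param mirna miRNA [expression_dataset()] (needed for layers touching
#'   miRNAs).
#' @param layer One of `"tf_mrna"`, `"mirna_mrna"`, `"tf_mirna"`.
#' @param alpha Significance level for retention (default 0.05; widening
#'   to 0.1 admits the weakest annotated tier).
#' @param tumor_subtype Subtype label defining the correlation samples
#'   (default `"MTC"`); ignored when `samples` is given.
#' @param samples Optional explicit character vector of sample ids.
#' @return A tibble of class `validated_edges`: `source`, `target`,
#'   `layer`, `rho`, `p_value`, `sign`, `tier` for the retained pairs.
#' @export
validate_edges <- function(pairs, mrna, mirna = NULL,
                           layer = c("tf_mrna", "mirna_mrna", "tf_mirna"),
                           alpha = 0.05, tumor_subtype = "MTC",
                           samples = NULL) {
  layer <- match.arg(layer)
  pairs <- tibble::as_tibble(pairs)
  src_data <- if (layer == "mirna_mrna") mirna else mrna
  tgt_data <- if (layer == "tf_mirna") mirna else mrna
  if (is.null(src_data) || is.null(tgt_data)) {
    stop("the miRNA dataset is required for this layer", call. = FALSE)
  }
  if (is.null(samples)) {
    ann <- mrna$annotations
    samples <- if ("subtype" %in% names(ann) && tumor_subtype %in% ann$subtype) {
      ann$sample_id[ann$subtype == tumor_subtype]
    } else {
      sample_ids(mrna)
    }
  }
  samples <- Reduce(intersect, list(samples, sample_ids(src_data),
                                    sample_ids(tgt_data)))
  if (length(samples) < 3) stop("fewer than 3 common samples", call. = FALSE)

  out <- purrr::pmap_dfr(list(pairs[[1]], pairs[[2]]), function(src, tgt) {
    if (!src %in% feature_ids(src_data) || !tgt %in% feature_ids(tgt_data)) {
      message(sprintf("pair %s -> %s skipped: member absent from its matrix",
                      src, tgt))
      return(NULL)
    }
    cr <- spearman_correlation(src_data$values[src, samples],
                               tgt_data$values[tgt, samples])
    tibble::tibble(source = src, target = tgt, layer = layer,
                   rho = cr$rho, p_value = cr$p_value)
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(source = character(), target = character(),
                          layer = character(), rho = numeric(),
                          p_value = numeric())
  }
  out <- out |>
    dplyr::mutate(sign = ifelse(.data$rho >= 0, 1L, -1L),
                  tier = p_tier(.data$p_value))
  retained <- switch(layer,
    mirna_mrna = out$rho < 0 & out$p_value < alpha,
    tf_mirna = out$rho > 0 & out$p_value < alpha,
    tf_mrna = out$p_value < alpha
  )
  res <- out[retained, , drop = FALSE]
  class(res) <- c("validated_edges", class(res))
  res
}

#' Assemble the tri-partite TF-mRNA-miRNA network
#'
#' Nodes are typed TF / gene / miRNA; one validated edge list per layer.
#' A gene participates in a linear TF-gene-miRNA chain only when it has
#' both a retained TF edge and a retained miRNA edge; genes lacking either
#' remain in the network flagged non-linear.
#'
#' @param tf_edges,mirna_edges,tfmir_edges [validate_edges()] outputs for
#'   the `tf_mrna`, `mirna_mrna`, `tf_mirna` layers (any may be empty).
#' @return A list of class `regulatory_network` with `edges` (all layers,
#'   one tibble), `nodes` (`id`, `type`, `linear`), and `chains` (tibble
#'   of TF-gene-miRNA triples, Sankey-ready).
#' @export
assemble_network <- function(tf_edges, mirna_edges, tfmir_edges = NULL) {
  empty_edges <- tibble::tibble(source = character(), target = character(),
                                layer = character(), rho = numeric(),
                                p_value = numeric(), sign = integer(),
                                tier = character())
  norm <- function(x) if (is.null(x) || nrow(x) == 0) empty_edges else
    tibble::as_tibble(x)[, names(empty_edges)]
  edges <- dplyr::bind_rows(norm(tf_edges), norm(mirna_edges), norm(tfmir_edges))

  tfs <- unique(c(edges$source[edges$layer %in% c("tf_mrna", "tf_mirna")]))
  mirnas <- unique(c(edges$source[edges$layer == "mirna_mrna"],
                     edges$target[edges$layer == "tf_mirna"]))
  genes <- unique(c(edges$target[edges$layer %in% c("tf_mrna", "mirna_mrna")]))

  te <- edges[edges$layer == "tf_mrna", ]
  me <- edges[edges$layer == "mirna_mrna", ]
  chains <- dplyr::inner_join(
    dplyr::select(te, tf = "source", gene = "target", tf_sign = "sign"),
    dplyr::select(me, mirna = "source", gene = "target", mirna_sign = "sign"),
    by = "gene", relationship = "many-to-many"
  )
  linear_genes <- unique(chains$gene)
  nodes <- dplyr::bind_rows(
    tibble::tibble(id = tfs, type = "TF"),
    tibble::tibble(id = genes, type = "gene"),
    tibble::tibble(id = mirnas, type = "miRNA")
  ) |>
    dplyr::distinct(.data$id, .keep_all = TRUE) |>
    dplyr::mutate(linear = .data$type != "gene" | .data$id %in% linear_genes)

  structure(list(edges = edges, nodes = nodes, chains = chains),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  tab <- table(x$edges$layer)
  cat(sprintf("regulatory_network: %d nodes, %d edges (%s), %d linear chains\n",
              nrow(x$nodes), nrow(x$edges),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              nrow(x$chains)))
  invisible(x)
}

#' Enumerate and classify feed-forward loops
#'
#' Every (TF, gene, miRNA) triple whose three edges (TF->gene, TF->miRNA,
#' miRNA->gene) are all present in the network is emitted.  The loop is
#' coherent iff the direct edge sign equals the product of the indirect
#' path's signs: `s_tg = s_tm * s_mg`.
#'
#' @param network A [assemble_network()] result.
#' @return A tibble of class `ffl_table`: `tf`, `gene`, `mirna`, `s_tg`,
#'   `s_tm`, `s_mg`, `classification`.
#' @export
find_ffls <- function(network) {
  e <- network$edges
  tg <- dplyr::select(e[e$layer == "tf_mrna", ],
                      tf = "source", gene = "target", s_tg = "sign")
  tm <- dplyr::select(e[e$layer == "tf_mirna", ],
                      tf = "source", mirna = "target", s_tm = "sign")
  mg <- dplyr::select(e[e$layer == "mirna_mrna", ],
                      mirna = "source", gene = "target", s_mg = "sign")
  res <- tg |>
    dplyr::inner_join(tm, by = "tf", relationship = "many-to-many") |>
    dplyr::inner_join(mg, by = c("mirna", "gene")) |>
    dplyr::mutate(
      classification = ifelse(.data$s_tg == .data$s_tm * .data$s_mg,
                              "coherent", "incoherent")
    ) |>
    dplyr::select("tf", "gene", "mirna", "s_tg", "s_tm", "s_mg",
                  "classification")
  class(res) <- c("ffl_table", class(res))
  res
}
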