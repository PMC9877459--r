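#' Build a confidence-filtered PPI graph
#'
#' Keeps edges with confidence score strictly greater than `min_score`
#' (the conventional 0.4 medium-confidence threshold) and optionally
#' restricts the node set to a supplied DEG list; isolated nodes are
#' retained only when `restrict_to` is given (they are part of the
#' declared universe).
#'
#' @param edges A ppi edge tibble (`node_a`, `node_b`, `score`), e.g. from
#'   [read_edge_list()] or [export_ppi()].
#' @param min_score Retention threshold (strict `>`).
#' @param restrict_to Optional character vector of allowed node ids.
#' @return An undirected [igraph::graph] with a `score` edge attribute.
#' @export
build_ppi <- function(edges, min_score = 0.4, restrict_to = NULL) {
  edges <- validate_edge_list(edges, "ppi")
  edges <- edges[edges$score > min_score, , drop = FALSE]
  if (!is.null(restrict_to)) {
    edges <- edges[edges$node_a %in% restrict_to & edges$node_b %in% restrict_to, ]
    vertices <- unique(restrict_to)
  } else {
    vertices <- unique(c(edges$node_a, edges$node_b))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = sort(vertices))
  g
}

#' Maximal clique centrality (MCC) hub ranking
#'
#' `MCC(v)` is the sum over all maximal cliques `C` containing `v` of
#' `(|C| - 1)!`; a node whose only maximal clique is itself scores
#' `0! = 1`.  Clique enumeration is exact.  Ties in the score are broken
#' by node degree, then lexicographic id, so the ranking is deterministic.
#'
#' @param graph An undirected igraph, e.g. from [build_ppi()].
#' @param top_k Size of the reported hub selection (default 15).
#' @return A tibble of class `hub_ranking` with columns `node`,
#'   `mcc_score`, `degree`, `rank`, `is_hub` (TRUE for the top `top_k`).
#' @export
mcc_ranking <- function(graph, top_k = 15) {
  if (igraph::vcount(graph) < 1) stop("graph has no nodes", call. = FALSE)
  nodes <- igraph::V(graph)$name
  score <- stats::setNames(numeric(length(nodes)), nodes)
  cliques <- igraph::max_cliques(graph)
  for (cl in cliques) {
    members <- nodes[as.integer(cl)]
    score[members] <- score[members] + factorial(length(members) - 1)
  }
  deg <- igraph::degree(graph)[nodes]
  res <- tibble::tibble(node = nodes, mcc_score = unname(score),
                        degree = unname(deg)) |>
    dplyr::arrange(dplyr::desc(.data$mcc_score), dplyr::desc(.data$degree),
                   .data$node) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  is_hub = .data$rank <= top_k)
  class(res) <- c("hub_ranking", class(res))
  res
}

# density 2E/(n(n-1)) of an igraph (0 for n < 2); no self-loops by invariant
graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

# MCODE stage-1 vertex weight: (density of the highest k-core of the closed
# neighborhood) x (that core's k)
mcode_vertex_weights <- function(graph) {
  nodes <- igraph::V(graph)$name
  vapply(seq_along(nodes), function(i) {
    nb <- c(i, as.integer(igraph::neighbors(graph, i)))
    sub <- igraph::induced_subgraph(graph, unique(nb))
    if (igraph::ecount(sub) == 0) return(0)
    cores <- igraph::coreness(sub)
    k <- max(cores)
    core_sub <- igraph::induced_subgraph(sub, which(cores >= k))
    k * graph_density(core_sub)
  }, numeric(1)) |> stats::setNames(nodes)
}

#' MCODE dense-module detection
#'
#' Three stages: (1) each node is weighted by the product of the highest
#' k-core number of its closed neighborhood and the density of that core;
#' (2) complexes grow from the highest-weighted unassigned seed,
#' breadth-first including neighbors whose weight exceeds
#' `(1 - vwp) * seed weight`, never revisiting nodes already assigned to a
#' complex; (3) the haircut removes singly-connected nodes (the module is
#' reduced to its 2-core).  Modules smaller than `min_module_size` are
#' dropped; `score = density * n`; modules are reported in descending
#' score order.
#'
#' @param graph An undirected igraph.
#' @param vwp Vertex weight percentage (default 0.2).
#' @param haircut Apply the 2-core haircut (default TRUE).
#' @param fluff Accepted for interface completeness; the fluff
#'   post-processing stage is not implemented and must be FALSE.
#' @param min_module_size Minimum module size after post-processing.
#' @return A tibble of class `mcode_result`: `module`, `seed`, `n`,
#'   `density`, `score`, `members` (list-column), sorted by score.
#' @export
mcode_modules <- function(graph, vwp = 0.2, haircut = TRUE, fluff = FALSE,
                          min_module_size = 3) {
  if (fluff) stop("fluff post-processing is not implemented", call. = FALSE)
  nodes <- igraph::V(graph)$name
  if (length(nodes) == 0 || igraph::ecount(graph) == 0) {
    return(empty_mcode_result())
  }
  w <- mcode_vertex_weights(graph)
  deg <- igraph::degree(graph)[nodes]
  order_ids <- nodes[order(-w[nodes], -deg[nodes], nodes)]
  assigned <- character(0)
  modules <- list()

  for (seed in order_ids) {
    if (seed %in% assigned) next
    threshold <- (1 - vwp) * w[seed]
    members <- seed
    queue <- seed
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- nodes[as.integer(igraph::neighbors(graph, v))]
      nb <- setdiff(nb, c(assigned, members))
      keep <- nb[w[nb] > threshold]
      members <- c(members, keep)
      queue <- c(queue, keep)
    }
    assigned <- c(assigned, members)
    sub <- igraph::induced_subgraph(graph, members)
    if (haircut && igraph::vcount(sub) > 0) {
      cores <- igraph::coreness(sub)
      sub <- igraph::induced_subgraph(sub, which(cores >= 2))
    }
    n <- igraph::vcount(sub)
    if (n >= min_module_size) {
      d <- graph_density(sub)
      modules[[length(modules) + 1]] <- tibble::tibble(
        seed = seed, n = n, density = d, score = d * n,
        members = list(sort(igraph::V(sub)$name))
      )
    }
  }
  if (length(modules) == 0) return(empty_mcode_result())
  res <- dplyr::bind_rows(modules) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$seed) |>
    dplyr::mutate(module = dplyr::row_number(), .before = 1)
  class(res) <- c("mcode_result", class(res))
  res
}

empty_mcode_result <- function() {
  res <- tibble::tibble(module = integer(), seed = character(), n = integer(),
                        density = numeric(), score = numeric(),
                        members = list())
  class(res) <- c("mcode_result", class(res))
  res
}
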