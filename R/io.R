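#' Construct an expression dataset
#'
#' The common currency of the pipeline: a log2-scale features x samples
#' matrix plus a per-sample annotation table.  Invariants enforced: unique
#' feature and sample ids, annotation rows exactly matching the sample ids,
#' survival time present iff the event flag is present.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   rownames (feature ids) and colnames (sample ids).
#' @param annotations Data frame keyed by a `sample_id` column; recognised
#'   optional columns: `subtype`, `batch`, `time` (months, > 0), `event`
#'   (0/1), `mutation`.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, annotations) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids", call. = FALSE)
  annotations <- tibble::as_tibble(annotations)
  if (!"sample_id" %in% names(annotations)) {
    stop("annotations need a `sample_id` column", call. = FALSE)
  }
  if (anyDuplicated(annotations$sample_id)) {
    stop("duplicate sample ids in annotations", call. = FALSE)
  }
  if (!setequal(annotations$sample_id, colnames(values))) {
    stop("annotation sample ids must exactly match the matrix samples", call. = FALSE)
  }
  annotations <- annotations[match(colnames(values), annotations$sample_id), ]
  if (xor("time" %in% names(annotations), "event" %in% names(annotations))) {
    stop("survival `time` must be present iff `event` is present", call. = FALSE)
  }
  if ("time" %in% names(annotations) &&
      any(annotations$time <= 0, na.rm = TRUE)) {
    stop("survival times must be positive", call. = FALSE)
  }
  if ("event" %in% names(annotations) &&
      !all(annotations$event %in% c(0, 1, NA))) {
    stop("event flag must be 0/1", call. = FALSE)
  }
  structure(list(values = values, annotations = annotations),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if ("subtype" %in% names(x$annotations)) {
    tab <- table(x$annotations$subtype)
    cat("subtypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Feature and sample accessors
#' @param dataset An `expression_dataset`.
#' @return Character vector of ids.
#' @export
feature_ids <- function(dataset) rownames(dataset$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(dataset) colnames(dataset$values)

#' Subset an expression dataset by sample ids
#' @param dataset An `expression_dataset`.
#' @param samples Character vector of sample ids to keep (order preserved).
#' @export
subset_samples <- function(dataset, samples) {
  samples <- intersect(samples, sample_ids(dataset))
  expression_dataset(
    dataset$values[, samples, drop = FALSE],
    dataset$annotations[match(samples, dataset$annotations$sample_id), ]
  )
}

#' Read a delimited expression matrix plus its sample annotation
#'
#' Expects tab-separated text with the feature id in the first column and a
#' header row of sample ids; the annotation table is keyed by `sample_id`.
#' Duplicate feature rows are collapsed to the row with the highest mean
#' expression (the usual multi-probe microarray convention), with a message
#' reporting the count.  Features with more than `max_missing` missing
#' values are dropped; `log2_transform` applies `log2(x + 1)` for raw-scale
#' input.
#'
#' @param path Path to the expression matrix TSV.
#' @param annotation_path Path to the annotation TSV.
#' @param log2_transform Apply `log2(x + 1)` to the values.
#' @param max_missing Maximum tolerated fraction of missing values per
#'   feature (default 0.2).
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, annotation_path, log2_transform = FALSE,
                            max_missing = 0.2) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2) stop("malformed expression file: need id + samples", call. = FALSE)
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1])
  if (!is.numeric(mat)) stop("non-numeric expression cell", call. = FALSE)
  rownames(mat) <- ids

  if (anyDuplicated(ids)) {
    n_dup <- sum(duplicated(ids))
    means <- rowMeans(mat, na.rm = TRUE)
    ord <- order(means, decreasing = TRUE)
    mat <- mat[ord, , drop = FALSE]
    mat <- mat[!duplicated(rownames(mat)), , drop = FALSE]
    message(sprintf("collapsed %d duplicate feature row(s) to highest-mean row", n_dup))
  }
  miss <- rowMeans(is.na(mat))
  if (any(miss > max_missing)) {
    message(sprintf("dropped %d feature(s) with > %.0f%% missing values",
                    sum(miss > max_missing), 100 * max_missing))
    mat <- mat[miss <= max_missing, , drop = FALSE]
  }
  if (log2_transform) mat <- log2(mat + 1)

  ann <- readr::read_tsv(annotation_path, show_col_types = FALSE, progress = FALSE)
  expression_dataset(mat, ann)
}

#' Write an expression dataset to TSV files
#'
#' @param dataset An [expression_dataset()].
#' @param path Output path for the matrix TSV (feature id column + sample
#'   columns).
#' @param annotation_path Output path for the annotation TSV.
#' @return `dataset`, invisibly.
#' @export
write_expression <- function(dataset, path, annotation_path = NULL) {
  tab <- tibble::as_tibble(dataset$values, rownames = "feature_id")
  readr::write_tsv(tab, path, progress = FALSE)
  if (!is.null(annotation_path)) {
    readr::write_tsv(dataset$annotations, annotation_path, progress = FALSE)
  }
  invisible(dataset)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member ids.  Duplicate members within a set are de-duplicated;
#' duplicate set names or lines with fewer than three fields are errors.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors with a `description`
#'   attribute per set (class `gene_set_collection`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3
  if (any(bad)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", which(bad)[1]), call. = FALSE)
  }
  nm <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate gene-set name: %s", nm[duplicated(nm)][1]), call. = FALSE)
  }
  sets <- lapply(parts, function(p) {
    members <- unique(p[-(1:2)])
    members <- members[nzchar(members)]
    attr(members, "description") <- p[[2]]
    members
  })
  names(sets) <- nm
  if (any(vapply(sets, length, 1L) == 0)) stop("empty gene set", call. = FALSE)
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of character vectors (optionally with a
#'   `description` attribute per set).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    d <- attr(sets[[nm]], "description")
    if (is.null(d)) d <- nm
    paste(c(nm, d, as.character(sets[[nm]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(sets)
}

#' Read a typed edge list
#'
#' Three dialects share one tab-separated layout:
#' * `ppi`: `node_a`, `node_b`, `score` in `[0, 1]`.  Self-edges are
#'   dropped (count reported); duplicate undirected pairs keep the maximum
#'   score.
#' * `tf_prior`: `tf`, `target`, `nes` (>= 0).
#' * `mirna_prior`: `mirna`, `target`, `tool_count` (positive integer).
#'
#' @param path Path to the edge-list TSV (with header).
#' @param kind One of `"ppi"`, `"tf_prior"`, `"mirna_prior"`.
#' @return A tibble of validated edge records.
#' @export
read_edge_list <- function(path, kind = c("ppi", "tf_prior", "mirna_prior")) {
  kind <- match.arg(kind)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_edge_list(tab, kind)
}

#' Validate an in-memory edge table against a dialect
#' @inheritParams read_edge_list
#' @param tab A data frame with the three dialect columns.
#' @export
validate_edge_list <- function(tab, kind = c("ppi", "tf_prior", "mirna_prior")) {
  kind <- match.arg(kind)
  tab <- tibble::as_tibble(tab)
  if (ncol(tab) < 3) stop("edge list needs 3 columns", call. = FALSE)
  if (kind == "ppi") {
    names(tab)[1:3] <- c("node_a", "node_b", "score")
    if (any(tab$score < 0 | tab$score > 1, na.rm = TRUE)) {
      stop("ppi scores must lie in [0, 1]", call. = FALSE)
    }
    n_self <- sum(tab$node_a == tab$node_b)
    if (n_self > 0) {
      message(sprintf("dropped %d self-edge(s)", n_self))
      tab <- tab[tab$node_a != tab$node_b, ]
    }
    # canonical unordered orientation, then max-merge duplicates
    flip <- tab$node_a > tab$node_b
    tmp <- tab$node_a[flip]
    tab$node_a[flip] <- tab$node_b[flip]
    tab$node_b[flip] <- tmp
    if (nrow(tab) > 0) {
      tab <- tab |>
        dplyr::group_by(.data$node_a, .data$node_b) |>
        dplyr::summarise(score = max(.data$score), .groups = "drop")
    }
  } else if (kind == "tf_prior") {
    names(tab)[1:3] <- c("tf", "target", "nes")
    if (any(tab$nes < 0, na.rm = TRUE)) stop("NES must be >= 0", call. = FALSE)
  } else {
    names(tab)[1:3] <- c("mirna", "target", "tool_count")
    if (any(tab$tool_count != round(tab$tool_count)) ||
        any(tab$tool_count < 1)) {
      stop("tool_count must be a positive integer", call. = FALSE)
    }
    tab$tool_count <- as.integer(tab$tool_count)
  }
  tab
}

#' Default run configuration
#'
#' All pipeline thresholds with the study defaults: mRNA DE at adjusted
#' p < 0.05 and |log2FC| >= 1; miRNA DE at adjusted p < 0.1 and
#' |log2FC| >= 0.58; PPI edge score > 0.4; NES > 5.0; at least 2
#' prediction tools; correlation retention alpha 0.05; ssGSEA exponent
#' 0.25; cutpoint minimum group proportion 0.1.
#'
#' @param ... Named overrides for individual fields.
#' @return A list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    mrna_p_cut = 0.05, mrna_lfc_cut = 1,
    mirna_p_cut = 0.1, mirna_lfc_cut = 0.58,
    ppi_min_score = 0.4,
    nes_min = 5.0, min_tools = 2L,
    cor_alpha = 0.05,
    ssgsea_alpha = 0.25,
    cutpoint_minprop = 0.1,
    decoy_fraction = 1,
    seed = 1L,
    top_k_hubs = 15L
  )
  over <- list(...)
  cfg[names(over)] <- over
  validate_config(cfg)
}

#' Read a YAML run configuration
#' @param path Path to a YAML file of threshold overrides.
#' @return A validated `run_config` list.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(cfg$mrna_p_cut >= 0 && cfg$mrna_p_cut <= 1, "mrna_p_cut must be in [0,1]")
  chk(cfg$mirna_p_cut >= 0 && cfg$mirna_p_cut <= 1, "mirna_p_cut must be in [0,1]")
  chk(cfg$mrna_lfc_cut >= 0, "mrna_lfc_cut must be >= 0")
  chk(cfg$mirna_lfc_cut >= 0, "mirna_lfc_cut must be >= 0")
  chk(cfg$ppi_min_score >= 0 && cfg$ppi_min_score <= 1, "ppi_min_score must be in [0,1]")
  chk(cfg$nes_min >= 0, "nes_min must be >= 0")
  chk(cfg$min_tools >= 1, "min_tools must be >= 1")
  chk(cfg$cor_alpha > 0 && cfg$cor_alpha <= 1, "cor_alpha must be in (0,1]")
  chk(cfg$ssgsea_alpha >= 0, "ssgsea_alpha must be >= 0")
  chk(cfg$cutpoint_minprop > 0 && cfg$cutpoint_minprop < 0.5 ||
        cfg$cutpoint_minprop == 0.5, "cutpoint_minprop must be in (0, 0.5]")
  chk(cfg$decoy_fraction >= 0 && cfg$decoy_fraction <= 5, "decoy_fraction must be in [0,5]")
  structure(cfg, class = "run_config")
}
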