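#' Single-sample gene-set enrichment (ssGSEA) scores
#'
#' For each sample, features are ranked by expression (descending, average
#' ranks for ties; ordering ties broken by feature id for determinism).
#' The enrichment score is the sum over the ranked list of the difference
#' between the weighted in-set cumulative distribution (weights
#' `rank^alpha`, normalized to 1) and the unweighted out-of-set
#' cumulative.  With `normalize = TRUE` every score in the output batch is
#' divided by the range (max - min) of scores across the batch's samples.
#'
#' Set members absent from the matrix are dropped with a warning; scoring
#' errors only if no member remains or the effective set covers every
#' feature (the out-of-set cumulative would be empty).
#'
#' @param dataset An [expression_dataset()].
#' @param gene_set Character vector of feature ids.
#' @param alpha Rank-weighting exponent (default 0.25).
#' @param normalize Divide by the cross-sample score range.
#' @return A named numeric vector of per-sample scores.
#' @export
ssgsea_score <- function(dataset, gene_set, alpha = 0.25, normalize = FALSE) {
  X <- dataset$values
  p <- nrow(X)
  set <- unique(gene_set)
  missing <- setdiff(set, rownames(X))
  if (length(missing) > 0) {
    warning(sprintf("%d of %d set member(s) absent from the matrix; scoring on the rest",
                    length(missing), length(set)), call. = FALSE)
    set <- setdiff(set, missing)
  }
  if (length(set) == 0) stop("no set member present in the matrix", call. = FALSE)
  if (length(set) >= p) stop("gene set covers all features (empty out-of-set)", call. = FALSE)
  in_set <- rownames(X) %in% set
  m <- sum(in_set)

  scores <- vapply(seq_len(ncol(X)), function(j) {
    r <- rank(X[, j], ties.method = "average")   # highest expression -> rank p
    ord <- order(-r, rownames(X))                # descending, id tie-break
    ins <- in_set[ord]
    w <- (r[ord]^alpha) * ins
    cum_in <- cumsum(w) / sum(w)
    cum_out <- cumsum(!ins) / (p - m)
    sum(cum_in - cum_out)
  }, numeric(1))
  names(scores) <- colnames(X)
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  scores
}

#' TF / hub-gene / miRNA signature scores with mean-split groups
#'
#' The TF and hub-gene scores are ssGSEA scores on the mRNA matrix, the
#' miRNA score on the miRNA matrix (all range-normalized within the
#' batch).  For each score, samples are labelled `high` iff the score is
#' strictly greater than the cross-sample mean, else `low`.
#'
#' @param mrna,mirna [expression_dataset()] objects over the same samples.
#' @param tf_set,hub_set,mirna_set Character vectors of signature members.
#' @param alpha ssGSEA exponent.
#' @param samples Optional subset of sample ids to score (e.g. tumor
#'   samples only).
#' @return A tibble of class `score_table`: `sample_id`, `tf_score`,
#'   `hub_score`, `mirna_score`, `tf_group`, `hub_group`, `mirna_group`.
#' @export
signature_scores <- function(mrna, mirna, tf_set, hub_set, mirna_set,
                             alpha = 0.25, samples = NULL) {
  if (!identical(sample_ids(mrna), sample_ids(mirna))) {
    stop("mRNA and miRNA datasets must share identical, ordered samples", call. = FALSE)
  }
  if (!is.null(samples)) {
    mrna <- subset_samples(mrna, samples)
    mirna <- subset_samples(mirna, samples)
  }
  mean_split <- function(x) ifelse(x > mean(x), "high", "low")
  tf_score <- ssgsea_score(mrna, tf_set, alpha, normalize = TRUE)
  hub_score <- ssgsea_score(mrna, hub_set, alpha, normalize = TRUE)
  mirna_score <- ssgsea_score(mirna, mirna_set, alpha, normalize = TRUE)
  res <- tibble::tibble(
    sample_id = sample_ids(mrna),
    tf_score = unname(tf_score),
    hub_score = unname(hub_score),
    mirna_score = unname(mirna_score),
    tf_group = mean_split(tf_score),
    hub_group = mean_split(hub_score),
    mirna_group = mean_split(mirna_score)
  )
  class(res) <- c("score_table", class(res))
  res
}

#' Stromal, immune, combined and purity scores
#'
#' Stromal and immune scores are unnormalized ssGSEA scores (the
#' convention of the two-signature stromal/immune method); the combined
#' score is their sum, and tumor purity follows the published cosine
#' calibration `purity = cos(0.6049872018 + 0.0001467884 * combined)`.
#' The calibration was fitted on a specific platform, so purity is best
#' read as "purity (ESTIMATE formula)".
#'
#' @param dataset An [expression_dataset()].
#' @param stromal_set,immune_set Character vectors of signature genes.
#' @param alpha ssGSEA exponent.
#' @return A tibble: `sample_id`, `stromal_score`, `immune_score`,
#'   `estimate_score`, `tumor_purity`.
#' @export
estimate_scores <- function(dataset, stromal_set, immune_set, alpha = 0.25) {
  stromal <- ssgsea_score(dataset, stromal_set, alpha, normalize = FALSE)
  immune <- ssgsea_score(dataset, immune_set, alpha, normalize = FALSE)
  est <- stromal + immune
  tibble::tibble(
    sample_id = sample_ids(dataset),
    stromal_score = unname(stromal),
    immune_score = unname(immune),
    estimate_score = unname(est),
    tumor_purity = cos(0.6049872018 + 0.0001467884 * unname(est))
  )
}

#' Associate a signature with a per-sample immune quantity
#'
#' Two association modes: `"wilcoxon"` contrasts the quantity between the
#' signature's high and low groups (direction = sign of the high-minus-low
#' mean difference); `"spearman"` correlates the quantity with the
#' signature score itself (direction = sign of rho).  Significance tiers
#' are annotated at 0.1 / 0.05 / 0.01 / 0.001.
#'
#' @param scores A [signature_scores()] table.
#' @param values Numeric vector of the per-sample quantity, aligned with
#'   `scores$sample_id` (or named by sample id).
#' @param signature One of `"hub"`, `"tf"`, `"mirna"`.
#' @param method `"wilcoxon"` (group contrast) or `"spearman"`.
#' @return A one-row tibble: `signature`, `method`, `statistic`,
#'   `p_value`, `direction`, `tier`.
#' @export
immune_associations <- function(scores, values,
                                signature = c("hub", "tf", "mirna"),
                                method = c("wilcoxon", "spearman")) {
  signature <- match.arg(signature)
  method <- match.arg(method)
  if (!is.null(names(values))) values <- values[scores$sample_id]
  if (length(values) != nrow(scores)) {
    stop("`values` must align with the score table samples", call. = FALSE)
  }
  if (method == "wilcoxon") {
    grp <- scores[[paste0(signature, "_group")]]
    hi <- values[grp == "high"]
    lo <- values[grp == "low"]
    if (length(hi) < 2 || length(lo) < 2) {
      stop("need at least 2 samples per group", call. = FALSE)
    }
    tst <- wilcoxon_rank_sum(hi, lo)
    diff <- mean(hi) - mean(lo)
    direction <- if (tst$p_value >= 1 || diff == 0) 0L else as.integer(sign(diff))
    tibble::tibble(signature = signature, method = "wilcoxon",
                   statistic = tst$statistic, p_value = tst$p_value,
                   direction = direction, tier = p_tier(tst$p_value))
  } else {
    sc <- scores[[paste0(signature, "_score")]]
    cr <- spearman_correlation(sc, values)
    tibble::tibble(signature = signature, method = "spearman",
                   statistic = cr$rho, p_value = cr$p_value,
                   direction = as.integer(sign(cr$rho)),
                   tier = p_tier(cr$p_value))
  }
}
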