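#' Spearman rank correlation with t-approximation p-value
#'
#' Computes Spearman's rho on average-ranked data after dropping pairs with a
#' missing value in either vector.  The two-sided p-value uses the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2`
#' degrees of freedom, applied uniformly (no exact permutation p for small
#' n).  For `|rho| = 1` the tail underflows to zero and is reported as the
#' smallest representable positive double.
#'
#' @param x,y Numeric vectors of equal length; pairs with `NA` in either are
#'   dropped before ranking.
#' @return A one-row tibble with columns `rho`, `p_value`, `n`.
#' @examples
#' spearman_correlation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) {
    stop("need at least 3 complete pairs for a Spearman correlation", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("rho undefined: zero variance in a rank vector", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    p <- max(min(p, 1), .Machine$double.xmin)
  }
  tibble::tibble(rho = rho, p_value = p, n = n)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the pooled sample size is at most 20 and there are
#' no ties; otherwise the normal approximation with tie correction and
#' continuity correction.  Ranks use average ties throughout.
#'
#' @param a,b Non-empty numeric vectors (the two groups).
#' @return A one-row tibble with columns `statistic` (the Mann-Whitney U of
#'   group `a`), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  use_exact <- (length(a) + length(b)) <= 20
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE,
                       alternative = "two.sided")
  )
  p <- res$p.value
  if (is.nan(p)) p <- 1   # fully tied samples: zero-variance normal approx
  tibble::tibble(
    statistic = unname(res$statistic),
    p_value = min(p, 1),
    method = "wilcoxon"
  )
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order, monotone-enforced and
#'   clipped at 1.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' ROC curve and AUC by pairwise (Mann-Whitney) scoring
#'
#' The AUC equals `(#(pos > neg) + 0.5 * #(pos = neg)) / (n_pos * n_neg)`,
#' computed through average ranks.  Higher scores indicate the positive
#' class unless `flip = TRUE`.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (0/1, logical, or two-level factor); 1/TRUE is
#'   the positive class.
#' @param flip If `TRUE`, lower scores indicate the positive class.
#' @return A list of class `roc_result` with elements `auc`, `n_pos`,
#'   `n_neg`, and `curve` (a tibble of ordered `fpr`, `tpr` points from
#'   (0,0) to (1,1)).
#' @export
roc_auc <- function(scores, labels, flip = FALSE) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels) | labels == 1L)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  if (length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  if (flip) scores <- -scores
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # curve: sweep thresholds from +Inf down, grouping tied scores
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1)
  fp <- cumsum(labels[ord] == 0)
  last_of_tie <- c(diff(scores[ord]) != 0, TRUE)
  curve <- tibble::tibble(
    fpr = c(0, fp[last_of_tie] / n_neg),
    tpr = c(0, tp[last_of_tie] / n_pos)
  )
  structure(
    list(auc = auc, n_pos = n_pos, n_neg = n_neg, curve = curve),
    class = "roc_result"
  )
}

#' Hypergeometric over-representation test
#'
#' Upper-tail `P(X >= k)` for the overlap `k` between a query set and an
#' annotation set inside a finite universe.  The annotation is intersected
#' with the universe before testing; the query must be contained in the
#' universe.
#'
#' @param query,universe,annotation Character vectors of feature
#'   identifiers.
#' @return A one-row tibble with columns `statistic` (the overlap `k`),
#'   `p_value`, `method`, `k`, `query_size`, `annotation_size`,
#'   `universe_size`.
#' @export
hypergeometric_ora <- function(query, universe, annotation) {
  query <- unique(query)
  universe <- unique(universe)
  annotation <- unique(annotation)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (!all(query %in% universe)) {
    stop("query must be contained in the universe", call. = FALSE)
  }
  ann <- intersect(annotation, universe)
  k <- length(intersect(query, ann))
  p <- stats::phyper(k - 1, length(ann), length(universe) - length(ann),
                     length(query), lower.tail = FALSE)
  tibble::tibble(
    statistic = k, p_value = min(p, 1), method = "hypergeometric",
    k = k, query_size = length(query), annotation_size = length(ann),
    universe_size = length(universe)
  )
}

#' Significance tier label for a p-value
#'
#' Tiers follow the reporting convention used throughout the package:
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `#` p < 0.1, `ns`
#' otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of tier labels.
#' @export
p_tier <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    p < 0.1 ~ "#",
    TRUE ~ "ns"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}
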