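# Inverse of the trigamma function by Newton iteration (monotone on (0, Inf)).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

# Moment-matching fit of the scaled-F prior (d0, s0^2) on the distribution
# of log sample variances; features with zero variance are excluded from the
# fit.  Returns list(d0, s02); d0 may be Inf when the variances are
# underdispersed relative to pure chi-square sampling noise.
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0
  if (sum(ok) < 2) return(list(d0 = Inf, s02 = mean(s2[s2 > 0], na.rm = TRUE)))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated two-group differential expression
#'
#' Per-feature two-sample comparison with empirical-Bayes variance
#' moderation: the posterior variance is
#' `(d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)`, where the prior
#' `(d0, s0^2)` is estimated by moment matching on the distribution of log
#' sample variances across features.  The moderated t uses the posterior
#' variance with `d0 + d_g` degrees of freedom; p-values are two-sided and
#' adjusted by Benjamini-Hochberg across features.  `log2FC` is the mean
#' difference `group_a - group_b` on the log2 scale.
#'
#' @param dataset An [expression_dataset()] with a `subtype` annotation.
#' @param group_a,group_b Subtype labels (each with >= 2 samples);
#'   `group_a` is the tumor/numerator group.
#' @param p_cut,lfc_cut Thresholds used to annotate the `call` column
#'   (strict `<` on adjusted p, inclusive `>=` on |log2FC|).
#' @param d0,s02 Optional fixed prior values, bypassing estimation
#'   (`d0 = 0` gives the ordinary pooled-variance t).
#' @param batch_center If `TRUE` and a `batch` annotation exists, each
#'   feature is median-centered within batch before testing.
#' @return A tibble of class `de_result` with columns `feature`, `log2FC`,
#'   `t_mod`, `p_value`, `adj_p`, `call`; attributes `d0`, `s02`,
#'   `groups`, `df_total`.
#' @export
moderated_de <- function(dataset, group_a, group_b, p_cut = 0.05,
                         lfc_cut = 1, d0 = NULL, s02 = NULL,
                         batch_center = FALSE) {
  ann <- dataset$annotations
  if (!"subtype" %in% names(ann)) stop("dataset lacks a `subtype` annotation", call. = FALSE)
  if (!group_a %in% ann$subtype) stop(sprintf("group label `%s` absent", group_a), call. = FALSE)
  if (!group_b %in% ann$subtype) stop(sprintf("group label `%s` absent", group_b), call. = FALSE)
  X <- dataset$values
  if (batch_center && "batch" %in% names(ann)) {
    for (b in unique(ann$batch)) {
      idx <- which(ann$batch == b)
      med <- apply(X[, idx, drop = FALSE], 1, stats::median, na.rm = TRUE)
      X[, idx] <- X[, idx] - med
    }
  }
  ia <- which(ann$subtype == group_a)
  ib <- which(ann$subtype == group_b)
  na <- length(ia); nb <- length(ib)
  if (na < 2 || nb < 2) stop("both groups need at least 2 samples", call. = FALSE)

  A <- X[, ia, drop = FALSE]
  B <- X[, ib, drop = FALSE]
  ma <- rowMeans(A, na.rm = TRUE)
  mb <- rowMeans(B, na.rm = TRUE)
  va <- apply(A, 1, stats::var, na.rm = TRUE)
  vb <- apply(B, 1, stats::var, na.rm = TRUE)
  dg <- na + nb - 2
  s2 <- ((na - 1) * va + (nb - 1) * vb) / dg
  lfc <- ma - mb

  if (is.null(d0) || is.null(s02)) {
    prior <- fit_variance_prior(s2, dg)
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s02)) s02 <- prior$s02
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else {
    (d0 * s02 + dg * s2) / (d0 + dg)
  }
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  t_mod <- ifelse(se > 0, lfc / se, 0)
  df_total <- d0 + dg
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  adj <- benjamini_hochberg(p)

  lfc <- unname(lfc); t_mod <- unname(t_mod)
  p <- unname(p); adj <- unname(adj)
  res <- tibble::tibble(
    feature = rownames(X),
    log2FC = lfc, t_mod = t_mod, p_value = p, adj_p = adj,
    call = dplyr::case_when(
      adj < p_cut & lfc >= lfc_cut ~ "up",
      adj < p_cut & lfc <= -lfc_cut ~ "down",
      TRUE ~ "none"
    )
  )
  attr(res, "d0") <- d0
  attr(res, "s02") <- s02
  attr(res, "df_total") <- df_total
  attr(res, "groups") <- c(group_a, group_b)
  class(res) <- c("de_result", class(res))
  res
}

#' Call up/down DEG sets from a DE table
#'
#' Strict `<` on the adjusted p-value and inclusive `>=` on the absolute
#' log2 fold change, exactly as the thresholds are stated: the mRNA regime
#' is adjusted p < 0.05 with |log2FC| >= 1, the miRNA regime adjusted
#' p < 0.1 with |log2FC| >= 0.58.
#'
#' @param de A [moderated_de()] result (or any table with `feature`,
#'   `log2FC`, `adj_p`).
#' @param p_cut Adjusted-p threshold (strict).
#' @param lfc_cut |log2FC| threshold (inclusive).
#' @return A list with character vectors `up` and `down`.
#' @export
call_degs <- function(de, p_cut = 0.05, lfc_cut = 1) {
  stopifnot(p_cut >= 0, p_cut <= 1, lfc_cut >= 0)
  list(
    up = de$feature[de$adj_p < p_cut & de$log2FC >= lfc_cut],
    down = de$feature[de$adj_p < p_cut & de$log2FC <= -lfc_cut]
  )
}

#' Subtype-exclusive DEG set algebra
#'
#' An exclusive DEG is one called in the target subtype and in no
#' comparator subtype.  Disqualification is direction-agnostic: a gene DE
#' in any comparator in either direction is removed (Venn intersection of
#' gene lists, not signed lists).  Comparator subtypes may first be merged
#' (e.g. PTC/FTC/OTC into a well-differentiated group); merging is a union
#' of DEG sets, not of samples.  An optional second-cohort DEG set is then
#' subtracted to give the post-exclusion sets.
#'
#' @param per_subtype_calls Named list, one entry per subtype, each a list
#'   with `up` and `down` character vectors (as from [call_degs()]).
#' @param target The subtype whose exclusive DEGs are sought.
#' @param merge_plan Optional named list: merged-name -> member subtypes.
#' @param second_cohort_degs Optional character vector of DEGs from an
#'   independent cohort to subtract.
#' @return A list of class `exclusivity_result` with `exclusive_up`,
#'   `exclusive_down`, `post_exclusion_up`, `post_exclusion_down`, and a
#'   `report` tibble of set sizes at each step.
#' @export
exclusive_degs <- function(per_subtype_calls, target, merge_plan = NULL,
                           second_cohort_degs = NULL) {
  if (!target %in% names(per_subtype_calls)) {
    stop(sprintf("target `%s` absent from the calls", target), call. = FALSE)
  }
  calls <- per_subtype_calls
  if (!is.null(merge_plan)) {
    if (target %in% unlist(merge_plan)) {
      stop("target listed as its own comparator via the merge plan", call. = FALSE)
    }
    for (nm in names(merge_plan)) {
      members <- merge_plan[[nm]]
      merged <- list(
        up = unique(unlist(lapply(calls[members], `[[`, "up"))),
        down = unique(unlist(lapply(calls[members], `[[`, "down")))
      )
      calls[members] <- NULL
      calls[[nm]] <- merged
    }
  }
  comparators <- calls[setdiff(names(calls), target)]
  comp_union <- unique(unlist(comparators))
  tgt <- calls[[target]]
  exclusive_up <- setdiff(tgt$up, comp_union)
  exclusive_down <- setdiff(tgt$down, comp_union)
  post_up <- setdiff(exclusive_up, second_cohort_degs)
  post_down <- setdiff(exclusive_down, second_cohort_degs)

  report <- tibble::tibble(
    step = c("target_up", "target_down",
             paste0("comparator_", names(comparators)),
             "exclusive_up", "exclusive_down",
             "post_exclusion_up", "post_exclusion_down"),
    size = c(length(tgt$up), length(tgt$down),
             vapply(comparators, function(x) length(unique(unlist(x))), 1L),
             length(exclusive_up), length(exclusive_down),
             length(post_up), length(post_down))
  )
  structure(
    list(exclusive_up = exclusive_up, exclusive_down = exclusive_down,
         post_exclusion_up = post_up, post_exclusion_down = post_down,
         report = report),
    class = "exclusivity_result"
  )
}

#' @export
print.exclusivity_result <- function(x, ...) {
  cat("exclusivity_result\n")
  print(x$report, n = Inf)
  invisible(x)
}

#' @export
tidy.de_result <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_up = sum(x$call == "up"),
    n_down = sum(x$call == "down"),
    d0 = attr(x, "d0"),
    s02 = attr(x, "s02")
  )
}
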