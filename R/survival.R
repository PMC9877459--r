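#' Two-group log-rank test
#'
#' Standard log-rank chi-square on the pooled ordered event times with
#' hypergeometric expected counts; p from chi-square with 1 df.
#'
#' @param time Positive survival times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Binary group labels (two levels).
#' @return A one-row tibble: `statistic`, `p_value`, `method`, and the two
#'   group sizes `n1`, `n2`.
#' @export
logrank_test <- function(time, event, group) {
  if (length(unique(group)) != 2) stop("exactly two groups required", call. = FALSE)
  if (sum(event) == 0) stop("no events", call. = FALSE)
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  tibble::tibble(statistic = sd$chisq, p_value = p, method = "logrank",
                 n1 = sd$n[1], n2 = sd$n[2])
}

#' Optimal log-rank cutpoint for a continuous score
#'
#' Candidate cutoffs are the midpoints between consecutive distinct
#' observed scores whose induced split leaves at least a `minprop`
#' fraction of the samples on each side.  The cutoff maximizing the
#' two-group log-rank statistic is returned; ties in the statistic are
#' broken toward the more balanced split, then toward the lower cutoff.
#' The maximally-selected-statistic p-value correction is not applied: the
#' reported p is the plain log-rank p at the chosen cutoff, which is
#' anti-conservative because the cutoff was optimized.
#'
#' @param score Numeric vector.
#' @param time,event Survival outcome.
#' @param minprop Minimum group proportion (default 0.1).
#' @return A list of class `cutpoint_result`: `cutoff`, `statistic`,
#'   `p_value`, `n_high`, `n_low`, and the full `scan` tibble.
#' @export
optimal_cutpoint <- function(score, time, event, minprop = 0.1) {
  vals <- sort(unique(score))
  if (length(vals) < 2) stop("constant scores: no admissible cutoff", call. = FALSE)
  n <- length(score)
  mids <- (vals[-1] + vals[-length(vals)]) / 2
  n_low <- vapply(mids, function(c) sum(score <= c), 1L)
  ok <- n_low >= minprop * n & (n - n_low) >= minprop * n
  mids <- mids[ok]
  if (length(mids) == 0) stop("no admissible cutoff under minprop", call. = FALSE)

  scan <- purrr::map_dfr(mids, function(c) {
    grp <- score > c
    lr <- logrank_test(time, event, grp)
    tibble::tibble(cutoff = c, statistic = lr$statistic, p_value = lr$p_value,
                   n_high = sum(grp), n_low = sum(!grp))
  })
  best <- scan |>
    dplyr::arrange(dplyr::desc(.data$statistic),
                   abs(.data$n_high - .data$n_low),
                   .data$cutoff) |>
    dplyr::slice(1)
  structure(
    list(cutoff = best$cutoff, statistic = best$statistic,
         p_value = best$p_value, n_high = best$n_high, n_low = best$n_low,
         scan = scan),
    class = "cutpoint_result"
  )
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("optimal cutpoint %.4g: log-rank chi-sq = %.3f, p = %.3g (%d high / %d low)\n",
              x$cutoff, x$statistic, x$p_value, x$n_high, x$n_low))
  invisible(x)
}

#' @export
tidy.cutpoint_result <- function(x, ...) x$scan

#' @export
glance.cutpoint_result <- function(x, ...) {
  tibble::tibble(cutoff = x$cutoff, statistic = x$statistic,
                 p_value = x$p_value, n_high = x$n_high, n_low = x$n_low)
}

#' Multivariate proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling (suited to the
#' heavily tied month-resolution times the cohort generator produces).
#' Reports the log-hazard coefficient, hazard ratio, Wald 95% CI and p per
#' covariate.  Zero-variance covariates are an error; a diverging
#' coefficient (|beta| > 15) is flagged as probable complete separation.
#'
#' @param data A data frame with `time`, `event`, and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @return A tibble of class `cox_result`: `term`, `estimate`,
#'   `hazard_ratio`, `conf_low`, `conf_high`, `p_value`, `tier`.
#' @export
cox_fit <- function(data, covariates) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("time", "event") %in% names(data)),
            all(covariates %in% names(data)))
  if (sum(data$event) == 0) stop("no events", call. = FALSE)
  for (cv in covariates) {
    if (stats::var(data[[cv]], na.rm = TRUE) == 0) {
      stop(sprintf("covariate `%s` has zero variance", cv), call. = FALSE)
    }
  }
  fml <- stats::reformulate(covariates,
                            response = "survival::Surv(time, event)")
  fit <- survival::coxph(fml, data = data, ties = "efron",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50))
  if (any(abs(stats::coef(fit)) > 15)) {
    warning("diverging coefficient (> 15): probable complete separation",
            call. = FALSE)
  }
  s <- summary(fit)
  res <- tibble::tibble(
    term = rownames(s$coefficients),
    estimate = as.numeric(s$coefficients[, "coef"]),
    hazard_ratio = as.numeric(s$coefficients[, "exp(coef)"]),
    conf_low = as.numeric(s$conf.int[, "lower .95"]),
    conf_high = as.numeric(s$conf.int[, "upper .95"]),
    p_value = as.numeric(s$coefficients[, "Pr(>|z|)"])
  ) |>
    dplyr::mutate(tier = p_tier(.data$p_value))
  attr(res, "fit") <- fit
  class(res) <- c("cox_result", class(res))
  res
}

#' @export
tidy.cox_result <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.cox_result <- function(x, ...) {
  fit <- attr(x, "fit")
  tibble::tibble(n = fit$n, n_event = fit$nevent,
                 logLik = as.numeric(stats::logLik(fit)))
}

#' Univariate + multivariate survival report for signature scores
#'
#' For each score variable: a univariate optimal-cutpoint log-rank row
#' (direction from which side of the cutoff has better survival, via the
#' hazard ratio of the high group) and a multivariate proportional-hazards
#' row adjusting for stromal score, immune score and tumor purity.  All
#' continuous covariates entering the multivariate fit are standardized,
#' so its hazard ratios are per standard deviation (the raw covariates
#' live on very different scales: range-normalized signature scores,
#' unnormalized enrichment sums, a cosine purity).
#'
#' @param data A data frame with `time`, `event`, the score columns, and
#'   (for the multivariate rows) `stromal_score`, `immune_score`,
#'   `tumor_purity`.
#' @param score_vars Character vector of score column names.
#' @param endpoint Endpoint label carried into the output (e.g. "OS",
#'   "PFS").
#' @param minprop Cutpoint minimum group proportion.
#' @return A tibble of class `survival_report`: one univariate and one
#'   multivariate row per variable with `cutoff`, `statistic`,
#'   `hazard_ratio`, `conf_low`, `conf_high`, `p_value`, `tier`, and
#'   `direction` (+1 = high score has better survival, -1 = worse).
#' @export
survival_report <- function(data, score_vars, endpoint = "OS",
                            minprop = 0.1) {
  data <- tibble::as_tibble(data)
  adj <- c("stromal_score", "immune_score", "tumor_purity")
  has_adj <- all(adj %in% names(data))

  rows <- purrr::map_dfr(score_vars, function(v) {
    cp <- optimal_cutpoint(data[[v]], data$time, data$event, minprop)
    grp_fit <- cox_fit(dplyr::mutate(data, .high = as.integer(data[[v]] > cp$cutoff)),
                       ".high")
    uni <- tibble::tibble(
      variable = v, endpoint = endpoint, analysis = "univariate",
      cutoff = cp$cutoff, statistic = cp$statistic,
      hazard_ratio = grp_fit$hazard_ratio[1],
      conf_low = grp_fit$conf_low[1], conf_high = grp_fit$conf_high[1],
      p_value = cp$p_value, tier = p_tier(cp$p_value),
      direction = ifelse(grp_fit$hazard_ratio[1] < 1, 1L, -1L)
    )
    if (has_adj) {
      std <- data
      for (cv in c(v, adj)) std[[cv]] <- as.numeric(scale(std[[cv]]))
      mv <- cox_fit(std, c(v, adj))
      mv1 <- mv[mv$term == v, ]
      multi <- tibble::tibble(
        variable = v, endpoint = endpoint, analysis = "multivariate",
        cutoff = NA_real_, statistic = mv1$estimate,
        hazard_ratio = mv1$hazard_ratio,
        conf_low = mv1$conf_low, conf_high = mv1$conf_high,
        p_value = mv1$p_value, tier = mv1$tier,
        direction = ifelse(mv1$hazard_ratio < 1, 1L, -1L)
      )
      dplyr::bind_rows(uni, multi)
    } else {
      uni
    }
  })
  class(rows) <- c("survival_report", class(rows))
  rows
}
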