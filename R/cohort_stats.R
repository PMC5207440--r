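#' Pearson chi-square test of independence
#'
#' Pearson statistic without continuity correction on an r x c count
#' table, with (r-1)(c-1) degrees of freedom.
#'
#' @param tab matrix of non-negative counts, at least 2 x 2, with no zero
#'   row or column margin.
#' @return List: `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(is.numeric(tab), all(tab >= 0))
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("contingency table must be at least 2 x 2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Cochran-Armitage test for trend
#'
#' Trend in binomial proportions across k ordered categories. Rows of the
#' table are (successes, failures); columns are the ordered categories.
#' The standardized statistic Z is positive when the success proportion
#' increases with the scores; the p-value is two-sided normal.
#'
#' @param tab 2 x k matrix of counts (row 1 = successes).
#' @param scores column scores (default equally spaced `1..k`).
#' @return List: `Z`, `p_value`.
#' @export
cochran_armitage_trend <- function(tab, scores = NULL) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2 || ncol(tab) < 2)
    stop("trend test needs a 2 x k table with k >= 2")
  k <- ncol(tab)
  if (is.null(scores)) scores <- seq_len(k)
  stopifnot(length(scores) == k)
  x <- tab[1, ]          # successes per category
  n <- colSums(tab)      # totals per category
  N <- sum(n)
  if (N == 0 || any(n == 0)) stop("degenerate margins in trend test")
  pbar <- sum(x) / N
  if (pbar == 0 || pbar == 1) stop("all successes or all failures")
  num <- sum(scores * (x - n * pbar))
  den <- pbar * (1 - pbar) * (sum(n * scores^2) - sum(n * scores)^2 / N)
  if (den <= 0) stop("degenerate score configuration")
  z <- num / sqrt(den)
  list(Z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Kruskal-Wallis rank-sum test
#'
#' Rank-based comparison of g >= 2 groups with tie correction, chi-square
#' reference with g - 1 df. When every value is identical the statistic is
#' 0 by convention and the p-value 1.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values`.
#' @return List: `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("empty group")
  if (length(unique(values)) == 1)
    return(list(H = 0, df = nlevels(groups) - 1, p_value = 1))
  res <- stats::kruskal.test(values, groups)
  list(H = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate with Greenwood standard errors and 95%
#' confidence intervals on the complementary log-log scale (the common
#' clinical-paper default). Ties are handled with the standard convention
#' that events at a time precede censorings at the same time.
#'
#' @param times non-negative event/censoring times.
#' @param events 0/1 (or logical) event indicators.
#' @return Data frame of class `km_curve`, one row per event time:
#'   `time`, `n_risk`, `n_event`, `survival`, `se` (Greenwood SE of the
#'   survival probability), `ci_low`, `ci_high`. The fitted
#'   `survival::survfit` object is kept in attribute `fit`.
#' @export
kaplan_meier <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1)
  if (any(times < 0)) stop("negative survival time")
  events <- as.integer(as.logical(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log")
  s <- summary(fit, censored = FALSE)
  out <- data.frame(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
                    survival = s$surv, se = s$std.err,
                    ci_low = s$lower, ci_high = s$upper)
  out <- out[out$n_event > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("km_curve", "data.frame")
  attr(out, "fit") <- fit
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param curve a [kaplan_meier()] result.
#' @param at times at which to read off the estimate.
#' @return Data frame: `time`, `survival`, `ci_low`, `ci_high` (NA beyond
#'   follow-up).
#' @export
km_at <- function(curve, at) {
  fit <- attr(curve, "fit")
  s <- summary(fit, times = at, extend = TRUE)
  data.frame(time = s$time, survival = s$surv,
             ci_low = s$lower, ci_high = s$upper)
}

#' k-group log-rank test
#'
#' Standard log-rank chi-square comparing event-time distributions across
#' k >= 2 groups, on k - 1 degrees of freedom.
#'
#' @param times non-negative times.
#' @param events 0/1 event indicators (at least one event overall).
#' @param groups group labels.
#' @return List: `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  stopifnot(length(times) == length(events), length(times) == length(groups))
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  events <- as.integer(as.logical(events))
  if (sum(events) == 0) stop("no events")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}
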