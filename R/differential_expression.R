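#' Empirical-Bayes moderated two-group statistics
#'
#' Per-gene comparison of two sample groups with variance moderation: the
#' pooled residual variance s^2 (d = n_a + n_b - 2 residual df) is shrunk
#' toward a prior variance s0^2 with d0 prior df, giving the posterior
#' variance s~^2 = (d0 s0^2 + d s^2) / (d0 + d). The hyperparameters
#' (d0, s0^2) are fitted by method of moments on log s^2, matching the
#' mean and variance of log s^2 to its scaled-F sampling theory via
#' digamma/trigamma identities. The moderated t is
#' log2FC / (s~ sqrt(1/n_a + 1/n_b)) on d0 + d degrees of freedom, and the
#' moderated F is its square.
#'
#' @param x an `expr_matrix`, or a plain genes-by-samples numeric matrix.
#' @param group_a,group_b disjoint character vectors of sample ids (or
#'   integer column indices), each of size >= 2. The log2 fold change is
#'   `mean(group_a) - mean(group_b)`.
#' @param prior_df optional override of the fitted d0: `0` disables
#'   shrinkage (ordinary pooled t), `Inf` forces every gene onto the
#'   common prior variance.
#' @return Data frame with one row per gene: `gene`, `log2_fold_change`,
#'   `moderated_t`, `moderated_F`, `p_value`, `by_adjusted_p`. The fitted
#'   hyperparameters are in attributes `prior_df` and `prior_var`.
#' @export
moderated_two_group_stats <- function(x, group_a, group_b, prior_df = NULL) {
  vals <- if (inherits(x, "expr_matrix")) x$values else x
  stopifnot(is.matrix(vals), is.numeric(vals))
  idx <- function(g) {
    if (is.numeric(g)) return(as.integer(g))
    i <- match(g, colnames(vals))
    if (anyNA(i)) stop("unknown sample id(s): ",
                       paste(g[is.na(i)], collapse = ", "))
    i
  }
  a <- idx(group_a); b <- idx(group_b)
  if (length(intersect(a, b))) stop("groups must be disjoint")
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 samples")

  xa <- vals[, a, drop = FALSE]; xb <- vals[, b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  lfc <- ma - mb
  d <- na + nb - 2
  s2 <- (rowSums((xa - ma)^2) + rowSums((xb - mb)^2)) / d
  if (all(s2 == 0)) stop("all genes have zero residual variance")

  if (is.null(prior_df)) {
    fit <- fit_f_dist(s2[s2 > 0], d)
    d0 <- fit$df_prior; s02 <- fit$var_prior
  } else {
    d0 <- prior_df
    s02 <- if (is.finite(d0) && d0 == 0) NA_real_ else mean(s2[s2 > 0])
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else if (d0 == 0) s2
             else (d0 * s02 + d * s2) / (d0 + d)
  tstat <- lfc / sqrt(s2_post * (1 / na + 1 / nb))
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(gene = rownames(vals), log2_fold_change = lfc,
                    moderated_t = tstat, moderated_F = tstat^2,
                    p_value = p, by_adjusted_p = by_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  attr(out, "residual_df") <- d
  out
}

# Method-of-moments fit of the scaled-F model for gene-wise sample
# variances: s^2 ~ s0^2 F(d, d0). Matches mean and variance of
# e = log s^2 - digamma(d/2) + log(d/2) to the theory:
#   E[e]  = log s0^2 + digamma(d0/2) - log(d0/2)
#   Var[e] = trigamma(d/2) + trigamma(d0/2)
# Under-dispersed variances (moment variance <= 0) fall back to d0 = Inf,
# i.e. full shrinkage to a common variance, with a warning.
fit_f_dist <- function(s2, df) {
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  if (n < 2) {
    warning("too few positive variances to fit prior df; using d0 = Inf")
    return(list(df_prior = Inf, var_prior = exp(emean)))
  }
  evar <- sum((e - emean)^2) / (n - 1) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    warning("variance moment estimate non-positive; using d0 = Inf ",
            "(full shrinkage)")
    return(list(df_prior = Inf, var_prior = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(df_prior = d0, var_prior = s02)
}

# Newton solve of trigamma(y) = x for y > 0.
trigamma_inverse <- function(x) {
  stopifnot(length(x) == 1, is.finite(x), x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Benjamini-Yekutieli adjustment
#'
#' Step-up false-discovery-rate control valid under arbitrary dependence:
#' the Benjamini-Hochberg adjustment inflated by the harmonic factor
#' c(m) = sum_{k=1..m} 1/k. Wraps `stats::p.adjust(method = "BY")`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order, capped at 1.
#' @export
by_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BY")
}

#' Derive a claudin-low gene signature
#'
#' Runs the moderated two-group comparison of claudin-low samples against
#' each of the other subtypes present (six comparisons for a full
#' compendium). A gene enters the signature iff in every comparison its
#' Benjamini-Yekutieli adjusted p-value is below `alpha`, its absolute
#' log2 fold change is at least `log2(fold_change_min)`, and the sign of
#' the fold change is identical across all comparisons; the signature
#' direction is that common sign.
#'
#' @param x an `expr_matrix` with subtype labels including
#'   `"claudin-low"`; every labeled subtype needs >= 2 samples.
#' @param fold_change_min minimum fold change on the natural scale
#'   (default 2, i.e. |log2FC| >= 1).
#' @param alpha significance level on the adjusted scale (default 0.05).
#' @param cl_label label of the claudin-low group.
#' @return Data frame with columns `symbol` and `direction` (`"up"` =
#'   higher in claudin-low). The per-comparison statistics are in
#'   attribute `comparisons` (a named list of
#'   [moderated_two_group_stats()] results).
#' @export
derive_cl_signature <- function(x, fold_change_min = 2, alpha = 0.05,
                                cl_label = "claudin-low") {
  stopifnot(inherits(x, "expr_matrix"), fold_change_min >= 1,
            alpha > 0, alpha < 1)
  if (is.null(x$subtype)) stop("subtype labels required")
  labeled <- !is.na(x$subtype)
  subtypes <- unique(x$subtype[labeled])
  if (!cl_label %in% subtypes) stop("no samples labeled '", cl_label, "'")
  others <- setdiff(subtypes, cl_label)
  if (length(others) == 0) stop("no non-claudin-low subtypes present")
  sizes <- table(x$subtype[labeled])
  if (any(sizes < 2))
    stop("subtype(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  ids <- colnames(x$values)
  cl_ids <- ids[labeled][x$subtype[labeled] == cl_label]
  lfc_min <- log2(fold_change_min)

  comparisons <- lapply(others, function(s) {
    other_ids <- ids[labeled][x$subtype[labeled] == s]
    moderated_two_group_stats(x, cl_ids, other_ids)
  })
  names(comparisons) <- others

  genes <- comparisons[[1]]$gene
  sig_mat <- sapply(comparisons, function(cmp)
    cmp$by_adjusted_p < alpha & abs(cmp$log2_fold_change) >= lfc_min)
  sign_mat <- sapply(comparisons, function(cmp) sign(cmp$log2_fold_change))
  if (length(others) == 1) {
    sig_mat <- matrix(sig_mat, ncol = 1)
    sign_mat <- matrix(sign_mat, ncol = 1)
  }
  all_sig <- rowSums(sig_mat) == length(others)
  consistent <- apply(sign_mat, 1, function(s) length(unique(s)) == 1)
  keep <- all_sig & consistent
  out <- data.frame(symbol = genes[keep],
                    direction = ifelse(sign_mat[keep, 1] > 0, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "comparisons") <- comparisons
  out
}
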