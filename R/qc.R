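#' Spearman rank correlation
#'
#' Pearson correlation of average-tied ranks, the similarity measure used
#' both for sample quality control and for centroid-based subtype
#' assignment.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` (with a warning) when either
#'   vector is constant.
#' @export
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("Spearman correlation undefined for a constant vector")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Housekeeping-gene sample quality filter
#'
#' After merging datasets, sample quality is screened by pairwise Spearman
#' correlation restricted to a panel of housekeeping genes: a sample is
#' kept iff its housekeeping profile correlates above `threshold` with at
#' least `min_fraction` of the other samples (rounded up; self-correlation
#' excluded). The filter is a single pass - removals do not trigger
#' re-evaluation. Pairs where either sample's housekeeping profile is
#' constant have undefined correlation and do not count toward the
#' requirement.
#'
#' @param x an `expr_matrix`.
#' @param housekeeping_genes gene symbols to correlate over (all must be
#'   present in `x`); defaults to the `housekeeping_genes` attribute.
#' @param threshold correlation cutoff (default 0.95).
#' @param min_fraction required fraction of the other samples (default 0.5).
#' @return List of class `hk_filter`: `kept` and `dropped` sample ids
#'   (a partition of the input), `pass_counts` (per-sample number of
#'   above-threshold partners), `required` (the partner count needed) and
#'   `rho` (the pairwise correlation matrix over housekeeping genes).
#' @export
housekeeping_filter <- function(x,
                                housekeeping_genes = attr(x, "housekeeping_genes"),
                                threshold = 0.95, min_fraction = 0.5) {
  stopifnot(inherits(x, "expr_matrix"),
            threshold > -1, threshold < 1,
            min_fraction > 0, min_fraction <= 1)
  if (is.null(housekeeping_genes) || length(housekeeping_genes) == 0)
    stop("housekeeping gene list is empty")
  absent <- setdiff(housekeeping_genes, rownames(x$values))
  if (length(absent))
    stop("housekeeping gene(s) missing from matrix: ",
         paste(absent, collapse = ", "))
  hk <- x$values[housekeeping_genes, , drop = FALSE]
  rho <- suppressWarnings(stats::cor(hk, method = "spearman"))
  diag(rho) <- NA
  n <- ncol(hk)
  required <- ceiling(min_fraction * (n - 1))
  pass_counts <- rowSums(rho > threshold, na.rm = TRUE)
  kept <- colnames(hk)[pass_counts >= required]
  structure(list(kept = kept,
                 dropped = setdiff(colnames(hk), kept),
                 pass_counts = pass_counts,
                 required = required,
                 threshold = threshold,
                 rho = rho),
            class = "hk_filter")
}

#' @export
print.hk_filter <- function(x, ...) {
  cat(sprintf(paste0("housekeeping filter: kept %d, dropped %d ",
                     "(rho > %.2f with >= %d other samples)\n"),
              length(x$kept), length(x$dropped), x$threshold, x$required))
  invisible(x)
}

#' Per-batch mean centering
#'
#' A deliberately simple batch-adjustment utility: for each gene, the
#' per-batch mean is subtracted and the gene's global mean restored, so
#' batches share a common location while the overall expression level is
#' preserved. Idempotent. Batches of size 1 are left uncentered with a
#' warning.
#'
#' @param x an `expr_matrix` with batch labels.
#' @return The centered `expr_matrix` (attributes preserved).
#' @export
center_batches <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(x$batch)) stop("batch labels required for centering")
  vals <- x$values
  global <- rowMeans(vals)
  for (b in unique(x$batch)) {
    cols <- which(x$batch == b)
    if (length(cols) < 2) {
      warning("batch '", b, "' has a single sample; left uncentered")
      next
    }
    vals[, cols] <- vals[, cols] -
      rowMeans(vals[, cols, drop = FALSE]) + global
  }
  out <- expression_matrix(vals, batch = x$batch, subtype = x$subtype)
  attr(out, "housekeeping_genes") <- attr(x, "housekeeping_genes")
  attr(out, "classifier_genes") <- attr(x, "classifier_genes")
  out
}
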