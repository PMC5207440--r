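#' Train standardized subtype centroids
#'
#' For every subtype present in the labels, each classifier gene's centroid
#' value is the within-subtype mean expression divided by the
#' within-subtype standard deviation (sample SD, n-1 denominator). Genes
#' with zero SD in any subtype are dropped from the classifier gene list
#' everywhere (a message lists them), so all centroids share one gene
#' list - a requirement for rank-correlation comparison.
#'
#' @param x an `expr_matrix` with subtype labels (NA labels are ignored).
#' @param classifier_genes gene symbols to build the centroids over; all
#'   must be present in `x`.
#' @return List of class `centroid_set`: `subtypes`, `genes` (the
#'   surviving classifier genes) and `values` (genes x subtypes matrix).
#' @export
train_centroids <- function(x, classifier_genes = attr(x, "classifier_genes")) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(x$subtype)) stop("subtype labels required to train centroids")
  if (is.null(classifier_genes)) stop("classifier_genes must be supplied")
  if (anyDuplicated(classifier_genes)) stop("duplicate classifier genes")
  absent <- setdiff(classifier_genes, rownames(x$values))
  if (length(absent))
    stop("classifier gene(s) missing from matrix: ",
         paste(absent, collapse = ", "))
  labeled <- !is.na(x$subtype)
  subtypes <- sort(unique(x$subtype[labeled]))
  sizes <- table(x$subtype[labeled])
  if (any(sizes < 2))
    stop("subtype(s) with fewer than 2 labeled samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  vals <- x$values[classifier_genes, labeled, drop = FALSE]
  lab <- x$subtype[labeled]
  mu <- sapply(subtypes, function(s) rowMeans(vals[, lab == s, drop = FALSE]))
  sdv <- sapply(subtypes, function(s)
    apply(vals[, lab == s, drop = FALSE], 1, stats::sd))
  zero <- rowSums(sdv == 0) > 0
  if (any(zero)) {
    message("dropping ", sum(zero), " classifier gene(s) with zero ",
            "within-subtype SD: ",
            paste(utils::head(classifier_genes[zero], 10), collapse = ", "))
    mu <- mu[!zero, , drop = FALSE]
    sdv <- sdv[!zero, , drop = FALSE]
    classifier_genes <- classifier_genes[!zero]
  }
  if (length(classifier_genes) == 0)
    stop("no classifier genes survive the zero-SD filter")
  centroids <- mu / sdv
  dimnames(centroids) <- list(classifier_genes, subtypes)
  structure(list(subtypes = subtypes, genes = classifier_genes,
                 values = centroids),
            class = "centroid_set")
}

#' @export
print.centroid_set <- function(x, ...) {
  cat(sprintf("centroid_set: %d subtypes x %d classifier genes\n",
              length(x$subtypes), length(x$genes)))
  invisible(x)
}

#' Assign one sample to a molecular subtype
#'
#' Spearman correlation of the sample's expression vector against each
#' standardized centroid; the subtype with the highest correlation is
#' assigned provided that correlation reaches `cutoff` (default 0.3,
#' strictly-below values are unclassified). An exact tie for the maximum
#' leaves the sample unclassified with `tie = TRUE`. Because the measure
#' is rank-based, assignment is invariant to any strictly increasing
#' transform of the sample's values.
#'
#' @param sample named numeric vector covering all centroid genes (extra
#'   genes are ignored).
#' @param centroids a [train_centroids()] result.
#' @param cutoff minimum correlation for assignment (default 0.3).
#' @param sample_id optional identifier carried into the result.
#' @return List of class `subtype_assignment`: `sample_id`,
#'   `best_subtype` (`NA` if unclassified), `correlations` (named vector),
#'   `cutoff_used`, `tie`.
#' @export
assign_subtype <- function(sample, centroids, cutoff = 0.3,
                           sample_id = NA_character_) {
  stopifnot(inherits(centroids, "centroid_set"))
  absent <- setdiff(centroids$genes, names(sample))
  if (length(absent))
    stop("sample is missing classifier gene(s): ",
         paste(utils::head(absent, 10), collapse = ", "))
  v <- sample[centroids$genes]
  if (anyNA(v)) stop("sample has missing values on classifier genes")
  rho <- suppressWarnings(
    stats::cor(v, centroids$values, method = "spearman"))[1, ]
  best <- max(rho, na.rm = TRUE)
  tie <- sum(rho == best, na.rm = TRUE) > 1
  assigned <- if (!tie && is.finite(best) && best >= cutoff)
    names(rho)[which.max(rho)] else NA_character_
  structure(list(sample_id = sample_id, best_subtype = assigned,
                 correlations = rho, cutoff_used = cutoff, tie = tie),
            class = "subtype_assignment")
}

#' Classify every sample of a compendium
#'
#' Vectorised subtype assignment: rank-correlates every sample against
#' every centroid and applies the cutoff rule of [assign_subtype()].
#'
#' @param x an `expr_matrix` (typically QC-filtered).
#' @param centroids a [train_centroids()] result.
#' @param cutoff minimum correlation for assignment (default 0.3).
#' @return List of class `compendium_classification`: `assignments` (data
#'   frame with `sample_id`, `subtype` - `"unclassified"` when no centroid
#'   reaches the cutoff or the maximum is tied - `best_rho` and `tie`),
#'   `correlations` (samples x subtypes matrix) and `frequency` (counts
#'   and percentages to 0.1 over subtypes plus unclassified).
#' @export
classify_compendium <- function(x, centroids, cutoff = 0.3) {
  stopifnot(inherits(x, "expr_matrix"), inherits(centroids, "centroid_set"))
  n <- ncol(x$values)
  if (n == 0) {
    assignments <- data.frame(sample_id = character(), subtype = character(),
                              best_rho = numeric(), tie = logical(),
                              stringsAsFactors = FALSE)
    return(structure(list(assignments = assignments,
                          correlations = matrix(numeric(), 0,
                                                length(centroids$subtypes)),
                          frequency = NULL),
                     class = "compendium_classification"))
  }
  absent <- setdiff(centroids$genes, rownames(x$values))
  if (length(absent))
    stop("matrix is missing classifier gene(s): ",
         paste(utils::head(absent, 10), collapse = ", "))
  v <- x$values[centroids$genes, , drop = FALSE]
  # cor() correlates columns against columns: samples x subtypes
  rho <- suppressWarnings(
    stats::cor(v, centroids$values, method = "spearman"))
  best <- apply(rho, 1, max, na.rm = TRUE)
  tie <- vapply(seq_len(n), function(i)
    sum(rho[i, ] == best[i], na.rm = TRUE) > 1, logical(1))
  subtype <- ifelse(!tie & is.finite(best) & best >= cutoff,
                    colnames(rho)[apply(rho, 1, which.max)],
                    "unclassified")
  assignments <- data.frame(sample_id = colnames(x$values),
                            subtype = subtype, best_rho = best, tie = tie,
                            stringsAsFactors = FALSE)
  lev <- c(centroids$subtypes, "unclassified")
  cnt <- table(factor(subtype, levels = lev))
  freq <- data.frame(subtype = names(cnt), n = as.integer(cnt),
                     percent = percent_of(as.integer(cnt), n),
                     stringsAsFactors = FALSE)
  structure(list(assignments = assignments, correlations = rho,
                 frequency = freq),
            class = "compendium_classification")
}
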