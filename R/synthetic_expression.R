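#' Configuration for the synthetic expression compendium
#'
#' Describes a log2-scale microarray compendium with 7 molecular subtypes,
#' additive batch effects, a block of classifier genes carrying
#' subtype-specific mean shifts, and a block of housekeeping genes whose
#' means are identical across subtypes and batches (the basis of the
#' sample-quality filter).
#'
#' @param n_per_subtype integer: samples per subtype. Either a single count
#'   or a named vector over [expression_subtypes()].
#' @param n_genes total number of genes.
#' @param n_classifier_genes genes with subtype-specific means; assigned to
#'   subtypes round-robin with alternating sign.
#' @param n_housekeeping genes with one shared mean, untouched by batch
#'   effects (default 68, the size of the housekeeping probe set used for
#'   compendium quality control).
#' @param effect_size mean shift, in log2 units, that a classifier gene
#'   carries in its own subtype.
#' @param noise_sd residual (within-sample) Gaussian SD, log2 units, for
#'   non-housekeeping genes.
#' @param housekeeping_noise_sd residual SD of the housekeeping genes;
#'   defaults to `noise_sd / 4`. Housekeeping probe sets are selected for
#'   stability, so their residual variance sits well below that of
#'   subtype-informative genes; with the default baseline spread this puts
#'   the expected between-sample rank correlation over the housekeeping
#'   panel near 0.98 for clean samples - above the 0.95 QC cutoff, as in
#'   real compendia.
#' @param n_batches number of batches, assigned cyclically across samples.
#' @param batch_sd SD of the per-gene, per-batch Gaussian offsets applied to
#'   all non-housekeeping genes.
#' @param seed integer seed; all downstream draws derive from it.
#' @return A list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_per_subtype = 30,
                                  n_genes = 1000,
                                  n_classifier_genes = 210,
                                  n_housekeeping = 68,
                                  effect_size = 2,
                                  noise_sd = 1,
                                  housekeeping_noise_sd = noise_sd / 4,
                                  n_batches = 3,
                                  batch_sd = 0.5,
                                  seed = 1L) {
  subtypes <- expression_subtypes()
  if (length(n_per_subtype) == 1)
    n_per_subtype <- stats::setNames(rep(n_per_subtype, 7), subtypes)
  if (!setequal(names(n_per_subtype), subtypes))
    stop("n_per_subtype must be a single count or named over the 7 subtypes")
  n_per_subtype <- n_per_subtype[subtypes]
  stopifnot(all(n_per_subtype >= 1), n_genes >= 1,
            n_classifier_genes >= 1, n_housekeeping >= 1,
            effect_size >= 0, noise_sd > 0, housekeeping_noise_sd > 0,
            n_batches >= 1, batch_sd >= 0)
  if (n_classifier_genes + n_housekeeping > n_genes)
    stop("n_classifier_genes + n_housekeeping exceeds n_genes")
  structure(list(n_per_subtype = n_per_subtype, n_genes = n_genes,
                 n_classifier_genes = n_classifier_genes,
                 n_housekeeping = n_housekeeping, effect_size = effect_size,
                 noise_sd = noise_sd,
                 housekeeping_noise_sd = housekeeping_noise_sd,
                 n_batches = n_batches,
                 batch_sd = batch_sd, seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Simulate an expression compendium with subtype and batch structure
#'
#' Generates a genes-by-samples matrix on the log2 scale. Every gene gets a
#' baseline level drawn once from N(8, 2^2). Classifier genes additionally
#' carry a +/- `effect_size` shift in the one subtype they are assigned to;
#' housekeeping genes (named `HK0001`, ...) keep one mean everywhere and
#' receive no batch offset; all other genes receive additive per-batch
#' Gaussian offsets. Residual noise is N(0, `noise_sd`^2) for
#' non-housekeeping genes and N(0, `housekeeping_noise_sd`^2) for the
#' stable housekeeping block.
#'
#' @param config an [expression_sim_config()].
#' @return An [expression_matrix()] with `batch` and `subtype` labels; the
#'   housekeeping gene symbols are in `attr(, "housekeeping_genes")` and the
#'   classifier gene symbols in `attr(, "classifier_genes")`.
#' @export
simulate_expression_compendium <- function(config = expression_sim_config()) {
  stopifnot(inherits(config, "expression_sim_config"))
  cfg <- config
  subtypes <- names(cfg$n_per_subtype)
  n_samples <- sum(cfg$n_per_subtype)
  subtype <- rep(subtypes, cfg$n_per_subtype)
  batch <- paste0("batch", rep_len(seq_len(cfg$n_batches), n_samples))
  sample_ids <- sprintf("S%04d", seq_len(n_samples))

  n_hk <- cfg$n_housekeeping
  n_clf <- cfg$n_classifier_genes
  genes <- c(sprintf("HK%04d", seq_len(n_hk)),
             sprintf("CLF%04d", seq_len(n_clf)),
             sprintf("G%04d", seq_len(cfg$n_genes - n_hk - n_clf)))
  hk_genes <- genes[seq_len(n_hk)]
  clf_genes <- genes[n_hk + seq_len(n_clf)]

  set.seed(split_seed(cfg$seed, "expression-baseline"))
  baseline <- stats::rnorm(cfg$n_genes, mean = 8, sd = 2)
  mu <- matrix(baseline, nrow = cfg$n_genes, ncol = n_samples)

  # classifier genes: round-robin subtype assignment, alternating sign
  clf_subtype <- rep_len(subtypes, n_clf)
  clf_sign <- rep_len(c(1, -1), n_clf)
  for (j in seq_len(n_clf)) {
    cols <- subtype == clf_subtype[j]
    mu[n_hk + j, cols] <- mu[n_hk + j, cols] + clf_sign[j] * cfg$effect_size
  }

  # batch offsets on every non-housekeeping gene
  set.seed(split_seed(cfg$seed, "expression-batch"))
  if (cfg$batch_sd > 0) {
    for (b in unique(batch)) {
      off <- stats::rnorm(cfg$n_genes - n_hk, sd = cfg$batch_sd)
      cols <- batch == b
      mu[-seq_len(n_hk), cols] <- mu[-seq_len(n_hk), cols] + off
    }
  }

  set.seed(split_seed(cfg$seed, "expression-noise"))
  sd_per_gene <- c(rep(cfg$housekeeping_noise_sd, n_hk),
                   rep(cfg$noise_sd, cfg$n_genes - n_hk))
  vals <- mu + matrix(stats::rnorm(length(mu), sd = sd_per_gene),
                      nrow = nrow(mu))
  dimnames(vals) <- list(genes, sample_ids)
  out <- expression_matrix(vals, batch = batch, subtype = subtype)
  attr(out, "housekeeping_genes") <- hk_genes
  attr(out, "classifier_genes") <- clf_genes
  out
}

#' Corrupt the housekeeping block of a fraction of samples
#'
#' Test harness for the housekeeping quality filter: in each selected
#' sample the housekeeping values are independently permuted across genes,
#' destroying that sample's rank agreement with clean samples while leaving
#' its marginal distribution intact. All other genes and samples are
#' untouched.
#'
#' @param x an `expr_matrix` produced by [simulate_expression_compendium()]
#'   (or any `expr_matrix`, with `housekeeping_genes` supplied).
#' @param fraction fraction of samples to corrupt, in `[0, 1]`. The number
#'   corrupted is `round(fraction * n_samples)`.
#' @param seed integer seed.
#' @param housekeeping_genes gene symbols to permute; defaults to the
#'   `housekeeping_genes` attribute of `x`.
#' @return A list with elements `matrix` (the corrupted `expr_matrix`) and
#'   `corrupted` (the corrupted sample ids).
#' @export
corrupt_samples <- function(x, fraction, seed = 1L,
                            housekeeping_genes = attr(x, "housekeeping_genes")) {
  stopifnot(inherits(x, "expr_matrix"), fraction >= 0, fraction <= 1)
  if (is.null(housekeeping_genes))
    stop("housekeeping_genes not given and not stored on 'x'")
  n <- ncol(x$values)
  n_bad <- round(fraction * n)
  set.seed(split_seed(seed, "corrupt-samples"))
  bad <- sort(sample(n, n_bad))
  vals <- x$values
  hk <- match(housekeeping_genes, rownames(vals))
  if (anyNA(hk)) stop("housekeeping genes missing from matrix")
  for (j in bad) vals[hk, j] <- vals[hk[sample(length(hk))], j]
  out <- expression_matrix(vals, batch = x$batch, subtype = x$subtype)
  attr(out, "housekeeping_genes") <- housekeeping_genes
  attr(out, "classifier_genes") <- attr(x, "classifier_genes")
  list(matrix = out, corrupted = colnames(vals)[bad])
}
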