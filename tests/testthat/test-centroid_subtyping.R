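make_labeled <- function(seed = 1, n_per = 3, n_genes = 12) {
  set.seed(seed)
  subs <- expression_subtypes()
  lab <- rep(subs, each = n_per)
  vals <- matrix(stats::rnorm(n_genes * length(lab)), n_genes,
                 dimnames = list(sprintf("g%02d", 1:n_genes),
                                 sprintf("s%02d", seq_along(lab))))
  expression_matrix(vals, subtype = lab)
}

test_that("centroid values are within-subtype mean over sample SD", {
  vals <- matrix(0, 2, 14,
                 dimnames = list(c("gA", "gB"), sprintf("s%02d", 1:14)))
  lab <- rep(expression_subtypes(), each = 2)
  set.seed(2)
  vals[] <- stats::rnorm(length(vals))
  vals["gA", lab == "claudin-low"] <- c(1, 3)   # mean 2, sd sqrt(2)
  x <- expression_matrix(vals, subtype = lab)
  cen <- train_centroids(x, classifier_genes = c("gA", "gB"))
  expect_equal(cen$values["gA", "claudin-low"], 2 / stats::sd(c(1, 3)))

  y <- expression_matrix(rbind(gA = c(1, 2, 3), gB = stats::rnorm(3)) |>
                           `colnames<-`(c("a", "b", "c")),
                         subtype = rep("luminal A", 3))
  cenA <- train_centroids(y, classifier_genes = c("gA", "gB"))
  expect_equal(cenA$values["gA", "luminal A"], 2)  # mean 2 / sd 1
})

test_that("identical data across subtypes gives identical centroids", {
  x <- make_labeled()
  block <- x$values[, 1:3]
  vals <- do.call(cbind, rep(list(block), 7))
  colnames(vals) <- sprintf("s%02d", 1:21)
  y <- expression_matrix(vals, subtype = rep(expression_subtypes(), each = 3))
  cen <- train_centroids(y, classifier_genes = rownames(vals))
  expect_true(all(apply(cen$values, 1, function(r) max(r) - min(r) == 0)))
})

test_that("zero-SD genes are dropped globally; degenerate inputs error", {
  x <- make_labeled()
  x$values["g01", x$subtype == "luminal B"] <- 5  # constant in one subtype
  expect_message(cen <- train_centroids(x, classifier_genes = rownames(x$values)),
                 "zero")
  expect_false("g01" %in% cen$genes)
  expect_false("g01" %in% rownames(cen$values))

  small <- expression_matrix(x$values[, 1:4, drop = FALSE],
                             subtype = c("luminal A", "luminal A",
                                         "basal-like", "claudin-low"))
  expect_error(train_centroids(small, classifier_genes = rownames(x$values)),
               "fewer than 2")
})

test_that("a sample equal to a centroid is assigned with rho 1", {
  x <- make_labeled(seed = 5, n_genes = 30)
  cen <- train_centroids(x, classifier_genes = rownames(x$values))
  samp <- stats::setNames(cen$values[, "basal-like"], cen$genes)
  res <- assign_subtype(samp, cen)
  expect_equal(res$best_subtype, "basal-like")
  expect_equal(unname(res$correlations["basal-like"]), 1)
})

test_that("maximum correlation strictly below the cutoff is unclassified", {
  x <- make_labeled(seed = 8, n_genes = 40)
  cen <- train_centroids(x, classifier_genes = rownames(x$values))
  set.seed(42)
  for (i in 1:20) {
    samp <- stats::setNames(stats::rnorm(length(cen$genes)), cen$genes)
    res <- assign_subtype(samp, cen)
    best <- max(res$correlations)
    if (best < 0.3) {
      expect_true(is.na(res$best_subtype))
    } else {
      expect_equal(unname(res$correlations[res$best_subtype]), best)
    }
    # a cutoff just above the max always unclassifies
    expect_true(is.na(assign_subtype(samp, cen,
                                     cutoff = best + 1e-9)$best_subtype))
  }
})

test_that("exact ties for the maximum leave the sample unclassified", {
  vals <- matrix(stats::rnorm(50 * 8), 50,
                 dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:8)))
  lab <- rep(c("luminal A", "claudin-low"), each = 4)
  # two identical subtypes: duplicate the first block
  vals[, 5:8] <- vals[, 1:4]
  x <- expression_matrix(vals, subtype = lab)
  cen <- train_centroids(x, classifier_genes = rownames(vals))
  samp <- stats::setNames(x$values[, 1], rownames(vals))
  res <- assign_subtype(samp, cen)
  expect_true(res$tie)
  expect_true(is.na(res$best_subtype))
})

test_that("assignment is invariant to strictly monotone transforms", {
  x <- make_labeled(seed = 3, n_genes = 40)
  cen <- train_centroids(x, classifier_genes = rownames(x$values))
  set.seed(9)
  for (i in 1:10) {
    samp <- stats::setNames(stats::rnorm(length(cen$genes), 8, 2), cen$genes)
    a <- assign_subtype(samp, cen)
    b <- assign_subtype(2^samp + 3, cen)       # strictly increasing
    expect_equal(a$correlations, b$correlations)
    expect_identical(a$best_subtype, b$best_subtype)
  }
})

test_that("spearman assignment agrees with explicit rank + Pearson to 1e-12", {
  x <- make_labeled(seed = 6, n_genes = 60)
  cen <- train_centroids(x, classifier_genes = rownames(x$values))
  set.seed(10)
  for (i in 1:10) {
    samp <- stats::setNames(stats::rnorm(length(cen$genes)), cen$genes)
    res <- assign_subtype(samp, cen)
    brute <- apply(cen$values, 2, function(cv)
      stats::cor(rank(samp[cen$genes]), rank(cv)))
    expect_lt(max(abs(res$correlations - brute)), 1e-12)
  }
})

test_that("strong subtype signal is recovered at >= 95% and cutoff is monotone", {
  accs <- numeric(3)
  for (s in 1:3) {
    x <- simulate_expression_compendium(
      expression_sim_config(n_per_subtype = 20, n_genes = 700,
                            n_classifier_genes = 210, effect_size = 4,
                            noise_sd = 1, seed = s))
    cen <- train_centroids(x)
    cls <- classify_compendium(x, cen)
    accs[s] <- mean(cls$assignments$subtype == x$subtype)
    fracs <- vapply(c(0, 0.3, 0.6, 0.9), function(ct)
      mean(classify_compendium(x, cen, cutoff = ct)$assignments$subtype !=
             "unclassified"), numeric(1))
    expect_true(all(diff(fracs) <= 0))
  }
  expect_true(all(accs >= 0.95))
})

test_that("an all-noise compendium is mostly unclassified at cutoff 0.3", {
  set.seed(77)
  vals <- matrix(stats::rnorm(710 * 60), 710,
                 dimnames = list(sprintf("g%03d", 1:710),
                                 sprintf("s%03d", 1:60)))
  lab <- rep_len(expression_subtypes(), 60)
  x <- expression_matrix(vals, subtype = lab)
  cen <- train_centroids(x, classifier_genes = rownames(vals))
  noise <- matrix(stats::rnorm(710 * 50), 710,
                  dimnames = list(rownames(vals), sprintf("n%03d", 1:50)))
  cls <- classify_compendium(expression_matrix(noise), cen)
  expect_gt(mean(cls$assignments$subtype == "unclassified"), 0.5)
})

test_that("an empty matrix classifies to an empty assignment list", {
  x <- make_labeled(seed = 2, n_genes = 20)
  cen <- train_centroids(x, classifier_genes = rownames(x$values))
  empty <- expression_matrix(x$values[, 0, drop = FALSE])
  res <- classify_compendium(empty, cen)
  expect_equal(nrow(res$assignments), 0)
})
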