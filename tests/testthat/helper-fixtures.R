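# Shared fixture builders for the test suite.

# small labeled expression matrix: `n_per` samples for each of the 7
# subtypes, `n_planted` genes shifted by `shift` in claudin-low only
planted_cl_matrix <- function(seed, n_per = 30, n_genes = 1000,
                              n_planted = 20, shift = 2, noise_sd = 1) {
  set.seed(seed)
  subs <- expression_subtypes()
  lab <- rep(subs, each = n_per)
  genes <- sprintf("g%04d", seq_len(n_genes))
  vals <- matrix(stats::rnorm(n_genes * length(lab), sd = noise_sd),
                 n_genes, length(lab),
                 dimnames = list(genes, sprintf("s%04d", seq_along(lab))))
  sgn <- rep_len(c(1, -1), n_planted)
  cl <- lab == "claudin-low"
  for (j in seq_len(n_planted))
    vals[j, cl] <- vals[j, cl] + sgn[j] * shift
  x <- expression_matrix(vals, subtype = lab)
  attr(x, "planted") <- genes[seq_len(n_planted)]
  x
}

# cell-line fixture as a core-level table (one core per marker)
cell_line_cores <- function() {
  lines <- load_table2_cell_lines()
  markers <- setdiff(names(lines), c("cell_line", "declared_subtype"))
  do.call(rbind, lapply(seq_len(nrow(lines)), function(i) {
    data.frame(tumor_id = lines$cell_line[i], core_index = 1L,
               marker = markers,
               allred_raw = as.numeric(lines[i, markers]),
               ki67_percent = NA_real_, fish_ratio = NA_real_,
               stringsAsFactors = FALSE)
  }))
}

# quick profile builder for classify_tumor tests
profile_of <- function(..., ki67 = NA, fish = NA, id = "t1") {
  scores <- c(...)
  tumor_ihc_profile(id, scores, ki67_percent = ki67, fish_ratio = fish)
}

# independent product-limit oracle (no ties handling subtleties needed:
# events at t before censorings at t is implied by >= in the risk set)
km_oracle <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  data.frame(time = ut, survival = surv)
}

# step-up Benjamini-Yekutieli oracle, straight from the definition
by_oracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  raw <- p[o] * m * cm / seq_len(m)
  adj <- pmin(rev(cummin(rev(raw))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# textbook Pearson chi-square oracle
chisq_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# tie-free Kruskal-Wallis oracle
kw_oracle <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  rs <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  h <- 12 / (N * (N + 1)) * sum(ns * (rs - (N + 1) / 2)^2)
  list(H = h, df = length(ns) - 1,
       p_value = stats::pchisq(h, length(ns) - 1, lower.tail = FALSE))
}

# two-group log-rank oracle: squared standardized O - E
logrank_oracle <- function(times, events, groups) {
  g <- unique(groups)
  ut <- sort(unique(times[events == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ut) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == g[1])
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & groups == g[1])
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}
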