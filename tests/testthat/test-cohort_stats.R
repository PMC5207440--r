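test_that("chi-square statistic matches hand computation and the textbook oracle", {
  even <- matrix(c(10, 10, 10, 10), 2)
  res <- chi_square_test(even)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  diag40 <- matrix(c(20, 0, 0, 20), 2)
  expect_equal(chi_square_test(diag40)$statistic, 40)
  set.seed(1)
  for (i in 1:10) {
    tab <- matrix(stats::rpois(6, 20) + 1, 2, 3)
    a <- chi_square_test(tab)
    b <- chisq_oracle(tab)
    expect_lt(abs(a$statistic - b$statistic), 1e-10)
    expect_lt(abs(a$p_value - b$p_value), 1e-10)
    expect_equal(a$df, b$df)
  }
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("claudin-low age split reproduces the printed cohort p-value", {
  # printed as 0.003; the uncorrected Pearson value is 0.002 (the printed
  # figure matches the continuity-corrected variant of the same test)
  tab <- rbind(cl = c(47, 79 - 47), rest = c(651, 863 - 651))
  p <- chi_square_test(tab)$p_value
  expect_gt(p, 0.001)
  expect_lt(p, 0.005)
})

test_that("Cochran-Armitage trend agrees with the base-R trend oracle", {
  flat <- rbind(c(10, 10, 10), c(90, 90, 90))
  expect_equal(cochran_armitage_trend(flat)$Z, 0)
  up <- rbind(c(10, 20, 30), c(90, 80, 70))
  res <- cochran_armitage_trend(up)
  expect_gt(res$Z, 0)
  expect_lt(res$p_value, 0.05)
  down <- up[, 3:1]
  expect_equal(cochran_armitage_trend(down)$Z, -res$Z)
  set.seed(2)
  for (i in 1:10) {
    x <- stats::rpois(4, 15) + 1
    n <- x + stats::rpois(4, 30) + 1
    tab <- rbind(x, n - x)
    mine <- cochran_armitage_trend(tab)
    ref <- stats::prop.trend.test(x, n)
    expect_lt(abs(mine$Z^2 - unname(ref$statistic)), 1e-10)
  }
})

test_that("Kruskal-Wallis matches the tie-free oracle and rank invariances", {
  expect_equal(kruskal_wallis(rep(5, 10), rep(1:2, 5))$H, 0)
  expect_equal(kruskal_wallis(rep(5, 10), rep(1:2, 5))$p_value, 1)
  # disjoint supports: maximal separation for the 5+5 design
  v <- c(1:5, 101:105)
  g <- rep(c("a", "b"), each = 5)
  res <- kruskal_wallis(v, g)
  oracle <- kw_oracle(v, g)
  expect_equal(res$H, oracle$H)
  expect_equal(res$H, 12 / (10 * 11) * (5 * (3 - 5.5)^2 + 5 * (8 - 5.5)^2))
  set.seed(3)
  for (i in 1:10) {
    vals <- stats::rnorm(30)
    grp <- sample(letters[1:3], 30, replace = TRUE)
    if (length(unique(grp)) < 2) next
    a <- kruskal_wallis(vals, grp)
    b <- kw_oracle(vals, grp)
    expect_lt(abs(a$H - b$H), 1e-10)
    expect_lt(abs(a$p_value - b$p_value), 1e-10)
    # invariance under strictly monotone transform
    expect_equal(kruskal_wallis(exp(vals), grp)$H, a$H)
  }
})

test_that("Kaplan-Meier matches the hand product-limit and the brute oracle", {
  all_cens <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(all_cens), 0)
  expect_equal(km_at(all_cens, 2.5)$survival, 1)

  km <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$survival, c(2 / 3, 0))
  expect_equal(km$time, c(1, 3))

  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "negative")

  set.seed(4)
  for (i in 1:10) {
    n <- 40
    times <- round(stats::rexp(n, 0.2), 2)
    events <- stats::rbinom(n, 1, 0.7)
    if (sum(events) == 0) next
    km <- kaplan_meier(times, events)
    oracle <- km_oracle(times, events)
    expect_lt(max(abs(km$survival - oracle$survival)), 1e-10)
  }
})

test_that("with all events and no ties the KM estimate is the empirical survival function", {
  set.seed(5)
  times <- sort(stats::runif(25))
  km <- kaplan_meier(times, rep(1, 25))
  expect_equal(km$survival, (24:0) / 25)
})

test_that("KM confidence bands bracket the estimate and stay in [0, 1]", {
  set.seed(6)
  km <- kaplan_meier(stats::rexp(200, 0.1), stats::rbinom(200, 1, 0.8))
  ok <- !is.na(km$ci_low)
  expect_true(all(km$ci_low[ok] >= 0 & km$ci_high[ok] <= 1))
  expect_true(all(km$ci_low[ok] <= km$survival[ok] + 1e-12))
  expect_true(all(km$ci_high[ok] >= km$survival[ok] - 1e-12))
  expect_true(all(diff(km$survival) <= 1e-12))
})

test_that("log-rank test matches the squared standardized O-E oracle", {
  t0 <- c(1, 2, 3, 4, 5, 6)
  expect_equal(logrank_test(c(t0, t0), rep(1, 12),
                            rep(c("a", "b"), each = 6))$statistic, 0)
  expect_error(logrank_test(t0, rep(1, 6), rep("a", 6)), "2 groups")
  expect_error(logrank_test(t0, rep(0, 6), rep(c("a", "b"), 3)), "no events")
  set.seed(7)
  for (i in 1:10) {
    n <- 30
    times <- stats::rexp(n, c(0.1, 0.3))
    events <- stats::rbinom(n, 1, 0.8)
    groups <- rep(c("a", "b"), length.out = n)
    if (sum(events) == 0) next
    mine <- logrank_test(times, events, groups)
    expect_lt(abs(mine$statistic - logrank_oracle(times, events, groups)),
              1e-8)
  }
})

test_that("log-rank p-values are approximately uniform under the null", {
  set.seed(8)
  ps <- replicate(100, {
    times <- stats::rexp(60, 0.2)
    events <- stats::rbinom(60, 1, 0.8)
    logrank_test(times, events, rep(c("a", "b"), 30))$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("characteristics table percentages are consistent and complete", {
  co <- simulate_ihc_cohort(cohort_sim_config(n_tumors = 500, seed = 41))
  res <- classify_cohort(co$cores, co$clinical)
  tab <- build_characteristics_table(res$calls, co$clinical)
  expect_null(tab$note)
  # group-size percentages sum to 100 up to rounding
  nrow_cells <- tab$table[tab$table$variable == "N", tab$groups]
  pcts <- as.numeric(sub(".*\\(([-0-9.]+)\\)", "\\1", unlist(nrow_cells)))
  expect_lt(abs(sum(pcts) - 100), 0.5)
  # grade percentages per group sum to 100 up to rounding
  grades <- tab$table[tab$table$variable == "Tumor grade" &
                        tab$table$level %in% c("I", "II", "III"), ]
  for (g in tab$groups) {
    p3 <- as.numeric(sub(".*\\(([-0-9.]+)\\)", "\\1", grades[[g]]))
    expect_lt(abs(sum(p3) - 100), 0.5)
  }
  # simulated extensive-infiltrate proportion near its generating value
  det <- tab$details$lymphocytic_infiltrate
  p_cl <- det$n[["claudin-low"]] / det$denom[["claudin-low"]]
  n_cl <- det$denom[["claudin-low"]]
  expect_lt(abs(p_cl - 0.419), 3 * sqrt(0.419 * 0.581 / n_cl))
})

test_that("single-subtype cohorts suppress the claudin-low comparison with a note", {
  co <- simulate_ihc_cohort(cohort_sim_config(
    n_tumors = 60,
    subtype_frequencies = c("claudin-low" = 0, "luminal A" = 1,
                            "luminal B" = 0, "HER2-enriched" = 0,
                            "basal-like" = 0, "unclassified" = 0),
    seed = 2))
  res <- classify_cohort(co$cores, co$clinical)
  tab <- build_characteristics_table(res$calls, co$clinical)
  expect_match(tab$note, "suppressed")
  expect_true(all(tab$table$cl_vs_rest == ""))
})

test_that("an empty join is an error", {
  calls <- data.frame(tumor_id = "A", subtype = "luminal A")
  clin <- data.frame(tumor_id = "B", os_time = 1, os_event = 1,
                     dfs_time = 1, dfs_event = 1, lr_time = 1, lr_event = 0)
  expect_error(build_characteristics_table(calls, clin), "no tumors shared")
})
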