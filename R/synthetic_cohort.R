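#' Default subtype-conditional Allred score distributions
#'
#' One probability vector per subtype per marker over the attainable raw
#' scores (0, 2-8), chosen so that each subtype's scores are consistent
#' with its own defining IHC rule under highest-score triplicate
#' aggregation: e.g. claudin-low tumors draw ER/PR/HER2 from {0, 2} and all
#' four adhesion markers from scores <= 4, luminal tumors draw ER from
#' {6, 7, 8}, basal-like tumors draw CK5/EGFR high and at most one adhesion
#' marker low. Probabilities are loosely informed by the marker prevalences
#' reported for tissue-microarray breast-cancer cohorts.
#'
#' @return Nested list: `dist[[subtype]][[marker]]` is a named probability
#'   vector over scores `c("0","2",...,"8")`.
#' @export
default_marker_distributions <- function() {
  sc <- function(...) {
    p <- c(...)
    stopifnot(all(names(p) %in% as.character(c(0, 2:8))))
    out <- stats::setNames(rep(0, 8), as.character(c(0, 2:8)))
    out[names(p)] <- p
    out / sum(out)
  }
  neg <- sc("0" = 0.8, "2" = 0.2)
  high <- sc("6" = 0.3, "7" = 0.4, "8" = 0.3)
  mid_high <- sc("5" = 0.3, "6" = 0.4, "7" = 0.3)
  low <- sc("0" = 0.5, "2" = 0.3, "3" = 0.2)
  list(
    "luminal A" = list(
      ER = high, PR = sc("0" = 0.2, "5" = 0.2, "6" = 0.3, "7" = 0.3),
      HER2 = neg, CK5 = sc("0" = 1), EGFR = neg,
      CLDN3 = high, CLDN4 = high, CLDN7 = high, ECAD = high,
      CD24 = mid_high, CD44 = sc("0" = 0.4, "2" = 0.2, "4" = 0.2, "5" = 0.2),
      ALDH1 = sc("0" = 0.9, "4" = 0.1)),
    "luminal B" = list(
      ER = high, PR = sc("0" = 0.3, "4" = 0.2, "6" = 0.3, "7" = 0.2),
      HER2 = sc("0" = 0.4, "2" = 0.2, "7" = 0.2, "8" = 0.2),
      CK5 = sc("0" = 1), EGFR = neg,
      CLDN3 = high, CLDN4 = high, CLDN7 = high, ECAD = high,
      CD24 = mid_high, CD44 = sc("0" = 0.4, "2" = 0.3, "4" = 0.3),
      ALDH1 = sc("0" = 0.85, "4" = 0.15)),
    "HER2-enriched" = list(
      ER = sc("0" = 1), PR = sc("0" = 1),
      HER2 = sc("7" = 0.5, "8" = 0.5),
      CK5 = neg, EGFR = sc("0" = 0.5, "2" = 0.2, "4" = 0.3),
      CLDN3 = mid_high, CLDN4 = high, CLDN7 = high, ECAD = high,
      CD24 = mid_high, CD44 = sc("0" = 0.5, "2" = 0.3, "4" = 0.2),
      ALDH1 = sc("0" = 0.85, "4" = 0.15)),
    "basal-like" = list(
      ER = sc("0" = 1), PR = sc("0" = 1), HER2 = neg,
      CK5 = sc("6" = 0.3, "7" = 0.4, "8" = 0.3),
      EGFR = sc("6" = 0.3, "7" = 0.3, "8" = 0.4),
      CLDN3 = sc("0" = 0.3, "6" = 0.4, "7" = 0.3),
      CLDN4 = mid_high, CLDN7 = high, ECAD = high,
      CD24 = sc("0" = 0.4, "4" = 0.3, "5" = 0.3),
      CD44 = sc("4" = 0.3, "6" = 0.4, "8" = 0.3),
      ALDH1 = sc("0" = 0.7, "4" = 0.2, "6" = 0.1)),
    "claudin-low" = list(
      ER = neg, PR = neg, HER2 = neg,
      CK5 = neg, EGFR = sc("0" = 0.3, "6" = 0.2, "7" = 0.3, "8" = 0.2),
      CLDN3 = low, CLDN4 = low, CLDN7 = low, ECAD = low,
      CD24 = low, CD44 = sc("4" = 0.2, "6" = 0.3, "7" = 0.3, "8" = 0.2),
      ALDH1 = sc("0" = 0.8, "4" = 0.2))
  )
}

# Table-3-style defaults for covariates and hazards, keyed by true class.
default_cohort_profiles <- function() {
  cls <- c("claudin-low", "luminal A", "luminal B", "HER2-enriched",
           "basal-like", "unclassified")
  list(
    classes = cls,
    age_mean = stats::setNames(c(52.8, 60.5, 58.3, 56.4, 51.9, 59.0), cls),
    age_sd = stats::setNames(c(11.9, 10.3, 11.8, 11.1, 10.9, 11.1), cls),
    grade_probs = stats::setNames(list(
      c(I = 0.069, II = 0.250, III = 0.681),
      c(I = 0.303, II = 0.661, III = 0.036),
      c(I = 0.124, II = 0.684, III = 0.192),
      c(I = 0.053, II = 0.526, III = 0.421),
      c(I = 0.023, II = 0.140, III = 0.837),
      c(I = 0.243, II = 0.615, III = 0.142)), cls),
    size_ge2_prob = stats::setNames(
      c(0.329, 0.131, 0.261, 0.333, 0.340, 0.139), cls),
    adjuvant_probs = stats::setNames(list(
      c(tamoxifen = 0.203, chemotherapy = 0.405, none = 0.392),
      c(tamoxifen = 0.512, chemotherapy = 0.028, none = 0.460),
      c(tamoxifen = 0.474, chemotherapy = 0.077, none = 0.449),
      c(tamoxifen = 0.095, chemotherapy = 0.429, none = 0.476),
      c(tamoxifen = 0.094, chemotherapy = 0.585, none = 0.321),
      c(tamoxifen = 0.386, chemotherapy = 0.090, none = 0.524)), cls),
    lvi_prob = stats::setNames(
      c(0.127, 0.108, 0.210, 0.048, 0.173, 0.078), cls),
    infiltrate_extensive_prob = stats::setNames(
      c(0.419, 0.011, 0.091, 0.333, 0.458, 0.077), cls),
    margin_prob = stats::setNames(
      c(0.443, 0.170, 0.228, 0.286, 0.385, 0.205), cls),
    # exponential hazards per year, back-solved from 10-year
    # survival fractions typical of node-negative cohorts
    hazard_os = stats::setNames(
      c(0.0203, 0.0153, 0.0176, 0.0100, 0.0241, 0.0210), cls),
    hazard_dfs = stats::setNames(
      c(0.0321, 0.0326, 0.0420, 0.0567, 0.0491, 0.0440), cls),
    hazard_lr = stats::setNames(
      c(0.0013, 0.0051, 0.0072, 0.0237, 0.0090, 0.0080), cls)
  )
}

#' Configuration for the synthetic IHC / clinical cohort
#'
#' Describes a tissue-microarray cohort of tumors arrayed in triplicate,
#' with subtype-conditional Allred score distributions, subtype-conditional
#' clinical covariates, and exponential event times for overall survival,
#' disease-free survival and local recurrence with independent exponential
#' censoring.
#'
#' @param n_tumors cohort size (default 942).
#' @param subtype_frequencies named proportions over the five IHC classes
#'   plus `"unclassified"`, summing to 1 (default: the observed cohort
#'   distribution 79/389/234/21/53/166 out of 942).
#' @param marker_score_distributions per-subtype, per-marker score
#'   distributions; see [default_marker_distributions()].
#' @param ki67_ranges named list of `c(min, max)` Ki67 percentage ranges
#'   per subtype (luminal A below 14, luminal B at or above 14 by default).
#' @param hazards list of three named vectors (`os`, `dfs`, `lr`) of
#'   per-year exponential hazards per class.
#' @param censoring_rate per-year exponential censoring hazard.
#' @param missing_core_rate probability that an individual core record is
#'   lost (absent row, never a zero score).
#' @param seed integer seed.
#' @return List of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_tumors = 942,
                              subtype_frequencies = NULL,
                              marker_score_distributions = default_marker_distributions(),
                              ki67_ranges = NULL,
                              hazards = NULL,
                              censoring_rate = 0.02,
                              missing_core_rate = 0.02,
                              seed = 1L) {
  prof <- default_cohort_profiles()
  cls <- prof$classes
  if (is.null(subtype_frequencies))
    subtype_frequencies <- stats::setNames(
      c(79, 389, 234, 21, 53, 166) / 942,
      c("claudin-low", "luminal A", "luminal B", "HER2-enriched",
        "basal-like", "unclassified"))
  if (!setequal(names(subtype_frequencies), cls))
    stop("subtype_frequencies must be named over: ", paste(cls, collapse = ", "))
  subtype_frequencies <- subtype_frequencies[cls]
  if (abs(sum(subtype_frequencies) - 1) > 1e-9)
    stop("subtype_frequencies must sum to 1")
  if (is.null(ki67_ranges))
    ki67_ranges <- list("luminal A" = c(1, 12), "luminal B" = c(20, 80),
                        "HER2-enriched" = c(5, 60), "basal-like" = c(20, 90),
                        "claudin-low" = c(10, 70))
  if (is.null(hazards))
    hazards <- list(os = prof$hazard_os, dfs = prof$hazard_dfs,
                    lr = prof$hazard_lr)
  for (h in hazards) if (any(h <= 0)) stop("hazards must be positive")
  stopifnot(n_tumors >= 1, censoring_rate >= 0, censoring_rate <= 1,
            missing_core_rate >= 0, missing_core_rate <= 1)
  cfg <- structure(list(n_tumors = as.integer(n_tumors),
                        subtype_frequencies = subtype_frequencies,
                        marker_score_distributions = marker_score_distributions,
                        ki67_ranges = ki67_ranges,
                        hazards = hazards,
                        censoring_rate = censoring_rate,
                        missing_core_rate = missing_core_rate,
                        seed = as.integer(seed),
                        profiles = prof),
                   class = "cohort_sim_config")
  check_cohort_config(cfg)
  cfg
}

# Warn when a subtype's score distributions cannot satisfy that subtype's
# own defining rule under highest-score aggregation (certain violations
# only; probabilistic near-misses are the user's business).
check_cohort_config <- function(cfg, rules = marker_cutoff_rules()) {
  d <- cfg$marker_score_distributions
  support_max <- function(sub, m) {
    p <- d[[sub]][[m]]
    if (is.null(p)) return(NA_real_)
    max(as.numeric(names(p)[p > 0]))
  }
  warn <- function(sub, msg)
    warning(sprintf("score distribution for '%s' inconsistent with its rule: %s",
                    sub, msg), call. = FALSE)
  tn_ok <- function(sub) {
    all(c(support_max(sub, "ER"), support_max(sub, "PR")) <
          rules$er_pr_positive_min) &&
      support_max(sub, "HER2") < min(rules$her2_equivocal)
  }
  if ("claudin-low" %in% names(d)) {
    if (!tn_ok("claudin-low"))
      warn("claudin-low", "ER/PR/HER2 support is not triple-negative")
    n_low <- sum(vapply(adhesion_markers(), function(m)
      support_max("claudin-low", m) <= rules$adhesion_low_max, logical(1)))
    if (n_low < 2)
      warn("claudin-low", "fewer than 2 adhesion markers certainly low")
  }
  if ("basal-like" %in% names(d) && !tn_ok("basal-like"))
    warn("basal-like", "ER/PR/HER2 support is not triple-negative")
  if ("luminal A" %in% names(d) &&
      support_max("luminal A", "ER") < rules$er_pr_positive_min &&
      support_max("luminal A", "PR") < rules$er_pr_positive_min)
    warn("luminal A", "neither ER nor PR can be positive")
  invisible(cfg)
}

#' Simulate a tissue-microarray IHC cohort with clinical outcomes
#'
#' Draws a true class for each tumor, generates three replicate core
#' scores per marker from the subtype-conditional distributions (dropping
#' individual cores at `missing_core_rate`), a Ki67 percentage channel,
#' FISH ratios for HER2-equivocal tumors, subtype-conditional clinical
#' covariates, and exponential OS/DFS/LR event times with independent
#' exponential censoring. Tumors whose true class is `"unclassified"` are
#' generated from a random subtype and then stripped of their ER and PR
#' cores (emulating loss of invasive tumor on sequential TMA slides).
#'
#' @param config a [cohort_sim_config()].
#' @return List with `cores` (core-level score table), `clinical`
#'   (clinical/outcome table) and `true_subtype` (named character vector).
#' @export
simulate_ihc_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  cfg <- config
  prof <- cfg$profiles
  cls <- prof$classes
  n <- cfg$n_tumors
  ids <- sprintf("T%04d", seq_len(n))

  set.seed(split_seed(cfg$seed, "cohort-subtypes"))
  truth <- sample(cls, n, replace = TRUE, prob = cfg$subtype_frequencies)
  names(truth) <- ids
  # unclassified tumors still carry scores drawn from some subtype
  latent <- truth
  unc <- truth == "unclassified"
  latent[unc] <- sample(setdiff(cls, "unclassified"), sum(unc), replace = TRUE)

  set.seed(split_seed(cfg$seed, "cohort-cores"))
  markers <- names(cfg$marker_score_distributions[[1]])
  core_list <- vector("list", length(cls))
  grid <- expand.grid(tumor = ids, marker = markers, core_index = 1:3,
                      stringsAsFactors = FALSE)
  grid$latent <- latent[grid$tumor]
  grid$allred_raw <- NA_real_
  for (sub in unique(latent)) {
    for (m in markers) {
      sel <- grid$latent == sub & grid$marker == m
      p <- cfg$marker_score_distributions[[sub]][[m]]
      grid$allred_raw[sel] <- sample(as.numeric(names(p)), sum(sel),
                                     replace = TRUE, prob = p)
    }
  }
  # Ki67 channel: uniform percentage within the subtype range
  ki <- expand.grid(tumor = ids, marker = "KI67", core_index = 1:3,
                    stringsAsFactors = FALSE)
  ki$latent <- latent[ki$tumor]
  rng <- do.call(rbind, cfg$ki67_ranges[ki$latent])
  ki$allred_raw <- NA_real_
  ki$ki67_percent <- stats::runif(nrow(ki), rng[, 1], rng[, 2])
  grid$ki67_percent <- NA_real_
  cores <- rbind(grid, ki)

  # drop individual cores; unclassified tumors lose ER and PR entirely
  set.seed(split_seed(cfg$seed, "cohort-missing"))
  keep <- stats::runif(nrow(cores)) >= cfg$missing_core_rate
  keep[cores$tumor %in% ids[unc] & cores$marker %in% c("ER", "PR")] <- FALSE
  cores <- cores[keep, , drop = FALSE]

  # FISH for tumors whose aggregated HER2 is equivocal (4-5): amplified
  # when the latent subtype is HER2-driven, not otherwise
  set.seed(split_seed(cfg$seed, "cohort-fish"))
  cores$fish_ratio <- NA_real_
  her2 <- cores[cores$marker == "HER2", ]
  agg <- tapply(her2$allred_raw, her2$tumor, aggregate_cores)
  eq_ids <- names(agg)[!is.na(agg) & agg %in% c(4, 5)]
  for (id in eq_ids) {
    amp <- latent[id] %in% c("HER2-enriched", "luminal B")
    ratio <- if (amp) stats::runif(1, 2, 5) else stats::runif(1, 0.8, 1.8)
    cores$fish_ratio[cores$tumor == id & cores$marker == "HER2"] <- ratio
  }

  cores <- data.frame(tumor_id = cores$tumor, core_index = cores$core_index,
                      marker = cores$marker, allred_raw = cores$allred_raw,
                      ki67_percent = cores$ki67_percent,
                      fish_ratio = cores$fish_ratio, stringsAsFactors = FALSE)
  cores <- cores[order(cores$tumor_id, cores$marker, cores$core_index), ]
  rownames(cores) <- NULL

  # clinical covariates, subtype-conditional
  set.seed(split_seed(cfg$seed, "cohort-clinical"))
  age <- stats::rnorm(n, prof$age_mean[truth], prof$age_sd[truth])
  grade <- vapply(truth, function(s)
    sample(c("I", "II", "III"), 1, prob = prof$grade_probs[[s]]), character(1))
  big <- stats::runif(n) < prof$size_ge2_prob[truth]
  size <- ifelse(big, stats::runif(n, 2, 5), stats::runif(n, 0.5, 1.99))
  adjuvant <- vapply(truth, function(s)
    sample(c("tamoxifen", "chemotherapy", "none"), 1,
           prob = prof$adjuvant_probs[[s]]), character(1))
  lvi <- stats::runif(n) < prof$lvi_prob[truth]
  infl <- ifelse(stats::runif(n) < prof$infiltrate_extensive_prob[truth],
                 "extensive",
                 sample(c("none", "minimal", "moderate"), n, replace = TRUE,
                        prob = c(0.5, 0.3, 0.2)))
  margin <- stats::runif(n) < prof$margin_prob[truth]

  set.seed(split_seed(cfg$seed, "cohort-survival"))
  surv_channel <- function(hz) {
    ev <- stats::rexp(n, hz[truth])
    cn <- if (cfg$censoring_rate > 0) stats::rexp(n, cfg$censoring_rate)
          else rep(Inf, n)
    list(time = pmin(ev, cn), event = as.integer(ev <= cn))
  }
  os <- surv_channel(cfg$hazards$os)
  dfs <- surv_channel(cfg$hazards$dfs)
  lr <- surv_channel(cfg$hazards$lr)

  clinical <- data.frame(
    tumor_id = ids, age_years = round(age, 1),
    tumor_size_cm = round(size, 2), grade = grade, lvi = lvi,
    lymphocytic_infiltrate = infl, circumscribed_margin = margin,
    adjuvant = adjuvant,
    os_time = os$time, os_event = os$event,
    dfs_time = dfs$time, dfs_event = dfs$event,
    lr_time = lr$time, lr_event = lr$event,
    stringsAsFactors = FALSE)

  list(cores = cores, clinical = clinical, true_subtype = truth)
}
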