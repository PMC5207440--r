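#' Compose an Allred raw score from intensity and proportion
#'
#' The Allred composite adds a staining-intensity score (absent 0, weak 1,
#' moderate 2, strong 3) to a stained-proportion category (none 0, <1% 1,
#' 1-10% 2, 11-33% 3, 34-66% 4, 67-100% 5), yielding a raw score of 0 or
#' 2-8; a raw score of 1 is unrepresentable because a core with any
#' staining has both intensity >= 1 and proportion category >= 1.
#'
#' @param intensity integer 0-3 (vectorised).
#' @param proportion_percent percentage of cells stained, 0-100
#'   (vectorised). Must be 0 exactly when `intensity` is 0.
#' @return Integer vector of raw scores in `{0, 2..8}`.
#' @export
#' @examples
#' allred_raw(3, 80)  # 8
#' allred_raw(1, 0.5) # 2
allred_raw <- function(intensity, proportion_percent) {
  stopifnot(length(intensity) == length(proportion_percent))
  if (!all(intensity %in% 0:3)) stop("intensity must be 0, 1, 2 or 3")
  if (any(proportion_percent < 0 | proportion_percent > 100))
    stop("proportion_percent must be within 0-100")
  bad <- xor(intensity == 0, proportion_percent == 0)
  if (any(bad))
    stop("inconsistent score: intensity is 0 exactly when proportion is 0 ",
         "(offending index ", which(bad)[1], ")")
  as.integer(intensity + allred_proportion_category(proportion_percent))
}

#' Proportion category of the Allred scheme
#'
#' @param proportion_percent percentage of cells stained, 0-100.
#' @return Integer category 0-5 per the printed bins.
#' @export
allred_proportion_category <- function(proportion_percent) {
  p <- proportion_percent
  stopifnot(all(p >= 0 & p <= 100))
  ifelse(p == 0, 0L,
  ifelse(p < 1, 1L,
  ifelse(p <= 10, 2L,
  ifelse(p <= 33, 3L,
  ifelse(p <= 66, 4L, 5L)))))
}

#' Marker cutoff rules for the surrogate IHC classifier
#'
#' The positivity / low-expression thresholds applied to aggregated Allred
#' raw scores: ER and PR positive at 3-8 (0 and 2 negative); HER2 positive
#' at >= 6, equivocal at 4-5 (resolved by FISH amplification at ratio >= 2),
#' negative at <= 3; CK5, EGFR, CD24, CD44 and ALDH1 positive at >= 4;
#' claudin 3/4/7 and E-cadherin "low" at <= 4; Ki67 "high" at >= 14%.
#' The overlap at exactly 4 (positive for the generic markers, low for the
#' adhesion markers) is intentional.
#'
#' @param er_pr_positive_min,her2_positive_min,her2_equivocal,generic_positive_min,adhesion_low_max,ki67_high_min,fish_amplified_min
#'   override any threshold.
#' @return A list of class `marker_cutoff_rules`.
#' @export
marker_cutoff_rules <- function(er_pr_positive_min = 3,
                                her2_positive_min = 6,
                                her2_equivocal = c(4, 5),
                                generic_positive_min = 4,
                                adhesion_low_max = 4,
                                ki67_high_min = 14,
                                fish_amplified_min = 2) {
  structure(list(er_pr_positive_min = er_pr_positive_min,
                 her2_positive_min = her2_positive_min,
                 her2_equivocal = her2_equivocal,
                 generic_positive_min = generic_positive_min,
                 adhesion_low_max = adhesion_low_max,
                 ki67_high_min = ki67_high_min,
                 fish_amplified_min = fish_amplified_min),
            class = "marker_cutoff_rules")
}

#' Aggregate replicate core scores for one tumor and marker
#'
#' Tissue-microarray tumors are arrayed in triplicate; the highest raw
#' score across the available cores is carried into analysis. Lost cores
#' are absent values, and a tumor with no scorable core is missing, not 0.
#'
#' @param raws raw scores from up to three replicate cores (NAs allowed).
#' @return The maximum available raw score, or `NA` if none.
#' @export
#' @examples
#' aggregate_cores(c(3, 5, NA)) # 5
aggregate_cores <- function(raws) {
  raws <- raws[!is.na(raws)]
  if (length(raws) == 0) return(NA_real_)
  max(raws)
}

#' Resolve HER2 status from the Allred score and optional FISH ratio
#'
#' @param raw aggregated HER2 Allred raw score (0 or 2-8).
#' @param fish_ratio optional HER2/CEP17 FISH ratio, consulted only for
#'   equivocal scores.
#' @param rules a [marker_cutoff_rules()].
#' @return `"positive"`, `"negative"`, or `"unresolved"` (equivocal score
#'   with no FISH result, or missing score).
#' @export
#' @examples
#' resolve_her2(6)         # positive
#' resolve_her2(4, 2.5)    # positive (amplified)
#' resolve_her2(5)         # unresolved
resolve_her2 <- function(raw, fish_ratio = NA, rules = marker_cutoff_rules()) {
  if (is.na(raw)) return("unresolved")
  if (!raw %in% c(0, 2:8)) stop("HER2 raw score must be 0 or 2-8")
  if (raw >= rules$her2_positive_min) return("positive")
  if (raw %in% rules$her2_equivocal) {
    if (is.na(fish_ratio)) return("unresolved")
    return(if (fish_ratio >= rules$fish_amplified_min) "positive" else "negative")
  }
  "negative"
}

#' Build a per-tumor IHC profile from aggregated marker scores
#'
#' Derives the marker-level calls (hormone-receptor positivity, HER2
#' status, Ki67 high/low, adhesion-low count over claudin 3/4/7 and
#' E-cadherin, stem-cell markers) that the subtype decision rule consumes.
#'
#' @param tumor_id identifier.
#' @param scores named numeric vector of aggregated Allred raw scores over
#'   (a subset of) [allred_markers()]; markers not named are missing.
#' @param ki67_percent aggregated Ki67 percentage, or `NA`.
#' @param fish_ratio HER2 FISH ratio, or `NA`.
#' @param rules a [marker_cutoff_rules()].
#' @return A list of class `tumor_ihc_profile`.
#' @export
tumor_ihc_profile <- function(tumor_id, scores, ki67_percent = NA,
                              fish_ratio = NA, rules = marker_cutoff_rules()) {
  full <- stats::setNames(rep(NA_real_, length(allred_markers())),
                          allred_markers())
  if (length(scores)) {
    bad <- setdiff(names(scores), allred_markers())
    if (length(bad)) stop("unknown marker(s): ", paste(bad, collapse = ", "))
    ok <- is.na(scores) | scores %in% c(0, 2:8)
    if (!all(ok)) stop("Allred raw scores must be 0 or 2-8")
    full[names(scores)] <- as.numeric(scores)
  }
  pos <- function(m, cut) if (is.na(full[[m]])) NA else full[[m]] >= cut
  adh <- full[adhesion_markers()]
  structure(list(
    tumor_id = tumor_id,
    scores = full,
    ki67_percent = ki67_percent,
    fish_ratio = fish_ratio,
    er_pos = pos("ER", rules$er_pr_positive_min),
    pr_pos = pos("PR", rules$er_pr_positive_min),
    her2_status = resolve_her2(full[["HER2"]], fish_ratio, rules),
    ki67_high = if (is.na(ki67_percent)) NA else ki67_percent >= rules$ki67_high_min,
    ck5_pos = pos("CK5", rules$generic_positive_min),
    egfr_pos = pos("EGFR", rules$generic_positive_min),
    adhesion_low_count = sum(adh <= rules$adhesion_low_max, na.rm = TRUE),
    adhesion_missing = sum(is.na(adh)),
    aldh1_pos = pos("ALDH1", rules$generic_positive_min),
    cd24_pos = pos("CD24", rules$generic_positive_min),
    cd44_pos = pos("CD44", rules$generic_positive_min)
  ), class = "tumor_ihc_profile")
}

#' Assign a molecular subtype from an IHC profile
#'
#' The surrogate five-class decision rule. Tumors expressing ER or PR are
#' luminal: luminal B if HER2-positive or Ki67-high, luminal A if
#' HER2-negative and Ki67-low. Hormone-receptor-negative, HER2-positive
#' tumors are HER2-enriched. Triple-negative tumors are claudin-low if at
#' least two of claudin 3, claudin 4, claudin 7 and E-cadherin score low
#' (<= 4); otherwise basal-like if CK5 and/or EGFR is positive; otherwise
#' triple-negative-other. Claudin-low takes precedence over basal-like: a
#' triple-negative tumor meeting the adhesion-low criterion is claudin-low
#' even if CK5 or EGFR is positive. A tumor whose first applicable rule
#' needs a missing (or FISH-unresolved) marker is unclassified, with the
#' missing marker named in `reason`.
#'
#' @param profile a [tumor_ihc_profile()].
#' @param rules a [marker_cutoff_rules()] (used only for documentation of
#'   provenance; the profile already carries the derived calls).
#' @return A list of class `subtype_call`: `tumor_id`, `subtype` (one of
#'   [ihc_call_levels()]) and `reason` (the rule that fired or the marker
#'   that was missing).
#' @export
classify_tumor <- function(profile, rules = marker_cutoff_rules()) {
  stopifnot(inherits(profile, "tumor_ihc_profile"))
  call <- function(subtype, reason) {
    structure(list(tumor_id = profile$tumor_id, subtype = subtype,
                   reason = reason), class = "subtype_call")
  }
  p <- profile

  hr_pos <- isTRUE(p$er_pos) || isTRUE(p$pr_pos)
  if (!hr_pos && (is.na(p$er_pos) || is.na(p$pr_pos))) {
    miss <- c("ER", "PR")[c(is.na(p$er_pos), is.na(p$pr_pos))]
    return(call("unclassified", paste0("missing:", paste(miss, collapse = ","))))
  }

  if (hr_pos) {
    if (p$her2_status == "positive")
      return(call("luminal B", "HR+;HER2+"))
    if (isTRUE(p$ki67_high))
      return(call("luminal B", "HR+;Ki67 high"))
    if (p$her2_status == "negative") {
      if (isFALSE(p$ki67_high))
        return(call("luminal A", "HR+;HER2-;Ki67 low"))
      return(call("unclassified", "missing:Ki67"))
    }
    return(call("unclassified", "missing:HER2"))
  }

  # hormone-receptor negative
  if (p$her2_status == "positive")
    return(call("HER2-enriched", "HR-;HER2+"))
  if (p$her2_status != "negative")
    return(call("unclassified", "missing:HER2"))

  # triple negative; claudin-low takes precedence over basal-like
  if (p$adhesion_low_count >= 2)
    return(call("claudin-low",
                sprintf("TN;adhesion low x%d", p$adhesion_low_count)))
  if (p$adhesion_low_count + p$adhesion_missing >= 2)
    return(call("unclassified", "missing:adhesion"))
  if (isTRUE(p$ck5_pos) || isTRUE(p$egfr_pos))
    return(call("basal-like", "TN;CK5/EGFR+"))
  if (is.na(p$ck5_pos) || is.na(p$egfr_pos)) {
    miss <- c("CK5", "EGFR")[c(is.na(p$ck5_pos), is.na(p$egfr_pos))]
    return(call("unclassified", paste0("missing:", paste(miss, collapse = ","))))
  }
  call("triple-negative-other", "TN;no basal or claudin-low criteria")
}

#' Cancer stem-cell phenotype calls
#'
#' ALDH1 positivity (raw >= 4) and the CD44-high / CD24-negative-or-low
#' phenotype (CD44 raw >= 4 together with CD24 raw < 4). Either call is
#' `NA` when the marker(s) it needs are missing.
#'
#' @param profile a [tumor_ihc_profile()].
#' @param rules a [marker_cutoff_rules()].
#' @return List with logical elements `aldh1_pos` and `cd44_cd24`.
#' @export
stemness_phenotype <- function(profile, rules = marker_cutoff_rules()) {
  stopifnot(inherits(profile, "tumor_ihc_profile"))
  cd44 <- profile$scores[["CD44"]]
  cd24 <- profile$scores[["CD24"]]
  cd44_cd24 <- if (is.na(cd44) || is.na(cd24)) NA else
    cd44 >= rules$generic_positive_min && cd24 < rules$generic_positive_min
  list(aldh1_pos = profile$aldh1_pos, cd44_cd24 = cd44_cd24)
}

#' Classify a cohort from core-level IHC scores
#'
#' For each tumor, replicate cores are aggregated per marker by the
#' highest-score rule (Ki67 percentages likewise by maximum), HER2 is
#' resolved against any FISH result, the profile is built and the subtype
#' decision rule applied.
#'
#' @param cores core-level score table as returned by [read_core_scores()]
#'   or [simulate_ihc_cohort()].
#' @param clinical optional clinical table; tumors present in `cores` but
#'   absent from `clinical` trigger a warning and are still classified.
#' @param rules a [marker_cutoff_rules()].
#' @return A list with `calls` (data frame: `tumor_id`, `subtype`,
#'   `reason`, `aldh1_pos`, `cd44_cd24`) and `frequency` (data frame of
#'   counts and percentages over the call categories, percentages to 0.1).
#' @export
classify_cohort <- function(cores, clinical = NULL,
                            rules = marker_cutoff_rules()) {
  cores <- validate_core_scores(cores)
  ids <- unique(cores$tumor_id)
  if (!is.null(clinical)) {
    absent <- setdiff(ids, clinical$tumor_id)
    if (length(absent))
      warning(length(absent), " tumor(s) in core table absent from clinical ",
              "table: ", paste(utils::head(absent, 5), collapse = ", "))
  }
  rows <- lapply(ids, function(id) {
    sub <- cores[cores$tumor_id == id, , drop = FALSE]
    allred <- sub[sub$marker != "KI67", , drop = FALSE]
    scores <- vapply(split(allred$allred_raw, allred$marker),
                     aggregate_cores, numeric(1))
    ki67 <- sub$ki67_percent[sub$marker == "KI67"]
    ki67 <- if (all(is.na(ki67))) NA_real_ else max(ki67, na.rm = TRUE)
    fish <- sub$fish_ratio[!is.na(sub$fish_ratio)]
    fish <- if (length(fish)) max(fish) else NA_real_
    prof <- tumor_ihc_profile(id, scores, ki67_percent = ki67,
                              fish_ratio = fish, rules = rules)
    cl <- classify_tumor(prof, rules)
    stem <- stemness_phenotype(prof, rules)
    data.frame(tumor_id = id, subtype = cl$subtype, reason = cl$reason,
               aldh1_pos = stem$aldh1_pos, cd44_cd24 = stem$cd44_cd24,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  if (is.null(calls))
    calls <- data.frame(tumor_id = character(), subtype = character(),
                        reason = character(), aldh1_pos = logical(),
                        cd44_cd24 = logical(), stringsAsFactors = FALSE)
  n <- table(factor(calls$subtype, levels = ihc_call_levels()))
  freq <- data.frame(subtype = names(n), n = as.integer(n),
                     percent = if (nrow(calls)) percent_of(as.integer(n), nrow(calls))
                               else rep(NA_real_, length(n)),
                     stringsAsFactors = FALSE)
  list(calls = calls, frequency = freq)
}
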