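#' Clinical-pathologic characteristics table
#'
#' Builds the cohort summary comparing IHC subtype groups: group sizes,
#' age (mean/SD and the >= 50 split), grade distribution, tumor size
#' >= 2 cm, adjuvant treatment, extensive lymphocytic infiltrate,
#' circumscribed margins, LVI, stem-cell markers, and Kaplan-Meier
#' estimates at 3/5/10 years for overall survival and 5/10 years for
#' local recurrence and disease-free survival. Each row carries a test
#' across all subtype groups (chi-square for categorical rows,
#' Kruskal-Wallis for age, log-rank for the survival endpoints) and, when
#' a claudin-low group is present alongside others, a claudin-low versus
#' rest comparison (the grade row uses the Cochran-Armitage trend test
#' over the ordered grades).
#'
#' @param calls subtype-call data frame from [classify_cohort()]
#'   (`tumor_id`, `subtype`, optionally `aldh1_pos`, `cd44_cd24`).
#' @param clinical clinical table as validated by [read_clinical()].
#' @return List of class `characteristics_table`: `table` (data frame of
#'   formatted cells: `variable`, `level`, one column per group,
#'   `cl_vs_rest`, and p-value columns), `details` (per-variable numeric
#'   counts and denominators for programmatic use) and `note` (set when
#'   the claudin-low comparison is suppressed).
#' @export
build_characteristics_table <- function(calls, clinical) {
  stopifnot(all(c("tumor_id", "subtype") %in% names(calls)))
  clinical <- validate_clinical(clinical)
  dat <- merge(calls, clinical, by = "tumor_id")
  if (nrow(dat) == 0) stop("no tumors shared between calls and clinical")

  order_pref <- c("claudin-low", "luminal A", "luminal B", "HER2-enriched",
                  "basal-like", "triple-negative-other", "unclassified")
  groups <- intersect(order_pref, unique(dat$subtype))
  dat$group <- factor(dat$subtype, levels = groups)
  has_cl <- "claudin-low" %in% groups && length(groups) >= 2
  note <- if (!has_cl)
    "claudin-low vs rest comparison suppressed: need a claudin-low group plus at least one other"
  dat$is_cl <- dat$subtype == "claudin-low"

  rows <- list()
  details <- list()
  n_total <- nrow(dat)
  blank <- stats::setNames(as.list(rep("", length(groups))), groups)

  add_row <- function(variable, level, cells, cl_cell = "",
                      p_value = NA_real_, p_cl = NA_real_) {
    row <- data.frame(variable = variable, level = level,
                      stringsAsFactors = FALSE)
    for (g in groups) row[[g]] <- cells[[g]] %||% ""
    row$cl_vs_rest <- cl_cell
    row$p_value <- p_value
    row$p_cl <- p_cl
    rows[[length(rows) + 1]] <<- row
  }

  safe_p <- function(expr) tryCatch(expr, error = function(e) NA_real_)

  # ---- group sizes ----
  n_by <- table(dat$group)
  cells <- lapply(groups, function(g) fmt_n_pct(n_by[[g]], n_total))
  names(cells) <- groups
  add_row("N", "", cells,
          cl_cell = if (has_cl) as.character(sum(!dat$is_cl)) else "")

  # ---- age ----
  if ("age_years" %in% names(dat)) {
    cells <- lapply(groups, function(g) {
      a <- dat$age_years[dat$group == g]
      sprintf("%.1f (%.1f)", mean(a, na.rm = TRUE), stats::sd(a, na.rm = TRUE))
    })
    names(cells) <- groups
    rest <- dat$age_years[!dat$is_cl]
    add_row("Age", "mean (sd)", cells,
            cl_cell = if (has_cl)
              sprintf("%.1f (%.1f)", mean(rest, na.rm = TRUE),
                      stats::sd(rest, na.rm = TRUE)) else "",
            p_value = safe_p(kruskal_wallis(dat$age_years, dat$group)$p_value),
            p_cl = if (has_cl)
              safe_p(kruskal_wallis(dat$age_years, dat$is_cl)$p_value)
            else NA_real_)
    binary_row("Age", ">=50", dat$age_years >= 50, dat, groups, has_cl,
               add_row, safe_p)
    details[["age_ge50"]] <- binary_details(dat$age_years >= 50, dat$group)
  }

  # helper-driven binary rows
  bin_vars <- list(
    c("Tumor size", ">=2 cm", "tumor_size_cm"),
    c("LVI", "positive", "lvi"),
    c("Lymphocytic infiltrate", "extensive", "lymphocytic_infiltrate"),
    c("Circumscribed margins", "positive", "circumscribed_margin"),
    c("ALDH1", "positive", "aldh1_pos"),
    c("CD44+/CD24-low", "positive", "cd44_cd24"))
  for (v in bin_vars) {
    col <- v[3]
    if (!col %in% names(dat)) next
    val <- switch(col,
                  tumor_size_cm = dat$tumor_size_cm >= 2,
                  lymphocytic_infiltrate = dat$lymphocytic_infiltrate == "extensive",
                  as.logical(dat[[col]]))
    binary_row(v[1], v[2], val, dat, groups, has_cl, add_row, safe_p)
    details[[col]] <- binary_details(val, dat$group)
  }

  # ---- grade (ordered; trend test for CL vs rest) ----
  if ("grade" %in% names(dat)) {
    for (g_lev in c("I", "II", "III")) {
      val <- dat$grade == g_lev
      cells <- lapply(groups, function(g) {
        v <- val[dat$group == g]
        fmt_n_pct(sum(v, na.rm = TRUE), max(1, sum(!is.na(v))))
      })
      names(cells) <- groups
      rest <- val[!dat$is_cl]
      add_row("Tumor grade", g_lev, cells,
              cl_cell = if (has_cl)
                fmt_n_pct(sum(rest, na.rm = TRUE),
                          max(1, sum(!is.na(rest)))) else "")
    }
    tab <- table(dat$group, dat$grade)
    p_all <- safe_p(chi_square_test(tab)$p_value)
    p_cl <- if (has_cl) safe_p({
      t2 <- rbind(table(factor(dat$grade[dat$is_cl], levels = c("I", "II", "III"))),
                  table(factor(dat$grade[!dat$is_cl], levels = c("I", "II", "III"))))
      cochran_armitage_trend(t2)$p_value
    }) else NA_real_
    add_row("Tumor grade", "p", blank, p_value = p_all, p_cl = p_cl)
    details[["grade"]] <- list(counts = tab)
  }

  # ---- adjuvant treatment ----
  if ("adjuvant" %in% names(dat)) {
    levs <- c("tamoxifen", "chemotherapy", "none")
    for (lv in levs) {
      val <- dat$adjuvant == lv
      cells <- lapply(groups, function(g) {
        v <- val[dat$group == g]
        fmt_n_pct(sum(v, na.rm = TRUE), max(1, sum(!is.na(v))))
      })
      names(cells) <- groups
      rest <- val[!dat$is_cl]
      add_row("Adjuvant treatment", lv, cells,
              cl_cell = if (has_cl)
                fmt_n_pct(sum(rest, na.rm = TRUE),
                          max(1, sum(!is.na(rest)))) else "")
    }
    tab <- table(dat$group, dat$adjuvant)
    add_row("Adjuvant treatment", "p", blank,
            p_value = safe_p(chi_square_test(tab)$p_value),
            p_cl = if (has_cl)
              safe_p(chi_square_test(table(dat$is_cl, dat$adjuvant))$p_value)
            else NA_real_)
    details[["adjuvant"]] <- list(counts = tab)
  }

  # ---- survival endpoints ----
  endpoints <- list(
    list(label = "Overall survival", time = "os_time", event = "os_event",
         at = c(3, 5, 10)),
    list(label = "Local recurrence", time = "lr_time", event = "lr_event",
         at = c(5, 10)),
    list(label = "Disease-free survival", time = "dfs_time",
         event = "dfs_event", at = c(5, 10)))
  for (ep in endpoints) {
    tm <- dat[[ep$time]]; ev <- dat[[ep$event]]
    cells <- lapply(groups, function(g) {
      sel <- dat$group == g
      fmt_n_pct(sum(ev[sel]), sum(sel))
    })
    names(cells) <- groups
    p_all <- safe_p(logrank_test(tm, ev, dat$group)$p_value)
    p_cl <- if (has_cl) safe_p(logrank_test(tm, ev, dat$is_cl)$p_value)
            else NA_real_
    add_row(ep$label, "n (%) events", cells,
            cl_cell = if (has_cl) fmt_n_pct(sum(ev[!dat$is_cl]),
                                            sum(!dat$is_cl)) else "",
            p_value = p_all, p_cl = p_cl)
    for (yr in ep$at) {
      cells <- lapply(groups, function(g) {
        sel <- dat$group == g
        km <- km_at(kaplan_meier(tm[sel], ev[sel]), yr)
        if (is.na(km$survival)) return("-")
        sprintf("%.1f (%.1f-%.1f)", 100 * km$survival,
                100 * km$ci_low, 100 * km$ci_high)
      })
      names(cells) <- groups
      rest_cell <- if (has_cl) {
        km <- km_at(kaplan_meier(tm[!dat$is_cl], ev[!dat$is_cl]), yr)
        if (is.na(km$survival)) "-" else
          sprintf("%.1f (%.1f-%.1f)", 100 * km$survival,
                  100 * km$ci_low, 100 * km$ci_high)
      } else ""
      add_row(ep$label, sprintf("%d-year", yr), cells, cl_cell = rest_cell)
    }
  }

  tab <- do.call(rbind, rows)
  structure(list(table = tab, details = details, note = note,
                 groups = groups),
            class = "characteristics_table")
}

# one binary characteristic row: "n (pct)" per group + chi-square tests
binary_row <- function(variable, level, val, dat, groups, has_cl,
                       add_row, safe_p) {
  cells <- lapply(groups, function(g) {
    v <- val[dat$group == g]
    fmt_n_pct(sum(v, na.rm = TRUE), max(1, sum(!is.na(v))))
  })
  names(cells) <- groups
  ok <- !is.na(val)
  p_all <- safe_p(chi_square_test(table(dat$group[ok], val[ok]))$p_value)
  p_cl <- if (has_cl)
    safe_p(chi_square_test(table(dat$is_cl[ok], val[ok]))$p_value)
  else NA_real_
  rest <- val[!dat$is_cl]
  add_row(variable, level, cells,
          cl_cell = if (has_cl)
            fmt_n_pct(sum(rest, na.rm = TRUE), max(1, sum(!is.na(rest))))
          else "",
          p_value = p_all, p_cl = p_cl)
}

binary_details <- function(val, group) {
  list(n = tapply(val, group, function(v) sum(v, na.rm = TRUE)),
       denom = tapply(val, group, function(v) sum(!is.na(v))))
}

#' @export
print.characteristics_table <- function(x, ...) {
  print(x$table, right = FALSE)
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}
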