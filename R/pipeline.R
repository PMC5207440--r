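#' Classify the bundled cell-line Allred profiles
#'
#' Runs the surrogate IHC decision rule on the 9 bundled cell-line
#' profiles (no Ki67 is available for the lines, so hormone-receptor-
#' positive, HER2-negative lines whose luminal A/B split would need Ki67
#' come out unclassified - the claudin-low and HER2-driven calls do not
#' depend on Ki67).
#'
#' @param rules a [marker_cutoff_rules()].
#' @return Data frame: `cell_line`, `declared_subtype`, `call`, `reason`.
#' @export
classify_cell_lines <- function(rules = marker_cutoff_rules()) {
  lines <- load_table2_cell_lines()
  markers <- setdiff(names(lines), c("cell_line", "declared_subtype"))
  calls <- lapply(seq_len(nrow(lines)), function(i) {
    scores <- stats::setNames(as.numeric(lines[i, markers]), markers)
    prof <- tumor_ihc_profile(lines$cell_line[i], scores, rules = rules)
    classify_tumor(prof, rules)
  })
  data.frame(cell_line = lines$cell_line,
             declared_subtype = lines$declared_subtype,
             call = vapply(calls, `[[`, character(1), "subtype"),
             reason = vapply(calls, `[[`, character(1), "reason"),
             stringsAsFactors = FALSE)
}

#' Re-run the in-package fixture analyses
#'
#' End-to-end check of everything that is reproducible from the bundled
#' fixtures alone: the cell-line subtype calls, the signature gene count,
#' and the printed-count percentage arithmetic of the cohort summaries.
#'
#' @return List: `cell_line_calls` (data frame from
#'   [classify_cell_lines()]), `signature_n` (number of signature genes),
#'   `arithmetic` (data frame of numerator, denominator and the one-decimal
#'   percentage produced by [percent_of()]).
#' @export
reproduce_fixtures <- function() {
  calls <- classify_cell_lines()
  sig <- load_table1_signature()
  counts <- data.frame(
    quantity = c("claudin-low of cohort", "unclassified of cohort",
                 "classified of compendium", "claudin-low local recurrences",
                 "claudin-low grade III", "claudin-low ALDH1 positive",
                 "claudin-low circumscribed margins"),
    numerator = c(79, 166, 1196, 1, 49, 12, 35),
    denominator = c(942, 942, 1593, 79, 72, 70, 79),
    stringsAsFactors = FALSE)
  counts$percent <- percent_of(counts$numerator, counts$denominator)
  list(cell_line_calls = calls, signature_n = nrow(sig),
       arithmetic = counts)
}

#' Run the full synthetic-analysis pipeline
#'
#' Wires the stages end to end on synthetic data: simulate an expression
#' compendium, housekeeping QC, centroid training and compendium
#' classification, claudin-low signature derivation, IHC cohort simulation
#' and classification, and the clinical characteristics report. Every
#' output is written under `output_dir` and listed, with its MD5 hash, in
#' a JSON manifest; rerunning with the same configuration and seed
#' reproduces identical hashes.
#'
#' @param config either a list or the path of a YAML file with (all
#'   optional) entries `seed`, `output_dir`, `expression` (arguments for
#'   [expression_sim_config()]), `qc` (`threshold`, `min_fraction`),
#'   `cutoff` (centroid assignment cutoff), `signature` (`fold_change_min`,
#'   `alpha`), and `cohort` (arguments for [cohort_sim_config()]).
#' @return Invisibly, a list with `status` (0 on success), `manifest`
#'   (file -> MD5 map) and the in-memory stage results.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  outdir <- config$output_dir %||% tempfile("claudinlow_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(name) files[[length(files) + 1]] <<- file.path(outdir, name)

  # stage 1: expression compendium
  expr_cfg <- do.call(expression_sim_config,
                      c(config$expression %||% list(),
                        if (is.null(config$expression$seed))
                          list(seed = split_seed(seed, "expression"))))
  compendium <- simulate_expression_compendium(expr_cfg)
  emit("expression_matrix.tsv")
  write_expression_matrix(compendium, file.path(outdir, "expression_matrix.tsv"))

  # stage 2: housekeeping QC
  qc_cfg <- config$qc %||% list()
  qc <- housekeeping_filter(compendium,
                            threshold = qc_cfg$threshold %||% 0.95,
                            min_fraction = qc_cfg$min_fraction %||% 0.5)
  emit("qc_kept_samples.txt")
  writeLines(qc$kept, file.path(outdir, "qc_kept_samples.txt"))
  emit("qc_pass_counts.tsv")
  utils::write.table(
    data.frame(sample_id = names(qc$pass_counts),
               pass_count = qc$pass_counts, row.names = NULL),
    file.path(outdir, "qc_pass_counts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 3: centroid subtyping of the QC-passed compendium
  keep <- colnames(compendium$values) %in% qc$kept
  passed <- expression_matrix(compendium$values[, keep, drop = FALSE],
                              batch = compendium$batch[keep],
                              subtype = compendium$subtype[keep])
  attr(passed, "classifier_genes") <- attr(compendium, "classifier_genes")
  centroids <- train_centroids(passed)
  cls <- classify_compendium(passed, centroids,
                             cutoff = config$cutoff %||% 0.3)
  emit("expression_subtype_calls.tsv")
  utils::write.table(cls$assignments,
                     file.path(outdir, "expression_subtype_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 4: claudin-low signature
  sig_cfg <- config$signature %||% list()
  sig <- derive_cl_signature(passed,
                             fold_change_min = sig_cfg$fold_change_min %||% 2,
                             alpha = sig_cfg$alpha %||% 0.05)
  emit("cl_signature.csv")
  write_signature(sig, file.path(outdir, "cl_signature.csv"))

  # stage 5: IHC cohort
  cohort_cfg <- do.call(cohort_sim_config,
                        c(config$cohort %||% list(),
                          if (is.null(config$cohort$seed))
                            list(seed = split_seed(seed, "cohort"))))
  cohort <- simulate_ihc_cohort(cohort_cfg)
  emit("cohort_cores.csv")
  write_core_scores(cohort$cores, file.path(outdir, "cohort_cores.csv"))
  emit("cohort_clinical.csv")
  write_clinical(cohort$clinical, file.path(outdir, "cohort_clinical.csv"))
  ihc <- classify_cohort(cohort$cores, cohort$clinical)
  emit("ihc_subtype_calls.csv")
  utils::write.csv(ihc$calls, file.path(outdir, "ihc_subtype_calls.csv"),
                   row.names = FALSE, quote = FALSE)
  emit("ihc_subtype_frequency.csv")
  utils::write.csv(ihc$frequency,
                   file.path(outdir, "ihc_subtype_frequency.csv"),
                   row.names = FALSE, quote = FALSE)

  # stage 6: characteristics report
  report <- build_characteristics_table(ihc$calls, cohort$clinical)
  emit("characteristics_table.tsv")
  utils::write.table(report$table,
                     file.path(outdir, "characteristics_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  paths <- unlist(files)
  manifest <- as.list(stats::setNames(tools::md5sum(paths), basename(paths)))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(list(seed = seed, files = manifest), manifest_path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(status = 0L, manifest = manifest, output_dir = outdir,
                 qc = qc, classification = cls, signature = sig,
                 ihc = ihc, report = report))
}
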