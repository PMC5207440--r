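#' Construct an expression matrix object
#'
#' A light container for a genes-by-samples matrix of log2-scale expression
#' values with optional per-sample batch and molecular-subtype labels.
#' Values are assumed to be already normalised and on the log2 scale; no
#' transformation is applied.
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids). All values must be finite.
#' @param batch optional character vector of per-sample batch labels.
#' @param subtype optional character vector of per-sample subtype labels
#'   (`NA` for unlabeled samples).
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `batch` and `subtype`.
#' @export
expression_matrix <- function(values, batch = NULL, subtype = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (ncol(values) > 0 && is.null(colnames(values)))
    stop("'values' must have sample ids as colnames")
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("'values' must have gene symbols as rownames")
  if (is.null(colnames(values)))
    colnames(values) <- character(0)
  if (is.null(rownames(values)))
    rownames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix")
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  check_lab <- function(lab, what) {
    if (is.null(lab)) return(NULL)
    if (length(lab) != ncol(values))
      stop(sprintf("'%s' must have one entry per sample", what))
    as.character(lab)
  }
  structure(list(values = values,
                 batch = check_lab(batch, "batch"),
                 subtype = check_lab(subtype, "subtype")),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$batch))
    cat(sprintf("  batches: %s\n", paste(unique(x$batch), collapse = ", ")))
  if (!is.null(x$subtype)) {
    tab <- table(x$subtype, useNA = "ifany")
    cat(sprintf("  subtypes: %s\n",
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read a tab-delimited expression matrix
#'
#' Expects sample ids in the header row and gene symbols in the first
#' column, with a numeric body. Duplicate gene symbols are collapsed to a
#' single row by taking the per-sample maximum (a message reports how many
#' rows were collapsed); duplicate sample ids are an error, as is any cell
#' that does not parse as a finite number (including literal "NA").
#'
#' @param path path to a tab-delimited text file.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dat <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(dat) < 2) stop("expression file needs a gene column plus >= 1 sample")
  genes <- dat[[1]]
  samples <- colnames(dat)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  body <- as.matrix(dat[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                 body[bad[1, 1], bad[1, 2]], genes[bad[1, 1]],
                 samples[bad[1, 2]]))
  }
  dimnames(num) <- list(genes, samples)
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    num <- do.call(rbind, lapply(split(seq_along(genes), genes), function(i) {
      apply(num[i, , drop = FALSE], 2, max)
    }))
    # split() orders by symbol; keep first-appearance order of the input
    num <- num[unique(genes), , drop = FALSE]
    message(sprintf("collapsed %d duplicate gene row(s) by per-sample maximum",
                    n_dup))
  }
  expression_matrix(num)
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [read_expression_matrix()]: header row of sample ids, gene
#' symbols in the first column (headed `gene`).
#'
#' @param x an `expr_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  out <- data.frame(gene = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load the bundled 60-gene claudin-low signature
#'
#' The published signature distinguishing claudin-low tumors from all other
#' molecular subtypes: 23 genes up-regulated and 37 down-regulated in
#' claudin-low tumors. Shipped as a plain-text fixture.
#'
#' @return Data frame with columns `symbol` and `direction` (`"up"`/`"down"`,
#'   relative to claudin-low vs all other subtypes).
#' @export
load_table1_signature <- function() {
  path <- system.file("extdata", "cl_signature_60genes.csv",
                      package = "claudinlow", mustWork = TRUE)
  read_signature(path)
}

#' Read / write a claudin-low signature file
#'
#' CSV with columns `symbol` and `direction`; directions must be `"up"` or
#' `"down"` and symbols unique.
#'
#' @param path file path.
#' @return `read_signature`: data frame with columns `symbol`, `direction`.
#' @export
read_signature <- function(path) {
  sig <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("symbol", "direction") %in% names(sig)))
    stop("signature file needs columns 'symbol' and 'direction'")
  if (!all(sig$direction %in% c("up", "down")))
    stop("signature directions must be 'up' or 'down'")
  if (anyDuplicated(sig$symbol))
    stop("duplicate symbols in signature file")
  sig[, c("symbol", "direction")]
}

#' @param sig data frame with columns `symbol` and `direction`.
#' @rdname read_signature
#' @return `write_signature`: `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  stopifnot(all(c("symbol", "direction") %in% names(sig)))
  utils::write.csv(sig[, c("symbol", "direction")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Load the bundled cell-line Allred profiles
#'
#' Immunohistochemical Allred scores (0 or 2-8) for 10 markers across 9
#' breast cancer cell lines of known molecular subtype (5 luminal, 2
#' basal-like, 2 claudin-low), as printed in the source study. These
#' profiles anchor the surrogate IHC classifier: applied to them it must
#' call exactly BT549 and MDA-MB-231 claudin-low.
#'
#' @return Data frame with columns `cell_line`, `declared_subtype` and one
#'   column per marker (`ER`, `PR`, `HER2`, `CK5`, `EGFR`, `CLDN3`, `CLDN4`,
#'   `CLDN7`, `ECAD`, `CD24`).
#' @export
load_table2_cell_lines <- function() {
  path <- system.file("extdata", "cell_line_allred_profiles.csv",
                      package = "claudinlow", mustWork = TRUE)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  markers <- setdiff(names(dat), c("cell_line", "declared_subtype"))
  for (m in markers) {
    if (!all(dat[[m]] %in% c(0L, 2:8)))
      stop("invalid Allred score in fixture, marker ", m)
  }
  dat
}

#' Read / write core-level IHC score tables
#'
#' CSV with one row per (tumor, core, marker): columns `tumor_id`,
#' `core_index` (1-3), `marker`, `allred_raw` (0 or 2-8; empty when the
#' channel is Ki67 or the core was lost), optional `ki67_percent` (0-100,
#' for `marker == "KI67"` rows) and `fish_ratio` (positive, on HER2 rows).
#' Missing cores are absent rows, never zero scores (0 is a legitimate
#' Allred score).
#'
#' @param path file path.
#' @return `read_core_scores`: validated data frame.
#' @export
read_core_scores <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_core_scores(dat)
}

#' @param cores core-score data frame as described above.
#' @rdname read_core_scores
#' @export
write_core_scores <- function(cores, path) {
  validate_core_scores(cores)
  utils::write.csv(cores, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

validate_core_scores <- function(dat) {
  need <- c("tumor_id", "core_index", "marker", "allred_raw")
  if (!all(need %in% names(dat)))
    stop("core score table needs columns: ", paste(need, collapse = ", "))
  if (!"ki67_percent" %in% names(dat))
    dat$ki67_percent <- rep(NA_real_, nrow(dat))
  if (!"fish_ratio" %in% names(dat))
    dat$fish_ratio <- rep(NA_real_, nrow(dat))
  if (!all(dat$core_index %in% 1:3)) stop("core_index must be 1, 2 or 3")
  ok_raw <- is.na(dat$allred_raw) | dat$allred_raw %in% c(0, 2:8)
  if (!all(ok_raw))
    stop("allred_raw must be 0 or 2-8 (never 1); offending rows: ",
         paste(utils::head(which(!ok_raw)), collapse = ", "))
  ok_marker <- dat$marker %in% c(allred_markers(), "KI67")
  if (!all(ok_marker))
    stop("unknown marker(s): ",
         paste(unique(dat$marker[!ok_marker]), collapse = ", "))
  k <- !is.na(dat$ki67_percent)
  if (any(dat$ki67_percent[k] < 0 | dat$ki67_percent[k] > 100))
    stop("ki67_percent must be within 0-100")
  f <- !is.na(dat$fish_ratio)
  if (any(dat$fish_ratio[f] <= 0)) stop("fish_ratio must be positive")
  dat
}

#' Read / write clinical outcome tables
#'
#' CSV keyed by `tumor_id` carrying the covariates and the three endpoints
#' used in the cohort analysis: overall survival (`os_*`), disease-free
#' survival (`dfs_*`) and local recurrence (`lr_*`), each as a time in
#' years plus a 0/1 event indicator.
#'
#' @param path file path.
#' @return `read_clinical`: validated data frame.
#' @export
read_clinical <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clinical(dat)
}

#' @param clinical clinical data frame.
#' @rdname read_clinical
#' @export
write_clinical <- function(clinical, path) {
  validate_clinical(clinical)
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

validate_clinical <- function(dat) {
  need <- c("tumor_id", "os_time", "os_event", "dfs_time", "dfs_event",
            "lr_time", "lr_event")
  if (!all(need %in% names(dat)))
    stop("clinical table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(dat$tumor_id)) stop("duplicate tumor_id in clinical table")
  for (tm in c("os_time", "dfs_time", "lr_time"))
    if (any(dat[[tm]] < 0, na.rm = TRUE)) stop(tm, " must be non-negative")
  for (ev in c("os_event", "dfs_event", "lr_event"))
    if (!all(dat[[ev]] %in% c(0, 1, NA))) stop(ev, " must be 0/1")
  if ("grade" %in% names(dat) &&
      !all(dat$grade %in% c("I", "II", "III", NA)))
    stop("grade must be I, II or III")
  dat
}
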