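#' Percentage of a count, rounded to one decimal
#'
#' The formatting convention used in cohort summary tables: `100 * n / d`
#' rounded to `digits` decimal places (so 79 of 942 prints as 8.4).
#'
#' @param n numerator count(s).
#' @param d denominator count(s); must be positive.
#' @param digits decimal places (default 1).
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' percent_of(79, 942)   # 8.4
#' percent_of(1196, 1593) # 75.1
percent_of <- function(n, d, digits = 1) {
  stopifnot(is.numeric(n), is.numeric(d), all(d > 0))
  round(100 * n / d, digits)
}

# "n (pct)" cell used in characteristics tables
fmt_n_pct <- function(n, d, digits = 1) {
  sprintf("%d (%.*f)", n, digits, percent_of(n, d, digits))
}

# Deterministic substream seeds from one global seed. Each named stage gets
# its own seed so adding a stage never perturbs the draws of earlier stages.
split_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1, is.finite(seed))
  if (is.character(stream)) {
    stream <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  }
  as.integer((as.numeric(seed) %% 69999989 * 2654435 + stream * 40503 + 1) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
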