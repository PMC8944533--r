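# Reference summary tables from a nine-month observational study on two
# New Zealand pasture-based dairy farms (rotary parlours, DairyNZ 0-3
# locomotion scale, every third cow in-parlour scored), shipped as plain-text
# CSVs. They are the inputs from which the published descriptive and
# classifier statistics can be recomputed, and the calibration source for the
# synthetic-herd presets.

study_file <- function(name) {
  system.file("extdata", name, package = "parlourscore", mustWork = TRUE)
}

#' Reference study tables
#'
#' Monthly summary counts from the two-farm reference study:
#' `study_ls_counts()` gives per-farm, per-month locomotion score counts
#' (3006 scored observations on farm 1, 1119 on farm 2, 4125 pooled);
#' `study_indicator_counts()` gives per-farm, per-month absent/present counts
#' for each in-parlour indicator together with the distribution of the number
#' of positive indicators per cow (`total0`-`total3`; no cow showed all
#' four); `study_confusion_matrix()` gives the held-out confusion matrix of
#' the study's best cross-validated decision-tree classifier (1030 test
#' observations).
#'
#' @return `study_ls_counts()` and `study_indicator_counts()` return tibbles
#'   of counts; `study_confusion_matrix()` returns a [confusion_matrix3()].
#' @export
#' @examples
#' sum(dplyr::select(study_ls_counts(), ls0:ls3))  # 4125 observations
study_ls_counts <- function() {
  readr::read_csv(study_file("study_ls_counts.csv"),
                  col_types = readr::cols(
                    farm = readr::col_character(),
                    .default = readr::col_integer()
                  ))
}

#' @rdname study_ls_counts
#' @export
study_indicator_counts <- function() {
  readr::read_csv(study_file("study_indicator_counts.csv"),
                  col_types = readr::cols(
                    farm = readr::col_character(),
                    .default = readr::col_integer()
                  ))
}

#' @rdname study_ls_counts
#' @export
study_confusion_matrix <- function() {
  raw <- readr::read_csv(study_file("study_confusion.csv"),
                         col_types = readr::cols(
                           truth = readr::col_character(),
                           .default = readr::col_integer()
                         ))
  confusion_matrix3_from_counts(as.matrix(raw[, -1L]))
}

#' Reconstruct a 2x2 screening table from marginal counts
#'
#' Recovers the unpublished joint 2x2 table of a screening rule against the
#' lame reference from its marginals: the number of lame cows, the number of
#' screening-positive cows, the total, and the sensitivity as reported to one
#' decimal on the percent scale. The true-positive count is the unique integer
#' consistent with the rounded sensitivity (a rounding-consistency search);
#' an error is raised if no integer, or more than one, is consistent.
#'
#' @param n_lame Number of reference-positive (lame) observations.
#' @param n_positive Number of screening-positive observations.
#' @param n_total Total observations.
#' @param sensitivity_pct Reported sensitivity, percent, one decimal.
#' @return A `contingency_2x2` (see [contingency_table()]).
#' @export
#' @examples
#' # composite ">= 2 indicators" rule: 133 lame, 181 positive of 4125,
#' # reported sensitivity 93.2% -> TP = 124
#' reconstruct_composite_table(133, 181, 4125, 93.2)
reconstruct_composite_table <- function(n_lame, n_positive, n_total,
                                        sensitivity_pct) {
  lo <- max(0L, n_positive - (n_total - n_lame))
  hi <- min(n_lame, n_positive)
  candidates <- lo:hi
  ok <- abs(100 * candidates / n_lame - sensitivity_pct) < 0.05
  if (sum(ok) != 1L) {
    abort("Marginals and rounded sensitivity do not identify a unique table.",
          class = "parlourscore_validation_error")
  }
  tp <- candidates[ok]
  contingency_table(
    tp = tp, fp = n_positive - tp, fn = n_lame - tp,
    tn = n_total - n_lame - (n_positive - tp)
  )
}

#' Round half-up on the percent scale
#'
#' Converts a proportion to a percentage rounded half-up to one decimal place
#' — the convention used by the rendered report tables, where `0.96602`
#' prints as `96.6`.
#'
#' @param p Proportion(s) in `[0, 1]`.
#' @return Percentages rounded half-up to one decimal.
#' @export
#' @examples
#' percent_1dp(995 / 1030)
percent_1dp <- function(p) {
  trunc(1000 * p + 0.5) / 10
}
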