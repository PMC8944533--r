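#' Pair locomotion-score and in-parlour records
#'
#' Inner join of locomotion-score records and in-parlour indicator records on
#' `(farm, month, cow_id)` — only cows with a locomotion score followed by an
#' in-parlour score contribute to the analysis. Unmatched records on either
#' side are dropped and counted in a join report attached to the result.
#'
#' @param ls_records Data frame with `farm`, `month`, `cow_id`, `ls`.
#' @param ips_records Data frame with `farm`, `month`, `cow_id` and the four
#'   indicator columns `sw`, `awd`, `shh`, `oh` (optionally `oci`, `scb`,
#'   `ab`).
#' @return A tibble of matched observations carrying a `join_report`
#'   attribute; retrieve it with [join_report()].
#' @export
#' @examples
#' sim <- simulate_herd(herd_config(n_cows = 50, n_visits = 1, seed = 3))
#' matched <- pair_records(
#'   dplyr::select(sim, farm, month, cow_id, ls),
#'   dplyr::select(sim, -ls)
#' )
#' join_report(matched)
pair_records <- function(ls_records, ips_records) {
  key <- c("farm", "month", "cow_id")
  check_columns(ls_records, c(key, "ls"), "ls_records")
  check_columns(ips_records, c(key, IPS_INDICATORS), "ips_records")
  check_unique_key(ls_records, key, "ls_records")
  check_unique_key(ips_records, key, "ips_records")
  matched <- dplyr::inner_join(ls_records, ips_records, by = key)
  if (anyNA(matched$ls) || anyNA(matched[IPS_INDICATORS])) {
    abort("Matched records must have non-missing `ls` and indicator flags.",
          class = "parlourscore_validation_error")
  }
  report <- list(
    matched = nrow(matched),
    ls_only = nrow(dplyr::anti_join(ls_records, ips_records, by = key)),
    ips_only = nrow(dplyr::anti_join(ips_records, ls_records, by = key))
  )
  attr(matched, "join_report") <- report
  matched
}

#' @rdname pair_records
#' @param matched A tibble returned by [pair_records()].
#' @export
join_report <- function(matched) {
  attr(matched, "join_report") %||%
    abort("No join report: was this tibble produced by `pair_records()`?",
          class = "parlourscore_validation_error")
}

check_columns <- function(data, cols, arg) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(paste0("`", arg, "` lacks column(s): ", paste(missing, collapse = ", ")),
          class = "parlourscore_validation_error")
  }
  invisible(data)
}

check_unique_key <- function(data, key, arg) {
  dups <- data |>
    dplyr::count(dplyr::across(dplyr::all_of(key))) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dups)) {
    k <- dups[1L, key]
    abort(paste0("Duplicate key in `", arg, "`: farm=", k$farm,
                 ", month=", k$month, ", cow_id=", k$cow_id),
          class = "parlourscore_validation_error")
  }
  invisible(data)
}

#' Count positive in-parlour indicators
#'
#' The composite score of an observation: the number of the four analysed
#' indicators (SW, AWD, SHH, OH) that are present, 0-4.
#'
#' @param data Data frame with binary columns `sw`, `awd`, `shh`, `oh`.
#' @return Integer vector of per-row indicator counts.
#' @export
#' @examples
#' indicator_count(data.frame(sw = 1, awd = 0, shh = 1, oh = 0))
indicator_count <- function(data) {
  check_columns(data, IPS_INDICATORS, "data")
  flags <- as.matrix(data[IPS_INDICATORS])
  if (anyNA(flags) || !all(flags %in% c(0L, 1L))) {
    abort("Indicator flags must be 0/1 with no missing values.",
          class = "parlourscore_validation_error")
  }
  as.integer(rowSums(flags))
}

#' Composite indicator-count classification
#'
#' Classifies each observation as screening-positive from its indicator count:
#' in `"at_least"` mode a cow is positive when `k` or more indicators are
#' present (the thresholds evaluated in the study are \eqn{\ge 1}, \eqn{\ge 2},
#' \eqn{\ge 3}); in `"exactly"` mode when exactly `k` are present (the study's
#' "three indicators" row equals the \eqn{\ge 3} rule only because no cow
#' showed all four).
#'
#' @inheritParams indicator_count
#' @param k Integer threshold in `1:4`.
#' @param mode `"at_least"` (default) or `"exactly"`.
#' @return Integer 0/1 vector of test-positive flags.
#' @export
#' @examples
#' classify_composite(data.frame(sw = 0, awd = 0, shh = 1, oh = 1), k = 2)
classify_composite <- function(data, k, mode = c("at_least", "exactly")) {
  mode <- match.arg(mode)
  if (length(k) != 1L || is.na(k) || !k %in% 1:4) {
    abort("`k` must be an integer in 1..4.", class = "parlourscore_argument_error")
  }
  count <- indicator_count(data)
  if (mode == "at_least") as.integer(count >= k) else as.integer(count == k)
}

#' Amalgamate locomotion scores into the lame reference flag
#'
#' Scores 2 (lame) and 3 (severely lame) are amalgamated into a single lame
#' class — the reference standard for all diagnostic statistics.
#'
#' @param ls Integer vector of locomotion scores in `0:3`.
#' @return Integer 0/1 vector: 1 when `ls >= 2`.
#' @export
#' @examples
#' amalgamate_ls(0:3)
amalgamate_ls <- function(ls) {
  if (anyNA(ls) || !all(ls %in% 0:3)) {
    abort("`ls` must be locomotion scores in 0..3.",
          class = "parlourscore_validation_error")
  }
  as.integer(ls >= 2L)
}

#' Three-class locomotion outcome
#'
#' Maps locomotion scores to the outcome classified by the decision tree:
#' `"0"`, `"1"`, or `">=2"` (scores 2 and 3 amalgamated).
#'
#' @inheritParams amalgamate_ls
#' @return Factor with levels `"0"`, `"1"`, `">=2"`.
#' @export
#' @examples
#' ls_class3(c(0, 1, 2, 3))
ls_class3 <- function(ls) {
  if (anyNA(ls) || !all(ls %in% 0:3)) {
    abort("`ls` must be locomotion scores in 0..3.",
          class = "parlourscore_validation_error")
  }
  factor(LS_CLASSES[pmin(as.integer(ls), 2L) + 1L], levels = LS_CLASSES)
}
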