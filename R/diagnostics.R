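#' Build a 2x2 contingency table against the lame reference
#'
#' Cross-classifies a binary screening result against the binary lame
#' reference (locomotion score >= 2). `contingency()` counts from paired
#' vectors; `contingency_table()` constructs the same object from the four
#' cell counts directly (e.g. counts reconstructed from published marginals).
#'
#' @param test_positive Binary 0/1 vector of screening results.
#' @param lame Binary 0/1 vector of the reference standard, same length.
#' @return A `contingency_2x2` object: list with `tp`, `fp`, `fn`, `tn`.
#' @export
#' @examples
#' contingency(c(1, 0, 1, 0), c(1, 0, 0, 0))
#' contingency_table(tp = 124, fp = 57, fn = 9, tn = 3935)
contingency <- function(test_positive, lame) {
  if (length(test_positive) != length(lame)) {
    abort("`test_positive` and `lame` must have equal length.",
          class = "parlourscore_validation_error")
  }
  if (anyNA(test_positive) || anyNA(lame) ||
      !all(test_positive %in% 0:1) || !all(lame %in% 0:1)) {
    abort("Inputs must be binary 0/1 with no missing values.",
          class = "parlourscore_validation_error")
  }
  contingency_table(
    tp = sum(test_positive == 1L & lame == 1L),
    fp = sum(test_positive == 1L & lame == 0L),
    fn = sum(test_positive == 0L & lame == 1L),
    tn = sum(test_positive == 0L & lame == 0L)
  )
}

#' @rdname contingency
#' @param tp,fp,fn,tn Non-negative cell counts (true/false positives,
#'   false/true negatives).
#' @export
contingency_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    abort("Cell counts must be non-negative integers.",
          class = "parlourscore_validation_error")
  }
  if (sum(cells) == 0) {
    abort("The table must contain at least one observation.",
          class = "parlourscore_validation_error")
  }
  cells <- as.integer(cells)
  structure(list(tp = cells[1L], fp = cells[2L], fn = cells[3L], tn = cells[4L]),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2L, 2L,
              dimnames = list(test = c("positive", "negative"),
                              reference = c("lame", "not lame")))
  print(m)
  invisible(x)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact (beta-quantile) interval for a binomial proportion: lower bound
#' `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`), upper bound
#' `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`). Coverage is
#' conservative (at least nominal).
#'
#' @param x Number of successes (vectorised).
#' @param n Number of trials.
#' @param level Confidence level, default 0.95.
#' @return A tibble with columns `estimate`, `lower`, `upper`.
#' @export
#' @examples
#' clopper_pearson_ci(133, 133)  # lower bound 0.973
clopper_pearson_ci <- function(x, n, level = 0.95) {
  if (anyNA(x) || anyNA(n) || any(n < 1) || any(x < 0) || any(x > n)) {
    abort("Require 0 <= x <= n and n >= 1.", class = "parlourscore_argument_error")
  }
  alpha <- 1 - level
  lower <- ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1))
  upper <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  tibble::tibble(estimate = x / n, lower = lower, upper = upper)
}

#' Standard-logit confidence interval for a proportion
#'
#' Wald interval on the logit scale, back-transformed — the conventional
#' interval for predictive values. Degenerate proportions (`x = 0` or
#' `x = n`) have no logit-scale interval and return `NA` bounds, which the
#' rendered reports print as a bare point estimate.
#'
#' @inheritParams clopper_pearson_ci
#' @return A tibble with columns `estimate`, `lower`, `upper`.
#' @export
standard_logit_ci <- function(x, n, level = 0.95) {
  if (anyNA(x) || anyNA(n) || any(n < 1) || any(x < 0) || any(x > n)) {
    abort("Require 0 <= x <= n and n >= 1.", class = "parlourscore_argument_error")
  }
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  degenerate <- x == 0 | x == n
  se <- ifelse(degenerate, NA_real_, sqrt(1 / x + 1 / (n - x)))
  lo <- stats::plogis(stats::qlogis(p) - z * se)
  hi <- stats::plogis(stats::qlogis(p) + z * se)
  tibble::tibble(estimate = p,
                 lower = ifelse(degenerate, NA_real_, lo),
                 upper = ifelse(degenerate, NA_real_, hi))
}

#' Diagnostic test metrics with confidence intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)` from a 2x2
#' table against the lame reference. Sensitivity and specificity intervals are
#' Clopper-Pearson exact; predictive-value intervals use the standard-logit
#' method. A metric with a zero denominator is reported with `NA` estimate and
#' bounds (undefined, never coerced to 0 or 1); the remaining metrics are
#' still returned.
#'
#' @param table A `contingency_2x2` from [contingency()] or
#'   [contingency_table()].
#' @param level Confidence level, default 0.95.
#' @return A tibble with one row per metric (`se`, `sp`, `ppv`, `npv`) and
#'   columns `metric`, `x`, `n`, `estimate`, `conf.low`, `conf.high`,
#'   `method`.
#' @export
#' @examples
#' test_metrics(contingency_table(tp = 124, fp = 57, fn = 9, tn = 3935))
test_metrics <- function(table, level = 0.95) {
  if (!inherits(table, "contingency_2x2")) {
    abort("`table` must be a `contingency_2x2` object.",
          class = "parlourscore_validation_error")
  }
  spec <- tibble::tibble(
    metric = c("se", "sp", "ppv", "npv"),
    x = c(table$tp, table$tn, table$tp, table$tn),
    n = c(table$tp + table$fn, table$tn + table$fp,
          table$tp + table$fp, table$tn + table$fn),
    method = c("clopper-pearson", "clopper-pearson", "logit", "logit")
  )
  one <- function(x, n, method) {
    if (n == 0L) {
      return(tibble::tibble(estimate = NA_real_, lower = NA_real_, upper = NA_real_))
    }
    if (method == "clopper-pearson") clopper_pearson_ci(x, n, level)
    else standard_logit_ci(x, n, level)
  }
  ci <- purrr::pmap(spec[c("x", "n", "method")],
                    function(x, n, method) one(x, n, method)) |>
    dplyr::bind_rows()
  out <- dplyr::bind_cols(spec, ci) |>
    dplyr::rename(conf.low = "lower", conf.high = "upper") |>
    dplyr::relocate("method", .after = "conf.high")
  attr(out, "level") <- level
  class(out) <- c("ips_test_metrics", class(out))
  out
}

#' Phi coefficient of a 2x2 table
#'
#' Association between two binary variables:
#' \eqn{\phi = (ad - bc) / \sqrt{(a+b)(c+d)(a+c)(b+d)}}, identical to the
#' Pearson correlation of the two 0/1 columns. Undefined (returned as `NA`
#' with a warning) when any margin is zero.
#'
#' @param a,b,c,d Cell counts: `a` = both present, `b` = first only,
#'   `c` = second only, `d` = both absent.
#' @return Phi in `[-1, 1]`, or `NA` if undefined.
#' @export
#' @examples
#' phi_coefficient(2, 1, 1, 2)  # 1/3
phi_coefficient <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0)) {
    abort("Cell counts must be non-negative.", class = "parlourscore_argument_error")
  }
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    warn("Phi undefined: a margin of the 2x2 table is zero.")
    return(NA_real_)
  }
  (a * d - b * c) / sqrt(prod(margins))
}

phi_binary <- function(x, y) {
  phi_coefficient(
    a = sum(x == 1L & y == 1L), b = sum(x == 1L & y == 0L),
    c = sum(x == 0L & y == 1L), d = sum(x == 0L & y == 0L)
  )
}

#' Phi association screen of indicators and the lame flag
#'
#' Pairwise Phi coefficients among the four in-parlour indicators and between
#' each indicator and the lame reference (LS >= 2) — the collinearity screen
#' run before tree fitting. Pairs involving a constant column are undefined
#' and returned as `NA`.
#'
#' @param data Matched observations with columns `sw`, `awd`, `shh`, `oh`,
#'   `ls`.
#' @return A symmetric `phi_matrix` with labels
#'   `SW, AWD, SHH, OH, LS>=2` and `NA` diagonal. Use [tidy()] for a long
#'   tibble or [autoplot()] for a tile plot.
#' @export
#' @examples
#' sim <- simulate_herd(herd_config(n_cows = 300, n_visits = 3, seed = 9))
#' phi_screen(sim)
phi_screen <- function(data) {
  check_columns(data, c(IPS_INDICATORS, "ls"), "data")
  if (nrow(data) == 0L) {
    abort("`data` must be non-empty.", class = "parlourscore_validation_error")
  }
  cols <- c(
    as.list(data[IPS_INDICATORS]),
    list(lame = amalgamate_ls(data$ls))
  )
  labels <- c(toupper(IPS_INDICATORS), "LS>=2")
  k <- length(cols)
  m <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      v <- suppressWarnings(phi_binary(cols[[i]], cols[[j]]))
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  structure(m, class = c("phi_matrix", "matrix"))
}

#' @export
print.phi_matrix <- function(x, digits = 3, ...) {
  cat("Phi association screen\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' @method tidy phi_matrix
#' @export
tidy.phi_matrix <- function(x, ...) {
  m <- unclass(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(
    var1 = rownames(m)[idx[, 1L]],
    var2 = colnames(m)[idx[, 2L]],
    phi = m[idx]
  )
}

#' Prevalence summary by farm
#'
#' Per-farm and pooled distribution of locomotion scores, lameness prevalence
#' (share of LS >= 2), and the share of cows screening positive on the
#' "two or more indicators" composite rule. Values are returned at full
#' precision; rendered reports round to one decimal on the percent scale.
#'
#' @param data Matched observations with `farm`, `ls` and the four indicator
#'   columns.
#' @return A tibble with one row per farm plus a `"pooled"` row.
#' @export
prevalence_summary <- function(data) {
  check_columns(data, c("farm", "ls", IPS_INDICATORS), "data")
  summarise_one <- function(d, label) {
    n <- nrow(d)
    tibble::tibble(
      farm = label,
      n = n,
      ls0 = sum(d$ls == 0L) / n, ls1 = sum(d$ls == 1L) / n,
      ls2 = sum(d$ls == 2L) / n, ls3 = sum(d$ls == 3L) / n,
      lame_prevalence = sum(amalgamate_ls(d$ls)) / n,
      ips_ge2_prevalence = sum(classify_composite(d, k = 2L)) / n
    )
  }
  per_farm <- data |>
    dplyr::group_split(.data$farm) |>
    purrr::map(~ summarise_one(.x, .x$farm[[1L]])) |>
    dplyr::bind_rows()
  dplyr::bind_rows(per_farm, summarise_one(data, "pooled"))
}

#' Composite and single-indicator diagnostics table
#'
#' The full diagnostic evaluation against the lame reference: each single
#' indicator (SW, AWD, SHH, OH) plus the composite thresholds ">= 1", ">= 2"
#' and "exactly 3" positive indicators, each with sensitivity, specificity and
#' predictive values and their confidence intervals (see [test_metrics()]).
#' The "exactly 3" row is reported in `"exactly"` mode, matching a study
#' population in which no cow showed all four indicators; set
#' `three_mode = "at_least"` for the \eqn{\ge 3} rule.
#'
#' @inheritParams prevalence_summary
#' @param level Confidence level.
#' @param three_mode Mode for the third composite row: `"exactly"` (default)
#'   or `"at_least"`.
#' @return A tibble with one row per test and columns
#'   `test`, `metric`, `x`, `n`, `estimate`, `conf.low`, `conf.high` in long
#'   form.
#' @export
composite_diagnostics <- function(data, level = 0.95,
                                  three_mode = c("exactly", "at_least")) {
  three_mode <- match.arg(three_mode)
  check_columns(data, c("ls", IPS_INDICATORS), "data")
  lame <- amalgamate_ls(data$ls)
  tests <- list(
    SW = data$sw, AWD = data$awd, SHH = data$shh, OH = data$oh,
    ">=1" = classify_composite(data, 1L),
    ">=2" = classify_composite(data, 2L),
    "3" = classify_composite(data, 3L, mode = three_mode)
  )
  purrr::imap(tests, function(flag, name) {
    tm <- test_metrics(contingency(as.integer(flag), lame), level = level)
    dplyr::mutate(tibble::as_tibble(tm), test = name, .before = 1L)
  }) |>
    dplyr::bind_rows()
}
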