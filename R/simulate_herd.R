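#' Simulate cow-visit observations for a synthetic herd
#'
#' Draws one locomotion score (0-3) per scored cow-visit from the configured
#' class distribution, then generates the four binary in-parlour indicators
#' (SW, AWD, SHH, OH) from a latent Gaussian threshold model: given class
#' \eqn{c}, the latent 4-vector has an exchangeable correlation
#' `latent_rho`, and indicator \eqn{i} is present when its latent coordinate
#' falls below the normal quantile of `indicator_probs[c, i]`. With
#' `latent_rho = 0` the indicators are conditionally independent given class;
#' degenerate probabilities 0 and 1 produce deterministic flags.
#'
#' Cow identities are drawn from a herd of `n_cows` and reused across visits,
#' but observations are treated as independent draws (matching an analysis
#' that pools repeated visits without a repeated-measures adjustment).
#'
#' @param config A [herd_config()] object.
#' @return A tibble of cow-visit observations with columns
#'   `farm, month, cow_id, ls, sw, awd, shh, oh, oci, scb, ab`. The three
#'   indicators dropped from analysis (`oci`, `scb`, `ab`) are `NA` unless
#'   `oci_prob` is set.
#' @export
#' @examples
#' sim <- simulate_herd(herd_config(n_cows = 100, n_visits = 2, seed = 42))
#' dplyr::count(sim, ls)
simulate_herd <- function(config) {
  if (!inherits(config, "herd_config")) {
    abort("`config` must be a `herd_config` object.",
          class = "parlourscore_config_error")
  }
  withr::with_seed(config$seed, {
    visits <- purrr::map(seq_len(config$n_visits), function(m) {
      order_ids <- sample.int(config$n_cows)
      if (config$sampling_step > 1L) {
        offset <- sample.int(config$sampling_step, 1L) - 1L
        order_ids <- every_kth_sampling(order_ids, config$sampling_step, offset)
      }
      if (!is.null(config$visit_sizes)) {
        order_ids <- head(order_ids, config$visit_sizes[[m]])
      }
      n <- length(order_ids)
      ls <- sample(0:3, n, replace = TRUE, prob = config$class_probs)
      flags <- draw_indicators(ls, config$indicator_probs, config$latent_rho)
      oci <- if (is.null(config$oci_prob)) {
        NA_integer_
      } else {
        stats::rbinom(n, 1L, config$oci_prob)
      }
      tibble::tibble(
        farm = config$farm_label,
        month = m,
        cow_id = sprintf("cow_%04d", order_ids),
        ls = as.integer(ls),
        sw = flags[, "sw"], awd = flags[, "awd"],
        shh = flags[, "shh"], oh = flags[, "oh"],
        oci = oci, scb = NA_integer_, ab = NA_integer_
      )
    })
    dplyr::bind_rows(visits)
  })
}

# Latent exchangeable-threshold draw of the four indicator flags.
# Z_i = sqrt(rho) * W + sqrt(1 - rho) * E_i with W, E_i iid N(0,1);
# flag i is 1 when Z_i <= qnorm(p[class, i]).
draw_indicators <- function(ls, indicator_probs, rho) {
  n <- length(ls)
  w <- rnorm(n)
  z <- sqrt(rho) * w + sqrt(1 - rho) * matrix(rnorm(n * 4L), nrow = n)
  thresholds <- qnorm(indicator_probs)[as.character(ls), , drop = FALSE]
  flags <- matrix(as.integer(z <= thresholds), nrow = n,
                  dimnames = list(NULL, IPS_INDICATORS))
  flags
}

#' Exact tail probability of the composite indicator count
#'
#' Closed-form oracle for the composite screening rule under conditional
#' independence: the probability that at least `k` of four independent
#' Bernoulli indicators with success probabilities `p` are present
#' (a Poisson-binomial tail, computed by exact enumeration of the 16
#' outcomes).
#'
#' @param p Numeric 4-vector of presence probabilities in `[0, 1]`.
#' @param k Threshold in `1:4`.
#' @return The probability that the indicator count is `>= k`.
#' @export
#' @examples
#' # tail of the composite ">= 2 indicators" rule at the per-indicator
#' # sensitivities of the reference study
#' composite_tail_probability(c(0.421, 0.474, 0.767, 0.429), k = 2)
composite_tail_probability <- function(p, k) {
  if (length(p) != 4L || any(p < 0) || any(p > 1) || anyNA(p)) {
    abort("`p` must be 4 probabilities in [0, 1].",
          class = "parlourscore_argument_error")
  }
  if (length(k) != 1L || is.na(k) || k < 1 || k > 4 || k != round(k)) {
    abort("`k` must be an integer in 1..4.", class = "parlourscore_argument_error")
  }
  outcomes <- as.matrix(expand.grid(rep(list(0:1), 4L)))
  probs <- apply(outcomes, 1L, function(x) prod(ifelse(x == 1L, p, 1 - p)))
  sum(probs[rowSums(outcomes) >= k])
}

#' Systematic every-k-th sampling
#'
#' Keeps elements at positions `offset, offset + step, offset + 2 * step, ...`
#' (zero-based offset), preserving order — the in-parlour protocol of scoring
#' every third cow on a fast rotary platform corresponds to `step = 3`.
#' `step = 1` is the identity.
#'
#' @param x A vector or data frame of observations in platform order.
#' @param step Positive integer sampling step.
#' @param offset Zero-based starting offset, `0 <= offset < step`.
#' @return The sampled subset of `x`, same type as the input.
#' @export
#' @examples
#' every_kth_sampling(1:10, step = 3, offset = 1)
every_kth_sampling <- function(x, step, offset = 0L) {
  if (length(step) != 1L || is.na(step) || step < 1 || step != round(step)) {
    abort("`step` must be a positive integer.", class = "parlourscore_argument_error")
  }
  if (length(offset) != 1L || is.na(offset) || offset < 0 || offset >= step) {
    abort("`offset` must satisfy 0 <= offset < step.",
          class = "parlourscore_argument_error")
  }
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  idx <- if (n == 0L || offset + 1L > n) integer() else seq.int(offset + 1L, n, by = step)
  if (is.data.frame(x)) x[idx, , drop = FALSE] else x[idx]
}

herd_col_types <- function() {
  readr::cols(
    farm = readr::col_character(),
    month = readr::col_integer(),
    cow_id = readr::col_character(),
    ls = readr::col_integer(),
    sw = readr::col_integer(), awd = readr::col_integer(),
    shh = readr::col_integer(), oh = readr::col_integer(),
    oci = readr::col_integer(), scb = readr::col_integer(),
    ab = readr::col_integer()
  )
}

#' Read and write cow-visit observation tables
#'
#' CSV schema: header `farm,month,cow_id,ls,sw,awd,shh,oh,oci,scb,ab`,
#' missing values as empty fields, UTF-8, LF line endings.
#'
#' @param path File path.
#' @param data A cow-observation tibble as produced by [simulate_herd()].
#' @return `read_herd_csv()` returns a tibble; `write_herd_csv()` returns
#'   `data` invisibly.
#' @export
read_herd_csv <- function(path) {
  readr::read_csv(path, col_types = herd_col_types(), na = "")
}

#' @rdname read_herd_csv
#' @export
write_herd_csv <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(data)
}
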