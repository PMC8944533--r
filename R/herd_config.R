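# Study conditions for the default presets.
#
# Per-farm locomotion score class distributions and per-visit scored-cow counts
# are the monthly reference counts of the two-farm study (see
# `study_ls_counts()`); indicator probabilities for the lame class (LS >= 2)
# are the per-indicator sensitivities, and for the sound/imperfect classes are
# derived from the study's marginal counts (see the methods vignette).
STUDY_CLASS_PROBS <- list(
  farm1 = c(0.709, 0.260, 0.029, 0.002),
  farm2 = c(0.662, 0.302, 0.033, 0.003)
)
STUDY_VISIT_SIZES <- list(
  farm1 = c(310L, 326L, 338L, 336L, 350L, 341L, 332L, 336L, 337L),
  farm2 = c(108L, 118L, 121L, 126L, 122L, 129L, 124L, 134L, 137L)
)
STUDY_HERD_SIZES <- c(farm1 = 1200L, farm2 = 400L)

P_IND_LAME <- c(sw = 0.421, awd = 0.474, shh = 0.767, oh = 0.429)
P_IND_NONLAME <- c(sw = 0.061, awd = 0.072, shh = 0.029, oh = 0.149)
P_IND_CLASS0 <- c(sw = 0.010, awd = 0.010, shh = 0.004, oh = 0.040)
P_IND_CLASS1 <- c(sw = 0.193, awd = 0.233, shh = 0.092, oh = 0.430)

#' Class-conditional indicator probability presets
#'
#' Returns the 4 x 4 matrix of conditional probabilities
#' \eqn{p[\mathrm{class}, \mathrm{indicator}]} that an in-parlour indicator is
#' present given the cow's locomotion score class, used as the default by
#' [herd_config()]. Rows are locomotion scores 0-3, columns the four analysed
#' indicators (SW, AWD, SHH, OH). Scores 2 and 3 always share probabilities
#' (severe lameness is too rare to resolve separately).
#'
#' @param resolve_class1 If `TRUE` (default), locomotion score 1 cows get their
#'   own indicator rates, solved by moment-matching the study's pooled
#'   per-indicator marginal counts, with score-0 cows at low background rates.
#'   If `FALSE`, scores 0 and 1 share the non-lame rates (one minus the
#'   per-indicator specificities), so the indicators carry no information to
#'   separate score 0 from score 1.
#' @return A numeric matrix with rownames `"0".."3"` and colnames
#'   `c("sw","awd","shh","oh")`.
#' @export
#' @examples
#' default_indicator_probs()
default_indicator_probs <- function(resolve_class1 = TRUE) {
  if (resolve_class1) {
    rows <- rbind(P_IND_CLASS0, P_IND_CLASS1, P_IND_LAME, P_IND_LAME)
  } else {
    rows <- rbind(P_IND_NONLAME, P_IND_NONLAME, P_IND_LAME, P_IND_LAME)
  }
  dimnames(rows) <- list(as.character(0:3), names(P_IND_LAME))
  rows
}

#' Configure a synthetic herd
#'
#' Builds a validated configuration for [simulate_herd()]: herd size, number of
#' monthly visits, the locomotion-score class distribution, the 4 x 4 matrix of
#' class-conditional indicator probabilities, and the within-class latent
#' correlation of the indicators.
#'
#' @param n_cows Herd size (cow identities are drawn from this pool and reused
#'   across visits).
#' @param n_visits Number of monthly visits.
#' @param farm_label Farm identifier written into the `farm` column.
#' @param class_probs Probability 4-vector over locomotion scores 0-3; must sum
#'   to 1.
#' @param indicator_probs 4 x 4 matrix `p[class, indicator]`; rows are scores
#'   0-3, columns SW, AWD, SHH, OH. Defaults to [default_indicator_probs()].
#' @param latent_rho Within-class exchangeable correlation of the latent
#'   Gaussian vector that is thresholded to produce the four indicator flags;
#'   must lie in `[0, 1)`. `0` gives conditional independence given class.
#' @param sampling_step Systematic sampling step applied to each visit's
#'   milking order (`1` scores every cow, `3` every third cow as in a fast
#'   rotary parlour).
#' @param seed Integer seed; simulation is deterministic given the
#'   configuration.
#' @param visit_sizes Optional integer vector (length `n_visits`) of cows
#'   scored per visit, e.g. the study's monthly scored counts. When `NULL`,
#'   every cow in milking order is eligible and `sampling_step` decides how
#'   many are scored.
#' @param oci_prob Optional probability of the rare "observed claw injury"
#'   indicator; `NULL` (default) emits it as missing, as it was dropped from
#'   analysis.
#' @return A `herd_config` object (a validated list).
#' @seealso [study_farm_config()] for the two-farm study presets.
#' @export
#' @examples
#' cfg <- herd_config(n_cows = 200, n_visits = 3, seed = 1)
#' sim <- simulate_herd(cfg)
herd_config <- function(n_cows = 400L,
                        n_visits = 9L,
                        farm_label = "farm1",
                        class_probs = STUDY_CLASS_PROBS$farm1,
                        indicator_probs = default_indicator_probs(),
                        latent_rho = 0,
                        sampling_step = 1L,
                        seed = 1L,
                        visit_sizes = NULL,
                        oci_prob = NULL) {
  if (!is.numeric(n_cows) || length(n_cows) != 1L || n_cows < 1) {
    abort("`n_cows` must be a positive integer.", class = "parlourscore_config_error")
  }
  if (!is.numeric(n_visits) || length(n_visits) != 1L || n_visits < 1) {
    abort("`n_visits` must be a positive integer.", class = "parlourscore_config_error")
  }
  if (length(class_probs) != 4L || any(class_probs < 0) || any(class_probs > 1)) {
    abort("`class_probs` must be 4 probabilities in [0, 1].",
          class = "parlourscore_config_error")
  }
  if (abs(sum(class_probs) - 1) > 1e-12) {
    abort("`class_probs` must sum to 1 (within 1e-12).",
          class = "parlourscore_config_error")
  }
  indicator_probs <- as.matrix(indicator_probs)
  if (!all(dim(indicator_probs) == c(4L, 4L)) ||
      any(indicator_probs < 0) || any(indicator_probs > 1) ||
      anyNA(indicator_probs)) {
    abort("`indicator_probs` must be a 4 x 4 matrix of probabilities in [0, 1].",
          class = "parlourscore_config_error")
  }
  dimnames(indicator_probs) <- list(as.character(0:3), IPS_INDICATORS)
  if (!is.numeric(latent_rho) || length(latent_rho) != 1L ||
      latent_rho < 0 || latent_rho >= 1) {
    abort("`latent_rho` must lie in [0, 1).", class = "parlourscore_config_error")
  }
  if (!is.numeric(sampling_step) || length(sampling_step) != 1L || sampling_step < 1) {
    abort("`sampling_step` must be a positive integer.",
          class = "parlourscore_config_error")
  }
  if (!is.null(visit_sizes)) {
    if (length(visit_sizes) != n_visits || any(visit_sizes < 1) ||
        any(visit_sizes > n_cows)) {
      abort("`visit_sizes` must have one entry per visit, each in [1, n_cows].",
            class = "parlourscore_config_error")
    }
  }
  if (!is.null(oci_prob) &&
      (!is.numeric(oci_prob) || oci_prob < 0 || oci_prob > 1)) {
    abort("`oci_prob` must be a probability.", class = "parlourscore_config_error")
  }
  structure(
    list(
      n_cows = as.integer(n_cows),
      n_visits = as.integer(n_visits),
      farm_label = as.character(farm_label),
      class_probs = as.numeric(class_probs),
      indicator_probs = indicator_probs,
      latent_rho = as.numeric(latent_rho),
      sampling_step = as.integer(sampling_step),
      seed = as.integer(seed),
      visit_sizes = if (is.null(visit_sizes)) NULL else as.integer(visit_sizes),
      oci_prob = oci_prob
    ),
    class = "herd_config"
  )
}

#' @export
print.herd_config <- function(x, ...) {
  cat("<herd_config> farm", x$farm_label, "-", x$n_cows, "cows,",
      x$n_visits, "visits\n")
  cat("  class probs:", paste(format(x$class_probs), collapse = " "), "\n")
  cat("  latent rho:", x$latent_rho,
      " sampling step:", x$sampling_step, " seed:", x$seed, "\n")
  invisible(x)
}

#' Study presets for the two reference farms
#'
#' Herd configurations reproducing the conditions of the two-farm reference
#' study: nine monthly visits at the study's scored-cow counts per visit, the
#' per-farm locomotion score distributions, and the default class-conditional
#' indicator probabilities. Simulating both farms and pooling gives 4125
#' observations, matching the study's paired data set.
#'
#' @param farm `"farm1"` (3006 observations over 9 visits) or `"farm2"`
#'   (1119 observations).
#' @param seed Integer seed for [simulate_herd()].
#' @param resolve_class1 Passed to [default_indicator_probs()].
#' @param latent_rho Within-class latent indicator correlation (default 0; the
#'   study's printed inter-indicator associations are negligible to weak).
#' @return A [herd_config()] object.
#' @export
#' @examples
#' nrow(simulate_herd(study_farm_config("farm2", seed = 7)))
study_farm_config <- function(farm = c("farm1", "farm2"), seed = 1L,
                              resolve_class1 = TRUE, latent_rho = 0) {
  farm <- match.arg(farm)
  herd_config(
    n_cows = STUDY_HERD_SIZES[[farm]],
    n_visits = 9L,
    farm_label = farm,
    class_probs = STUDY_CLASS_PROBS[[farm]],
    indicator_probs = default_indicator_probs(resolve_class1),
    latent_rho = latent_rho,
    sampling_step = 1L,
    seed = seed,
    visit_sizes = STUDY_VISIT_SIZES[[farm]]
  )
}
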