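# Shared fixtures and independent oracles, built in code.

# Independent Poisson-binomial oracle: distribution of the indicator count by
# polynomial convolution of (1 - p_i + p_i z), then tail sum. Deliberately a
# different algorithm from composite_tail_probability()'s outcome enumeration.
pb_tail_convolution <- function(p, k) {
  coef <- 1
  for (pi in p) {
    coef <- c(coef * (1 - pi), 0) + c(0, coef * pi)
  }
  sum(coef[(k + 1):length(coef)])
}

# Independent best-split oracle: direct arithmetic over candidate features,
# no calls into the package's tree code.
brute_force_split <- function(data, class, features) {
  gini <- function(y) {
    n <- length(y)
    1 - sum((table(factor(y, levels = levels(class))) / n)^2)
  }
  best <- NULL
  for (f in features) {
    x <- data[[f]]
    if (all(x == 0) || all(x == 1)) next
    n <- length(x)
    dec <- gini(class) -
      (sum(x == 0) / n * gini(class[x == 0]) +
         sum(x == 1) / n * gini(class[x == 1]))
    if (dec > 1e-15 && (is.null(best) || dec > best$decrease + 1e-12)) {
      best <- list(feature = f, decrease = dec)
    }
  }
  best
}

# Random cow-observation tibble with arbitrary class-indicator dependence.
random_obs <- function(n, seed, p_flags = runif(4, 0.2, 0.8)) {
  withr::with_seed(seed, {
    tibble::tibble(
      farm = "f", month = 1L, cow_id = sprintf("c%04d", seq_len(n)),
      ls = sample(0:3, n, replace = TRUE, prob = c(0.55, 0.3, 0.1, 0.05)),
      sw = stats::rbinom(n, 1, p_flags[1]), awd = stats::rbinom(n, 1, p_flags[2]),
      shh = stats::rbinom(n, 1, p_flags[3]), oh = stats::rbinom(n, 1, p_flags[4])
    )
  })
}

# Expand per-class counts into a minimal observation tibble.
obs_from_ls_counts <- function(farm, counts) {
  ls <- rep(0:3, counts)
  n <- length(ls)
  tibble::tibble(
    farm = farm, month = 1L, cow_id = sprintf("%s_c%05d", farm, seq_len(n)),
    ls = ls, sw = 0L, awd = 0L, shh = 0L, oh = 0L
  )
}

# The pooled two-farm simulated data set under the study preset.
study_simulation <- function(seed = 20) {
  dplyr::bind_rows(
    simulate_herd(study_farm_config("farm1", seed = seed)),
    simulate_herd(study_farm_config("farm2", seed = seed + 1L))
  )
}

# A noiseless data set whose class is a deterministic function of the flags:
# >=2 iff SHH present and at least two indicators, 1 iff any indicator, else 0.
deterministic_obs <- function(n, seed, p_flags = rep(0.5, 4)) {
  d <- random_obs(n, seed, p_flags = p_flags)
  count <- d$sw + d$awd + d$shh + d$oh
  d$ls <- ifelse(d$shh == 1L & count >= 2L, 2L, ifelse(count >= 1L, 1L, 0L))
  d
}
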