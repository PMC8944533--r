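test_that("simulation is deterministic given config and seed", {
  cfg <- herd_config(n_cows = 150, n_visits = 3, seed = 7)
  a <- simulate_herd(cfg)
  b <- simulate_herd(cfg)
  expect_identical(a, b)
  c <- simulate_herd(herd_config(n_cows = 150, n_visits = 3, seed = 8))
  expect_false(identical(a, c))
  # byte-for-byte after serialization
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_herd_csv(a, fa)
  write_herd_csv(b, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("degenerate indicator probabilities give deterministic flags", {
  # classes 0/2 never show indicators, classes 1/3 always do
  probs <- matrix(rep(c(0, 1, 0, 1), 4), 4, 4,
                  dimnames = list(as.character(0:3), c("sw", "awd", "shh", "oh")))
  for (rho in c(0, 0.5, 0.9)) {
    sim <- simulate_herd(herd_config(n_cows = 100, n_visits = 2,
                                     class_probs = c(0.25, 0.25, 0.25, 0.25),
                                     indicator_probs = probs,
                                     latent_rho = rho, seed = 3))
    expect_true(all(indicator_count(sim) == ifelse(sim$ls %in% c(1L, 3L), 4L, 0L)))
  }
})

test_that("empirical class frequencies match class_probs within 3 SE", {
  probs <- c(0.709, 0.260, 0.029, 0.002)
  sim <- simulate_herd(herd_config(n_cows = 1000, n_visits = 100,
                                   class_probs = probs, seed = 41))
  n <- nrow(sim)
  expect_identical(n, 100000L)
  freq <- as.numeric(table(factor(sim$ls, levels = 0:3))) / n
  se <- sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(freq - probs) <= 3 * se))
})

test_that("indicator prevalence converges to the class mixture", {
  cfg <- herd_config(n_cows = 1000, n_visits = 50, seed = 13)
  sim <- simulate_herd(cfg)
  n <- nrow(sim)
  target <- as.numeric(cfg$class_probs %*% cfg$indicator_probs)
  emp <- colMeans(sim[c("sw", "awd", "shh", "oh")])
  se <- sqrt(target * (1 - target) / n)
  expect_true(all(abs(emp - target) <= 3 * se))
})

test_that("with rho = 0 the composite rate per class matches the closed form", {
  p <- c(0.421, 0.474, 0.767, 0.429)
  probs <- matrix(rep(p, each = 4), 4, 4,
                  dimnames = list(as.character(0:3), c("sw", "awd", "shh", "oh")))
  sim <- simulate_herd(herd_config(n_cows = 1000, n_visits = 50,
                                   class_probs = c(0, 0, 1, 0),
                                   indicator_probs = probs,
                                   latent_rho = 0, seed = 17))
  n <- nrow(sim)
  for (k in 1:4) {
    expected <- composite_tail_probability(p, k)
    emp <- mean(classify_composite(sim, k))
    expect_lt(abs(emp - expected), 3 * sqrt(expected * (1 - expected) / n) + 1e-12)
  }
})

test_that("within-class indicator association is nondecreasing in latent_rho", {
  mean_pairwise_phi <- function(rho) {
    sim <- simulate_herd(herd_config(n_cows = 1000, n_visits = 100,
                                     class_probs = c(1, 0, 0, 0),
                                     latent_rho = rho, seed = 29,
                                     indicator_probs = matrix(
                                       0.3, 4, 4,
                                       dimnames = list(as.character(0:3),
                                                       c("sw", "awd", "shh", "oh")))))
    flags <- as.matrix(sim[c("sw", "awd", "shh", "oh")])
    cors <- stats::cor(flags)
    mean(cors[upper.tri(cors)])
  }
  phis <- vapply(c(0, 0.3, 0.6), mean_pairwise_phi, numeric(1))
  expect_true(all(diff(phis) > 0))
  expect_lt(abs(phis[1]), 0.02)  # conditional independence at rho = 0
})

test_that("composite_tail_probability matches an independent convolution oracle", {
  expect_identical(composite_tail_probability(c(0, 0, 0, 0), 1), 0)
  expect_identical(composite_tail_probability(c(1, 1, 1, 1), 4), 1)
  expect_equal(composite_tail_probability(c(0.421, 0.474, 0.767, 0.429), 2),
               0.7297, tolerance = 1e-4)
  withr::with_seed(5, {
    for (i in 1:25) {
      p <- runif(4)
      k <- sample(1:4, 1)
      expect_equal(composite_tail_probability(p, k), pb_tail_convolution(p, k),
                   tolerance = 1e-12)
    }
  })
  expect_error(composite_tail_probability(c(0.5, 0.5, 0.5, 0.5), 5),
               class = "parlourscore_argument_error")
  expect_error(composite_tail_probability(c(0.5, 0.5, 0.5, 1.5), 2),
               class = "parlourscore_argument_error")
})

test_that("every_kth_sampling follows the systematic protocol", {
  expect_identical(every_kth_sampling(1:9, 3, 0), c(1L, 4L, 7L))
  expect_identical(every_kth_sampling(1:10, 3, 1), c(2L, 5L, 8L))
  expect_identical(every_kth_sampling(1:7, 1), 1:7)
  expect_identical(every_kth_sampling(integer(), 3), integer())
  d <- random_obs(9, seed = 1)
  expect_identical(every_kth_sampling(d, 3, 0), d[c(1, 4, 7), ])
  expect_error(every_kth_sampling(1:5, 3, 3), class = "parlourscore_argument_error")
  expect_error(every_kth_sampling(1:5, 0), class = "parlourscore_argument_error")
})

test_that("invalid configurations are rejected", {
  expect_error(herd_config(class_probs = c(0.5, 0.5, 0.1, -0.1)),
               class = "parlourscore_config_error")
  expect_error(herd_config(class_probs = c(0.5, 0.3, 0.1, 0.2)),
               class = "parlourscore_config_error")
  expect_error(herd_config(latent_rho = 1), class = "parlourscore_config_error")
  bad <- default_indicator_probs()
  bad[2, 3] <- 1.2
  expect_error(herd_config(indicator_probs = bad),
               class = "parlourscore_config_error")
})

test_that("herd CSV round-trips losslessly", {
  sim <- simulate_herd(herd_config(n_cows = 80, n_visits = 2, seed = 9,
                                   oci_prob = 0.01))
  f <- withr::local_tempfile(fileext = ".csv")
  write_herd_csv(sim, f)
  expect_identical(readLines(f)[1], "farm,month,cow_id,ls,sw,awd,shh,oh,oci,scb,ab")
  back <- read_herd_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(sim))
})

test_that("mixing rare lame classes induces the expected association pattern", {
  # pooled indicator-vs-lame association strong relative to inter-indicator
  # association, SHH the strongest single indicator
  sim <- simulate_herd(herd_config(n_cows = 2000, n_visits = 50, seed = 31))
  phi <- unclass(phi_screen(sim))
  ind_lame <- phi[1:4, "LS>=2"]
  inter <- phi[1:4, 1:4][upper.tri(diag(4))]
  expect_true(all(ind_lame > 0.1))
  expect_identical(names(which.max(ind_lame)), "SHH")
  expect_true(all(abs(inter) < 0.3))
  expect_lt(max(abs(inter)), max(ind_lame))
})
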