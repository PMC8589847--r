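# small synthetic dataset shared by the MCMC contract tests
# combines a borderless and a bordered layout so the FB coefficient k is
# identified from the between-field contrast
bayes_test_data <- function(rows = 12, cobs = 4, seed = 17) {
  combine_datasets(
    simulate_experiment(sim_config(small_layout("nofb", fb = 0, rows = rows),
                                   cobs_per_grid = cobs, seed = seed)),
    simulate_experiment(sim_config(small_layout("fb", fb = 6.75, rows = rows),
                                   cobs_per_grid = cobs, seed = seed + 1))
  )
}

test_that("settings control the retained draw count exactly", {
  s <- mcmc_settings(n_iter = 3000, burn_in = 1000, thin = 4, seed = 1)
  target <- function(th) sum(dnorm(th, log = TRUE))
  ch <- adaptive_metropolis(target, c(a = 0, b = 1), s)
  expect_equal(nrow(ch$draws), (3000 - 1000) %/% 4)
  expect_identical(colnames(ch$draws), c("a", "b"))
  # paper profile retains 2000 draws
  sp <- mcmc_settings(profile = "paper")
  expect_equal((sp$n_iter - sp$burn_in) / sp$thin, 2000)
})

test_that("the sampler targets the correct distribution on a known problem", {
  # standard bivariate normal target
  s <- mcmc_settings(n_iter = 12000, burn_in = 4000, thin = 2, seed = 2)
  ch <- adaptive_metropolis(function(th) sum(dnorm(th, log = TRUE)),
                            c(0.5, -0.5), s)
  for (j in 1:2) {
    expect_lt(abs(mean(ch$draws[, j])), 4 * batch_se(ch$draws[, j]))
    expect_equal(sd(ch$draws[, j]), 1, tolerance = 0.1)
  }
  expect_gt(ch$acceptance_rate, 0.1)
  expect_lt(ch$acceptance_rate, 0.6)
})

test_that("chains are bitwise reproducible from the seed", {
  d <- bayes_test_data()
  s <- mcmc_settings(n_iter = 2000, burn_in = 800, thin = 4, seed = 31)
  p1 <- run_mcmc(d, "ZExpoB", s)
  p2 <- run_mcmc(d, "ZExpoB", s)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$dic, p2$dic)
  # acceptance rate within the healthy range after adaptation
  expect_gt(p1$acceptance_rate, 0.1)
  expect_lt(p1$acceptance_rate, 0.6)
  # only ZIP models are supported by the Bayesian path
  expect_error(run_mcmc(d, "PExpoB", s), "ZIP")
})

test_that("DIC reduces to the plug-in deviance for a degenerate chain", {
  d <- bayes_test_data()
  p <- default_truth_params()
  draws <- matrix(rep(p, each = 50), nrow = 50,
                  dimnames = list(NULL, names(p)))
  post <- structure(list(draws = draws, posterior_mean = p,
                         spec = model_spec("ZExpoB"),
                         k_grains = k_grains(d)),
                    class = "fb_posterior")
  val <- dic(post, d)
  expect_equal(attr(val, "p_d"), 0, tolerance = 1e-8)
  expect_equal(as.numeric(val), -2 * log_likelihood(d, "ZExpoB", p))
  # likelihood additivity: duplicating the data doubles the mean deviance
  dd <- fb_dataset(rbind(as.data.frame(d), as.data.frame(d)), k_grains(d))
  expect_equal(attr(dic(post, dd), "mean_deviance"),
               2 * attr(val, "mean_deviance"))
})

test_that("predictive bands are ordered, seeded and respect the d* domain", {
  d <- bayes_test_data()
  s <- mcmc_settings(n_iter = 2500, burn_in = 1000, thin = 3, seed = 7)
  post <- run_mcmc(d, "ZExpoB", s)
  band <- posterior_predictive_band(post, seq(6.75, 12, by = 0.75),
                                    fb_width = 6.75, n_draws = 2000)
  expect_true(all(band$lower_2_5 <= band$mean_cp + 1e-12))
  expect_true(all(band$mean_cp <= band$upper_97_5 + 1e-12))
  b2 <- posterior_predictive_band(post, seq(6.75, 12, by = 0.75),
                                  fb_width = 6.75, n_draws = 2000)
  expect_identical(band, b2)
  # distances inside the border violate the model's d* domain
  expect_error(posterior_predictive_band(post, 3, fb_width = 6.75,
                                         n_draws = 2000), "negative")
  expect_error(posterior_predictive_band(post, 8, fb_width = 6.75,
                                         n_draws = 10), ">= 1000")
})

test_that("a zero-variance chain with vanishing rate collapses the band", {
  # all draws identical, lambda ~ 0 far away, structural zeros certain
  p <- c(Ke = 1e-6, a1 = 2, a2 = 2, k = 0, D = 1, b1 = 0, b2 = 0)
  draws <- matrix(rep(p, each = 20), nrow = 20,
                  dimnames = list(NULL, names(p)))
  post <- structure(list(draws = draws, spec = model_spec("ZExpoB"),
                         k_grains = 400,
                         settings = mcmc_settings(seed = 1)),
                    class = "fb_posterior")
  band <- posterior_predictive_band(post, c(10, 20), fb_width = 0,
                                    n_draws = 2000)
  expect_equal(band$mean_cp, c(0, 0))
  expect_equal(band$upper_97_5, c(0, 0))
})

test_that("posterior SD shrinks with more data (root-n behaviour)", {
  s <- mcmc_settings(n_iter = 6000, burn_in = 3000, thin = 3, seed = 11)
  small <- bayes_test_data(rows = 15, cobs = 2, seed = 5)
  big <- bayes_test_data(rows = 15, cobs = 8, seed = 5)
  ps <- run_mcmc(small, "ZExpoB", s)
  pb <- run_mcmc(big, "ZExpoB", s)
  # quadrupled sample size: posterior SD of the main kernel parameters
  # should drop by at least ~30%
  shrink <- pb$posterior_sd[c("Ke", "a1")] / ps$posterior_sd[c("Ke", "a1")]
  expect_true(all(shrink < 0.7))
})
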