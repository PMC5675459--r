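test_that("R-squared matches its definition, including negative values", {
  y <- c(0.2, 0.5, 0.9)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(c(0, 1), c(1, 0)), 1 - 2 / 0.5)  # -3
  expect_error(r_squared(c(1, 1), c(0.9, 1.1)), "zero variance")
  expect_error(r_squared(1:3, 1:4), "lengths differ")
})

test_that("a model evaluated on its own inputs is perfect", {
  fx <- table2_fixture()
  rep2 <- evaluate_models(fx, models = list("pairs"), min_order = 2,
                          max_order = 2)[[1L]]
  expect_equal(rep2$r2, 1)
})

test_that("the alpha scan is flat on exactly Bliss-consistent data", {
  scr <- generate_screen(synthetic_config(n_drugs = 5, max_order = 4,
                                          pair_interaction_sd = 0,
                                          noise_sigma = 0, seed = 8))
  scan <- alpha_scan(scr, alpha_grid = seq(0, 1, 0.25))
  expect_lt(diff(range(scan$r2_values)), 1e-10)
})

test_that("a one-point grid returns that point", {
  scr <- generate_screen(synthetic_config(n_drugs = 4, max_order = 3,
                                          seed = 2))
  expect_equal(alpha_scan(scr, alpha_grid = 0.3)$best_alpha, 0.3)
})

test_that("ranking accuracy handles perfect, reversed, and transformed predictors", {
  obs <- seq(0.05, 1, length.out = 20)
  expect_equal(ranking_accuracy(obs, obs, 0.1), 1)
  expect_equal(ranking_accuracy(obs, rev(obs), 0.1), 0)
  # invariant under strictly increasing transforms of the prediction
  set.seed(13)
  pred <- stats::runif(20)
  expect_equal(ranking_accuracy(obs, pred, 0.2),
               ranking_accuracy(obs, exp(3 * pred) - 0.5, 0.2))
  expect_error(ranking_accuracy(obs, obs, 0.01), "below 1")
})

test_that("random predictions recover the hypergeometric baseline", {
  set.seed(29)
  acc <- replicate(300, {
    obs <- stats::runif(200)
    ranking_accuracy(obs, stats::runif(200), 0.1)
  })
  expect_equal(mean(acc), 0.1, tolerance = 0.03)
})

test_that("analytic noise factors reproduce the closed forms for triplets", {
  expect_equal(noise_amplification_analytic("bliss", 3)$factor, sqrt(3))
  expect_equal(noise_amplification_analytic("regression", 3)$factor,
               sqrt(6))
  expect_equal(noise_amplification_analytic("pairs", 3)$factor,
               sqrt(3 / 4))
})

test_that("noise factors order pairs < bliss < regression for M in 3..6", {
  for (M in 3:6) {
    f <- vapply(c("pairs", "bliss", "regression"), function(fam) {
      noise_amplification_analytic(fam, M)$factor
    }, 0)
    expect_true(f[["pairs"]] < f[["bliss"]],
                label = paste("pairs < bliss at M =", M))
    expect_true(f[["bliss"]] < f[["regression"]],
                label = paste("bliss < regression at M =", M))
  }
})

test_that("log-linear noise factor hits the named models at the endpoint alphas", {
  for (M in 3:5) {
    expect_equal(
      noise_amplification_analytic("loglinear", M, alpha = 0)$factor,
      noise_amplification_analytic("bliss", M)$factor)
    expect_equal(
      noise_amplification_analytic("loglinear", M, alpha = 1)$factor,
      noise_amplification_analytic("regression", M)$factor)
    expect_equal(
      noise_amplification_analytic("loglinear", M,
                                   alpha = 1 / (M - 1))$factor,
      noise_amplification_analytic("pairs", M)$factor)
  }
})

test_that("Monte-Carlo noise factors agree with the analytic ones", {
  for (fam in c("bliss", "pairs")) {
    mc <- noise_amplification_mc(fam, 3, sigma = 0.05, n_sims = 2e4,
                                 seed = 61)
    expect_lt(abs(mc - noise_amplification_analytic(fam, 3)$factor),
              3 * attr(mc, "mc_se"))
  }
})
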