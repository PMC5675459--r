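test_that("identical configs generate bit-identical screens", {
  cfg <- synthetic_config(n_drugs = 4, seed = 77)
  a <- generate_screen(cfg)
  b <- generate_screen(cfg)
  expect_identical(a$records, b$records)
  expect_identical(attr(a, "truth"), attr(b, "truth"))
  c2 <- generate_screen(synthetic_config(n_drugs = 4, seed = 78))
  expect_false(identical(a$records$viability, c2$records$viability))
})

test_that("the degenerate generator collapses to exact Bliss products", {
  scr <- generate_screen(synthetic_config(n_drugs = 5, max_order = 5,
                                          pair_interaction_sd = 0,
                                          noise_sigma = 0, seed = 4))
  singles <- singles_map(scr, "SIM")
  rec <- scr$records[scr$records$order >= 2L, ]
  for (i in seq_len(nrow(rec))) {
    dd <- strsplit(rec$drugs[i], "+", fixed = TRUE)[[1L]]
    expect_equal(rec$viability[i], prod(singles[dd]), tolerance = 1e-12)
  }
})

test_that("a noiseless pairs-world screen is reproduced exactly by the pairs model", {
  scr <- generate_screen(synthetic_config(n_drugs = 4, max_order = 3,
                                          true_alpha = 0.5,
                                          noise_sigma = 0, seed = 12))
  preds <- predict_dataset(scr, "SIM", "pairs")
  expect_equal(preds$predicted, preds$observed, tolerance = 1e-12)
})

test_that("a full factorial of six drugs has 63 cocktails", {
  scr <- generate_screen(synthetic_config(n_drugs = 6, max_order = 6,
                                          seed = 5))
  expect_equal(nrow(scr$records), 63L)
  expect_equal(as.integer(table(scr$records$order)),
               c(6L, 15L, 20L, 15L, 6L, 1L))
})

test_that("observed means converge to the Bliss truth over many repeats", {
  scr <- generate_screen(synthetic_config(n_drugs = 3, max_order = 3,
                                          pair_interaction_sd = 0,
                                          noise_sigma = 0.05,
                                          n_repeats = 400, seed = 30))
  truth <- attr(scr, "truth")
  rec <- scr$records
  # E[g * exp(sigma Z)] = g * exp(sigma^2 / 2); correct for the lognormal mean
  expected <- truth[rec$drugs] * exp(0.05^2 / 2)
  expect_true(all(abs(rec$viability - expected) <= 3 * rec$ste))
})

test_that("the generative alpha is recovered from noiseless and noisy screens", {
  noiseless <- generate_screen(synthetic_config(n_drugs = 5, max_order = 3,
                                                true_alpha = 0.37,
                                                noise_sigma = 0, seed = 21))
  expect_equal(recover_alpha(noiseless, alpha_grid = seq(0, 1, 0.025)),
               0.375)  # nearest grid point to the truth

  noisy <- generate_screen(synthetic_config(n_drugs = 6, max_order = 3,
                                            true_alpha = 0.5,
                                            noise_sigma = 0.02, seed = 1))
  expect_lt(abs(recover_alpha(noisy) - 0.5), 0.05 + 1e-9)

  mixed <- generate_screen(synthetic_config(n_drugs = 5, max_order = 5,
                                            seed = 9))
  expect_error(recover_alpha(mixed), "mixes cocktail orders")
})

test_that("Monte-Carlo noise factors recover the analytic values at several sigmas", {
  for (sig in c(0.02, 0.1)) {
    mc <- noise_amplification_mc("regression", 4, sigma = sig,
                                 n_sims = 2e4, seed = 71)
    expect_lt(abs(mc - noise_amplification_analytic("regression",
                                                    4)$factor),
              3 * attr(mc, "mc_se"))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_drugs = 2), "n_drugs")
  expect_error(synthetic_config(single_range = c(0, 0.9)))
  expect_error(synthetic_config(single_range = c(0.5, 1.2)))
  expect_error(synthetic_config(n_repeats = 1))
  expect_error(synthetic_config(max_order = 9, n_drugs = 6))
})
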