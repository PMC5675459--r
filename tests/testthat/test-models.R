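test_that("Bliss prediction is the product of singles", {
  expect_equal(predict_bliss(c(A = 1, B = 1), "A+B")$value, 1)
  expect_equal(predict_bliss(c(A = 0.5, B = 0), "A+B")$value, 0)
  # H1299 CPT x CisPt singles
  expect_equal(predict_bliss(c(CPT = 0.77, CISPT = 0.82),
                             "CPT+CisPt")$value, 0.77 * 0.82)
  expect_error(predict_bliss(c(A = 0.5), "A+B"), "missing single.*B")
})

test_that("pairs model is the (M-1)-th root of the pair product", {
  p3 <- c("A+B" = 1, "A+C" = 1, "B+C" = 1)
  expect_equal(predict_pairs(p3, "A+B+C")$value, 1)
  # H1299 CPT+CisPt+CbPt pair block
  p <- c("CPT+CISPT" = 0.67, "CBPT+CPT" = 0.58, "CBPT+CISPT" = 0.73)
  expect_equal(predict_pairs(p, "CPT+CisPt+CbPt")$value,
               sqrt(0.67 * 0.58 * 0.73))
  # M = 2 returns the measured pair itself
  expect_equal(predict_pairs(c("A+B" = 0.42), "A+B")$value, 0.42)
  expect_error(predict_pairs(p3[-1], "A+B+C"), "missing pair.*A\\+B")
})

test_that("regression divides the pair product by the singles", {
  s <- c(A = 0.8, B = 0.8, C = 0.8)
  p <- c("A+B" = 0.5, "A+C" = 0.5, "B+C" = 0.5)
  expect_equal(predict_regression(s, p, "A+B+C")$value, 0.125 / 0.512)
  s0 <- s; s0[["A"]] <- 0
  expect_error(predict_regression(s0, p, "A+B+C"), "degenerate")
})

test_that("Isserlis matches its printed triplet/quadruplet forms and clamps negatives", {
  s <- c(A = 0.8, B = 0.8, C = 0.8)
  p <- c("A+B" = 0.7, "A+C" = 0.7, "B+C" = 0.7)
  pr <- predict_isserlis(s, p, "A+B+C")
  expect_equal(pr$value, 3 * 0.8 * 0.7 - 2 * 0.8^3)
  expect_false(pr$clamped)

  s4 <- c(s, D = 0.9)
  p4 <- c(p, "A+D" = 0.6, "B+D" = 0.6, "C+D" = 0.6)
  expect_equal(predict_isserlis(s4, p4, "A+B+C+D")$value,
               3 * 0.7 * 0.6 - 2 * prod(s4))

  neg <- predict_isserlis(c(A = 0.9, B = 0.9, C = 0.9),
                          c("A+B" = 0.01, "A+C" = 0.01, "B+C" = 0.01),
                          "A+B+C")
  expect_equal(neg$value, 0)
  expect_true(neg$clamped)

  expect_error(predict_isserlis(c(s4, E = 0.5), p4, "A+B+C+D+E"),
               "3 or 4 drugs")
})

test_that("log-linear worked value and derived beta are right", {
  s <- c(A = 0.9, B = 0.9, C = 0.9)
  p <- c("A+B" = 0.8, "A+C" = 0.8, "B+C" = 0.8)
  pr <- predict_loglinear(s, p, "A+B+C", alpha = 0.5)
  expect_equal(pr$value, 0.512^0.5)
  expect_equal(pr$beta, 0)
})

test_that("Bliss conservation holds across the family on Bliss-consistent inputs", {
  set.seed(41)
  for (rep in 1:250) {
    M <- sample(2:6, 1L)
    inp <- random_bliss_inputs(M)
    target <- prod(inp$singles)
    lbl <- paste(inp$drugs, collapse = "+")
    expect_equal(predict_pairs(inp$pairs, lbl)$value, target,
                 tolerance = 1e-12)
    a <- stats::runif(1, -0.5, 1.5)
    expect_equal(predict_loglinear(inp$singles, inp$pairs, lbl, a)$value,
                 target, tolerance = 1e-12)
    if (M >= 3) {
      expect_equal(predict_regression(inp$singles, inp$pairs, lbl)$value,
                   target, tolerance = 1e-12)
    }
    if (M %in% 3:4) {
      expect_equal(predict_isserlis(inp$singles, inp$pairs, lbl)$value,
                   target, tolerance = 1e-12)
    }
  }
})

test_that("log-linear endpoints coincide with the named models", {
  set.seed(42)
  for (rep in 1:50) {
    M <- sample(3:6, 1L)
    inp <- random_bliss_inputs(M)
    # break Bliss consistency so the endpoints are a real check
    inp$pairs <- inp$pairs * exp(stats::rnorm(length(inp$pairs), 0, 0.2))
    lbl <- paste(inp$drugs, collapse = "+")
    expect_equal(predict_loglinear(inp$singles, inp$pairs, lbl, 0)$value,
                 predict_bliss(inp$singles, lbl)$value, tolerance = 1e-12)
    expect_equal(predict_loglinear(inp$singles, inp$pairs, lbl, 1)$value,
                 predict_regression(inp$singles, inp$pairs, lbl)$value,
                 tolerance = 1e-12)
    expect_equal(
      predict_loglinear(inp$singles, inp$pairs, lbl, 1 / (M - 1))$value,
      predict_pairs(inp$pairs, lbl)$value, tolerance = 1e-12)
  }
})

test_that("predictions are invariant to drug ordering within the cocktail", {
  inp <- random_bliss_inputs(4)
  inp$pairs <- inp$pairs * exp(stats::rnorm(6, 0, 0.1))
  perm <- sample(inp$drugs)
  for (f in list(
    function(d) predict_pairs(inp$pairs, d)$value,
    function(d) predict_regression(inp$singles, inp$pairs, d)$value,
    function(d) predict_isserlis(inp$singles, inp$pairs, d)$value)) {
    expect_equal(f(paste(perm, collapse = "+")),
                 f(paste(inp$drugs, collapse = "+")))
  }
})

test_that("the pairs model is non-decreasing in each pair viability", {
  inp <- random_bliss_inputs(4)
  base <- predict_pairs(inp$pairs, paste(inp$drugs, collapse = "+"))$value
  for (k in seq_along(inp$pairs)) {
    up <- inp$pairs
    up[k] <- up[k] * 1.3
    expect_gte(predict_pairs(up, paste(inp$drugs, collapse = "+"))$value,
               base)
  }
})

test_that("dataset-level prediction covers the H1299 block and skips the broken HeLa cocktails", {
  fx <- table2_fixture()
  h <- predict_dataset(fx, "H1299", "pairs")
  expect_equal(nrow(h), 42L)  # 20 + 15 + 6 + 1
  expect_equal(nrow(attr(h, "skipped")), 0L)
  expect_false(anyNA(h$observed))

  he <- predict_dataset(fx, "HeLa", "pairs")
  sk <- attr(he, "skipped")
  expect_gt(nrow(sk), 0L)
  contains_both <- vapply(sk$drugs, function(d) {
    all(c("CBPT", "NCZ") %in% strsplit(d, "+", fixed = TRUE)[[1L]])
  }, TRUE)
  expect_true(all(contains_both))
  expect_true(all(grepl("missing pair", sk$reason)))

  empty <- combination_dataset(minimal_records())
  expect_equal(nrow(predict_dataset(empty, "A", "pairs")), 0L)
  expect_error(predict_dataset(fx, "NoSuchLine", "pairs"), "unknown cell")
})
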