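# Summary statistics and the randomization test, checked against
# exhaustive enumeration.

test_that("summaries report mean, SD and SEM", {
  s <- summarize_values(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$sem, 1 / sqrt(3))
  expect_equal(s$n, 3)

  s1 <- summarize_values(5)
  expect_equal(s1$mean, 5)
  expect_false(s1$sd_defined)
  expect_true(is.na(s1$sd))

  expect_error(summarize_values(numeric(0)))

  set.seed(10)
  x <- rnorm(10000, 1.2, 0.5)
  sx <- summarize_values(x)
  expect_lt(abs(sx$mean - 1.2), 3 * sx$sem)
})

test_that("exhaustive randomization p-values are exact", {
  r <- permutation_test(c(1, 2), c(3, 4))
  expect_true(r$exhaustive)
  expect_equal(r$p_value, 1 / 3)
  expect_equal(r$n_permutations, 6)

  same <- permutation_test(c(2, 4, 6), c(2, 4, 6))
  expect_equal(same$observed_diff, 0)
  expect_equal(same$p_value, 1.0)

  expect_error(permutation_test(1, c(2, 3)))
})

test_that("the test is exchangeable in its two groups", {
  set.seed(20)
  a <- rnorm(6); b <- rnorm(5, 0.5)
  expect_equal(permutation_test(a, b)$p_value,
               permutation_test(b, a)$p_value)
})

test_that("Monte-Carlo p-values converge to the exhaustive oracle", {
  set.seed(30)
  a <- rnorm(5); b <- rnorm(5, 1)
  p_ex <- permutation_test(a, b)$p_value
  p_mc <- permutation_test(a, b, n_permutations = 4000, seed = 7,
                           exhaustive_limit = 1)$p_value
  se <- sqrt(p_ex * (1 - p_ex) / 4000)
  expect_lt(abs(p_mc - p_ex), 3 * se + 2 / 4001)
})

test_that("a huge location shift attains the minimum possible p", {
  a <- rnorm(3); b <- rnorm(3) + 100
  r_ex <- permutation_test(a, b)
  expect_equal(r_ex$p_value, 2 / choose(6, 3))

  a2 <- rnorm(20); b2 <- rnorm(20) + 100
  r_mc <- permutation_test(a2, b2, n_permutations = 999, seed = 5)
  expect_false(r_mc$exhaustive)
  expect_equal(r_mc$p_value, 1 / 1000)
})

test_that("the median statistic is available", {
  set.seed(40)
  a <- c(rnorm(10), 50)  # outlier
  b <- rnorm(10)
  r <- permutation_test(a, b, statistic = "median", n_permutations = 500,
                        seed = 2)
  expect_true(is.finite(r$p_value))
  expect_equal(r$observed_diff, median(a) - median(b))
})
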