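test_that("normality screening behaves under null, degenerate and heavy-tailed samples", {
  set.seed(1)
  p <- normality_check(rnorm(20))
  expect_true(p > 0 && p <= 1)
  expect_error(normality_check(rep(2, 10)), "constant")
  expect_error(normality_check(c(1, 2)), "n >= 3")
  # heavy tails at n = 200 are rejected far more often than 5%
  set.seed(2)
  rej <- mean(vapply(1:200, function(i) {
    suppressWarnings(normality_check(rt(200, df = 2))) < 0.05
  }, logical(1)))
  expect_gt(rej, 0.5)
})

test_that("group comparison maps p-values to the star convention", {
  x <- c(1.1, 0.9, 1.0, 1.2, 0.8)
  same <- compare_groups(x, x)
  expect_equal(same$p_value, 1)
  expect_identical(same$label, "ns")
  expect_identical(significance_label(c(0.2, 0.049, 0.009, 0.0009)),
                   c("ns", "*", "**", "***"))
  expect_error(compare_groups(1, c(1, 2)), "n >= 2")
  # Welch option is honored
  set.seed(3)
  a <- rnorm(20); b <- rnorm(20, 1, 3)
  expect_false(isTRUE(all.equal(compare_groups(a, b)$p_value,
                                compare_groups(a, b, var_equal = FALSE)$p_value)))
})

test_that("a three-pooled-sd shift at n = 20 is essentially always highly significant", {
  set.seed(4)
  p <- vapply(1:200, function(i) {
    compare_groups(rnorm(20), rnorm(20, 3))$p_value
  }, numeric(1))
  expect_gte(mean(p < 0.001), 0.99)
})
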