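test_that("pearson matches the textbook product-moment formula", {
  expect_equal(pearson(1:10, 1:10), 1.0)
  expect_equal(pearson(1:10, -(1:10)), -1.0)

  textbook_r <- function(x, y) {
    n <- length(x)
    num <- sum(x * y) - n * mean(x) * mean(y)
    den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
    num / den
  }
  x <- c(2.1, 4.7, 1.3, 9.8, 5.5, 3.2)
  y <- c(1.0, 3.9, 2.2, 8.1, 6.6, 2.8)
  expect_equal(pearson(x, y), textbook_r(x, y), tolerance = 1e-12)
  set.seed(19)
  for (i in 1:50) {
    a <- rnorm(sample(3:30, 1)); b <- rnorm(length(a))
    expect_equal(pearson(a, b), textbook_r(a, b), tolerance = 1e-12)
  }

  expect_error(pearson(1:5, 1:4), "equal length")
  expect_error(pearson(1:2, 1:2), "at least 3")
  expect_error(pearson(rep(1, 5), 1:5), "degenerate")
})

test_that("cov_percent is 100*SD/mean, scale-invariant, zero for constants", {
  expect_equal(cov_percent(rep(42, 6)), 0)
  expect_equal(cov_percent(c(90, 110)), 100 * sqrt(200) / 100, tolerance = 1e-12)
  v <- c(80, 95, 104, 121)
  expect_equal(cov_percent(3.7 * v), cov_percent(v), tolerance = 1e-12)
  expect_error(cov_percent(c(-1, 1)), "zero mean")
  expect_error(cov_percent(5), "at least 2")
})

test_that("tissue_contrast is a two-sided Student t-test with sign symmetry", {
  a <- c(10, 12, 9, 11)
  expect_equal(unname(tissue_contrast(a, a)), c(0, 1))

  # textbook pooled-variance formula as oracle
  x <- c(30.3, 27.1, 45.0, 38.2, 22.9)
  y <- c(89.0, 105.4, 76.3, 99.8, 91.2, 84.4)
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  got <- tissue_contrast(x, y)
  expect_equal(got[["t"]], t_oracle, tolerance = 1e-6)
  expect_equal(got[["p"]],
               2 * pt(abs(t_oracle), length(x) + length(y) - 2, lower.tail = FALSE),
               tolerance = 1e-9)

  swapped <- tissue_contrast(y, x)
  expect_equal(swapped[["t"]], -got[["t"]])
  expect_equal(swapped[["p"]], got[["p"]])

  paired <- tissue_contrast(x, y[1:5], paired = TRUE)
  d <- x - y[1:5]
  expect_equal(paired[["t"]], mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-9)

  expect_error(tissue_contrast(1, 1:3), "at least 2")
})
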