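skew_mixture <- function(theta = 110) {
  s <- default_mixture_shape()
  mixture_distribution(theta, s$offsets, s$weights, s$sds)
}

test_that("constructor enforces the mixture invariants", {
  expect_error(mixture_distribution(110, c(0, -1, 1, 2, 3),
                                    rep(0.2, 5), rep(9, 5)),
               "increasing")
  expect_error(mixture_distribution(110, c(-2, -1, 0, 1, 2),
                                    c(0.5, 0.5, 0.5, 0.5, 0.5), rep(9, 5)),
               "sum to 1")
  expect_error(mixture_distribution(110, c(-2, -1, 0, 1, 2),
                                    rep(0.2, 5), c(9, 9, 0, 9, 9)),
               "positive")
  expect_error(mixture_distribution(110, c(-2, -1, 0, 1, 5),
                                    rep(0.2, 5), rep(9, 5)),
               "centred")
})

test_that("analytic mean equals the location parameter exactly", {
  d <- skew_mixture(97.3)
  expect_identical(mixture_mean(d), 97.3)
  # and against Monte Carlo
  set.seed(1)
  expect_lt(abs(mean(mixture_rand(d, 1e6)) - 97.3), 0.05)
})

test_that("single-component degenerate mixture reproduces the Normal law", {
  # near-degenerate weights; offsets keep strict ordering
  d <- mixture_distribution(0, center_offsets(c(0, 1, 2, 3, 4) * 1e-9,
                                              c(1 - 4e-16, rep(1e-16, 4))),
                            c(1 - 4e-16, rep(1e-16, 4)), rep(10, 5))
  h <- seq(-30, 30, by = 5)
  expect_equal(mixture_pdf(d, h), dnorm(h, 0, 10), tolerance = 1e-9)
  expect_equal(mixture_cdf(d, h), pnorm(h, 0, 10), tolerance = 1e-9)
})

test_that("pdf integrates to one and cdf has the right limits", {
  d <- skew_mixture()
  expect_equal(integrate(function(h) mixture_pdf(d, h), 0, 250,
                         rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
  expect_equal(mixture_cdf(d, 1e4), 1, tolerance = 1e-12)
  expect_lt(mixture_cdf(d, 0), 1e-8)
})

test_that("symmetric mixtures are symmetric about the location", {
  d <- mixture_distribution(120, c(-10, -5, 0, 5, 10),
                            c(0.1, 0.2, 0.4, 0.2, 0.1), c(8, 7, 6, 7, 8))
  expect_equal(mixture_cdf(d, 120), 0.5, tolerance = 1e-12)
  expect_equal(mixture_pdf(d, 120 + 7), mixture_pdf(d, 120 - 7),
               tolerance = 1e-12)
})

test_that("cdf is monotone in cutoff and decreasing in location", {
  d <- skew_mixture()
  cuts <- seq(60, 170, by = 5)
  expect_true(all(diff(mixture_cdf(d, cuts)) > 0))
  d2 <- skew_mixture(115)
  expect_true(all(mixture_cdf(d2, cuts) < mixture_cdf(d, cuts)))
})

test_that("mixture cdf matches a Monte-Carlo fraction within 0.002", {
  d <- skew_mixture(110)
  set.seed(42)
  draws <- mixture_rand(d, 1e6)
  for (cutoff in c(90, 110, 125))
    expect_lt(abs(mixture_cdf(d, cutoff) - mean(draws < cutoff)), 0.002)
})

test_that("combined-women density interpolates the two groups", {
  d_np <- skew_mixture(126)
  d_p <- skew_mixture(115)
  h <- seq(60, 180, by = 10)
  expect_equal(combined_women_pdf(0, d_np, d_p, h), mixture_pdf(d_np, h))
  expect_equal(combined_women_pdf(1, d_np, d_p, h), mixture_pdf(d_p, h))
  # combined mean is the pregnant-fraction mixture of the means
  p <- 0.35
  m <- integrate(function(h) h * combined_women_pdf(p, d_np, d_p, h),
                 0, 300, rel.tol = 1e-10)$value
  expect_equal(m, (1 - p) * 126 + p * 115, tolerance = 1e-6)
  expect_equal(combined_women_cdf(p, d_np, d_p, 120),
               (1 - p) * mixture_cdf(d_np, 120) + p * mixture_cdf(d_p, 120))
})
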