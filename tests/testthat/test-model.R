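prepared_women <- function() {
  if (!is.null(.fix_env$datw)) return(.fix_env$datw)
  dd <- load_survey_data(tiny_world_dir())
  .fix_env$datw <- prepare_model_data("women", dd$observations,
                                      dd$individuals, dd$covariates,
                                      dd$regions)
  .fix_env$datw
}

test_that("location collapses to the global line when deviations vanish", {
  dat <- prepared_women()
  st <- dat$layout
  x <- numeric(st$d)
  x[st$a0] <- 124; x[st$b0] <- 0.5
  for (yy in c(1991, 2000, 2007.5)) {
    th <- location_mean(dat, x, "C03", yy, "non_pregnant")
    expect_equal(th, 124 + 0.5 * (yy - 2000))
  }
  # at the reference year the slope term vanishes exactly
  x2 <- x; x2[st$b0] <- -3
  expect_equal(location_mean(dat, x2, "C03", 2000, "non_pregnant"),
               location_mean(dat, x, "C03", 2000, "non_pregnant"))
  expect_error(location_mean(dat, x, "ZZZ", 2000, "non_pregnant"),
               "unknown country")
})

test_that("pregnant location is the non-pregnant location minus the offset", {
  dat <- prepared_women()
  st <- dat$layout
  set.seed(1)
  x <- rnorm(st$d, 0, 0.3)
  x[st$a0] <- 125
  for (delta in c(0, 4.7, 12)) {
    x[st$dc] <- delta
    expect_equal(location_mean(dat, x, "C05", 2003, "pregnant"),
                 location_mean(dat, x, "C05", 2003, "non_pregnant") - delta)
  }
})

test_that("summary-mean loglik collapses to the textbook Normal density", {
  obs <- list(group = "children", coverage = "national",
              age_range_matches = TRUE, mean_hb = 108, n = 400, sd_hb = 13)
  shape <- default_mixture_shape()
  ll <- loglik_observation(obs, theta = 110, shape = shape,
                           sig = c(s_ns = 0, s_sub = 0, s_age = 0))
  expect_equal(ll, dnorm(108, 110, 13 / sqrt(400), log = TRUE))
  expect_error(loglik_observation(list(group = "children", n = 10,
                                       coverage = "national",
                                       age_range_matches = TRUE),
                                  110, shape, c(s_ns = 0)),
               "neither")
})

test_that("individual records contribute the sum of log mixture densities", {
  shape <- default_mixture_shape()
  d <- mixture_distribution(105, shape$offsets, shape$weights, shape$sds)
  h <- c(92, 104, 117, 130)
  ll <- loglik_observation(list(h = h), theta = 105, shape = shape,
                           sig = c(s_ns = 0))
  expect_equal(ll, sum(log(mixture_pdf(d, h))))
})

test_that("design inflation flattens the likelihood in the location", {
  obs <- function(sub) list(group = "children",
                            coverage = if (sub) "subnational" else "national",
                            age_range_matches = TRUE, mean_hb = 100, n = 900,
                            sd_hb = 12)
  shape <- default_mixture_shape()
  sig <- c(s_ns = 2, s_sub = 4, s_age = 1)
  num_grad <- function(sub, th) {
    e <- 1e-4
    (loglik_observation(obs(sub), th + e, shape, sig) -
       loglik_observation(obs(sub), th - e, shape, sig)) / (2 * e)
  }
  # same residual, larger variance: gradient strictly smaller in magnitude
  expect_lt(abs(num_grad(TRUE, 103)), abs(num_grad(FALSE, 103)))
})

test_that("log posterior is log prior plus summed log likelihood", {
  dat <- prepared_women()
  set.seed(2)
  state <- hbtrends:::.init_state(dat)
  lp <- logprior(dat, state$x, state$sig, state$zeta)
  shape <- shape_from_zeta(state$zeta, dat$cfg$K)
  prep <- hbtrends:::.prev_prep(dat, shape)
  eta <- as.vector(dat$ROWS %*% state$x)
  parts <- hbtrends:::.data_loglik_parts(dat, eta, state$sig, shape, prep)
  expect_equal(logposterior(dat, state$x, state$sig, state$zeta),
               lp + parts$lin + parts$prev + parts$ic)
})

test_that("shrinkage prior decreases when a country deviation doubles", {
  dat <- prepared_women()
  st <- dat$layout
  set.seed(3)
  state <- hbtrends:::.init_state(dat)
  x2 <- state$x
  x2[st$ac[4]] <- 2 * state$x[st$ac[4]] + 3   # move further from 0
  expect_lt(logprior(dat, x2, state$sig, state$zeta),
            logprior(dat, state$x, state$sig, state$zeta))
  # outside the support: negative pregnancy offset
  x3 <- state$x; x3[st$dc[1]] <- -1
  expect_equal(logprior(dat, x3, state$sig, state$zeta), -Inf)
})

test_that("the RW2 penalty is zero for lines and positive for curvature", {
  Tn <- 5
  D <- diff(diag(Tn), differences = 2)
  K <- crossprod(D)
  u_lin <- 3 + 0.7 * seq_len(Tn)
  expect_lt(abs(as.numeric(u_lin %*% K %*% u_lin)), 1e-12)
  # every interior perturbation with the same endpoints is penalised
  for (i in 2:4) {
    u <- u_lin; u[i] <- u[i] + 0.5
    expect_gt(as.numeric(u %*% K %*% u), 0)
  }
  # the constrained basis keeps the penalty full rank
  bb <- hbtrends:::.rw2_basis(Tn)
  expect_equal(qr(bb$Kc)$rank, Tn - 2)
})

test_that("probit prevalence terms see the shape through the mixture cdf", {
  shape <- default_mixture_shape()
  obs <- list(group = "children", coverage = "national",
              age_range_matches = TRUE, prev_anaemia = 0.4, n = 500)
  # theta solving F(110) = 0.4 maximises the prevalence likelihood
  d0 <- mixture_distribution(0, shape$offsets, shape$weights, shape$sds)
  th_star <- 110 - hbtrends:::std_mixture_quantile(shape, 0.4)
  ll_star <- loglik_observation(obs, th_star, shape, c(s_ns = 0))
  for (th in c(th_star - 2, th_star + 2))
    expect_lt(loglik_observation(obs, th, shape, c(s_ns = 0)), ll_star)
})
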