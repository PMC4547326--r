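small_children_dat <- function() {
  if (!is.null(.fix_env$datc)) return(.fix_env$datc)
  dd <- load_survey_data(toy_fit()$dir)
  .fix_env$datc <- prepare_model_data("children", dd$observations,
                                      dd$individuals, dd$covariates,
                                      dd$regions,
                                      model_config(years = 1998:2006,
                                                   t_ref = 2002))
  .fix_env$datc
}

test_that("identical seeds give identical draws; retained count is exact", {
  dat <- small_children_dat()
  cfg <- fit_config(chains = 2, warmup = 30, target_retained = 60, seed = 42)
  f1 <- fit_hb_model(dat, cfg)
  f2 <- fit_hb_model(dat, cfg)
  expect_identical(f1$draws$x, f2$draws$x)
  expect_identical(f1$draws$sig, f2$draws$sig)
  expect_identical(f1$draws$zeta, f2$draws$zeta)
  expect_equal(nrow(f1$draws$x), 60)
  # a chain count that does not divide the target still yields the target
  f3 <- fit_hb_model(dat, fit_config(chains = 3, warmup = 10,
                                     target_retained = 50, seed = 1))
  expect_equal(nrow(f3$draws$x), 50)
})

test_that("draws round-trip through write_draws and read_draws", {
  toy <- toy_fit()
  d <- tempfile()
  write_draws(toy$children, d)
  back <- read_draws(d, toy$children$dat)
  expect_equal(back$draws$x, toy$children$draws$x, tolerance = 1e-12)
  expect_equal(back$draws$sig, toy$children$draws$sig, tolerance = 1e-12)
  expect_equal(back$draws$zeta, toy$children$draws$zeta, tolerance = 1e-12)
  expect_identical(back$draws$chain, toy$children$draws$chain)
})

test_that("a single large survey pins the posterior location near its mean", {
  # one country, one summary survey: conjugate-style sanity check
  obs <- data.frame(source_id = "S01", country = "C01", year = 2002,
                    group = "children", coverage = "national",
                    n_regions_covered = NA, data_form = "summary", n = 4000,
                    mean_hb = 104, sd_hb = 13, prev_anaemia = NA,
                    prev_severe = NA, altitude_adjusted = TRUE,
                    smoking_adjusted = FALSE, age_range_matches = TRUE,
                    pregnant_fraction = NA)
  covs <- expand.grid(country = "C01", year = 1999:2005)
  for (nm in c("maternal_education", "urban_prop", "abs_latitude",
               "hb_disorder_prev", "mean_bmi", "mean_waz"))
    covs[[nm]] <- 0.5
  regions <- data.frame(country = "C01", region = "R01")
  dat <- prepare_model_data("children", validate_observations(obs), NULL,
                            covs, regions,
                            model_config(years = 1999:2005, t_ref = 2002))
  fit <- fit_hb_model(dat, fit_config(chains = 2, warmup = 200,
                                      target_retained = 800, seed = 5))
  th <- theta_draws(fit, "C01", 2002, "children")
  expect_lt(abs(mean(th) - 104), 2 * sd(th))
})

test_that("split R-hat separates mixed and disjoint chains", {
  set.seed(10)
  chain <- rep(1:2, each = 500)
  v_ok <- rnorm(1000)
  expect_lt(abs(split_rhat(v_ok, chain) - 1), 0.03)
  v_bad <- c(rnorm(500, 0), rnorm(500, 10))
  expect_gt(split_rhat(v_bad, chain), 1.5)
  expect_gt(ess_basic(v_ok, chain), 500)
})

test_that("diagnostics report covers every scalar parameter", {
  toy <- toy_fit()
  di <- fit_diagnostics(toy$children)
  st <- toy$children$dat$layout
  expect_equal(nrow(di),
               st$d + ncol(toy$children$draws$sig) +
                 ncol(toy$children$draws$zeta))
  expect_true(all(is.finite(di$ess)))
})

test_that("posterior predictive check has one row per summary observation", {
  toy <- toy_fit()
  pp <- posterior_predictive_check(toy$women)
  expect_equal(nrow(pp), length(toy$women$dat$lin))
  expect_true(is.numeric(attr(pp, "coverage")))
  # an observation equal to its predictive median is inside any interval
  expect_true(all(pp$pred_lo <= pp$pred_hi))
})

test_that("with no data the posterior reproduces the prior (smoke test)", {
  obs0 <- obs_fixture(1)[0, ]
  covs <- expand.grid(country = "C01", year = 1999:2005)
  for (nm in c("maternal_education", "urban_prop", "abs_latitude",
               "hb_disorder_prev", "mean_bmi", "mean_waz"))
    covs[[nm]] <- 0.5
  regions <- data.frame(country = "C01", region = "R01")
  dat <- prepare_model_data("children", validate_observations(obs0), NULL,
                            covs, regions,
                            model_config(years = 1999:2005, t_ref = 2002))
  fit <- fit_hb_model(dat, fit_config(chains = 2, warmup = 200,
                                      target_retained = 1500, seed = 2))
  # half-Normal(scale) has sd = scale * sqrt(1 - 2/pi)
  hn_sd <- function(scale) scale * sqrt(1 - 2 / pi)
  for (nm in c("s_ac", "s_ns")) {
    prior_sd <- hn_sd(c(s_ac = 10, s_ns = 5)[[nm]])
    expect_lt(abs(sd(fit$draws$sig[, nm]) - prior_sd) / prior_sd, 0.25)
  }
})
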