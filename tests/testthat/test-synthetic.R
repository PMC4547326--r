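test_that("the same seed reproduces the world and surveys exactly", {
  w1 <- generate_true_world(world_config(seed = 5))
  w2 <- generate_true_world(world_config(seed = 5))
  expect_identical(w1$theta, w2$theta)
  expect_identical(w1$covariates, w2$covariates)
  s1 <- generate_surveys(w1, survey_design(), seed = 6)
  s2 <- generate_surveys(w2, survey_design(), seed = 6)
  expect_identical(s1, s2)
})

test_that("a collapsed hierarchy puts every country exactly on the global line", {
  cfg <- world_config(seed = 2, region_intercept_sd = 0, region_slope_sd = 0,
                      country_intercept_sd = 0, country_slope_sd = 0,
                      nonlinear_sd = c(global = 0, region = 0, country = 0),
                      covariate_effects = c(maternal_education = 0,
                                            urban_prop = 0, abs_latitude = 0,
                                            hb_disorder_prev = 0,
                                            mean_bmi = 0, mean_waz = 0))
  w <- generate_true_world(cfg)
  line <- cfg$global_intercept["children"] +
    cfg$global_slope["children"] * (w$years - cfg$t_ref)
  for (ci in seq_along(w$countries))
    expect_equal(unname(w$theta$children[ci, ]), unname(line))
})

test_that("pregnant locations sit strictly below non-pregnant locations", {
  w <- tiny_world()
  expect_true(all(w$delta > 0))
  for (cc in w$countries)
    for (yy in range(w$years))
      expect_lt(world_theta(w, cc, yy, "pregnant"),
                world_theta(w, cc, yy, "non_pregnant"))
})

test_that("truth table prevalences match the mixture cdf and Monte Carlo", {
  w <- tiny_world()
  tt <- world_truth_table(w)
  expect_true(all(tt$true_severe_prev <= tt$true_prev))
  expect_true(all(tt$true_prev >= 0 & tt$true_prev <= 1))
  # Monte-Carlo oracle on one cell
  row <- tt[tt$group == "children" & tt$year == 2000, ][1, ]
  sh <- w$shape
  d <- mixture_distribution(row$true_mean, sh$offsets, sh$weights, sh$sds)
  set.seed(9)
  draws <- mixture_rand(d, 1e6)
  expect_lt(abs(row$true_prev - mean(draws < 110)), 0.002)
  expect_equal(row$true_mean,
               world_theta(w, row$country, row$year, "children"))
})

test_that("a symmetric single-normal world has prevalence 0.5 at its mean", {
  sh <- list(offsets = c(-2e-9, -1e-9, 0, 1e-9, 2e-9),
             weights = rep(0.2, 5), sds = rep(10, 5))
  d <- mixture_distribution(110, center_offsets(sh$offsets, sh$weights),
                            sh$weights, sh$sds)
  expect_equal(mixture_cdf(d, 110), 0.5, tolerance = 1e-9)
})

test_that("summary-only designs emit no individual records", {
  w <- tiny_world()
  sv <- generate_surveys(w, survey_design(frac_summary_only = 1), seed = 3)
  expect_null(sv$individuals)
  expect_true(all(sv$observations$data_form == "summary"))
  expect_true(all(sv$observations$sd_hb > 0))
  pr <- c(sv$observations$prev_anaemia, sv$observations$prev_severe)
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("with no non-sampling noise, huge surveys converge on the truth", {
  w <- tiny_world()
  sv <- generate_surveys(w, survey_design(nonsampling_sd = 0,
                                          subnational_extra_sd = 0,
                                          frac_summary_only = 1,
                                          frac_subnational = 0,
                                          surveys_per_country_decade = 0.8,
                                          n_per_survey = c(1e5, 1e5)),
                         seed = 13)
  obs <- sv$observations[sv$observations$group == "children" &
                           sv$observations$altitude_adjusted, ]
  for (i in seq_len(nrow(obs)))
    expect_lt(abs(obs$mean_hb[i] -
                    world_theta(w, obs$country[i], obs$year[i], "children")),
              0.5)
})

test_that("combined surveys record the realised pregnant fraction", {
  w <- tiny_world()
  sv <- generate_surveys(w, survey_design(frac_combined_women = 1,
                                          frac_summary_only = 0),
                         seed = 14)
  ind <- sv$individuals[sv$individuals$group == "women_combined", ]
  obs <- sv$observations[sv$observations$group == "women_combined", ]
  for (i in seq_len(nrow(obs))) {
    gw <- ind$gestational_weeks[ind$source_id == obs$source_id[i]]
    share <- mean(!is.na(gw) & gw > pregnancy_week_threshold())
    expect_equal(obs$pregnant_fraction[i], share)
  }
})
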