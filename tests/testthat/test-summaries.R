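test_that("cutoffs and iron shifts carry the published values", {
  co <- cutoff_set()
  expect_equal(group_cutoffs(co, "children"), c(total = 110, severe = 70))
  expect_equal(group_cutoffs(co, "pregnant"), c(total = 110, severe = 70))
  expect_equal(group_cutoffs(co, "non_pregnant"), c(total = 120, severe = 80))
  expect_equal(unname(iron_shifts()[c("pregnant", "non_pregnant", "children")]),
               c(10.17, 8.64, 8.0))
})

test_that("draw summaries follow the documented order-statistics rule", {
  s <- summarize_draws(rep(7, 100))
  expect_equal(c(s$point, s$lo, s$hi), c(7, 7, 7))
  s2 <- summarize_draws(1:1000)
  expect_equal(s2$lo, 25.975)
  expect_equal(s2$hi, 975.025)
  expect_true(s2$lo >= 25 && s2$lo <= 26 && s2$hi >= 975 && s2$hi <= 976)
  set.seed(4)
  v <- rnorm(500)
  expect_equal(summarize_draws(v), summarize_draws(sample(v)))
  expect_error(summarize_draws(numeric(0)), "empty")
})

test_that("trend probability is 0.5 under symmetry and complements on swap", {
  expect_equal(prob_increase(rep(0, 10), rep(1, 10)), 1)
  d <- c(seq(-3, 3, by = 0.25))        # symmetric changes about zero
  expect_equal(prob_increase(rep(0, length(d)), d), 0.5)
  set.seed(6)
  v1 <- rnorm(999); v2 <- rnorm(999)
  expect_equal(prob_increase(v1, v2), 1 - prob_increase(v2, v1))
})

test_that("decadal change matches its closed forms", {
  expect_equal(decadal_change(100, 100, 1995, 2011, "mean_hb"), 0)
  expect_equal(decadal_change(0.3, 0.3, 1995, 2011, "prevalence"), 0)
  expect_equal(decadal_change(100, 108, 1995, 2011, "mean_hb"), 5)
  expect_equal(decadal_change(0.4, 0.2, 1995, 2011, "prevalence"),
               0.5^(10 / 16) - 1)
  expect_equal(decadal_change(0.4, 0.2, 1995, 2011, "prevalence",
                              "arithmetic"), -0.5 * 10 / 16)
})

test_that("iron-amenable share matches the Normal closed form and is monotone", {
  near_normal <- mixture_distribution(
    110, center_offsets(c(0, 1, 2, 3, 4) * 1e-9, c(1 - 4e-16, rep(1e-16, 4))),
    c(1 - 4e-16, rep(1e-16, 4)), rep(12, 5))
  share <- iron_amenable_share(near_normal, 8, 110)
  expect_equal(share, (0.5 - pnorm(-8 / 12)) / 0.5, tolerance = 1e-8)
  expect_lt(abs(share - 0.495), 0.001)
  shifts <- c(0.5, 2, 5, 8, 15, 40, 200)
  shares <- vapply(shifts, function(s)
    iron_amenable_share(near_normal, s, 110), numeric(1))
  expect_true(all(diff(shares) > 0))
  expect_gt(shares[length(shares)], 0.9999)   # shift to infinity clears all
  expect_lt(shares[1], 0.07)                  # shift to zero clears none
  expect_error(iron_amenable_share(near_normal, 8, -500), "undefined")
})

test_that("per-draw distributions have length S and obey the mean identity", {
  toy <- toy_fit()
  fit <- toy$children
  pd <- per_draw_distribution(fit, "C01", 2002, "children")
  expect_equal(length(pd), nrow(fit$draws$x))
  th <- theta_draws(fit, "C01", 2002, "children")
  for (s in c(1, 57, 200))
    expect_equal(mixture_mean(pd[[s]]), th[s])
  # collapsing posterior variance: repeating one draw gives identical mixtures
  fit1 <- fit
  keep <- rep(13, 5)
  fit1$draws$x <- fit$draws$x[keep, ]
  fit1$draws$zeta <- fit$draws$zeta[keep, ]
  pd1 <- per_draw_distribution(fit1, "C01", 2002, "children")
  expect_equal(pd1[[1]], pd1[[5]], tolerance = 1e-12)
})

test_that("prevalence draws respect limits, nesting, and Monte Carlo", {
  toy <- toy_fit()
  fit <- toy$women
  th <- theta_draws(fit, "C02", 2004, "non_pregnant")
  expect_gt(min(hbtrends:::.prev_draws_theta(fit, th, 250)), 0.999999)
  p_tot <- prevalence_draws(fit, "C02", 2004, "non_pregnant", 120)
  p_sev <- prevalence_draws(fit, "C02", 2004, "non_pregnant", 80)
  expect_true(all(p_sev <= p_tot))
  cuts <- seq(60, 180, by = 20)
  pm <- vapply(cuts, function(co)
    mean(prevalence_draws(fit, "C02", 2004, "non_pregnant", co)), numeric(1))
  expect_true(all(diff(pm) > 0))
  # Monte-Carlo oracle on one posterior mixture
  d1 <- per_draw_distribution(fit, "C02", 2004, "non_pregnant")[[25]]
  set.seed(11)
  mc <- mean(mixture_rand(d1, 1e6) < 120)
  expect_lt(abs(mixture_cdf(d1, 120) - p_tot[25]), 1e-12)
  expect_lt(abs(p_tot[25] - mc), 0.002)
})

test_that("aggregation is population-weighted and conserves exactly", {
  toy <- toy_fit()
  fit <- toy$children
  pops <- toy$data$population
  countries <- toy$data$regions$country
  # single-member aggregate equals the country itself
  one <- aggregate_draws(fit, countries[1], 2002, "children", pops,
                         "prevalence", 110)
  expect_equal(one, prevalence_draws(fit, countries[1], 2002, "children", 110))
  # global aggregate equals the explicit weighted sum, draw by draw
  agg <- aggregate_draws(fit, countries, 2002, "children", pops,
                         "prevalence", 110)
  w <- vapply(countries, function(cc)
    pops$population[pops$country == cc & pops$year == 2002 &
                      pops$group == "children"], numeric(1))
  ref <- (w[1] * prevalence_draws(fit, countries[1], 2002, "children", 110) +
            w[2] * prevalence_draws(fit, countries[2], 2002, "children", 110)) /
    sum(w)
  expect_lt(max(abs(agg - ref)), 1e-12)
  expect_error(aggregate_draws(fit, countries, 2002, "children",
                               pops[pops$country != countries[1], ],
                               "prevalence", 110),
               "missing population")
  # counts: prevalence times population, severe nested under total
  ct <- hb_counts(fit, countries, 2002, "children", pops, 110,
                  scope = "globe", scope_id = "globe")
  cs <- hb_counts(fit, countries, 2002, "children", pops, 70,
                  scope = "globe", scope_id = "globe")
  expect_true(cs$point <= ct$point && cs$hi <= ct$hi)
  expect_gt(ct$point, 0)
})

test_that("halving probability matches an explicit per-draw loop", {
  toy <- toy_fit()
  fit <- toy$women
  pops <- toy$data$population
  countries <- toy$data$regions$country
  hp <- halving_probability(fit, countries, "non_pregnant", pops, 120,
                            base_year = 2005, target_year = 2020)
  p_base <- aggregate_draws(fit, countries, 2005, "non_pregnant", pops,
                            "prevalence", 120)
  p_tgt <- aggregate_draws(fit, countries, 2020, "non_pregnant", pops,
                           "prevalence", 120)
  n_halved <- 0L
  for (s in seq_along(p_base))
    if (p_tgt[s] <= 0.5 * p_base[s]) n_halved <- n_halved + 1L
  expect_identical(hp, n_halved / length(p_base))
  expect_error(halving_probability(fit, countries, "non_pregnant", pops, 120,
                                   base_year = 1950), "base_year")
})

test_that("halving probability responds to the trend direction", {
  toy <- toy_fit()
  fit <- toy$women
  st <- fit$dat$layout
  pops <- toy$data$population
  countries <- toy$data$regions$country
  # force strong improvement in every draw
  up <- fit
  up$draws$x[, c(st$b0, st$br, st$bc)] <- 0
  up$draws$x[, st$b0] <- 3
  expect_gt(halving_probability(up, countries, "non_pregnant", pops, 120,
                                base_year = 2005, target_year = 2020), 0.99)
  # no trend at all: the extrapolated prevalence cannot halve
  flat <- fit
  flat$draws$x[, c(st$b0, st$br, st$bc)] <- 0
  expect_lt(halving_probability(flat, countries, "non_pregnant", pops, 120,
                                base_year = 2005, target_year = 2020), 0.01)
})
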