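test_that("CDC shift matches the polynomial and its published anchors", {
  expect_equal(cdc_altitude_shift(0), 0)
  expect_equal(cdc_altitude_shift(1500), 3.753222077, tolerance = 1e-8)
  expect_equal(cdc_altitude_shift(2200), 9.151449872, tolerance = 1e-8)
  expect_gte(cdc_altitude_shift(1500), 3)   # at least 3 g/L at 1500 m
  expect_gte(cdc_altitude_shift(2200), 8)   # roughly 8 g/L above 2000 m
  expect_error(cdc_altitude_shift(-10), "non-negative")
})

test_that("shift is zero below the application altitude and monotone above 1455 m", {
  expect_equal(cdc_altitude_shift(c(200, 800, 999)), c(0, 0, 0))
  grid <- seq(1455, 4500, by = 15)
  expect_true(all(diff(cdc_altitude_shift(grid)) >= 0))
  expect_true(all(cdc_altitude_shift(seq(0, 5000, by = 50)) >= 0))
})

test_that("individual adjustment subtracts the shift and keeps an audit trail", {
  rec <- list(hb = 120, altitude_m = 2200, altitude_adjusted = FALSE)
  out <- adjust_individual(rec)
  expect_equal(out$hb, 110.8485501, tolerance = 1e-7)
  expect_equal(out$hb_raw, 120)
  expect_true(out$altitude_adjusted)
  expect_error(adjust_individual(out), "twice")

  sea <- adjust_individual(list(hb = 120, altitude_m = 0))
  expect_equal(sea$hb, 120)

  noalt <- adjust_individual(list(hb = 120, altitude_m = NA))
  expect_equal(noalt$hb, 120)
  expect_equal(noalt$adjust_note, "unadjusted_no_altitude")
})

test_that("summary adjustment applies the population-weighted shift", {
  obs <- data.frame(source_id = "S1", country = "C01", year = 2000,
                    group = "children", coverage = "national",
                    n_regions_covered = NA, data_form = "summary", n = 500,
                    mean_hb = 115, sd_hb = 14, prev_anaemia = NA,
                    prev_severe = NA, altitude_adjusted = FALSE,
                    smoking_adjusted = FALSE, age_range_matches = TRUE,
                    pregnant_fraction = NA)
  half_high <- data.frame(band_midpoint_m = c(0, 2200),
                          population_share = c(0.5, 0.5))
  out <- adjust_summary(obs, half_high)
  expect_equal(out$mean_hb, 115 - 4.575724936, tolerance = 1e-8)
  expect_equal(out$adjust_note, "summary_adjusted")
  # n, sd and group are never changed
  expect_equal(out[c("n", "sd_hb", "group")], obs[c("n", "sd_hb", "group")])

  lowland <- data.frame(band_midpoint_m = 0, population_share = 1)
  out2 <- adjust_summary(obs, lowland)
  expect_equal(out2$mean_hb, 115)
  expect_equal(out2$adjust_note, "low_altitude_country")
})

test_that("summary-level shift equals the brute-force mean of per-band shifts", {
  set.seed(8)
  bands <- data.frame(band_midpoint_m = c(0, 700, 1200, 1900, 2600, 3400),
                      population_share = as.vector(prop.table(runif(6))))
  obs <- data.frame(source_id = "S1", country = "C01", year = 2000,
                    group = "children", coverage = "national",
                    n_regions_covered = NA, data_form = "summary", n = 100,
                    mean_hb = 120, sd_hb = 12, prev_anaemia = NA,
                    prev_severe = NA, altitude_adjusted = FALSE,
                    smoking_adjusted = FALSE, age_range_matches = TRUE,
                    pregnant_fraction = NA)
  out <- adjust_summary(obs, bands)
  # oracle: individuals living at the band midpoints, in band proportions
  brute <- 0
  for (i in seq_len(nrow(bands)))
    brute <- brute + bands$population_share[i] *
      cdc_altitude_shift(bands$band_midpoint_m[i])
  expect_equal(120 - out$mean_hb, brute, tolerance = 1e-9)
})

test_that("smoking policy never modifies data and is idempotent", {
  obs <- list(mean_hb = 120, smoking_adjusted = TRUE)
  out <- smoking_policy(obs)
  expect_equal(out$mean_hb, 120)
  expect_equal(out$smoking_note, "pre_adjusted")
  obs2 <- smoking_policy(list(mean_hb = 120, smoking_adjusted = FALSE))
  expect_equal(obs2$smoking_note, "not_adjusted")
  expect_equal(smoking_policy(obs2), obs2)
})
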