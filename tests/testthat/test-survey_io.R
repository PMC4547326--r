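test_that("an empty file with a valid header yields an empty set", {
  p <- write_obs_csv(obs_fixture(3)[0, ])
  obs <- read_observations(p)
  expect_equal(nrow(obs), 0)
  expect_equal(nrow(attr(obs, "rejected")), 0)
})

test_that("a missing required column is a schema error", {
  o <- obs_fixture(2); o$mean_hb <- NULL
  expect_error(read_observations(write_obs_csv(o)), "missing required column")
})

test_that("invalid rows are rejected with row-level reasons", {
  o <- obs_fixture(3)
  o$sd_hb[2] <- -1
  obs <- read_observations(write_obs_csv(o))
  expect_equal(nrow(obs), 2)
  rej <- attr(obs, "rejected")
  expect_equal(rej$source_id, "S02")
  expect_equal(rej$reason, "sd_hb_nonpositive")
})

test_that("observations round-trip through write and read", {
  o <- obs_fixture(4)
  o$coverage[2] <- "subnational"; o$n_regions_covered[2] <- 4
  p1 <- write_obs_csv(o)
  obs <- read_observations(p1)
  p2 <- tempfile(fileext = ".csv")
  write_observations(obs, p2)
  expect_equal(read_observations(p2), obs, ignore_attr = TRUE)
})

test_that("inclusion rules follow the three-region representativeness rule", {
  o <- obs_fixture(4)
  o$coverage <- c("national", "subnational", "subnational", "subnational")
  o$n_regions_covered <- c(NA, 2, 3, 5)
  res <- apply_inclusion_rules(validate_observations(o))
  expect_equal(res$included$source_id, c("S01", "S03", "S04"))
  expect_equal(res$excluded$source_id, "S02")
  expect_equal(res$excluded$reason, "subnational_lt_3_regions")
  # partition: nothing lost or duplicated
  expect_setequal(c(res$included$source_id, res$excluded$source_id),
                  o$source_id)
  # idempotence
  again <- apply_inclusion_rules(res$included)
  expect_equal(again$included, res$included)
  expect_equal(nrow(again$excluded), 0)
})

test_that("pregnancy classification is strictly after 8 gestational weeks", {
  rec <- function(gw) list(group = "non_pregnant", gestational_weeks = gw)
  expect_equal(classify_pregnancy(rec(12)), "pregnant")
  expect_equal(classify_pregnancy(rec(8)), "non_pregnant")
  expect_equal(classify_pregnancy(rec(8.5)), "pregnant")
  expect_equal(classify_pregnancy(rec(NA)), "non_pregnant")
  expect_error(classify_pregnancy(list(group = "children",
                                       gestational_weeks = 12)),
               "women")
})

test_that("summarising individuals matches hand computation and a loop oracle", {
  recs <- data.frame(source_id = "S01", country = "C01", year = 2000,
                     group = "non_pregnant", hb = c(100, 120))
  s <- summarize_individuals(recs)
  expect_equal(s$mean_hb, 110)
  expect_equal(s$sd_hb, 14.14213562, tolerance = 1e-8)
  expect_equal(s$prev_anaemia, 0.5)   # cutoff 120 g/L, one of two below
  expect_equal(s$n, 2)

  # brute-force prevalence oracle on a random cell
  set.seed(3)
  recs2 <- data.frame(source_id = "S02", country = "C01", year = 2001,
                      group = "children", hb = rnorm(400, 108, 15))
  s2 <- summarize_individuals(recs2)
  cnt <- 0
  for (h in recs2$hb) if (h < 110) cnt <- cnt + 1
  expect_equal(s2$prev_anaemia, cnt / 400, tolerance = 1e-9)
  expect_equal(s2$mean_hb, sum(recs2$hb) / 400, tolerance = 1e-9)

  # degenerate zero-variance cell is flagged
  recs3 <- data.frame(source_id = "S03", country = "C01", year = 2002,
                      group = "children", hb = c(110, 110, 110))
  expect_true(summarize_individuals(recs3)$degenerate)
  # single-record cell: sd undefined
  expect_error(summarize_individuals(recs3[1, ]), "single record")
})

test_that("individual records outside 25-220 g/L are flagged, not dropped silently", {
  ind <- data.frame(source_id = "S01", country = "C01", year = 2000,
                    group = "children", hb = c(110, 20, 230, 95),
                    altitude_m = NA, gestational_weeks = NA, age = 30,
                    cluster_id = NA, coverage = "national",
                    n_regions_covered = NA, altitude_adjusted = TRUE,
                    age_range_matches = TRUE)
  suppressMessages(out <- validate_individuals(ind))
  expect_equal(nrow(out), 2)
  expect_equal(nrow(attr(out, "flagged")), 2)
})
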