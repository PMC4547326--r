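# small programmatic fixtures shared across test files

obs_fixture <- function(n = 3) {
  data.frame(
    source_id = sprintf("S%02d", seq_len(n)),
    country = "C01", year = 2000 + seq_len(n), group = "children",
    coverage = "national", n_regions_covered = NA,
    data_form = "summary", n = 500, mean_hb = 110, sd_hb = 14,
    prev_anaemia = 0.4, prev_severe = 0.05,
    altitude_adjusted = TRUE, smoking_adjusted = FALSE,
    age_range_matches = TRUE, pregnant_fraction = NA,
    stringsAsFactors = FALSE)
}

write_obs_csv <- function(obs, path = tempfile(fileext = ".csv")) {
  write.csv(obs, path, row.names = FALSE, na = "")
  path
}

# a tiny simulated data directory (one world + surveys), memoised per session
.fix_env <- new.env(parent = emptyenv())

tiny_world_dir <- function() {
  if (!is.null(.fix_env$dir)) return(.fix_env$dir)
  w <- generate_true_world(world_config(seed = 11))
  sv <- generate_surveys(w, survey_design(), seed = 12)
  d <- file.path(tempdir(), "tiny_world")
  write_world(w, sv, d)
  .fix_env$world <- w
  .fix_env$dir <- d
  d
}

tiny_world <- function() {
  tiny_world_dir()
  .fix_env$world
}

# a very small two-country world fitted for both group families, used by
# sampler, summary, and pipeline tests
toy_fit <- function() {
  if (!is.null(.fix_env$toy)) return(.fix_env$toy)
  cfgw <- world_config(n_regions = 1, countries_per_region = 2,
                       year_start = 1998, year_end = 2006, seed = 21)
  w <- generate_true_world(cfgw)
  sv <- generate_surveys(w, survey_design(surveys_per_country_decade = 6),
                         seed = 22)
  d <- file.path(tempdir(), "toy_world")
  write_world(w, sv, d)
  mc <- model_config(years = 1998:2006, t_ref = 2002)
  fits <- run_fit(d, mc, fit_config(chains = 2, warmup = 150,
                                    target_retained = 500, seed = 7))
  .fix_env$toy <- c(fits, list(world = w, dir = d, model_cfg = mc))
  .fix_env$toy
}
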