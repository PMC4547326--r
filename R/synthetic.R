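#' Configuration of a synthetic world
#'
#' The generator mirrors the model's data-generating assumptions: country
#' locations are a global line plus region and country deviations, a smooth
#' nonlinear component (second-order random walk, detrended so it carries
#' no linear part) at each level, and a covariate term; pregnant women's
#' locations are the non-pregnant location minus a country-level offset
#' drawn from `pregnancy_offset_range` (haemoglobin is 8--15 g/L lower in
#' pregnancy). All settings are in g/L (slopes in g/L per year).
#'
#' @param n_regions number of regions.
#' @param countries_per_region countries per region.
#' @param year_start,year_end analysis years (default 1990--2012).
#' @param seed integer seed; the world is deterministic given the seed.
#' @param global_intercept named (children, women) global intercepts at
#'   `t_ref` in g/L.
#' @param global_slope named (children, women) global slopes, g/L per year.
#' @param region_intercept_sd,region_slope_sd,country_intercept_sd,country_slope_sd
#'   sds of the hierarchical deviations.
#' @param nonlinear_sd named (global, region, country) RW2 innovation sds,
#'   g/L per year.
#' @param pregnancy_offset_range interval from which country pregnancy
#'   offsets are drawn uniformly, g/L.
#' @param covariate_effects named vector of effects in g/L per covariate
#'   unit (covariates are centred within the world before entering).
#' @param mixture_shape population mixture shape (see
#'   [default_mixture_shape()]).
#' @param t_ref reference year of the linear trend.
#' @param frac_highland fraction of countries with a substantial
#'   high-altitude population.
#' @return a list of class `hb_world_config`.
#' @export
world_config <- function(n_regions = 2, countries_per_region = 5,
                         year_start = 1990, year_end = 2012, seed = 1,
                         global_intercept = c(children = 105, women = 125),
                         global_slope = c(children = 0.25, women = 0.12),
                         region_intercept_sd = 6, region_slope_sd = 0.12,
                         country_intercept_sd = 5, country_slope_sd = 0.12,
                         nonlinear_sd = c(global = 0.12, region = 0.08,
                                          country = 0.1),
                         pregnancy_offset_range = c(8, 15),
                         covariate_effects = c(maternal_education = 0.3,
                                               urban_prop = 2,
                                               abs_latitude = 0.02,
                                               hb_disorder_prev = -20,
                                               mean_bmi = 0.3,
                                               mean_waz = 3),
                         mixture_shape = default_mixture_shape(),
                         t_ref = 2000, frac_highland = 0.2) {
  stopifnot(n_regions >= 1, countries_per_region >= 1,
            year_end - year_start >= 2,
            pregnancy_offset_range[1] > 0,
            diff(pregnancy_offset_range) >= 0)
  structure(as.list(environment()), class = "hb_world_config")
}

# detrended RW2 path of length Tn with innovation sd `s` (zero when s = 0)
.rw2_path <- function(Tn, s) {
  if (s == 0) return(numeric(Tn))
  inc <- stats::rnorm(Tn - 2, 0, s)
  u <- c(0, 0, cumsum(cumsum(inc)))  # double integration of innovations
  t <- seq_len(Tn)
  stats::residuals(stats::lm(u ~ t))
}

#' Generate a synthetic world with known true haemoglobin distributions
#'
#' @param cfg a [world_config()].
#' @return an object of class `hb_world` holding, per country-year-group,
#'   the true location (the mixture mean), the shared mixture shape,
#'   covariates, the region map, populations, and altitude bands.
#' @export
generate_true_world <- function(cfg = world_config()) {
  if (cfg$n_regions < 1 || cfg$countries_per_region < 1)
    stop("degenerate configuration: need at least one region and country")
  set.seed(cfg$seed)
  R <- cfg$n_regions; Cn <- R * cfg$countries_per_region
  years <- cfg$year_start:cfg$year_end; Tn <- length(years)
  regions <- sprintf("R%02d", seq_len(R))
  countries <- sprintf("C%02d", seq_len(Cn))
  region_of <- rep(seq_len(R), each = cfg$countries_per_region)

  # covariates: smooth country series, centred before applying effects
  cov_names <- names(cfg$covariate_effects)
  covariates <- expand.grid(country = countries, year = years,
                            KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
  covariates <- covariates[order(covariates$country, covariates$year), ]
  base <- list(
    maternal_education = stats::runif(Cn, 2, 10),
    urban_prop = stats::runif(Cn, 0.2, 0.7),
    abs_latitude = stats::runif(Cn, 0, 60),
    hb_disorder_prev = stats::runif(Cn, 0, 0.1),
    mean_bmi = stats::runif(Cn, 21, 27),
    mean_waz = stats::runif(Cn, -1.5, 0.5))
  trend <- list(maternal_education = 0.08, urban_prop = 0.004,
                abs_latitude = 0, hb_disorder_prev = 0,
                mean_bmi = 0.03, mean_waz = 0.01)
  for (nm in cov_names) {
    v <- rep(base[[nm]], each = Tn) + trend[[nm]] * rep(years - cfg$t_ref, Cn)
    if (nm == "urban_prop") v <- pmin(pmax(v, 0), 1)
    if (nm == "hb_disorder_prev") v <- pmin(pmax(v, 0), 1)
    covariates[[nm]] <- v
  }

  # hierarchical linear deviations and RW2 components per family
  fam_cov <- list(children = .family_covariates("children"),
                  women = .family_covariates("women"))
  theta <- list()
  for (fam in c("children", "women")) {
    ar <- stats::rnorm(R, 0, cfg$region_intercept_sd)
    br <- stats::rnorm(R, 0, cfg$region_slope_sd)
    ac <- stats::rnorm(Cn, 0, cfg$country_intercept_sd)
    bc <- stats::rnorm(Cn, 0, cfg$country_slope_sd)
    u0 <- .rw2_path(Tn, cfg$nonlinear_sd["global"])
    ur <- vapply(seq_len(R), function(r)
      .rw2_path(Tn, cfg$nonlinear_sd["region"]), numeric(Tn))
    uc <- vapply(seq_len(Cn), function(ci)
      .rw2_path(Tn, cfg$nonlinear_sd["country"]), numeric(Tn))
    th <- matrix(0, Cn, Tn, dimnames = list(countries, years))
    for (ci in seq_len(Cn)) {
      r <- region_of[ci]
      zt <- 0
      for (nm in fam_cov[[fam]]) {
        zc <- covariates[[nm]][covariates$country == countries[ci]]
        zt <- zt + cfg$covariate_effects[nm] * (zc - mean(covariates[[nm]]))
      }
      th[ci, ] <- cfg$global_intercept[fam] + ar[r] + ac[ci] +
        (cfg$global_slope[fam] + br[r] + bc[ci]) * (years - cfg$t_ref) +
        u0 + ur[, r] + uc[, ci] + zt
    }
    theta[[fam]] <- th
  }
  delta <- stats::runif(Cn, cfg$pregnancy_offset_range[1],
                        cfg$pregnancy_offset_range[2])

  # populations (persons) by country-year-group, mild growth
  pop0 <- stats::runif(Cn, 5e5, 5e6)           # children under 5
  growth <- stats::runif(Cn, 0, 0.02)
  preg_rate <- stats::runif(Cn, 0.04, 0.08)    # pregnant share of women
  pops <- do.call(rbind, lapply(seq_len(Cn), function(ci) {
    g <- pop0[ci] * (1 + growth[ci])^(years - years[1])
    women <- 3 * g
    rbind(
      data.frame(country = countries[ci], year = years, group = "children",
                 population = g),
      data.frame(country = countries[ci], year = years, group = "non_pregnant",
                 population = women * (1 - preg_rate[ci])),
      data.frame(country = countries[ci], year = years, group = "pregnant",
                 population = women * preg_rate[ci]))
  }))

  # altitude bands: most countries lowland, a fraction highland
  n_high <- round(cfg$frac_highland * Cn)
  highland <- seq_len(Cn) <= n_high   # deterministic given ordering
  alt <- do.call(rbind, lapply(seq_len(Cn), function(ci) {
    if (highland[ci])
      data.frame(country = countries[ci],
                 band_midpoint_m = c(500, 1800, 2500),
                 population_share = c(0.55, 0.25, 0.2))
    else
      data.frame(country = countries[ci], band_midpoint_m = 200,
                 population_share = 1)
  }))

  structure(list(cfg = cfg, years = years, countries = countries,
                 regions = regions, region_of = region_of,
                 region_map = data.frame(country = countries,
                                         region = regions[region_of],
                                         stringsAsFactors = FALSE),
                 covariates = covariates, theta = theta, delta = delta,
                 preg_rate = preg_rate, shape = cfg$mixture_shape,
                 populations = pops, altitude_bands = alt,
                 highland = highland),
            class = "hb_world")
}

#' True location of a country-year-group in a synthetic world
#' @param world an `hb_world`.
#' @param country,year,group cell identifiers.
#' @return true mean haemoglobin in g/L.
#' @export
world_theta <- function(world, country, year, group) {
  ti <- match(year, world$years); ci <- match(country, world$countries)
  if (is.na(ti) || is.na(ci)) stop("unknown country-year")
  if (group == "children") world$theta$children[ci, ti]
  else if (group == "non_pregnant") world$theta$women[ci, ti]
  else if (group == "pregnant") world$theta$women[ci, ti] - world$delta[ci]
  else stop("unknown group: ", group)
}

#' Survey design of the synthetic generator
#'
#' Controls the heterogeneity of the emitted surveys: summary-only versus
#' individual-record sources, combined reporting of women, subnational
#' coverage, age-range mismatch, embedded (unadjusted) altitude effects,
#' and non-sampling noise.
#'
#' @param surveys_per_country_decade expected surveys per country per
#'   decade.
#' @param frac_summary_only fraction of surveys emitting summary rows only.
#' @param frac_combined_women fraction of surveys pooling pregnant and
#'   non-pregnant women.
#' @param frac_subnational fraction of subnational surveys.
#' @param frac_age_mismatch fraction of surveys not covering the target age
#'   range exactly.
#' @param frac_unadjusted_altitude among highland-country surveys, the
#'   fraction left unadjusted for altitude at the source.
#' @param n_per_survey integer range of per-group sample sizes.
#' @param nonsampling_sd survey-level non-sampling sd, g/L.
#' @param subnational_extra_sd extra survey-level sd for subnational
#'   sources, g/L.
#' @return a list of class `hb_survey_design`.
#' @export
survey_design <- function(surveys_per_country_decade = 2,
                          frac_summary_only = 0.5,
                          frac_combined_women = 0.3,
                          frac_subnational = 0.25,
                          frac_age_mismatch = 0.1,
                          frac_unadjusted_altitude = 0.7,
                          n_per_survey = c(150, 800),
                          nonsampling_sd = 2, subnational_extra_sd = 3) {
  fr <- c(frac_summary_only, frac_combined_women, frac_subnational,
          frac_age_mismatch, frac_unadjusted_altitude)
  if (any(fr < 0 | fr > 1)) stop("design fractions must lie in [0, 1]")
  stopifnot(nonsampling_sd >= 0, subnational_extra_sd >= 0,
            n_per_survey[1] >= 2)
  structure(as.list(environment())[c(
    "surveys_per_country_decade", "frac_summary_only", "frac_combined_women",
    "frac_subnational", "frac_age_mismatch", "frac_unadjusted_altitude",
    "n_per_survey", "nonsampling_sd", "subnational_extra_sd")],
    class = "hb_survey_design")
}

# uniform integer in [lo, hi]; safe when lo == hi
.runif_int <- function(lo, hi) {
  if (lo == hi) return(lo)
  sample(seq(lo, hi), 1)
}

.rmix_shape <- function(n, theta, shape) {
  k <- sample.int(length(shape$weights), n, replace = TRUE,
                  prob = shape$weights)
  stats::rnorm(n, theta + shape$offsets[k], shape$sds[k])
}

#' Generate synthetic surveys from a world
#'
#' Survey country-years are sampled; each survey receives a non-sampling
#' location offset (larger for subnational sources), draws individuals from
#' the perturbed mixtures, and is emitted either as individual records (with
#' a stub observation row) or as summary statistics with prevalences
#' against the group cutoffs. Combined-women surveys pool pregnant and
#' non-pregnant draws and record the realised pregnant fraction (by the
#' strictly-after-8-weeks operational definition applied to simulated
#' gestational ages). Surveys in highland countries embed altitude effects;
#' a fraction are left unadjusted so the adjustment pipeline is exercised.
#'
#' @param world an `hb_world`.
#' @param design a [survey_design()].
#' @param seed integer seed.
#' @param cutoffs a [cutoff_set()].
#' @return list with `observations` (summary rows and individual-source
#'   stubs) and `individuals` (record-level data).
#' @export
generate_surveys <- function(world, design = survey_design(), seed = 1,
                             cutoffs = cutoff_set()) {
  set.seed(seed)
  years <- world$years
  decades <- (max(years) - min(years) + 1) / 10
  obs <- list(); ind <- list()
  sid <- 0L
  for (ci in seq_along(world$countries)) {
    cc <- world$countries[ci]
    n_surv <- stats::rpois(1, design$surveys_per_country_decade * decades)
    if (n_surv == 0) next
    yrs <- sample(years, n_surv, replace = TRUE)
    for (yy in yrs) {
      sid <- sid + 1L
      source_id <- sprintf("S%04d", sid)
      summary_only <- stats::runif(1) < design$frac_summary_only
      subnat <- stats::runif(1) < design$frac_subnational
      n_reg_cov <- if (subnat) sample(1:5, 1) else NA
      age_ok <- stats::runif(1) > design$frac_age_mismatch
      combined <- stats::runif(1) < design$frac_combined_women
      highland <- world$highland[ci]
      embed_alt <- highland
      pre_adjusted <- highland &&
        stats::runif(1) > design$frac_unadjusted_altitude
      ti <- match(yy, years)
      extra <- if (subnat) design$subnational_extra_sd else 0
      eps <- stats::rnorm(2, 0, sqrt(design$nonsampling_sd^2 + extra^2))
      bands <- world$altitude_bands[world$altitude_bands$country == cc, ]

      draw_cell <- function(theta, n) .rmix_shape(n, theta, world$shape)
      alt_of <- function(n) {
        if (!embed_alt) return(rep(NA_real_, n))
        bands$band_midpoint_m[sample.int(nrow(bands), n, replace = TRUE,
                                         prob = bands$population_share)]
      }

      # children cell
      n_c <- .runif_int(design$n_per_survey[1], design$n_per_survey[2])
      hb_c <- draw_cell(world$theta$children[ci, ti] + eps[1], n_c)
      alt_c <- alt_of(n_c)
      hb_c_obs <- hb_c + ifelse(is.na(alt_c), 0, cdc_altitude_shift(alt_c))
      if (pre_adjusted) hb_c_obs <- hb_c_obs - ifelse(is.na(alt_c), 0,
                                                      cdc_altitude_shift(alt_c))

      # women: gestational ages, operational classification
      n_w <- .runif_int(design$n_per_survey[1], design$n_per_survey[2])
      pregnant_bio <- stats::runif(n_w) < world$preg_rate[ci]
      gw <- ifelse(pregnant_bio, stats::runif(n_w, 0, 42), NA)
      op_preg <- !is.na(gw) & gw > pregnancy_week_threshold()
      th_np <- world$theta$women[ci, ti] + eps[2]
      th_p <- th_np - world$delta[ci]
      hb_w <- numeric(n_w)
      hb_w[!op_preg] <- draw_cell(th_np, sum(!op_preg))
      hb_w[op_preg] <- draw_cell(th_p, sum(op_preg))
      alt_w <- alt_of(n_w)
      hb_w_obs <- hb_w + ifelse(is.na(alt_w), 0, cdc_altitude_shift(alt_w))
      if (pre_adjusted) hb_w_obs <- hb_w_obs - ifelse(is.na(alt_w), 0,
                                                      cdc_altitude_shift(alt_w))
      altitude_adjusted <- !embed_alt || pre_adjusted

      obs_row <- function(group, form, n, mean_hb = NA, sd_hb = NA,
                          prev_t = NA, prev_s = NA, pfrac = NA)
        data.frame(source_id = source_id, country = cc, year = yy,
                   group = group,
                   coverage = if (subnat) "subnational" else "national",
                   n_regions_covered = ifelse(subnat, n_reg_cov, NA),
                   data_form = form, n = n, mean_hb = mean_hb, sd_hb = sd_hb,
                   prev_anaemia = prev_t, prev_severe = prev_s,
                   altitude_adjusted = altitude_adjusted,
                   smoking_adjusted = FALSE, age_range_matches = age_ok,
                   pregnant_fraction = pfrac, stringsAsFactors = FALSE)
      ind_rows <- function(group, hb, alt, gw_v, age)
        data.frame(source_id = source_id, country = cc, year = yy,
                   group = group, hb = hb, altitude_m = alt,
                   gestational_weeks = gw_v, age = age,
                   cluster_id = NA_character_,
                   coverage = if (subnat) "subnational" else "national",
                   n_regions_covered = ifelse(subnat, n_reg_cov, NA),
                   altitude_adjusted = altitude_adjusted,
                   age_range_matches = age_ok, stringsAsFactors = FALSE)

      co_c <- group_cutoffs(cutoffs, "children")
      if (summary_only) {
        obs[[length(obs) + 1L]] <- obs_row(
          "children", "summary", n_c, mean(hb_c_obs), stats::sd(hb_c_obs),
          mean(hb_c_obs < co_c["total"]), mean(hb_c_obs < co_c["severe"]))
        if (combined) {
          cut_t <- ifelse(op_preg, group_cutoffs(cutoffs, "pregnant")["total"],
                          group_cutoffs(cutoffs, "non_pregnant")["total"])
          cut_s <- ifelse(op_preg, group_cutoffs(cutoffs, "pregnant")["severe"],
                          group_cutoffs(cutoffs, "non_pregnant")["severe"])
          obs[[length(obs) + 1L]] <- obs_row(
            "women_combined", "summary", n_w, mean(hb_w_obs),
            stats::sd(hb_w_obs), mean(hb_w_obs < cut_t),
            mean(hb_w_obs < cut_s), pfrac = mean(op_preg))
        } else {
          co_np <- group_cutoffs(cutoffs, "non_pregnant")
          hnp <- hb_w_obs[!op_preg]
          obs[[length(obs) + 1L]] <- obs_row(
            "non_pregnant", "summary", length(hnp), mean(hnp),
            stats::sd(hnp), mean(hnp < co_np["total"]),
            mean(hnp < co_np["severe"]))
          hp <- hb_w_obs[op_preg]
          if (length(hp) >= 10) {
            co_p <- group_cutoffs(cutoffs, "pregnant")
            obs[[length(obs) + 1L]] <- obs_row(
              "pregnant", "summary", length(hp), mean(hp), stats::sd(hp),
              mean(hp < co_p["total"]), mean(hp < co_p["severe"]))
          }
        }
      } else {
        obs[[length(obs) + 1L]] <- obs_row("children", "individual", n_c)
        ind[[length(ind) + 1L]] <- ind_rows("children", hb_c_obs, alt_c,
                                            NA_real_,
                                            stats::runif(n_c, 6, 59))
        grp_w <- if (combined) "women_combined" else
          ifelse(op_preg, "pregnant", "non_pregnant")
        obs[[length(obs) + 1L]] <- obs_row(
          if (combined) "women_combined" else "non_pregnant",
          "individual", n_w, pfrac = if (combined) mean(op_preg) else NA)
        ind[[length(ind) + 1L]] <- ind_rows(grp_w, hb_w_obs, alt_w, gw,
                                            stats::runif(n_w, 15, 49))
      }
    }
  }
  observations <- if (length(obs) > 0) do.call(rbind, obs) else NULL
  individuals <- if (length(ind) > 0) do.call(rbind, ind) else NULL
  list(observations = observations, individuals = individuals)
}

#' Ground-truth table of a synthetic world
#'
#' True mean and true prevalences of total and severe anaemia per
#' country-year-group, computed from the mixture cdf at the group cutoffs.
#'
#' @param world an `hb_world`.
#' @param cutoffs a [cutoff_set()].
#' @return data frame with `country`, `year`, `group`, `true_mean`,
#'   `true_prev`, `true_severe_prev`.
#' @export
world_truth_table <- function(world, cutoffs = cutoff_set()) {
  sh <- world$shape
  rows <- list()
  for (grp in c("children", "non_pregnant", "pregnant")) {
    co <- group_cutoffs(cutoffs, grp)
    for (ci in seq_along(world$countries)) {
      th <- vapply(world$years, function(yy)
        world_theta(world, world$countries[ci], yy, grp), numeric(1))
      d0 <- mixture_distribution(0, sh$offsets, sh$weights, sh$sds)
      rows[[length(rows) + 1L]] <- data.frame(
        country = world$countries[ci], year = world$years, group = grp,
        true_mean = th,
        true_prev = vapply(th, function(t1)
          mixture_cdf(mixture_distribution(t1, sh$offsets, sh$weights, sh$sds),
                      co["total"]), numeric(1)),
        true_severe_prev = vapply(th, function(t1)
          mixture_cdf(mixture_distribution(t1, sh$offsets, sh$weights, sh$sds),
                      co["severe"]), numeric(1)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a synthetic world and its surveys to CSV files
#'
#' Emits the same schemas consumed by the readers
#' ([read_observations()] and friends) plus `truth.csv`.
#'
#' @param world an `hb_world`.
#' @param surveys result of [generate_surveys()].
#' @param dir output directory (created if needed).
#' @return named vector of written file paths, invisibly.
#' @export
write_world <- function(world, surveys, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(observations = file.path(dir, "observations.csv"),
             individuals = file.path(dir, "individuals.csv"),
             covariates = file.path(dir, "covariates.csv"),
             regions = file.path(dir, "regions.csv"),
             population = file.path(dir, "population.csv"),
             altitude_bands = file.path(dir, "altitude_bands.csv"),
             truth = file.path(dir, "truth.csv"))
  utils::write.csv(surveys$observations, paths["observations"],
                   row.names = FALSE, na = "")
  ind <- surveys$individuals
  if (is.null(ind))
    ind <- as.data.frame(setNames(rep(list(logical(0)),
                                      length(.schema$individuals)),
                                  .schema$individuals))
  utils::write.csv(ind, paths["individuals"], row.names = FALSE, na = "")
  utils::write.csv(world$covariates, paths["covariates"], row.names = FALSE)
  utils::write.csv(world$region_map, paths["regions"], row.names = FALSE)
  utils::write.csv(world$populations, paths["population"], row.names = FALSE)
  utils::write.csv(world$altitude_bands, paths["altitude_bands"],
                   row.names = FALSE)
  utils::write.csv(world_truth_table(world), paths["truth"],
                   row.names = FALSE)
  invisible(paths)
}
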