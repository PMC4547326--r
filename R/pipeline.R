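#' Write a manifest of output artifacts
#'
#' Records every artifact with its md5 content hash plus the seed and a
#' hash of the configuration, so reruns can be verified byte-for-byte.
#'
#' @param dir output directory.
#' @param paths character vector of file paths.
#' @param seed integer seed of the run.
#' @param config_hash hash string identifying the configuration.
#' @return path of the manifest file, invisibly.
#' @export
write_manifest <- function(dir, paths, seed, config_hash = "") {
  mf <- data.frame(file = basename(unlist(paths)),
                   md5 = unname(tools::md5sum(unlist(paths))),
                   stringsAsFactors = FALSE)
  out <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(seed = seed, config_hash = config_hash,
                            files = mf),
                       out, auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

.config_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f)
  # hash of the serialised configuration (not content-stable across R
  # versions, but stable within a run environment, which is what reruns use)
  unname(tools::md5sum(f))
}

#' Simulate a synthetic world and write its survey CSVs
#'
#' Generates the world and surveys, writes all schema CSVs plus `truth.csv`
#' and a manifest of content hashes. Refuses to overwrite a non-empty
#' directory unless `force = TRUE`.
#'
#' @param out_dir output directory.
#' @param world_cfg a [world_config()].
#' @param design a [survey_design()].
#' @param seed integer seed for the survey stage (the world uses
#'   `world_cfg$seed`).
#' @param force overwrite a non-empty output directory.
#' @return list with `world`, `surveys`, and written `paths`.
#' @export
run_simulate <- function(out_dir, world_cfg = world_config(),
                         design = survey_design(), seed = world_cfg$seed,
                         force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop("output directory ", out_dir, " is not empty (use force = TRUE)")
  world <- generate_true_world(world_cfg)
  surveys <- generate_surveys(world, design, seed = seed)
  paths <- write_world(world, surveys, out_dir)
  write_manifest(out_dir, paths, seed,
                 .config_hash(list(world_cfg, design)))
  invisible(list(world = world, surveys = surveys, paths = paths))
}

#' Validate, filter, and adjust a survey data directory
#'
#' Reads the schema CSVs from `dir`, validates them, applies the
#' representativeness inclusion rules, the altitude adjustments (individual
#' records via the CDC formula where altitude is known; summary sources
#' from high-altitude countries via the population altitude distribution),
#' and the no-post-adjustment smoking policy.
#'
#' @param dir directory holding the schema CSVs.
#' @param policy an [altitude_policy()].
#' @return list with `observations`, `individuals`, `covariates`,
#'   `regions`, `population`, `altitude_bands`, and an `exclusions` report.
#' @export
load_survey_data <- function(dir, policy = altitude_policy()) {
  obs <- read_observations(file.path(dir, "observations.csv"))
  ind <- read_individuals(file.path(dir, "individuals.csv"))
  covs <- read_covariates(file.path(dir, "covariates.csv"))
  regions <- read_regions(file.path(dir, "regions.csv"))
  pops <- read_population(file.path(dir, "population.csv"))
  bands <- read_altitude_bands(file.path(dir, "altitude_bands.csv"))

  incl <- apply_inclusion_rules(obs)
  obs <- incl$included
  keep_src <- unique(obs$source_id[obs$data_form == "individual"])
  ind <- ind[ind$source_id %in% keep_src, , drop = FALSE]

  # altitude adjustment: individual records with known altitude
  todo <- !ind$altitude_adjusted & !is.na(ind$altitude_m)
  if (any(todo)) {
    adj <- adjust_individuals(ind[todo, , drop = FALSE], policy)
    ind$hb[todo] <- adj$hb
    ind$altitude_adjusted[todo] <- TRUE
  }
  # summary sources from high-altitude countries
  for (i in which(obs$data_form == "summary" & !obs$altitude_adjusted)) {
    b <- bands[bands$country == obs$country[i], , drop = FALSE]
    o1 <- adjust_summary(obs[i, ], b, policy)
    o1 <- smoking_policy(o1)
    obs[i, c("mean_hb", "prev_anaemia", "prev_severe", "altitude_adjusted")] <-
      o1[c("mean_hb", "prev_anaemia", "prev_severe", "altitude_adjusted")]
  }
  list(observations = obs, individuals = ind, covariates = covs,
       regions = regions, population = pops, altitude_bands = bands,
       exclusions = incl$excluded)
}

#' Fit both group-family models to a prepared data directory
#'
#' Runs [load_survey_data()], prepares the children and women model data,
#' and fits each by MCMC.
#'
#' @param dir data directory (as written by [run_simulate()]).
#' @param model_cfg a [model_config()].
#' @param fit_cfg a [fit_config()].
#' @return list with `children` and `women` `hb_fit` objects and the
#'   loaded `data`.
#' @export
run_fit <- function(dir, model_cfg = model_config(),
                    fit_cfg = fit_config()) {
  dd <- load_survey_data(dir)
  fits <- list()
  for (fam in c("children", "women")) {
    dat <- prepare_model_data(fam, dd$observations, dd$individuals,
                              dd$covariates, dd$regions, model_cfg)
    fits[[fam]] <- fit_hb_model(dat, fit_cfg)
  }
  c(fits, list(data = dd))
}

#' Summarise fitted models into estimate tables
#'
#' Writes `estimates.csv` (country, region, and global mean haemoglobin and
#' total/severe anaemia prevalence and counts, with 95\% credibility
#' intervals), `trends.csv` (change per decade and posterior trend
#' probabilities between `y1` and `y2`), `halving.csv` (probability of
#' halving prevalence from `y1_halving` by `target_year`), and
#' `iron_share.csv` (share of anaemia amenable to iron under the
#' supplementation shifts), and verifies per-draw conservation of the
#' global aggregate.
#'
#' @param fits result of [run_fit()].
#' @param out_dir output directory.
#' @param years years at which levels are reported.
#' @param y1,y2 trend years.
#' @param target_year halving target year.
#' @param cutoffs a [cutoff_set()].
#' @param shifts iron supplementation shifts, see [iron_shifts()].
#' @param seed seed recorded in the manifest.
#' @return list of the four tables, invisibly; files are written to
#'   `out_dir`.
#' @export
run_summarize <- function(fits, out_dir, years = c(1995, 2011),
                          y1 = 1995, y2 = 2011, target_year = 2025,
                          cutoffs = cutoff_set(), shifts = iron_shifts(),
                          seed = 0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pops <- fits$data$population
  regions <- fits$data$regions
  est <- list(); trd <- list(); hlv <- list(); irn <- list()
  scopes <- c(list(globe = regions$country),
              split(regions$country, regions$region))
  for (grp in c("children", "non_pregnant", "pregnant")) {
    fit <- if (grp == "children") fits$children else fits$women
    co <- group_cutoffs(cutoffs, grp)
    for (yy in years) {
      for (cc in regions$country) {
        th <- theta_draws(fit, cc, yy, grp)
        est[[length(est) + 1L]] <- summarize_draws(
          th, scope = "country", scope_id = cc, year = yy, group = grp,
          metric = "mean_hb")
        for (mm in c("prev_total", "prev_severe")) {
          cutoff <- co[if (mm == "prev_total") "total" else "severe"]
          pd <- .prev_draws_theta(fit, th, cutoff)
          est[[length(est) + 1L]] <- summarize_draws(
            pd, scope = "country", scope_id = cc, year = yy, group = grp,
            metric = mm)
          pop <- .pop_of(pops, cc, yy, grp)
          est[[length(est) + 1L]] <- summarize_draws(
            pd * pop, scope = "country", scope_id = cc, year = yy,
            group = grp, metric = sub("prev", "count", mm))
        }
      }
      for (sc in names(scopes)) {
        members <- scopes[[sc]]
        scope_kind <- if (sc == "globe") "globe" else "region"
        est[[length(est) + 1L]] <- summarize_draws(
          aggregate_draws(fit, members, yy, grp, pops, "mean_hb"),
          scope = scope_kind, scope_id = sc, year = yy, group = grp,
          metric = "mean_hb")
        for (mm in c("prev_total", "prev_severe")) {
          cutoff <- co[if (mm == "prev_total") "total" else "severe"]
          ad <- aggregate_draws(fit, members, yy, grp, pops, "prevalence",
                                cutoff)
          est[[length(est) + 1L]] <- summarize_draws(
            ad, scope = scope_kind, scope_id = sc, year = yy, group = grp,
            metric = mm)
          pop <- sum(.pop_of(pops, members, yy, grp))
          est[[length(est) + 1L]] <- summarize_draws(
            ad * pop, scope = scope_kind, scope_id = sc, year = yy,
            group = grp, metric = sub("prev", "count", mm))
        }
      }
    }
    # conservation check: global prevalence equals the population-weighted
    # aggregate over all countries, draw by draw
    cutoff <- co["total"]
    gl <- aggregate_draws(fit, regions$country, y2, grp, pops, "prevalence",
                          cutoff)
    w <- .pop_of(pops, regions$country, y2, grp)
    acc <- 0
    for (i in seq_along(regions$country))
      acc <- acc + w[i] * prevalence_draws(fit, regions$country[i], y2, grp,
                                           cutoff)
    if (max(abs(gl - acc / sum(w))) > 1e-12 * max(abs(gl)))
      stop("conservation check failed for group ", grp)

    for (sc in names(scopes)) {
      members <- scopes[[sc]]
      scope_kind <- if (sc == "globe") "globe" else "region"
      for (mm in c("mean_hb", "prevalence")) {
        cpd <- change_per_decade(fit, members, grp, pops, mm,
                                 cutoff = co["total"], y1 = y1, y2 = y2)
        cpd$scope <- scope_kind; cpd$scope_id <- sc
        cpd$prob_increase <- posterior_probability_increase(
          fit, members, grp, pops, mm, cutoff = co["total"], y1 = y1, y2 = y2)
        trd[[length(trd) + 1L]] <- cpd
      }
      hlv[[length(hlv) + 1L]] <- data.frame(
        scope = scope_kind, scope_id = sc, group = grp,
        base_year = y2, target_year = target_year,
        prob_halving = halving_probability(fit, members, grp, pops,
                                           co["total"], base_year = y2,
                                           target_year = target_year),
        stringsAsFactors = FALSE)
    }
    # iron-amenable share at the posterior mean distribution, global scope
    th_bar <- mean(aggregate_draws(fit, regions$country, y2, grp, pops,
                                   "mean_hb"))
    sh <- list(offsets = colMeans(fit$draws$shape_o),
               weights = colMeans(fit$draws$shape_w),
               sds = colMeans(fit$draws$shape_t))
    sh$weights <- sh$weights / sum(sh$weights)
    d_bar <- mixture_distribution(th_bar, center_offsets(sh$offsets, sh$weights),
                                  sh$weights, sh$sds)
    for (mm in c("total", "severe"))
      irn[[length(irn) + 1L]] <- data.frame(
        group = grp, year = y2, cutoff_kind = mm,
        cutoff = unname(co[mm]), shift = unname(shifts[grp]),
        share = iron_amenable_share(d_bar, shifts[grp], co[mm]),
        variant = "sub_cutoff_shift", stringsAsFactors = FALSE)
  }
  tables <- list(estimates = do.call(rbind, est),
                 trends = do.call(rbind, trd),
                 halving = do.call(rbind, hlv),
                 iron_share = do.call(rbind, irn))
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  write_manifest(out_dir, paths, seed, .config_hash(list(years, y1, y2)))
  invisible(tables)
}
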