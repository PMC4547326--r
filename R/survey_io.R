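# CSV schemas (version "1"); documented in inst/schemas/README.md.
.schema <- list(
  observations = c("source_id", "country", "year", "group", "coverage",
                   "n_regions_covered", "data_form", "n", "mean_hb", "sd_hb",
                   "prev_anaemia", "prev_severe", "altitude_adjusted",
                   "smoking_adjusted", "age_range_matches", "pregnant_fraction"),
  individuals  = c("source_id", "country", "year", "group", "hb", "altitude_m",
                   "gestational_weeks", "age", "cluster_id", "coverage",
                   "n_regions_covered", "altitude_adjusted", "age_range_matches"),
  covariates   = c("country", "year", "maternal_education", "urban_prop",
                   "abs_latitude", "hb_disorder_prev", "mean_bmi", "mean_waz"),
  regions      = c("country", "region"),
  population   = c("country", "year", "group", "population"),
  altitude_bands = c("country", "band_midpoint_m", "population_share")
)

.groups <- c("children", "pregnant", "non_pregnant", "women_combined")

.read_schema_csv <- function(path, what, schema_version = "1") {
  if (!identical(schema_version, "1"))
    stop("unknown schema version: ", schema_version)
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- .schema[[what]]
  missing <- setdiff(want, names(df))
  if (length(missing) > 0)
    stop("schema error in ", path, ": missing required column(s) ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(df), want)
  if (length(extra) > 0)
    warning("ignoring unknown column(s) in ", path, ": ",
            paste(extra, collapse = ", "))
  df[want]
}

#' Read and validate survey observations
#'
#' Reads `observations.csv` (one row per source-group cell: either an
#' individual-level source stub or a summary source with mean/sd/n and
#' optional prevalences). Rows violating the invariants (n >= 1, mean in
#' (40, 190), sd > 0, proportions in `[0, 1]`, subnational rows carrying the
#' number of regions covered) are rejected, not silently coerced; rejected
#' rows are returned in the `"rejected"` attribute with the row number,
#' source id, and a reason.
#'
#' @param path path to the CSV file.
#' @param schema_version schema version string (only `"1"` is defined).
#' @return a data frame of validated observations with attribute
#'   `"rejected"` (data frame: `row`, `source_id`, `reason`).
#' @export
read_observations <- function(path, schema_version = "1") {
  df <- .read_schema_csv(path, "observations", schema_version)
  validate_observations(df)
}

#' @rdname read_observations
#' @param obs a data frame with the observation schema columns.
#' @export
validate_observations <- function(obs) {
  for (cc in c("altitude_adjusted", "smoking_adjusted", "age_range_matches"))
    obs[[cc]] <- as.logical(obs[[cc]])
  reasons <- character(0); rows <- integer(0); ids <- character(0)
  reject <- function(i, why) {
    rows <<- c(rows, i); ids <<- c(ids, as.character(obs$source_id[i]))
    reasons <<- c(reasons, why)
  }
  num_bad <- function(x) !is.na(x) & is.na(suppressWarnings(as.numeric(x)))
  keep <- rep(TRUE, nrow(obs))
  for (i in seq_len(nrow(obs))) {
    o <- obs[i, ]
    why <- NULL
    if (!(o$group %in% .groups)) why <- "unknown_group"
    else if (!(o$coverage %in% c("national", "subnational"))) why <- "unknown_coverage"
    else if (!(o$data_form %in% c("individual", "summary"))) why <- "unknown_data_form"
    else if (num_bad(o$n) || num_bad(o$mean_hb) || num_bad(o$sd_hb) ||
             num_bad(o$prev_anaemia) || num_bad(o$prev_severe) ||
             num_bad(o$year)) why <- "unparseable_numeric"
    else if (is.na(o$n) || o$n < 1) why <- "n_lt_1"
    else if (!is.na(o$mean_hb) && (o$mean_hb <= 40 || o$mean_hb >= 190)) why <- "mean_hb_out_of_range"
    else if (!is.na(o$sd_hb) && o$sd_hb <= 0) why <- "sd_hb_nonpositive"
    else if (!is.na(o$prev_anaemia) && (o$prev_anaemia < 0 || o$prev_anaemia > 1)) why <- "prev_out_of_range"
    else if (!is.na(o$prev_severe) && (o$prev_severe < 0 || o$prev_severe > 1)) why <- "prev_out_of_range"
    else if (o$coverage == "subnational" && is.na(o$n_regions_covered)) why <- "subnational_missing_n_regions"
    else if (!is.na(o$pregnant_fraction) &&
             (o$pregnant_fraction < 0 || o$pregnant_fraction > 1)) why <- "pregnant_fraction_out_of_range"
    else if (o$data_form == "summary" && is.na(o$mean_hb) &&
             is.na(o$prev_anaemia) && is.na(o$prev_severe)) why <- "summary_without_statistics"
    if (!is.null(why)) { keep[i] <- FALSE; reject(i, why) }
  }
  out <- obs[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (cc in c("year", "n", "mean_hb", "sd_hb", "prev_anaemia", "prev_severe",
               "n_regions_covered", "pregnant_fraction"))
    out[[cc]] <- as.numeric(out[[cc]])
  attr(out, "rejected") <- data.frame(row = rows, source_id = ids,
                                      reason = reasons, stringsAsFactors = FALSE)
  out
}

#' Write observations back to CSV
#' @param obs validated observations data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(obs[.schema$observations], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read individual haemoglobin records
#'
#' Individual records outside the biologically plausible range (25--220 g/L)
#' are flagged in the `"flagged"` attribute and excluded from the returned
#' set (with a count), never silently dropped.
#'
#' @inheritParams read_observations
#' @return data frame of records with attribute `"flagged"`.
#' @export
read_individuals <- function(path, schema_version = "1") {
  df <- .read_schema_csv(path, "individuals", schema_version)
  validate_individuals(df)
}

#' @rdname read_individuals
#' @param ind data frame with the individual-record schema columns.
#' @export
validate_individuals <- function(ind) {
  for (cc in c("hb", "altitude_m", "gestational_weeks", "age", "year",
               "n_regions_covered"))
    ind[[cc]] <- as.numeric(ind[[cc]])
  for (cc in c("altitude_adjusted", "age_range_matches"))
    ind[[cc]] <- as.logical(ind[[cc]])
  bad_gw <- !is.na(ind$gestational_weeks) &
    (ind$gestational_weeks < 0 | ind$gestational_weeks > 44)
  if (any(bad_gw)) stop("gestational_weeks outside [0, 44] for ",
                        sum(bad_gw), " record(s)")
  out_of_range <- ind$hb < 25 | ind$hb > 220
  flagged <- ind[out_of_range, , drop = FALSE]
  out <- ind[!out_of_range, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "flagged") <- flagged
  if (nrow(flagged) > 0)
    message(nrow(flagged), " record(s) outside 25-220 g/L flagged and excluded")
  out
}

#' Read country-year covariates
#' @inheritParams read_observations
#' @return data frame of covariates; errors if sickle-cell/thalassaemia
#'   prevalence varies over time within a country.
#' @export
read_covariates <- function(path, schema_version = "1") {
  df <- .read_schema_csv(path, "covariates", schema_version)
  for (cc in setdiff(names(df), "country")) df[[cc]] <- as.numeric(df[[cc]])
  v <- tapply(df$hb_disorder_prev, df$country, function(x) diff(range(x)))
  if (any(v > 1e-9))
    stop("hb_disorder_prev must be constant over time within a country")
  df
}

#' Read the country-to-region map
#' @inheritParams read_observations
#' @export
read_regions <- function(path, schema_version = "1") {
  df <- .read_schema_csv(path, "regions", schema_version)
  if (anyDuplicated(df$country))
    stop("each country must map to exactly one region")
  df
}

#' Read population counts by country, year, and group
#' @inheritParams read_observations
#' @export
read_population <- function(path, schema_version = "1") {
  df <- .read_schema_csv(path, "population", schema_version)
  df$year <- as.numeric(df$year); df$population <- as.numeric(df$population)
  if (any(df$population <= 0)) stop("populations must be positive")
  df
}

#' Read population altitude bands
#' @inheritParams read_observations
#' @export
read_altitude_bands <- function(path, schema_version = "1") {
  df <- .read_schema_csv(path, "altitude_bands", schema_version)
  df$band_midpoint_m <- as.numeric(df$band_midpoint_m)
  df$population_share <- as.numeric(df$population_share)
  s <- tapply(df$population_share, df$country, sum)
  if (any(abs(s - 1) > 1e-9)) stop("band shares must sum to 1 per country")
  df
}

#' Apply the representativeness inclusion rules
#'
#' National sources are always included; subnational sources are included
#' only when they covered at least three regions within the country. The
#' result is a partition of the input: every observation appears in exactly
#' one of `included` or `excluded`, and every exclusion carries a
#' machine-readable reason code.
#'
#' @param obs validated observations data frame.
#' @return list with `included` and `excluded` data frames (`excluded` gains
#'   a `reason` column).
#' @export
apply_inclusion_rules <- function(obs) {
  subnat <- obs$coverage == "subnational"
  excl <- subnat & (is.na(obs$n_regions_covered) | obs$n_regions_covered < 3)
  excluded <- obs[excl, , drop = FALSE]
  if (nrow(excluded) > 0) excluded$reason <- "subnational_lt_3_regions"
  else excluded$reason <- character(0)
  included <- obs[!excl, , drop = FALSE]
  rownames(included) <- rownames(excluded) <- NULL
  list(included = included, excluded = excluded)
}

#' Classify a woman's record by pregnancy status
#'
#' The operational definition of pregnancy is strictly after 8 completed
#' weeks of gestation: reporting of pregnancy in household surveys becomes
#' consistent only around weeks 6--10, which is also when the pregnancy
#' decline in haemoglobin is steepest. Records with unknown gestational age
#' are classified non-pregnant.
#'
#' @param rec a record (list or one-row data frame) with `group` and
#'   optionally `gestational_weeks`.
#' @return `"pregnant"` or `"non_pregnant"`.
#' @export
classify_pregnancy <- function(rec) {
  if (identical(as.character(rec$group), "children"))
    stop("classify_pregnancy applies to women's records only")
  gw <- rec$gestational_weeks
  if (is.null(gw) || is.na(gw)) return("non_pregnant")
  if (gw > pregnancy_week_threshold()) "pregnant" else "non_pregnant"
}

#' Gestational-week threshold of the operational pregnancy definition
#' @return 8 (weeks); classification is strict (`> 8`).
#' @export
pregnancy_week_threshold <- function() 8

#' Summarise individual records into summary observations
#'
#' Collapses individual records to one summary observation per
#' source-country-year-group cell: mean, unbiased sd, n, and prevalences of
#' total and severe anaemia against the group's cutoffs. Used for fixtures
#' and diagnostics; the model consumes individual records directly.
#'
#' @param recs data frame of individual records (already classified into
#'   `children` / `pregnant` / `non_pregnant`).
#' @param cutoffs a [cutoff_set()].
#' @return data frame with the observation schema columns; cells whose
#'   records are all identical are flagged via a `degenerate` column.
#' @export
summarize_individuals <- function(recs, cutoffs = cutoff_set()) {
  key <- interaction(recs$source_id, recs$country, recs$year, recs$group,
                     drop = TRUE)
  out <- lapply(split(recs, key), function(g) {
    if (nrow(g) < 2)
      stop("cell with a single record: sd undefined (source ",
           g$source_id[1], ")")
    grp <- as.character(g$group[1])
    co <- group_cutoffs(cutoffs, grp)
    s <- stats::sd(g$hb)
    data.frame(
      source_id = g$source_id[1], country = g$country[1], year = g$year[1],
      group = grp,
      coverage = if (!is.null(g$coverage)) g$coverage[1] else "national",
      n_regions_covered = if (!is.null(g$n_regions_covered)) g$n_regions_covered[1] else NA,
      data_form = "summary", n = nrow(g),
      mean_hb = mean(g$hb), sd_hb = s,
      prev_anaemia = mean(g$hb < co["total"]),
      prev_severe = mean(g$hb < co["severe"]),
      altitude_adjusted = if (!is.null(g$altitude_adjusted)) all(g$altitude_adjusted) else FALSE,
      smoking_adjusted = FALSE,
      age_range_matches = if (!is.null(g$age_range_matches)) all(g$age_range_matches) else TRUE,
      pregnant_fraction = NA_real_,
      degenerate = s == 0,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
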