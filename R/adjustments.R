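#' Altitude adjustment policy
#'
#' Haemoglobin rises with altitude of residence, so measured concentrations
#' are adjusted downward before comparison against sea-level cutoffs. The
#' policy mirrors common practice: adjustment is applied only for residence
#' at or above `apply_above_m` (1000 m); a country is treated as
#' "high altitude" (requiring summary-level adjustment) when more than
#' `high_altitude_country_threshold` of its population lives at or above
#' `high_altitude_m`.
#'
#' @param high_altitude_country_threshold population share at high altitude
#'   above which summary data must be adjusted (default 0.05).
#' @param high_altitude_m altitude defining "high altitude" residence,
#'   metres (default 1500).
#' @param apply_above_m altitude at and above which the individual-level
#'   adjustment applies, metres (default 1000).
#' @return a list of class `hb_altitude_policy`.
#' @export
altitude_policy <- function(high_altitude_country_threshold = 0.05,
                            high_altitude_m = 1500,
                            apply_above_m = 1000) {
  stopifnot(high_altitude_country_threshold > 0, high_altitude_m > 0,
            apply_above_m > 0)
  structure(list(high_altitude_country_threshold = high_altitude_country_threshold,
                 high_altitude_m = high_altitude_m,
                 apply_above_m = apply_above_m),
            class = "hb_altitude_policy")
}

#' CDC altitude adjustment of haemoglobin
#'
#' Downward shift (g/L) applied to haemoglobin measured at altitude, using
#' the CDC polynomial in thousands of feet:
#' `shift = -0.32 A + 0.22 A^2`, `A = altitude_m * 0.0032808`. The shift is
#' clamped at zero and applied only at or above `apply_above_m` (1000 m by
#' default); below that altitude the shift is defined as exactly 0.
#'
#' At 1500 m the shift is about 3.75 g/L and at 2200 m about 9.15 g/L.
#'
#' @param altitude_m altitude of residence in metres (vectorised, >= 0).
#' @param policy an [altitude_policy()].
#' @return downward shift in g/L (>= 0).
#' @export
cdc_altitude_shift <- function(altitude_m, policy = altitude_policy()) {
  if (any(altitude_m < 0, na.rm = TRUE)) stop("altitude_m must be non-negative")
  a <- altitude_m * 0.0032808  # thousands of feet
  shift <- pmax(0, -0.32 * a + 0.22 * a^2)
  shift[altitude_m < policy$apply_above_m] <- 0
  shift
}

#' Adjust an individual haemoglobin record for altitude
#'
#' Subtracts the CDC shift from the record's haemoglobin when altitude of
#' residence is known; the unadjusted value is retained in `hb_raw` for
#' audit. Records without altitude are returned unchanged and flagged.
#'
#' @param rec a one-row data frame (or list) with at least `hb` and
#'   optionally `altitude_m` and `altitude_adjusted`.
#' @param policy an [altitude_policy()].
#' @return the record with `hb` adjusted, `hb_raw`, `altitude_adjusted` and
#'   an `adjust_note` field (`"adjusted"` or `"unadjusted_no_altitude"`).
#' @export
adjust_individual <- function(rec, policy = altitude_policy()) {
  if (isTRUE(rec$altitude_adjusted))
    stop("record is already altitude adjusted; refusing to adjust twice")
  rec$hb_raw <- rec$hb
  if (is.null(rec$altitude_m) || is.na(rec$altitude_m)) {
    rec$adjust_note <- "unadjusted_no_altitude"
    rec$altitude_adjusted <- FALSE
    return(rec)
  }
  rec$hb <- rec$hb - cdc_altitude_shift(rec$altitude_m, policy)
  rec$altitude_adjusted <- TRUE
  rec$adjust_note <- "adjusted"
  rec
}

#' Altitude adjustment of individual records in bulk
#'
#' Vectorised form of [adjust_individual()] over an `individuals` data frame.
#'
#' @param ind data frame of individual records with columns `hb`,
#'   `altitude_m` (NA allowed) and optionally `altitude_adjusted`.
#' @param policy an [altitude_policy()].
#' @return the data frame with adjusted `hb`, original values in `hb_raw`,
#'   and logical `altitude_adjusted`.
#' @export
adjust_individuals <- function(ind, policy = altitude_policy()) {
  if (is.null(ind$altitude_adjusted)) ind$altitude_adjusted <- FALSE
  if (any(ind$altitude_adjusted))
    stop("some records are already altitude adjusted")
  ind$hb_raw <- ind$hb
  has_alt <- !is.na(ind$altitude_m)
  ind$hb[has_alt] <- ind$hb[has_alt] -
    cdc_altitude_shift(ind$altitude_m[has_alt], policy)
  ind$altitude_adjusted <- has_alt
  ind
}

#' Adjust a summary observation for altitude using a population altitude
#' distribution
#'
#' Summary statistics from countries where more than the policy threshold of
#' the population lives at high altitude are shifted down by the
#' population-weighted mean of the CDC shift over altitude bands. Mean
#' haemoglobin is shifted exactly; reported prevalences cannot be shifted
#' exactly and are recomputed from a normal approximation with the shifted
#' mean and the reported sd (the approximation is recorded in
#' `adjust_note`). Sample size, sd, and group are never changed.
#'
#' @param obs one summary observation (one-row data frame or list) with
#'   `data_form == "summary"`, `altitude_adjusted == FALSE`, `mean_hb`, and
#'   optionally `sd_hb`, `prev_anaemia`, `prev_severe`.
#' @param alt altitude distribution for the country: data frame with columns
#'   `band_midpoint_m` and `population_share` (shares summing to 1).
#' @param policy an [altitude_policy()].
#' @param cutoffs a [cutoff_set()] used when recomputing prevalences.
#' @return the adjusted observation with `adjust_note` one of
#'   `"summary_adjusted"` or `"low_altitude_country"`.
#' @export
adjust_summary <- function(obs, alt, policy = altitude_policy(),
                           cutoffs = cutoff_set()) {
  if (!identical(as.character(obs$data_form), "summary"))
    stop("adjust_summary applies to summary observations only")
  if (isTRUE(obs$altitude_adjusted))
    stop("observation is already altitude adjusted")
  high_share <- high_altitude_share(alt, policy)
  if (high_share <= policy$high_altitude_country_threshold) {
    obs$adjust_note <- "low_altitude_country"
    return(obs)
  }
  if (is.null(alt) || nrow(alt) == 0)
    stop("altitude distribution required for high-altitude country")
  shift <- sum(alt$population_share *
                 cdc_altitude_shift(alt$band_midpoint_m, policy))
  old_mean <- obs$mean_hb
  obs$mean_hb <- obs$mean_hb - shift
  # prevalence summaries: recompute under a normal approximation with the
  # shifted mean and the reported sd
  if (!is.null(obs$sd_hb) && !is.na(obs$sd_hb)) {
    co <- group_cutoffs(cutoffs, as.character(obs$group))
    if (!is.null(obs$prev_anaemia) && !is.na(obs$prev_anaemia))
      obs$prev_anaemia <- stats::pnorm(co["total"], obs$mean_hb, obs$sd_hb)[[1]]
    if (!is.null(obs$prev_severe) && !is.na(obs$prev_severe))
      obs$prev_severe <- stats::pnorm(co["severe"], obs$mean_hb, obs$sd_hb)[[1]]
  }
  obs$altitude_adjusted <- TRUE
  obs$adjust_note <- "summary_adjusted"
  obs
}

#' Population share living at or above the high-altitude threshold
#' @param alt altitude band data frame (`band_midpoint_m`, `population_share`).
#' @param policy an [altitude_policy()].
#' @return proportion of the population at high altitude.
#' @export
high_altitude_share <- function(alt, policy = altitude_policy()) {
  if (is.null(alt) || nrow(alt) == 0) return(0)
  if (abs(sum(alt$population_share) - 1) > 1e-9)
    stop("altitude band shares must sum to 1")
  if (any(alt$band_midpoint_m < 0)) stop("band midpoints must be non-negative")
  sum(alt$population_share[alt$band_midpoint_m >= policy$high_altitude_m])
}

#' Smoking adjustment policy: no post-adjustment
#'
#' Data already adjusted for smoking are used as such; data not adjusted are
#' used without post-adjustment (the smoking effect, roughly 0.3 g/L, is an
#' order of magnitude below the altitude effect). The observation is never
#' modified; only metadata is recorded.
#'
#' @param obs a summary observation with a `smoking_adjusted` flag.
#' @return the observation unchanged, with `smoking_note` set to
#'   `"pre_adjusted"` or `"not_adjusted"`.
#' @export
smoking_policy <- function(obs) {
  obs$smoking_note <- if (isTRUE(obs$smoking_adjusted)) "pre_adjusted" else "not_adjusted"
  obs
}
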