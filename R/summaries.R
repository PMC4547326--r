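#' Anaemia cutoffs by population group
#'
#' WHO haemoglobin cutoffs: total anaemia below 110 g/L for children under
#' 5 and pregnant women and below 120 g/L for non-pregnant women; severe
#' anaemia below 70 g/L for children and pregnant women and below 80 g/L
#' for non-pregnant women. Because full distributions are estimated,
#' prevalences at any other cutoff can be computed with [hb_prevalence()].
#'
#' @param total named numeric vector of total-anaemia cutoffs (g/L).
#' @param severe named numeric vector of severe-anaemia cutoffs (g/L).
#' @return a list of class `hb_cutoffs`.
#' @export
cutoff_set <- function(total = c(children = 110, pregnant = 110, non_pregnant = 120),
                       severe = c(children = 70, pregnant = 70, non_pregnant = 80)) {
  stopifnot(all(names(total) == names(severe)), all(severe < total))
  structure(list(total = total, severe = severe), class = "hb_cutoffs")
}

#' @rdname cutoff_set
#' @param cutoffs an `hb_cutoffs`.
#' @param group group name.
#' @return named vector `c(total=, severe=)` for the group.
#' @export
group_cutoffs <- function(cutoffs, group) {
  if (identical(group, "women_combined")) group <- "non_pregnant"
  if (!group %in% names(cutoffs$total)) stop("unknown group: ", group)
  c(total = unname(cutoffs$total[group]), severe = unname(cutoffs$severe[group]))
}

#' Average haemoglobin shifts achieved by iron supplementation
#'
#' Mean increases in haemoglobin among those anaemic at baseline observed
#' in randomised iron-supplementation trials: 10.17 g/L for pregnant women,
#' 8.64 g/L for non-pregnant women, and 8.0 g/L for children.
#' @return named numeric vector of shifts in g/L.
#' @export
iron_shifts <- function() {
  c(children = 8.0, pregnant = 10.17, non_pregnant = 8.64)
}

#' Summarise a set of posterior draws into an estimate cell
#'
#' Point estimate is the posterior mean; `lo`/`hi` are the empirical
#' 2.5th/97.5th centiles computed with the standard linear order-statistics
#' interpolation (`quantile(type = 7)`), the rule used everywhere in the
#' package.
#'
#' @param draws numeric vector of per-draw values.
#' @param ... metadata columns (scope, year, group, metric, ...) carried
#'   into the result.
#' @return one-row data frame with `point`, `lo`, `hi`, `S`.
#' @export
summarize_draws <- function(draws, ...) {
  if (length(draws) == 0) stop("empty draw set")
  q <- stats::quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  data.frame(..., point = mean(draws), lo = q[1], hi = q[2],
             S = length(draws), stringsAsFactors = FALSE)
}

#' Fraction of draws in which a quantity increased
#'
#' The posterior probability of an increasing trend: the fraction of draws
#' with `v2 > v1`, ties counted as 0.5. It equals 0.5 when increases and
#' decreases are statistically indistinguishable.
#'
#' @param v1,v2 per-draw values at the earlier and later time.
#' @return probability in `[0, 1]`.
#' @export
prob_increase <- function(v1, v2) {
  stopifnot(length(v1) == length(v2))
  mean((v2 > v1) + 0.5 * (v2 == v1))
}

#' Share of anaemia amenable to iron supplementation
#'
#' If everyone below the cutoff gains `shift` g/L, the share of
#' currently-anaemic people who clear the cutoff is
#' `(F(cutoff) - F(cutoff - shift)) / F(cutoff)` with `F` the mixture cdf.
#'
#' @param d an `hb_mixture`.
#' @param shift haemoglobin gain in g/L (> 0), see [iron_shifts()].
#' @param cutoff anaemia cutoff in g/L.
#' @return proportion of anaemia amenable to iron.
#' @export
iron_amenable_share <- function(d, shift, cutoff) {
  stopifnot(shift > 0)
  Fc <- mixture_cdf(d, cutoff)
  if (Fc <= 0) stop("zero anaemia prevalence at cutoff: share undefined")
  (Fc - mixture_cdf(d, cutoff - shift)) / Fc
}

# ---- draw-level accessors on a fitted model --------------------------

# design row for a country-year-group at grid years; extrapolation beyond
# the grid continues the linear trend, freezes the RW2 components at the
# last grid year, and holds covariates at their last value
.fit_row <- function(fit, country, year, group) {
  dat <- fit$dat
  ci <- dat$ci_of(country)
  ti <- dat$ti_of(year)
  .design_row(dat, ci, ti, year, group)
}

.group_family <- function(group) {
  if (group %in% c("pregnant", "non_pregnant", "women_combined")) "women"
  else "children"
}

.check_fit_group <- function(fit, group) {
  fam <- .group_family(group)
  if (!identical(fit$dat$family, fam))
    stop("fit is for family '", fit$dat$family, "', not for group '", group, "'")
}

#' Per-draw locations of a country-year-group distribution
#' @param fit an `hb_fit`.
#' @param country country code.
#' @param year decimal year (years beyond the fitted grid continue the
#'   linear trend with the nonlinear component frozen).
#' @param group population group.
#' @return numeric vector of length S (one location per retained draw).
#' @export
theta_draws <- function(fit, country, year, group) {
  .check_fit_group(fit, group)
  if (identical(group, "children")) group <- "children"
  rw <- .fit_row(fit, country, year, group)
  as.vector(fit$draws$x[, rw$idx, drop = FALSE] %*% rw$val)
}

#' Posterior-draw mixture distributions for a country-year-group
#'
#' One mixture per retained draw, built from that draw's location and
#' mixture-shape parameters.
#' @inheritParams theta_draws
#' @return list of `hb_mixture` objects of length S.
#' @export
per_draw_distribution <- function(fit, country, year, group) {
  th <- theta_draws(fit, country, year, group)
  lapply(seq_along(th), function(s) {
    sh <- fit_shape(fit, s)
    mixture_distribution(th[s], sh$offsets, sh$weights, sh$sds)
  })
}

#' Mixture shape of one retained draw
#' @param fit an `hb_fit`.
#' @param s draw index.
#' @return list with `offsets`, `weights`, `sds`.
#' @export
fit_shape <- function(fit, s) {
  shape_from_zeta(fit$draws$zeta[s, ], fit$dat$cfg$K)
}

# per-draw prevalence below `cutoff` for one country-year-group,
# vectorised over draws via the stored shape matrices
.prev_draws_theta <- function(fit, th, cutoff) {
  W <- fit$draws$shape_w; O <- fit$draws$shape_o; Tau <- fit$draws$shape_t
  out <- numeric(length(th))
  for (k in seq_len(ncol(W)))
    out <- out + W[, k] * stats::pnorm((cutoff - th - O[, k]) / Tau[, k])
  out
}

#' Per-draw anaemia prevalence for a country-year-group
#' @inheritParams theta_draws
#' @param cutoff haemoglobin cutoff in g/L.
#' @return numeric vector of length S of proportions below the cutoff.
#' @export
prevalence_draws <- function(fit, country, year, group, cutoff) {
  th <- theta_draws(fit, country, year, group)
  .prev_draws_theta(fit, th, cutoff)
}

#' Country-level anaemia prevalence estimate
#'
#' Computes the per-draw mixture cdf at the cutoff and summarises the draws
#' (posterior mean point estimate, 2.5th--97.5th centile credibility
#' interval). Default cutoffs come from [cutoff_set()].
#'
#' @inheritParams theta_draws
#' @param cutoff haemoglobin cutoff in g/L (> 0); defaults to the group's
#'   total-anaemia cutoff.
#' @param cutoffs a [cutoff_set()].
#' @return one-row data frame (estimate cell).
#' @export
hb_prevalence <- function(fit, country, year, group,
                          cutoff = NULL, cutoffs = cutoff_set()) {
  if (is.null(cutoff)) cutoff <- group_cutoffs(cutoffs, group)["total"]
  stopifnot(cutoff > 0)
  pd <- prevalence_draws(fit, country, year, group, cutoff)
  summarize_draws(pd, scope = "country", scope_id = country, year = year,
                  group = group, metric = "prevalence")
}

# population lookup: pops is a data frame (country, year, group, population);
# years outside the table (eg extrapolation targets) use the nearest
# available year's weights
.pop_of <- function(pops, countries, year, group) {
  vapply(countries, function(cc) {
    sel <- pops$country == cc & pops$group == group
    if (!any(sel)) stop("missing population for country ", cc,
                        ", group ", group)
    yrs <- pops$year[sel]
    m <- pops$population[sel][which.min(abs(yrs - year))]
    m[1]
  }, numeric(1))
}

#' Per-draw population-weighted aggregate over countries
#'
#' Regional and global quantities are population-weighted averages of the
#' constituent countries, draw by draw:
#' `agg = sum(pop_c * val_c) / sum(pop_c)`.
#'
#' @param fit an `hb_fit`.
#' @param countries member countries of the scope.
#' @param year decimal year.
#' @param group population group.
#' @param pops population table (`country`, `year`, `group`, `population`).
#' @param metric `"mean_hb"` or `"prevalence"`.
#' @param cutoff cutoff for prevalence metrics.
#' @return numeric vector of length S.
#' @export
aggregate_draws <- function(fit, countries, year, group, pops,
                            metric = c("mean_hb", "prevalence"),
                            cutoff = NULL) {
  metric <- match.arg(metric)
  w <- .pop_of(pops, countries, round(year), group)
  acc <- NULL
  for (i in seq_along(countries)) {
    v <- if (metric == "mean_hb") theta_draws(fit, countries[i], year, group)
         else prevalence_draws(fit, countries[i], year, group, cutoff)
    acc <- if (is.null(acc)) w[i] * v else acc + w[i] * v
  }
  acc / sum(w)
}

#' Numbers of people with anaemia
#'
#' Per draw, count = aggregate prevalence x total population of the scope;
#' summarised into an estimate cell.
#'
#' @inheritParams aggregate_draws
#' @param scope `"country"`, `"region"`, or `"globe"` (metadata only).
#' @param scope_id identifier recorded in the output.
#' @return one-row data frame with `point`, `lo`, `hi` in persons.
#' @export
hb_counts <- function(fit, countries, year, group, pops, cutoff,
                      scope = "region", scope_id = scope) {
  w <- .pop_of(pops, countries, round(year), group)
  acc <- 0
  for (i in seq_along(countries))
    acc <- acc + w[i] * prevalence_draws(fit, countries[i], year, group, cutoff)
  summarize_draws(acc, scope = scope, scope_id = scope_id, year = year,
                  group = group, metric = "count")
}

#' Per-draw change per decade between two values
#'
#' Mean haemoglobin changes are absolute (`(v2 - v1) * 10/(y2 - y1)` g/L
#' per decade); prevalence changes are proportional, by default with the
#' geometric convention `(v2/v1)^(10/(y2-y1)) - 1` per decade (the
#' arithmetic convention `(v2 - v1)/v1 * 10/(y2-y1)` is available).
#'
#' @param v1,v2 values (or per-draw vectors) at `y1` and `y2`.
#' @param y1,y2 years, `y2 > y1`.
#' @param metric `"mean_hb"` or `"prevalence"`.
#' @param convention proportional-change convention for prevalence.
#' @return change per decade (g/L for means, proportion for prevalence).
#' @export
decadal_change <- function(v1, v2, y1, y2, metric = c("mean_hb", "prevalence"),
                           convention = c("geometric", "arithmetic")) {
  metric <- match.arg(metric); convention <- match.arg(convention)
  stopifnot(y2 > y1)
  f <- 10 / (y2 - y1)
  if (metric == "mean_hb") return((v2 - v1) * f)
  if (convention == "geometric") (v2 / v1)^f - 1 else (v2 - v1) / v1 * f
}

#' Change per decade between two years
#'
#' Mean haemoglobin changes are absolute: `(m(y2) - m(y1)) * 10 / (y2 - y1)`
#' g/L per decade. Prevalence changes are proportional; the default
#' geometric convention reports `(p(y2)/p(y1))^(10/(y2-y1)) - 1` per decade
#' (an arithmetic convention is available). Draws with zero baseline
#' prevalence are excluded with a recorded count.
#'
#' @inheritParams aggregate_draws
#' @param y1,y2 first and last reporting year (defaults 1995 and 2011).
#' @param convention `"geometric"` (default) or `"arithmetic"` for
#'   proportional prevalence change.
#' @return one-row data frame; attribute `"excluded_draws"` records draws
#'   dropped for zero baseline prevalence.
#' @export
change_per_decade <- function(fit, countries, group, pops,
                              metric = c("mean_hb", "prevalence"),
                              cutoff = NULL, y1 = 1995, y2 = 2011,
                              convention = c("geometric", "arithmetic")) {
  metric <- match.arg(metric); convention <- match.arg(convention)
  stopifnot(y2 > y1)
  v1 <- aggregate_draws(fit, countries, y1, group, pops, metric, cutoff)
  v2 <- aggregate_draws(fit, countries, y2, group, pops, metric, cutoff)
  if (metric == "mean_hb") {
    ch <- decadal_change(v1, v2, y1, y2, metric)
    excl <- 0L
  } else {
    ok <- v1 > 0
    excl <- sum(!ok)
    ch <- decadal_change(v1[ok], v2[ok], y1, y2, metric, convention)
  }
  out <- summarize_draws(ch, scope = "aggregate", year = NA, group = group,
                         metric = paste0(metric, "_change_per_decade"))
  out$convention <- if (metric == "mean_hb") "absolute" else convention
  attr(out, "excluded_draws") <- excl
  out
}

#' Posterior probability that a quantity increased between two years
#'
#' Fraction of posterior draws in which the (population-weighted) metric is
#' larger in `y2` than in `y1`; ties count 0.5.
#' @inheritParams change_per_decade
#' @return probability in `[0, 1]`.
#' @export
posterior_probability_increase <- function(fit, countries, group, pops,
                                           metric = c("mean_hb", "prevalence"),
                                           cutoff = NULL, y1 = 1995, y2 = 2011) {
  metric <- match.arg(metric)
  v1 <- aggregate_draws(fit, countries, y1, group, pops, metric, cutoff)
  v2 <- aggregate_draws(fit, countries, y2, group, pops, metric, cutoff)
  prob_increase(v1, v2)
}

#' Probability of halving anaemia prevalence by a target year
#'
#' Per draw, the country locations are extrapolated to `target_year` by
#' continuing the linear trend components, with the nonlinear (RW2)
#' components frozen at their last fitted value and covariates held at
#' their last year; prevalence is recomputed and compared with half its
#' `base_year` value. Returns the fraction of draws achieving the halving.
#'
#' @inheritParams aggregate_draws
#' @param base_year baseline year (default 2011).
#' @param target_year target year (default 2025).
#' @return probability in `[0, 1]`.
#' @export
halving_probability <- function(fit, countries, group, pops, cutoff,
                                base_year = 2011, target_year = 2025) {
  if (base_year < min(fit$dat$years) || base_year > max(fit$dat$years))
    stop("fit does not cover base_year")
  p_base <- aggregate_draws(fit, countries, base_year, group, pops,
                            "prevalence", cutoff)
  p_tgt <- aggregate_draws(fit, countries, target_year, group, pops,
                           "prevalence", cutoff)
  mean(p_tgt <= 0.5 * p_base)
}
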