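#' Five-component normal mixture for a population haemoglobin distribution
#'
#' A population haemoglobin distribution is represented as a normal mixture
#' with a location parameter `theta` (g/L), component offsets `offsets`
#' (strictly increasing, g/L), component weights `weights` (summing to 1) and
#' component standard deviations `sds` (g/L). The offsets satisfy
#' `sum(weights * offsets) == 0`, so the analytic mean of the mixture equals
#' `theta` exactly; skewness is carried by the offsets and weights.
#'
#' @param theta location (analytic mean) in g/L.
#' @param offsets numeric vector of component offsets in g/L, strictly
#'   increasing, centred so that `sum(weights * offsets) == 0` (a small
#'   residual is re-centred; a large one is an error).
#' @param weights numeric vector of component weights, non-negative, summing
#'   to 1.
#' @param sds numeric vector of positive component standard deviations, g/L.
#' @return an object of class `hb_mixture`.
#' @examples
#' d <- mixture_distribution(110, c(-20, -10, 0, 5, 10),
#'                           c(0.05, 0.15, 0.35, 0.3, 0.15), rep(9, 5))
#' mixture_mean(d)            # 110
#' mixture_cdf(d, 110)        # anaemia prevalence at a 110 g/L cutoff
#' @export
mixture_distribution <- function(theta, offsets, weights, sds) {
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta))
  k <- length(offsets)
  if (length(weights) != k || length(sds) != k)
    stop("offsets, weights and sds must have the same length")
  if (any(!is.finite(offsets)) || any(!is.finite(weights)) || any(!is.finite(sds)))
    stop("mixture parameters must be finite")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  if (any(diff(offsets) <= 0)) stop("offsets must be strictly increasing")
  if (any(sds <= 0)) stop("component sds must be positive")
  m <- sum(weights * offsets)
  if (abs(m) > 1e-6)
    stop("offsets are not centred: sum(weights * offsets) = ", signif(m, 4))
  offsets <- offsets - m  # remove numerical residual so the mean identity is exact
  structure(list(theta = theta, offsets = offsets, weights = weights, sds = sds),
            class = "hb_mixture")
}

#' Centre raw component offsets so the mixture mean equals its location
#'
#' @param raw_offsets strictly increasing raw offsets (g/L).
#' @param weights mixture weights.
#' @return centred offsets with `sum(weights * offsets) == 0`.
#' @export
center_offsets <- function(raw_offsets, weights) {
  raw_offsets - sum(weights * raw_offsets)
}

#' @export
print.hb_mixture <- function(x, ...) {
  cat("Haemoglobin mixture: ", length(x$weights), " components, mean ",
      format(x$theta), " g/L, sd ", format(round(mixture_sd(x), 2)), " g/L\n",
      sep = "")
  invisible(x)
}

#' Analytic mean of a haemoglobin mixture
#' @param d an `hb_mixture`.
#' @return mean in g/L (equals the location parameter by construction).
#' @export
mixture_mean <- function(d) {
  d$theta + sum(d$weights * d$offsets)
}

#' Analytic standard deviation of a haemoglobin mixture
#' @param d an `hb_mixture`.
#' @return standard deviation in g/L.
#' @export
mixture_sd <- function(d) {
  sqrt(sum(d$weights * (d$sds^2 + d$offsets^2)) - sum(d$weights * d$offsets)^2)
}

#' Mixture density
#' @param d an `hb_mixture`.
#' @param h haemoglobin values, g/L (vectorised).
#' @return density per g/L.
#' @export
mixture_pdf <- function(d, h) {
  out <- numeric(length(h))
  for (k in seq_along(d$weights))
    out <- out + d$weights[k] * stats::dnorm(h, d$theta + d$offsets[k], d$sds[k])
  out
}

#' Mixture cumulative distribution function
#'
#' `mixture_cdf(d, cutoff)` is the proportion of the population below
#' `cutoff`, i.e. the anaemia prevalence when `cutoff` is the group's
#' anaemia threshold.
#'
#' @param d an `hb_mixture`.
#' @param cutoff haemoglobin cutoffs, g/L (vectorised).
#' @return proportion below each cutoff.
#' @export
mixture_cdf <- function(d, cutoff) {
  out <- numeric(length(cutoff))
  for (k in seq_along(d$weights))
    out <- out + d$weights[k] * stats::pnorm(cutoff, d$theta + d$offsets[k], d$sds[k])
  out
}

#' Random draws from a haemoglobin mixture
#' @param d an `hb_mixture`.
#' @param n number of draws.
#' @return numeric vector of haemoglobin values, g/L.
#' @export
mixture_rand <- function(d, n) {
  k <- sample.int(length(d$weights), n, replace = TRUE, prob = d$weights)
  stats::rnorm(n, d$theta + d$offsets[k], d$sds[k])
}

#' Density of haemoglobin among women reported without pregnancy stratification
#'
#' Sources that report pregnant and non-pregnant women together observe the
#' two-group mixture `(1 - p) f_np + p f_p`, where `p` is the pregnant
#' fraction of the sample.
#'
#' @param p pregnant fraction in `[0, 1]`.
#' @param d_np non-pregnant `hb_mixture`.
#' @param d_p pregnant `hb_mixture`.
#' @param h haemoglobin values, g/L.
#' @return density per g/L.
#' @export
combined_women_pdf <- function(p, d_np, d_p, h) {
  stopifnot(p >= 0, p <= 1)
  (1 - p) * mixture_pdf(d_np, h) + p * mixture_pdf(d_p, h)
}

#' @rdname combined_women_pdf
#' @param cutoff haemoglobin cutoff, g/L.
#' @export
combined_women_cdf <- function(p, d_np, d_p, cutoff) {
  stopifnot(p >= 0, p <= 1)
  (1 - p) * mixture_cdf(d_np, cutoff) + p * mixture_cdf(d_p, cutoff)
}

# cdf of the standardised (theta = 0) mixture shape, used to map observed
# prevalences onto the location scale
std_mixture_cdf <- function(shape, s) {
  out <- numeric(length(s))
  for (k in seq_along(shape$weights))
    out <- out + shape$weights[k] * stats::pnorm(s, shape$offsets[k], shape$sds[k])
  out
}

std_mixture_pdf <- function(shape, s) {
  out <- numeric(length(s))
  for (k in seq_along(shape$weights))
    out <- out + shape$weights[k] * stats::dnorm(s, shape$offsets[k], shape$sds[k])
  out
}

# inverse of std_mixture_cdf by monotone root finding
std_mixture_quantile <- function(shape, p) {
  vapply(p, function(pp) {
    lo <- min(shape$offsets) - 10 * max(shape$sds)
    hi <- max(shape$offsets) + 10 * max(shape$sds)
    stats::uniroot(function(s) std_mixture_cdf(shape, s) - pp, c(lo, hi),
                   tol = 1e-10, extendInt = "upX")$root
  }, numeric(1))
}
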