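#' Model configuration
#'
#' Hyperprior scales and structural switches for the hierarchical
#' haemoglobin model. Locations follow a linear trend plus a smooth
#' nonlinear trend (second-order random walk, RW2) at the global, regional,
#' and national level; covariates enter after standardisation; pregnant
#' women's locations are the non-pregnant location minus a non-negative
#' country-level offset shrunk towards a region mean. Population
#' distributions are K-component normal mixtures (K = 5) whose shape
#' (offsets, weights, component sds) is shared across countries within a
#' group family, with the location varying.
#'
#' All scales are in g/L (slopes in g/L per year). `sd` hyperpriors are
#' half-Normal with the stated scale.
#'
#' @param K number of mixture components (default 5).
#' @param t_ref reference year at which the time axis is centred.
#' @param years integer year grid of the analysis.
#' @param prior_a0_mean,prior_a0_sd prior for the global intercept.
#' @param prior_b0_sd prior sd for the global slope (mean 0).
#' @param prior_beta_sd prior sd for standardised covariate coefficients.
#' @param prior_delta_mean,prior_delta_sd prior for region-level pregnancy
#'   offsets (g/L; haemoglobin is 8--15 g/L lower in pregnancy).
#' @param hn_region_int,hn_region_slope,hn_country_int,hn_country_slope
#'   half-Normal scales for the hierarchical deviation sds.
#' @param hn_rw2_global,hn_rw2_region,hn_rw2_country half-Normal scales for
#'   the RW2 innovation sds.
#' @param hn_delta half-Normal scale for the country pregnancy-offset sd.
#' @param hn_ns,hn_sub,hn_age half-Normal scales for the non-sampling,
#'   subnational, and age-mismatch sds.
#' @param hn_tau half-Normal scale for mixture component sds.
#' @param use_prevalence include reported prevalences in the likelihood in
#'   addition to means (default TRUE). Prevalence summaries implying fewer
#'   than one event (or fewer than one non-event) are excluded from the
#'   likelihood with a logged count: the probit-scale Normal approximation
#'   is meaningless for zero counts.
#' @param fallback_sd sd (g/L) used for a summary mean whose source did not
#'   report an sd.
#' @param shape_init initial/default mixture shape (list with `offsets`,
#'   `weights`, `sds`), mildly left-skewed.
#' @return a list of class `hb_model_config`.
#' @export
model_config <- function(K = 5, t_ref = 2000, years = 1990:2012,
                         prior_a0_mean = 120, prior_a0_sd = 30,
                         prior_b0_sd = 1, prior_beta_sd = 5,
                         prior_delta_mean = 11.5, prior_delta_sd = 3,
                         hn_region_int = 10, hn_region_slope = 0.25,
                         hn_country_int = 10, hn_country_slope = 0.25,
                         hn_rw2_global = 0.15, hn_rw2_region = 0.15,
                         hn_rw2_country = 0.15,
                         hn_delta = 2, hn_ns = 5, hn_sub = 5, hn_age = 5,
                         hn_tau = 12,
                         use_prevalence = TRUE, fallback_sd = 14,
                         shape_init = default_mixture_shape()) {
  stopifnot(K == length(shape_init$weights), length(years) >= 5)
  structure(as.list(environment()), class = "hb_model_config")
}

#' Default mixture shape for haemoglobin distributions
#'
#' A mildly left-skewed five-component shape (heavier low tail) with an
#' overall sd of about 13 g/L, centred so the mixture mean equals the
#' location parameter.
#' @return list with `offsets`, `weights`, `sds`.
#' @export
default_mixture_shape <- function() {
  w <- c(0.06, 0.12, 0.22, 0.35, 0.25)
  o <- center_offsets(c(-28, -15, -6, 2, 8), w)
  list(offsets = o, weights = w, sds = c(12, 10, 9, 8, 7.5))
}

# covariates used by each group family
.family_covariates <- function(family) {
  base <- c("maternal_education", "urban_prop", "abs_latitude", "hb_disorder_prev")
  if (family == "children") c(base, "mean_waz") else c(base, "mean_bmi")
}

# orthonormal basis of the complement of span{1, t}; RW2 components live in
# this space so they are identified against the linear trend
.rw2_basis <- function(Tn) {
  t <- seq_len(Tn)
  Q <- qr.Q(qr(cbind(1, t)), complete = TRUE)
  B <- Q[, 3:Tn, drop = FALSE]
  D <- diff(diag(Tn), differences = 2)
  K <- crossprod(D)
  list(B = B, Kc = crossprod(B, K %*% B))
}

# index layout of the latent Gaussian field x
.layout <- function(R, C, T2, p, women, n_eps) {
  st <- list(); pos <- 0L
  add <- function(name, n) {
    st[[name]] <<- if (n > 0) pos + seq_len(n) else integer(0)
    pos <<- pos + n
  }
  add("a0", 1L); add("b0", 1L)
  add("ar", R); add("br", R); add("ac", C); add("bc", C)
  add("g0", T2); add("gr", R * T2); add("gc", C * T2)
  add("beta", p)
  if (women) { add("dreg", R); add("dc", C) } else { st$dreg <- st$dc <- integer(0) }
  add("eps", n_eps)
  st$d <- pos; st$R <- R; st$C <- C; st$T2 <- T2; st$p <- p; st$women <- women
  st
}

.idx_gr <- function(st, r) st$gr[(r - 1L) * st$T2 + seq_len(st$T2)]
.idx_gc <- function(st, ci) st$gc[(ci - 1L) * st$T2 + seq_len(st$T2)]

# sparse design row mapping x -> theta for a (country, time, group) cell;
# `year_dec` is the decimal survey year used for the linear term, `ti` the
# grid index used for the RW2 term. Returns list(idx, val).
.design_row <- function(dat, ci, ti, year_dec, group, eps_i = NA) {
  st <- dat$layout
  r <- dat$region_of[ci]
  dt <- year_dec - dat$cfg$t_ref
  Bt <- dat$B[ti, ]
  idx <- c(st$a0, st$b0, st$ar[r], st$br[r], st$ac[ci], st$bc[ci],
           st$g0, .idx_gr(st, r), .idx_gc(st, ci), st$beta)
  val <- c(1, dt, 1, dt, 1, dt, Bt, Bt, Bt, dat$Z[ci, ti, ])
  if (identical(group, "pregnant")) {
    idx <- c(idx, st$dc[ci]); val <- c(val, -1)
  }
  if (!is.na(eps_i)) { idx <- c(idx, st$eps[eps_i]); val <- c(val, 1) }
  list(idx = idx, val = val)
}

#' Prepare survey data for model fitting
#'
#' Assembles the validated, included, and adjusted observations and
#' individual records of one group family (`"children"` or `"women"`) into
#' the internal structures used by the sampler: the latent-field layout,
#' the RW2 basis, standardised covariates, Gaussian likelihood terms for
#' summary means, probit-scale terms for summary prevalences, and
#' individual-record cells (each individual-level source receives a latent
#' non-sampling offset). Records from sources reporting women without
#' pregnancy stratification are classified with [classify_pregnancy()].
#'
#' @param family `"children"` or `"women"`.
#' @param obs validated + included observations (individual-level sources
#'   appear as stub rows with `data_form == "individual"`).
#' @param individuals validated, altitude-adjusted individual records.
#' @param covariates covariate table covering every modelled country-year.
#' @param regions country-to-region map.
#' @param cfg a [model_config()].
#' @param cutoffs a [cutoff_set()].
#' @return an object of class `hb_model_data`.
#' @export
prepare_model_data <- function(family, obs, individuals, covariates, regions,
                               cfg = model_config(), cutoffs = cutoff_set()) {
  stopifnot(family %in% c("children", "women"))
  groups <- if (family == "children") "children" else
    c("pregnant", "non_pregnant", "women_combined")
  obs <- obs[obs$group %in% groups, , drop = FALSE]
  if (!is.null(individuals) && nrow(individuals) > 0) {
    individuals <- individuals[individuals$group %in% groups, , drop = FALSE]
    if (family == "women" && nrow(individuals) > 0) {
      comb <- individuals$group == "women_combined"
      if (any(comb)) {
        cls <- vapply(which(comb), function(i)
          classify_pregnancy(individuals[i, ]), character(1))
        individuals$group[comb] <- cls
      }
    }
  }

  countries <- sort(unique(regions$country))
  region_names <- sort(unique(regions$region))
  region_of <- match(regions$region[match(countries, regions$country)],
                     region_names)
  years <- cfg$years; Tn <- length(years)
  bb <- .rw2_basis(Tn)
  covs <- .family_covariates(family)
  C <- length(countries); R <- length(region_names); p <- length(covs)

  # standardised covariate array [C, T, p]
  Z <- array(NA_real_, c(C, Tn, p))
  for (j in seq_along(covs)) {
    m <- covariates[[covs[j]]][match(
      paste(rep(countries, each = Tn), rep(years, C)),
      paste(covariates$country, covariates$year))]
    if (anyNA(m)) stop("covariate ", covs[j], " missing for some country-year")
    Z[, , j] <- matrix(m, C, Tn, byrow = TRUE)
  }
  z_mean <- apply(Z, 3, mean); z_sd <- apply(Z, 3, stats::sd)
  z_sd[z_sd == 0] <- 1
  for (j in seq_len(p)) Z[, , j] <- (Z[, , j] - z_mean[j]) / z_sd[j]

  # individual cells: one per source x classified group, one latent
  # non-sampling offset per individual-level source
  icells <- list(); eps_src <- character(0); eps_sub <- logical(0)
  if (!is.null(individuals) && nrow(individuals) > 0) {
    for (sid in unique(individuals$source_id)) {
      gsrc <- individuals[individuals$source_id == sid, , drop = FALSE]
      eps_src <- c(eps_src, sid)
      eps_sub <- c(eps_sub, identical(gsrc$coverage[1], "subnational"))
      for (grp in unique(gsrc$group)) {
        gg <- gsrc[gsrc$group == grp, , drop = FALSE]
        icells[[length(icells) + 1L]] <- list(
          source_id = sid, country = gg$country[1], year = gg$year[1],
          group = grp, h = gg$hb, eps_i = length(eps_src))
      }
    }
  }
  layout <- .layout(R, C, bb$Kc |> nrow(), p, family == "women",
                    length(eps_src))
  dat <- list(family = family, cfg = cfg, cutoffs = cutoffs,
              countries = countries, region_names = region_names,
              region_of = region_of, years = years, B = bb$B, Kc = bb$Kc,
              covs = covs, Z = Z, z_mean = z_mean, z_sd = z_sd,
              layout = layout, eps_src = eps_src, eps_sub = eps_sub)
  class(dat) <- "hb_model_data"

  ti_of <- function(year) {
    ti <- round(year) - years[1] + 1L
    min(max(ti, 1L), Tn)
  }
  ci_of <- function(country) {
    ci <- match(country, countries)
    if (is.na(ci)) stop("unknown country: ", country)
    ci
  }

  # --- likelihood terms ------------------------------------------------
  rows_i <- list(); rows_v <- list()            # base sparse rows
  add_row <- function(rw) { rows_i[[length(rows_i) + 1L]] <<- rw$idx
                            rows_v[[length(rows_v) + 1L]] <<- rw$val
                            length(rows_i) }
  lin <- list(); prev <- list(); prev_dropped <- 0L
  summ <- obs[obs$data_form == "summary", , drop = FALSE]
  for (i in seq_len(nrow(summ))) {
    o <- summ[i, ]
    ci <- ci_of(o$country); ti <- ti_of(o$year)
    sub <- identical(o$coverage, "subnational")
    mis <- !isTRUE(o$age_range_matches)
    grp <- as.character(o$group)
    if (grp == "women_combined") {
      pf <- o$pregnant_fraction
      if (is.na(pf)) stop("combined-women summary without pregnant_fraction: ",
                          o$source_id)
      r_np <- add_row(.design_row(dat, ci, ti, o$year, "non_pregnant"))
      r_dc <- add_row(list(idx = layout$dc[ci], val = 1))
      if (!is.na(o$mean_hb)) {
        # pooled mean = (1-p) theta_np + p (theta_np - delta_c)
        rw <- .design_row(dat, ci, ti, o$year, "non_pregnant")
        r_cm <- add_row(list(idx = c(rw$idx, layout$dc[ci]),
                             val = c(rw$val, -pf)))
        sdv <- if (!is.na(o$sd_hb)) o$sd_hb else cfg$fallback_sd
        lin[[length(lin) + 1L]] <- list(row = r_cm, y = o$mean_hb,
                                        base_var = sdv^2 / o$n,
                                        sub = sub, mis = mis)
      }
      if (cfg$use_prevalence) {
        for (sv in c(FALSE, TRUE)) {
          pv <- if (sv) o$prev_severe else o$prev_anaemia
          if (is.na(pv)) next
          if (pv * o$n < 1 || (1 - pv) * o$n < 1) {
            prev_dropped <- prev_dropped + 1L
            next
          }
          prev[[length(prev) + 1L]] <- list(
            type = "combined", row1 = r_np, row2 = r_dc, pfrac = pf,
            cut_np = unname(group_cutoffs(cutoffs, "non_pregnant")[if (sv) "severe" else "total"]),
            cut_p  = unname(group_cutoffs(cutoffs, "pregnant")[if (sv) "severe" else "total"]),
            p_obs = pv, n = o$n, sub = sub, mis = mis)
        }
      }
    } else {
      r1 <- add_row(.design_row(dat, ci, ti, o$year, grp))
      if (!is.na(o$mean_hb)) {
        sdv <- if (!is.na(o$sd_hb)) o$sd_hb else cfg$fallback_sd
        lin[[length(lin) + 1L]] <- list(row = r1, y = o$mean_hb,
                                        base_var = sdv^2 / o$n,
                                        sub = sub, mis = mis)
      }
      if (cfg$use_prevalence) {
        co <- group_cutoffs(cutoffs, grp)
        for (sv in c(FALSE, TRUE)) {
          pv <- if (sv) o$prev_severe else o$prev_anaemia
          if (is.na(pv)) next
          if (pv * o$n < 1 || (1 - pv) * o$n < 1) {
            prev_dropped <- prev_dropped + 1L
            next
          }
          prev[[length(prev) + 1L]] <- list(
            type = "single", row1 = r1, row2 = NA,
            cutoff = unname(co[if (sv) "severe" else "total"]),
            p_obs = pv, n = o$n, sub = sub, mis = mis)
        }
      }
    }
  }
  for (j in seq_along(icells)) {
    ic <- icells[[j]]
    ci <- ci_of(ic$country); ti <- ti_of(ic$year)
    icells[[j]]$row <- add_row(.design_row(dat, ci, ti, ic$year, ic$group,
                                           eps_i = ic$eps_i))
  }

  n_rows <- length(rows_i)
  if (n_rows > 0) {
    ii <- rep(seq_len(n_rows), lengths(rows_i))
    ROWS <- Matrix::sparseMatrix(i = ii, j = unlist(rows_i), x = unlist(rows_v),
                                 dims = c(n_rows, layout$d))
  } else ROWS <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                      dims = c(0L, layout$d))
  if (prev_dropped > 0)
    message(prev_dropped,
            " prevalence summaries with zero expected counts excluded")
  dat$ROWS <- ROWS
  dat$lin <- lin; dat$prev <- prev; dat$icells <- icells
  dat$prev_dropped <- prev_dropped
  dat$lin_rows <- vapply(lin, function(tm) as.numeric(tm$row), numeric(1))
  dat$lin_y <- vapply(lin, function(tm) as.numeric(tm$y), numeric(1))
  dat$lin_base_var <- vapply(lin, function(tm) as.numeric(tm$base_var), numeric(1))
  dat$lin_sub <- vapply(lin, function(tm) as.numeric(tm$sub), numeric(1))
  dat$lin_mis <- vapply(lin, function(tm) as.numeric(tm$mis), numeric(1))
  # flat arrays over prevalence terms (vectorised likelihood path)
  np <- length(prev)
  dat$pv_comb <- vapply(prev, function(tm) tm$type == "combined", logical(1))
  dat$pv_row1 <- vapply(prev, function(tm) as.numeric(tm$row1), numeric(1))
  dat$pv_row2 <- vapply(prev, function(tm)
    if (tm$type == "combined") as.numeric(tm$row2) else 1, numeric(1))
  dat$pv_pfrac <- vapply(prev, function(tm)
    if (tm$type == "combined") tm$pfrac else 0, numeric(1))
  dat$pv_cutA <- vapply(prev, function(tm)
    if (tm$type == "combined") tm$cut_np else tm$cutoff, numeric(1))
  dat$pv_cutB <- vapply(prev, function(tm)
    if (tm$type == "combined") tm$cut_p else 0, numeric(1))
  dat$pv_n <- vapply(prev, function(tm) as.numeric(tm$n), numeric(1))
  dat$pv_sub <- vapply(prev, function(tm) as.numeric(tm$sub), numeric(1))
  dat$pv_mis <- vapply(prev, function(tm) as.numeric(tm$mis), numeric(1))
  dat$pv_pobs <- vapply(prev, function(tm) as.numeric(tm$p_obs), numeric(1))
  dat$ic_rows <- vapply(icells, function(ic) as.numeric(ic$row), numeric(1))
  dat$ic_cell <- rep(seq_along(icells),
                     vapply(icells, function(ic) length(ic$h), integer(1)))
  dat$ic_h <- unlist(lapply(icells, `[[`, "h"), use.names = FALSE)
  dat$ti_of <- ti_of; dat$ci_of <- ci_of
  dat
}

# ---- parameter pack/unpack -------------------------------------------

#' Unpack a latent-field vector into named parameter blocks
#' @param dat an `hb_model_data`.
#' @param x latent-field vector.
#' @return named list of parameter blocks (`a0`, `b0`, `ar`, `br`, `ac`,
#'   `bc`, RW2 coefficient blocks, `beta`, pregnancy offsets, survey
#'   offsets).
#' @export
unpack_params <- function(dat, x) {
  st <- dat$layout
  list(a0 = x[st$a0], b0 = x[st$b0], ar = x[st$ar], br = x[st$br],
       ac = x[st$ac], bc = x[st$bc],
       g0 = x[st$g0],
       gr = matrix(x[st$gr], st$T2, st$R),
       gc = matrix(x[st$gc], st$T2, st$C),
       beta = x[st$beta],
       dreg = x[st$dreg], dc = x[st$dc], eps = x[st$eps])
}

#' Location of a country-year-group haemoglobin distribution
#'
#' theta = (a0 + a_r + a_c) + (b0 + b_r + b_c)(year - t_ref)
#' + u0(t) + u_r(t) + u_c(t) + z' beta, with the pregnant group's location
#' lowered by the country pregnancy offset. RW2 components are evaluated on
#' the year grid; the linear term uses the (decimal) year exactly.
#'
#' @param dat an `hb_model_data`.
#' @param x latent-field vector (see [unpack_params()]).
#' @param country country code.
#' @param year decimal year.
#' @param group `"children"`, `"non_pregnant"` or `"pregnant"`.
#' @return location in g/L.
#' @export
location_mean <- function(dat, x, country, year, group = dat$family) {
  ci <- dat$ci_of(country)
  ti <- dat$ti_of(year)
  if (identical(group, "women")) group <- "non_pregnant"
  rw <- .design_row(dat, ci, ti, year, group)
  sum(x[rw$idx] * rw$val)
}

# ---- likelihood ------------------------------------------------------

.lin_var <- function(dat, sig) {
  dat$lin_base_var + sig[["s_ns"]]^2 + dat$lin_sub * sig[["s_sub"]]^2 +
    dat$lin_mis * sig[["s_age"]]^2
}

# fast vectorised inverse of the standardised mixture cdf (grid + monotone
# interpolation); used inside the sampler where it is called repeatedly
.std_quantile_grid <- function(shape, p) {
  lo <- min(shape$offsets) - 8 * max(shape$sds)
  hi <- max(shape$offsets) + 8 * max(shape$sds)
  s <- seq(lo, hi, length.out = 512)
  Fs <- std_mixture_cdf(shape, s)
  stats::approx(Fs, s, xout = p, rule = 2, ties = "ordered")$y
}

# shape-dependent preparation of probit-scale prevalence terms: observed
# probit value, delta-method binomial variance, and the probit slope used
# to map the design-inflation variance (g/L^2) onto the probit scale
.prev_prep <- function(dat, shape) {
  if (length(dat$prev) == 0) return(NULL)
  pc <- pmin(pmax(dat$pv_pobs, 1 / (2 * dat$pv_n)), 1 - 1 / (2 * dat$pv_n))
  z <- stats::qnorm(pc)
  s_at <- .std_quantile_grid(shape, pc)
  slope <- std_mixture_pdf(shape, s_at) / stats::dnorm(z)
  list(z = z, binvar = pc * (1 - pc) / (dat$pv_n * stats::dnorm(z)^2),
       slope2 = slope^2)
}

# design-inflation variance (g/L^2) per prevalence term
.prev_infl <- function(dat, sig) {
  sig[["s_ns"]]^2 + dat$pv_sub * sig[["s_sub"]]^2 +
    dat$pv_mis * sig[["s_age"]]^2
}

.prev_var <- function(prep, dat, sig) prep$binvar + .prev_infl(dat, sig) * prep$slope2

# probit-transformed model prevalences of all prevalence terms at once
# (and the gradients wrt their 1-2 linear coordinates)
.prev_G_all <- function(dat, eta, shape, grad = FALSE) {
  if (length(dat$prev) == 0)
    return(list(G = numeric(0), g1 = numeric(0), g2 = numeric(0)))
  eta1 <- eta[dat$pv_row1]
  eta2 <- ifelse(dat$pv_comb, eta[dat$pv_row2], 0)
  sA <- dat$pv_cutA - eta1
  sB <- dat$pv_cutB - eta1 + eta2
  FA <- std_mixture_cdf(shape, sA)
  FB <- std_mixture_cdf(shape, sB)
  Fm <- ifelse(dat$pv_comb, (1 - dat$pv_pfrac) * FA + dat$pv_pfrac * FB, FA)
  Fm <- pmin(pmax(Fm, 1e-12), 1 - 1e-12)
  G <- stats::qnorm(Fm)
  if (!grad) return(list(G = G))
  fA <- std_mixture_pdf(shape, sA)
  fB <- std_mixture_pdf(shape, sB)
  dphi <- stats::dnorm(G)
  g1 <- ifelse(dat$pv_comb,
               -((1 - dat$pv_pfrac) * fA + dat$pv_pfrac * fB),
               -fA) / dphi
  g2 <- ifelse(dat$pv_comb, dat$pv_pfrac * fB, 0) / dphi
  list(G = G, g1 = g1, g2 = g2)
}

# G(eta) = probit(model prevalence) and its gradient wrt the 1-2 eta coords
.prev_G <- function(tm, shape, eta1, eta2 = NULL, grad = FALSE) {
  if (tm$type == "single") {
    Fm <- std_mixture_cdf(shape, tm$cutoff - eta1)
    Fm <- min(max(Fm, 1e-12), 1 - 1e-12)
    G <- stats::qnorm(Fm)
    if (!grad) return(list(G = G))
    f <- std_mixture_pdf(shape, tm$cutoff - eta1)
    list(G = G, g = c(-f / stats::dnorm(G)))
  } else {
    # eta1 = theta_np, eta2 = delta_c; theta_p = eta1 - eta2
    Fnp <- std_mixture_cdf(shape, tm$cut_np - eta1)
    Fp <- std_mixture_cdf(shape, tm$cut_p - eta1 + eta2)
    Fm <- (1 - tm$pfrac) * Fnp + tm$pfrac * Fp
    Fm <- min(max(Fm, 1e-12), 1 - 1e-12)
    G <- stats::qnorm(Fm)
    if (!grad) return(list(G = G))
    fnp <- std_mixture_pdf(shape, tm$cut_np - eta1)
    fp <- std_mixture_pdf(shape, tm$cut_p - eta1 + eta2)
    dphi <- stats::dnorm(G)
    list(G = G,
         g = c(-((1 - tm$pfrac) * fnp + tm$pfrac * fp) / dphi,
               tm$pfrac * fp / dphi))
  }
}

# log-likelihood, gradient and curvature of one individual-record cell as a
# function of its location eta (analytic; curvature clamped positive)
.icell_llgh <- function(h, eta, shape, want_deriv = FALSE) {
  K <- length(shape$weights)
  n <- length(h)
  dens <- matrix(0, n, K); z <- matrix(0, n, K)
  for (k in seq_len(K)) {
    zk <- (h - eta - shape$offsets[k]) / shape$sds[k]
    z[, k] <- zk
    dens[, k] <- shape$weights[k] * stats::dnorm(zk) / shape$sds[k]
  }
  f <- rowSums(dens)
  f <- pmax(f, 1e-300)
  ll <- sum(log(f))
  if (!want_deriv) return(list(ll = ll))
  fp <- rowSums(dens * z / rep(shape$sds, each = n))          # d f / d eta
  fpp <- rowSums(dens * (z^2 - 1) / rep(shape$sds^2, each = n))
  lp <- fp / f
  lpp <- fpp / f - lp^2
  g <- sum(lp)
  hcurv <- max(-sum(lpp), n / (4 * max(shape$sds)^2))
  list(ll = ll, g = g, h = hcurv)
}

# per-cell log-likelihood (and derivatives) of all individual-record cells
# at once, vectorised over the concatenated record vector
.icells_llgh_all <- function(dat, eta, shape, want_deriv = FALSE) {
  n_cell <- length(dat$icells)
  if (n_cell == 0)
    return(list(ll = numeric(0), g = numeric(0), h = numeric(0)))
  eta_rec <- eta[dat$ic_rows][dat$ic_cell]
  h <- dat$ic_h
  K <- length(shape$weights)
  n <- length(h)
  f <- numeric(n); fp <- numeric(n); fpp <- numeric(n)
  for (k in seq_len(K)) {
    zk <- (h - eta_rec - shape$offsets[k]) / shape$sds[k]
    dk <- shape$weights[k] * stats::dnorm(zk) / shape$sds[k]
    f <- f + dk
    if (want_deriv) {
      fp <- fp + dk * zk / shape$sds[k]
      fpp <- fpp + dk * (zk^2 - 1) / shape$sds[k]^2
    }
  }
  f <- pmax(f, 1e-300)
  ll <- rowsum(log(f), dat$ic_cell)[, 1]
  if (!want_deriv) return(list(ll = ll))
  lp <- fp / f
  g <- rowsum(lp, dat$ic_cell)[, 1]
  lpp <- fpp / f - lp^2
  hc <- -rowsum(lpp, dat$ic_cell)[, 1]
  nrec <- tabulate(dat$ic_cell, nbins = n_cell)
  hc <- pmax(hc, nrec / (4 * max(shape$sds)^2))
  list(ll = ll, g = g, h = hc)
}

# data log-likelihood components at latent field x (eta = ROWS %*% x)
.data_loglik_parts <- function(dat, eta, sig, shape, prevprep) {
  ll_lin <- if (length(dat$lin) > 0)
    sum(stats::dnorm(dat$lin_y, eta[dat$lin_rows],
                     sqrt(.lin_var(dat, sig)), log = TRUE)) else 0
  ll_prev <- if (length(dat$prev) > 0) {
    vz <- .prev_var(prevprep, dat, sig)
    G <- .prev_G_all(dat, eta, shape)$G
    sum(stats::dnorm(prevprep$z, G, sqrt(vz), log = TRUE))
  } else 0
  ll_ic <- sum(.icells_llgh_all(dat, eta, shape)$ll)
  list(lin = ll_lin, prev = ll_prev, ic = ll_ic)
}

.data_loglik <- function(dat, eta, sig, shape, prevprep) {
  p <- .data_loglik_parts(dat, eta, sig, shape, prevprep)
  p$lin + p$prev + p$ic
}

#' Log-likelihood contribution of one observation
#'
#' Summary means contribute a Normal log-density with variance
#' `sd^2/n + sigma_ns^2 + [subnational] sigma_sub^2 + [age mismatch]
#' sigma_age^2`; summary prevalences contribute a Normal log-density on the
#' probit scale with delta-method binomial variance plus the same design
#' inflation mapped through the probit slope; individual records contribute
#' the sum of log mixture densities at the cell's location (plus an optional
#' survey-level non-sampling offset); combined-women data use the
#' pregnant-fraction mixture of the two distributions.
#'
#' @param obs a one-row summary observation, or a list with `h` (individual
#'   records), `group`, and location info.
#' @param theta location (g/L) of the observation's cell (for combined
#'   observations, the non-pregnant location).
#' @param shape mixture shape (list with `offsets`, `weights`, `sds`).
#' @param sig named vector with `s_ns`, `s_sub`, `s_age` (g/L).
#' @param cutoffs a [cutoff_set()].
#' @param delta pregnancy offset (g/L), used for combined observations.
#' @param eps survey-level non-sampling offset for individual-level data
#'   (default 0, in which case individual records contribute exactly
#'   `sum(log(mixture_pdf(...)))`).
#' @return log-density.
#' @export
loglik_observation <- function(obs, theta, shape, sig, cutoffs = cutoff_set(),
                               delta = 0, eps = 0) {
  sig <- c(s_ns = unname(sig["s_ns"]), s_sub = unname(sig["s_sub"]),
           s_age = unname(sig["s_age"]))
  sig[is.na(sig)] <- 0
  if (!is.null(obs$h)) {             # individual-record cell
    return(.icell_llgh(obs$h, theta + eps, shape)$ll)
  }
  grp <- as.character(obs$group)
  sub <- identical(as.character(obs$coverage), "subnational")
  mis <- !isTRUE(obs$age_range_matches)
  infl <- sig["s_ns"]^2 + (if (sub) sig["s_sub"]^2 else 0) +
    (if (mis) sig["s_age"]^2 else 0)
  has_mean <- !is.null(obs$mean_hb) && !is.na(obs$mean_hb)
  has_prev <- !is.null(obs$prev_anaemia) && !is.na(obs$prev_anaemia)
  if (!has_mean && !has_prev)
    stop("observation has neither mean, prevalence, nor records")
  ll <- 0
  if (has_mean) {
    sdv <- if (!is.null(obs$sd_hb) && !is.na(obs$sd_hb)) obs$sd_hb else 14
    mu <- if (grp == "women_combined") theta - obs$pregnant_fraction * delta else theta
    ll <- ll + stats::dnorm(obs$mean_hb, mu, sqrt(sdv^2 / obs$n + infl),
                            log = TRUE)
  }
  if (has_prev) {
    pc <- min(max(obs$prev_anaemia, 1 / (2 * obs$n)), 1 - 1 / (2 * obs$n))
    zj <- stats::qnorm(pc)
    if (grp == "women_combined") {
      tm <- list(type = "combined", pfrac = obs$pregnant_fraction,
                 cut_np = unname(group_cutoffs(cutoffs, "non_pregnant")["total"]),
                 cut_p = unname(group_cutoffs(cutoffs, "pregnant")["total"]))
      G <- .prev_G(tm, shape, theta, delta)$G
    } else {
      tm <- list(type = "single",
                 cutoff = unname(group_cutoffs(cutoffs, grp)["total"]))
      G <- .prev_G(tm, shape, theta)$G
    }
    s_at <- std_mixture_quantile(shape, pc)
    slope <- std_mixture_pdf(shape, s_at) / stats::dnorm(zj)
    vz <- pc * (1 - pc) / (obs$n * stats::dnorm(zj)^2) + infl * slope^2
    ll <- ll + stats::dnorm(zj, G, sqrt(vz), log = TRUE)
  }
  unname(ll)
}

# ---- prior -----------------------------------------------------------

.half_normal_lp <- function(s, scale) {
  if (s <= 0) return(-Inf)
  stats::dnorm(s, 0, scale, log = TRUE) + log(2)
}

# prior precision of x given hyper sds, with prior mean mu0
.prior_precision <- function(dat, sig) {
  st <- dat$layout; cfg <- dat$cfg
  Qp <- matrix(0, st$d, st$d)
  adddiag <- function(idx, prec) {
    if (length(idx) > 0) Qp[cbind(idx, idx)] <<- Qp[cbind(idx, idx)] + prec
  }
  adddiag(st$a0, 1 / cfg$prior_a0_sd^2)
  adddiag(st$b0, 1 / cfg$prior_b0_sd^2)
  adddiag(st$ar, 1 / sig["s_ar"]^2)
  adddiag(st$br, 1 / sig["s_br"]^2)
  adddiag(st$ac, 1 / sig["s_ac"]^2)
  adddiag(st$bc, 1 / sig["s_bc"]^2)
  adddiag(st$beta, 1 / cfg$prior_beta_sd^2)
  addK <- function(idx, s) {
    Qp[idx, idx] <<- Qp[idx, idx] + dat$Kc / s^2
  }
  addK(st$g0, sig["s_u0"])
  for (r in seq_len(st$R)) addK(.idx_gr(st, r), sig["s_ur"])
  for (ci in seq_len(st$C)) addK(.idx_gc(st, ci), sig["s_uc"])
  if (st$women) {
    adddiag(st$dreg, 1 / cfg$prior_delta_sd^2)
    # dc ~ N(dreg[region], s_delta^2): coupling terms
    sd2 <- 1 / sig["s_delta"]^2
    for (ci in seq_len(st$C)) {
      i <- st$dc[ci]; j <- st$dreg[dat$region_of[ci]]
      Qp[i, i] <- Qp[i, i] + sd2
      Qp[j, j] <- Qp[j, j] + sd2
      Qp[i, j] <- Qp[i, j] - sd2
      Qp[j, i] <- Qp[j, i] - sd2
    }
  }
  if (length(st$eps) > 0) {
    ve <- sig["s_ns"]^2 + ifelse(dat$eps_sub, sig["s_sub"]^2, 0)
    Qp[cbind(st$eps, st$eps)] <- Qp[cbind(st$eps, st$eps)] + 1 / ve
  }
  Qp
}

.prior_mean <- function(dat) {
  st <- dat$layout
  mu0 <- numeric(st$d)
  mu0[st$a0] <- dat$cfg$prior_a0_mean
  if (st$women) mu0[st$dreg] <- dat$cfg$prior_delta_mean
  mu0
}

# log prior density of x given hyper sds (quadratic part plus the
# sigma-dependent normalising constants, needed for hyper updates), plus
# the positivity constraint on pregnancy offsets
.logprior_x <- function(dat, x, sig, Qp = NULL, mu0 = NULL) {
  st <- dat$layout
  if (st$women && any(x[st$dc] < 0)) return(-Inf)
  if (is.null(Qp)) Qp <- .prior_precision(dat, sig)
  if (is.null(mu0)) mu0 <- .prior_mean(dat)
  xc <- x - mu0
  -0.5 * sum(xc * (Qp %*% xc))
}

#' Log prior density of the model parameters
#'
#' Sums the Gaussian shrinkage priors of the hierarchical deviations, the
#' RW2 smoothness priors, the covariate and pregnancy-offset priors, the
#' half-Normal hyperpriors on all sd parameters, and the mixture-shape
#' prior. Returns `-Inf` outside the support (negative sds, negative
#' pregnancy offsets, unordered offsets).
#'
#' @param dat an `hb_model_data`.
#' @param x latent-field vector.
#' @param sig named vector of sd parameters.
#' @param zeta transformed mixture-shape parameter vector (see
#'   [shape_from_zeta()]).
#' @return log prior density (up to a constant).
#' @export
logprior <- function(dat, x, sig, zeta) {
  cfg <- dat$cfg
  if (any(sig <= 0)) return(-Inf)
  lp <- .logprior_x(dat, x, sig)
  if (!is.finite(lp)) return(lp)
  st <- dat$layout
  # sigma-dependent Gaussian normalisers
  lp <- lp - st$R * (log(sig["s_ar"]) + log(sig["s_br"])) -
    st$C * (log(sig["s_ac"]) + log(sig["s_bc"])) -
    st$T2 * log(sig["s_u0"]) - st$R * st$T2 * log(sig["s_ur"]) -
    st$C * st$T2 * log(sig["s_uc"])
  if (st$women) lp <- lp - st$C * log(sig["s_delta"])
  if (length(st$eps) > 0) {
    ve <- sig["s_ns"]^2 + ifelse(dat$eps_sub, sig["s_sub"]^2, 0)
    lp <- lp - 0.5 * sum(log(ve))
  }
  # half-Normal hyperpriors
  hn <- c(s_ar = cfg$hn_region_int, s_br = cfg$hn_region_slope,
          s_ac = cfg$hn_country_int, s_bc = cfg$hn_country_slope,
          s_u0 = cfg$hn_rw2_global, s_ur = cfg$hn_rw2_region,
          s_uc = cfg$hn_rw2_country, s_delta = cfg$hn_delta,
          s_ns = cfg$hn_ns, s_sub = cfg$hn_sub, s_age = cfg$hn_age)
  for (nm in names(hn)) if (nm %in% names(sig))
    lp <- lp + .half_normal_lp(unname(sig[nm]), hn[nm])
  lp + .shape_logprior(zeta, cfg)
}

# ---- mixture shape transform -----------------------------------------
# zeta = (lw[2..K] weight logits, o1 first raw offset, lg[2..K] log gaps,
#         lt[1..K] log component sds); offsets are centred so the mixture
#         mean equals the location

#' Mixture shape from its unconstrained parameterisation
#' @param zeta numeric vector of length `3K - 1`.
#' @param K number of components.
#' @return list with `offsets` (centred, strictly increasing), `weights`,
#'   `sds`.
#' @export
shape_from_zeta <- function(zeta, K = 5) {
  lw <- zeta[seq_len(K - 1)]
  o1 <- zeta[K]
  lg <- zeta[K + seq_len(K - 1)]
  lt <- zeta[2 * K - 1 + seq_len(K)]
  ew <- exp(c(0, lw)); w <- ew / sum(ew)
  raw <- o1 + c(0, cumsum(exp(lg)))
  list(offsets = center_offsets(raw, w), weights = w, sds = exp(lt))
}

#' @rdname shape_from_zeta
#' @param shape list with `offsets`, `weights`, `sds`.
#' @export
zeta_from_shape <- function(shape) {
  K <- length(shape$weights)
  lw <- log(shape$weights[-1] / shape$weights[1])
  # invert centring through an arbitrary raw anchor: raw gaps are preserved
  gaps <- diff(shape$offsets)
  c(lw, shape$offsets[1], log(gaps), log(shape$sds))
}

.shape_logprior <- function(zeta, cfg) {
  K <- cfg$K
  lw <- zeta[seq_len(K - 1)]
  o1 <- zeta[K]
  lg <- zeta[K + seq_len(K - 1)]
  lt <- zeta[2 * K - 1 + seq_len(K)]
  tau <- exp(lt)
  sum(stats::dnorm(lw, 0, 1.5, log = TRUE)) +
    stats::dnorm(o1, -20, 8, log = TRUE) +
    sum(stats::dnorm(lg, log(9), 0.6, log = TRUE)) +
    sum(stats::dnorm(tau, 0, cfg$hn_tau, log = TRUE) + log(2) + lt)
}

#' Log posterior density (up to a constant)
#'
#' Definitional identity `logposterior = logprior + sum(loglik)` used by
#' the sampler.
#' @inheritParams logprior
#' @return log posterior density.
#' @export
logposterior <- function(dat, x, sig, zeta) {
  lp <- logprior(dat, x, sig, zeta)
  if (!is.finite(lp)) return(lp)
  shape <- shape_from_zeta(zeta, dat$cfg$K)
  prevprep <- .prev_prep(dat, shape)
  eta <- as.vector(dat$ROWS %*% x)
  lp + .data_loglik(dat, eta, sig, shape, prevprep)
}
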