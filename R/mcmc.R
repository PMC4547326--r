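#' MCMC fitting configuration
#'
#' Defaults: 4 chains with 1000 warmup iterations each, pooled and trimmed
#' so that exactly `target_retained` (2500) posterior draws are kept.
#'
#' @param chains number of chains.
#' @param warmup warmup iterations per chain (discarded; adaptation happens
#'   only here).
#' @param target_retained total retained draws pooled across chains
#'   (default 2500).
#' @param thin thinning interval after warmup.
#' @param seed integer seed controlling initial jitter and sampling.
#' @return a list of class `hb_fit_config`.
#' @export
fit_config <- function(chains = 4, warmup = 1000, target_retained = 2500,
                       thin = 1, seed = 1) {
  stopifnot(chains >= 1, warmup >= 0, target_retained >= 1, thin >= 1)
  structure(list(chains = chains, warmup = warmup,
                 target_retained = target_retained, thin = thin, seed = seed),
            class = "hb_fit_config")
}

.sig_names <- function(dat) {
  nm <- c("s_ar", "s_br", "s_ac", "s_bc", "s_u0", "s_ur", "s_uc",
          "s_ns", "s_sub", "s_age")
  if (dat$layout$women) nm <- append(nm, "s_delta", after = 7)
  nm
}

.init_state <- function(dat, jitter_sd = 0.05) {
  st <- dat$layout
  x <- .prior_mean(dat)
  if (length(dat$lin_y) > 0) x[st$a0] <- mean(dat$lin_y)
  else if (length(dat$ic_h) > 0) x[st$a0] <- mean(dat$ic_h)
  x <- x + stats::rnorm(st$d, 0, jitter_sd)
  if (st$women) x[st$dc] <- pmax(x[st$dc], 0.5)
  sig <- c(s_ar = 3, s_br = 0.1, s_ac = 3, s_bc = 0.1,
           s_u0 = 0.05, s_ur = 0.05, s_uc = 0.05,
           s_delta = 1, s_ns = 2, s_sub = 2, s_age = 2)
  sig <- sig[.sig_names(dat)]
  sig <- sig * exp(stats::rnorm(length(sig), 0, jitter_sd))
  zeta <- zeta_from_shape(dat$cfg$shape_init) +
    stats::rnorm(3 * dat$cfg$K - 1, 0, jitter_sd / 5)
  list(x = x, sig = sig, zeta = zeta)
}

# Taylor (Gaussian) approximation pieces of the data likelihood at eta:
# sparse combination matrix W (terms x base rows), weights, working resp.
.taylor_terms <- function(dat, eta, shape, prevprep, sig) {
  n_lin <- length(dat$lin); n_prev <- length(dat$prev)
  n_ic <- length(dat$icells)
  nterm <- n_lin + n_prev + n_ic
  if (nterm == 0L) return(list(W = NULL, w = numeric(0), r = numeric(0)))
  ti <- list(); tj <- list(); tx <- list()
  w <- numeric(nterm); r <- numeric(nterm)
  if (n_lin > 0) {
    ti[[1]] <- seq_len(n_lin); tj[[1]] <- dat$lin_rows
    tx[[1]] <- rep(1, n_lin)
    w[seq_len(n_lin)] <- 1 / .lin_var(dat, sig)
    r[seq_len(n_lin)] <- dat$lin_y
  }
  if (n_prev > 0) {
    jj <- n_lin + seq_len(n_prev)
    gg <- .prev_G_all(dat, eta, shape, grad = TRUE)
    eta1 <- eta[dat$pv_row1]
    eta2 <- ifelse(dat$pv_comb, eta[dat$pv_row2], 0)
    ti[[2]] <- c(jj, jj[dat$pv_comb])
    tj[[2]] <- c(dat$pv_row1, dat$pv_row2[dat$pv_comb])
    tx[[2]] <- c(gg$g1, gg$g2[dat$pv_comb])
    w[jj] <- 1 / .prev_var(prevprep, dat, sig)
    r[jj] <- prevprep$z - gg$G + gg$g1 * eta1 + gg$g2 * eta2
  }
  if (n_ic > 0) {
    jj <- n_lin + n_prev + seq_len(n_ic)
    dv <- .icells_llgh_all(dat, eta, shape, want_deriv = TRUE)
    ti[[3]] <- jj; tj[[3]] <- dat$ic_rows; tx[[3]] <- rep(1, n_ic)
    w[jj] <- dv$h
    r[jj] <- eta[dat$ic_rows] + dv$g / dv$h
  }
  W <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(nterm, nrow(dat$ROWS)))
  list(W = W, w = w, r = r)
}

# Gaussian proposal N(m, Q^-1) from the Taylor expansion at the current
# state; returns the Cholesky factor, mean, and pieces to evaluate logq
.taylor_gaussian <- function(dat, eta, shape, prevprep, sig, Qp, bp) {
  tt <- .taylor_terms(dat, eta, shape, prevprep, sig)
  Q <- Qp
  b <- bp
  if (!is.null(tt$W)) {
    A <- tt$W %*% dat$ROWS
    Aw <- A * sqrt(tt$w)
    Q <- Q + as.matrix(Matrix::crossprod(Aw))
    b <- b + as.vector(Matrix::crossprod(A, tt$w * tt$r))
  }
  R <- tryCatch(chol(Q), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  m <- backsolve(R, backsolve(R, b, transpose = TRUE))
  list(R = R, m = m, logdethalf = sum(log(diag(R))))
}

.gauss_rand <- function(tg) {
  z <- stats::rnorm(length(tg$m))
  tg$m + backsolve(tg$R, z)
}

.gauss_logq <- function(tg, x) {
  u <- tg$R %*% (x - tg$m)
  tg$logdethalf - 0.5 * sum(u^2)
}

# one Metropolis-Hastings update of the latent field using the one-block
# Gaussian-Taylor proposal; exact for purely Gaussian data terms
.update_x <- function(dat, state, cache) {
  tg <- .taylor_gaussian(dat, cache$eta, cache$shape, cache$prevprep,
                         state$sig, cache$Qp, cache$bp)
  if (is.null(tg)) return(list(state = state, cache = cache, acc = FALSE))
  xs <- .gauss_rand(tg)
  st <- dat$layout
  if (st$women && any(xs[st$dc] < 0))
    return(list(state = state, cache = cache, acc = FALSE))
  eta_s <- as.vector(dat$ROWS %*% xs)
  llp_s <- .data_loglik_parts(dat, eta_s, state$sig, cache$shape,
                              cache$prevprep)
  ll_s <- llp_s$lin + llp_s$prev + llp_s$ic
  lp_s <- .logprior_x(dat, xs, state$sig, cache$Qp, cache$mu0)
  tg_rev <- .taylor_gaussian(dat, eta_s, cache$shape, cache$prevprep,
                             state$sig, cache$Qp, cache$bp)
  if (is.null(tg_rev)) return(list(state = state, cache = cache, acc = FALSE))
  la <- (lp_s + ll_s) - (cache$lp_x + cache$ll) +
    .gauss_logq(tg_rev, state$x) - .gauss_logq(tg, xs)
  if (is.finite(la) && log(stats::runif(1)) < la) {
    state$x <- xs
    cache$eta <- eta_s; cache$llp <- llp_s; cache$ll <- ll_s
    cache$lp_x <- lp_s
    return(list(state = state, cache = cache, acc = TRUE))
  }
  list(state = state, cache = cache, acc = FALSE)
}

# block sum-of-squares for the Gaussian hierarchy sds
.block_ss <- function(dat, x) {
  st <- dat$layout
  qf <- function(g) as.numeric(g %*% (dat$Kc %*% g))
  ss <- list(
    s_ar = list(ss = sum(x[st$ar]^2), n = st$R),
    s_br = list(ss = sum(x[st$br]^2), n = st$R),
    s_ac = list(ss = sum(x[st$ac]^2), n = st$C),
    s_bc = list(ss = sum(x[st$bc]^2), n = st$C),
    s_u0 = list(ss = qf(x[st$g0]), n = st$T2),
    s_ur = list(ss = sum(vapply(seq_len(st$R), function(r)
      qf(x[.idx_gr(st, r)]), numeric(1))), n = st$R * st$T2),
    s_uc = list(ss = sum(vapply(seq_len(st$C), function(ci)
      qf(x[.idx_gc(st, ci)]), numeric(1))), n = st$C * st$T2))
  if (st$women) {
    dev <- x[st$dc] - x[st$dreg][dat$region_of]
    ss$s_delta <- list(ss = sum(dev^2), n = st$C)
  }
  ss
}

.hn_scales <- function(cfg) {
  c(s_ar = cfg$hn_region_int, s_br = cfg$hn_region_slope,
    s_ac = cfg$hn_country_int, s_bc = cfg$hn_country_slope,
    s_u0 = cfg$hn_rw2_global, s_ur = cfg$hn_rw2_region,
    s_uc = cfg$hn_rw2_country, s_delta = cfg$hn_delta,
    s_ns = cfg$hn_ns, s_sub = cfg$hn_sub, s_age = cfg$hn_age)
}

# MH updates (log scale) of the hierarchy sds; cheap, no data likelihood
.update_hier_sds <- function(dat, state, cache, prop_sd = 0.4,
                             n_sweeps = 3) {
  ss <- .block_ss(dat, state$x)
  hn <- .hn_scales(dat$cfg)
  tgt <- function(s, nm) -ss[[nm]]$n * log(s) - ss[[nm]]$ss / (2 * s^2) +
    .half_normal_lp(s, hn[[nm]]) + log(s)
  for (sw in seq_len(n_sweeps)) for (nm in names(ss)) {
    s0 <- state$sig[[nm]]
    s1 <- s0 * exp(stats::rnorm(1, 0, prop_sd))
    if (log(stats::runif(1)) < tgt(s1, nm) - tgt(s0, nm)) state$sig[nm] <- s1
  }
  # prior precision changed
  cache$Qp <- .prior_precision(dat, state$sig)
  cache$bp <- as.vector(cache$Qp %*% cache$mu0)
  cache$lp_x <- .logprior_x(dat, state$x, state$sig, cache$Qp, cache$mu0)
  list(state = state, cache = cache)
}

# data-variance components: non-sampling, subnational, age-mismatch sds;
# these enter summary-term variances, probit-term variances, and the prior
# of the latent survey offsets
.update_noise_sds <- function(dat, state, cache, prop_sd = 0.3) {
  st <- dat$layout
  hn <- .hn_scales(dat$cfg)
  eps <- state$x[st$eps]
  Gv <- if (length(dat$prev) > 0)
    .prev_G_all(dat, cache$eta, cache$shape)$G else numeric(0)
  et_lin <- cache$eta[dat$lin_rows]
  part <- function(sig) {
    v_eps <- 0
    if (length(st$eps) > 0) {
      ve <- sig[["s_ns"]]^2 + dat$eps_sub * sig[["s_sub"]]^2
      v_eps <- sum(stats::dnorm(eps, 0, sqrt(ve), log = TRUE))
    }
    ll_lin <- if (length(dat$lin) > 0)
      sum(stats::dnorm(dat$lin_y, et_lin, sqrt(.lin_var(dat, sig)),
                       log = TRUE)) else 0
    ll_prev <- if (length(dat$prev) > 0)
      sum(stats::dnorm(cache$prevprep$z, Gv,
                       sqrt(.prev_var(cache$prevprep, dat, sig)),
                       log = TRUE)) else 0
    v_eps + ll_lin + ll_prev
  }
  cur <- part(state$sig)
  for (nm in c("s_ns", "s_sub", "s_age")) {
    s0 <- state$sig[[nm]]
    s1 <- s0 * exp(stats::rnorm(1, 0, prop_sd))
    sig1 <- state$sig; sig1[nm] <- s1
    prop <- part(sig1)
    la <- prop - cur +
      .half_normal_lp(s1, hn[[nm]]) - .half_normal_lp(s0, hn[[nm]]) +
      log(s1) - log(s0)
    if (is.finite(la) && log(stats::runif(1)) < la) {
      state$sig[nm] <- s1; cur <- prop
    }
  }
  cache$Qp <- .prior_precision(dat, state$sig)
  cache$bp <- as.vector(cache$Qp %*% cache$mu0)
  cache$lp_x <- .logprior_x(dat, state$x, state$sig, cache$Qp, cache$mu0)
  cache$llp$lin <- if (length(dat$lin) > 0)
    sum(stats::dnorm(dat$lin_y, et_lin, sqrt(.lin_var(dat, state$sig)),
                     log = TRUE)) else 0
  cache$llp$prev <- if (length(dat$prev) > 0)
    sum(stats::dnorm(cache$prevprep$z, Gv,
                     sqrt(.prev_var(cache$prevprep, dat, state$sig)),
                     log = TRUE)) else 0
  cache$ll <- cache$llp$lin + cache$llp$prev + cache$llp$ic
  list(state = state, cache = cache)
}

# shape-dependent part of the log target (prior + individual cells +
# prevalence terms)
.shape_target <- function(dat, eta, sig, zeta) {
  lp <- .shape_logprior(zeta, dat$cfg)
  shape <- shape_from_zeta(zeta, dat$cfg$K)
  prevprep <- .prev_prep(dat, shape)
  ll_ic <- sum(.icells_llgh_all(dat, eta, shape)$ll)
  ll_prev <- 0
  if (length(dat$prev) > 0) {
    vz <- .prev_var(prevprep, dat, sig)
    G <- .prev_G_all(dat, eta, shape)$G
    ll_prev <- sum(stats::dnorm(prevprep$z, G, sqrt(vz), log = TRUE))
  }
  list(val = lp + ll_ic + ll_prev, shape = shape, prevprep = prevprep,
       ll_ic = ll_ic, ll_prev = ll_prev)
}

# mixture-shape update: joint adaptive-covariance Metropolis over the
# transformed shape vector (Haario-style; the empirical covariance and the
# global scale are adapted during warmup only and frozen afterwards)
.update_shape <- function(dat, state, cache, ad, adapt = FALSE,
                          n_sweeps = 2) {
  d <- length(state$zeta)
  cur_val <- .shape_logprior(state$zeta, dat$cfg) + cache$llp$ic +
    cache$llp$prev
  cur <- list(val = cur_val, shape = cache$shape, prevprep = cache$prevprep,
              ll_ic = cache$llp$ic, ll_prev = cache$llp$prev)
  for (sw in seq_len(n_sweeps)) {
    L <- ad$chol
    step <- ad$scale * as.vector(L %*% stats::rnorm(d))
    zeta1 <- state$zeta + step
    prop <- .shape_target(dat, cache$eta, state$sig, zeta1)
    la <- prop$val - cur$val
    acc <- is.finite(la) && log(stats::runif(1)) < la
    if (acc) { state$zeta <- zeta1; cur <- prop }
    if (adapt) {
      ad$n <- ad$n + 1
      ad$scale <- ad$scale * exp(0.05 * ((if (acc) 1 else 0) - 0.25))
      # running mean / covariance of the shape draws
      dlt <- state$zeta - ad$mean
      ad$mean <- ad$mean + dlt / ad$n
      ad$M2 <- ad$M2 + tcrossprod(dlt, state$zeta - ad$mean)
      if (ad$n >= 50 && ad$n %% 25 == 0) {
        cv <- ad$M2 / (ad$n - 1) + diag(1e-8, d)
        ch <- tryCatch(t(chol(cv)), error = function(e) NULL)
        if (!is.null(ch)) ad$chol <- ch
      }
    }
  }
  cache$shape <- cur$shape
  cache$prevprep <- cur$prevprep
  cache$llp$ic <- cur$ll_ic
  cache$llp$prev <- cur$ll_prev
  cache$ll <- cache$llp$lin + cache$llp$prev + cache$llp$ic
  list(state = state, cache = cache, ad = ad)
}

.shape_adapt_init <- function(d) {
  list(n = 0, scale = 0.5, mean = numeric(d), M2 = matrix(0, d, d),
       chol = diag(0.03, d))
}

.make_cache <- function(dat, state) {
  cache <- list()
  cache$mu0 <- .prior_mean(dat)
  cache$Qp <- .prior_precision(dat, state$sig)
  cache$bp <- as.vector(cache$Qp %*% cache$mu0)
  cache$shape <- shape_from_zeta(state$zeta, dat$cfg$K)
  cache$prevprep <- .prev_prep(dat, cache$shape)
  cache$eta <- as.vector(dat$ROWS %*% state$x)
  cache$llp <- .data_loglik_parts(dat, cache$eta, state$sig, cache$shape,
                                  cache$prevprep)
  cache$ll <- cache$llp$lin + cache$llp$prev + cache$llp$ic
  cache$lp_x <- .logprior_x(dat, state$x, state$sig, cache$Qp, cache$mu0)
  cache
}

# move the latent field to (near) its conditional mode by iterating the
# Taylor approximation; used only to initialise chains in a region where
# the one-block proposal is locally accurate
.newton_x <- function(dat, state, cache, iters = 15) {
  st <- dat$layout
  for (i in seq_len(iters)) {
    tg <- .taylor_gaussian(dat, cache$eta, cache$shape, cache$prevprep,
                           state$sig, cache$Qp, cache$bp)
    if (is.null(tg)) break
    xn <- tg$m
    if (st$women) xn[st$dc] <- pmax(xn[st$dc], 0.01)
    eta_n <- as.vector(dat$ROWS %*% xn)
    llp_n <- .data_loglik_parts(dat, eta_n, state$sig, cache$shape,
                                cache$prevprep)
    ll_n <- llp_n$lin + llp_n$prev + llp_n$ic
    lp_n <- .logprior_x(dat, xn, state$sig, cache$Qp, cache$mu0)
    if (!is.finite(ll_n + lp_n)) break
    conv <- abs((ll_n + lp_n) - (cache$ll + cache$lp_x)) < 1e-4
    state$x <- xn
    cache$eta <- eta_n; cache$llp <- llp_n; cache$ll <- ll_n
    cache$lp_x <- lp_n
    if (conv) break
  }
  list(state = state, cache = cache)
}

.run_chain <- function(dat, fit_cfg, chain_id, n_keep) {
  set.seed(fit_cfg$seed * 1000L + chain_id)
  state <- .init_state(dat)
  cache <- .make_cache(dat, state)
  up <- .newton_x(dat, state, cache)
  state <- up$state; cache <- up$cache
  if (!is.finite(cache$ll))
    stop("non-finite log-likelihood at initialization (data terms)")
  if (!is.finite(cache$lp_x))
    stop("non-finite log-prior at initialization (latent field block)")
  ad <- .shape_adapt_init(length(state$zeta))
  n_iter <- fit_cfg$warmup + n_keep * fit_cfg$thin
  d <- dat$layout$d
  X <- matrix(NA_real_, n_keep, d)
  SIG <- matrix(NA_real_, n_keep, length(state$sig),
                dimnames = list(NULL, names(state$sig)))
  ZETA <- matrix(NA_real_, n_keep, length(state$zeta))
  acc_x <- 0L; kept <- 0L
  for (it in seq_len(n_iter)) {
    up <- .update_x(dat, state, cache)
    state <- up$state; cache <- up$cache
    if (up$acc) acc_x <- acc_x + 1L
    up <- .update_hier_sds(dat, state, cache)
    state <- up$state; cache <- up$cache
    up <- .update_noise_sds(dat, state, cache)
    state <- up$state; cache <- up$cache
    up <- .update_shape(dat, state, cache, ad,
                        adapt = it <= fit_cfg$warmup)
    state <- up$state; cache <- up$cache; ad <- up$ad
    if (it > fit_cfg$warmup &&
        (it - fit_cfg$warmup) %% fit_cfg$thin == 0) {
      kept <- kept + 1L
      X[kept, ] <- state$x
      SIG[kept, ] <- state$sig
      ZETA[kept, ] <- state$zeta
    }
  }
  list(x = X, sig = SIG, zeta = ZETA, accept_x = acc_x / n_iter,
       shape_scale = ad$scale)
}

#' Fit the hierarchical haemoglobin model by MCMC
#'
#' Metropolis-within-Gibbs sampler: the latent Gaussian field (intercepts,
#' slopes, RW2 coefficients, covariate effects, pregnancy offsets, survey
#' offsets) is updated in one block with a Gaussian proposal built from a
#' local quadratic (Taylor) expansion of the non-Gaussian likelihood terms,
#' accepted by Metropolis-Hastings; hierarchy and noise sds are updated by
#' univariate log-scale random walks; the mixture shape is updated in three
#' adaptive random-walk sub-blocks (adaptation during warmup only). Chains
#' run sequentially with seeds derived from `fit_cfg$seed`; draws are
#' pooled across chains after warmup and thinning and trimmed to exactly
#' `target_retained`.
#'
#' @param dat an `hb_model_data` from [prepare_model_data()].
#' @param fit_cfg a [fit_config()].
#' @return an object of class `hb_fit` with elements `dat`, `draws`
#'   (matrices `x`, `sig`, `zeta`, per-draw mixture shape matrices, chain
#'   ids), and `meta` (config, acceptance rates, runtime).
#' @export
fit_hb_model <- function(dat, fit_cfg = fit_config()) {
  t0 <- proc.time()[["elapsed"]]
  per_chain <- ceiling(fit_cfg$target_retained / fit_cfg$chains)
  res <- lapply(seq_len(fit_cfg$chains), function(ch)
    .run_chain(dat, fit_cfg, ch, per_chain))
  X <- do.call(rbind, lapply(res, `[[`, "x"))
  SIG <- do.call(rbind, lapply(res, `[[`, "sig"))
  ZETA <- do.call(rbind, lapply(res, `[[`, "zeta"))
  chain <- rep(seq_len(fit_cfg$chains), each = per_chain)
  keep <- seq_len(fit_cfg$target_retained)
  X <- X[keep, , drop = FALSE]; SIG <- SIG[keep, , drop = FALSE]
  ZETA <- ZETA[keep, , drop = FALSE]; chain <- chain[keep]
  K <- dat$cfg$K
  S <- nrow(X)
  W <- O <- Tau <- matrix(NA_real_, S, K)
  for (s in seq_len(S)) {
    sh <- shape_from_zeta(ZETA[s, ], K)
    W[s, ] <- sh$weights; O[s, ] <- sh$offsets; Tau[s, ] <- sh$sds
  }
  structure(list(
    dat = dat,
    draws = list(x = X, sig = SIG, zeta = ZETA, chain = chain,
                 shape_w = W, shape_o = O, shape_t = Tau),
    meta = list(fit_cfg = fit_cfg,
                accept_x = vapply(res, `[[`, numeric(1), "accept_x"),
                runtime_s = proc.time()[["elapsed"]] - t0)),
    class = "hb_fit")
}

#' @export
print.hb_fit <- function(x, ...) {
  cat("Hierarchical haemoglobin model fit (", x$dat$family, ")\n", sep = "")
  cat("  retained draws: ", nrow(x$draws$x), " across ",
      x$meta$fit_cfg$chains, " chain(s)\n", sep = "")
  cat("  latent-field acceptance: ",
      paste(round(x$meta$accept_x, 2), collapse = ", "), "\n", sep = "")
  cat("  runtime: ", round(x$meta$runtime_s, 1), " s\n", sep = "")
  invisible(x)
}

# ---- convergence diagnostics -----------------------------------------

#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half and the usual between/within variance ratio
#' is computed over the resulting sequences.
#' @param v numeric vector of draws (all chains concatenated).
#' @param chain integer chain id per draw.
#' @return R-hat (NA for a single sequence or zero-variance draws).
#' @export
split_rhat <- function(v, chain) {
  seqs <- list()
  for (ch in unique(chain)) {
    vc <- v[chain == ch]
    h <- floor(length(vc) / 2)
    if (h < 2) return(NA_real_)
    seqs <- c(seqs, list(vc[seq_len(h)], vc[h + seq_len(h)]))
  }
  m <- length(seqs); n <- length(seqs[[1]])
  if (stats::var(v) == 0) return(NA_real_)
  means <- vapply(seqs, mean, numeric(1))
  vars <- vapply(seqs, stats::var, numeric(1))
  B <- n * stats::var(means)
  Wv <- mean(vars)
  if (Wv == 0) return(NA_real_)
  sqrt(((n - 1) / n * Wv + B / n) / Wv)
}

#' Effective sample size (initial positive-sequence estimator)
#' @inheritParams split_rhat
#' @return estimated effective sample size.
#' @export
ess_basic <- function(v, chain) {
  ess <- 0
  for (ch in unique(chain)) {
    vc <- v[chain == ch]
    n <- length(vc)
    if (stats::var(vc) == 0) { ess <- ess + n; next }
    ac <- stats::acf(vc, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
    s <- 0
    for (k in seq_along(ac)) {
      if (ac[k] < 0) break
      s <- s + ac[k]
    }
    ess <- ess + n / (1 + 2 * s)
  }
  ess
}

#' Convergence diagnostics for a fitted model
#'
#' Per-parameter split R-hat and effective sample size for every scalar
#' parameter (latent field, sd parameters, mixture-shape parameters), with
#' an overall pass flag at the documented thresholds.
#'
#' @param fit an `hb_fit`.
#' @param rhat_max R-hat threshold (default 1.05).
#' @param ess_min effective-sample-size threshold (default 100).
#' @return data frame (`parameter`, `rhat`, `ess`) with attribute `"pass"`;
#'   R-hat is omitted (NA, with a warning) for single-chain fits.
#' @export
fit_diagnostics <- function(fit, rhat_max = 1.05, ess_min = 100) {
  st <- fit$dat$layout
  M <- cbind(fit$draws$x, fit$draws$sig, fit$draws$zeta)
  colnames(M) <- c(paste0("x", seq_len(st$d)), colnames(fit$draws$sig),
                   paste0("zeta", seq_len(ncol(fit$draws$zeta))))
  chain <- fit$draws$chain
  single <- length(unique(chain)) < 2
  if (single) warning("single chain: R-hat omitted")
  rh <- if (single) rep(NA_real_, ncol(M)) else
    apply(M, 2, split_rhat, chain = chain)
  es <- apply(M, 2, ess_basic, chain = chain)
  out <- data.frame(parameter = colnames(M), rhat = rh, ess = es,
                    stringsAsFactors = FALSE)
  attr(out, "pass") <- all(is.na(out$rhat) | out$rhat <= rhat_max) &&
    all(out$ess >= ess_min | apply(M, 2, stats::var) == 0)
  out
}

#' Posterior predictive check for summary observations
#'
#' For each summary mean observation, draws from the posterior predictive
#' distribution (per retained draw: the linear predictor plus noise at the
#' observation's total variance), the central 95\% predictive interval, and
#' whether the observed value falls inside. Aggregate coverage is attached
#' as an attribute.
#'
#' @param fit an `hb_fit`.
#' @return data frame with one row per summary mean observation (`y`,
#'   `pred_lo`, `pred_hi`, `inside`), attribute `"coverage"`.
#' @export
posterior_predictive_check <- function(fit) {
  dat <- fit$dat
  if (length(dat$lin) == 0)
    return(structure(data.frame(), coverage = NA_real_))
  S <- nrow(fit$draws$x)
  n <- length(dat$lin)
  ETA <- as.matrix(fit$draws$x %*% Matrix::t(dat$ROWS[dat$lin_rows, ,
                                                      drop = FALSE]))
  out <- data.frame(y = dat$lin_y, pred_lo = NA_real_, pred_hi = NA_real_,
                    inside = NA)
  for (j in seq_len(n)) {
    tm <- dat$lin[[j]]
    v <- tm$base_var + fit$draws$sig[, "s_ns"]^2 +
      (if (tm$sub) fit$draws$sig[, "s_sub"]^2 else 0) +
      (if (tm$mis) fit$draws$sig[, "s_age"]^2 else 0)
    pred <- ETA[, j] + stats::rnorm(S, 0, sqrt(v))
    q <- stats::quantile(pred, c(0.025, 0.975), names = FALSE, type = 7)
    out$pred_lo[j] <- q[1]; out$pred_hi[j] <- q[2]
    out$inside[j] <- out$y[j] >= q[1] && out$y[j] <= q[2]
  }
  attr(out, "coverage") <- mean(out$inside)
  out
}

#' Persist retained draws to a directory
#'
#' Writes the retained draws in a documented tabular format: one CSV per
#' parameter block (`draws_x.csv`, `draws_sig.csv`, `draws_zeta.csv`, plus
#' `draws_chain.csv`) and a `meta.json` sidecar recording the family,
#' chain count, seed, warmup, and acceptance rates.
#'
#' @param fit an `hb_fit`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_draws <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(fit$draws$x),
                   file.path(dir, "draws_x.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(fit$draws$sig),
                   file.path(dir, "draws_sig.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(fit$draws$zeta),
                   file.path(dir, "draws_zeta.csv"), row.names = FALSE)
  utils::write.csv(data.frame(chain = fit$draws$chain),
                   file.path(dir, "draws_chain.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(family = fit$dat$family,
         chains = fit$meta$fit_cfg$chains,
         warmup = fit$meta$fit_cfg$warmup,
         target_retained = fit$meta$fit_cfg$target_retained,
         thin = fit$meta$fit_cfg$thin,
         seed = fit$meta$fit_cfg$seed,
         accept_x = fit$meta$accept_x),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Read persisted draws back into a fit object
#'
#' @param dir directory written by [write_draws()].
#' @param dat the `hb_model_data` the fit was produced from.
#' @return an `hb_fit`.
#' @export
read_draws <- function(dir, dat) {
  X <- as.matrix(utils::read.csv(file.path(dir, "draws_x.csv")))
  SIG <- as.matrix(utils::read.csv(file.path(dir, "draws_sig.csv")))
  ZETA <- as.matrix(utils::read.csv(file.path(dir, "draws_zeta.csv")))
  chain <- utils::read.csv(file.path(dir, "draws_chain.csv"))$chain
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  dimnames(X) <- NULL; dimnames(ZETA) <- NULL
  K <- dat$cfg$K
  S <- nrow(X)
  W <- O <- Tau <- matrix(NA_real_, S, K)
  for (s in seq_len(S)) {
    sh <- shape_from_zeta(ZETA[s, ], K)
    W[s, ] <- sh$weights; O[s, ] <- sh$offsets; Tau[s, ] <- sh$sds
  }
  structure(list(
    dat = dat,
    draws = list(x = X, sig = SIG, zeta = ZETA, chain = chain,
                 shape_w = W, shape_o = O, shape_t = Tau),
    meta = list(fit_cfg = fit_config(chains = meta$chains,
                                     warmup = meta$warmup,
                                     target_retained = meta$target_retained,
                                     thin = meta$thin, seed = meta$seed),
                accept_x = meta$accept_x, runtime_s = NA_real_)),
    class = "hb_fit")
}
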