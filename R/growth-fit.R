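# Three-level hierarchical Bayesian logistic growth model.
#
# Level 1 (population): means mu of (log r, log Hmax, iD), optionally with a
# linear Amax term on (log r, log Hmax); between-line SDs tau_line.
# Level 2 (line): theta_l ~ N(mu [+ beta * Amax_l], tau_line).
# Level 3 (replicate): deviations delta_rep ~ N(0, tau_rep) on each
# parameter; observed heights ~ N(logistic(t; theta_l + delta_rep),
# sigma_res).
#
# Inference is single-chain random-walk Metropolis-Hastings. Line and
# replicate blocks are updated jointly across all lines/replicates in one
# vectorised proposal with per-line (per-replicate) accept/reject, which is
# valid because lines are conditionally independent given the
# hyperparameters (and replicates given their line). Population means (and
# beta) are conjugate and drawn by Gibbs; the seven SD parameters use
# scalar random walks on the log scale. Proposal scales adapt toward
# 20-40% acceptance during burn-in only, so retained samples come from a
# fixed kernel.

#' MCMC settings for the growth fitter
#'
#' @param n_iterations Total iterations (single chain).
#' @param n_burnin Discarded burn-in iterations (< `n_iterations`).
#' @param thin Keep 1 retained sample per `thin` post-burn-in iterations.
#' @param seed Integer seed.
#' @param init_scales Optional named list overriding initial proposal
#'   scales (`theta`, `delta`: length-3; `sd`: scalar).
#' @return List of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iterations = 20000, n_burnin = 10000, thin = 5,
                          seed = 1L, init_scales = NULL) {
  sched <- mcmc_schedule(n_iterations, n_burnin, thin)  # validates
  structure(
    list(n_iterations = n_iterations, n_burnin = n_burnin, thin = thin,
         seed = seed, init_scales = init_scales,
         n_retained = sched$n_retained),
    class = "mcmc_settings"
  )
}

#' Fit the hierarchical logistic growth model
#'
#' Fits the three-level model described above to replicate-level height
#' series by Metropolis-Hastings MCMC and returns retained posterior
#' samples for every level. Fit one treatment at a time; block effects are
#' absorbed by the replicate-level deviations.
#'
#' @param obs Tibble with columns `line`, `replicate` (unique per physical
#'   plant), `time_dd`, `height_cm` (>= 0).
#' @param settings An [mcmc_settings()].
#' @param amax Optional tibble `line`, `amax`; when supplied the line-level
#'   means of (log r, log Hmax) gain a linear term `beta * amax`, factoring
#'   genotype-level carbon availability out of the growth parameters. Every
#'   line in `obs` must appear in the table.
#' @return Object of class `growth_fit`: retained samples (`theta`
#'   `n_retained x lines x 3`, `delta` for replicate deviations, `hyper`
#'   for population parameters), acceptance rates, diagnostics, and the
#'   settings echo. Use [tidy()] for per-line FVT summaries and
#'   [credible_envelopes()] for fitted-curve envelopes.
#' @export
fit_hierarchical_growth <- function(obs, settings = mcmc_settings(),
                                    amax = NULL) {
  stopifnot(inherits(settings, "mcmc_settings"))
  need <- c("line", "replicate", "time_dd", "height_cm")
  if (!all(need %in% names(obs))) {
    abort("obs needs columns line, replicate, time_dd, height_cm")
  }
  if (any(obs$height_cm < 0)) abort("heights must be non-negative")
  set.seed(as.integer(settings$seed))

  lines <- sort(unique(obs$line))
  reps <- sort(unique(obs$replicate))
  L <- length(lines); R <- length(reps)
  li <- match(obs$line, lines)
  ri <- match(obs$replicate, reps)
  rep_line <- li[match(reps, obs$replicate)]  # line index of each replicate
  t_obs <- obs$time_dd; h_obs <- obs$height_cm
  n_obs <- length(h_obs)

  use_amax <- !is.null(amax)
  if (use_amax) {
    av <- amax$amax[match(lines, amax$line)]
    if (anyNA(av)) {
      abort(paste("amax table missing lines:",
                  paste(lines[is.na(av)], collapse = ", ")))
    }
  } else av <- NULL

  flat_lines <- tapply(h_obs, li, function(h) diff(range(h)) == 0)
  diagnostics <- list(constant_height_lines = lines[which(flat_lines)])

  ## --- initialisation from per-line curve heuristics -------------------
  init_line <- function(idx) {
    tt <- t_obs[idx]; hh <- h_obs[idx]
    hmax0 <- max(hh) * 1.05 + 1e-6
    id0 <- tt[which.min(abs(hh - hmax0 / 2))]
    sl <- if (length(tt) > 1) max(diff(hh) / diff(tt), 1e-4) else 1e-2
    r0 <- min(max(4 * sl / hmax0, 1e-4), 1)
    c(log(r0), log(hmax0), id0)
  }
  theta <- t(vapply(split(seq_len(n_obs), li), init_line, numeric(3)))
  colnames(theta) <- c("log_r", "log_hmax", "id")
  delta <- matrix(0, R, 3)
  mu <- colMeans(theta)
  beta <- c(0, 0)
  tau_line <- pmax(apply(theta, 2, sd), c(0.02, 0.02, 5))
  tau_rep <- c(0.05, 0.05, 5)
  fitted_h <- function(theta, delta) {
    th <- theta[li, ] + delta[ri, ]
    logistic_height(t_obs, exp(th[, 1]), exp(th[, 2]), th[, 3])
  }
  f <- fitted_h(theta, delta)
  sigma <- max(sd(h_obs - f), 0.05)

  ## --- priors (weakly informative, data-scaled) ------------------------
  mu_prior_mean <- mu
  mu_prior_sd <- c(3, 3, max(100, 2 * sd(t_obs)))
  beta_prior_sd <- 3
  hn_line <- c(1, 1, max(50, sd(t_obs)))
  hn_rep <- c(0.5, 0.5, max(25, sd(t_obs) / 2))
  hn_sigma <- max(sd(h_obs), 1)

  ## --- proposal scales -------------------------------------------------
  sc <- list(theta = c(0.02, 0.02, 5), delta = c(0.02, 0.02, 4),
             shift = c(0.02, 0.02, 5), sd = rep(0.2, 7))
  if (!is.null(settings$init_scales)) {
    sc <- modifyList(sc, settings$init_scales)
  }

  n_iter <- settings$n_iterations
  n_burn <- settings$n_burnin
  thin <- settings$thin
  n_ret <- settings$n_retained

  keep_theta <- array(NA_real_, c(n_ret, L, 3),
                      dimnames = list(NULL, lines, colnames(theta)))
  keep_delta <- array(NA_real_, c(n_ret, R, 3),
                      dimnames = list(NULL, reps, colnames(theta)))
  hyper_names <- c("mu_log_r", "mu_log_hmax", "mu_id",
                   "beta_log_r", "beta_log_hmax",
                   "tau_line_log_r", "tau_line_log_hmax", "tau_line_id",
                   "tau_rep_log_r", "tau_rep_log_hmax", "tau_rep_id",
                   "sigma_res")
  keep_hyper <- matrix(NA_real_, n_ret, length(hyper_names),
                       dimnames = list(NULL, hyper_names))
  acc <- c(theta = 0, delta = 0, shift = 0, sd = 0)
  acc_n <- acc; win <- acc; win_n <- acc

  ## group-sum indicator matrices (dense; L and R are modest) replace
  ## repeated rowsum() calls in the hot loop
  Mli <- matrix(0, L, n_obs); Mli[cbind(li, seq_len(n_obs))] <- 1
  Mri <- matrix(0, R, n_obs); Mri[cbind(ri, seq_len(n_obs))] <- 1
  Mlr <- matrix(0, L, R); Mlr[cbind(rep_line, seq_len(R))] <- 1
  ldn <- function(x, m, s) -0.5 * ((x - m) / s)^2 - log(s)  # constant dropped
  line_prior <- function(theta) {
    m1 <- mu[1]; m2 <- mu[2]
    if (use_amax) { m1 <- m1 + beta[1] * av; m2 <- m2 + beta[2] * av }
    ldn(theta[, 1], m1, tau_line[1]) + ldn(theta[, 2], m2, tau_line[2]) +
      ldn(theta[, 3], mu[3], tau_line[3])
  }
  rep_prior <- function(delta) {
    ldn(delta[, 1], 0, tau_rep[1]) + ldn(delta[, 2], 0, tau_rep[2]) +
      ldn(delta[, 3], 0, tau_rep[3])
  }
  ll_line_of <- function(f) as.numeric(Mli %*% ldn(h_obs, f, sigma))
  ll_rep_of <- function(f) as.numeric(Mri %*% ldn(h_obs, f, sigma))

  ll_line <- ll_line_of(f)
  ll_rep <- ll_rep_of(f)
  k <- 0L
  for (it in seq_len(n_iter)) {
    ## line-level block
    prop <- theta + matrix(rnorm(L * 3) * rep(sc$theta, each = L), L)
    f_prop <- fitted_h(prop, delta)
    ll_prop <- ll_line_of(f_prop)
    lr <- (ll_prop + line_prior(prop)) - (ll_line + line_prior(theta))
    take <- log(runif(L)) < lr
    if (any(take)) {
      theta[take, ] <- prop[take, ]
      sel <- take[li]
      f[sel] <- f_prop[sel]
      ll_line[take] <- ll_prop[take]
      ll_rep <- ll_rep_of(f)
    }
    rate <- sum(take) / L
    win["theta"] <- win["theta"] + rate; win_n["theta"] <- win_n["theta"] + 1
    if (it > n_burn) { acc["theta"] <- acc["theta"] + rate; acc_n["theta"] <- acc_n["theta"] + 1 }

    ## replicate-level block
    propd <- delta + matrix(rnorm(R * 3) * rep(sc$delta, each = R), R)
    f_prop <- fitted_h(theta, propd)
    llr_prop <- ll_rep_of(f_prop)
    lr <- (llr_prop + rep_prior(propd)) - (ll_rep + rep_prior(delta))
    take <- log(runif(R)) < lr
    if (any(take)) {
      delta[take, ] <- propd[take, ]
      sel <- take[ri]
      f[sel] <- f_prop[sel]
      ll_rep[take] <- llr_prop[take]
      ll_line <- ll_line_of(f)
    }
    rate <- sum(take) / R
    win["delta"] <- win["delta"] + rate; win_n["delta"] <- win_n["delta"] + 1
    if (it > n_burn) { acc["delta"] <- acc["delta"] + rate; acc_n["delta"] <- acc_n["delta"] + 1 }

    ## translation move along the line/replicate degeneracy: shift a
    ## line's parameters and subtract the shift from its replicates'
    ## deviations; the likelihood is untouched (theta + delta invariant),
    ## so acceptance depends on the priors alone. Without this move the
    ## line level mixes poorly and line effects leak into tau_rep.
    e <- matrix(rnorm(L * 3) * rep(sc$shift, each = L), L)
    th_prop <- theta + e
    de_prop <- delta - e[rep_line, , drop = FALSE]
    pr_line <- line_prior(th_prop) - line_prior(theta)
    pr_rep <- as.numeric(Mlr %*% (rep_prior(de_prop) - rep_prior(delta)))
    take <- log(runif(L)) < (pr_line + pr_rep)
    if (any(take)) {
      theta[take, ] <- th_prop[take, ]
      sel <- take[rep_line]
      delta[sel, ] <- de_prop[sel, ]
    }
    rate <- sum(take) / L
    win["shift"] <- win["shift"] + rate; win_n["shift"] <- win_n["shift"] + 1
    if (it > n_burn) { acc["shift"] <- acc["shift"] + rate; acc_n["shift"] <- acc_n["shift"] + 1 }

    ## population means (and Amax slopes): conjugate Gibbs draw
    for (j in 1:3) {
      if (use_amax && j <= 2) {
        # 2-parameter Bayesian regression with known variance, 2x2 inverse
        t2 <- tau_line[j]^2
        a11 <- L / t2 + 1 / mu_prior_sd[j]^2
        a12 <- sum(av) / t2
        a22 <- sum(av * av) / t2 + 1 / beta_prior_sd^2
        b1 <- sum(theta[, j]) / t2 + mu_prior_mean[j] / mu_prior_sd[j]^2
        b2 <- sum(av * theta[, j]) / t2
        det <- a11 * a22 - a12 * a12
        m1 <- (a22 * b1 - a12 * b2) / det
        m2 <- (a11 * b2 - a12 * b1) / det
        # draw via the Cholesky of the 2x2 covariance [a22,-a12;-a12,a11]/det
        c11 <- sqrt(a22 / det)
        c21 <- -a12 / det / c11
        c22 <- sqrt(a11 / det - c21 * c21)
        z <- rnorm(2)
        mu[j] <- m1 + c11 * z[1]
        beta[j] <- m2 + c21 * z[1] + c22 * z[2]
      } else {
        v <- 1 / (L / tau_line[j]^2 + 1 / mu_prior_sd[j]^2)
        m <- v * (sum(theta[, j]) / tau_line[j]^2 +
                    mu_prior_mean[j] / mu_prior_sd[j]^2)
        mu[j] <- rnorm(1, m, sqrt(v))
      }
    }

    ## SD parameters: scalar log-scale random walks (half-Normal priors,
    ## log-scale Jacobian included)
    sd_take <- 0
    for (j in 1:3) {  # tau_line
      cur <- tau_line[j]; prop_s <- cur * exp(rnorm(1, 0, sc$sd[j]))
      m <- mu[j] + if (use_amax && j <= 2) beta[j] * av else 0
      lp_cur <- sum(ldn(theta[, j], m, cur)) -
        0.5 * (cur / hn_line[j])^2 + log(cur)
      lp_prop <- sum(ldn(theta[, j], m, prop_s)) -
        0.5 * (prop_s / hn_line[j])^2 + log(prop_s)
      if (log(runif(1)) < lp_prop - lp_cur) { tau_line[j] <- prop_s; sd_take <- sd_take + 1 }
    }
    for (j in 1:3) {  # tau_rep
      cur <- tau_rep[j]; prop_s <- cur * exp(rnorm(1, 0, sc$sd[3 + j]))
      lp_cur <- sum(ldn(delta[, j], 0, cur)) -
        0.5 * (cur / hn_rep[j])^2 + log(cur)
      lp_prop <- sum(ldn(delta[, j], 0, prop_s)) -
        0.5 * (prop_s / hn_rep[j])^2 + log(prop_s)
      if (log(runif(1)) < lp_prop - lp_cur) { tau_rep[j] <- prop_s; sd_take <- sd_take + 1 }
    }
    { # residual SD
      cur <- sigma; prop_s <- cur * exp(rnorm(1, 0, sc$sd[7]))
      res2 <- sum((h_obs - f)^2)
      lp_cur <- -n_obs * log(cur) - res2 / (2 * cur^2) -
        0.5 * (cur / hn_sigma)^2 + log(cur)
      lp_prop <- -n_obs * log(prop_s) - res2 / (2 * prop_s^2) -
        0.5 * (prop_s / hn_sigma)^2 + log(prop_s)
      if (log(runif(1)) < lp_prop - lp_cur) {
        sigma <- prop_s; sd_take <- sd_take + 1
        ll_line <- ll_line_of(f); ll_rep <- ll_rep_of(f)
      }
    }
    win["sd"] <- win["sd"] + sd_take / 7; win_n["sd"] <- win_n["sd"] + 1
    if (it > n_burn) { acc["sd"] <- acc["sd"] + sd_take / 7; acc_n["sd"] <- acc_n["sd"] + 1 }

    ## burn-in adaptation toward 20-40% acceptance, frozen afterwards
    if (it <= n_burn && it %% 50 == 0) {
      for (b in names(sc)) {
        rate <- win[b] / win_n[b]
        adj <- exp(0.6 * (rate - 0.3))
        sc[[b]] <- pmin(pmax(sc[[b]] * adj, 1e-5), 100)
      }
      win[] <- 0; win_n[] <- 0
    }

    if (it > n_burn && (it - n_burn) %% thin == 0 && k < n_ret) {
      k <- k + 1L
      keep_theta[k, , ] <- theta
      keep_delta[k, , ] <- delta
      keep_hyper[k, ] <- c(mu, beta, tau_line, tau_rep, sigma)
    }
  }

  structure(
    list(samples = list(theta = keep_theta, delta = keep_delta,
                        hyper = keep_hyper),
         lines = lines, replicates = reps, rep_line = rep_line,
         acceptance = acc / pmax(acc_n, 1),
         settings = settings, amax = if (use_amax) av else NULL,
         diagnostics = diagnostics,
         data = tibble(line = obs$line, replicate = obs$replicate,
                       time_dd = t_obs, height_cm = h_obs)),
    class = "growth_fit"
  )
}

#' Per-line FVT posterior summaries
#'
#' One row per line and FVT parameter (`r`, `hmax`, `id`, `d`), with the
#' posterior median and equal-tailed credible bounds. `d` is computed per
#' retained sample as `id + ln(19)/r` and then summarised, so its
#' uncertainty propagates from the joint posterior.
#'
#' @param x A `growth_fit`.
#' @param level Credible level (default 0.95).
#' @param ... Unused.
#' @return Tibble: `line`, `param`, `estimate`, `conf.low`, `conf.high`.
#' @exportS3Method
tidy.growth_fit <- function(x, level = 0.95, ...) {
  th <- x$samples$theta
  a <- (1 - level) / 2
  per_line <- function(i) {
    r <- exp(th[, i, 1]); hmax <- exp(th[, i, 2]); id <- th[, i, 3]
    d <- id + log(19) / r
    purrr::map_dfr(list(r = r, hmax = hmax, id = id, d = d), function(v) {
      tibble(estimate = median(v),
             conf.low = unname(quantile(v, a)),
             conf.high = unname(quantile(v, 1 - a)))
    }, .id = "param")
  }
  purrr::map_dfr(seq_along(x$lines), per_line) %>%
    mutate(line = rep(x$lines, each = 4), .before = 1)
}

#' One-row fit summary
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return Tibble with retained-sample count, block acceptance rates, and
#'   the posterior median residual SD.
#' @exportS3Method
glance.growth_fit <- function(x, ...) {
  tibble(
    n_lines = length(x$lines),
    n_replicates = length(x$replicates),
    n_retained = dim(x$samples$theta)[1],
    accept_line = unname(x$acceptance["theta"]),
    accept_replicate = unname(x$acceptance["delta"]),
    accept_shift = unname(x$acceptance["shift"]),
    accept_sd = unname(x$acceptance["sd"]),
    sigma_res = median(x$samples$hyper[, "sigma_res"])
  )
}

#' Trace and autocorrelation diagnostics
#'
#' Retained-sample traces and lag autocorrelations for the population-level
#' parameters, for eyeballing mixing the way single-chain MH runs are
#' usually checked.
#'
#' @param x A `growth_fit`.
#' @param lags Autocorrelation lags to report.
#' @return Tibble: `param`, `lag`, `acf`, plus effective sample size (from
#'   the summed positive-lag autocorrelation).
#' @export
mcmc_diagnostics <- function(x, lags = c(1, 5, 10, 20)) {
  h <- x$samples$hyper
  purrr::map_dfr(colnames(h), function(p) {
    v <- h[, p]
    if (sd(v) == 0) return(tibble(param = p, lag = lags, acf = 0, ess = nrow(h)))
    ac <- stats::acf(v, lag.max = max(lags), plot = FALSE)$acf[, 1, 1]
    pos <- ac[-1][ac[-1] > 0]
    tibble(param = p, lag = lags, acf = ac[lags + 1],
           ess = nrow(h) / (1 + 2 * sum(pos)))
  })
}

#' Credible envelopes for a line's growth curve
#'
#' Two pointwise envelopes over a time grid: the model envelope (quantiles
#' of the line-level logistic curve over retained samples) and the
#' predictive envelope (the same curves with a fresh replicate deviation
#' and measurement noise added per sample, i.e. where future observations
#' from the same environment are expected). The predictive envelope is
#' forced to contain the model envelope pointwise, removing Monte-Carlo
#' quantile crossing at finite sample counts.
#'
#' @param fit A `growth_fit`.
#' @param line Line id present in the fit.
#' @param grid Time grid in DD (default: 100 points over the observed span).
#' @param level Credible level in (0, 1), default 0.95.
#' @return Tibble of class `credible_envelope`: `time_dd`, `model_lo`,
#'   `model_hi`, `pred_lo`, `pred_hi`, `median`.
#' @export
credible_envelopes <- function(fit, line, grid = NULL, level = 0.95) {
  if (level <= 0 || level >= 1) abort("level must be in (0, 1)")
  i <- match(line, fit$lines)
  if (is.na(i)) abort(sprintf("line %s not in fit", line))
  if (is.null(grid)) {
    rng <- range(fit$data$time_dd)
    grid <- seq(rng[1], rng[2], length.out = 100)
  }
  th <- fit$samples$theta
  hy <- fit$samples$hyper
  S <- dim(th)[1]
  a <- (1 - level) / 2
  curves <- vapply(seq_len(S), function(s) {
    logistic_height(grid, exp(th[s, i, 1]), exp(th[s, i, 2]), th[s, i, 3])
  }, numeric(length(grid)))                      # grid x S
  dev <- cbind(rnorm(S, 0, hy[, "tau_rep_log_r"]),
               rnorm(S, 0, hy[, "tau_rep_log_hmax"]),
               rnorm(S, 0, hy[, "tau_rep_id"]))
  pred <- vapply(seq_len(S), function(s) {
    logistic_height(grid, exp(th[s, i, 1] + dev[s, 1]),
                    exp(th[s, i, 2] + dev[s, 2]),
                    th[s, i, 3] + dev[s, 3]) +
      rnorm(length(grid), 0, hy[s, "sigma_res"])
  }, numeric(length(grid)))
  qs <- function(m, p) apply(m, 1, quantile, probs = p)
  out <- tibble(
    time_dd = grid,
    median = qs(curves, 0.5),
    model_lo = qs(curves, a), model_hi = qs(curves, 1 - a),
    pred_lo = qs(pred, a), pred_hi = qs(pred, 1 - a)
  ) %>%
    mutate(pred_lo = pmin(.data$pred_lo, .data$model_lo),
           pred_hi = pmax(.data$pred_hi, .data$model_hi))
  attr(out, "line") <- line
  attr(out, "level") <- level
  class(out) <- c("credible_envelope", class(out))
  out
}
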