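# The logistic growth model on a thermal-time axis, and the derived
# function-valued traits (FVT) it is summarised by.

#' Logistic height curve
#'
#' Height follows dH/dt = r H (Hmax - H) / Hmax on a degree-day axis, whose
#' solution is the standard logistic H(t) = Hmax / (1 + exp(-r (t - iD)))
#' with inflection point iD (where H = Hmax/2).
#'
#' @param t Time in degree days (vectorised).
#' @param r Growth rate (1/DD, > 0).
#' @param hmax Asymptotic height (cm, > 0).
#' @param id Inflection time (DD).
#' @return Heights in cm.
#' @export
logistic_height <- function(t, r, hmax, id) {
  hmax / (1 + exp(-r * (t - id)))
}

#' Derive function-valued traits from logistic parameters
#'
#' The duration of growth `d` is the time at which the curve reaches 95% of
#' its asymptote: solving Hmax/(1+exp(-r(d-iD))) = 0.95 Hmax gives
#' d = iD + ln(19)/r. `iD` is passed through as the inflection time (the
#' transition from accelerating to decelerating growth).
#'
#' @param r,hmax,id Logistic parameters (vectorised; `r > 0`, `hmax > 0`).
#' @return Tibble with columns `r`, `hmax`, `id`, `d`.
#' @export
derive_fvt <- function(r, hmax, id) {
  if (any(r <= 0) || any(hmax <= 0)) abort("r and hmax must be positive")
  r <- unname(r); hmax <- unname(hmax); id <- unname(id)
  tibble(r = r, hmax = hmax, id = id, d = id + log(19) / r)
}

#' Degree days from a temperature series
#'
#' Accumulates thermal time above a base temperature. The default base,
#' 0.96 degrees C, is the Brassica rapa-specific value. With
#' `resolution = "daily"` each day contributes max(0, daily mean - base);
#' with `"hourly"` each hourly reading contributes max(0, T - base)/24, so
#' days whose mean is above base but with sub-base hours accumulate slightly
#' differently between the two modes.
#'
#' @param temps Tibble with columns `day` (integer or date-like, ordered),
#'   `hour` (0-23; may be absent for daily data) and `temp_C`.
#' @param base Base temperature in degrees C (default 0.96).
#' @param resolution `"daily"` (default) or `"hourly"`.
#' @return Tibble with `day`, `dd` (that day's increment) and `cum_dd`.
#' @export
degree_days <- function(temps, base = 0.96, resolution = c("daily", "hourly")) {
  resolution <- match.arg(resolution)
  if (nrow(temps) == 0) abort("empty temperature series")
  ord <- if ("hour" %in% names(temps)) {
    order(temps$day, temps$hour)
  } else {
    order(temps$day)
  }
  if (!identical(ord, seq_len(nrow(temps)))) {
    abort("temperature series must be in increasing time order")
  }
  daily <- if (resolution == "daily" || !("hour" %in% names(temps))) {
    temps %>%
      group_by(day = .data$day) %>%
      summarise(dd = max(0, mean(.data$temp_C) - base), .groups = "drop")
  } else {
    temps %>%
      group_by(day = .data$day) %>%
      summarise(dd = sum(pmax(0, .data$temp_C - base)) / 24, .groups = "drop")
  }
  daily %>% mutate(cum_dd = cumsum(.data$dd))
}

#' MCMC retention schedule
#'
#' Given total iterations, burn-in and thinning interval, returns the number
#' of post-burn-in iterations and the number of retained samples,
#' `floor((n_iterations - n_burnin) / thin)`. The single-chain schedule of
#' 500,000 iterations with 440,000 burn-in thinned 1-in-20 retains 3,000
#' samples per parameter.
#'
#' @param n_iterations,n_burnin,thin Schedule (burn-in < iterations,
#'   thin >= 1).
#' @return Named list with `n_post_burnin` and `n_retained`.
#' @export
mcmc_schedule <- function(n_iterations, n_burnin, thin = 1L) {
  if (n_burnin >= n_iterations) abort("burn-in must be smaller than n_iterations")
  if (thin < 1) abort("thin must be >= 1")
  post <- n_iterations - n_burnin
  list(n_post_burnin = post, n_retained = floor(post / thin))
}
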