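# Synthetic longitudinal growth studies with known ground truth.
#
# The generator plants a growth architecture -- QTL on the logistic
# parameters, genotype-level correlation among them, an optional Amax
# (carbon availability) covariate, treatment and genotype-by-treatment
# structure -- and emits replicate-level height series the way a field
# experiment would: randomized blocks within treatments, 5-13 measurement
# dates per replicate on a degree-day schedule, Gaussian measurement noise.

#' Specify a growth architecture
#'
#' Describes how line-level logistic parameters (log r, log Hmax, iD) are
#' generated: population means, QTL anchored at markers with additive
#' effects per parameter, a genotype-level residual with a correlation
#' structure, an optional linear Amax coefficient on (log r, log Hmax),
#' replicate-level deviations, and measurement noise. Effects on r and Hmax
#' act on the log scale, so positivity is automatic.
#'
#' @param mean_log_r,mean_log_hmax,mean_id Population means. Defaults give
#'   r ~ 0.02/DD, Hmax ~ 110 cm, iD ~ 600 DD, typical of field-grown
#'   B. rapa on a thermal-time axis.
#' @param qtl Tibble with columns `marker`, `param`
#'   (`"log_r"|"log_hmax"|"id"`), `effect` (additive effect, +1/-1 coding,
#'   so the AA-BB difference is twice the effect). `NULL` for none.
#' @param sd_line Named vector of genotype-level residual SDs for
#'   `log_r`, `log_hmax`, `id`.
#' @param cor_line 3x3 correlation matrix among the genotype-level residuals
#'   (order log_r, log_hmax, id); defaults to a negative r--Hmax/duration
#'   trade-off structure.
#' @param amax_coef Length-2 coefficient of a genotype-level Amax covariate
#'   on (log_r, log_hmax); 0 disables.
#' @param sd_rep Named vector of replicate-level deviation SDs.
#' @param sd_noise Measurement noise SD in cm.
#' @param treatment_shift Named list: per-parameter additive shift applied
#'   in the second treatment (plasticity main effect).
#' @param sd_gxt Named vector of genotype-by-treatment interaction SDs
#'   (genetic variation in plasticity); 0 disables.
#' @param sd_block Block effect SD (cm, additive on height).
#' @return A list of class `growth_architecture`.
#' @export
growth_architecture <- function(mean_log_r = log(0.02),
                                mean_log_hmax = log(110),
                                mean_id = 600,
                                qtl = NULL,
                                sd_line = c(log_r = 0.15, log_hmax = 0.15, id = 40),
                                cor_line = default_cor_line(),
                                amax_coef = c(0, 0),
                                sd_rep = c(log_r = 0.05, log_hmax = 0.05, id = 10),
                                sd_noise = 1.5,
                                treatment_shift = list(log_r = 0, log_hmax = 0, id = 0),
                                sd_gxt = c(log_r = 0, log_hmax = 0, id = 0),
                                sd_block = 1) {
  structure(
    list(mean = c(log_r = mean_log_r, log_hmax = mean_log_hmax, id = mean_id),
         qtl = qtl, sd_line = sd_line, cor_line = cor_line,
         amax_coef = amax_coef, sd_rep = sd_rep, sd_noise = sd_noise,
         treatment_shift = treatment_shift, sd_gxt = sd_gxt,
         sd_block = sd_block),
    class = "growth_architecture"
  )
}

default_cor_line <- function() {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- -0.3  # faster growers plateau lower
  m
}

rmvn <- function(n, sd, corr) {
  z <- matrix(rnorm(n * length(sd)), n)
  L <- chol(corr)
  sweep(z %*% L, 2, sd, `*`)
}

#' Simulate a longitudinal growth study
#'
#' Generates replicate-level height observations for every line in
#' `genotypes` under the supplied architecture and design, plus the true
#' line-by-treatment parameter table for recovery tests.
#'
#' @param genotypes Character genotype matrix from [simulate_rils()].
#' @param arch A [growth_architecture()].
#' @param map Genetic map (needed when `arch$qtl` anchors effects at
#'   markers; may be `NULL` otherwise).
#' @param treatments Character vector of treatment labels (default
#'   `c("UN", "CR")`).
#' @param blocks_per_treatment Number of randomized blocks per treatment.
#' @param reps_per_line Replicates per line per treatment, assigned to
#'   blocks round-robin.
#' @param schedule Measurement times in DD (increasing, non-negative);
#'   lengths outside 5-13 are allowed but flagged with a warning, since the
#'   design this emulates used between 5 and 13 dates per replicate.
#' @param amax Optional tibble `line`, `amax` of genotype-level covariate
#'   values; generated N(0,1) internally when `arch$amax_coef` is nonzero
#'   and `amax` is `NULL`.
#' @param seed Integer seed.
#' @return List with `observations` (tibble: line, treatment, block,
#'   replicate, time_dd, height_cm), `truth` (tibble: line, treatment, r,
#'   hmax, id, d), and `amax` (tibble or NULL).
#' @export
simulate_growth_study <- function(genotypes, arch = growth_architecture(),
                                  map = NULL,
                                  treatments = c("UN", "CR"),
                                  blocks_per_treatment = 8,
                                  reps_per_line = 3,
                                  schedule = seq(100, 1300, length.out = 9),
                                  amax = NULL, seed = 1L) {
  stopifnot(inherits(arch, "growth_architecture"))
  if (any(diff(schedule) <= 0) || any(schedule < 0)) {
    abort("schedule must be non-negative and increasing")
  }
  n_t <- length(schedule)
  if (n_t < 5 || n_t > 13) {
    warn(sprintf("schedule has %d measurements; the emulated design used 5-13", n_t))
  }
  set.seed(as.integer(seed))
  lines <- rownames(genotypes)
  n <- length(lines)
  x <- code_genotypes(genotypes)

  # genotype-level parameter construction
  par_names <- c("log_r", "log_hmax", "id")
  base <- matrix(rep(arch$mean, each = n), n,
                 dimnames = list(lines, par_names))
  if (!is.null(arch$qtl)) {
    for (k in seq_len(nrow(arch$qtl))) {
      mk <- arch$qtl$marker[k]
      if (!mk %in% colnames(x)) abort(sprintf("QTL marker %s not in genotypes", mk))
      dos <- x[, mk]
      dos[is.na(dos)] <- 0
      base[, arch$qtl$param[k]] <- base[, arch$qtl$param[k]] +
        arch$qtl$effect[k] * dos
    }
  }
  base <- base + rmvn(n, arch$sd_line, arch$cor_line)
  if (any(arch$amax_coef != 0)) {
    if (is.null(amax)) amax <- tibble(line = lines, amax = rnorm(n))
    av <- amax$amax[match(lines, amax$line)]
    if (anyNA(av)) abort("amax table missing some lines")
    base[, "log_r"] <- base[, "log_r"] + arch$amax_coef[1] * av
    base[, "log_hmax"] <- base[, "log_hmax"] + arch$amax_coef[2] * av
  }

  truth <- list()
  obs <- list()
  for (ti in seq_along(treatments)) {
    tr <- treatments[ti]
    shift <- if (ti == 1) c(0, 0, 0) else unlist(arch$treatment_shift)[par_names]
    gxt <- if (ti == 1) matrix(0, n, 3) else
      sweep(matrix(rnorm(n * 3), n), 2, arch$sd_gxt[par_names], `*`)
    theta <- sweep(base + gxt, 2, shift, `+`)
    truth[[tr]] <- derive_fvt(exp(theta[, "log_r"]), exp(theta[, "log_hmax"]),
                              theta[, "id"]) %>%
      mutate(line = lines, treatment = tr, .before = 1)
    block_eff <- rnorm(blocks_per_treatment, 0, arch$sd_block)
    for (rep_i in seq_len(reps_per_line)) {
      blk <- ((seq_len(n) + rep_i - 2L) %% blocks_per_treatment) + 1L
      dev <- sweep(matrix(rnorm(n * 3), n), 2, arch$sd_rep[par_names], `*`)
      th <- theta + dev
      h <- logistic_height(
        rep(schedule, each = n),
        exp(th[, "log_r"]), exp(th[, "log_hmax"]), th[, "id"]
      )
      h <- h + block_eff[blk] + rnorm(n * n_t, 0, arch$sd_noise)
      obs[[length(obs) + 1L]] <- tibble(
        line = rep(lines, times = n_t),
        treatment = tr,
        block = sprintf("%s_b%d", tr, rep(blk, times = n_t)),
        replicate = sprintf("%s_r%d_%s", tr, rep_i, rep(lines, times = n_t)),
        time_dd = rep(schedule, each = n),
        height_cm = as.numeric(pmax(h, 0))
      )
    }
  }
  list(
    observations = bind_rows(obs) %>% arrange(.data$line, .data$treatment,
                                              .data$replicate, .data$time_dd),
    truth = bind_rows(truth),
    amax = amax
  )
}

#' Simulate an hourly temperature series
#'
#' Hourly temperatures with a specified daily mean profile and a sinusoidal
#' diel cycle of the given amplitude, plus optional Gaussian jitter. The
#' diel sine integrates to zero over 24 h, so each day's mean equals the
#' profile value (up to jitter).
#'
#' @param n_days Number of days (>= 1).
#' @param daily_mean Scalar or length-`n_days` vector of daily mean
#'   temperatures (degrees C).
#' @param amplitude Diel half-range (degrees C).
#' @param jitter_sd Hourly Gaussian jitter SD.
#' @param seed Integer seed.
#' @return Tibble with `day`, `hour`, `temp_C`.
#' @export
simulate_temperatures <- function(n_days, daily_mean = 20, amplitude = 5,
                                  jitter_sd = 0, seed = 1L) {
  if (n_days < 1) abort("n_days must be >= 1")
  set.seed(as.integer(seed))
  mu <- rep_len(daily_mean, n_days)
  tibble(
    day = rep(seq_len(n_days), each = 24L),
    hour = rep(0:23, times = n_days),
    temp_C = rep(mu, each = 24L) +
      amplitude * sin(2 * pi * (rep(0:23, times = n_days) - 9) / 24) +
      rnorm(24L * n_days, 0, jitter_sd)
  )
}
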