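#' Configuration for the capture-history simulator
#'
#' Bundles the generating quantities of the simulator: the study layout,
#' survival on the logit scale (intercept plus covariate slopes), capture
#' level and Markovian trap-dependence offset, transient contamination, sex
#' ratio and recruitment schedule. Defaults emulate the long-term shearwater
#' monitoring: 4,555 individuals over the two-panel 1978--2011 design,
#' survival intercept at logit(0.915), covariate slopes (-0.104, -0.212,
#' -0.137) for the longline-effort, annual-SOI and two-year-SST covariates,
#' a high capture probability (0.8) with a positive trap offset, and a
#' modest transient fraction.
#'
#' @param n_individuals Number of capture histories.
#' @param design A [study_design()].
#' @param phi_intercept Survival intercept on the logit scale.
#' @param slopes Named numeric vector of covariate slopes on the logit
#'   scale; names define the covariates the simulator generates (or expects).
#' @param p_intercept Capture intercept (logit scale), trap state m2.
#' @param trap_offset Additive logit-scale capture offset in state m1
#'   (captured at the previous non-gap occasion); positive = trap-happiness.
#' @param transient_fraction Probability that a newly marked individual is a
#'   transient (permanently emigrates immediately after marking).
#' @param sex_ratio Proportion of females.
#' @param panel_weights Recruitment shares per panel (defaults proportional
#'   to the historical panel sizes).
#' @param recruitment `"geometric"` (entry weight decaying along the panel's
#'   years) or `"uniform"`.
#' @param recruit_rate Geometric decay rate per year.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 4555,
                       design = shearwater_design(),
                       phi_intercept = qlogis(0.915),
                       slopes = c(LL_CC_br = -0.104, SOIyr = -0.212,
                                  SST_CC_2yr = -0.137),
                       p_intercept = qlogis(0.8),
                       trap_offset = 1.0,
                       transient_fraction = 0.15,
                       sex_ratio = 0.5,
                       panel_weights = NULL,
                       recruitment = c("geometric", "uniform"),
                       recruit_rate = 0.15) {
  recruitment <- match.arg(recruitment)
  if (transient_fraction < 0 || transient_fraction >= 1) {
    stop("transient_fraction must be in [0, 1)", call. = FALSE)
  }
  if (is.null(panel_weights)) {
    np <- nrow(design$panels)
    panel_weights <- if (np == 2L) c(3227, 1330) / 4557 else rep(1 / np, np)
  }
  structure(
    list(n_individuals = n_individuals, design = design,
         phi_intercept = phi_intercept, slopes = slopes,
         p_intercept = p_intercept, trap_offset = trap_offset,
         transient_fraction = transient_fraction, sex_ratio = sex_ratio,
         panel_weights = panel_weights, recruitment = recruitment,
         recruit_rate = recruit_rate),
    class = "sim_config"
  )
}

ar1_series <- function(n, phi_ar, sd) {
  x <- numeric(n)
  if (n == 0) return(x)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, 0, sd * sqrt(max(0, 1 - phi_ar^2)))
    for (t in 2:n) x[t] <- phi_ar * x[t - 1] + innov[t - 1]
  }
  x
}

#' Simulate monthly environmental index series
#'
#' Generates the three kinds of monthly series the covariate-reduction
#' machinery consumes: sea surface temperature as a seasonal cycle plus
#' AR(1) anomalies (per region), the Southern Oscillation Index as a plain
#' AR(1) series, and longlining effort as a positive trended series with
#' noise. A common latent AR(1) factor with loading `factor_loading` can be
#' injected into the non-breeding-ground LL and SST series to exercise the
#' correlation-reduction rules.
#'
#' @param years Calendar years to cover.
#' @param seed Random seed.
#' @param ar Autoregressive coefficient of the anomaly processes.
#' @param sst_mean,sst_amp,sst_sd Seasonal mean, cycle amplitude and anomaly
#'   standard deviation of SST (degrees C).
#' @param soi_sd Standard deviation of the SOI series.
#' @param ll_level,ll_trend,ll_sd Level (hooks), linear trend per year
#'   (fraction of level) and noise fraction of longlining effort.
#' @param factor_loading Loading of the shared latent factor on the BA
#'   (non-breeding) LL and SST anomalies; 0 disables it.
#' @return A monthly tibble `(year, month, region, variable, value)`.
#' @export
simulate_covariates <- function(years, seed = 1, ar = 0.8,
                                sst_mean = 20, sst_amp = 3, sst_sd = 0.5,
                                soi_sd = 1,
                                ll_level = 1e6, ll_trend = 0.02, ll_sd = 0.1,
                                factor_loading = 0) {
  set.seed(seed)
  months <- tidyr::expand_grid(year = years, month = 1:12)
  n <- nrow(months)
  tt <- seq_len(n)
  cycle <- sst_amp * cos(2 * pi * (months$month - 8) / 12)
  shared <- ar1_series(n, ar, 1)
  mk <- function(region, variable, value) {
    tibble::tibble(year = months$year, month = months$month,
                   region = region, variable = variable, value = value)
  }
  out <- list(
    mk("CC", "SST", sst_mean + cycle + ar1_series(n, ar, sst_sd)),
    mk("BA", "SST", sst_mean + cycle + ar1_series(n, ar, sst_sd) +
         factor_loading * shared),
    mk("global", "SOI", ar1_series(n, ar, soi_sd)),
    mk("CC", "LL", pmax(0, ll_level * (1 + ll_trend * tt / 12) *
                          (1 + stats::rnorm(n, 0, ll_sd)))),
    mk("BA", "LL", pmax(0, ll_level * (1 + ll_trend * tt / 12) *
                          (1 + stats::rnorm(n, 0, ll_sd)) +
                          factor_loading * ll_level * ll_sd * shared))
  )
  dplyr::bind_rows(out)
}

#' Simulate capture histories under the CJS generative model
#'
#' Each recruit is marked at its entry occasion. With probability
#' `transient_fraction` it is a transient and permanently emigrates
#' immediately after marking (post-marking survival zero). Residents survive
#' each annual interval with probability
#' `plogis(phi_intercept + slopes . covariates_t)` and, while alive, are
#' detected with probability `plogis(p_intercept + trap_offset * m1)`, where
#' `m1` indicates detection at the previous non-gap occasion. Capture is
#' impossible in gap years and outside the individual's panel.
#'
#' @param config A [sim_config()].
#' @param covariates Optional tibble `(year, <names of config$slopes>)` of
#'   annual standardized covariate values per interval start year; generated
#'   as standardized AR(1) series when `NULL` (and slopes are present).
#' @param seed Random seed; recorded in the output.
#' @return A `sim_cmr` list: `histories` (encounter-history tibble),
#'   `truth` (tibble of per-interval survival and the capture parameters),
#'   `covariates`, `config`, `seed`.
#' @export
simulate_histories <- function(config = sim_config(), covariates = NULL,
                               seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  design <- config$design
  K <- n_occasions(design)
  years <- design$years
  iy <- years[-K]

  slopes <- config$slopes
  if (is.null(covariates) && length(slopes)) {
    covariates <- tibble::tibble(year = iy)
    for (nm in names(slopes)) {
      z <- ar1_series(K - 1L, 0.3, 1)
      covariates[[nm]] <- as.numeric(scale(z))
    }
  }
  eta <- rep(config$phi_intercept, K - 1L)
  if (length(slopes)) {
    cv <- covariates[match(iy, covariates$year), names(slopes), drop = FALSE]
    eta <- eta + as.numeric(as.matrix(cv) %*% slopes)
  }
  phi <- plogis(eta)
  pm2 <- plogis(config$p_intercept)
  pm1 <- plogis(config$p_intercept + config$trap_offset)

  mask <- capture_mask(design)
  prev <- prev_nongap(design)
  pw <- config$panel_weights / sum(config$panel_weights)
  n <- config$n_individuals
  panel_idx <- sample.int(nrow(design$panels), n, replace = TRUE, prob = pw)
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "female", "male")

  H <- matrix(0L, n, K)
  for (i in seq_len(n)) {
    allowed <- which(mask[panel_idx[i], ])
    wts <- if (config$recruitment == "geometric") {
      (1 - config$recruit_rate)^(seq_along(allowed) - 1L)
    } else {
      rep(1, length(allowed))
    }
    e <- allowed[sample.int(length(allowed), 1L, prob = wts)]
    H[i, e] <- 1L
    if (stats::runif(1) < config$transient_fraction) next
    alive <- TRUE
    for (t in (e + 1L):K) {
      if (e == K) break
      if (stats::runif(1) > phi[t - 1L]) { alive <- FALSE; break }
      if (mask[panel_idx[i], t]) {
        state_m1 <- !is.na(prev[t]) && H[i, prev[t]] == 1L
        pr <- if (state_m1) pm1 else pm2
        if (stats::runif(1) < pr) H[i, t] <- 1L
      }
    }
  }
  histories <- new_histories(sprintf("sim%05d", seq_len(n)), sex,
                             design$panels$panel[panel_idx], H, design)
  structure(
    list(histories = histories,
         truth = tibble::tibble(year = iy, phi = phi),
         p = list(m1 = pm1, m2 = pm2),
         covariates = covariates,
         config = config, seed = seed),
    class = "sim_cmr"
  )
}

#' @export
print.sim_cmr <- function(x, ...) {
  cat("<sim_cmr> ", nrow(x$histories), " histories, ",
      n_occasions(x$config$design), " occasions (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}
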