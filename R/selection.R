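#' Quasi-likelihood AICc
#'
#' `QAICc = DEV / c_hat + 2 np`, plus the small-sample correction
#' `2 np (np + 1) / (ess - np - 1)` when `small_sample = TRUE`. The
#' correction needs an effective sample size `ess` (conventionally the total
#' number of releases) exceeding `np + 1`.
#'
#' @param dev Model deviance (-2 maximized conditional log-likelihood).
#' @param np Number of estimable parameters.
#' @param c_hat Variance inflation factor (> 0).
#' @param ess Effective sample size (required if `small_sample`).
#' @param small_sample Apply the small-sample correction term?
#' @return The QAICc value.
#' @examples
#' qaicc(28553.4, 29, c_hat = 1.746)
#' @export
qaicc <- function(dev, np, c_hat = 1, ess = NULL, small_sample = FALSE) {
  if (c_hat <= 0) stop("c_hat must be positive", call. = FALSE)
  out <- dev / c_hat + 2 * np
  if (small_sample) {
    if (is.null(ess)) stop("`ess` is required when small_sample = TRUE",
                           call. = FALSE)
    if (any(ess <= np + 1)) {
      stop("effective sample size must exceed np + 1", call. = FALSE)
    }
    out <- out + 2 * np * (np + 1) / (ess - np - 1)
  }
  out
}

#' Rank a table of fitted models by QAICc
#'
#' Adds `qaicc`, `delta_qaicc` (difference to the best model) and a
#' `preferred` flag (`delta_qaicc` of every other model exceeds 2) to a
#' model table with columns `np` and `dev`.
#'
#' @param table A data frame with at least columns `np` and `dev`; any other
#'   columns (model labels, formulas) are carried through.
#' @inheritParams qaicc
#' @return A tibble sorted as given, with ranking columns appended.
#' @export
selection_table <- function(table, c_hat = 1, ess = NULL,
                            small_sample = FALSE) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("np", "dev") %in% names(table)))
  table$qaicc <- qaicc(table$dev, table$np, c_hat, ess, small_sample)
  table$delta_qaicc <- table$qaicc - min(table$qaicc)
  second <- sort(table$delta_qaicc)[2]
  table$preferred <- table$delta_qaicc == 0 &
    (is.na(second) || second > 2)
  table
}

#' Analysis-of-deviance F-test for covariate effects on survival
#'
#' Locates a covariate model between a constant-survival reference and the
#' fully time-dependent model:
#' `F = [(DEV(Mcst) - DEV(Mcov)) / n_cov] / [(DEV(Mcov) - DEV(Mt)) / (n - n_cov - 1)]`
#' on `(n_cov, n - n_cov - 1)` degrees of freedom, where `n_cov` is the
#' number of covariates and `n` the number of time-varying survival
#' parameters of the time-dependent reference model.
#'
#' @param dev_cst,dev_cov,dev_t Deviances of the constant, covariate and
#'   time-dependent models.
#' @param n_cov Number of covariates in the covariate model.
#' @param n Number of parameters of the time-dependent reference model.
#' @return A tibble `(statistic, df1, df2, p_value, ordering_ok)`. A zero
#'   denominator (covariate model reaches the time-dependent deviance)
#'   yields an infinite statistic with `p_value = 0`.
#' @examples
#' anodev(100, 80, 60, n_cov = 1, n = 12)  # F = 10
#' @export
anodev <- function(dev_cst, dev_cov, dev_t, n_cov, n) {
  if (n <= n_cov + 1) stop("need n > n_cov + 1", call. = FALSE)
  ordering_ok <- dev_t <= dev_cov && dev_cov <= dev_cst
  df1 <- n_cov
  df2 <- n - n_cov - 1
  num <- (dev_cst - dev_cov) / df1
  den <- (dev_cov - dev_t) / df2
  if (den == 0) {
    return(tibble::tibble(statistic = Inf, df1 = df1, df2 = df2,
                          p_value = 0, ordering_ok = ordering_ok))
  }
  f <- num / den
  tibble::tibble(statistic = f, df1 = df1, df2 = df2,
                 p_value = pf(f, df1, df2, lower.tail = FALSE),
                 ordering_ok = ordering_ok)
}

#' Deviance R-squared of a covariate model
#'
#' Fraction of the temporal deviance variation explained by the covariates:
#' `(DEV(Mcst) - DEV(Mcov)) / (DEV(Mcst) - DEV(Mt))`.
#'
#' @inheritParams anodev
#' @return A scalar in `[0, 1]` when the deviances are properly ordered.
#' @examples
#' r_squared(28553.4, 28525.5, 28418.3)  # about 0.207
#' @export
r_squared <- function(dev_cst, dev_cov, dev_t) {
  if (dev_cst <= dev_t) {
    stop("no time variation to explain: dev_cst must exceed dev_t",
         call. = FALSE)
  }
  (dev_cst - dev_cov) / (dev_cst - dev_t)
}
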