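#' @importFrom stats model.matrix optim optimHess plogis qlogis pf qnorm sd
NULL

# ---- design construction ---------------------------------------------------

# Survival design data: one row per (interval x sex). `time` is a factor over
# interval start years; `period` distinguishes the panel eras; covariate
# columns are z-standardized over the interval years.
phi_design_data <- function(design, sexes, covariates = NULL) {
  K <- n_occasions(design)
  iy <- design$years[-K]
  d <- tidyr::expand_grid(sex = factor(sexes, levels = sexes), year = iy)
  d <- dplyr::arrange(d, .data$sex, .data$year)
  d$time <- factor(d$year)
  d$period <- period_factor(d$year, design)
  scaling <- NULL
  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    if (!"year" %in% names(covariates)) {
      stop("`covariates` must have a `year` column", call. = FALSE)
    }
    miss <- setdiff(iy, covariates$year)
    if (length(miss)) {
      stop("covariates missing for interval years: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    cv <- covariates[match(iy, covariates$year), , drop = FALSE]
    vars <- setdiff(names(cv), "year")
    scaling <- lapply(cv[vars], function(x) {
      list(mean = mean(x), sd = sd(x))
    })
    for (v in vars) {
      z <- (cv[[v]] - scaling[[v]]$mean) / scaling[[v]]$sd
      d[[v]] <- z[match(d$year, iy)]
    }
  }
  attr(d, "scaling") <- scaling
  d
}

# Capture design data: one row per (occasion 2..K x trap state x sex).
p_design_data <- function(design, sexes) {
  oy <- design$years[-1L]
  d <- tidyr::expand_grid(sex = factor(sexes, levels = sexes),
                          trap = factor(c("m2", "m1"), levels = c("m2", "m1")),
                          year = oy)
  d <- dplyr::arrange(d, .data$sex, .data$trap, .data$year)
  d$time <- factor(d$year)
  d$period <- period_factor(d$year, design)
  d
}

period_factor <- function(years, design) {
  pan <- design$panels
  lev <- paste0(pan$start, "-", pan$end)
  idx <- rep(1L, length(years))
  for (i in seq_len(nrow(pan))) {
    idx[years >= pan$start[i]] <- i
  }
  factor(lev[idx], levels = lev)
}

#' Build CJS design matrices from model formulas
#'
#' Survival is modelled on one row per (interval x sex); capture on one row
#' per (occasion x trap state x sex). Formulas may use `time` (factor of
#' years), `sex`, `period` (panel era), `trap` (capture only; levels `m2`,
#' `m1` so the `m1` coefficient is the trap-happiness offset on the logit
#' scale), and any covariate column supplied through `covariates` (values
#' are z-standardized over the interval years before entering the design).
#' Identifiability uses corner-point (treatment) contrasts.
#'
#' @param design A [study_design()].
#' @param phi,p Model formulas for survival and capture, e.g.
#'   `phi = ~ time`, `p = ~ trap + time`.
#' @param sexes Character vector of sex levels present in the data.
#' @param covariates Optional tibble `(year, <covariate columns>)` of annual
#'   covariate values for the survival model.
#' @return A list with design matrices `X_phi`, `X_p`, the underlying data
#'   frames, and the covariate scaling used.
#' @export
build_cjs_design <- function(design, phi = ~1, p = ~1,
                             sexes = "unknown", covariates = NULL) {
  dphi <- phi_design_data(design, sexes, covariates)
  dp <- p_design_data(design, sexes)
  phi_vars <- all.vars(phi)
  p_vars <- all.vars(p)
  unknown <- setdiff(phi_vars, names(dphi))
  if (length(unknown)) {
    stop("unknown covariate(s) in survival formula: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unknown_p <- setdiff(p_vars, names(dp))
  if (length(unknown_p)) {
    stop("unknown term(s) in capture formula: ",
         paste(unknown_p, collapse = ", "), call. = FALSE)
  }
  X_phi <- model.matrix(phi, dphi)
  X_p <- model.matrix(p, dp)
  list(X_phi = X_phi, X_p = X_p, phi_data = dphi, p_data = dp,
       scaling = attr(dphi, "scaling"), design = design, sexes = sexes,
       phi_formula = phi, p_formula = p)
}

# map a parameter vector through the designs to probability arrays
theta_to_arrays <- function(theta, dm) {
  q1 <- ncol(dm$X_phi)
  K <- n_occasions(dm$design)
  S <- length(dm$sexes)
  beta_phi <- theta[seq_len(q1)]
  beta_p <- theta[-seq_len(q1)]
  phi_mat <- matrix(plogis(drop(dm$X_phi %*% beta_phi)), K - 1L, S)
  pv <- plogis(drop(dm$X_p %*% beta_p))
  # rows ordered sex (outer), trap (m2 then m1), year (inner)
  p_arr <- array(pv, dim = c(K - 1L, 2L, S))
  pm2 <- rbind(rep(0, S), matrix(p_arr[, 1L, ], K - 1L, S))
  pm1 <- rbind(rep(0, S), matrix(p_arr[, 2L, ], K - 1L, S))
  list(phi = phi_mat, pm1 = pm1, pm2 = pm2)
}

# ---- fitting ----------------------------------------------------------------

#' Fit a Cormack-Jolly-Seber model
#'
#' Maximizes the conditional CJS likelihood by quasi-Newton (BFGS) iteration
#' with optional random restarts. The number of estimable parameters `np` is
#' the numerical rank of the Hessian at the optimum (tolerance `1e-6` times
#' its largest eigenvalue), so structurally confounded terms -- such as the
#' terminal survival x capture product of a fully time-dependent model -- are
#' counted once. Standard errors come from the (pseudo-)inverse Hessian;
#' real-scale survival and capture estimates use the inverse-logit transform
#' with delta-method standard errors.
#'
#' @inheritParams history_matrix
#' @inheritParams build_cjs_design
#' @param c_hat Variance inflation factor recorded with the fit (used by
#'   [glance.cjs_fit()] for QAICc).
#' @param n_starts Number of starting points (first is the zero vector;
#'   further starts are random normal draws).
#' @param seed Seed for random restarts.
#' @param maxit Maximum BFGS iterations per start.
#' @return A `cjs_fit` object; see [tidy.cjs_fit()], [glance.cjs_fit()],
#'   [predict_survival()], [autoplot.cjs_fit()].
#' @export
fit_cjs <- function(histories, design, phi = ~1, p = ~1, covariates = NULL,
                    c_hat = 1, n_starts = 1, seed = NULL, maxit = 500) {
  prep <- prep_histories(histories, design)
  dm <- build_cjs_design(design, phi = phi, p = p, sexes = prep$sexes,
                         covariates = covariates)
  npar <- ncol(dm$X_phi) + ncol(dm$X_p)
  nll <- function(theta) {
    if (any(!is.finite(theta))) return(1e10)
    a <- theta_to_arrays(theta, dm)
    cjs_nll_arrays(prep, a$phi, a$pm1, a$pm2)
  }
  starts <- list(rep(0, npar))
  if (n_starts > 1) {
    if (!is.null(seed)) set.seed(seed)
    for (s in seq_len(n_starts - 1L)) {
      starts[[s + 1L]] <- stats::rnorm(npar, 0, 1)
    }
  }
  best <- NULL
  for (st in starts) {
    opt <- optim(st, nll, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  theta <- best$par
  grad <- num_gradient(nll, theta)
  hess <- optimHess(theta, nll)
  ev <- eigen(hess, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-6 * max(abs(ev))
  np <- sum(abs(ev) > tol)
  vcov <- tryCatch(solve(hess), error = function(e) pseudo_inverse(hess))
  se <- sqrt(pmax(diag(vcov), 0))
  terms <- c(paste0("phi:", colnames(dm$X_phi)),
             paste0("p:", colnames(dm$X_p)))
  gradient_norm <- sqrt(sum(grad^2))
  structure(
    list(coefficients = tibble::tibble(
           block = rep(c("phi", "p"), c(ncol(dm$X_phi), ncol(dm$X_p))),
           term = terms, estimate = theta, std_error = se),
         theta = theta, vcov = vcov,
         np = np, n_columns = npar,
         loglik = -best$value, deviance = 2 * best$value,
         converged = best$convergence == 0 &&
           gradient_norm < 1e-3 * (1 + abs(best$value)),
         gradient_norm = gradient_norm,
         c_hat = c_hat,
         ess = prep$n_releases,
         n_individuals = prep$n_individuals,
         design_matrices = dm, prep = prep,
         phi_formula = phi, p_formula = p),
    class = "cjs_fit"
  )
}

num_gradient <- function(fn, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- eps * (1 + abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (fn(xp) - fn(xm)) / (2 * h)
  }, numeric(1))
}

pseudo_inverse <- function(m, tol = 1e-10) {
  e <- eigen(m, symmetric = TRUE)
  keep <- abs(e$values) > tol * max(abs(e$values))
  v <- e$vectors[, keep, drop = FALSE]
  v %*% diag(1 / e$values[keep], sum(keep)) %*% t(v)
}

#' @export
print.cjs_fit <- function(x, ...) {
  cat("<cjs_fit> phi ", deparse(x$phi_formula), ", p ",
      deparse(x$p_formula), "\n", sep = "")
  cat(sprintf("  deviance = %.1f, np = %d, converged = %s\n",
              x$deviance, x$np, x$converged))
  invisible(x)
}

#' Broom-style accessors for fitted CJS models
#'
#' `tidy()` returns the coefficient table on the logit scale; `glance()`
#' returns a one-row model summary including the QAICc at the fit's recorded
#' `c_hat`.
#'
#' @param x A `cjs_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cjs_fit
#' @export
tidy.cjs_fit <- function(x, ...) x$coefficients

#' @rdname tidy.cjs_fit
#' @method glance cjs_fit
#' @export
glance.cjs_fit <- function(x, ...) {
  tibble::tibble(
    np = x$np, deviance = x$deviance, logLik = x$loglik,
    qaicc = qaicc(x$deviance, x$np, x$c_hat),
    c_hat = x$c_hat, n = x$n_individuals, converged = x$converged
  )
}

#' Annual survival series from a fitted model
#'
#' Inverse-logit transform of the survival linear predictor per interval
#' (and sex, if modelled), with delta-method standard errors and confidence
#' intervals computed on the logit scale (so bounds stay in (0, 1)).
#' Intervals adjacent to a monitoring gap are flagged: in time-dependent
#' models their annual survivals are estimable only through the multi-year
#' product spanning the gap.
#'
#' @param fit A `cjs_fit`.
#' @param level Confidence level.
#' @return A tibble `(year, sex, estimate, se, lower, upper, spans_gap)`.
#' @export
predict_survival <- function(fit, level = 0.95) {
  dm <- fit$design_matrices
  q1 <- ncol(dm$X_phi)
  beta <- fit$theta[seq_len(q1)]
  V <- fit$vcov[seq_len(q1), seq_len(q1), drop = FALSE]
  eta <- as.numeric(dm$X_phi %*% beta)
  se_eta <- sqrt(pmax(rowSums((dm$X_phi %*% V) * dm$X_phi), 0))
  z <- qnorm(1 - (1 - level) / 2)
  est <- plogis(eta)
  gap_adjacent <- spans_gap_flag(dm$design)
  out <- tibble::tibble(
    year = dm$phi_data$year,
    sex = as.character(dm$phi_data$sex),
    estimate = est,
    se = se_eta * est * (1 - est),
    lower = plogis(eta - z * se_eta),
    upper = plogis(eta + z * se_eta),
    spans_gap = gap_adjacent[match(dm$phi_data$year, dm$design$years)]
  )
  if (!("sex" %in% all.vars(fit$phi_formula))) {
    out <- out[!duplicated(out$year), ]
    out$sex <- "all"
  }
  out
}

# intervals starting in a gap year, or entering the gap, are not separately
# estimable under time-dependent survival
spans_gap_flag <- function(design) {
  gap <- is_gap(design)
  K <- n_occasions(design)
  flag <- logical(K)
  for (k in seq_len(K - 1L)) {
    flag[k] <- gap[k] || gap[k + 1L]
  }
  flag
}

#' @rdname predict_survival
#' @param object A `cjs_fit`.
#' @param ... Unused.
#' @method autoplot cjs_fit
#' @export
autoplot.cjs_fit <- function(object, level = 0.95, ...) {
  s <- predict_survival(object, level = level)
  s <- s[!s$spans_gap, ]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$year, y = .data$estimate,
                                  colour = .data$sex)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Year", y = "Annual adult survival") +
    ggplot2::theme_minimal()
}
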