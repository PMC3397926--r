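test_that("constant-model estimates recover the generating rates", {
  d <- plain_design(15)
  s <- simulate_histories(null_config(2000, d, phi = 0.9, p = 0.6), seed = 2)
  f <- fit_cjs(s$histories, d, phi = ~1, p = ~1)
  expect_true(f$converged)
  co <- tidy(f)
  expect_lt(abs(co$estimate[1] - qlogis(0.9)), 2 * co$std_error[1])
  expect_lt(abs(co$estimate[2] - qlogis(0.6)), 2 * co$std_error[2])
})

test_that("saturated three-occasion fit reproduces m-array proportions", {
  d <- plain_design(3)
  s <- simulate_histories(null_config(600, d, phi = 0.8, p = 0.6), seed = 12)
  f <- fit_cjs(s$histories, d, phi = ~time, p = ~time)
  a <- shearwaterCMR:::theta_to_arrays(f$theta, f$design_matrices)
  ma <- build_m_array(s$histories, d)
  # cell probabilities of next re-encounter from the fitted arrays
  phi <- a$phi[, 1]; p <- a$pm2[, 1]
  p11 <- phi[1] * p[2]
  p12 <- phi[1] * (1 - p[2]) * phi[2] * p[3]
  p22 <- phi[2] * p[3]
  expect_equal(p11, ma$recaptures[1, 1] / ma$releases[1],
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(p12, ma$recaptures[1, 2] / ma$releases[1],
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(p22, ma$recaptures[2, 2] / ma$releases[2],
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("terminal confounding reduces np below the column count", {
  d <- plain_design(8)
  s <- simulate_histories(null_config(600, d), seed = 14)
  f <- fit_cjs(s$histories, d, phi = ~time, p = ~time)
  expect_equal(f$np, f$n_columns - 1L)
})

test_that("design bookkeeping matches the declared structures", {
  d <- plain_design(5)
  dm <- build_cjs_design(d, phi = ~time, p = ~trap + time, sexes = "f")
  expect_equal(ncol(dm$X_phi), 4L)          # one per interval
  expect_equal(ncol(dm$X_p), 1L + 1L + 3L)  # intercept + trap + 3 years
  dm2 <- build_cjs_design(d, phi = ~1, p = ~1, sexes = "f")
  expect_equal(ncol(dm2$X_phi), 1L)
  expect_equal(ncol(dm2$X_p), 1L)
  # three standardized covariate slopes add three columns to the intercept
  cov <- tibble::tibble(year = d$years[-5], LL = rnorm(4), SOI = rnorm(4),
                        SST = rnorm(4))
  dm3 <- build_cjs_design(d, phi = ~LL + SOI + SST, p = ~1, sexes = "f",
                          covariates = cov)
  expect_equal(ncol(dm3$X_phi), 4L)
  expect_error(build_cjs_design(d, phi = ~nosuch, p = ~1, sexes = "f"),
               "unknown covariate")
})

test_that("survival predictions respect the link and centering identities", {
  d <- plain_design(10)
  s <- simulate_histories(null_config(800, d, phi = 0.87, p = 0.6), seed = 15)
  f <- fit_cjs(s$histories, d, phi = ~1, p = ~1)
  sv <- predict_survival(f)
  expect_equal(nrow(sv), 9L)
  expect_equal(length(unique(sv$estimate)), 1L)  # flat series
  expect_true(all(sv$lower >= 0 & sv$upper <= 1))
  expect_equal(unique(sv$estimate), plogis(f$theta[1]))

  # slope-only model at covariate 0 returns inverse-logit of the intercept
  cov <- tibble::tibble(year = d$years[-10], z = rnorm(9))
  f2 <- fit_cjs(s$histories, d, phi = ~z, p = ~1, covariates = cov)
  sv2 <- predict_survival(f2)
  zstd <- (cov$z - mean(cov$z)) / sd(cov$z)
  at0 <- which.min(abs(zstd))
  expect_equal(sv2$estimate[at0],
               plogis(f2$theta[1] + f2$theta[2] * zstd[at0]))
})

test_that("covariate models track the generating survival series", {
  d <- plain_design(15)
  s <- simulate_histories(sim_config(
    n_individuals = 1500, design = d, slopes = c(z = -0.6),
    phi_intercept = qlogis(0.85), p_intercept = qlogis(0.6),
    trap_offset = 0, transient_fraction = 0,
    panel_weights = 1, recruitment = "uniform"), seed = 16)
  f <- fit_cjs(s$histories, d, phi = ~z, p = ~1, covariates = s$covariates)
  sv <- predict_survival(f)
  rmse <- sqrt(mean((sv$estimate - s$truth$phi)^2))
  expect_lt(rmse, mean(sv$se) + 0.02)
})

test_that("autoplot returns a ggplot of the survival series", {
  d <- plain_design(6)
  s <- simulate_histories(null_config(300, d), seed = 17)
  f <- fit_cjs(s$histories, d, phi = ~1, p = ~1)
  expect_s3_class(autoplot(f), "ggplot")
  g <- glance(f)
  expect_equal(g$deviance, f$deviance)
  expect_equal(g$qaicc, f$deviance + 2 * f$np)
})
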