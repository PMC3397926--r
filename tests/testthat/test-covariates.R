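test_that("seasonal windows average the stated months", {
  m <- tidyr::expand_grid(year = 1999:2002, month = 1:12)
  m$value <- 7  # constant series
  br <- seasonal_average(m, "breeding")
  expect_true(all(br$value == 7))
  nb <- seasonal_average(m, "nonbreeding")
  expect_true(all(nb$value == 7))

  m$value <- ifelse(m$month %in% 4:9, m$month - 3, 0)  # Apr..Sep = 1..6
  br <- seasonal_average(m, "breeding")
  expect_true(all(br$value == 3.5))

  # Dec = 2, Jan = 4, Feb = 6 -> 4, labelled with the Jan/Feb year
  m$value <- c(`12` = 2, `1` = 4, `2` = 6)[as.character(m$month)]
  nb <- seasonal_average(m, "nonbreeding")
  expect_true(all(nb$value == 4))
  expect_equal(nb$year, 2000:2002)  # first winter needs Dec 1999

  expect_error(
    seasonal_average(m[!(m$year == 2000 & m$month == 5), ], "breeding",
                     years = 2000),
    "missing month.*5"
  )
})

test_that("season lags shift by half-year steps", {
  seas <- tidyr::expand_grid(year = 2000:2004,
                             season = c("nonbreeding", "breeding"))
  seas$value <- seq_len(nrow(seas))
  expect_error(lag_covariate(seas, 0), "1, 2, 3, 4")
  expect_error(lag_covariate(seas, 5), "1, 2, 3, 4")
  l2 <- lag_covariate(seas, 2)  # one full year
  merged <- merge(seas, l2, by = c("year", "season"),
                  suffixes = c("", "_lag"))
  merged <- merged[merged$year > 2000, ]
  orig <- seas$value[match(paste(merged$year - 1, merged$season),
                           paste(seas$year, seas$season))]
  expect_equal(merged$value_lag, orig)
  # lag 1 maps the breeding value onto the following non-breeding slot
  l1 <- lag_covariate(seas, 1)
  expect_equal(l1$value[l1$year == 2001 & l1$season == "nonbreeding"],
               seas$value[seas$year == 2000 & seas$season == "breeding"])
})

test_that("standardization round-trips and yields unit scale", {
  x <- rnorm(40, 5, 3)
  z <- standardize_covariate(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(destandardize(z), x, tolerance = 1e-12)
})

test_that("PCA reduction is orthonormal with decreasing variance shares", {
  set.seed(5)
  tb <- tibble::tibble(year = 2000:2039,
                       a = rnorm(40), b = rnorm(40), c = rnorm(40))
  tb$d <- tb$a + tb$b + rnorm(40, 0, 0.5)
  pr <- pca_reduce(tb, c("a", "b", "c", "d"), n_keep = 4)
  expect_equal(crossprod(pr$loadings), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(pr$all_variance_fractions) <= 1e-12))
  expect_lte(sum(pr$all_variance_fractions), 1 + 1e-12)
  # largest-magnitude loading is positive in each retained component
  for (j in 1:4) {
    expect_gt(pr$loadings[which.max(abs(pr$loadings[, j])), j], 0)
  }
  # two identical series: PC1 carries everything
  tb2 <- tibble::tibble(year = 2000:2029, x = rnorm(30))
  tb2$y <- tb2$x
  pr2 <- pca_reduce(tb2, c("x", "y"))
  expect_equal(pr2$variance_fraction[1], 1)
})

test_that("correlation screening groups and reduces as specified", {
  set.seed(6)
  tb <- tibble::tibble(year = 2000:2039, a = rnorm(40))
  tb$b <- tb$a + rnorm(40, 0, 0.1)   # same units
  tb$c <- tb$a + rnorm(40, 0, 0.1)   # different units -> PCA with a? no: grouped with a,b
  tb$d <- rnorm(40)                  # independent
  # same-unit trio: average; independent singleton passes through
  red <- reduce_correlated(tb[, c("year", "a", "b")],
                           units = c(a = "degC", b = "degC"))
  expect_equal(red$provenance$method, "average")
  avg <- as.numeric(standardize_covariate(rowMeans(cbind(tb$a, tb$b))))
  expect_equal(red$covariates[[2]], avg)

  red2 <- reduce_correlated(tb[, c("year", "a", "c", "d")],
                            units = c(a = "degC", c = "hooks", d = "index"))
  expect_setequal(red2$provenance$method, c("pca", "passthrough"))
  pcs <- grep("^PC", names(red2$covariates), value = TRUE)
  expect_length(pcs, 2L)
  # reduced covariates are standardized
  for (nm in setdiff(names(red2$covariates), "year")) {
    expect_equal(mean(red2$covariates[[nm]]), 0, tolerance = 1e-10)
    expect_equal(sd(red2$covariates[[nm]]), 1, tolerance = 1e-10)
  }

  # threshold boundaries: alpha = 1 groups everything, alpha ~ 0 nothing
  all_one <- reduce_correlated(tb, units = c(a = "u", b = "u", c = "u",
                                             d = "u"), alpha = 1.0000001)
  expect_equal(nrow(all_one$provenance), 1L)
  none <- reduce_correlated(tb, units = c(a = "u", b = "u", c = "u",
                                          d = "u"), alpha = 1e-300)
  expect_equal(nrow(none$provenance), 4L)
})

test_that("a two-factor covariance model's variance shares are recovered", {
  set.seed(7)
  n <- 4000
  f1 <- rnorm(n); f2 <- rnorm(n)
  tb <- tibble::tibble(
    year = seq_len(n),
    ll1 = 1.0 * f1 + 0.4 * rnorm(n),
    ll2 = 1.0 * f1 + 0.4 * rnorm(n),
    sst1 = 1.0 * f2 + 0.4 * rnorm(n),
    sst2 = 1.0 * f2 + 0.4 * rnorm(n)
  )
  pr <- pca_reduce(tb, c("ll1", "ll2", "sst1", "sst2"), n_keep = 2)
  # within-pair correlation r = 1/1.16; leading eigenvalues are (1 + r)/4
  expected <- (1 + 1 / 1.16) / 4
  expect_equal(pr$variance_fraction[1], expected, tolerance = 0.05)
  expect_equal(pr$variance_fraction[2], expected, tolerance = 0.05)
})
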