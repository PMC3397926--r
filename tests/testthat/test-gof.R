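test_that("handcrafted contingency tables give the known chi-squares", {
  # transience-style 2x2: new animals re-sighted far less
  t1 <- rbind(new = c(10, 40), old = c(40, 10))
  pc1 <- shearwaterCMR:::pooled_chisq(t1)
  expect_equal(pc1$chi2, 36.0)
  expect_equal(pc1$df, 1L)
  # timing 2x2
  t2 <- rbind(new = c(5, 15), old = c(15, 5))
  expect_equal(shearwaterCMR:::pooled_chisq(t2)$chi2, 10.0)
  # immediate-recapture 2x2
  t3 <- rbind(caught = c(30, 10), missed = c(10, 30))
  expect_equal(shearwaterCMR:::pooled_chisq(t3)$chi2, 20.0)
  # degenerate: single informative column
  expect_true(shearwaterCMR:::pooled_chisq(rbind(c(1, 0), c(2, 0)))$degenerate)
})

test_that("sparse columns are pooled until expected counts suffice", {
  tab <- cbind(a = c(50, 50), b = c(30, 28), c = c(1, 0))
  pc <- shearwaterCMR:::pooled_chisq(tab, min_expected = 2)
  expect_equal(ncol(pc$table), 2L)
  expect_equal(sum(pc$table), sum(tab))
  expect_equal(pc$df, 1L)
})

test_that("3SR recovers the handcrafted occasion table from histories", {
  d <- plain_design(3)
  h <- hist_tbl(c("011", "010", "111", "110"), d,
                counts = c(10L, 40L, 40L, 10L))
  g <- gof_3sr(h, d)
  expect_equal(g$chi2, 36.0)
  expect_equal(g$df, 1L)
  expect_gt(g$direction, 0)  # new animals re-sighted less: transience
})

test_that("3SM recovers the handcrafted timing table from histories", {
  d <- plain_design(4)
  h <- hist_tbl(c("0110", "0101", "1110", "1101"), d,
                counts = c(5L, 15L, 15L, 5L))
  g <- gof_3sm(h, d)
  expect_equal(g$chi2, 10.0)
  expect_equal(g$df, 1L)
})

test_that("2CT recovers the handcrafted table with positive direction", {
  d <- plain_design(4)
  h <- hist_tbl(c("1110", "1101", "1010", "1001"), d,
                counts = c(30L, 10L, 10L, 30L))
  g <- gof_2ct(h, d)
  expect_equal(g$chi2, 20.0)
  expect_equal(g$df, 1L)
  expect_gt(g$direction, 0)  # trap-happiness
})

test_that("2CL recovers a handcrafted delayed-timing table", {
  d <- plain_design(5)
  h <- hist_tbl(c("11010", "11001", "10010", "10001"), d,
                counts = c(15L, 5L, 5L, 15L))
  g <- gof_2cl(h, d)
  expect_equal(g$chi2, 10.0)
  expect_equal(g$df, 1L)
})

test_that("homogeneous data give near-zero component statistics", {
  d <- plain_design(4)
  # identical re-sighting behaviour for new and old animals
  h <- hist_tbl(c("0110", "0100", "1110", "1100"), d,
                counts = c(20L, 20L, 20L, 20L))
  expect_equal(gof_3sr(h, d)$chi2, 0)
  h2 <- hist_tbl(c("1110", "1101", "1010", "1001"), d,
                 counts = c(20L, 20L, 20L, 20L))
  expect_equal(gof_2ct(h2, d)$chi2, 0)
})

test_that("suite totals conserve component sums and c-hat", {
  d <- plain_design(10)
  s <- simulate_histories(sim_config(
    n_individuals = 800, design = d, slopes = numeric(),
    phi_intercept = qlogis(0.85), p_intercept = qlogis(0.5),
    trap_offset = 1, transient_fraction = 0.2,
    panel_weights = 1, recruitment = "uniform"), seed = 8)
  rep <- gof_suite(s$histories, d, by = "sex")
  expect_equal(rep$total_chi2, sum(rep$components$chi2))
  expect_equal(rep$total_df, sum(rep$components$df))
  expect_equal(rep$c_hat, rep$total_chi2 / rep$total_df)
  # component-selection control for the c-hat denominator
  resid <- gof_suite(s$histories, d, by = "sex",
                     components = c("3SM", "2CL"))
  expect_true(all(resid$components$test %in% c("3SM", "2CL")))
  expect_equal(resid$c_hat, resid$total_chi2 / resid$total_df)
})

test_that("c-hat helper and the chi2 = df identity behave", {
  expect_equal(c_hat(100, 100), 1)
  expect_equal(c_hat(354.7, 203), 354.7 / 203)
  expect_error(c_hat(10, 0), "positive")
})

test_that("null simulations keep component means near their df", {
  d <- plain_design(8)
  cfg <- null_config(800, d, phi = 0.85, p = 0.5)
  stats <- vapply(1:60, function(r) {
    s <- simulate_histories(cfg, seed = 3000 + r)
    g <- gof_3sr(s$histories, d)
    c(g$chi2, g$df)
  }, numeric(2))
  ratio <- mean(stats[1, ]) / mean(stats[2, ])
  expect_gt(ratio, 0.75)
  expect_lt(ratio, 1.25)
})
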