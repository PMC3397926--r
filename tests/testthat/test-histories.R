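test_that("MARK .inp records parse, expand and validate", {
  d <- plain_design(3)
  path <- withr::local_tempfile(fileext = ".inp")
  writeLines(c("/* two males, one female */", "101 2 1;", "110 0 1;"), path)
  h <- read_inp(path, d)
  expect_equal(nrow(h), 4L)
  expect_equal(sum(h$sex == "male"), 2L)
  first <- h[h$sex == "male", ][1, ]
  expect_equal(unlist(first[, c("2001", "2002", "2003")], use.names = FALSE),
               c(1L, 0L, 1L))

  writeLines("121 1 0;", path)
  expect_error(read_inp(path, d), "other than 0/1")
  writeLines("10 1 0;", path)
  expect_error(read_inp(path, d), "length")
})

test_that("validation names the offending individual", {
  d <- study_design(2001:2004, gap_years = 2003)
  h <- hist_tbl(c("1100", "1010"), d)
  expect_error(validate_histories(h, d), "h0002.*gap year")
  h2 <- hist_tbl(c("0000"), d)
  expect_error(validate_histories(h2, d), "no detections")
})

test_that("write/read round-trips preserve the collection", {
  d <- shearwater_design()
  s <- simulate_histories(sim_config(n_individuals = 100), seed = 4)
  key <- function(h) sort(paste(h$sex, apply(history_matrix(h, d), 1,
                                             paste, collapse = "")))
  inp <- withr::local_tempfile(fileext = ".inp")
  write_inp(s$histories, inp, d)
  expect_identical(key(read_inp(inp, d)), key(s$histories))

  csv <- withr::local_tempfile(fileext = ".csv")
  write_histories_csv(s$histories, csv)
  expect_identical(read_histories_csv(csv, d), s$histories)
})

test_that("first-encounter suppression recodes and drops as defined", {
  d <- plain_design(4)
  h <- hist_tbl(c("0101", "1000"), d)
  r <- suppress_first_encounter(h, d)
  expect_equal(nrow(r), 1L)
  expect_equal(attr(r, "n_dropped"), 1L)
  expect_equal(unname(history_matrix(r, d)[1, ]), c(0L, 0L, 0L, 1L))

  d3 <- plain_design(3)
  h3 <- hist_tbl(c("111", "101", "100"), d3)
  r3 <- suppress_first_encounter(h3, d3)
  expect_equal(attr(r3, "n_dropped"), 1L)
  expect_equal(sort(unname(apply(history_matrix(r3, d3), 1, paste,
                                 collapse = ""))),
               c("001", "011"))
  # applying twice drops all records that had exactly two detections
  r3b <- suppress_first_encounter(r3, d3)
  expect_equal(attr(r3b, "n_dropped"), 1L)
  expect_equal(nrow(r3b), 1L)
})

test_that("m-array matches hand counts and the per-individual scan oracle", {
  d <- plain_design(3)
  ma <- build_m_array(hist_tbl(c("101", "110", "111"), d), d)
  expect_equal(unname(ma$releases), c(3L, 2L))
  expect_equal(unname(ma$recaptures[1, ]), c(2L, 1L))
  expect_equal(unname(ma$recaptures[2, ]), c(0L, 1L))
  expect_equal(unname(ma$never_seen), c(0L, 1L))

  d2 <- plain_design(2)
  ma2 <- build_m_array(hist_tbl("11", d2), d2)
  expect_equal(unname(ma2$releases), 1L)
  expect_equal(unname(ma2$recaptures[1, 1]), 1L)

  # property: agreement with a brute-force scan; row sums conserve releases
  for (seed in 1:5) {
    dd <- plain_design(sample(4:10, 1))
    s <- simulate_histories(null_config(200, dd), seed = seed)
    ma <- build_m_array(s$histories, dd)
    oracle <- marray_by_scan(s$histories, dd)
    expect_equal(unname(ma$releases), oracle$releases)
    expect_equal(unname(ma$recaptures), oracle$recaptures)
    expect_true(all(ma$never_seen >= 0))
    expect_equal(unname(ma$releases),
                 unname(rowSums(ma$recaptures) + ma$never_seen))
    # total releases = total detections minus terminal-occasion detections
    H <- history_matrix(s$histories, dd)
    expect_equal(sum(ma$releases), sum(H[, -ncol(H)]))
  }
  expect_error(build_m_array(s$histories, dd, sex = "nosuch"), "no histories")
})

test_that("trap states follow the previous non-gap occasion rule", {
  d <- plain_design(4)
  ts <- split_by_trap_state(hist_tbl("1101", d), d)
  expect_equal(ts$trap_state, c("m1", "m1", "m2"))
  # the occasion right after first capture is m1 (marking counts as capture)
  ts2 <- split_by_trap_state(hist_tbl("1000", d), d)
  expect_equal(ts2$trap_state, c("m1", "m2", "m2"))

  # across a monitoring gap the previous occasion of 2004 is 1999
  dg <- study_design(1997:2006, gap_years = 2000:2003)
  h <- hist_tbl("1010000100", dg)
  ts3 <- split_by_trap_state(h, dg)
  expect_true(is.na(ts3$trap_state[ts3$year %in% 2000:2003]) |> all())
  expect_equal(ts3$trap_state[ts3$year == 1998], "m1")
  expect_equal(ts3$trap_state[ts3$year == 1999], "m2")
  expect_equal(ts3$trap_state[ts3$year == 2004], "m1")  # detected 1999
  expect_equal(ts3$trap_state[ts3$year == 2005], "m1")  # detected 2004
  expect_equal(ts3$trap_state[ts3$year == 2006], "m2")
})
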