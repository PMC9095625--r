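test_that("delta notation converts ratios as (R/Rstd - 1)*1000", {
  expect_equal(delta_from_ratios(0.011, 0.011), 0.0)
  expect_equal(delta_from_ratios(1.001, 1), 1.0)
  expect_equal(delta_from_ratios(0.999, 1), -1.0)
  expect_error(delta_from_ratios(1, 0), "positive")
})

test_that("pyrolysis correction is the fixed affine rescaling", {
  expect_equal(correct_pyrolysis(0), 1.45)
  expect_equal(correct_pyrolysis(-22.0), -23.0624)
  # linearity: unit input difference maps to the slope
  x <- c(-30, -24.7, -19.6, 0, 5)
  expect_equal(correct_pyrolysis(x + 1) - correct_pyrolysis(x),
               rep(1.1142, length(x)))
  s18 <- isotope_series(2000:2005, rnorm(6), "T1", "d18O")
  expect_error(correct_pyrolysis(s18), "carbon")
})

test_that("Suess correction removes the atmospheric decline", {
  s <- isotope_series(1790:1820, rep(-22, 31), "T1", "d13C")
  flat <- atmospheric_co2_record(1780:1830, rep(-6.4, 51))
  expect_equal(correct_suess(s, flat)$value, s$value)

  atm <- atmospheric_co2_record(1780:1830,
                                c(rep(-6.4, 20), seq(-6.4, -7.9, length.out = 31)))
  out <- correct_suess(s, atm)
  y <- 1820
  decline <- -6.4 - atm$delta13c_atm[atm$year == y]
  expect_equal(out$value[out$year == y], -22 + decline)
  expect_equal(out$value[out$year < 1800], rep(-22, sum(s$year < 1800)))
  expect_error(correct_suess(s, atmospheric_co2_record(1801:1830, rep(-7, 30))),
               "baseline")
  s18 <- isotope_series(1800:1810, rnorm(11), "T1", "d18O")
  expect_error(correct_suess(s18, flat), "carbon")
})

test_that("a generated Suess decline round-trips to a flat record", {
  cfg <- noiseless_config(years = c(1700L, 2016L),
                          suess_total_decline = 2.0)
  # flat couplings: carbon signal is constant + Suess decline only
  cfg$coupling$d13c <- c(intercept = -22, p_july = 0, t_prevsep = 0)
  cl <- simulate_climate(cfg)
  tr <- simulate_isotope_trees(cl, cfg)
  s13 <- Filter(function(s) attr(s, "isotope") == "d13C", tr)[[1]]
  raw_slope <- linear_trend(data.frame(year = s13$year, value = s13$value),
                            window = c(1800, 2016))$slope
  expect_lt(raw_slope, -1e-3)  # decline embedded
  corr <- correct_suess(s13, simulate_atmospheric_co2(cfg))
  post <- corr[corr$year >= 1800, ]
  slope <- linear_trend(data.frame(year = post$year, value = post$value))$slope
  expect_lt(abs(slope), 1e-3)
})

test_that("juvenile exclusion drops exactly the first rings", {
  s <- isotope_series(1600:1949, rnorm(350), "T1", "d13C")
  out <- exclude_juvenile(s, 30)
  expect_equal(nrow(out), 320)
  expect_equal(out$year[1], 1630)
  expect_equal(out$value, s$value[-(1:30)])
  expect_identical(exclude_juvenile(s, 0), s)
  expect_error(exclude_juvenile(isotope_series(1:30, rnorm(30), "T", "d13C"), 30),
               "no rings left")
})

test_that("chronology pools trees with per-year replication statistics", {
  s1 <- isotope_series(2000:2009, rep(10, 10), "A", "d13C")
  s2 <- isotope_series(2000:2009, rep(12, 10), "B", "d13C")
  ch <- build_chronology(list(s1, s2))
  expect_equal(ch$mean, rep(11, 10))
  expect_equal(ch$sd, rep(sqrt(2), 10))
  expect_equal(ch$n, rep(2L, 10))
  expect_equal(ch$se, rep(sqrt(2) / sqrt(2), 10))

  single <- build_chronology(list(s1))
  expect_equal(single$mean, s1$value)
  expect_true(all(single$n == 1L))

  s18 <- isotope_series(2000:2009, rnorm(10), "C", "d18O")
  expect_error(build_chronology(list(s1, s18)), "mixed")
  expect_error(build_chronology(list()), "empty")
})

test_that("a full synthetic stand covers every configured year", {
  st <- quick_stand(seed = 5, years = c(1516L, 2016L), n_trees = 12L)
  ss <- Filter(function(s) attr(s, "isotope") == "d13C", st$trees)
  ch <- build_chronology(ss)
  expect_equal(ch$year, 1516:2016)
  expect_true(all(ch$n >= 1L & ch$n <= 12L))
})

test_that("pyrolysis correction commutes with pooling (affine map)", {
  st <- quick_stand(seed = 2, years = c(1966L, 2016L), n_trees = 4L)
  ss <- Filter(function(s) attr(s, "isotope") == "d13C", st$trees)
  a <- correct_pyrolysis(build_chronology(ss))
  b <- build_chronology(lapply(ss, correct_pyrolysis))
  expect_equal(a$mean, b$mean, tolerance = 1e-12)
})

test_that("EPS follows the Wigley form and its monotonicities", {
  expect_equal(eps_value(0.8, 8), 6.4 / 6.6)
  expect_gt(eps_value(0.8, 8), 0.9)
  # monotone in both arguments, bounded by 1
  rb <- seq(0.05, 1, by = 0.05)
  for (n in c(2, 5, 10)) {
    e <- eps_value(rb, n)
    expect_true(all(diff(e) > 0))
    expect_true(all(e > 0 & e <= 1))
  }
  expect_true(all(diff(eps_value(0.5, 2:20)) > 0))
})

test_that("inter-series statistics behave at the two limits", {
  s <- isotope_series(1900:1999, sin(1:100), "A", "d18O")
  s2 <- isotope_series(1900:1999, sin(1:100), "B", "d18O")
  st <- interseries_stats(list(s, s2))
  expect_equal(st$rbar, 1.0)
  expect_equal(st$eps, 1.0)

  # independent white noise: rbar near zero on average
  rbars <- vapply(1:40, function(k) {
    set.seed(k)
    ss <- lapply(1:5, function(i)
      isotope_series(1500:1999, rnorm(500), paste0("T", i), "d18O"))
    interseries_stats(ss)$rbar
  }, numeric(1))
  expect_lt(abs(mean(rbars)), 0.05)

  a <- isotope_series(1900:1999, rnorm(100), "A", "d13C")
  b <- isotope_series(2100:2199, rnorm(100), "B", "d13C")
  expect_error(interseries_stats(list(a, b)), "overlap")
})

test_that("sigma anomalies standardize and label extremes", {
  # printed-statistics arithmetic: the record extremes against the
  # whole-period mean -22.04 and SD 0.75
  ev <- classify_anomalies(year_df(c(686, 1900, 2016), c(-24.7, -22.04, -19.6)),
                           3, 3, center = -22.04, scale = 0.75)
  expect_equal(ev$z[ev$year == 2016], 3.2, tolerance = 0.1 / 3.2)
  expect_equal(ev$z[ev$year == 686], -3.6, tolerance = 0.1 / 3.6)
  expect_equal(ev$label[ev$year == 2016], "extreme-high")
  expect_equal(ev$label[ev$year == 686], "extreme-low")
  expect_equal(ev$z[ev$year == 1900], 0)
  expect_equal(ev$label[ev$year == 1900], "none")

  # self-standardization oracle: mean 0, sd 1 to machine precision
  set.seed(9)
  ev2 <- classify_anomalies(year_df(1:200, rnorm(200, 5, 2)), 2.5, 2.5)
  expect_equal(mean(ev2$z), 0, tolerance = 1e-12)
  expect_equal(sd(ev2$z), 1, tolerance = 1e-12)
  expect_true(all((abs(ev2$z) >= 2.5) == (ev2$label != "none")))

  expect_error(classify_anomalies(year_df(1:5, rep(1, 5))), "variance")
})

test_that("|z| >= 3 stays rare (< 1%) for 1500 standard-normal years", {
  frac <- vapply(1:50, function(k) {
    set.seed(k)
    ev <- classify_anomalies(year_df(1:1500, rnorm(1500)), 3, 3)
    mean(ev$label != "none")
  }, numeric(1))
  # expected ~0.27%; the 1% bound holds overwhelmingly
  expect_lt(mean(frac), 0.01)
  expect_true(all(frac < 0.02))
})

test_that("implied baseline solves printed (value, sigma) pairs", {
  ib <- implied_baseline(19.9, -6.3, 32.2, 4.4)
  expect_equal(ib$sd, 1.15, tolerance = 0.005 / 1.15)
  expect_equal(ib$mean, 27.14, tolerance = 0.01)
  # round trip on exact inputs
  ib2 <- implied_baseline(10, (10 - 7) / 2, 4, (4 - 7) / 2)
  expect_equal(ib2$mean, 7)
  expect_equal(ib2$sd, 2)
})
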