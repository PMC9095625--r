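test_that("monthly screening locates the generating month", {
  hits <- vapply(1:25, function(s) {
    st <- quick_stand(seed = s)
    ch <- stand_chronology(st, "d18O")
    sm <- monthly_screen(ch, st$climate, window = c(1966, 2015))
    best <- sm[which.max(abs(sm$r)), ]
    best$variable == "temperature" && best$month == "JUL"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("screening recovers the previous-September cross-coupling sign", {
  neg <- vapply(1:25, function(s) {
    st <- quick_stand(seed = s)
    ch <- stand_chronology(st, "d13C")
    sm <- monthly_screen(ch, st$climate, months = "prevSEP",
                         variables = "temperature", window = c(1966, 2015))
    sm$r < 0
  }, logical(1))
  expect_gte(mean(neg), 0.9)
})

test_that("screening a series against itself gives r = 1", {
  yrs <- 1966:2015
  set.seed(1)
  v <- rnorm(50)
  fake <- climate_table(data.frame(year = yrs, month = 7L,
                                   variable = "temperature", value = v))
  sm <- monthly_screen(year_df(yrs, v), fake, months = "JUL",
                       variables = "temperature")
  expect_equal(sm$r, 1.0)
  expect_error(monthly_screen(year_df(yrs, v), fake, months = "JUL",
                              variables = "humidity"), "unknown")
})

test_that("the default drought index has the De Martonne properties", {
  st <- quick_stand(seed = 3)
  di <- drought_index(st$climate)
  cl2 <- st$climate
  cl2$value[cl2$variable == "precipitation"] <-
    2 * cl2$value[cl2$variable == "precipitation"]
  expect_equal(drought_index(cl2)$value, 2 * di$value, tolerance = 1e-12)
  cl0 <- st$climate
  cl0$value[cl0$variable == "precipitation"] <- 0
  expect_equal(drought_index(cl0)$value, rep(0, nrow(di)))
})

test_that("drought index correlates with July precipitation, hence against d13C", {
  st <- quick_stand(seed = 4)
  di <- drought_index(st$climate)
  pj <- monthly_series(st$climate, "precipitation", "JUL", "sum")
  m <- merge(di, pj, by = "year")
  expect_gt(cor(m$value.x, m$value.y), 0)
  ch <- stand_chronology(st, "d13C")
  m2 <- merge(di, data.frame(year = ch$year, chron = ch$mean), by = "year")
  m2 <- m2[m2$year >= 1966, ]
  expect_lt(cor(m2$value, m2$chron), 0)
})

test_that("transfer fit is exact on affine data and reports consistent stats", {
  yrs <- 1970:2009
  proxy <- year_df(yrs, sin(seq_along(yrs)))
  target <- year_df(yrs, 3 - 2 * proxy$value)
  m <- fit_transfer(proxy, target)
  expect_equal(m$stats$r2, 1.0, tolerance = 1e-12)
  expect_equal(m$stats$see, 0, tolerance = 1e-9)
  expect_equal(m$slope, -2)
  expect_equal(m$intercept, 3)
  expect_error(fit_transfer(year_df(yrs, rep(1, 40)), target), "degenerate")
})

test_that("F = r^2 (n-2) / (1 - r^2) holds on every fit", {
  for (s in 1:10) {
    set.seed(s)
    yrs <- 1966:2015
    x <- rnorm(50)
    y <- 0.6 * x + rnorm(50, 0, 0.8)
    m <- fit_transfer(year_df(yrs, x), year_df(yrs, y))
    r2 <- m$stats$r^2
    expect_equal(m$stats$F, r2 * (50 - 2) / (1 - r2), tolerance = 1e-9)
    expect_equal(m$stats$r2, r2, tolerance = 1e-9)
    expect_equal(m$stats$df, c(1L, 48L))
  }
})

test_that("independent proxy and target rarely exceed R^2 = 0.15 at n = 50", {
  r2 <- vapply(1:100, function(s) {
    set.seed(s)
    fit_transfer(year_df(1:50, rnorm(50)), year_df(1:50, rnorm(50)))$stats$r2
  }, numeric(1))
  expect_gte(mean(r2 < 0.15), 0.9)
})

test_that("transfer slope is recovered with < 5% bias at n = 50", {
  # paper-like coupling: calibration r ~ 0.6
  slopes <- vapply(1:500, function(s) {
    set.seed(s)
    x <- rnorm(50, 0, 1.5)
    y <- 14 + 0.9 * x + rnorm(50, 0, 1.8)
    fit_transfer(year_df(1:50, x), year_df(1:50, y))$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.9) / 0.9, 0.05)
})

test_that("skill scores hit their defining special cases", {
  obs <- c(3, 5, 2, 6, 4)
  expect_equal(skill_scores(obs, obs, cal_mean = 10),
               list(RE = 1, CE = 1))
  # predicting the calibration mean gives RE = 0 exactly
  sk <- skill_scores(obs, rep(4.2, 5), cal_mean = 4.2)
  expect_equal(sk$RE, 0)
  expect_lt(sk$CE, 0)
})

test_that("RE >= CE on random inputs and in full split verification", {
  for (s in 1:200) {
    set.seed(s)
    obs <- rnorm(20); pred <- rnorm(20); cal_mean <- rnorm(1)
    sk <- skill_scores(obs, pred, cal_mean)
    expect_gte(sk$RE, sk$CE)
  }
  skilled <- vapply(1:60, function(s) {
    set.seed(s)
    yrs <- 1930:2009
    x <- rnorm(80)
    y <- 0.6 * x + rnorm(80, 0, sqrt(1 - 0.36))
    v <- split_verify(year_df(yrs, x), year_df(yrs, y),
                      c(1970, 2009), c(1930, 1969))
    expect_gte(v$RE, v$CE)
    v$RE > 0
  }, logical(1))
  expect_gte(mean(skilled), 0.9)
})

test_that("split verification validates its windows", {
  yrs <- 1930:2009
  x <- year_df(yrs, rnorm(80)); y <- year_df(yrs, rnorm(80))
  expect_error(split_verify(x, y, c(1960, 2009), c(1930, 1969)), "overlap")
  expect_error(split_verify(x, y, c(1970, 2009), c(1925, 1929)), "paired years")
})

test_that("Gleichlaeufigkeit counts sign agreements with half-weight ties", {
  a <- c(1, 2, 1, 3, 2)
  b <- c(0, 1, 2, 4, 1)
  expect_equal(gleichlaufigkeit(a, b), 0.75)
  expect_equal(gleichlaufigkeit(a, a), 1.0)
  mono <- 1:10
  expect_equal(gleichlaufigkeit(mono, -mono), 0.0)
  # ties: a zero step on one side scores 1/2
  expect_equal(gleichlaufigkeit(c(1, 1, 2), c(5, 6, 7)), 0.75)
  expect_error(gleichlaufigkeit(1, 2), "span")
})

test_that("Gleichlaeufigkeit is symmetric and invariant to positive affine maps", {
  set.seed(12)
  for (k in 1:20) {
    a <- rnorm(30); b <- rnorm(30)
    ks <- gleichlaufigkeit(a, b)
    expect_equal(gleichlaufigkeit(b, a), ks)
    expect_equal(gleichlaufigkeit(2.5 * a + 7, 0.3 * b - 2), ks)
  }
})

test_that("first differences kill constants and shared trends", {
  set.seed(5)
  x <- rnorm(30)
  fd <- first_difference_test(x, x + 100)
  expect_equal(fd$fd_r, 1.0)
  # invariance under adding constants
  y <- cumsum(rnorm(30))
  f1 <- first_difference_test(x, y)
  f2 <- first_difference_test(x + 3, y - 11)
  expect_equal(f1$fd_r, f2$fd_r)
  # a shared linear trend with independent noise leaves fd_r near zero
  rs <- vapply(1:100, function(s) {
    set.seed(s)
    t <- 1:50
    first_difference_test(0.5 * t + rnorm(50), 0.5 * t + rnorm(50))$fd_r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
  expect_error(first_difference_test(1:2, 1:2), "span")
})

test_that("Durbin-Watson matches its closed forms", {
  n <- 12
  alt <- rep(c(1, -1), length.out = n)
  expect_equal(durbin_watson(alt), 4 * (n - 1) / n)
  expect_equal(durbin_watson(rep(2, 10)), 0)
  expect_error(durbin_watson(rep(0, 10)), "zero")
  dws <- vapply(1:30, function(s) {
    set.seed(s)
    durbin_watson(rnorm(1000))
  }, numeric(1))
  expect_lt(abs(mean(dws) - 2), 0.15)
})

test_that("verification report fields are internally coherent", {
  st <- quick_stand(seed = 8)
  ch <- stand_chronology(st, "d18O")
  tj <- monthly_series(st$climate, "temperature", "JUL", "mean")
  v <- split_verify(ch, tj, c(1977, 2016), c(1967, 1976) + c(-30, 0))
  expect_true(v$Ks >= 0 && v$Ks <= 1)
  expect_true(v$DW >= 0 && v$DW <= 4)
  expect_gte(v$RE, v$CE)
  expect_gt(v$r_cal, 0)  # d18O is positively coupled to July temperature
})
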