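test_that("harmonization passes annual inputs through and interpolates decadal", {
  a <- proxy_record(2000:2009, 1:10, "A", 1L)
  b <- proxy_record(2000:2009, 11:20, "B", 1L)
  H <- harmonize_proxies(list(A = a, B = b), "annual")
  expect_equal(H$year, 2000:2009)
  expect_equal(H$A, 1:10)
  expect_equal(H$B, 11:20)

  const <- proxy_record(seq(1900L, 1990L, 10L), rep(5, 10), "C", 10L)
  Hc <- harmonize_proxies(list(A = proxy_record(1900:1990, rnorm(91), "A", 1L),
                               C = const), "annual")
  expect_equal(Hc$C, rep(5, 91))

  ramp <- proxy_record(c(1900L, 1910L), c(0, 10), "D", 10L)
  Hr <- harmonize_proxies(list(D = ramp), "annual")
  expect_equal(Hr$D[Hr$year == 1905], 5)

  expect_error(harmonize_proxies(list(
    A = proxy_record(1900:1920, rnorm(21), "A", 1L),
    B = proxy_record(1980:1999, rnorm(20), "B", 1L))), "disjoint")
})

test_that("decadal mode block-averages annual records over complete decades", {
  yrs <- 1900:1929
  a <- proxy_record(yrs, as.numeric(yrs), "A", 1L)
  d <- proxy_record(c(1900L, 1910L, 1920L), c(1, 2, 3), "D", 10L)
  H <- harmonize_proxies(list(A = a, D = d), "decadal")
  expect_equal(H$year, c(1900L, 1910L, 1920L))
  expect_equal(H$A, c(mean(1900:1909), mean(1910:1919), mean(1920:1929)))
  expect_equal(H$D, c(1, 2, 3))
})

test_that("a single-predictor composite reduces to the simple transfer fit", {
  set.seed(4)
  yrs <- 1950:2009
  x <- rnorm(60)
  y <- 5 - 1.2 * x + rnorm(60, 0, 0.7)
  H <- data.frame(year = yrs, P = x)
  cm <- fit_composite(year_df(yrs, y), H)
  tm <- fit_transfer(year_df(yrs, x), year_df(yrs, y))
  expect_equal(cm$stats$r2, tm$stats$r2, tolerance = 1e-9)
  expect_equal(cm$stats$F, tm$stats$F, tolerance = 1e-9)
  expect_equal(cm$stats$see, tm$stats$see, tolerance = 1e-9)
  expect_equal(cm$variance_shares$lmg_pct, 100)
  rec <- apply_composite(cm, H)
  expect_equal(rec$value, unname(fitted(lm(y ~ x))), tolerance = 1e-9)
})

test_that("an exact linear mix of proxies is recovered with R^2 = 1", {
  set.seed(6)
  yrs <- 1930:2009
  X <- matrix(rnorm(80 * 3), ncol = 3)
  H <- data.frame(year = yrs, a = X[, 1], b = X[, 2], c = X[, 3])
  y <- 2 + 1.5 * X[, 1] - 0.8 * X[, 2] + 0.3 * X[, 3]
  cm <- fit_composite(year_df(yrs, y), H)
  expect_equal(cm$stats$r2, 1.0, tolerance = 1e-9)
  # coefficients on z-scored predictors recover the mix times each SD
  expect_equal(unname(cm$coefficients[-1]),
               c(1.5, -0.8, 0.3) * apply(X, 2, sd), tolerance = 1e-6)
})

test_that("composite calibration/verification skill is stable across the split", {
  ok <- vapply(1:30, function(s) {
    set.seed(s)
    yrs <- 1930:2009
    X <- matrix(rnorm(80 * 3), ncol = 3)
    y <- X %*% c(0.5, 0.4, 0.3) + rnorm(80, 0, 0.8)
    H <- data.frame(year = yrs, p1 = X[, 1], p2 = X[, 2], p3 = X[, 3])
    cm <- fit_composite(year_df(yrs, as.numeric(y)), H, window = c(1970, 2009))
    rec <- apply_composite(cm, H)
    v <- split_verify(rec, year_df(yrs, as.numeric(y)),
                      c(1970, 2009), c(1930, 1969))
    v$r_cal > 0.3 && v$r_ver > 0.3 && v$RE > 0
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("collinear predictors trip the condition-number guard by name", {
  yrs <- 1950:2009
  x <- rnorm(60)
  H <- data.frame(year = yrs, left = x, right = x + 1e-12 * rnorm(60), other = rnorm(60))
  err <- expect_error(fit_composite(year_df(yrs, rnorm(60)), H), "collinear")
  expect_match(conditionMessage(err), "left")
  expect_match(conditionMessage(err), "right")
})

test_that("LMG shares: single predictor takes 100%, orthogonal split by marginals", {
  # orthogonal design with exact marginal R2 of 0.30 and 0.10
  n <- 40
  t <- seq_len(n)
  e1 <- sin(2 * pi * t / n); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cos(2 * pi * t / n); e2 <- e2 / sqrt(sum(e2^2))
  e3 <- sin(4 * pi * t / n); e3 <- e3 / sqrt(sum(e3^2))
  y <- sqrt(0.30) * e1 + sqrt(0.10) * e2 + sqrt(0.60) * e3
  H <- data.frame(year = 1900 + t, x1 = e1, x2 = e2)
  vs <- variance_partition(matrix = H, target = year_df(1900 + t, y))
  expect_equal(sort(vs$lmg_pct, decreasing = TRUE), c(75, 25), tolerance = 1e-6)
  expect_equal(sum(vs$lmg_pct), 100, tolerance = 1e-9)
  expect_equal(vs$marginal_r2[vs$predictor == "x1"], 0.30, tolerance = 1e-6)
  expect_equal(vs$marginal_r2[vs$predictor == "x2"], 0.10, tolerance = 1e-6)
})

test_that("LMG equals brute-force enumeration of orderings at 3 predictors", {
  set.seed(9)
  n <- 60
  X <- matrix(rnorm(n * 3), ncol = 3)
  X[, 2] <- X[, 2] + 0.6 * X[, 1]          # correlated predictors
  y <- X %*% c(1, 0.5, -0.7) + rnorm(n)
  H <- data.frame(year = seq_len(n), a = X[, 1], b = X[, 2], c = X[, 3])
  vs <- variance_partition(matrix = H, target = year_df(seq_len(n), as.numeric(y)))

  # independent oracle: average incremental R2 over all 6 explicit orderings
  r2_of <- function(cols) {
    if (length(cols) == 0) return(0)
    summary(lm(y ~ ., data = as.data.frame(X[, cols, drop = FALSE])))$r.squared
  }
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  contrib <- matrix(0, 6, 3)
  for (k in seq_along(perms)) {
    pr <- perms[[k]]
    for (pos in 1:3) {
      before <- pr[seq_len(pos - 1)]
      contrib[k, pr[pos]] <- r2_of(c(before, pr[pos])) - r2_of(before)
    }
  }
  oracle <- colMeans(contrib)
  expect_equal(vs$lmg_r2, oracle, tolerance = 1e-9)
  expect_equal(sum(vs$lmg_pct), 100, tolerance = 1e-9)
})

test_that("LMG shares are label-permutation invariant and sum to 100", {
  set.seed(14)
  n <- 50
  X <- matrix(rnorm(n * 4), ncol = 4)
  y <- X %*% c(0.9, 0.6, 0.3, 0.1) + rnorm(n)
  H1 <- data.frame(year = 1:n, w = X[, 1], x = X[, 2], y = X[, 3], z = X[, 4])
  H2 <- H1[c("year", "z", "x", "w", "y")]
  tg <- year_df(1:n, as.numeric(y))
  v1 <- variance_partition(matrix = H1, target = tg)
  v2 <- variance_partition(matrix = H2, target = tg)
  expect_equal(sum(v1$lmg_pct), 100, tolerance = 1e-9)
  expect_equal(v2$lmg_r2[match(v1$predictor, v2$predictor)], v1$lmg_r2,
               tolerance = 1e-12)
  expect_true(all(v1$lmg_r2 >= 0 | abs(v1$lmg_r2) < 1e-12))
})

test_that("composite reconstruction is invariant to affine predictor rescaling", {
  set.seed(19)
  yrs <- 1940:2009
  X <- matrix(rnorm(70 * 2), ncol = 2)
  y <- X %*% c(1, -0.5) + rnorm(70, 0, 0.5)
  H1 <- data.frame(year = yrs, a = X[, 1], b = X[, 2])
  H2 <- data.frame(year = yrs, a = 100 + 7 * X[, 1], b = -3 * X[, 2])
  tg <- year_df(yrs, as.numeric(y))
  r1 <- apply_composite(fit_composite(tg, H1), H1)
  r2 <- apply_composite(fit_composite(tg, H2), H2)
  expect_equal(r1$value, r2$value, tolerance = 1e-9)
})

test_that("mean pairwise correlation averages over unordered pairs", {
  yrs <- 1900:1999
  base <- sin(seq_len(100) / 5)
  a <- proxy_record(yrs, base, "a", 1L)
  dup <- proxy_record(yrs, base, "b", 1L)
  expect_equal(mean_pairwise_correlation(list(a = a, b = dup)), 1.0)

  # third record constructed to correlate 0.5 with the first two
  set.seed(3)
  noise <- rnorm(100)
  noise <- as.numeric(residuals(lm(noise ~ base)))
  c_vals <- as.numeric(0.5 * scale(base) + sqrt(0.75) * scale(noise))
  cc <- proxy_record(yrs, c_vals, "c", 1L)
  r_ac <- cor(base, c_vals)
  expect_equal(r_ac, 0.5, tolerance = 1e-9)
  expect_equal(mean_pairwise_correlation(list(a = a, b = dup, c = cc)),
               mean(c(1, r_ac, r_ac)))

  rs <- vapply(1:40, function(s) {
    set.seed(s)
    mean_pairwise_correlation(list(
      x = proxy_record(yrs, rnorm(100), "x", 1L),
      y = proxy_record(yrs, rnorm(100), "y", 1L),
      z = proxy_record(yrs, rnorm(100), "z", 1L)))
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("the enumeration guard rejects more than eight predictors", {
  n <- 40
  X <- matrix(rnorm(n * 9), ncol = 9)
  H <- data.frame(year = 1:n, X)
  expect_error(variance_partition(matrix = H, target = year_df(1:n, rnorm(n))),
               "> 8 predictors")
})
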