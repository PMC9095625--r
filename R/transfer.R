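#' Monthly climate-proxy screening
#'
#' Correlates a proxy chronology with each (climate variable, month)
#' combination, including previous-year months, to locate the season the
#' proxy records. Returns Pearson r, two-sided p and the paired sample size
#' per cell; cells with fewer than `min_overlap` paired years are NA.
#'
#' @param chronology a [build_chronology()] result or year-value data.frame.
#' @param climate a [climate_table()].
#' @param months month specifications (see [parse_month_spec()]); defaults
#'   to all twelve current-year months plus previous-year May-December.
#' @param variables climate variables to screen; default all present.
#' @param window optional year range restriction.
#' @param min_overlap minimum paired years per cell (default 10).
#' @return data.frame `variable, month, r, p, n` (class `screening_matrix`).
#' @export
monthly_screen <- function(chronology, climate,
                           months = c(MONTH_ABBR,
                                      paste0("prev", MONTH_ABBR[5:12])),
                           variables = NULL, window = NULL,
                           min_overlap = 10L) {
  prox <- as_year_series(chronology)
  if (!is.null(window)) prox <- prox[prox$year >= window[1] & prox$year <= window[2], ]
  if (is.null(variables)) variables <- sort(unique(climate$variable))
  unknown <- setdiff(variables, unique(climate$variable))
  if (length(unknown)) stop("unknown climate variable: ", paste(unknown, collapse = ", "))
  out <- list()
  any_overlap <- FALSE
  for (v in variables) {
    stat <- if (v == "precipitation") "sum" else "mean"
    for (m in months) {
      sp <- parse_month_spec(m)
      cl <- monthly_series(climate, v, m, stat = stat)
      mm <- align_years(prox, cl)
      if (nrow(mm) >= min_overlap &&
          stats::sd(mm$value_a) > 0 && stats::sd(mm$value_b) > 0) {
        any_overlap <- TRUE
        ct <- stats::cor.test(mm$value_a, mm$value_b)
        row <- data.frame(variable = v, month = sp$label,
                          r = unname(ct$estimate), p = ct$p.value, n = nrow(mm))
      } else {
        row <- data.frame(variable = v, month = sp$label,
                          r = NA_real_, p = NA_real_, n = nrow(mm))
      }
      out[[length(out) + 1L]] <- row
    }
  }
  if (!any_overlap) stop("no (variable, month) cell has >= ", min_overlap,
                         " overlapping years")
  structure(do.call(rbind, out), class = c("screening_matrix", "data.frame"))
}

#' Monthly drought index
#'
#' Computes a year-indexed drought index from monthly temperature and
#' precipitation, averaged over the requested months. The shipped default is
#' the De Martonne aridity form, `12 * P_m / (T_m + 10)` per month (P in mm,
#' T in degC); larger values mean wetter conditions. The index function is
#' pluggable via `fun(P, T)` since published drought indices differ.
#'
#' @param climate a [climate_table()].
#' @param months month specifications, default May-July.
#' @param fun monthly index function of precipitation and temperature.
#' @return data.frame `year, value`.
#' @export
drought_index <- function(climate, months = c("MAY", "JUN", "JUL"),
                          fun = function(P, T) 12 * P / (T + 10)) {
  per_month <- lapply(months, function(m) {
    sp <- parse_month_spec(m)
    P <- monthly_series(climate, "precipitation", m, "sum")
    T <- monthly_series(climate, "temperature", m, "mean")
    mm <- align_years(P, T)
    if (nrow(mm) == 0L) stop("missing months for drought index: ", sp$label)
    data.frame(year = mm$year, v = fun(mm$value_a, mm$value_b))
  })
  out <- Reduce(function(a, b) merge(a, b, by = "year"),
                lapply(seq_along(per_month), function(i) {
                  d <- per_month[[i]]; names(d)[2] <- paste0("v", i); d
                }))
  out <- out[stats::complete.cases(out), , drop = FALSE]
  data.frame(year = out$year, value = rowMeans(as.matrix(out[, -1, drop = FALSE])))
}

#' Calibrate a proxy-climate transfer function
#'
#' Ordinary least squares of the climate target on the proxy (climate is
#' always the response, so the fitted model maps proxy values to climate
#' units directly). Reports slope, intercept, Pearson r (signed), R-squared,
#' the F statistic with its df pair, two-sided p and the standard error of
#' estimate.
#'
#' @param chronology proxy input: a chronology or year-value data.frame.
#' @param climate a [climate_table()], or a precomputed year-value
#'   data.frame target.
#' @param target for a climate table, `"variable:MONTH"` (e.g.
#'   `"precipitation:JUL"`, `"temperature:prevSEP"`) or a list
#'   `list(variable=, months=, stat=)`; ignored when `climate` is already a
#'   year series.
#' @param window optional calibration year range `c(first, last)`.
#' @param min_overlap minimum paired years (default 10).
#' @return A `transfer_model` list.
#' @export
fit_transfer <- function(chronology, climate, target = NULL, window = NULL,
                         min_overlap = 10L) {
  prox <- as_year_series(chronology)
  if (inherits(climate, "climate_table")) {
    tg <- parse_target(target)
    y <- monthly_series(climate, tg$variable, tg$months, stat = tg$stat)
    target_label <- tg$label
  } else {
    y <- as_year_series(climate)
    target_label <- if (is.character(target)) target else "target"
  }
  if (!is.null(window)) {
    prox <- prox[prox$year >= window[1] & prox$year <= window[2], ]
  }
  mm <- align_years(prox, y)
  if (nrow(mm) < min_overlap) {
    stop("only ", nrow(mm), " overlapping years; need >= ", min_overlap)
  }
  if (stats::sd(mm$value_a) == 0) stop("degenerate proxy: zero variance")
  fit <- stats::lm(value_b ~ value_a, data = mm)
  sm <- summary(fit)
  r <- stats::cor(mm$value_a, mm$value_b)
  n <- nrow(mm)
  Fv <- unname(sm$fstatistic[1])
  predictor <- if (inherits(chronology, "chronology")) {
    attr(chronology, "isotope")
  } else "proxy"
  structure(list(
    predictor = predictor,
    target = target_label,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    calibration_window = range(mm$year),
    stats = list(r = r, r2 = sm$r.squared, F = Fv,
                 df = c(1L, n - 2L), p = sm$coefficients[2, 4],
                 see = sm$sigma, n = n)
  ), class = "transfer_model")
}

parse_target <- function(target) {
  if (is.list(target)) {
    stat <- if (!is.null(target$stat)) target$stat else
      if (target$variable == "precipitation") "sum" else "mean"
    months <- target$months
    lbl <- paste0(target$variable, ":", paste(toupper(months), collapse = "+"))
    return(list(variable = target$variable, months = months, stat = stat, label = lbl))
  }
  if (!is.character(target) || !grepl(":", target)) {
    stop("target must be 'variable:MONTH' or a list(variable=, months=)")
  }
  parts <- strsplit(target, ":", fixed = TRUE)[[1]]
  variable <- parts[1]
  months <- strsplit(parts[2], "+", fixed = TRUE)[[1]]
  stat <- if (variable == "precipitation") "sum" else "mean"
  list(variable = variable, months = months, stat = stat, label = target)
}

#' @export
print.transfer_model <- function(x, ...) {
  cat(sprintf("<transfer_model> %s -> %s\n", x$predictor, x$target))
  cat(sprintf("  %s = %.4f + %.4f * proxy  (%d-%d)\n", x$target,
              x$intercept, x$slope, x$calibration_window[1], x$calibration_window[2]))
  s <- x$stats
  cat(sprintf("  r = %.2f, R2 = %.2f, F = %.2f, df = (%d, %d), p = %.2g, SEE = %.3f\n",
              s$r, s$r2, s$F, s$df[1], s$df[2], s$p, s$see))
  invisible(x)
}

#' Reduction and covariance error
#'
#' Verification-period skill scores against the two conventional null
#' predictors: `RE = 1 - SSE/sum((obs - mean_cal)^2)` and
#' `CE = 1 - SSE/sum((obs - mean_ver)^2)`, sums over the verification
#' window. RE >= CE always, and positive values indicate skill beyond the
#' respective climatological mean.
#'
#' @param obs observed verification-period values.
#' @param pred predicted values for the same years.
#' @param cal_mean calibration-period mean of the observations.
#' @return list with `RE` and `CE`.
#' @export
skill_scores <- function(obs, pred, cal_mean) {
  sse <- sum((obs - pred)^2)
  re <- 1 - sse / sum((obs - cal_mean)^2)
  ce <- 1 - sse / sum((obs - mean(obs))^2)
  list(RE = re, CE = ce)
}

#' Gleichlaeufigkeit (coefficient of synchronicity)
#'
#' Fraction of year-to-year first differences whose signs agree between two
#' series: 1 for a step with matching nonzero signs, 0 for opposing signs,
#' and 1/2 whenever either difference is exactly zero (the standard
#' tie-handling convention). Identical series give 1; sign-mirrored strictly
#' monotone series give 0.
#'
#' @param a,b year-indexed series or plain numeric vectors (then aligned by
#'   position).
#' @return Ks in [0, 1].
#' @export
gleichlaufigkeit <- function(a, b) {
  v <- paired_values(a, b)
  if (nrow(v) < 2L) stop("common span must be >= 2 years")
  sa <- sign(diff(v$value_a))
  sb <- sign(diff(v$value_b))
  score <- ifelse(sa == 0 | sb == 0, 0.5, as.numeric(sa == sb))
  mean(score)
}

paired_values <- function(a, b) {
  if (is.numeric(a) && is.null(names(a)) && is.numeric(b) && is.null(names(b))) {
    if (length(a) != length(b)) stop("unnamed numeric series must have equal length")
    return(data.frame(value_a = a, value_b = b))
  }
  align_years(a, b)
}

#' First-difference agreement test
#'
#' Correlates the year-to-year changes `x_t - x_{t-1}` of an observed and a
#' reconstructed series; agreement of first differences demonstrates
#' consistency in the high-frequency band independent of shared trends or
#' offsets. Returns Pearson r, the equivalent F statistic with its df pair,
#' and the two-sided p value.
#'
#' @param obs,rec year-indexed series or equal-length numeric vectors.
#' @return list `fd_r`, `fd_F`, `fd_df`, `fd_p`.
#' @export
first_difference_test <- function(obs, rec) {
  v <- paired_values(obs, rec)
  if (nrow(v) < 3L) stop("common span must be >= 3 years")
  da <- diff(v$value_a); db <- diff(v$value_b)
  ct <- stats::cor.test(da, db)
  r <- unname(ct$estimate)
  m <- length(da)
  list(fd_r = r,
       fd_F = r^2 * (m - 2) / (1 - r^2),
       fd_df = c(1L, m - 2L),
       fd_p = ct$p.value)
}

#' Durbin-Watson statistic
#'
#' `sum(diff(e)^2) / sum(e^2)` for a residual sequence; near 2 for
#' uncorrelated residuals, toward 0 under positive and 4 under negative
#' first-order autocorrelation.
#'
#' @param residuals numeric residual sequence, length >= 2, not all zero.
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2L) stop("need at least two residuals")
  denom <- sum(residuals^2)
  if (denom == 0) stop("all residuals are zero")
  sum(diff(residuals)^2) / denom
}

#' Split-period calibration and verification
#'
#' Fits the transfer regression on the calibration window, predicts the
#' disjoint verification window, and reports the full verification battery:
#' calibration and verification correlations, reduction and covariance
#' error, the Durbin-Watson statistic of the calibration residuals, the
#' Gleichlaeufigkeit and the first-difference test of the verification
#' window. The shipped default split mirrors common practice for records
#' ending mid-20th century overlap: verification 1930-1969, calibration
#' 1970-2009.
#'
#' @param proxy,target year-indexed series (chronology, reconstruction or
#'   `year, value` data.frame).
#' @param calibration_window,verification_window disjoint inclusive year
#'   ranges, each with >= `min_years` paired years.
#' @param min_years hard floor of paired years per window (default 10).
#' @return A `verification_report` list.
#' @export
split_verify <- function(proxy, target,
                         calibration_window = c(1970L, 2009L),
                         verification_window = c(1930L, 1969L),
                         min_years = 10L) {
  cw <- as.integer(calibration_window); vw <- as.integer(verification_window)
  if (max(min(cw[2], vw[2]) - max(cw[1], vw[1]) + 1L, 0L) > 0L) {
    stop("calibration and verification windows overlap")
  }
  mm <- align_years(proxy, target)
  cal <- mm[mm$year >= cw[1] & mm$year <= cw[2], ]
  ver <- mm[mm$year >= vw[1] & mm$year <= vw[2], ]
  if (nrow(cal) < min_years || nrow(ver) < min_years) {
    stop("need >= ", min_years, " paired years in both windows (have ",
         nrow(cal), " / ", nrow(ver), ")")
  }
  fit <- stats::lm(value_b ~ value_a, data = cal)
  pred_ver <- unname(stats::predict(fit, newdata = ver))
  sk <- skill_scores(ver$value_b, pred_ver, mean(cal$value_b))
  r_cal <- stats::cor(cal$value_a, cal$value_b)
  r_ver <- stats::cor(ver$value_b, pred_ver)
  fd <- first_difference_test(ver$value_b, pred_ver)
  structure(list(
    r_cal = r_cal, r_ver = r_ver,
    RE = sk$RE, CE = sk$CE,
    DW = durbin_watson(stats::residuals(fit)),
    Ks = gleichlaufigkeit(ver$value_b, pred_ver),
    fd_r = fd$fd_r, fd_F = fd$fd_F, fd_p = fd$fd_p,
    n_cal = nrow(cal), n_ver = nrow(ver),
    calibration_window = cw, verification_window = vw
  ), class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("<verification_report> cal %d-%d (n=%d), ver %d-%d (n=%d)\n",
              x$calibration_window[1], x$calibration_window[2], x$n_cal,
              x$verification_window[1], x$verification_window[2], x$n_ver))
  cat(sprintf("  r_cal = %.2f, r_ver = %.2f, RE = %.2f, CE = %.2f\n",
              x$r_cal, x$r_ver, x$RE, x$CE))
  cat(sprintf("  DW = %.2f, Ks = %.2f, fd_r = %.2f (F = %.2f, p = %.2g)\n",
              x$DW, x$Ks, x$fd_r, x$fd_F, x$fd_p))
  invisible(x)
}
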