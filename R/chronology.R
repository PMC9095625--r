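#' Delta notation from isotope ratios
#'
#' Converts a sample/standard isotope-ratio pair to the conventional
#' per-mil delta value, `(R_sample/R_standard - 1) * 1000`, relative to
#' VPDB (carbon) or VSMOW (oxygen).
#'
#' @param r_sample,r_standard isotope ratios (13C/12C or 18O/16O);
#'   `r_standard` must be positive.
#' @return Per-mil delta value(s).
#' @export
delta_from_ratios <- function(r_sample, r_standard) {
  if (any(r_standard <= 0)) stop("standard ratio must be positive")
  (r_sample / r_standard - 1) * 1000
}

#' Pyrolysis correction for carbon isotope measurements
#'
#' High-temperature pyrolysis adds a small carbon contribution from the
#' reactor filling to the measuring gas; raw delta13C values are rescaled by
#' the established linear correction `1.1142 * raw + 1.45`.
#'
#' @param raw per-mil delta13C value(s), an [isotope_series()], or a
#'   [build_chronology()] result.
#' @return Corrected values in the same container. Applying it to an oxygen
#'   series is an error (the correction is carbon-specific).
#' @export
correct_pyrolysis <- function(raw) {
  f <- function(x) 1.1142 * x + 1.45
  if (inherits(raw, "isotope_series")) {
    if (attr(raw, "isotope") != "d13C") {
      stop("pyrolysis correction applies to carbon series only")
    }
    raw$value <- f(raw$value)
    return(raw)
  }
  if (inherits(raw, "chronology")) {
    if (attr(raw, "isotope") != "d13C") {
      stop("pyrolysis correction applies to carbon series only")
    }
    raw$mean <- f(raw$mean)
    smry <- attr(raw, "summary")
    smry$mean <- f(smry$mean)
    smry$sd <- 1.1142 * smry$sd
    smry$se <- 1.1142 * smry$se
    attr(raw, "summary") <- smry
    return(raw)
  }
  f(raw)
}

#' Suess-effect correction
#'
#' Removes the industrial-era decline of atmospheric delta13C-of-CO2 from a
#' tree carbon-isotope series: for years at or after `baseline_year` the
#' atmospheric anomaly relative to the baseline year is subtracted,
#' `value(y) - (atm(y) - atm(baseline_year))`; earlier years are unchanged.
#' Since the atmospheric anomaly is negative after the onset of fossil-fuel
#' emissions, the correction raises recent values.
#'
#' @param series a carbon [isotope_series()].
#' @param atm an [atmospheric_co2_record()] covering the baseline year and
#'   every series year at/after it.
#' @param baseline_year reference year; defaults to 1800 CE, the onset of
#'   the anthropogenic decline.
#' @return The corrected [isotope_series()].
#' @export
correct_suess <- function(series, atm, baseline_year = 1800L) {
  stopifnot(inherits(series, "isotope_series"))
  if (attr(series, "isotope") != "d13C") {
    stop("Suess correction applies to carbon series only")
  }
  base <- atm$delta13c_atm[match(baseline_year, atm$year)]
  if (is.na(base)) stop("atmosphere record does not cover baseline year ", baseline_year)
  post <- series$year >= baseline_year
  if (any(post)) {
    av <- atm$delta13c_atm[match(series$year[post], atm$year)]
    if (anyNA(av)) {
      miss <- series$year[post][is.na(av)][1L]
      stop("atmosphere record missing year ", miss)
    }
    series$value[post] <- series$value[post] - (av - base)
  }
  series
}

#' Exclude juvenile rings
#'
#' Drops the earliest rings of a tree series, where age-related growth
#' trends bias the isotope ratios. The conventional exclusion span is the
#' first 30 rings.
#'
#' @param series an [isotope_series()].
#' @param n_rings number of initial rings to drop (default 30).
#' @return The truncated series; erroring if nothing would remain.
#' @export
exclude_juvenile <- function(series, n_rings = 30L) {
  stopifnot(inherits(series, "isotope_series"))
  n_rings <- as.integer(n_rings)
  if (n_rings < 0L) stop("n_rings must be >= 0")
  if (n_rings == 0L) return(series)
  if (nrow(series) <= n_rings) {
    stop("series of length ", nrow(series), " has no rings left after excluding ",
         n_rings)
  }
  out <- series[-seq_len(n_rings), , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("tree_id", "isotope", "class")] <-
    attributes(series)[c("tree_id", "isotope", "class")]
  out
}

#' Build a site chronology from tree series
#'
#' Averages all trees covering each year into a site mean with per-year
#' replication, SD and SE (`se = sd/sqrt(n)`). Physical pooling of several
#' trees' rings is emulated as this equal-weight mean. Whole-period summary
#' statistics (mean, SD, SE) are computed on the annual mean series.
#'
#' @param series_list list of [isotope_series()] of one isotope kind.
#' @return A `chronology`: data.frame `year, mean, n, sd, se` with an
#'   `isotope` attribute and a `summary` attribute
#'   (`mean`, `sd`, `se`, `n_years`, `n_trees`).
#' @export
build_chronology <- function(series_list) {
  if (inherits(series_list, "isotope_series")) series_list <- list(series_list)
  if (length(series_list) == 0L) stop("empty series list")
  isos <- vapply(series_list, function(s) attr(s, "isotope"), character(1))
  if (length(unique(isos)) != 1L) stop("mixed isotopes in chronology input")
  long <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(year = s$year, value = s$value)
  }))
  long <- long[!is.na(long$value), , drop = FALSE]
  if (nrow(long) == 0L) stop("no values in chronology input")
  yr <- sort(unique(long$year))
  g <- factor(long$year, levels = yr)
  mean_v <- as.numeric(tapply(long$value, g, mean))
  n_v <- as.integer(tapply(long$value, g, length))
  sd_v <- as.numeric(tapply(long$value, g, stats::sd))  # NA where n = 1
  se_v <- sd_v / sqrt(n_v)
  out <- data.frame(year = yr, mean = mean_v, n = n_v, sd = sd_v, se = se_v)
  smry <- list(mean = mean(mean_v),
               sd = stats::sd(mean_v),
               se = stats::sd(mean_v) / sqrt(length(mean_v)),
               n_years = length(mean_v),
               n_trees = length(series_list))
  structure(out, isotope = isos[1], summary = smry,
            class = c("chronology", "data.frame"))
}

#' Whole-period chronology summary
#'
#' @param chron a [build_chronology()] result.
#' @return list with `mean`, `sd`, `se` (of the annual mean series), the
#'   minimum and maximum with their years, and year coverage.
#' @export
chronology_summary <- function(chron) {
  stopifnot(inherits(chron, "chronology"))
  s <- attr(chron, "summary")
  i_min <- which.min(chron$mean); i_max <- which.max(chron$mean)
  c(s, list(min = chron$mean[i_min], min_year = chron$year[i_min],
            max = chron$mean[i_max], max_year = chron$year[i_max],
            first_year = min(chron$year), last_year = max(chron$year)))
}

#' @export
print.chronology <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<chronology> %s, %d years (%d-%d), %d trees\n",
              attr(x, "isotope"), nrow(x), min(x$year), max(x$year), s$n_trees))
  cat(sprintf("  period mean %.2f permil, SD %.2f, SE %.3f\n", s$mean, s$sd, s$se))
  invisible(x)
}

#' Express Population Signal from rbar and sample depth
#'
#' The Wigley et al. form `EPS = N*rbar / (N*rbar + (1 - rbar))`, the
#' standard replication-quality statistic for chronologies; values above
#' 0.85-0.9 conventionally indicate a robust common signal.
#'
#' @param rbar mean inter-series correlation.
#' @param n number of series.
#' @export
eps_value <- function(rbar, n) {
  n * rbar / (n * rbar + (1 - rbar))
}

#' Mean inter-series correlation and EPS
#'
#' Computes rbar as the mean pairwise Pearson correlation over a common
#' window and the Express Population Signal via [eps_value()]. Pairs must
#' overlap by at least 10 years within the window to contribute.
#'
#' @param series_list list of two or more [isotope_series()].
#' @param window optional inclusive year range `c(first, last)`.
#' @param min_overlap minimum paired years per tree pair (default 10).
#' @return list with `rbar`, `eps`, `n_series`, `n_pairs`.
#' @export
interseries_stats <- function(series_list, window = NULL, min_overlap = 10L) {
  if (length(series_list) < 2L) stop("need at least two series")
  ss <- lapply(series_list, function(s) {
    d <- as_year_series(s)
    if (!is.null(window)) d <- d[d$year >= window[1] & d$year <= window[2], ]
    d
  })
  n <- length(ss)
  rs <- c()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      m <- align_years(ss[[i]], ss[[j]])
      if (nrow(m) >= min_overlap) {
        rs <- c(rs, stats::cor(m$value_a, m$value_b))
      }
    }
  }
  if (length(rs) == 0L) stop("no series pair overlaps by >= ", min_overlap, " years")
  rbar <- mean(rs)
  list(rbar = rbar, eps = eps_value(rbar, n), n_series = n, n_pairs = length(rs))
}

#' Classify sigma anomalies and extremes
#'
#' Standardizes a year-indexed series against its full-period mean and SD
#' (z-scores) and labels extremes by sigma thresholds, the convention used
#' to flag exceptional years in millennial reconstructions (e.g. dry/wet
#' precipitation extremes beyond +/- 2.5 sigma, isotope extremes beyond
#' +/- 3 sigma).
#'
#' @param values year-indexed series: a chronology, reconstruction,
#'   data.frame `year, value` or named numeric vector.
#' @param low_threshold,high_threshold positive sigma thresholds; a year is
#'   `extreme-low` when `z <= -low_threshold`, `extreme-high` when
#'   `z >= high_threshold`.
#' @param center,scale optional externally supplied baseline mean and SD
#'   (e.g. published whole-period statistics); by default both are computed
#'   from the series itself.
#' @return data.frame `year, value, z, label` (class `anomaly_events`) for
#'   all years, with the baseline in attributes `center`/`scale`.
#' @export
classify_anomalies <- function(values, low_threshold = 3, high_threshold = 3,
                               center = NULL, scale = NULL) {
  d <- as_year_series(values)
  if (nrow(d) < 2L && is.null(scale)) stop("need at least two values")
  if (low_threshold <= 0 || high_threshold <= 0) stop("thresholds must be positive")
  mu <- if (is.null(center)) mean(d$value) else center
  sg <- if (is.null(scale)) stats::sd(d$value) else scale
  if (!is.finite(sg) || sg <= 0) stop("zero variance: cannot standardize")
  z <- (d$value - mu) / sg
  label <- rep("none", nrow(d))
  label[z <= -low_threshold] <- "extreme-low"
  label[z >= high_threshold] <- "extreme-high"
  structure(data.frame(year = d$year, value = d$value, z = z, label = label),
            center = mu, scale = sg,
            class = c("anomaly_events", "data.frame"))
}

#' Baseline mean and SD implied by printed (value, sigma) pairs
#'
#' Two standardized anomalies `z = (x - mu)/sd` reported for the same record
#' jointly determine the baseline: `sd = (x2 - x1)/(z2 - z1)` and
#' `mu = x1 - z1*sd`. Useful for consistency-checking published anomaly
#' tables against their stated summary statistics.
#'
#' @param x1,z1,x2,z2 two (value, sigma-anomaly) pairs.
#' @return list with `mean` and `sd`.
#' @export
implied_baseline <- function(x1, z1, x2, z2) {
  if (z1 == z2) stop("pairs must have distinct sigma anomalies")
  sd <- (x2 - x1) / (z2 - z1)
  list(mean = x1 - z1 * sd, sd = sd)
}
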