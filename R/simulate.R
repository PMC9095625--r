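#' Configuration for the synthetic proxy-system generator
#'
#' Bundles every tunable of the synthetic data generator: a continental
#' high-elevation monthly climate, a stand of larch-like trees whose ring
#' cellulose isotopes are linearly coupled to that climate, an industrial-era
#' atmospheric delta13C decline, and decadal lake-sediment proxies. Defaults
#' emulate the study system the package targets: a 516-2016 CE chronology
#' from 42 trees averaging ~350 rings, delta13C negatively coupled to July
#' precipitation (site-level r near -0.6), delta18O positively coupled to
#' July temperature (r near 0.64), a weaker previous-September temperature
#' cross-coupling of opposite sign per isotope, ~142.6 mm/yr precipitation,
#' and a ~2 permil post-1800 atmospheric delta13C decline.
#'
#' @param seed integer RNG seed; every simulator derives its stream from it.
#' @param years inclusive CE year range as a length-2 integer vector.
#' @param n_trees number of trees; must be large enough that sequential
#'   overlapping lifespans can cover the year range.
#' @param coupling list with numeric vectors `d13c` (`intercept`, `p_july`
#'   permil/mm, `t_prevsep` permil/degC) and `d18o` (`intercept`, `t_july`,
#'   `t_prevsep` permil/degC).
#' @param noise_sd_tree per-mil SD of tree-level year noise, named per
#'   isotope (`d13c`, `d18o`) or a single value for both.
#' @param noise_sd_year per-mil SD of the shared (stand-wide) year noise.
#' @param tree_offset_sd per-mil SD of constant between-tree offsets.
#' @param lifespan_mean,lifespan_spread tree lifespans are drawn uniformly in
#'   `lifespan_mean +/- lifespan_spread` years.
#' @param juvenile_rings length of the age-trend-affected early segment.
#' @param juvenile_amp per-mil amplitude of the juvenile depletion, decaying
#'   exponentially over the first `juvenile_rings` rings.
#' @param suess_onset_year first year of the atmospheric delta13C decline.
#' @param suess_total_decline total per-mil decline by the final year (>= 0).
#' @param atm_baseline pre-industrial atmospheric delta13C (permil, VPDB).
#' @param temp_mean_annual,temp_seasonal_amp annual-mean temperature and
#'   seasonal half-amplitude (degC) of the monthly climatology.
#' @param temp_ar1 AR(1) coefficient of monthly temperature anomalies.
#' @param temp_anom_sd marginal SD (degC) of those anomalies.
#' @param temp_trend linear trend (degC/yr) added to every month, 0 = none.
#' @param precip_annual_mean,precip_july_mean long-run annual total and July
#'   mean precipitation (mm); non-July monthly means are scaled to close the
#'   annual budget.
#' @param precip_shape gamma shape of monthly precipitation totals.
#' @param station_id,elevation_m metadata stamped on the climate table.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       years = c(516L, 2016L),
                       n_trees = 42L,
                       coupling = list(
                         d13c = c(intercept = -20.38, p_july = -0.02, t_prevsep = -0.19),
                         d18o = c(intercept = 19.61, t_july = 0.45, t_prevsep = 0.26)
                       ),
                       noise_sd_tree = c(d13c = 0.40, d18o = 0.50),
                       noise_sd_year = c(d13c = 0.55, d18o = 0.75),
                       tree_offset_sd = 0.30,
                       lifespan_mean = 350L,
                       lifespan_spread = 100L,
                       juvenile_rings = 30L,
                       juvenile_amp = 1.5,
                       suess_onset_year = 1800L,
                       suess_total_decline = 2.0,
                       atm_baseline = -6.4,
                       temp_mean_annual = -2.3,
                       temp_seasonal_amp = 15.8,
                       temp_ar1 = 0.3,
                       temp_anom_sd = 1.5,
                       temp_trend = 0,
                       precip_annual_mean = 142.6,
                       precip_july_mean = 30,
                       precip_shape = 2,
                       station_id = "SYN-STATION",
                       elevation_m = 1850) {
  if (missing(seed)) stop("seed is mandatory")
  seed <- as.integer(seed)
  years <- as.integer(years)
  if (length(years) != 2L || years[2] < years[1]) stop("empty or invalid year range")
  n_trees <- as.integer(n_trees)
  if (n_trees < 1L) stop("n_trees must be >= 1")
  pad2 <- function(x) if (length(x) == 1L) c(d13c = unname(x), d18o = unname(x)) else x
  noise_sd_tree <- pad2(noise_sd_tree)
  noise_sd_year <- pad2(noise_sd_year)
  if (any(c(noise_sd_tree, noise_sd_year, tree_offset_sd) < 0)) {
    stop("noise SDs must be >= 0")
  }
  if (suess_total_decline < 0) stop("suess_total_decline must be >= 0")
  if (precip_july_mean <= 0 || precip_annual_mean <= precip_july_mean) {
    stop("precipitation means must satisfy 0 < july < annual")
  }
  structure(list(
    seed = seed, years = years, n_trees = n_trees, coupling = coupling,
    noise_sd_tree = noise_sd_tree, noise_sd_year = noise_sd_year,
    tree_offset_sd = tree_offset_sd,
    lifespan_mean = as.integer(lifespan_mean),
    lifespan_spread = as.integer(lifespan_spread),
    juvenile_rings = as.integer(juvenile_rings), juvenile_amp = juvenile_amp,
    suess_onset_year = as.integer(suess_onset_year),
    suess_total_decline = suess_total_decline, atm_baseline = atm_baseline,
    temp_mean_annual = temp_mean_annual, temp_seasonal_amp = temp_seasonal_amp,
    temp_ar1 = temp_ar1, temp_anom_sd = temp_anom_sd, temp_trend = temp_trend,
    precip_annual_mean = precip_annual_mean, precip_july_mean = precip_july_mean,
    precip_shape = precip_shape, station_id = station_id,
    elevation_m = elevation_m
  ), class = "sim_config")
}

# Independent deterministic RNG streams per simulator stage, all derived from
# the one configured seed (kept well below .Machine$integer.max).
sim_seed <- function(config, stage) {
  offs <- c(climate = 0L, trees = 1L, lake = 2L, rings = 3L)
  (config$seed %% 2000000000L) + offs[[stage]]
}

# Monthly precipitation means (mm): continental regime with an Apr-Oct wet
# season; July pinned to precip_july_mean, remaining months scaled so the
# expected annual total equals precip_annual_mean.
precip_month_means <- function(config) {
  w <- c(2, 2, 4, 8, 12, 18, 30, 25, 18, 12, 6, 5)
  mu <- w
  mu[7] <- config$precip_july_mean
  mu[-7] <- w[-7] * (config$precip_annual_mean - config$precip_july_mean) / sum(w[-7])
  mu
}

#' Simulate a monthly station climate table
#'
#' Monthly temperature is a seasonal cycle plus an AR(1) anomaly and an
#' optional linear trend; monthly precipitation totals are gamma-distributed
#' around a seasonal mean profile whose annual sum matches the configured
#' long-run total. Vapour pressure deficit and sunshine duration are derived
#' from temperature with additive noise so that monthly screening has the
#' full four-variable menu. Identical config and seed give a byte-identical
#' table.
#'
#' @param config a [sim_config()].
#' @return A [climate_table()].
#' @export
simulate_climate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  yrs <- seq.int(config$years[1], config$years[2])
  n <- length(yrs)
  withr_seed <- sim_seed(config, "climate")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)

  months <- rep(1:12, times = n)
  years_m <- rep(yrs, each = 12L)
  clim <- config$temp_mean_annual +
    config$temp_seasonal_amp * cos(2 * pi * (months - 7) / 12)
  innov_sd <- config$temp_anom_sd * sqrt(1 - config$temp_ar1^2)
  anom <- as.numeric(stats::filter(stats::rnorm(n * 12L, 0, innov_sd),
                                   config$temp_ar1, method = "recursive"))
  temp <- clim + anom + config$temp_trend * (years_m - yrs[1])

  mu <- precip_month_means(config)[months]
  prec <- stats::rgamma(n * 12L, shape = config$precip_shape,
                        scale = mu / config$precip_shape)

  vpd <- pmax(0.1, 2 + 0.4 * temp + stats::rnorm(n * 12L, 0, 1))
  sun <- pmax(0, 170 + 5 * temp + stats::rnorm(n * 12L, 0, 15))

  rec <- rbind(
    data.frame(year = years_m, month = months, variable = "temperature", value = temp),
    data.frame(year = years_m, month = months, variable = "precipitation", value = prec),
    data.frame(year = years_m, month = months, variable = "vpd", value = vpd),
    data.frame(year = years_m, month = months, variable = "sunshine", value = sun)
  )
  climate_table(rec, station_id = config$station_id,
                elevation_m = config$elevation_m)
}

# Save/restore the global RNG state so simulators are deterministic without
# clobbering the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate the atmospheric delta13C-of-CO2 history
#'
#' Constant pre-industrial baseline before the onset year, then a smooth
#' monotone (quadratic-in-time) decline totalling `suess_total_decline`
#' permil by the final simulated year. Deterministic: no noise.
#'
#' @param config a [sim_config()].
#' @return An [atmospheric_co2_record()].
#' @export
simulate_atmospheric_co2 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$suess_total_decline < 0) stop("negative decline")
  onset <- config$suess_onset_year
  yrs <- seq.int(min(config$years[1], onset), config$years[2])
  val <- rep(config$atm_baseline, length(yrs))
  post <- yrs >= onset
  if (any(post) && config$years[2] > onset) {
    u <- (yrs[post] - onset) / (config$years[2] - onset)
    val[post] <- config$atm_baseline - config$suess_total_decline * u^2
  }
  atmospheric_co2_record(yrs, val)
}

# Tree birth/death plan: a sequential backbone with forced post-juvenile
# overlaps >= 30 yr guarantees gap-free coverage of the configured range;
# any remaining trees are scattered uniformly. Lifespans ~ U(mean +/- spread).
plan_lifespans <- function(config) {
  y0 <- config$years[1]; y1 <- config$years[2]
  draw_life <- function(k) {
    round(stats::runif(k, config$lifespan_mean - config$lifespan_spread,
                       config$lifespan_mean + config$lifespan_spread))
  }
  overlap <- 30L + config$juvenile_rings
  births <- integer(0); deaths <- integer(0)
  b <- y0
  repeat {
    life <- draw_life(1L)
    d <- min(b + life - 1L, y1)
    births <- c(births, b); deaths <- c(deaths, d)
    if (d >= y1) break
    b <- d - overlap + 1L
    if (b <= births[length(births)]) b <- births[length(births)] + 1L
  }
  n_back <- length(births)
  if (n_back > config$n_trees) {
    stop("n_trees too small to cover the year range with overlapping lifespans")
  }
  extra <- config$n_trees - n_back
  if (extra > 0L) {
    eb <- sort(round(stats::runif(extra, y0, max(y0, y1 - 2L * overlap))))
    el <- draw_life(extra)
    births <- c(births, eb)
    deaths <- c(deaths, pmin(eb + el - 1L, y1))
  }
  data.frame(tree = sprintf("T%02d", seq_along(births)),
             birth = as.integer(births), death = as.integer(deaths))
}

#' Simulate a stand of isotope-bearing trees
#'
#' Per tree t and year y the generator follows the linear proxy model
#' `d13C(t,y) = a + bP * P_July(y) + bS * T_Sep(y-1) + atm(y) + offset(t) +
#' eta(y) + eps(t,y)` and `d18O(t,y) = a' + bT * T_July(y) + bS' * T_Sep(y-1)
#' + offset'(t) + eta'(y) + eps'(t,y)`, where `atm(y)` is the post-onset
#' atmospheric delta13C anomaly (so the carbon record carries a Suess decline
#' for the correction stage to remove), `eta` is shared year noise and `eps`
#' tree-level noise. Trees have finite overlapping lifespans and an optional
#' exponentially decaying juvenile depletion over the first rings.
#'
#' @param climate a [climate_table()] covering the configured years.
#' @param config a [sim_config()].
#' @return Named list of [isotope_series()] (two per tree).
#' @export
simulate_isotope_trees <- function(climate, config) {
  stopifnot(inherits(config, "sim_config"))
  yrs <- seq.int(config$years[1], config$years[2])
  p_july <- monthly_series(climate, "precipitation", "JUL", stat = "sum")
  t_july <- monthly_series(climate, "temperature", "JUL", stat = "mean")
  t_psep <- monthly_series(climate, "temperature", "prevSEP", stat = "mean")
  if (!all(yrs %in% p_july$year) || !all(yrs %in% t_july$year)) {
    stop("climate does not cover the configured years")
  }
  idx <- function(s) s$value[match(yrs, s$year)]
  P <- idx(p_july); TJ <- idx(t_july)
  TS <- t_psep$value[match(yrs, t_psep$year)]
  # first simulated year has no previous September: fall back to its own Sep
  if (is.na(TS[1])) {
    sep0 <- monthly_series(climate, "temperature", "SEP", stat = "mean")
    TS[1] <- sep0$value[match(yrs[1], sep0$year)]
  }

  atm <- simulate_atmospheric_co2(config)
  atm_anom <- (atm$delta13c_atm - config$atm_baseline)[match(yrs, atm$year)]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(sim_seed(config, "trees"))

  plan <- plan_lifespans(config)
  cp13 <- config$coupling$d13c; cp18 <- config$coupling$d18o
  eta13 <- stats::rnorm(length(yrs), 0, config$noise_sd_year[["d13c"]])
  eta18 <- stats::rnorm(length(yrs), 0, config$noise_sd_year[["d18o"]])
  common13 <- cp13[["intercept"]] + cp13[["p_july"]] * P +
    cp13[["t_prevsep"]] * TS + atm_anom + eta13
  common18 <- cp18[["intercept"]] + cp18[["t_july"]] * TJ +
    cp18[["t_prevsep"]] * TS + eta18

  out <- list()
  for (i in seq_len(nrow(plan))) {
    off13 <- stats::rnorm(1, 0, config$tree_offset_sd)
    off18 <- stats::rnorm(1, 0, config$tree_offset_sd)
    ty <- seq.int(plan$birth[i], plan$death[i])
    k <- match(ty, yrs)
    age <- seq_along(ty) - 1L
    juv <- -config$juvenile_amp * exp(-age / (config$juvenile_rings / 3))
    v13 <- common13[k] + off13 + juv +
      stats::rnorm(length(ty), 0, config$noise_sd_tree[["d13c"]])
    v18 <- common18[k] + off18 + juv +
      stats::rnorm(length(ty), 0, config$noise_sd_tree[["d18o"]])
    id <- plan$tree[i]
    out[[paste0(id, "_d13C")]] <- isotope_series(ty, v13, id, "d13C")
    out[[paste0(id, "_d18O")]] <- isotope_series(ty, v18, id, "d18O")
  }
  out
}

#' Simulate decadal lake-sediment proxies
#'
#' Decadal-resolution elemental and scatter-ratio records emulating a lake
#' sediment core: Co/Inc and Rb/Sr coupled to decadal-mean JJA precipitation,
#' Ca, Ti and Br/Sr coupled to decadal-mean JJA temperature, each with
#' additive noise sized so single-proxy correlations with their driver sit
#' near r = 0.6-0.75. Record years are decade starts (complete decades only).
#'
#' @param climate a [climate_table()] spanning at least two full decades.
#' @param config a [sim_config()].
#' @param noise_scale multiplier on all proxy noise SDs (0 = noise-free).
#' @return Named list of decadal [proxy_record()]s: `CoInc`, `RbSr`, `Ca`,
#'   `Ti`, `BrSr`.
#' @export
simulate_lake_proxies <- function(climate, config, noise_scale = 1) {
  stopifnot(inherits(config, "sim_config"))
  jja_p <- monthly_series(climate, "precipitation", c("JUN", "JUL", "AUG"), "sum")
  jja_t <- monthly_series(climate, "temperature", c("JUN", "JUL", "AUG"), "mean")
  dec <- function(s) {
    d <- (s$year %/% 10L) * 10L
    full <- names(which(table(d) == 10L))
    keep <- d %in% as.integer(full)
    agg <- tapply(s$value[keep], d[keep], mean)
    data.frame(year = as.integer(names(agg)), value = as.numeric(agg))
  }
  pd <- dec(jja_p); td <- dec(jja_t)
  if (nrow(pd) < 2L) stop("climate span too short: need at least two full decades")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(sim_seed(config, "lake"))
  n <- nrow(pd)
  ns <- noise_scale
  mk <- function(year, value, name) proxy_record(year, value, name, 10L)
  list(
    CoInc = mk(pd$year, 1.0 + 0.010 * pd$value + stats::rnorm(n, 0, 0.09 * ns), "CoInc"),
    RbSr  = mk(pd$year, 0.30 + 0.003 * pd$value + stats::rnorm(n, 0, 0.030 * ns), "RbSr"),
    Ca    = mk(td$year, 3000 + 600 * td$value + stats::rnorm(n, 0, 250 * ns), "Ca"),
    Ti    = mk(td$year, 1500 + 250 * td$value + stats::rnorm(n, 0, 120 * ns), "Ti"),
    BrSr  = mk(td$year, 0.05 + 0.020 * td$value + stats::rnorm(n, 0, 0.009 * ns), "BrSr")
  )
}

#' Simulate annual ring-parameter proxies (TRW, MXD)
#'
#' Annual tree-ring width and maximum latewood density records coupled to
#' JJA mean temperature, the classical summer-temperature-sensitive ring
#' parameters used alongside isotope chronologies in regional composites.
#'
#' @inheritParams simulate_lake_proxies
#' @return Named list of annual [proxy_record()]s `TRW` and `MXD`.
#' @export
simulate_ring_proxies <- function(climate, config, noise_scale = 1) {
  stopifnot(inherits(config, "sim_config"))
  jja_t <- monthly_series(climate, "temperature", c("JUN", "JUL", "AUG"), "mean")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(sim_seed(config, "rings"))
  n <- nrow(jja_t)
  list(
    TRW = proxy_record(jja_t$year,
                       1.0 + 0.12 * jja_t$value + stats::rnorm(n, 0, 0.12 * noise_scale),
                       "TRW", 1L),
    MXD = proxy_record(jja_t$year,
                       0.80 + 0.05 * jja_t$value + stats::rnorm(n, 0, 0.05 * noise_scale),
                       "MXD", 1L)
  )
}
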