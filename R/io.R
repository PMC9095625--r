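#' Read a typed series CSV
#'
#' Dispatches on the header row to one of the three declared schemas:
#' per-tree isotope series (`year,tree_id,isotope,value_permil`), monthly
#' climate (`year,month,variable,value`), or generic proxies
#' (`year,proxy,value,resolution_years`). Values are validated (numeric
#' years/values, months 1-12, no duplicate keys) and returned as the
#' package's typed containers. CSV dialect: comma-separated, UTF-8, `.`
#' decimal, mandatory header; per-mil values carry no symbol.
#'
#' @param path CSV file path.
#' @return A named list of [isotope_series()], a [climate_table()], or a
#'   named list of [proxy_record()]s, depending on the schema.
#' @export
read_series_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  hdr <- sort(names(d))
  if (identical(hdr, sort(c("year", "tree_id", "isotope", "value_permil")))) {
    return(parse_isotope_csv(d, path))
  }
  if (identical(hdr, sort(c("year", "month", "variable", "value")))) {
    return(climate_table(d))
  }
  if (identical(hdr, sort(c("year", "proxy", "value", "resolution_years")))) {
    return(parse_proxy_csv(d))
  }
  stop("unknown schema in ", path, ": header is ", paste(names(d), collapse = ","))
}

parse_isotope_csv <- function(d, path) {
  if (!is.numeric(d$year) || !is.numeric(d$value_permil)) {
    stop("non-numeric year or value in ", path)
  }
  key <- paste(d$year, d$tree_id, d$isotope)
  if (anyDuplicated(key)) {
    bad <- d$year[duplicated(key)][1L]
    stop("duplicate (year, tree_id) entry at year ", bad)
  }
  out <- list()
  for (id in unique(d$tree_id)) {
    for (iso in unique(d$isotope[d$tree_id == id])) {
      sub <- d[d$tree_id == id & d$isotope == iso, ]
      sub <- sub[order(sub$year), ]
      out[[paste0(id, "_", iso)]] <- isotope_series(sub$year, sub$value_permil,
                                                    id, iso)
    }
  }
  out
}

parse_proxy_csv <- function(d) {
  out <- list()
  for (nm in unique(d$proxy)) {
    sub <- d[d$proxy == nm, ]
    sub <- sub[order(sub$year), ]
    res <- unique(sub$resolution_years)
    if (length(res) != 1L) stop("inconsistent resolution for proxy ", nm)
    out[[nm]] <- proxy_record(sub$year, sub$value, nm, res)
  }
  out
}

#' Write the typed containers back to their CSV schemas
#'
#' @param x object to write: list of isotope series, a climate table, list
#'   of proxy records, a chronology, or an atmosphere record.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @name write_series_csv
NULL

#' @rdname write_series_csv
#' @export
write_isotope_csv <- function(x, path) {
  if (inherits(x, "isotope_series")) x <- list(x)
  long <- do.call(rbind, lapply(x, function(s) {
    data.frame(year = s$year, tree_id = attr(s, "tree_id"),
               isotope = attr(s, "isotope"), value_permil = s$value)
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
write_climate_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x)[c("year", "month", "variable", "value")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
write_proxy_csv <- function(x, path) {
  if (inherits(x, "proxy_record")) x <- list(x)
  long <- do.call(rbind, lapply(x, function(p) {
    data.frame(year = p$year, proxy = attr(p, "name"), value = p$value,
               resolution_years = attr(p, "resolution_years"))
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
write_chronology_csv <- function(x, path) {
  stopifnot(inherits(x, "chronology"))
  utils::write.csv(as.data.frame(x)[c("year", "mean", "n", "sd", "se")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
write_atmosphere_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x)[c("year", "delta13c_atm")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Assembles and validates every setting of the end-to-end pipeline run:
#' the simulation design (or input file paths), isotope-processing settings,
#' calibration targets and windows, smoothing width, epochs and extreme
#' thresholds.
#'
#' @param seed mandatory integer seed.
#' @param out_dir output directory for stage CSVs and the manifest.
#' @param years simulated year range (chronologies start `juvenile_rings`
#'   later).
#' @param n_trees number of simulated trees.
#' @param input_isotopes,input_climate,input_atmosphere,input_proxies
#'   optional CSV paths; when all are given the simulate stage is skipped.
#' @param juvenile_rings rings excluded from each tree (default 30).
#' @param suess_baseline Suess-correction baseline year (default 1800).
#' @param pyrolysis_correction apply [correct_pyrolysis()] to carbon input
#'   (for raw pyrolysis measurements; default FALSE).
#' @param cal_window,ver_window split-period windows (calibration /
#'   verification), disjoint.
#' @param smooth_width Hamming width (odd, default 101).
#' @param epochs epoch data.frame `name, start, end`.
#' @param extreme_sigma sigma threshold(s) for extremes: one value or
#'   `c(low, high)` (default 2.5).
#' @param sim overrides passed to [sim_config()] as a named list.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed, out_dir = tempfile("isoclim_run_"),
                            years = c(516L, 2016L), n_trees = 42L,
                            input_isotopes = NULL, input_climate = NULL,
                            input_atmosphere = NULL, input_proxies = NULL,
                            juvenile_rings = 30L, suess_baseline = 1800L,
                            pyrolysis_correction = FALSE,
                            cal_window = c(1970L, 2009L),
                            ver_window = c(1930L, 1969L),
                            smooth_width = 101L,
                            epochs = default_epochs(),
                            extreme_sigma = 2.5,
                            sim = list()) {
  if (missing(seed)) stop("seed is mandatory")
  if (cal_window[1] > cal_window[2] || ver_window[1] > ver_window[2]) {
    stop("calibration/verification windows must be well-ordered")
  }
  if (smooth_width %% 2L == 0L) stop("smooth_width must be odd")
  paths <- c(input_isotopes, input_climate, input_atmosphere, input_proxies)
  for (p in paths) if (!file.exists(p)) stop("input path does not exist: ", p)
  if (length(extreme_sigma) == 1L) extreme_sigma <- rep(extreme_sigma, 2L)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 years = as.integer(years), n_trees = as.integer(n_trees),
                 input_isotopes = input_isotopes, input_climate = input_climate,
                 input_atmosphere = input_atmosphere, input_proxies = input_proxies,
                 juvenile_rings = as.integer(juvenile_rings),
                 suess_baseline = as.integer(suess_baseline),
                 pyrolysis_correction = isTRUE(pyrolysis_correction),
                 cal_window = as.integer(cal_window),
                 ver_window = as.integer(ver_window),
                 smooth_width = as.integer(smooth_width),
                 epochs = epochs, extreme_sigma = extreme_sigma,
                 sim = sim),
            class = "pipeline_config")
}

#' Read a key-value pipeline configuration file
#'
#' Plain-text `key = value` lines (`#` comments allowed). Recognized keys
#' mirror the [pipeline_config()] arguments; ranges are written as
#' `start:end` and the seed is mandatory.
#'
#' @param path configuration file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[`, character(1), 2L))
  get1 <- function(k, default = NULL) if (k %in% keys) vals[match(k, keys)] else default
  rng <- function(v) as.integer(strsplit(v, ":", fixed = TRUE)[[1]])
  seed <- get1("seed")
  if (is.null(seed)) stop("config must set seed")
  args <- list(seed = as.integer(seed))
  if (!is.null(v <- get1("out_dir"))) args$out_dir <- v
  if (!is.null(v <- get1("years"))) args$years <- rng(v)
  if (!is.null(v <- get1("n_trees"))) args$n_trees <- as.integer(v)
  if (!is.null(v <- get1("juvenile_rings"))) args$juvenile_rings <- as.integer(v)
  if (!is.null(v <- get1("suess_baseline"))) args$suess_baseline <- as.integer(v)
  if (!is.null(v <- get1("cal_window"))) args$cal_window <- rng(v)
  if (!is.null(v <- get1("ver_window"))) args$ver_window <- rng(v)
  if (!is.null(v <- get1("smooth_width"))) args$smooth_width <- as.integer(v)
  if (!is.null(v <- get1("extreme_sigma"))) args$extreme_sigma <- as.numeric(v)
  for (k in c("input_isotopes", "input_climate", "input_atmosphere", "input_proxies")) {
    if (!is.null(v <- get1(k))) args[[k]] <- v
  }
  do.call(pipeline_config, args)
}

#' Run the full reconstruction pipeline
#'
#' Executes the stages in sequence: simulate (or read) inputs; build
#' corrected, juvenile-excluded chronologies for both isotopes; calibrate
#' July transfer functions and verify them on the split windows; apply,
#' smooth and classify the local reconstructions; harmonize the multi-proxy
#' sets and fit the regional JJA composites with variance shares. All stage
#' outputs are written as CSVs under `config$out_dir` and summarized in a
#' run manifest with per-file checksums; a fixed seed reproduces identical
#' checksums. Any stage failure aborts with the stage name and cause.
#'
#' @param config a [pipeline_config()].
#' @return A `run_manifest` list (also written as `manifest.txt`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- simulate / ingest -----------------------------------------------------
  inputs <- stage("simulate", {
    if (!is.null(config$input_isotopes) && !is.null(config$input_climate) &&
        !is.null(config$input_atmosphere) && !is.null(config$input_proxies)) {
      list(climate = read_series_csv(config$input_climate),
           trees = read_series_csv(config$input_isotopes),
           atm = {
             a <- utils::read.csv(config$input_atmosphere)
             atmospheric_co2_record(a$year, a$delta13c_atm)
           },
           proxies = read_series_csv(config$input_proxies),
           simulated = FALSE)
    } else {
      sc <- do.call(sim_config, c(list(seed = config$seed, years = config$years,
                                       n_trees = config$n_trees), config$sim))
      climate <- simulate_climate(sc)
      list(climate = climate,
           trees = simulate_isotope_trees(climate, sc),
           atm = simulate_atmospheric_co2(sc),
           proxies = c(simulate_lake_proxies(climate, sc),
                       simulate_ring_proxies(climate, sc)),
           simulated = TRUE)
    }
  })
  counts$climate_rows <- nrow(inputs$climate)
  counts$tree_series <- length(inputs$trees)

  # -- chronologies ----------------------------------------------------------
  chrons <- stage("build-chronology", {
    out <- list()
    for (iso in c("d13C", "d18O")) {
      ss <- Filter(function(s) attr(s, "isotope") == iso, inputs$trees)
      if (length(ss) == 0L) stop("no ", iso, " series in input")
      ss <- lapply(ss, exclude_juvenile, n_rings = config$juvenile_rings)
      if (iso == "d13C") {
        if (config$pyrolysis_correction) ss <- lapply(ss, correct_pyrolysis)
        ss <- lapply(ss, correct_suess, atm = inputs$atm,
                     baseline_year = config$suess_baseline)
      }
      out[[iso]] <- build_chronology(ss)
    }
    out
  })
  counts$chronology_years <- vapply(chrons, nrow, integer(1))

  # -- calibrate -------------------------------------------------------------
  cal <- stage("calibrate", {
    full_cal <- range(c(config$cal_window, config$ver_window))
    m13 <- fit_transfer(chrons$d13C, inputs$climate, "precipitation:JUL",
                        window = full_cal)
    m18 <- fit_transfer(chrons$d18O, inputs$climate, "temperature:JUL",
                        window = full_cal)
    p_july <- monthly_series(inputs$climate, "precipitation", "JUL", "sum")
    t_july <- monthly_series(inputs$climate, "temperature", "JUL", "mean")
    list(m13 = m13, m18 = m18,
         v13 = split_verify(chrons$d13C, p_july, config$cal_window, config$ver_window),
         v18 = split_verify(chrons$d18O, t_july, config$cal_window, config$ver_window))
  })

  # -- reconstruct -----------------------------------------------------------
  rec <- stage("reconstruct", {
    r13 <- apply_transfer(cal$m13, chrons$d13C)
    r18 <- apply_transfer(cal$m18, chrons$d18O)
    list(
      precip = r13, temp = r18,
      precip_smooth = hamming_smooth(r13, config$smooth_width),
      temp_smooth = hamming_smooth(r18, config$smooth_width),
      precip_events = classify_anomalies(r13, config$extreme_sigma[1],
                                         config$extreme_sigma[2]),
      temp_events = classify_anomalies(r18, config$extreme_sigma[1],
                                       config$extreme_sigma[2]),
      precip_epochs = epoch_stats(r13, clip_epochs(config$epochs, r13)),
      temp_epochs = epoch_stats(r18, clip_epochs(config$epochs, r18))
    )
  })

  # -- composite -------------------------------------------------------------
  comp <- stage("composite", {
    d13_rec <- proxy_record(chrons$d13C$year, chrons$d13C$mean, "d13C", 1L)
    d18_rec <- proxy_record(chrons$d18O$year, chrons$d18O$mean, "d18O", 1L)
    px <- inputs$proxies
    mat_p <- harmonize_proxies(list(d13C = d13_rec, CoInc = px$CoInc,
                                    RbSr = px$RbSr), "annual")
    mat_t <- harmonize_proxies(list(d18O = d18_rec, TRW = px$TRW, MXD = px$MXD,
                                    Ca = px$Ca, Ti = px$Ti, BrSr = px$BrSr),
                               "annual")
    p_jja <- monthly_series(inputs$climate, "precipitation",
                            c("JUN", "JUL", "AUG"), "sum")
    t_jja <- monthly_series(inputs$climate, "temperature",
                            c("JUN", "JUL", "AUG"), "mean")
    cm_p <- fit_composite(p_jja, mat_p, window = config$cal_window)
    cm_t <- fit_composite(t_jja, mat_t, window = config$cal_window)
    list(model_p = cm_p, model_t = cm_t,
         recon_p = apply_composite(cm_p, mat_p),
         recon_t = apply_composite(cm_t, mat_t),
         rbar_p = mean_pairwise_correlation(list(d13C = d13_rec, CoInc = px$CoInc,
                                                 RbSr = px$RbSr)))
  })

  # -- write outputs ---------------------------------------------------------
  files <- stage("write", {
    od <- config$out_dir
    f <- character(0)
    wr <- function(obj, name, writer = utils::write.csv) {
      p <- file.path(od, name)
      if (is.function(writer) && identical(writer, utils::write.csv)) {
        utils::write.csv(obj, p, row.names = FALSE, quote = FALSE)
      } else writer(obj, p)
      f <<- c(f, p)
    }
    if (inputs$simulated) {
      wr(inputs$climate, "climate.csv", write_climate_csv)
      wr(inputs$trees, "isotopes.csv", write_isotope_csv)
      wr(inputs$atm, "atmosphere.csv", write_atmosphere_csv)
      wr(inputs$proxies, "proxies.csv", write_proxy_csv)
    }
    wr(chrons$d13C, "chronology_d13C.csv", write_chronology_csv)
    wr(chrons$d18O, "chronology_d18O.csv", write_chronology_csv)
    recon_df <- function(r, s) cbind(as.data.frame(r), smoothed = s$value)
    wr(recon_df(rec$precip, rec$precip_smooth), "reconstruction_precip_july.csv")
    wr(recon_df(rec$temp, rec$temp_smooth), "reconstruction_temp_july.csv")
    wr(as.data.frame(rec$precip_events), "events_precip.csv")
    wr(as.data.frame(rec$temp_events), "events_temp.csv")
    wr(as.data.frame(rec$precip_epochs), "epochs_precip.csv")
    wr(as.data.frame(rec$temp_epochs), "epochs_temp.csv")
    wr(as.data.frame(comp$recon_p), "regional_precip_jja.csv")
    wr(as.data.frame(comp$recon_t), "regional_temp_jja.csv")
    wr(comp$model_p$variance_shares, "shares_precip.csv")
    wr(comp$model_t$variance_shares, "shares_temp.csv")
    f
  })

  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("isoclim")),
    seed = config$seed,
    settings = list(eps_formula = "Wigley: N*rbar/(N*rbar + 1 - rbar)",
                    smoothing_edge_rule = "truncate-and-renormalize",
                    harmonization = "decadal->annual linear interpolation",
                    juvenile_rings = config$juvenile_rings,
                    suess_baseline = config$suess_baseline,
                    cal_window = config$cal_window,
                    ver_window = config$ver_window,
                    smooth_width = config$smooth_width,
                    extreme_sigma = config$extreme_sigma),
    counts = counts,
    calibration = list(r_d13C_precip_july = cal$m13$stats$r,
                       r_d18O_temp_july = cal$m18$stats$r,
                       RE_precip = cal$v13$RE, CE_precip = cal$v13$CE,
                       RE_temp = cal$v18$RE, CE_temp = cal$v18$CE),
    composite = list(r2_precip = comp$model_p$stats$r2,
                     r2_temp = comp$model_t$stats$r2,
                     rbar_precip_proxies = comp$rbar_p),
    checksums = tools::md5sum(files),
    warnings = warnings_log
  ), class = "run_manifest")

  writeLines(format_manifest(manifest), file.path(config$out_dir, "manifest.txt"))
  manifest
}

clip_epochs <- function(epochs, series) {
  d <- as_year_series(series)
  e <- epochs[epochs$start <= max(d$year) & epochs$end >= min(d$year), ]
  if (nrow(e) == 0L) stop("no epoch overlaps the reconstruction span")
  e
}

format_manifest <- function(m) {
  flat <- function(x) paste(unlist(x), collapse = " ")
  c(sprintf("isoclim %s seed=%d", m$package_version, m$seed),
    paste0("setting ", names(m$settings), " = ",
           vapply(m$settings, flat, character(1))),
    paste0("count ", names(m$counts), " = ",
           vapply(m$counts, flat, character(1))),
    paste0("calibration ", names(m$calibration), " = ",
           vapply(m$calibration, function(v) sprintf("%.6f", v), character(1))),
    paste0("composite ", names(m$composite), " = ",
           vapply(m$composite, function(v) sprintf("%.6f", v), character(1))),
    paste0("checksum ", basename(names(m$checksums)), " = ", m$checksums),
    if (length(m$warnings)) paste0("warning ", m$warnings) else character(0))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(format_manifest(x), sep = "\n")
  invisible(x)
}
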