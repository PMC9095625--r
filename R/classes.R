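#' Monthly station climate table
#'
#' Long-format container for monthly station observations: one row per
#' (year, month, variable). Variables follow the conventions of
#' high-elevation dendroclimatic calibration work: air temperature (degrees
#' C), precipitation totals (mm), vapour pressure deficit (hPa) and sunshine
#' duration (hours).
#'
#' @param records data.frame with columns `year`, `month`, `variable`,
#'   `value`.
#' @param station_id character station label.
#' @param elevation_m station elevation in metres.
#' @return A `climate_table`: the validated data.frame with station metadata
#'   attached as attributes.
#' @export
climate_table <- function(records, station_id = "unknown", elevation_m = NA_real_) {
  req <- c("year", "month", "variable", "value")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    stop("`records` must be a data.frame with columns year, month, variable, value")
  }
  records <- records[req]
  records$year <- as.integer(records$year)
  records$month <- as.integer(records$month)
  records$value <- as.numeric(records$value)
  if (anyNA(records$year) || anyNA(records$month)) {
    stop("non-numeric year or month in climate records")
  }
  if (any(records$month < 1L | records$month > 12L)) {
    stop("climate months must lie in 1-12")
  }
  key <- paste(records$year, records$month, records$variable)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (year, month, variable) entry: ", dup)
  }
  prec <- records$variable == "precipitation"
  if (any(prec & !is.na(records$value) & records$value < 0)) {
    stop("precipitation values must be >= 0")
  }
  records <- records[order(records$variable, records$year, records$month), , drop = FALSE]
  rownames(records) <- NULL
  structure(records,
            station_id = station_id,
            elevation_m = elevation_m,
            class = c("climate_table", "data.frame"))
}

#' @export
print.climate_table <- function(x, ...) {
  cat(sprintf("<climate_table> station %s (%.0f m), %d records\n",
              attr(x, "station_id"), attr(x, "elevation_m"), nrow(x)))
  cat("  years:", min(x$year), "-", max(x$year),
      "| variables:", paste(sort(unique(x$variable)), collapse = ", "), "\n")
  invisible(x)
}

#' Annual stable-isotope series for a single tree
#'
#' One tree's annual per-mil values for one isotope kind. Carbon values are
#' on the VPDB scale, oxygen values on the VSMOW scale; files and objects
#' carry plain numbers without the per-mil symbol.
#'
#' @param year integer CE years, strictly increasing.
#' @param value per-mil values.
#' @param tree_id character tree label.
#' @param isotope `"d13C"` or `"d18O"`.
#' @return An `isotope_series` data.frame with columns `year`, `value`.
#' @export
isotope_series <- function(year, value, tree_id, isotope = c("d13C", "d18O")) {
  isotope <- match.arg(isotope)
  year <- as.integer(year)
  value <- as.numeric(value)
  if (length(year) != length(value)) stop("year and value lengths differ")
  if (length(year) == 0L) stop("empty isotope series")
  if (anyNA(year)) stop("non-integer year in isotope series")
  if (is.unsorted(year, strictly = TRUE)) {
    stop("years must be strictly increasing with no duplicates (tree ", tree_id, ")")
  }
  structure(data.frame(year = year, value = value),
            tree_id = as.character(tree_id),
            isotope = isotope,
            class = c("isotope_series", "data.frame"))
}

#' @export
print.isotope_series <- function(x, ...) {
  cat(sprintf("<isotope_series> tree %s, %s, %d rings (%d-%d)\n",
              attr(x, "tree_id"), attr(x, "isotope"), nrow(x),
              min(x$year), max(x$year)))
  invisible(x)
}

#' Proxy record at annual or coarser resolution
#'
#' Generic year-value record for any climate proxy: tree-ring width (TRW),
#' maximum latewood density (MXD), isotope chronologies, or decadal lake
#' sediment series (Co/Inc scatter ratio, Rb/Sr, Ca, Ti, Br/Sr).
#'
#' @param year integer years (for decadal records, the first year of each
#'   block).
#' @param value proxy values, in native units.
#' @param name proxy label, e.g. `"TRW"`, `"RbSr"`.
#' @param resolution_years record resolution: 1 for annual, 10 for decadal.
#' @export
proxy_record <- function(year, value, name, resolution_years = 1L) {
  year <- as.integer(year)
  value <- as.numeric(value)
  if (length(year) != length(value) || length(year) == 0L) {
    stop("year and value must be non-empty and of equal length")
  }
  if (is.unsorted(year, strictly = TRUE)) {
    stop("proxy years must be strictly increasing (", name, ")")
  }
  resolution_years <- as.integer(resolution_years)
  if (is.na(resolution_years) || resolution_years < 1L) {
    stop("resolution_years must be >= 1")
  }
  structure(data.frame(year = year, value = value),
            name = as.character(name),
            resolution_years = resolution_years,
            class = c("proxy_record", "data.frame"))
}

#' @export
print.proxy_record <- function(x, ...) {
  cat(sprintf("<proxy_record> %s, %d values (%d-%d), resolution %d yr\n",
              attr(x, "name"), nrow(x), min(x$year), max(x$year),
              attr(x, "resolution_years")))
  invisible(x)
}

#' Atmospheric delta13C-of-CO2 history
#'
#' Year-indexed per-mil values of atmospheric CO2 delta13C (VPDB), used to
#' remove the industrial-era Suess-effect decline from plant carbon-isotope
#' records.
#'
#' @param year integer CE years, strictly increasing.
#' @param delta13c_atm per-mil values.
#' @export
atmospheric_co2_record <- function(year, delta13c_atm) {
  year <- as.integer(year)
  delta13c_atm <- as.numeric(delta13c_atm)
  if (length(year) != length(delta13c_atm) || length(year) == 0L) {
    stop("year and delta13c_atm must be non-empty and of equal length")
  }
  if (is.unsorted(year, strictly = TRUE)) stop("atmosphere years must be strictly increasing")
  structure(data.frame(year = year, delta13c_atm = delta13c_atm),
            class = c("atmospheric_co2_record", "data.frame"))
}

# Coerce the year-indexed inputs the statistics functions accept (chronology,
# reconstruction, proxy_record, plain data.frame, or named numeric vector)
# into a two-column data.frame(year, value).
as_year_series <- function(x, value_col = NULL) {
  if (inherits(x, "chronology")) {
    return(data.frame(year = x$year, value = x$mean))
  }
  if (is.data.frame(x)) {
    if (!("year" %in% names(x))) stop("year-indexed input needs a `year` column")
    vc <- value_col
    if (is.null(vc)) {
      vc <- intersect(c("value", "mean"), names(x))[1L]
      if (is.na(vc)) stop("cannot find a value column in year-indexed input")
    }
    return(data.frame(year = as.integer(x$year), value = as.numeric(x[[vc]])))
  }
  if (is.numeric(x) && !is.null(names(x))) {
    return(data.frame(year = as.integer(names(x)), value = as.numeric(x)))
  }
  stop("cannot interpret input as a year-indexed series")
}

# Inner-join two year series, complete pairs only.
align_years <- function(a, b) {
  a <- as_year_series(a)
  b <- as_year_series(b)
  m <- merge(a, b, by = "year", suffixes = c("_a", "_b"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  m[order(m$year), , drop = FALSE]
}
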