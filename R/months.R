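MONTH_ABBR <- c("JAN", "FEB", "MAR", "APR", "MAY", "JUN",
                "JUL", "AUG", "SEP", "OCT", "NOV", "DEC")

#' Parse a month specification
#'
#' Month specifications name a calendar month of either the growth year
#' (`"JUL"`) or the previous year (`"prevSEP"`). Previous-year months align
#' climate year y-1 with proxy year y, the convention for carry-over effects
#' of late-season conditions on the next ring.
#'
#' @param spec character like `"JUL"` or `"prevSEP"` (case-insensitive), or
#'   an integer month 1-12.
#' @return list with elements `month` (1-12), `lag` (0 or 1) and `label`.
#' @export
parse_month_spec <- function(spec) {
  if (is.numeric(spec)) {
    m <- as.integer(spec)
    if (is.na(m) || m < 1L || m > 12L) stop("month must lie in 1-12")
    return(list(month = m, lag = 0L, label = MONTH_ABBR[m]))
  }
  s <- toupper(trimws(as.character(spec)))
  lag <- 0L
  if (startsWith(s, "PREV")) {
    lag <- 1L
    s <- sub("^PREV", "", s)
  }
  m <- match(s, MONTH_ABBR)
  if (is.na(m)) stop("unknown month specification: ", spec)
  list(month = m, lag = lag,
       label = if (lag) paste0("prev", MONTH_ABBR[m]) else MONTH_ABBR[m])
}

#' Extract an annual series from a monthly climate table
#'
#' Aggregates one climate variable over a set of months into a year-indexed
#' series. Previous-year months (e.g. `"prevSEP"`) take the value from
#' climate year y-1 and assign it to year y. Years with any requested month
#' missing are dropped.
#'
#' @param climate a [climate_table()].
#' @param variable one of the variables present in the table.
#' @param months vector of month specifications (see [parse_month_spec()]).
#' @param stat `"mean"` (temperature-like) or `"sum"` (precipitation totals).
#' @return data.frame with columns `year`, `value`.
#' @export
monthly_series <- function(climate, variable, months, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  if (!variable %in% unique(climate$variable)) {
    stop("variable not present in climate table: ", variable)
  }
  specs <- lapply(months, parse_month_spec)
  sub <- climate[climate$variable == variable, c("year", "month", "value")]
  cols <- lapply(specs, function(sp) {
    rows <- sub[sub$month == sp$month, ]
    # climate year y - lag feeds proxy/target year y
    data.frame(year = rows$year + sp$lag, v = rows$value)
  })
  out <- Reduce(function(a, b) merge(a, b, by = "year"), lapply(seq_along(cols), function(i) {
    d <- cols[[i]]
    names(d)[2] <- paste0("v", i)
    d
  }))
  out <- out[stats::complete.cases(out), , drop = FALSE]
  if (nrow(out) == 0L) stop("no complete years for ", variable)
  vals <- as.matrix(out[, -1, drop = FALSE])
  data.frame(year = out$year,
             value = if (stat == "mean") rowMeans(vals) else rowSums(vals))
}
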