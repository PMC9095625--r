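#' Apply a transfer model over the full proxy period
#'
#' Maps each chronology year through the fitted linear transfer,
#' `value(y) = intercept + slope * proxy(y)`, with a constant uncertainty
#' band of plus/minus the calibration standard error of estimate. The band
#' is the flat regression SEE, not a prediction interval widening away from
#' the calibration mean (a deliberate simplification; see the package
#' vignette).
#'
#' @param model a [fit_transfer()] result.
#' @param chronology the proxy chronology to project; its isotope/name must
#'   match the model's predictor unless either is generic.
#' @return A `reconstruction` data.frame `year, value, se_low, se_high` with
#'   the target label attached.
#' @export
apply_transfer <- function(model, chronology) {
  stopifnot(inherits(model, "transfer_model"))
  prox_name <- if (inherits(chronology, "chronology")) {
    attr(chronology, "isotope")
  } else "proxy"
  if (model$predictor != "proxy" && prox_name != "proxy" &&
      model$predictor != prox_name) {
    stop("model predictor (", model$predictor, ") does not match chronology (",
         prox_name, ")")
  }
  d <- as_year_series(chronology)
  v <- model$intercept + model$slope * d$value
  structure(data.frame(year = d$year, value = v,
                       se_low = v - model$stats$see,
                       se_high = v + model$stats$see),
            target = model$target, model = model,
            class = c("reconstruction", "data.frame"))
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("<reconstruction> %s, %d years (%d-%d), mean %.2f\n",
              attr(x, "target"), nrow(x), min(x$year), max(x$year),
              mean(x$value)))
  invisible(x)
}

#' Hamming window weights
#'
#' Raw (unnormalized) Hamming weights
#' `w_k = 0.54 - 0.46 * cos(2*pi*k/(width-1))`, `k = 0, ..., width-1`.
#'
#' @param width odd window length >= 3.
#' @export
hamming_window <- function(width) {
  width <- as.integer(width)
  if (width < 3L || width %% 2L == 0L) stop("width must be odd and >= 3")
  k <- seq_len(width) - 1L
  0.54 - 0.46 * cos(2 * pi * k / (width - 1L))
}

#' Centered Hamming smoothing
#'
#' Weighted centered moving mean with Hamming weights normalized to sum 1,
#' the standard low-pass used to emphasize centennial-scale variability in
#' millennial series (width 101 by default). At the series edges the window
#' is truncated and the remaining weights renormalized, so the output spans
#' the full input period with no padding.
#'
#' @param series year-indexed series (chronology, reconstruction, `year,
#'   value` data.frame) or plain numeric vector.
#' @param width odd window length (default 101).
#' @return Same shape as the input: a data.frame `year, value` for
#'   year-indexed input, a numeric vector otherwise.
#' @export
hamming_smooth <- function(series, width = 101L) {
  w <- hamming_window(width)
  h <- (length(w) - 1L) %/% 2L
  smooth_vec <- function(x) {
    n <- length(x)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - h); hi <- min(n, i + h)
      wk <- w[(lo - i + h + 1L):(hi - i + h + 1L)]
      out[i] <- sum(wk * x[lo:hi]) / sum(wk)
    }
    out
  }
  if (is.numeric(series) && is.null(names(series))) {
    return(smooth_vec(series))
  }
  d <- as_year_series(series)
  data.frame(year = d$year, value = smooth_vec(d$value))
}

#' Linear trend of a year-indexed series
#'
#' OLS slope of value on year over a window, with its two-sided p value.
#' By reporting convention only slopes with p < 0.05 are flagged
#' significant and worth discussing.
#'
#' @param series year-indexed series.
#' @param window optional inclusive year range.
#' @param min_years minimum years required (default 10).
#' @return list `slope` (units/yr), `p`, `significant`, `n`.
#' @export
linear_trend <- function(series, window = NULL, min_years = 10L) {
  d <- as_year_series(series)
  if (!is.null(window)) d <- d[d$year >= window[1] & d$year <= window[2], ]
  if (nrow(d) < min_years) stop("window too short: ", nrow(d), " years")
  if (stats::sd(d$value) == 0) {
    return(list(slope = 0, p = 1, significant = FALSE, n = nrow(d)))
  }
  fit <- stats::lm(value ~ year, data = d)
  p <- summary(fit)$coefficients[2, 4]
  list(slope = unname(stats::coef(fit)[2]), p = p,
       significant = p < 0.05, n = nrow(d))
}

#' Shipped climatic epoch definitions
#'
#' The four conventional Common-Era epochs used to contextualize recent
#' change: Late Antique Little Ice Age (LALIA, 516-800 CE), Medieval Warm
#' Period (MWP, 800-1300 CE), Little Ice Age (LIA, 1400-1900 CE) and the
#' Recent Period (RP, 1900-2016 CE). The 1300-1400 CE interval belongs to no
#' epoch under these definitions and is deliberately left unassigned.
#'
#' @return data.frame `name, start, end`.
#' @export
default_epochs <- function() {
  data.frame(name = c("LALIA", "MWP", "LIA", "RP"),
             start = c(516L, 800L, 1400L, 1900L),
             end = c(800L, 1300L, 1900L, 2016L))
}

#' Per-epoch statistics of a reconstruction
#'
#' Mean, extremes (with their years), linear trend and significance per
#' named epoch, plus all pairwise epoch-mean differences.
#'
#' @param recon a reconstruction or any year-indexed series.
#' @param epochs data.frame `name, start, end`; defaults to
#'   [default_epochs()] clipped to the series span.
#' @return data.frame (class `epoch_table`) with one row per epoch and a
#'   `pairwise_diff` attribute (matrix of row mean minus column mean).
#' @export
epoch_stats <- function(recon, epochs = NULL) {
  d <- as_year_series(recon)
  if (is.null(epochs)) {
    epochs <- default_epochs()
    epochs <- epochs[epochs$start <= max(d$year) & epochs$end >= min(d$year), ]
  }
  if (nrow(epochs) == 0L) stop("no epochs to evaluate")
  rows <- lapply(seq_len(nrow(epochs)), function(i) {
    e <- d[d$year >= epochs$start[i] & d$year <= epochs$end[i], ]
    if (nrow(e) == 0L) stop("empty epoch: ", epochs$name[i])
    tr <- if (nrow(e) >= 10L) linear_trend(e) else list(slope = NA_real_, p = NA_real_)
    i_min <- which.min(e$value); i_max <- which.max(e$value)
    data.frame(name = epochs$name[i], start = epochs$start[i], end = epochs$end[i],
               n = nrow(e), mean = mean(e$value),
               min = e$value[i_min], min_year = e$year[i_min],
               max = e$value[i_max], max_year = e$year[i_max],
               trend_slope = tr$slope, trend_p = tr$p)
  })
  out <- do.call(rbind, rows)
  pw <- outer(out$mean, out$mean, "-")
  dimnames(pw) <- list(out$name, out$name)
  structure(out, pairwise_diff = pw, class = c("epoch_table", "data.frame"))
}

#' Percent change between two windows
#'
#' `100 * (mean(recent) - mean(reference)) / mean(reference)`: the headline
#' arithmetic for statements like "precipitation declined by 49% in the
#' recent window relative to the preceding millennium".
#'
#' @param recon year-indexed series.
#' @param window_recent,window_reference inclusive year ranges.
#' @return Percent change (negative for a decline).
#' @export
percent_change <- function(recon, window_recent, window_reference) {
  d <- as_year_series(recon)
  pick <- function(w) {
    v <- d$value[d$year >= w[1] & d$year <= w[2]]
    if (length(v) == 0L) stop("empty window ", w[1], "-", w[2])
    v
  }
  m_rec <- mean(pick(window_recent))
  m_ref <- mean(pick(window_reference))
  if (m_ref == 0) stop("reference mean is zero")
  100 * (m_rec - m_ref) / m_ref
}
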