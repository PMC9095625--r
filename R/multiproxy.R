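#' Harmonize mixed-resolution proxies onto a common grid
#'
#' Aligns annual tree-ring records and decadal lake-sediment records into a
#' year-by-proxy matrix. In `"annual"` mode (default) coarser records are
#' linearly interpolated between their record years; in `"decadal"` mode
#' finer records are block-averaged into complete decades. The result has
#' no missing cells inside the common span.
#'
#' @param records named list of [proxy_record()]s (chronologies and plain
#'   `year, value` data.frames are accepted and treated as annual).
#' @param resolution `"annual"` or `"decadal"`.
#' @return data.frame with a `year` column and one column per proxy,
#'   restricted to the common complete span.
#' @export
harmonize_proxies <- function(records, resolution = c("annual", "decadal")) {
  resolution <- match.arg(resolution)
  if (length(records) < 1L) stop("no proxy records")
  nm <- names(records)
  if (is.null(nm) || any(nm == "")) {
    nm <- vapply(seq_along(records), function(i) {
      n <- attr(records[[i]], "name")
      if (is.null(n)) paste0("proxy", i) else n
    }, character(1))
  }
  cols <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    res <- attr(rec, "resolution_years")
    if (is.null(res)) res <- 1L
    d <- as_year_series(rec)
    if (resolution == "annual") {
      if (res > 1L) {
        yrs <- seq.int(min(d$year), max(d$year))
        d <- data.frame(year = yrs,
                        value = stats::approx(d$year, d$value, xout = yrs,
                                              rule = 1)$y)
      }
    } else {
      if (res == 1L) {
        dec <- (d$year %/% 10L) * 10L
        full <- as.integer(names(which(table(dec) == 10L)))
        keep <- dec %in% full
        agg <- tapply(d$value[keep], dec[keep], mean)
        d <- data.frame(year = as.integer(names(agg)), value = as.numeric(agg))
      }
    }
    names(d)[2] <- nm[i]
    d
  })
  out <- Reduce(function(a, b) merge(a, b, by = "year"), cols)
  out <- out[stats::complete.cases(out), , drop = FALSE]
  if (nrow(out) == 0L) stop("proxy records have disjoint spans")
  rownames(out) <- NULL
  out
}

#' Fit a multi-proxy composite transfer model
#'
#' OLS of the climate target on z-scored predictors over a calibration
#' window. Predictors are standardized with calibration-window means and
#' SDs only, so applying the model over the full proxy span leaks no
#' information from the reconstruction period. Per-predictor explained
#' variance shares are computed by averaged-over-orderings incremental
#' R-squared ([variance_partition()]).
#'
#' @param target year-indexed climate series.
#' @param matrix a [harmonize_proxies()] result (year column + predictors).
#' @param window calibration year range `c(first, last)`; default the full
#'   overlap.
#' @param min_rows minimum complete calibration rows (default 10).
#' @param max_condition collinearity guard on the standardized predictor
#'   matrix condition number (default 1e6); the two most correlated
#'   predictors are named when it trips.
#' @return A `composite_model` list.
#' @export
fit_composite <- function(target, matrix, window = NULL, min_rows = 10L,
                          max_condition = 1e6) {
  tg <- as_year_series(target)
  preds <- setdiff(names(matrix), "year")
  if (length(preds) < 1L) stop("need at least one predictor")
  mm <- merge(tg, matrix, by = "year")
  mm <- mm[stats::complete.cases(mm), , drop = FALSE]
  cal <- if (is.null(window)) mm else mm[mm$year >= window[1] & mm$year <= window[2], ]
  if (nrow(cal) < min_rows) {
    stop("only ", nrow(cal), " complete calibration rows; need >= ", min_rows)
  }
  ctr <- vapply(preds, function(p) mean(cal[[p]]), numeric(1))
  scl <- vapply(preds, function(p) stats::sd(cal[[p]]), numeric(1))
  if (any(scl == 0)) {
    stop("degenerate predictor (zero variance): ", preds[which(scl == 0)[1]])
  }
  Z <- sweep(sweep(as.matrix(cal[preds]), 2, ctr), 2, scl, "/")
  if (length(preds) > 1L) {
    kp <- kappa(Z, exact = TRUE)
    if (kp > max_condition) {
      cm <- abs(stats::cor(Z)); diag(cm) <- 0
      worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      stop("collinear predictors (condition number ", format(kp, digits = 3),
           "): ", preds[worst[1]], " and ", preds[worst[2]])
    }
  }
  df_cal <- data.frame(.y = cal$value, Z, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df_cal)
  sm <- summary(fit)
  n <- nrow(cal); p <- length(preds)
  r2 <- sm$r.squared
  part <- lmg_partition(cal$value, Z)
  tlabel <- if (is.character(attr(target, "target"))) attr(target, "target") else "target"
  structure(list(
    target = tlabel,
    predictors = preds,
    coefficients = stats::coef(fit),
    scaling = list(center = ctr, scale = scl),
    calibration_window = range(cal$year),
    variance_shares = part,
    stats = list(r = stats::cor(stats::fitted(fit), cal$value),
                 r2 = r2,
                 F = unname(sm$fstatistic[1]),
                 df = c(p, n - p - 1L),
                 p = stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                               sm$fstatistic[3], lower.tail = FALSE),
                 see = sm$sigma, n = n)
  ), class = "composite_model")
}

#' @export
print.composite_model <- function(x, ...) {
  cat(sprintf("<composite_model> %s ~ %s  (%d-%d, n = %d)\n", x$target,
              paste(x$predictors, collapse = " + "),
              x$calibration_window[1], x$calibration_window[2], x$stats$n))
  cat(sprintf("  R2 = %.2f, F = %.2f, df = (%d, %d), p = %.2g, SEE = %.3f\n",
              x$stats$r2, x$stats$F, x$stats$df[1], x$stats$df[2],
              x$stats$p, x$stats$see))
  vs <- x$variance_shares
  cat("  explained-variance shares (%):",
      paste(sprintf("%s %.0f", vs$predictor, vs$lmg_pct), collapse = ", "), "\n")
  invisible(x)
}

#' Apply a composite model over the full proxy span
#'
#' Standardizes the harmonized matrix with the model's calibration-window
#' scaling and evaluates the fitted regression for every complete row,
#' yielding the regional reconstruction with a flat SEE band.
#'
#' @param model a [fit_composite()] result.
#' @param matrix a harmonized matrix containing all model predictors.
#' @return A `reconstruction` data.frame `year, value, se_low, se_high`.
#' @export
apply_composite <- function(model, matrix) {
  stopifnot(inherits(model, "composite_model"))
  miss <- setdiff(model$predictors, names(matrix))
  if (length(miss)) stop("matrix lacks predictors: ", paste(miss, collapse = ", "))
  X <- as.matrix(matrix[model$predictors])
  Z <- sweep(sweep(X, 2, model$scaling$center), 2, model$scaling$scale, "/")
  v <- as.numeric(model$coefficients[1] + Z %*% model$coefficients[-1])
  structure(data.frame(year = matrix$year, value = v,
                       se_low = v - model$stats$see,
                       se_high = v + model$stats$see),
            target = model$target, model = model,
            class = c("reconstruction", "data.frame"))
}

# R-squared of target on a subset of standardized predictor columns.
subset_r2 <- function(y, Z, idx) {
  if (length(idx) == 0L) return(0)
  fit <- stats::lm.fit(cbind(1, Z[, idx, drop = FALSE]), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

# combn() treats a length-1 x as seq_len(x); this wrapper keeps subset
# enumeration literal.
comb_list <- function(x, m) {
  if (m == 0L) return(list(integer(0)))
  if (length(x) == 1L) return(if (m == 1L) list(x) else list())
  utils::combn(x, m, simplify = FALSE)
}

# LMG relative importance: Shapley-weighted average of the incremental
# R-squared of each predictor over all orderings, computed by subset
# enumeration (2^p subsets; guarded at p <= 8).
lmg_partition <- function(y, Z) {
  p <- ncol(Z)
  if (p > 8L) stop("variance partition enumeration guard: > 8 predictors")
  preds <- colnames(Z)
  r2s <- new.env()
  key <- function(idx) paste0("s", paste(sort(idx), collapse = ","))
  all_idx <- seq_len(p)
  for (s in 0:p) {
    for (cc in comb_list(all_idx, s)) {
      assign(key(cc), subset_r2(y, Z, cc), envir = r2s)
    }
  }
  raw <- numeric(p)
  for (j in all_idx) {
    others <- setdiff(all_idx, j)
    tot <- 0
    for (s in 0:length(others)) {
      combs <- comb_list(others, s)
      w <- factorial(s) * factorial(p - 1L - s) / factorial(p)
      for (cc in combs) {
        tot <- tot + w * (get(key(c(cc, j)), envir = r2s) -
                            get(key(cc), envir = r2s))
      }
    }
    raw[j] <- tot
  }
  full <- get(key(all_idx), envir = r2s)
  marg <- vapply(all_idx, function(j) get(key(j), envir = r2s), numeric(1))
  # incremental R2 of each predictor given all others, the other bookend
  incr <- vapply(all_idx, function(j) {
    full - get(key(setdiff(all_idx, j)), envir = r2s)
  }, numeric(1))
  data.frame(predictor = preds,
             lmg_r2 = raw,
             lmg_pct = 100 * raw / full,
             marginal_r2 = marg,
             last_r2 = incr)
}

#' Per-predictor explained-variance shares
#'
#' Decomposes a composite model's explained variance into per-predictor
#' shares by the LMG method: the incremental R-squared of each predictor is
#' averaged over all orderings in which predictors can enter the model, and
#' the averages (which sum to the full R-squared) are normalized to 100% of
#' explained variance. For orthogonal predictors this reduces to marginal
#' R-squared ratios. Raw marginal and last-entry incremental R-squared are
#' reported alongside, since published share tables do not always state
#' their decomposition.
#'
#' @param model a [fit_composite()] result (the shares are recomputed from
#'   its stored calibration scaling), or `NULL` to use `matrix`/`target`
#'   directly.
#' @param matrix,target optional harmonized matrix and target series; when
#'   given with a model, shares are computed over the model's calibration
#'   window of these data.
#' @return data.frame `predictor, lmg_r2, lmg_pct, marginal_r2, last_r2`.
#' @export
variance_partition <- function(model = NULL, matrix = NULL, target = NULL) {
  if (is.null(model)) {
    if (is.null(matrix) || is.null(target)) {
      stop("supply a composite model, or matrix and target")
    }
    tg <- as_year_series(target)
    preds <- setdiff(names(matrix), "year")
    mm <- merge(tg, matrix, by = "year")
    mm <- mm[stats::complete.cases(mm), , drop = FALSE]
    Z <- scale(as.matrix(mm[preds]))
    return(lmg_partition(mm$value, Z))
  }
  stopifnot(inherits(model, "composite_model"))
  if (is.null(matrix) || is.null(target)) return(model$variance_shares)
  tg <- as_year_series(target)
  mm <- merge(tg, matrix, by = "year")
  w <- model$calibration_window
  mm <- mm[mm$year >= w[1] & mm$year <= w[2], ]
  mm <- mm[stats::complete.cases(mm), , drop = FALSE]
  Z <- sweep(sweep(as.matrix(mm[model$predictors]), 2, model$scaling$center),
             2, model$scaling$scale, "/")
  lmg_partition(mm$value, Z)
}

#' Mean pairwise correlation of a proxy set
#'
#' Arithmetic mean of Pearson correlations over all unordered proxy pairs on
#' the harmonized (annual) common span: the standard coherence summary for a
#' multi-proxy predictor set.
#'
#' @param records named list of proxy records.
#' @param window optional year range.
#' @param min_overlap minimum common years (default 10).
#' @return Mean pairwise r.
#' @export
mean_pairwise_correlation <- function(records, window = NULL, min_overlap = 10L) {
  if (length(records) < 2L) stop("need at least two records")
  H <- harmonize_proxies(records, "annual")
  if (!is.null(window)) H <- H[H$year >= window[1] & H$year <= window[2], ]
  if (nrow(H) < min_overlap) {
    stop("common span of ", nrow(H), " years is below ", min_overlap)
  }
  cm <- stats::cor(as.matrix(H[setdiff(names(H), "year")]))
  mean(cm[upper.tri(cm)])
}
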