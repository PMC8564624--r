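#' Resample a climate series onto a regular age lattice
#'
#' Values at multiples of `interval` within the series span, taken from
#' the nearest original sample (default) or linearly interpolated.
#'
#' @param series a [climate_series()].
#' @param interval lattice spacing in years (default 1000).
#' @param method `"nearest"` or `"linear"`.
#' @return a [climate_series()] on the lattice.
#' @export
resample_series <- function(series, interval = 1000,
                            method = c("nearest", "linear")) {
  stopifnot(inherits(series, "climate_series"))
  method <- match.arg(method)
  if (nrow(series) < 2L) stop("series too short to resample")
  rng <- range(series$age_bp)
  if (diff(rng) < 2 * interval) stop("series spans fewer than 2 intervals")
  targets <- seq(ceiling(rng[1L] / interval) * interval,
                 floor(rng[2L] / interval) * interval, by = interval)
  vals <- if (method == "nearest") {
    vapply(targets, function(a) {
      series$temp_c[which.min(abs(series$age_bp - a))]
    }, numeric(1))
  } else {
    approx(series$age_bp, series$temp_c, xout = targets, rule = 2)$y
  }
  climate_series(targets, vals, kind = attr(series, "kind"))
}

#' Rate of change of a temperature series
#'
#' Percent change per resampling interval:
#' \eqn{ROC_t = (T_t - T_{t-1}) / T_{t-1} \times 100}, where \eqn{T_{t-1}}
#' is the previous (older) sample. The oldest point has no predecessor and
#' is dropped. When `|T_{t-1}|` falls below `eps_guard` the ratio is
#' numerically meaningless (anomaly series cross zero); such points are
#' returned as `NA` and counted in attribute `n_nonfinite` rather than
#' silently propagated. `mode = "absolute"` returns the plain difference
#' per interval (degrees C), a scale-free alternative that has no zero
#' crossing problem.
#'
#' @param series a [climate_series()] (typically resampled).
#' @param mode `"relative"` (the percent formula) or `"absolute"`.
#' @param eps_guard guard threshold on the lagged denominator, degrees C.
#' @return data.frame with `age_bp` (the younger age of each pair) and
#'   `roc`, of class `roc_series`.
#' @export
rate_of_change <- function(series, mode = c("relative", "absolute"),
                           eps_guard = 0.1) {
  stopifnot(inherits(series, "climate_series"))
  mode <- match.arg(mode)
  if (nrow(series) < 2L) stop("need at least 2 points")
  # rows are ordered oldest first; lag(T) is the previous, older sample
  older <- series$temp_c[-nrow(series)]
  newer <- series$temp_c[-1L]
  age <- series$age_bp[-1L]
  roc <- if (mode == "relative") {
    out <- (newer - older) / older * 100
    out[abs(older) < eps_guard] <- NA_real_
    out
  } else {
    newer - older
  }
  res <- data.frame(age_bp = age, roc = roc)
  attr(res, "mode") <- mode
  attr(res, "n_nonfinite") <- sum(is.na(roc))
  attr(res, "step") <- stats::median(abs(diff(series$age_bp)))
  class(res) <- c("roc_series", "data.frame")
  res
}

#' Smooth a series by local linear regression with tricube weights
#'
#' A loess-style smoother: at each age the `max(3, floor(span * n))`
#' nearest neighbours are fit by weighted least squares (linear in age)
#' with tricube weights, and the fit is evaluated at that age. Constant
#' and globally linear series are reproduced exactly.
#'
#' @param series a [climate_series()].
#' @param span fraction of points in each local neighbourhood
#'   (default 0.05).
#' @return a [climate_series()] of smoothed values.
#' @export
smooth_series <- function(series, span = 0.05) {
  stopifnot(inherits(series, "climate_series"))
  n <- nrow(series)
  q <- max(3L, floor(span * n))
  if (n < max(5L, q)) stop("too few points for the requested span")
  x <- series$age_bp
  y <- series$temp_c
  fit <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    idx <- order(d)[seq_len(q)]
    h <- max(d[idx])
    w <- if (h > 0) (1 - pmin(d[idx] / h, 1)^3)^3 else rep(1, q)
    w[w <= 0] <- 1e-12
    xc <- x[idx] - x[i]
    sw <- sum(w); swx <- sum(w * xc); swx2 <- sum(w * xc^2)
    swy <- sum(w * y[idx]); swxy <- sum(w * xc * y[idx])
    det <- sw * swx2 - swx^2
    fit[i] <- if (abs(det) < 1e-12 * max(1, sw * swx2)) {
      swy / sw
    } else {
      (swx2 * swy - swx * swxy) / det  # intercept at xc = 0
    }
  }
  climate_series(x, fit, kind = attr(series, "kind"))
}

#' Detect rapid-change episodes from a ROC profile
#'
#' Flags points whose `|ROC|` exceeds the given quantile of all finite
#' `|ROC|` values, merges flagged runs separated by at most `merge_gap`
#' lattice steps, and returns the merged intervals. Each interval is
#' widened by half a step on both sides so a single flagged point has
#' width one step. The quantile threshold is scale-free; the value used
#' is recorded on the result.
#'
#' @param roc a `roc_series` from [rate_of_change()].
#' @param quantile_threshold quantile of `|ROC|` defining "rapid"
#'   (default 0.90).
#' @param merge_gap maximum number of sub-threshold steps bridged when
#'   merging adjacent episodes (default 1).
#' @return an `episode_set`: data.frame (`start_bp`, `end_bp`,
#'   `peak_roc`) with `start_bp > end_bp` (BP convention), plus
#'   attributes `threshold` and `quantile`.
#' @export
detect_episodes <- function(roc, quantile_threshold = 0.90, merge_gap = 1L) {
  stopifnot(inherits(roc, "roc_series"))
  finite <- is.finite(roc$roc)
  if (!any(finite)) stop("no finite ROC values")
  thr <- quantile(abs(roc$roc[finite]), quantile_threshold, names = FALSE)
  step <- attr(roc, "step")
  ages <- roc$age_bp           # descending
  flagged <- finite & abs(roc$roc) > thr
  idx <- which(flagged)
  if (!length(idx)) {
    out <- data.frame(start_bp = numeric(0), end_bp = numeric(0),
                      peak_roc = numeric(0))
  } else {
    runs <- split(idx, cumsum(c(1, diff(idx) > merge_gap + 1L)))
    out <- do.call(rbind, lapply(runs, function(r) {
      data.frame(start_bp = max(ages[r]) + step / 2,
                 end_bp = min(ages[r]) - step / 2,
                 peak_roc = roc$roc[r][which.max(abs(roc$roc[r]))])
    }))
    rownames(out) <- NULL
  }
  structure(out, threshold = thr, quantile = quantile_threshold,
            step = step, span = range(ages),
            class = c("episode_set", "data.frame"))
}

#' Overlap between a split-time interval and climate episodes
#'
#' The observed statistic is the fraction of the interval `[lo, hi]`
#' covered by the union of episode intervals. The null keeps the episode
#' pattern but shifts it circularly along the time axis; the p-value is
#' the fraction of shifts whose overlap is at least the observed one
#' (the identity shift is included, so p is never 0).
#'
#' @param interval numeric length-2, years BP (any order).
#' @param episodes an `episode_set` from [detect_episodes()].
#' @param series_span numeric length-2: the time span (years BP) over
#'   which episodes were detectable; defaults to the span recorded on
#'   `episodes`.
#' @param n_permutations number of circular shifts (default 999).
#' @param seed integer seed.
#' @return list with `overlap`, `p_value`, `null_mean`.
#' @export
interval_episode_overlap <- function(interval, episodes, series_span = NULL,
                                     n_permutations = 999, seed = NULL) {
  stopifnot(inherits(episodes, "episode_set"))
  if (is.null(series_span)) series_span <- attr(episodes, "span")
  lo <- min(interval); hi <- max(interval)
  span_lo <- min(series_span); span_hi <- max(series_span)
  if (lo < span_lo || hi > span_hi) {
    stop("split interval lies outside the series span")
  }
  L <- span_hi - span_lo
  cover <- function(shift) {
    if (!nrow(episodes)) return(0)
    tot <- 0
    for (k in seq_len(nrow(episodes))) {
      # shift episode (circularly within the span), may wrap into 2 pieces
      a <- (episodes$end_bp[k] - span_lo + shift) %% L
      b <- a + (episodes$start_bp[k] - episodes$end_bp[k])
      pieces <- if (b <= L) list(c(a, b)) else list(c(a, L), c(0, b - L))
      for (pc in pieces) {
        s <- max(pc[1] + span_lo, lo)
        e <- min(pc[2] + span_lo, hi)
        if (e > s) tot <- tot + (e - s)
      }
    }
    min(tot / (hi - lo), 1)
  }
  obs <- cover(0)
  if (!nrow(episodes)) {
    return(list(overlap = 0, p_value = 1, null_mean = 0))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  shifts <- runif(n_permutations, 0, L)
  null <- vapply(shifts, cover, numeric(1))
  p <- mean(c(null, obs) >= obs)
  list(overlap = obs, p_value = p, null_mean = mean(null))
}
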