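#' Climate series objects
#'
#' A thin wrapper around a data.frame with columns `age_bp` (years before
#' present, strictly monotone) and `temp_c` (temperature or temperature
#' anomaly in degrees Celsius; which one is up to the caller and should be
#' tracked via the `kind` label).
#'
#' @param age_bp ages in years BP.
#' @param temp_c temperatures in degrees C.
#' @param kind `"anomaly"` or `"absolute"` (a label, not a transform).
#' @return object of class `climate_series` (also a data.frame).
#' @export
climate_series <- function(age_bp, temp_c, kind = "anomaly") {
  if (length(age_bp) != length(temp_c)) stop("length mismatch")
  if (length(age_bp) < 1L) stop("empty series")
  d <- diff(age_bp)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("ages must be strictly monotone with no duplicates")
  }
  out <- data.frame(age_bp = as.numeric(age_bp),
                    temp_c = as.numeric(temp_c))
  out <- out[order(out$age_bp, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, kind = kind, class = c("climate_series", "data.frame"))
}

#' Simulate a temperature series with engineered rapid-change events
#'
#' Generates a series on a regular age grid: a piecewise-linear baseline,
#' plus step events with linear ramps (stadial/interstadial-style jumps),
#' plus AR(1) noise. Events are specified by onset age (years BP),
#' amplitude (degrees C, applied on the younger side of the onset) and
#' ramp length in years. The realization is deterministic under `seed`.
#'
#' @param duration total span in years (oldest age).
#' @param step sample spacing in years; must divide `duration`.
#' @param baseline either a single temperature or a data.frame
#'   (`age_bp`, `temp_c`) of knots interpolated linearly.
#' @param events list of `list(onset_bp=, amplitude=, ramp_years=)`.
#' @param ar1_coeff AR(1) coefficient of the noise, in [0, 1).
#' @param noise_sd innovation standard deviation, degrees C.
#' @param seed integer seed.
#' @return a [climate_series()] (ages descending from `duration` to 0),
#'   with the noise-free signal attached as attribute `signal`.
#' @export
simulate_climate <- function(duration, step, baseline = 0, events = list(),
                             ar1_coeff = 0, noise_sd = 0, seed = NULL) {
  if (step <= 0) stop("'step' must be > 0")
  if (duration <= 0 || abs(duration / step - round(duration / step)) > 1e-8) {
    stop("'duration' must be a positive multiple of 'step'")
  }
  if (ar1_coeff < 0 || ar1_coeff >= 1) stop("'ar1_coeff' must be in [0, 1)")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  ages <- seq(duration, 0, by = -step)
  base <- if (is.data.frame(baseline)) {
    approx(baseline$age_bp, baseline$temp_c, xout = ages, rule = 2)$y
  } else {
    rep(as.numeric(baseline), length(ages))
  }
  sig <- base
  for (ev in events) {
    onset <- ev$onset_bp
    amp <- ev$amplitude
    ramp <- max(ev$ramp_years, step)
    frac <- pmin(pmax((onset - ages) / ramp, 0), 1)
    sig <- sig + amp * frac
  }
  noise <- numeric(length(ages))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    innov <- rnorm(length(ages), 0, noise_sd)
    noise[1L] <- innov[1L]
    for (i in seq_along(ages)[-1L]) {
      noise[i] <- ar1_coeff * noise[i - 1L] + innov[i]
    }
  }
  out <- climate_series(ages, sig + noise)
  attr(out, "signal") <- sig
  out
}

#' @rdname climate_io
#' @title Read and write climate series CSV
#' @description CSV with columns `age_bp` and `temp_c`.
#' @param path file path.
#' @param x a [climate_series()].
#' @export
read_climate_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("age_bp", "temp_c") %in% names(d))) {
    stop("climate CSV needs columns age_bp, temp_c")
  }
  climate_series(d$age_bp, d$temp_c)
}

#' @rdname climate_io
#' @export
write_climate_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("age_bp", "temp_c")], path,
                   row.names = FALSE)
  invisible(path)
}
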