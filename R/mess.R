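#' Multivariate environmental similarity surface (MESS)
#'
#' For each point and variable, let `f` be the percentage of reference
#' values strictly below the point value, `minv`/`maxv` the reference
#' range. The similarity is
#' \itemize{
#'   \item `f = 0`: `100 * (p - minv) / (maxv - minv)` (negative below the
#'     reference minimum),
#'   \item `0 < f <= 50`: `2 f`,
#'   \item `50 < f < 100`: `2 (100 - f)`,
#'   \item `f = 100`: `100 * (maxv - p) / (maxv - minv)` (negative above
#'     the reference maximum).
#' }
#' The MESS value is the minimum over variables; values below zero flag
#' extrapolation in at least one variable. A degenerate reference
#' (`maxv == minv`) scores 0 at the reference value and decreases
#' linearly with distance from it, and is flagged via a warning.
#'
#' @param point_values matrix of variable values at the points to score
#'   (columns = variables), or an [env_stack()].
#' @param reference matrix of reference values (columns matching
#'   `point_values`), typically the variables at the occurrence cells.
#' @return list: `mess` (minimum similarity per point, or a raster matrix
#'   for a stack input) and `per_variable` (matrix or list of rasters).
#' @export
mess <- function(point_values, reference) {
  if (inherits(point_values, "env_stack")) {
    d <- dim(point_values$vars[[1L]])
    m <- vapply(names(point_values$vars), function(v) {
      as.vector(point_values$vars[[v]])
    }, numeric(prod(d)))
    res <- mess(m, reference)
    return(list(
      mess = matrix(res$mess, d[1L], d[2L]),
      per_variable = lapply(seq_len(ncol(res$per_variable)), function(j) {
        matrix(res$per_variable[, j], d[1L], d[2L])
      })
    ))
  }
  point_values <- as.matrix(point_values)
  reference <- as.matrix(reference)
  if (ncol(point_values) != ncol(reference)) {
    stop("point and reference variable sets differ")
  }
  if (!nrow(reference)) stop("empty reference sample")
  nv <- ncol(point_values)
  sim <- matrix(NA_real_, nrow(point_values), nv)
  for (j in seq_len(nv)) {
    ref <- sort(reference[, j])
    minv <- ref[1L]; maxv <- ref[length(ref)]
    p <- point_values[, j]
    f <- 100 * findInterval(p, ref, left.open = TRUE) / length(ref)
    # strictly-below count: left.open counts ref < p
    s <- numeric(length(p))
    rangev <- maxv - minv
    if (rangev <= 0) {
      warning("degenerate reference range for variable ",
              colnames(reference)[j] %||% j,
              "; similarity is distance-based")
      s <- -100 * abs(p - minv) / max(abs(minv), 1)
    } else {
      low <- f == 0
      high <- f == 100
      mid_lo <- f > 0 & f <= 50
      mid_hi <- f > 50 & f < 100
      s[low] <- 100 * (p[low] - minv) / rangev
      s[mid_lo] <- 2 * f[mid_lo]
      s[mid_hi] <- 2 * (100 - f[mid_hi])
      s[high] <- 100 * (maxv - p[high]) / rangev
    }
    sim[, j] <- s
  }
  colnames(sim) <- colnames(point_values)
  list(mess = apply(sim, 1, min), per_variable = sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Project an ensemble across time slices
#'
#' For each slice: the continuous ensemble suitability, a binary range
#' map at the ensemble threshold (mean of member max-TSS thresholds), the
#' suitable-cell count as an area proxy, and the MESS surface against the
#' training reference.
#'
#' @param ensemble an `sdm_ensemble` from [build_ensemble()].
#' @param stacks list of [env_stack()] objects (one per time slice).
#' @param reference MESS reference matrix (variables at the training
#'   presences); `NULL` skips MESS.
#' @return list with `area` (data.frame: time_bp, area,
#'   frac_extrapolated) and `slices` (per-slice rasters).
#' @export
project_time_slices <- function(ensemble, stacks, reference = NULL) {
  stopifnot(inherits(ensemble, "sdm_ensemble"))
  vars_needed <- unique(unlist(lapply(ensemble$members,
                                      function(m) m$model$vars)))
  slices <- vector("list", length(stacks))
  area <- data.frame(time_bp = numeric(length(stacks)),
                     area = numeric(length(stacks)),
                     frac_extrapolated = NA_real_)
  for (k in seq_along(stacks)) {
    st <- stacks[[k]]
    miss <- setdiff(vars_needed, names(st$vars))
    if (length(miss)) {
      stop("slice ", k, " is missing variable(s): ",
           paste(miss, collapse = ", "))
    }
    suit <- predict_ensemble(ensemble, st)
    binary <- suit >= ensemble$threshold & st$mask
    ms <- if (!is.null(reference)) mess(st, reference) else NULL
    slices[[k]] <- list(suitability = suit, binary = binary,
                        mess = ms$mess %||% NULL, time_bp = st$time_bp)
    area$time_bp[k] <- st$time_bp
    area$area[k] <- sum(binary)
    if (!is.null(ms)) {
      area$frac_extrapolated[k] <- mean(ms$mess[st$mask] < 0)
    }
  }
  list(area = area, slices = slices)
}

#' Detect range collapses in an area series
#'
#' Flags slices whose area falls below `drop_frac` times the series
#' median and merges adjacent flagged slices into collapse intervals.
#'
#' @param area data.frame with `time_bp` and `area` (as from
#'   [project_time_slices()]), or a numeric area vector.
#' @param drop_frac collapse threshold as a fraction of the median area
#'   (default 0.5).
#' @return data.frame of collapse intervals: `from_slice`, `to_slice`,
#'   `start_bp`, `end_bp`, `min_area`.
#' @export
detect_range_collapse <- function(area, drop_frac = 0.5) {
  if (is.data.frame(area)) {
    a <- area$area
    tb <- area$time_bp
  } else {
    a <- as.numeric(area)
    tb <- seq_along(a)
  }
  if (length(a) < 3L) stop("need at least 3 slices")
  thr <- drop_frac * median(a)
  idx <- which(a < thr)
  if (!length(idx)) {
    return(data.frame(from_slice = integer(0), to_slice = integer(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      min_area = numeric(0)))
  }
  runs <- split(idx, cumsum(c(1, diff(idx) > 1)))
  out <- do.call(rbind, lapply(runs, function(r) {
    data.frame(from_slice = min(r), to_slice = max(r),
               start_bp = max(tb[r]), end_bp = min(tb[r]),
               min_area = min(a[r]))
  }))
  rownames(out) <- NULL
  out
}
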