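#' Environmental raster stacks on a regular lon/lat grid
#'
#' A lightweight matrix-backed stack: named variable layers on a common
#' grid, a logical land/region mask, a geographic extent and a time label.
#' Rows run north to south, columns west to east; cell (1,1) is the
#' north-west corner.
#'
#' @param vars named list of numeric matrices with identical dimensions.
#' @param extent numeric length-4: xmin, xmax, ymin, ymax (degrees).
#' @param mask logical matrix (`TRUE` = usable cell); defaults to all.
#' @param time_bp time label in years BP (default 0 = present).
#' @return object of class `env_stack`.
#' @export
env_stack <- function(vars, extent = c(0, 10, 40, 50), mask = NULL,
                      time_bp = 0) {
  if (!length(vars) || is.null(names(vars)) || any(!nzchar(names(vars)))) {
    stop("'vars' must be a non-empty named list of matrices")
  }
  dims <- dim(vars[[1L]])
  for (v in vars) {
    if (!identical(dim(v), dims)) stop("all variables must share one grid")
  }
  if (is.null(mask)) mask <- matrix(TRUE, dims[1L], dims[2L])
  if (!identical(dim(mask), dims)) stop("mask must match the grid")
  if (length(extent) != 4L || extent[1L] >= extent[2L] ||
      extent[3L] >= extent[4L]) {
    stop("extent must be c(xmin, xmax, ymin, ymax) with min < max")
  }
  structure(list(vars = vars, mask = mask, extent = as.numeric(extent),
                 time_bp = time_bp),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  d <- dim(x$vars[[1L]])
  cat("<env_stack> ", d[1L], "x", d[2L], " cells, ",
      length(x$vars), " variables (", paste(names(x$vars), collapse = ", "),
      "), t = ", x$time_bp, " BP\n", sep = "")
  invisible(x)
}

# cell centers; row 1 is the northern edge
cell_centers <- function(stack) {
  d <- dim(stack$vars[[1L]])
  ex <- stack$extent
  dx <- (ex[2L] - ex[1L]) / d[2L]
  dy <- (ex[4L] - ex[3L]) / d[1L]
  list(lon = ex[1L] + (seq_len(d[2L]) - 0.5) * dx,
       lat = ex[4L] - (seq_len(d[1L]) - 0.5) * dy)
}

#' Row/column indices of the cells containing points
#' @param stack an [env_stack()].
#' @param lon,lat point coordinates in degrees.
#' @return two-column matrix of `row`, `col` indices (clamped to the
#'   grid).
#' @export
cell_index <- function(stack, lon, lat) {
  d <- dim(stack$vars[[1L]])
  ex <- stack$extent
  col <- pmin(pmax(ceiling((lon - ex[1L]) / (ex[2L] - ex[1L]) * d[2L]), 1L),
              d[2L])
  row <- pmin(pmax(ceiling((ex[4L] - lat) / (ex[4L] - ex[3L]) * d[1L]), 1L),
              d[1L])
  cbind(row = row, col = col)
}

#' Extract variable values at point locations
#' @param stack an [env_stack()].
#' @param pts data.frame with `lon`, `lat`.
#' @return matrix (points x variables).
#' @export
extract_env <- function(stack, pts) {
  idx <- cell_index(stack, pts$lon, pts$lat)
  out <- vapply(stack$vars, function(v) v[idx], numeric(nrow(idx)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(idx))
  colnames(out) <- names(stack$vars)
  out
}

#' Simulate an environmental landscape with a known niche
#'
#' Generates spatially autocorrelated variable rasters (Gaussian smoothing
#' of white noise with kernel standard deviation `spatial_corr_length`
#' cells, then re-standardized), a logistic true-suitability surface from
#' `niche_coeffs` (intercept + one coefficient per variable), presence
#' points sampled without replacement with probability proportional to
#' suitability, and background points sampled uniformly from the mask.
#'
#' @param grid_shape rows x cols.
#' @param n_vars number of environmental variables (default 4, named
#'   after breeding-season climate predictors).
#' @param spatial_corr_length smoothing kernel sd in cells; 0 gives
#'   spatially independent values.
#' @param niche_coeffs numeric length `n_vars + 1` (intercept first).
#'   All-zero coefficients give suitability 0.5 everywhere.
#' @param n_presence,n_background point counts.
#' @param extent geographic extent (xmin, xmax, ymin, ymax).
#' @param seed integer seed; output is bit-reproducible under it.
#' @return list: `stack` (an [env_stack()]), `suitability` (truth
#'   raster), `presences`, `background` (data.frames of lon/lat).
#' @export
simulate_landscape <- function(grid_shape = c(40, 60), n_vars = 4,
                               spatial_corr_length = 3,
                               niche_coeffs = c(-16, 8, -6, 6, -4),
                               n_presence = 200, n_background = 1000,
                               extent = c(-10, 30, 35, 60), seed = NULL) {
  if (length(niche_coeffs) != n_vars + 1L) {
    stop("'niche_coeffs' must have length n_vars + 1 (intercept first)")
  }
  nr <- grid_shape[1L]; nc <- grid_shape[2L]
  n_cells <- nr * nc
  if (n_presence > n_cells) stop("n_presence exceeds available cells")
  if (n_background > n_cells) stop("n_background exceeds available cells")
  if (!is.null(seed)) set.seed(as.integer(seed))
  default_names <- c("prec_var", "prec_min", "temp_mean", "temp_var")
  vnames <- if (n_vars <= 4L) default_names[seq_len(n_vars)] else
    paste0("var", seq_len(n_vars))
  vars <- stats::setNames(lapply(seq_len(n_vars), function(v) {
    z <- matrix(rnorm(n_cells), nr, nc)
    z <- gaussian_smooth(z, spatial_corr_length)
    (z - mean(z)) / max(sd(z), 1e-12)
  }), vnames)
  stack <- env_stack(vars, extent = extent, time_bp = 0)
  lin <- niche_coeffs[1L]
  for (v in seq_len(n_vars)) lin <- lin + niche_coeffs[v + 1L] * vars[[v]]
  suit <- 1 / (1 + exp(-lin))
  cc <- cell_centers(stack)
  all_cells <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  lonlat <- data.frame(lon = cc$lon[all_cells$col],
                       lat = cc$lat[all_cells$row])
  pres_idx <- sample(n_cells, n_presence, prob = as.vector(suit))
  bg_idx <- sample(n_cells, n_background)
  list(stack = stack, suitability = suit,
       presences = lonlat[pres_idx, , drop = FALSE],
       background = lonlat[bg_idx, , drop = FALSE])
}

# separable Gaussian blur with edge renormalization; sd in cells
gaussian_smooth <- function(z, sd_cells) {
  if (sd_cells <= 0) return(z)
  r <- ceiling(3 * sd_cells)
  k <- dnorm(seq(-r, r), sd = sd_cells)
  smooth_1d <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (i in seq_len(n)) {
      lo <- max(1L, i - r); hi <- min(n, i + r)
      kk <- k[(lo - i + r + 1L):(hi - i + r + 1L)]
      out[i, ] <- colSums(m[lo:hi, , drop = FALSE] * kk) / sum(kk)
    }
    out
  }
  t(smooth_1d(t(smooth_1d(z))))
}

#' Read and write delimited-grid rasters with a JSON sidecar
#'
#' The raster is a whitespace-delimited grid of values (rows north to
#' south); the sidecar `<path>.json` records the extent, the grid shape
#' and the nodata value.
#'
#' @param path raster text file path.
#' @param m numeric matrix.
#' @param extent numeric length-4 extent.
#' @param nodata value standing for missing cells.
#' @rdname grid_io
#' @export
write_grid <- function(m, path, extent = c(0, 1, 0, 1), nodata = -9999) {
  mm <- m
  mm[is.na(mm)] <- nodata
  write.table(format(mm, digits = 10, scientific = TRUE, trim = TRUE),
              path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(extent = extent, nrow = nrow(m), ncol = ncol(m), nodata = nodata),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname grid_io
#' @export
read_grid <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(read.table(path))
  dimnames(m) <- NULL
  if (!identical(dim(m), c(as.integer(meta$nrow), as.integer(meta$ncol)))) {
    stop("raster shape does not match its sidecar")
  }
  m[m == meta$nodata] <- NA
  attr(m, "extent") <- as.numeric(meta$extent)
  m
}
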