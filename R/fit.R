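#' Poisson composite log-likelihood of an observed spectrum
#'
#' Treats the unmasked cells of the observed spectrum as independent
#' Poisson counts with means `theta * expected`. The overall scale `theta`
#' is profiled analytically: \eqn{\hat\theta = \sum n / \sum e} over
#' unmasked cells, which maximizes the composite likelihood exactly.
#'
#' @param observed,expected [freq_spectrum()] objects with identical
#'   shapes, folding states and masks (`expected` at unit theta scale).
#' @return a list with `loglik`, `theta_hat` and the number of cells used.
#' @export
composite_loglik <- function(observed, expected) {
  stopifnot(inherits(observed, "freq_spectrum"),
            inherits(expected, "freq_spectrum"))
  if (!identical(dim(observed$counts), dim(expected$counts))) {
    stop("observed and expected spectra have different shapes")
  }
  if (!identical(observed$folded, expected$folded)) {
    stop("observed and expected spectra differ in folding")
  }
  if (!identical(observed$mask, expected$mask)) {
    stop("observed and expected spectra have different masks")
  }
  use <- !observed$mask
  n <- observed$counts[use]
  e <- expected$counts[use]
  if (sum(e) <= 0) stop("expected spectrum has no mass on unmasked cells")
  theta_hat <- sum(n) / sum(e)
  mu <- theta_hat * e
  ll <- sum(ifelse(n > 0, n * log(pmax(mu, .Machine$double.xmin)), 0) -
              mu - lgamma(n + 1))
  list(loglik = ll, theta_hat = theta_hat, n_cells = sum(use))
}

#' Fit a demographic model to an observed spectrum
#'
#' Multi-start bounded optimization of the Poisson composite likelihood.
#' Sizes and times are optimized in log space within `bounds`; migration
#' rates are optimized in linear space so that zero migration is
#' attainable, with bound violations handled by a smooth penalty.
#' Each start perturbs the initial point by a random factor of up to two
#' per coordinate; runs are deterministic under `seed`. The scale
#' parameter theta is profiled analytically at every evaluation rather
#' than optimized numerically.
#'
#' Convergence of a run means the optimizer reported success and the
#' fitted spectrum is finite; summaries (median and 25-75% interquartile
#' range per parameter, linear-interpolation quantiles) are computed over
#' converged runs only.
#'
#' @param observed a [freq_spectrum()].
#' @param model_id model family, see [demographic_model()].
#' @param n_starts number of optimization runs (default 50).
#' @param init optional named vector of starting values; defaults to 1
#'   for sizes, 0.1 for times, 1 for migration rates.
#' @param fixed optional named vector of parameters to hold fixed.
#' @param bounds list with elements `nu`, `t`, `m`, each a length-2
#'   range; defaults nu in [1e-3, 1e2], t in [1e-4, 10], M in [0, 20].
#' @param seed integer seed for start-point perturbations.
#' @param extra accuracy knob passed to [expected_sfs()].
#' @param maxit maximum Nelder-Mead iterations per run.
#' @return an object of class `sfs_fit`: per-run table (`runs`), the
#'   best run (`best`), parameter summaries (`summary`), and metadata.
#' @export
fit_model <- function(observed, model_id, n_starts = 50, init = NULL,
                      fixed = NULL, bounds = NULL, seed = NULL,
                      extra = 4L, maxit = 500) {
  stopifnot(inherits(observed, "freq_spectrum"))
  if (n_starts < 1) stop("n_starts must be >= 1")
  spec <- model_param_spec(model_id)
  if (length(observed$sample_sizes) != spec$n_pops) {
    stop("spectrum dimensionality does not match the model family")
  }
  bounds <- resolve_bounds(bounds)
  base <- spec$defaults
  base[spec$sizes] <- 1
  base[spec$times] <- 0.1
  base[spec$migs] <- 1
  if (!is.null(init)) {
    unknown <- setdiff(names(init), names(base))
    if (length(unknown)) stop("unknown init parameter(s): ",
                              paste(unknown, collapse = ", "))
    base[names(init)] <- init
  }
  fixed_names <- character()
  if (!is.null(fixed)) {
    unknown <- setdiff(names(fixed), names(base))
    if (length(unknown)) stop("unknown fixed parameter(s): ",
                              paste(unknown, collapse = ", "))
    base[names(fixed)] <- fixed
    fixed_names <- names(fixed)
  }
  free <- setdiff(names(base), fixed_names)
  if (!length(free)) stop("no free parameters to optimize")
  kinds <- vapply(free, param_kind, character(1))

  to_opt <- function(p) ifelse(kinds == "mig", p, log(p))
  from_opt <- function(z) ifelse(kinds == "mig", z, exp(z))
  kind_bounds <- function(k) switch(k, size = bounds$nu, time = bounds$t,
                                    mig = bounds$m)

  objective <- function(z) {
    p <- from_opt(z)
    pen <- 0
    for (i in seq_along(free)) {
      b <- kind_bounds(kinds[i])
      if (p[i] < b[1]) { pen <- pen + (b[1] - p[i])^2 / b[1]^2; p[i] <- b[1] }
      if (p[i] > b[2]) { pen <- pen + (p[i] - b[2])^2 / b[2]^2; p[i] <- b[2] }
    }
    full <- base
    full[free] <- p
    if (model_id == "three_pop_two_splits_mig" &&
        full[["t_split2"]] > full[["t_split"]]) {
      pen <- pen + (full[["t_split2"]] - full[["t_split"]])^2 * 1e4
      full[["t_split2"]] <- full[["t_split"]]
    }
    model <- tryCatch(demographic_model(model_id, full),
                      error = function(e) NULL)
    if (is.null(model)) return(1e10)
    exp_fs <- tryCatch(
      expected_sfs(model, observed$sample_sizes, folded = observed$folded,
                   extra = extra),
      error = function(e) NULL)
    if (is.null(exp_fs)) return(1e10)
    exp_fs$mask <- observed$mask  # likelihood over the observed cells only
    cl <- tryCatch(composite_loglik(observed, exp_fs),
                   error = function(e) NULL)
    if (is.null(cl) || !is.finite(cl$loglik)) return(1e10)
    -cl$loglik + pen * 1e4
  }

  if (!is.null(seed)) set.seed(as.integer(seed))
  clamp_start <- function(p) {
    for (i in seq_along(free)) {
      b <- kind_bounds(kinds[i])
      p[i] <- min(max(p[i], b[1]), b[2])
    }
    p
  }

  runs <- vector("list", n_starts)
  for (r in seq_len(n_starts)) {
    fac <- 2^runif(length(free), -1, 1)
    start <- base[free] * fac
    start[kinds == "mig" & base[free] == 0] <-
      runif(sum(kinds == "mig" & base[free] == 0), 0, 0.5)
    start <- clamp_start(start)
    # Nelder-Mead with restarts: re-seed the simplex at the incumbent until
    # the relative objective change falls below 1e-8 (or cycles run out).
    opt <- NULL
    converged_run <- FALSE
    z <- to_opt(start)
    prev_val <- Inf
    for (cycle in seq_len(6L)) {
      opt <- tryCatch(
        optim(z, objective, method = "Nelder-Mead",
              control = list(maxit = maxit, reltol = 1e-8)),
        error = function(e) NULL)
      if (is.null(opt)) break
      z <- opt$par
      if (opt$convergence == 0 ||
          (is.finite(prev_val) &&
           (prev_val - opt$value) < 1e-8 * (abs(opt$value) + 1e-8))) {
        converged_run <- TRUE
        break
      }
      prev_val <- opt$value
    }
    if (is.null(opt)) {
      runs[[r]] <- list(converged = FALSE, start = start)
      next
    }
    est <- from_opt(opt$par)
    names(est) <- free
    est <- clamp_start(est)
    full <- base
    full[free] <- est
    model <- demographic_model(model_id, full)
    exp_fs <- expected_sfs(model, observed$sample_sizes,
                           folded = observed$folded, extra = extra)
    exp_fs$mask <- observed$mask
    cl <- composite_loglik(observed, exp_fs)
    runs[[r]] <- list(
      converged = converged_run && is.finite(cl$loglik),
      start = start, params = full, loglik = cl$loglik,
      theta_hat = cl$theta_hat
    )
  }

  ok <- vapply(runs, function(x) isTRUE(x$converged), logical(1))
  if (!any(ok)) {
    stop("no optimization run converged; per-run diagnostics: ",
         paste(vapply(runs, function(x) {
           if (is.null(x$loglik)) "optimizer error" else
             sprintf("ll=%.2f", x$loglik)
         }, character(1)), collapse = "; "))
  }
  run_tab <- do.call(rbind, lapply(seq_along(runs), function(r) {
    x <- runs[[r]]
    row <- data.frame(run = r, converged = isTRUE(x$converged),
                      loglik = if (is.null(x$loglik)) NA_real_ else x$loglik,
                      theta_hat = if (is.null(x$theta_hat)) NA_real_
                                  else x$theta_hat)
    pars <- if (is.null(x$params)) stats::setNames(rep(NA_real_,
              length(base)), names(base)) else x$params
    cbind(row, as.data.frame(as.list(pars)))
  }))
  conv <- run_tab[run_tab$converged, , drop = FALSE]
  qs <- function(v) quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  summ <- do.call(rbind, lapply(c(names(base), "theta_hat"), function(nm) {
    v <- conv[[nm]]
    data.frame(parameter = nm, q25 = qs(v)[1], median = qs(v)[2],
               q75 = qs(v)[3])
  }))
  best <- runs[[which.max(ifelse(ok, run_tab$loglik, -Inf))]]
  structure(
    list(model_id = model_id, runs = run_tab, summary = summ,
         best = best, n_converged = sum(ok), free = free,
         fixed = fixed_names, sample_sizes = observed$sample_sizes,
         folded = observed$folded),
    class = "sfs_fit"
  )
}

resolve_bounds <- function(bounds) {
  out <- list(nu = c(1e-3, 1e2), t = c(1e-4, 10), m = c(0, 20))
  if (!is.null(bounds)) {
    unknown <- setdiff(names(bounds), names(out))
    if (length(unknown)) stop("unknown bounds: ",
                              paste(unknown, collapse = ", "))
    out[names(bounds)] <- bounds
  }
  out
}

#' @export
print.sfs_fit <- function(x, ...) {
  cat("<sfs_fit>", x$model_id, "on",
      paste(x$sample_sizes, collapse = " x "), "haploids",
      if (x$folded) "(folded)" else "(unfolded)", "\n")
  cat("  runs:", nrow(x$runs), " converged:", x$n_converged,
      " best loglik:", format(x$best$loglik, digits = 8), "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Summarize converted split times across optimization runs
#'
#' Converts each converged run's split time(s) to years through its own
#' profiled theta (see [convert_units()]) and reports the median and the
#' 25-75% interquartile range (linear-interpolation quantiles) across
#' runs, in thousands of years (kya).
#'
#' @param fit an [fit_model()] result.
#' @param units a [unit_system()].
#' @param param which time parameter to summarize (default `"t_split"`).
#' @return a data.frame with `median_kya`, `q25_kya`, `q75_kya` and the
#'   number of runs used. With fewer than 3 converged runs a warning is
#'   issued and the raw per-run values are attached as an attribute.
#' @export
summarize_split_times <- function(fit, units, param = "t_split") {
  stopifnot(inherits(fit, "sfs_fit"), inherits(units, "unit_system"))
  conv <- fit$runs[fit$runs$converged, , drop = FALSE]
  if (!param %in% names(conv)) stop("no parameter '", param, "' in fit")
  years <- vapply(seq_len(nrow(conv)), function(r) {
    cu <- convert_units(conv$theta_hat[r],
                        stats::setNames(conv[[param]][r], param), units)
    cu$real[[param]]
  }, numeric(1))
  kya <- years / 1000
  if (length(kya) < 3L) {
    warning("fewer than 3 converged runs; reporting raw values")
    out <- data.frame(median_kya = median(kya), q25_kya = NA_real_,
                      q75_kya = NA_real_, n_runs = length(kya))
    attr(out, "runs_kya") <- kya
    return(out)
  }
  q <- quantile(kya, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(median_kya = q[2], q25_kya = q[1], q75_kya = q[3],
             n_runs = length(kya))
}
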