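#' Thin occurrence records to one per grid cell
#'
#' Projects lon/lat onto a planar km grid (equirectangular, scaled at the
#' mean latitude) and keeps one record per `cell_km` x `cell_km` cell.
#' Which record survives is decided by a seeded shuffle, then first-wins.
#'
#' @param points data.frame with `lon`, `lat`.
#' @param cell_km thinning cell size in km (default 50).
#' @param seed integer seed.
#' @return the thinned data.frame, with attribute `n_input`.
#' @export
thin_occurrences <- function(points, cell_km = 50, seed = NULL) {
  stopifnot(all(c("lon", "lat") %in% names(points)))
  if (!nrow(points)) return(points)
  km_per_deg_lat <- 110.574
  km_per_deg_lon <- 111.320 * cos(mean(points$lat) * pi / 180)
  cx <- floor(points$lon * km_per_deg_lon / cell_km)
  cy <- floor(points$lat * km_per_deg_lat / cell_km)
  cell <- paste(cx, cy)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ord <- sample(nrow(points))
  keep_first <- !duplicated(cell[ord])
  out <- points[sort(ord[keep_first]), , drop = FALSE]
  attr(out, "n_input") <- nrow(points)
  out
}

#' Sample background (pseudo-absence) points
#'
#' Uniform sample of cell centers, without replacement, from the masked
#' region of an [env_stack()].
#'
#' @param stack an [env_stack()].
#' @param n number of points.
#' @param seed integer seed.
#' @return data.frame of `lon`, `lat`.
#' @export
sample_background <- function(stack, n, seed = NULL) {
  stopifnot(inherits(stack, "env_stack"))
  ok <- which(stack$mask)
  if (n > length(ok)) stop("n exceeds the number of masked cells")
  if (!is.null(seed)) set.seed(as.integer(seed))
  pick <- ok[sample(length(ok), n)]
  d <- dim(stack$mask)
  cc <- cell_centers(stack)
  rows <- ((pick - 1L) %% d[1L]) + 1L
  cols <- ((pick - 1L) %/% d[1L]) + 1L
  data.frame(lon = cc$lon[cols], lat = cc$lat[rows])
}

#' Fit a single SDM learner
#'
#' Two transparent learner families implement the ensemble contract:
#' \describe{
#'   \item{`logistic_quadratic`}{ridge-penalized logistic regression on
#'     linear + quadratic terms of the (standardized) variables; the small
#'     ridge penalty keeps perfectly separable data estimable.}
#'   \item{`range_envelope`}{a percentile envelope: each variable scores
#'     `1 - 2 * |F(x) - 0.5|` against the presence distribution (1 at the
#'     presence median, 0 at or beyond the presence range) and the cell
#'     score is the minimum over variables.}
#' }
#'
#' @param kind `"logistic_quadratic"` or `"range_envelope"`.
#' @param presences,background data.frames of `lon`, `lat`.
#' @param stack an [env_stack()] holding the calibration climate.
#' @return an `sdm_learner` with a `predict_learner()` method.
#' @export
fit_learner <- function(kind = c("logistic_quadratic", "range_envelope"),
                        presences, background, stack) {
  kind <- match.arg(kind)
  if (nrow(presences) < 20L) stop("at least 20 presences are required")
  xp <- extract_env(stack, presences)
  xb <- extract_env(stack, background)
  keep <- vapply(seq_len(ncol(xp)), function(j) {
    sd(c(xp[, j], xb[, j])) > 1e-10
  }, logical(1))
  if (!all(keep)) {
    warning("dropping degenerate predictor(s): ",
            paste(colnames(xp)[!keep], collapse = ", "))
  }
  vars <- colnames(xp)[keep]
  if (!length(vars)) stop("no usable predictors")
  if (kind == "logistic_quadratic") {
    x <- rbind(xp[, keep, drop = FALSE], xb[, keep, drop = FALSE])
    ctr <- colMeans(x); scl <- apply(x, 2, sd)
    xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
    X <- cbind(xs, xs^2)
    colnames(X) <- c(vars, paste0(vars, "_sq"))
    y <- c(rep(1L, nrow(xp)), rep(0L, nrow(xb)))
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = 1e-3, standardize = FALSE)
    model <- list(fit = fit, center = ctr, scale = scl)
  } else {
    model <- list(q = apply(xp[, keep, drop = FALSE], 2, sort))
  }
  structure(list(kind = kind, vars = vars, model = model),
            class = "sdm_learner")
}

#' Predict suitability from a fitted learner
#' @param learner an `sdm_learner`.
#' @param env matrix of variable values (columns named as in training) or
#'   an [env_stack()].
#' @return numeric suitability in [0, 1] per row (or a raster matrix for
#'   a stack input).
#' @export
predict_learner <- function(learner, env) {
  if (inherits(env, "env_stack")) {
    d <- dim(env$vars[[1L]])
    m <- vapply(learner$vars, function(v) {
      if (is.null(env$vars[[v]])) stop("missing variable: ", v)
      as.vector(env$vars[[v]])
    }, numeric(prod(d)))
    p <- predict_learner(learner, m)
    return(matrix(p, d[1L], d[2L]))
  }
  env <- as.matrix(env)
  if (is.null(colnames(env))) colnames(env) <- learner$vars
  miss <- setdiff(learner$vars, colnames(env))
  if (length(miss)) stop("missing variable: ", paste(miss, collapse = ", "))
  x <- env[, learner$vars, drop = FALSE]
  if (learner$kind == "logistic_quadratic") {
    xs <- sweep(sweep(x, 2, learner$model$center), 2, learner$model$scale,
                "/")
    X <- cbind(xs, xs^2)
    as.numeric(predict(learner$model$fit, X, type = "response"))
  } else {
    scores <- vapply(seq_along(learner$vars), function(j) {
      ref <- learner$model$q[, j]
      fr <- (findInterval(x[, j], ref) +
               findInterval(x[, j], ref, left.open = TRUE)) /
        (2 * length(ref))
      pmax(1 - 2 * abs(fr - 0.5), 0)
    }, numeric(nrow(x)))
    if (is.null(dim(scores))) scores <- matrix(scores, nrow = nrow(x))
    apply(scores, 1, min)
  }
}

#' True skill statistic maximized over thresholds
#'
#' TSS = sensitivity + specificity - 1 for binarized scores; the maximum
#' is taken over a 101-point threshold grid on [0, 1] augmented with the
#' observed score values themselves, so the optimum is attained exactly
#' and is invariant under strictly monotone transforms of the score.
#'
#' @param scores numeric predictions in [0, 1].
#' @param labels 0/1 observations.
#' @return list with `tss` and the optimizing `threshold`.
#' @export
max_tss <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("both classes are required to evaluate TSS")
  }
  grid <- sort(unique(c(seq(0, 1, length.out = 101L), scores)))
  tss <- vapply(grid, function(thr) {
    pred <- scores >= thr
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    sens + spec - 1
  }, numeric(1))
  k <- which.max(tss)
  list(tss = tss[k], threshold = grid[k])
}

#' Cross-evaluate a learner by repeated 70/30 splits
#'
#' Each repeat resamples presences and background into a calibration
#' (fraction `split`) and a validation set, fits the learner on the
#' calibration part and scores max-TSS on the validation part. A repeat
#' whose validation fold lacks either class is invalidated and flagged.
#'
#' @inheritParams fit_learner
#' @param split calibration fraction (default 0.70).
#' @param repeats number of repeats (default 2).
#' @param seed integer seed.
#' @return list: `mean_tss`, `mean_threshold`, `repeats` (per-repeat
#'   detail), `n_valid`.
#' @export
cross_evaluate <- function(kind, presences, background, stack,
                           split = 0.70, repeats = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  res <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    ip <- sample(nrow(presences), max(1L, round(split * nrow(presences))))
    ib <- sample(nrow(background), max(1L, round(split * nrow(background))))
    vp <- setdiff(seq_len(nrow(presences)), ip)
    vb <- setdiff(seq_len(nrow(background)), ib)
    if (!length(vp) || !length(vb)) {
      res[[r]] <- list(valid = FALSE)
      next
    }
    member <- tryCatch(
      fit_learner(kind, presences[ip, , drop = FALSE],
                  background[ib, , drop = FALSE], stack),
      error = function(e) NULL)
    if (is.null(member)) {
      res[[r]] <- list(valid = FALSE)
      next
    }
    sc <- c(predict_learner(member, extract_env(stack,
                                                presences[vp, , drop = FALSE])),
            predict_learner(member, extract_env(stack,
                                                background[vb, , drop = FALSE])))
    lb <- c(rep(1L, length(vp)), rep(0L, length(vb)))
    mt <- max_tss(sc, lb)
    res[[r]] <- list(valid = TRUE, tss = mt$tss, threshold = mt$threshold)
  }
  valid <- vapply(res, function(x) isTRUE(x$valid), logical(1))
  if (!any(valid)) stop("no valid cross-evaluation repeat")
  list(
    mean_tss = mean(vapply(res[valid], `[[`, 0, "tss")),
    mean_threshold = mean(vapply(res[valid], `[[`, 0, "threshold")),
    repeats = res, n_valid = sum(valid)
  )
}

#' Build a TSS-gated median ensemble
#'
#' Members whose cross-evaluation TSS falls below `gate` are excluded;
#' the ensemble prediction is the cell-wise median of the remaining
#' members. If no member passes the gate this is an explicit error — no
#' silent fallback.
#'
#' @param members list of `list(model = sdm_learner, tss =, threshold =)`.
#' @param gate minimum TSS (default 0.8).
#' @return an `sdm_ensemble`.
#' @export
build_ensemble <- function(members, gate = 0.8) {
  if (!length(members)) stop("at least one member is required")
  tss <- vapply(members, `[[`, 0, "tss")
  pass <- tss >= gate
  if (!any(pass)) {
    stop("no member reaches TSS >= ", gate, " (best: ",
         format(max(tss), digits = 3), ")")
  }
  kept <- members[pass]
  structure(
    list(members = kept, gate = gate,
         tss = vapply(kept, `[[`, 0, "tss"),
         threshold = mean(vapply(kept, `[[`, 0, "threshold"))),
    class = "sdm_ensemble"
  )
}

#' Predict the ensemble suitability surface
#' @param ensemble an `sdm_ensemble`.
#' @param stack an [env_stack()].
#' @return raster matrix of cell-wise median suitability.
#' @export
predict_ensemble <- function(ensemble, stack) {
  preds <- lapply(ensemble$members, function(m) {
    predict_learner(m$model, stack)
  })
  arr <- simplify2array(preds)
  if (length(dim(arr)) == 2L) return(arr)
  apply(arr, c(1, 2), median)
}
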