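# shared fixtures and independent oracles used across test files

# GL matrix of n individuals certain of genotype g (0/1/2)
certain_gl <- function(g, n) {
  m <- matrix(0, n, 3)
  m[, g + 1L] <- 1
  m
}

# total-variation distance between two spectra restricted to unmasked cells
tv_distance <- function(a, b, mask = NULL) {
  if (inherits(a, "freq_spectrum")) {
    mask <- a$mask
    a <- a$counts
  }
  if (inherits(b, "freq_spectrum")) b <- b$counts
  if (is.null(mask)) mask <- array(FALSE, dim = dim(a))
  pa <- a; pa[mask] <- 0; pa <- pa / sum(pa)
  pb <- b; pb[mask] <- 0; pb <- pb / sum(pb)
  0.5 * sum(abs(pa - pb))
}

# exhaustive grid-search oracle for the per-site frequency MLE
grid_maf <- function(gls, step = 1e-5) {
  f <- seq(0, 1, by = step)
  P <- rbind((1 - f)^2, 2 * f * (1 - f), f^2)
  ll <- colSums(log(pmax(gls %*% P, 1e-300)))
  list(f = f[which.max(ll)], loglik = max(ll))
}

# independently coded local-linear tricube smoother (the oracle for
# smooth_series); deliberately written as plain per-point WLS
brute_local_linear <- function(x, y, span) {
  n <- length(x)
  q <- max(3L, floor(span * n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    idx <- order(d)[1:q]
    h <- max(d[idx])
    w <- if (h > 0) (1 - pmin(d[idx] / h, 1)^3)^3 else rep(1, q)
    w[w <= 0] <- 1e-12
    fit <- stats::lm.wfit(cbind(1, x[idx] - x[i]), y[idx], w)
    out[i] <- fit$coefficients[1]
  }
  out
}

# brute-force MESS by direct counting (independent of the packaged code)
brute_mess <- function(pts, ref) {
  nv <- ncol(pts)
  sim <- matrix(NA_real_, nrow(pts), nv)
  for (j in seq_len(nv)) {
    r <- ref[, j]
    minv <- min(r); maxv <- max(r)
    for (i in seq_len(nrow(pts))) {
      p <- pts[i, j]
      f <- 100 * sum(r < p) / length(r)
      sim[i, j] <- if (f == 0) {
        100 * (p - minv) / (maxv - minv)
      } else if (f <= 50) {
        2 * f
      } else if (f < 100) {
        2 * (100 - f)
      } else {
        100 * (maxv - p) / (maxv - minv)
      }
    }
  }
  list(mess = apply(sim, 1, min), per_variable = sim)
}

# analytic equilibrium (unfolded) spectrum proportions for n haploids
equilibrium_props <- function(n) {
  v <- 1 / seq_len(n - 1)
  v / sum(v)
}

# a perfectly separable niche with a margin: presences occupy cells with
# the first variable above 0.5, background is restricted to cells with it
# below -0.5, so the classes are separable with a wide margin
separable_fixture <- function(seed) {
  L <- simulate_landscape(grid_shape = c(30, 30),
                          niche_coeffs = c(-200, 400, 0, 0, 0),
                          n_presence = 60, n_background = 900, seed = seed)
  v1_bg <- extract_env(L$stack, L$background)[, 1L]
  L$background <- utils::head(L$background[v1_bg < -0.5, , drop = FALSE], 200)
  L
}
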