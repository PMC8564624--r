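#' Expected joint SFS under a demographic model
#'
#' Computes the deterministic expectation of the (joint) site frequency
#' spectrum under a [demographic_model()] by integrating a closed system of
#' ordinary differential equations on the spectrum entries themselves.
#'
#' For a sample of `n` haploids from a population of relative size
#' \eqn{\nu}, the expected count \eqn{\Phi_n(i)} of sites with derived
#' allele count `i` evolves under genetic drift as a tridiagonal linear
#' system, with new mutations entering the singleton class at rate
#' \eqn{\theta n / 2}. Migration couples population axes; its moment
#' equations involve the spectrum at one extra sample in the source
#' population, which is closed by a local-quadratic jackknife (the
#' underlying allele-frequency density is treated as locally quadratic, so
#' the order-`n+1` spectrum is a fixed linear map of the order-`n`
#' spectrum). Within an epoch all coefficients are constant, so the affine
#' system is integrated exactly by a matrix exponential; population splits
#' redistribute the spectrum hypergeometrically across the new axes. The
#' two global corner cells (sites lost or fixed in every population) are
#' absorbing and are excluded from the state.
#'
#' The result is linear in `theta`; at the default `theta = 1` the
#' single-population equilibrium spectrum is exactly \eqn{1/i}.
#'
#' @param model a [demographic_model()].
#' @param sample_sizes haploid sample sizes per population (desk-scale
#'   contract: at most 40 per population).
#' @param folded return the folded (minor-allele) expectation?
#' @param theta scaled mutation rate multiplier (default 1).
#' @param extra extra working haploids per population axis: the system is
#'   integrated at `sample_sizes + extra` and projected down
#'   hypergeometrically, which dilutes the jackknife closure error of the
#'   migration term (analogous to the grid-refinement knob of diffusion
#'   SFS solvers). The default 4 balances accuracy against the cubic cost
#'   of the matrix exponential; raise it for high-accuracy one-off
#'   evaluations. With no migration the system is closed and `extra` only
#'   affects round-off.
#' @return a [freq_spectrum()] of expected cell values.
#' @examples
#' fs <- expected_sfs(demographic_model("one_pop_sizechange"), 6)
#' fs$counts[2:6]  # 1, 1/2, ..., 1/5
#' @export
expected_sfs <- function(model, sample_sizes, folded = FALSE, theta = 1,
                         extra = 4L) {
  stopifnot(inherits(model, "demographic_model"))
  sample_sizes <- as.integer(sample_sizes)
  if (length(sample_sizes) != model$n_pops) {
    stop("sample_sizes must give one haploid count per model population")
  }
  if (any(sample_sizes < 1L)) stop("sample sizes must be >= 1")
  if (any(sample_sizes > 40L)) {
    stop("expected_sfs supports at most 40 haploids per population")
  }
  if (!is.finite(theta) || theta < 0) stop("theta must be finite and >= 0")
  extra <- as.integer(extra)
  stopifnot(length(extra) == 1L, extra >= 0L)
  work_sizes <- sample_sizes + extra

  epochs <- demography_epochs(model)
  K <- length(epochs)
  sizes <- vector("list", K)
  sizes[[1L]] <- work_sizes
  for (e in seq_len(K - 1L) + 1L) {
    map <- epochs[[e - 1L]]$map
    d_next <- length(epochs[[e]]$nu)
    sizes[[e]] <- vapply(seq_len(d_next), function(j) {
      sum(sizes[[e - 1L]][map == j])
    }, integer(1L))
  }

  n_tot <- sizes[[K]]
  phi <- array(c(0, 1 / seq_len(n_tot - 1L), 0), dim = n_tot + 1L)

  for (e in rev(seq_len(K - 1L))) {
    phi <- transition_split(phi, sizes[[e + 1L]], epochs[[e]]$map, sizes[[e]])
    phi <- integrate_epoch(phi, sizes[[e]], epochs[[e]]$nu, epochs[[e]]$mig,
                           epochs[[e]]$duration)
  }
  if (any(!is.finite(phi))) {
    stop("expected SFS integration produced non-finite values")
  }
  phi <- array(phi, dim = work_sizes + 1L)
  for (p in seq_along(sample_sizes)) {
    if (work_sizes[p] > sample_sizes[p]) {
      phi <- project_axis(phi, p, work_sizes[p], sample_sizes[p])
    }
  }
  fs <- freq_spectrum(pmax(phi, 0) * theta, sample_sizes, folded = FALSE)
  if (folded) fs <- fold_spectrum(fs)
  fs
}

#' Project a spectrum onto smaller sample sizes
#'
#' Hypergeometric down-sampling of a spectrum to smaller haploid sample
#' sizes, axis by axis. Projection is exact for expected spectra and is
#' the standard way to compare spectra observed at different sample
#' depths.
#'
#' @param fs an unfolded [freq_spectrum()].
#' @param new_sizes target haploid sizes, one per population, each no
#'   larger than the current size.
#' @return a [freq_spectrum()] with the new sizes.
#' @export
project_spectrum <- function(fs, new_sizes) {
  stopifnot(inherits(fs, "freq_spectrum"))
  if (fs$folded) stop("project unfolded spectra, then fold")
  new_sizes <- as.integer(new_sizes)
  if (length(new_sizes) != length(fs$sample_sizes)) {
    stop("new_sizes must match the number of population axes")
  }
  if (any(new_sizes > fs$sample_sizes) || any(new_sizes < 1L)) {
    stop("new_sizes must be between 1 and the current sample sizes")
  }
  phi <- fs$counts
  cur <- fs$sample_sizes
  for (p in seq_along(new_sizes)) {
    if (new_sizes[p] < cur[p]) {
      phi <- project_axis(phi, p, cur[p], new_sizes[p])
      cur[p] <- new_sizes[p]
    }
  }
  freq_spectrum(phi, new_sizes, folded = FALSE, pop_ids = fs$pop_ids)
}

project_axis <- function(phi, axis, N, n) {
  P <- outer(0:n, 0:N, function(i, I) {
    choose(I, i) * choose(N - I, n - i) / choose(N, n)
  })
  d <- dim(phi)
  perm <- c(axis, setdiff(seq_along(d), axis))
  ph <- aperm(phi, perm)
  mat <- matrix(ph, nrow = d[axis])
  out <- P %*% mat
  arr <- array(out, dim = c(n + 1L, d[setdiff(seq_along(d), axis)]))
  aperm(arr, order(perm))
}

# ---- operators ------------------------------------------------------------

.op_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.op_cache[[key]])) .op_cache[[key]] <- build()
  .op_cache[[key]]
}

# Drift operator on one axis, sample size n (indices 0..n), unit 1/(2 nu).
drift_matrix <- function(n) {
  cached(paste0("D", n), function() {
    i <- 0:n
    rows <- integer(0); cols <- integer(0); vals <- numeric(0)
    rows <- c(rows, i); cols <- c(cols, i); vals <- c(vals, -2 * i * (n - i))
    ii <- 1:n  # from i-1
    rows <- c(rows, ii); cols <- c(cols, ii - 1L)
    vals <- c(vals, (ii - 1) * (n - ii + 1))
    ii <- 0:(n - 1L)  # from i+1
    rows <- c(rows, ii); cols <- c(cols, ii + 1L)
    vals <- c(vals, (ii + 1) * (n - ii - 1))
    Matrix::sparseMatrix(i = rows + 1L, j = cols + 1L, x = vals,
                         dims = c(n + 1L, n + 1L))
  })
}

# Local-quadratic jackknife: (n+2) x (n+1) map from the order-n spectrum to
# the order-(n+1) spectrum. Moments of a quadratic density a + b x + c x^2:
#   Phi_m(i) = a/(m+1) + b (i+1)/((m+1)(m+2)) + c (i+1)(i+2)/((m+1)(m+2)(m+3))
# Fit (a, b, c) on the 3 consecutive order-n entries nearest the target.
jackknife_matrix <- function(n) {
  cached(paste0("J", n), function() {
    moment_row <- function(m, i) {
      c(1 / (m + 1),
        (i + 1) / ((m + 1) * (m + 2)),
        (i + 1) * (i + 2) / ((m + 1) * (m + 2) * (m + 3)))
    }
    J <- matrix(0, n + 2L, n + 1L)
    for (k in 0:(n + 1L)) {
      x_star <- (k + 1) / (n + 3)
      j_mid <- round(x_star * (n + 2) - 1)
      j0 <- min(max(j_mid - 1, 0), n - 2L)
      js <- j0 + 0:2
      A <- t(vapply(js, function(j) moment_row(n, j), numeric(3)))
      tk <- moment_row(n + 1L, k)
      J[k + 1L, js + 1L] <- solve(t(A), tk)
    }
    Matrix::Matrix(J, sparse = TRUE)
  })
}

# Kronecker assembly of per-axis operators over a column-major vec() of an
# array with extents `dims`; ops[[k]] = NULL means identity on axis k.
axis_kron <- function(ops, dims) {
  mats <- lapply(seq_along(dims), function(k) {
    if (is.null(ops[[k]])) Matrix::Diagonal(dims[k]) else ops[[k]]
  })
  Reduce(kronecker, rev(mats))
}

# Migration template for migrants into pop p from pop q (rate multiplier
# M_pq applied by the caller): the exact moment operator with the
# order-raising along axis q closed by the jackknife.
migration_template <- function(ns, p, q) {
  key <- paste0("G", paste(ns, collapse = "_"), ":", p, ":", q)
  cached(key, function() {
    dims <- ns + 1L
    np <- ns[p]; nq <- ns[q]
    i <- 0:np
    Tm <- Matrix::sparseMatrix(
      i = c(1:np + 1L, i + 1L, 0:(np - 1L) + 1L),
      j = c(1:np, i + 1L, 1:np + 1L),
      x = c((np - (1:np) + 1), (2 * i - np), -(1:np)),
      dims = c(np + 1L, np + 1L))
    Xm <- Matrix::sparseMatrix(
      i = c(i + 1L, 0:(np - 1L) + 1L),
      j = c(i + 1L, 1:np + 1L),
      x = c(-i, 1:np),
      dims = c(np + 1L, np + 1L))
    j <- 0:nq
    S <- Matrix::sparseMatrix(i = j + 1L, j = j + 2L, x = (j + 1) / (nq + 1),
                              dims = c(nq + 1L, nq + 2L))
    Y <- S %*% jackknife_matrix(nq)
    ops1 <- vector("list", length(dims)); ops1[[p]] <- Tm; ops1[[q]] <- Y
    ops2 <- vector("list", length(dims)); ops2[[p]] <- Xm
    axis_kron(ops1, dims) + axis_kron(ops2, dims)
  })
}

# Mutation influx vector at theta = 1: rate n_p / 2 into the singleton cell
# of each population axis.
influx_vector <- function(ns) {
  dims <- ns + 1L
  b <- array(0, dim = dims)
  for (p in seq_along(ns)) {
    idx <- rep(1L, length(ns))
    idx[p] <- 2L
    b[matrix(idx, 1L)] <- ns[p] / 2
  }
  as.vector(b)
}

integrate_epoch <- function(phi, ns, nu, mig, duration) {
  if (!is.finite(duration)) stop("cannot integrate an infinite epoch")
  if (duration <= 0) return(phi)
  dims <- ns + 1L
  d <- length(ns)
  keep <- setdiff(seq_len(prod(dims)), c(1L, prod(dims)))
  key <- paste(ns, collapse = "_")
  # operator templates with the absorbing corner cells already dropped and
  # the influx column appended (state augmented by a constant 1)
  drift_tpl <- lapply(seq_len(d), function(p) {
    cached(paste0("DK", key, ":", p), function() {
      ops <- vector("list", d); ops[[p]] <- drift_matrix(ns[p])
      M <- axis_kron(ops, dims)[keep, keep, drop = FALSE]
      methods::as(pad_affine(M, numeric(length(keep))), "dgCMatrix")
    })
  })
  mig_tpl <- function(p, q) {
    cached(paste0("GK", key, ":", p, ":", q), function() {
      M <- migration_template(ns, p, q)[keep, keep, drop = FALSE]
      methods::as(pad_affine(M, numeric(length(keep))), "dgCMatrix")
    })
  }
  influx_tpl <- cached(paste0("BK", key), function() {
    m <- length(keep)
    methods::as(pad_affine(
      Matrix::sparseMatrix(i = integer(0), j = integer(0), dims = c(m, m)),
      influx_vector(ns)[keep]), "dgCMatrix")
  })
  A <- influx_tpl
  for (p in seq_len(d)) A <- A + drift_tpl[[p]] / (2 * nu[p])
  for (p in seq_len(d)) {
    for (q in seq_len(d)) {
      if (p != q && mig[p, q] > 0) A <- A + mig[p, q] * mig_tpl(p, q)
    }
  }
  m <- length(keep)
  v <- expmv_sparse(methods::as(A, "dgCMatrix"),
                    c(as.vector(phi)[keep], 1), duration)[seq_len(m)]
  out <- array(0, dim = dims)
  out[keep] <- v
  out
}

# embed an m x m operator and an influx vector into the (m+1) augmented
# affine generator [[A, b], [0, 0]]
pad_affine <- function(A, b) {
  rbind(cbind(A, b),
        Matrix::sparseMatrix(i = integer(0), j = integer(0),
                             dims = c(1L, ncol(A) + 1L)))
}

# Hypergeometric redistribution of one deme's axis onto two daughter axes
# (just after a split both daughters share the parental allele frequency).
transition_split <- function(phi, old_ns, map, new_ns) {
  d_old <- length(old_ns)
  split_j <- which(vapply(seq_len(d_old), function(j) sum(map == j), 0L) == 2L)
  if (!length(split_j)) {
    return(array(phi, dim = new_ns + 1L))  # pure rename / size change
  }
  if (length(split_j) > 1L) stop("at most one deme may split per boundary")
  children <- which(map == split_j)
  if (!identical(children, seq(children[1L], length.out = 2L))) {
    stop("daughter demes of a split must be consecutive")
  }
  na <- new_ns[children[1L]]; nb <- new_ns[children[2L]]
  n <- old_ns[split_j]
  stopifnot(na + nb == n)
  Ssp <- split_matrix(n, na, nb)
  # move split axis to the front, contract, then restore axis order
  perm <- c(split_j, setdiff(seq_len(d_old), split_j))
  ph <- aperm(array(phi, dim = old_ns + 1L), perm)
  mat <- matrix(ph, nrow = n + 1L)
  new_front <- as.matrix(Ssp %*% mat)
  new_dims_front <- c(na + 1L, nb + 1L, (old_ns + 1L)[setdiff(seq_len(d_old),
                                                              split_j)])
  arr <- array(new_front, dim = new_dims_front)
  # target axis order: children at their positions, others in old order
  others_new <- setdiff(seq_along(new_ns), children)
  cur_order <- c(children, others_new)
  aperm(arr, order(cur_order))
}

split_matrix <- function(n, na, nb) {
  key <- paste0("S", n, "_", na, "_", nb)
  cached(key, function() {
    rows <- integer(0); cols <- integer(0); vals <- numeric(0)
    for (k in 0:n) {
      ia <- max(0L, k - nb):min(na, k)
      ib <- k - ia
      rows <- c(rows, ia + (na + 1L) * ib + 1L)
      cols <- c(cols, rep(k + 1L, length(ia)))
      vals <- c(vals, choose(na, ia) * choose(nb, ib) / choose(n, k))
    }
    Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                         dims = c((na + 1L) * (nb + 1L), n + 1L))
  })
}
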