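#' Build a joint site frequency spectrum from genotype likelihoods
#'
#' Two estimators are provided.
#'
#' `mode = "posterior"` (default): per site and population, the
#' alternate-allele frequency is estimated by EM within that population;
#' each individual's posterior expected dosage under a binomial prior at
#' that frequency is summed and rounded to the nearest integer cell.
#' Individuals without data contribute their prior mean `2 f`. Fast, and
#' exact when genotypes are certain; slightly biased toward the prior at
#' low depth.
#'
#' `mode = "joint_em"`: an EM estimator of the full spectrum. Per site
#' and population the likelihood of every possible allele count k is
#' computed exactly by dynamic programming over individuals (the
#' coefficient of \eqn{z^k} in \eqn{\prod_i [GL_i(0) + 2 GL_i(1) z +
#' GL_i(2) z^2]}, divided by \eqn{\binom{2n}{k}}), and the spectrum is the
#' maximum-likelihood mixture over cells. Unbiased at any depth; the two
#' modes agree on high-depth data.
#'
#' @param x a [gl_matrix()] (typically after filtering).
#' @param pops population labels to use as axes, in order; default all
#'   populations present.
#' @param folded fold the result onto minor-allele counts?
#' @param mode `"posterior"` or `"joint_em"`.
#' @param em_iter,em_tol stopping rule for `"joint_em"`.
#' @return a [freq_spectrum()] whose axis `p` has haploid size
#'   `2 * n_individuals(pop p)`.
#' @export
build_joint_sfs <- function(x, pops = NULL, folded = FALSE,
                            mode = c("posterior", "joint_em"),
                            em_iter = 100L, em_tol = 1e-8) {
  stopifnot(inherits(x, "gl_matrix"))
  mode <- match.arg(mode)
  if (is.null(pops)) pops <- unique(x$pop)
  if (!all(pops %in% x$pop)) {
    stop("population(s) not present: ",
         paste(setdiff(pops, x$pop), collapse = ", "))
  }
  if (length(pops) < 1L || length(pops) > 3L) {
    stop("1 to 3 population axes are supported")
  }
  idx_by_pop <- lapply(pops, function(p) which(x$pop == p))
  n_hap <- vapply(idx_by_pop, function(i) 2L * length(i), integer(1))
  n_sites <- nrow(x$sites)

  # warn if a population is mostly data-free
  for (k in seq_along(pops)) {
    miss <- vapply(seq_len(n_sites), function(s) {
      all(apply(x$gl[s, idx_by_pop[[k]], , drop = FALSE][1, , ,
                                                         drop = TRUE],
                1, function(tr) max(tr) - min(tr) < 1e-12))
    }, logical(1))
    if (mean(miss) > 0.5) {
      warning("population '", pops[k],
              "' has no informative individuals at >50% of sites")
    }
  }

  counts <- array(0, dim = n_hap + 1L)
  if (mode == "posterior") {
    for (s in seq_len(n_sites)) {
      cell <- integer(length(pops))
      for (k in seq_along(pops)) {
        gls <- x$gl[s, idx_by_pop[[k]], , drop = FALSE][1, , ,
                                                        drop = TRUE]
        gls <- matrix(gls, ncol = 3L)
        est <- estimate_maf(gls)
        f <- if (is.na(est$f_alt)) 0 else est$f_alt
        pg <- c((1 - f)^2, 2 * f * (1 - f), f^2)
        w <- gls * rep(pg, each = nrow(gls))
        rs <- rowSums(w)
        informative <- apply(gls, 1, function(tr) max(tr) - min(tr) >= 1e-12)
        dosage <- ifelse(informative & rs > 0,
                         as.numeric((w %*% c(0, 1, 2)) / pmax(rs, 1e-300)),
                         2 * f)
        cell[k] <- min(max(0L, as.integer(round(sum(dosage)))), n_hap[k])
      }
      counts[matrix(cell + 1L, 1L)] <- counts[matrix(cell + 1L, 1L)] + 1
    }
  } else {
    # per-site, per-pop exact count likelihoods by DP
    like <- vector("list", length(pops))
    for (k in seq_along(pops)) {
      nk <- n_hap[k]
      L <- matrix(0, n_sites, nk + 1L)
      for (s in seq_len(n_sites)) {
        poly <- 1
        for (i in idx_by_pop[[k]]) {
          tr <- x$gl[s, i, ]
          poly <- convolve_poly(poly, c(tr[1L], 2 * tr[2L], tr[3L]))
        }
        L[s, ] <- poly / choose(nk, 0:nk)
      }
      L <- L / pmax(rowSums(L), 1e-300)
      like[[k]] <- L
    }
    # site x cell likelihood, cells in column-major order over dims
    cell_lik <- matrix(1, n_sites, prod(n_hap + 1L))
    dims <- n_hap + 1L
    cellidx <- arrayInd(seq_len(prod(dims)), dims)
    for (k in seq_along(pops)) {
      cell_lik <- cell_lik * like[[k]][, cellidx[, k], drop = FALSE]
    }
    mask0 <- as.vector(freq_spectrum(array(1, dims))$mask)
    phi <- rep(1, prod(dims))
    phi[mask0] <- 0
    phi <- phi / sum(phi)
    prev <- -Inf
    for (it in seq_len(em_iter)) {
      w <- cell_lik * rep(phi, each = n_sites)
      rs <- rowSums(w)
      ll <- sum(log(pmax(rs, 1e-300)))
      w <- w / pmax(rs, 1e-300)
      phi <- colSums(w)
      phi[mask0] <- 0
      phi <- phi / sum(phi)
      if (is.finite(prev) && ll - prev < em_tol * abs(ll)) break
      prev <- ll
    }
    counts <- array(phi * n_sites, dim = dims)
  }
  fs <- freq_spectrum(counts, n_hap, folded = FALSE, pop_ids = pops)
  if (folded) fs <- fold_spectrum(fs)
  fs
}

convolve_poly <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i + seq_along(b) - 1L] <- out[i + seq_along(b) - 1L] + a[i] * b
  }
  out
}
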