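#' Maximum-likelihood allele frequency from genotype likelihoods
#'
#' Estimates the alternate-allele frequency at one site by maximizing
#' \eqn{\ell(f) = \sum_i \log \sum_g GL_i(g) \binom{2}{g} f^g (1-f)^{2-g}}
#' over individuals with data, using EM: the update replaces `f` with the
#' mean posterior allele dosage divided by two. The likelihood is
#' non-decreasing at every iteration; convergence is declared when the
#' frequency moves by less than `tol` (default 1e-8) or after `max_iter`
#' (default 200) iterations.
#'
#' Individuals whose likelihood triple is flat carry no data; they are
#' excluded from the estimate and from `n_informative`.
#'
#' @param site_gls numeric matrix (individuals x 3) of linear-scale
#'   genotype likelihoods for one site.
#' @param tol,max_iter EM stopping rule.
#' @param trace keep the per-iteration log-likelihood trace?
#' @return a list: `f_alt` (ML alternate-allele frequency in [0,1]),
#'   `loglik`, `n_informative`, `converged`, `n_iter`, and optionally
#'   `trace`. If no individual has data, `f_alt` is `NA` and the site is
#'   unestimable.
#' @export
estimate_maf <- function(site_gls, tol = 1e-8, max_iter = 200L,
                         trace = FALSE) {
  gl <- as.matrix(site_gls)
  if (ncol(gl) != 3L) stop("site_gls must have 3 genotype columns")
  if (nrow(gl) < 1L) stop("at least one individual is required")
  informative <- apply(gl, 1, function(tr) max(tr) - min(tr) >= 1e-12)
  g <- gl[informative, , drop = FALSE]
  n <- nrow(g)
  if (n == 0L) {
    return(list(f_alt = NA_real_, loglik = NA_real_, n_informative = 0L,
                converged = FALSE, n_iter = 0L))
  }
  loglik_at <- function(f) {
    pg <- c((1 - f)^2, 2 * f * (1 - f), f^2)
    sum(log(pmax(g %*% pg, .Machine$double.xmin)))
  }
  # the per-site likelihood can be bimodal in f, so EM is run from a small
  # ladder of starting frequencies and the best mode is kept
  run_em <- function(f) {
    ll_trace <- if (trace) numeric(0) else NULL
    converged <- FALSE
    it <- 0L
    repeat {
      it <- it + 1L
      pg <- c((1 - f)^2, 2 * f * (1 - f), f^2)
      w <- g * rep(pg, each = n)
      w <- w / pmax(rowSums(w), .Machine$double.xmin)
      f_new <- mean(w %*% c(0, 1, 2)) / 2
      if (trace) ll_trace <- c(ll_trace, loglik_at(f_new))
      if (abs(f_new - f) < tol) {
        f <- f_new
        converged <- TRUE
        break
      }
      f <- f_new
      if (it >= max_iter) break
    }
    list(f = f, loglik = loglik_at(f), converged = converged, n_iter = it,
         trace = ll_trace)
  }
  cands <- lapply(c(0.05, 0.25, 0.5, 0.75, 0.95), run_em)
  best <- cands[[which.max(vapply(cands, `[[`, 0, "loglik"))]]
  # local polish: EM contracts slowly on nearly flat likelihoods
  lo <- max(0, best$f - 0.05); hi <- min(1, best$f + 0.05)
  pol <- stats::optimize(loglik_at, c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  for (fb in unique(c(lo, hi, pol$maximum))) {
    if (loglik_at(fb) > best$loglik + 1e-12) {
      best$f <- fb
      best$loglik <- loglik_at(fb)
    }
  }
  out <- list(f_alt = best$f, loglik = best$loglik, n_informative = n,
              converged = best$converged, n_iter = best$n_iter)
  if (trace) out$trace <- best$trace
  out
}

#' Likelihood-ratio test for polymorphism
#'
#' Tests the ML frequency against the null of a monomorphic site (minor
#' allele frequency zero): `LRT = 2 * (l(f_hat) - l(f0))` where `f0` fixes
#' the site at the major allele. The p-value uses the upper tail of
#' chi-squared with 1 degree of freedom; because the null lies on the
#' parameter boundary this is conservative (the test never overstates
#' significance), matching common genotype-likelihood callers.
#'
#' @inheritParams estimate_maf
#' @return list with `lrt` (>= 0), `p_value`, plus the [estimate_maf()]
#'   fields.
#' @export
polymorphism_test <- function(site_gls) {
  est <- estimate_maf(site_gls)
  if (is.na(est$f_alt)) {
    return(c(est, list(lrt = NA_real_, p_value = NA_real_)))
  }
  gl <- as.matrix(site_gls)
  informative <- apply(gl, 1, function(tr) max(tr) - min(tr) >= 1e-12)
  g <- gl[informative, , drop = FALSE]
  f0 <- if (est$f_alt <= 0.5) 0 else 1
  pg0 <- c((1 - f0)^2, 2 * f0 * (1 - f0), f0^2)
  ll0 <- sum(log(pmax(g %*% pg0, .Machine$double.xmin)))
  lrt <- max(0, 2 * (est$loglik - ll0))
  p <- if (lrt == 0) 1 else pchisq(lrt, df = 1, lower.tail = FALSE)
  c(est, list(lrt = lrt, p_value = p))
}

#' Infer major and minor alleles from genotype likelihoods
#'
#' The major allele is the one with the higher ML frequency; an exact tie
#' at 0.5 is broken lexicographically by allele label (and reported via
#' the `tie` flag).
#'
#' @inheritParams estimate_maf
#' @param allele1,allele2 the two allele labels of the site.
#' @return list with `major`, `minor`, `f_minor` (in [0, 0.5]) and `tie`.
#' @export
infer_major_minor <- function(site_gls, allele1 = "A", allele2 = "C") {
  est <- estimate_maf(site_gls)
  if (is.na(est$f_alt)) {
    return(list(major = NA_character_, minor = NA_character_,
                f_minor = NA_real_, tie = FALSE))
  }
  f2 <- est$f_alt  # frequency of allele2
  tie <- abs(f2 - 0.5) < 1e-12
  if (tie) {
    ord <- order(c(allele1, allele2))
    major <- c(allele1, allele2)[ord[1L]]
    minor <- c(allele1, allele2)[ord[2L]]
  } else if (f2 > 0.5) {
    major <- allele2; minor <- allele1
  } else {
    major <- allele1; minor <- allele2
  }
  list(major = major, minor = minor, f_minor = min(f2, 1 - f2), tie = tie)
}

#' Per-site frequency estimates for a whole gl_matrix
#'
#' Runs [estimate_maf()], [polymorphism_test()] and [infer_major_minor()]
#' across all sites and returns the site-estimate table used by the
#' filtering stage.
#'
#' @param x a [gl_matrix()].
#' @return data.frame with columns chrom, pos, major, minor, f_hat (minor
#'   allele frequency), f_alt, lrt, p_value, n_ind.
#' @export
estimate_site_frequencies <- function(x) {
  stopifnot(inherits(x, "gl_matrix"))
  n_sites <- nrow(x$sites)
  res <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    gls <- x$gl[s, , ]
    pt <- polymorphism_test(gls)
    mm <- if (is.na(pt$f_alt)) {
      list(major = NA_character_, minor = NA_character_, f_minor = NA_real_)
    } else {
      a1 <- x$sites$allele1[s]; a2 <- x$sites$allele2[s]
      f2 <- pt$f_alt
      if (abs(f2 - 0.5) < 1e-12) {
        ord <- order(c(a1, a2))
        list(major = c(a1, a2)[ord[1]], minor = c(a1, a2)[ord[2]],
             f_minor = 0.5)
      } else if (f2 > 0.5) {
        list(major = a2, minor = a1, f_minor = 1 - f2)
      } else {
        list(major = a1, minor = a2, f_minor = f2)
      }
    }
    res[[s]] <- data.frame(
      chrom = x$sites$chrom[s], pos = x$sites$pos[s],
      major = mm$major, minor = mm$minor, f_hat = mm$f_minor,
      f_alt = pt$f_alt, lrt = pt$lrt, p_value = pt$p_value,
      n_ind = pt$n_informative, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, res)
}
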