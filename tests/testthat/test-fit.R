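test_that("the Poisson composite likelihood profiles theta exactly", {
  one_cell <- function(v) {
    counts <- array(c(0, v, 0), dim = 3L)
    freq_spectrum(counts)
  }
  cl <- composite_loglik(one_cell(1), one_cell(1))
  expect_equal(cl$theta_hat, 1)
  expect_equal(cl$loglik, -1)  # 1*log(1) - 1 - log(1!)
  # observed = c * expected -> theta_hat = c exactly
  m <- two_pop_model(t_split = 0.2, m12 = 1, m21 = 1)
  e <- expected_sfs(m, c(6, 6))
  obs <- freq_spectrum(e$counts * 137.5, c(6, 6))
  expect_equal(composite_loglik(obs, e)$theta_hat, 137.5, tolerance = 1e-12)
})

test_that("the composite likelihood matches term-by-term hand evaluation", {
  obs_c <- array(c(0, 3, 1, 2, 5, 0, 1, 2, 0), c(3, 3))
  exp_c <- array(c(0, 2, 1, 3, 4, 1, 2, 1, 0), c(3, 3)) + 0.5
  obs <- freq_spectrum(obs_c)
  expd <- freq_spectrum(exp_c)
  expd$mask <- obs$mask
  cl <- composite_loglik(obs, expd)
  use <- !obs$mask
  th <- sum(obs_c[use]) / sum(exp_c[use])
  hand <- sum(obs_c[use] * log(th * exp_c[use]) - th * exp_c[use] -
                lgamma(obs_c[use] + 1))
  expect_equal(cl$loglik, hand, tolerance = 1e-12)
  # contract errors
  expect_error(composite_loglik(obs, freq_spectrum(array(1, c(4, 4)))),
               "shapes")
  expect_error(composite_loglik(obs, fold_spectrum(expd)), "folding")
})

test_that("fitting a model to its own expectation recovers the parameters", {
  truth <- two_pop_model(nu_anc = 3, t_anc = 0.3, nu1 = 1, nu2 = 1,
                         t_split = 0.1, m12 = 1, m21 = 1)
  efs <- expected_sfs(truth, c(8, 8), extra = 0)
  obs <- freq_spectrum(efs$counts * 5000, c(8, 8))
  fit <- fit_model(obs, "two_pop_sizechange_split_mig", n_starts = 3,
                   seed = 1, extra = 0, maxit = 400)
  expect_gte(fit$n_converged, 1L)
  rel <- abs(fit$best$params - truth$params) /
    pmax(abs(truth$params), 1e-12)
  expect_true(all(rel < 0.01))
  truth_ll <- composite_loglik(obs, expected_sfs(truth, c(8, 8),
                                                 extra = 0))$loglik
  expect_gte(fit$best$loglik, truth_ll - 1e-4)
})

test_that("likelihood at the generating parameters beats random perturbations", {
  truth <- two_pop_model(nu_anc = 2, t_anc = 0.25, t_split = 0.12,
                         m12 = 0.8, m21 = 1.2)
  efs <- expected_sfs(truth, c(6, 6), extra = 2)
  obs <- freq_spectrum(efs$counts * 2000, c(6, 6))
  ll_truth <- composite_loglik(obs, efs)$loglik
  set.seed(5)
  worse <- vapply(1:100, function(i) {
    p <- truth$params * 2^runif(length(truth$params), -0.7, 0.7)
    m <- demographic_model("two_pop_sizechange_split_mig", p)
    composite_loglik(obs, expected_sfs(m, c(6, 6), extra = 2))$loglik
  }, numeric(1))
  expect_true(all(worse <= ll_truth + 1e-6))
})

test_that("degenerate observed spectra do not crash the fit", {
  counts <- array(0, c(7, 7))
  counts[3, 1] <- 500
  obs <- freq_spectrum(counts)
  res <- tryCatch(
    fit_model(obs, "two_pop_sizechange_split_mig", n_starts = 2, seed = 2,
              extra = 0, maxit = 150),
    error = function(e) e
  )
  # either a fit object or an informative no-convergence error is fine
  expect_true(inherits(res, "sfs_fit") || inherits(res, "error"))
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "converge")
  }
})

test_that("fits are deterministic under a seed", {
  truth <- two_pop_model(t_split = 0.1, m12 = 1, m21 = 1)
  efs <- expected_sfs(truth, c(6, 6), extra = 0)
  obs <- freq_spectrum(efs$counts * 1000, c(6, 6))
  f1 <- fit_model(obs, "two_pop_sizechange_split_mig", n_starts = 2,
                  seed = 9, extra = 0, maxit = 150)
  f2 <- fit_model(obs, "two_pop_sizechange_split_mig", n_starts = 2,
                  seed = 9, extra = 0, maxit = 150)
  expect_equal(f1$runs, f2$runs)
})
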