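test_that("error-free deep reads identify the genotype", {
  m <- two_pop_model(t_split = 0.2, m12 = 1, m21 = 1)
  g <- simulate_coalescent(m, c(6, 6), 300, 0.1, seed = 3,
                           return_genotypes = TRUE)
  x <- simulate_genotype_likelihoods(g$genotypes, g$sites, g$pop,
                                     mean_depth = 30, error_rate = 0,
                                     seed = 1)
  dp <- attr(x, "depth")
  tot <- x$gl[, , 1] + x$gl[, , 2] + x$gl[, , 3]
  for (k in 1:3) {
    sel <- g$genotypes == (k - 1) & dp > 0
    expect_true(all((x$gl[, , k] / tot)[sel] > 0.999))
  }
})

test_that("zero-depth individuals get a flat (missing) likelihood triple", {
  geno <- matrix(c(0L, 2L), 1, 2)
  x <- simulate_genotype_likelihoods(geno, mean_depth = 0, error_rate = 0.01,
                                     seed = 2)
  expect_equal(x$gl[1, 1, ], c(1, 1, 1))
  expect_equal(x$gl[1, 2, ], c(1, 1, 1))
})

test_that("the single-read likelihood matches hand enumeration", {
  # one alternate read at error rate 0.01: P(alt|g) = (g/2)(1-e)+(1-g/2)e/3
  eps <- 0.01
  hand <- c(eps / 3, 0.5 * (1 - eps) + 0.5 * eps / 3, 1 - eps)
  # force depth 1 by resampling until exactly one kept alt read shows up
  found <- FALSE
  for (s in 1:200) {
    x <- simulate_genotype_likelihoods(matrix(2L), mean_depth = 1,
                                       error_rate = eps, seed = s)
    if (attr(x, "depth")[1, 1] == 1L && x$gl[1, 1, 3] == 1) {
      found <- TRUE
      expect_equal(x$gl[1, 1, ], hand / max(hand), tolerance = 1e-12)
      break
    }
  }
  expect_true(found)
  # ratio quoted from the per-read model
  expect_equal(hand[2] / hand[1],
               (0.5 * (1 - eps) + 0.5 * eps / 3) / (eps / 3))
})

test_that("GL simulation is deterministic under a fixed seed", {
  geno <- matrix(sample(0:2, 60, replace = TRUE), 10, 6)
  a <- simulate_genotype_likelihoods(geno, mean_depth = 6,
                                     error_rate = 0.02, seed = 11)
  b <- simulate_genotype_likelihoods(geno, mean_depth = 6,
                                     error_rate = 0.02, seed = 11)
  expect_identical(a$gl, b$gl)
  expect_error(simulate_genotype_likelihoods(geno, error_rate = 0.5),
               "0.5")
})

test_that("ML frequency estimation bias shrinks as depth grows", {
  m <- demographic_model("one_pop_sizechange")
  g <- simulate_coalescent(m, 24, 400, 0.3, seed = 5,
                           return_genotypes = TRUE)
  f_true <- rowSums(g$genotypes) / 24
  err_at_depth <- vapply(c(2, 8, 40), function(d) {
    x <- simulate_genotype_likelihoods(g$genotypes, g$sites, g$pop,
                                       mean_depth = d, error_rate = 0.01,
                                       seed = 6)
    f_hat <- vapply(seq_len(nrow(g$genotypes)), function(s) {
      estimate_maf(x$gl[s, , ])$f_alt
    }, numeric(1))
    mean(abs(f_hat - f_true))
  }, numeric(1))
  expect_true(all(diff(err_at_depth) < 0))
  expect_lt(err_at_depth[3], 0.01)
})
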