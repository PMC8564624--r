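test_that("the single-population equilibrium spectrum is theta/i", {
  for (n in c(4, 10, 20)) {
    fs <- expected_sfs(demographic_model("one_pop_sizechange"), n)
    expect_equal(as.numeric(fs$counts[2:n]), 1 / (1:(n - 1)),
                 tolerance = 0.005)
  }
})

test_that("a vanishing split time reduces to the projected panmictic spectrum", {
  m <- two_pop_model(t_split = 1e-4, m12 = 1, m21 = 1)
  fs <- expected_sfs(m, c(6, 6))
  pan <- c(0, 1 / (1:11), 0)
  proj <- array(0, c(7, 7))
  for (k in 0:12) {
    for (ia in max(0, k - 6):min(6, k)) {
      proj[ia + 1, k - ia + 1] <- proj[ia + 1, k - ia + 1] +
        choose(6, ia) * choose(6, k - ia) / choose(12, k) * pan[k + 1]
    }
  }
  expect_lt(tv_distance(fs, proj, fs$mask), 1e-3)
})

test_that("the expected spectrum is exactly linear in theta", {
  m <- two_pop_model(nu_anc = 2, t_anc = 0.3, t_split = 0.15, m12 = 1,
                     m21 = 0.5)
  a <- expected_sfs(m, c(6, 6), theta = 1)
  b <- expected_sfs(m, c(6, 6), theta = 7.3)
  expect_equal(b$counts, 7.3 * a$counts, tolerance = 1e-12)
})

test_that("population relabeling symmetry holds", {
  m_ab <- two_pop_model(nu_anc = 2, t_anc = 0.2, nu1 = 0.5, nu2 = 2,
                        t_split = 0.15, m12 = 1.5, m21 = 0.3)
  m_ba <- two_pop_model(nu_anc = 2, t_anc = 0.2, nu1 = 2, nu2 = 0.5,
                        t_split = 0.15, m12 = 0.3, m21 = 1.5)
  a <- expected_sfs(m_ab, c(6, 8))
  b <- expected_sfs(m_ba, c(8, 6))
  expect_equal(a$counts, t(b$counts), tolerance = 1e-10)
})

test_that("the two-population expectation matches the coalescent oracle without migration", {
  m <- two_pop_model(t_split = 0.2)
  e <- expected_sfs(m, c(6, 6))
  sim <- simulate_coalescent(m, c(6, 6), n_sites = 1e5,
                             theta_per_site = 0.2, seed = 41)
  expect_lt(tv_distance(e, sim$sfs$counts, e$mask), 0.012)
})

test_that("three-population spectra integrate and keep their mass sensible", {
  m3 <- three_pop_model(nu_anc = 1.5, t_anc = 0.2, t_split = 0.3,
                        t_split2 = 0.1, m12 = 0.5, m21 = 0.5)
  fs <- expected_sfs(m3, c(4, 4, 4), extra = 2)
  expect_equal(dim(fs$counts), c(5L, 5L, 5L))
  expect_true(all(fs$counts >= 0))
  expect_gt(spectrum_total(fs), 0)
  # oracle check at modest replication
  sim <- simulate_coalescent(m3, c(4, 4, 4), n_sites = 6e4,
                             theta_per_site = 0.2, seed = 43)
  expect_lt(tv_distance(fs, sim$sfs$counts, fs$mask), 0.03)
})

test_that("folding the expectation equals the folded expectation", {
  m <- two_pop_model(t_split = 0.2, m12 = 1, m21 = 1)
  a <- expected_sfs(m, c(6, 6), folded = TRUE)
  b <- fold_spectrum(expected_sfs(m, c(6, 6)))
  expect_equal(a$counts, b$counts, tolerance = 1e-12)
})

test_that("projection is hypergeometric and consistent", {
  m <- two_pop_model(t_split = 0.2, m12 = 1, m21 = 1)
  big <- expected_sfs(m, c(10, 10))
  small <- project_spectrum(big, c(6, 6))
  direct <- expected_sfs(m, c(6, 6))
  expect_lt(tv_distance(small, direct$counts, direct$mask), 2e-3)
  expect_error(project_spectrum(fold_spectrum(big), c(6, 6)), "unfolded")
})

test_that("invalid inputs are rejected", {
  m <- two_pop_model(t_split = 0.2)
  expect_error(expected_sfs(m, c(6, 6, 6)), "one haploid count")
  expect_error(expected_sfs(m, c(50, 6)), "at most 40")
  expect_error(expected_sfs(m, c(6, 6), theta = -1), "theta")
})
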