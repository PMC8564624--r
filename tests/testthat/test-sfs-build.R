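make_certain_gl_matrix <- function(genotypes, pop) {
  n_sites <- nrow(genotypes)
  gl <- array(0, dim = c(n_sites, ncol(genotypes), 3))
  for (g in 0:2) gl[, , g + 1][genotypes == g] <- 1
  sites <- data.frame(chrom = "c1", pos = seq_len(n_sites) * 10,
                      allele1 = "A", allele2 = "C")
  gl_matrix(gl, sites, pop)
}

test_that("certain genotypes tabulate exactly, in both modes", {
  m <- two_pop_model(t_split = 0.2, m12 = 1, m21 = 1)
  g <- simulate_coalescent(m, c(6, 6), 400, 0.1, seed = 13,
                           return_genotypes = TRUE)
  x <- make_certain_gl_matrix(g$genotypes, g$pop)
  fs_post <- build_joint_sfs(x, c("pop1", "pop2"))
  expect_equal(fs_post$counts, g$sfs$counts)
  fs_em <- build_joint_sfs(x, c("pop1", "pop2"), mode = "joint_em")
  expect_lt(tv_distance(fs_em, g$sfs$counts, fs_em$mask), 1e-6)
})

test_that("folding conserves counts and is idempotent", {
  m <- two_pop_model(t_split = 0.2, m12 = 1, m21 = 1)
  sim <- simulate_coalescent(m, c(6, 6), 3000, 0.1, seed = 14)
  folded <- fold_spectrum(sim$sfs)
  expect_equal(sum(folded$counts[!folded$mask]),
               sum(sim$sfs$counts[!sim$sfs$mask]))
  expect_identical(fold_spectrum(folded), folded)
  expect_true(folded$folded)
  # the non-canonical half-lattice (total derived count > n/2) is masked
  upper <- outer(0:6, 0:6, `+`) > 6
  expect_true(all(folded$mask[upper]))
})

test_that("spectra from noisy likelihoods stay close to the true tabulation", {
  m <- two_pop_model(t_split = 0.2, m12 = 1, m21 = 1)
  g <- simulate_coalescent(m, c(8, 8), 1200, 0.1, seed = 15,
                           return_genotypes = TRUE)
  x <- simulate_genotype_likelihoods(g$genotypes, g$sites, g$pop,
                                     mean_depth = 20, error_rate = 0.01,
                                     seed = 16)
  fs <- build_joint_sfs(x, c("pop1", "pop2"))
  expect_lt(tv_distance(fs, g$sfs$counts, fs$mask), 0.02)
  fs_em <- build_joint_sfs(x, c("pop1", "pop2"), mode = "joint_em")
  expect_lt(tv_distance(fs_em, g$sfs$counts, fs_em$mask), 0.02)
})

test_that(".fs files round-trip including folding, masks and labels", {
  m <- two_pop_model(t_split = 0.2, m12 = 1, m21 = 1)
  sim <- simulate_coalescent(m, c(6, 8), 500, 0.1, seed = 17)
  fs <- sim$sfs
  fs$pop_ids <- c("spain", "cne")
  f <- withr::local_tempfile(fileext = ".fs")
  write_fs(fs, f)
  back <- read_fs(f)
  expect_equal(back$counts, fs$counts)
  expect_identical(back$mask, fs$mask)
  expect_equal(back$pop_ids, fs$pop_ids)
  folded <- fold_spectrum(fs)
  write_fs(folded, f)
  back2 <- read_fs(f)
  expect_true(back2$folded)
  expect_equal(back2$counts, folded$counts)
})

test_that("Beagle files round-trip through write and read", {
  m <- two_pop_model(t_split = 0.2)
  g <- simulate_coalescent(m, c(4, 4), 200, 0.1, seed = 18,
                           return_genotypes = TRUE)
  x <- simulate_genotype_likelihoods(g$genotypes, g$sites, g$pop,
                                     mean_depth = 8, error_rate = 0.01,
                                     seed = 19)
  f <- withr::local_tempfile(fileext = ".beagle")
  write_beagle(x, f)
  back <- read_beagle(f, x$pop)
  expect_equal(back$gl, x$gl, tolerance = 1e-5)
  expect_equal(back$sites$pos, x$sites$pos)
  expect_equal(back$sites$allele2, x$sites$allele2)
})

test_that("low-MAF masking removes exactly the unobservable cells", {
  m <- two_pop_model(t_split = 0.2, m12 = 1, m21 = 1)
  sim <- simulate_coalescent(m, c(6, 6), 500, 0.1, seed = 20)
  masked <- mask_low_maf(sim$sfs, 0.05)
  tot <- outer(0:6, 0:6, `+`)
  expect_true(all(masked$mask[pmin(tot, 12 - tot) / 12 <= 0.05]))
  expect_false(any(masked$mask[pmin(tot, 12 - tot) / 12 > 0.05 &
                                 !sim$sfs$mask]))
})
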