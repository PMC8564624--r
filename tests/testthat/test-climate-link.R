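test_that("resampling keeps lattices fixed and interpolates irregular series", {
  lattice <- climate_series(seq(10000, 0, -1000), rnorm(11))
  expect_equal(resample_series(lattice)$temp_c, lattice$temp_c)
  fine <- climate_series(seq(10000, 0, -100), seq(10000, 0, -100) / 1000)
  rs <- resample_series(fine)
  expect_equal(nrow(rs), 11L)
  expect_equal(rs$temp_c, rs$age_bp / 1000)
  # hand-computed linear interpolation on an irregular 4-point fixture
  irr <- climate_series(c(3300, 2100, 900, 100), c(3, 9, 1, 5))
  li <- resample_series(irr, 1000, method = "linear")
  expect_equal(li$age_bp, c(3000, 2000, 1000))
  expect_equal(li$temp_c[1], 9 + (3 - 9) * (3000 - 2100) / (3300 - 2100))
  expect_equal(li$temp_c[2], 1 + (9 - 1) * (2000 - 900) / (2100 - 900))
  expect_equal(li$temp_c[3], 1 + (9 - 1) * (1000 - 900) / (2100 - 900))
})

test_that("the ROC formula and its guards behave as printed", {
  expect_equal(rate_of_change(climate_series(c(2000, 1000),
                                             c(10, 11)))$roc, 10)
  # zero-crossing anomaly denominators are flagged, not propagated
  r <- rate_of_change(climate_series(c(3000, 2000, 1000), c(1, 0, 2)))
  expect_true(is.na(r$roc[2]))
  expect_equal(attr(r, "n_nonfinite"), 1L)
  # absolute mode has no guard problem
  ra <- rate_of_change(climate_series(c(3000, 2000, 1000), c(1, 0, 2)),
                       mode = "absolute")
  expect_equal(ra$roc, c(-1, 2))
})

test_that("ROC is scale-equivariant and time-relabeling invariant", {
  set.seed(4)
  y <- cumsum(rnorm(50)) + 20
  a <- rate_of_change(climate_series(seq(50000, 1000, -1000), y))
  b <- rate_of_change(climate_series(seq(50000, 1000, -1000), 3 * y))
  expect_equal(a$roc, b$roc, tolerance = 1e-12)
  c2 <- rate_of_change(climate_series(seq(100000, 2000, -2000), y))
  expect_equal(a$roc, c2$roc, tolerance = 1e-12)
})

test_that("the smoother reproduces its fixed points and matches a brute-force WLS", {
  ages <- seq(100000, 0, -500)
  lin <- climate_series(ages, 2 + ages * 1e-4)
  expect_equal(smooth_series(lin, 0.05)$temp_c, lin$temp_c,
               tolerance = 1e-10)
  const <- climate_series(ages, rep(3, length(ages)))
  expect_equal(smooth_series(const, 0.05)$temp_c, const$temp_c,
               tolerance = 1e-12)
  set.seed(8)
  noisy <- climate_series(ages, sin(ages / 8000) + rnorm(length(ages), 0,
                                                         0.3))
  sm <- smooth_series(noisy, 0.05)
  oracle <- brute_local_linear(noisy$age_bp, noisy$temp_c, 0.05)
  expect_lt(sqrt(mean((sm$temp_c - oracle)^2)), 1e-6)
  expect_error(smooth_series(climate_series(c(3000, 2000), c(1, 2))),
               "too few")
})

test_that("episodes are detected at spikes and merged across small gaps", {
  mk_roc <- function(vals) {
    s <- climate_series(seq(length(vals) * 1000, 0, -1000),
                        c(0, cumsum(vals)))
    rate_of_change(s, mode = "absolute")
  }
  one <- mk_roc(c(rep(0, 10), 5, rep(0, 10)))
  ep <- detect_episodes(one, 0.9)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$start_bp - ep$end_bp, 1000)  # one-step width
  # two spikes with one sub-threshold step between them merge at gap 1
  two <- mk_roc(c(rep(0, 8), 5, 0, 5, rep(0, 8)))
  expect_equal(nrow(detect_episodes(two, 0.85, merge_gap = 1L)), 1L)
  expect_equal(nrow(detect_episodes(two, 0.85, merge_gap = 0L)), 2L)
  # intervals never overlap after merging
  set.seed(10)
  noisy <- mk_roc(rnorm(200))
  epn <- detect_episodes(noisy, 0.8)
  if (nrow(epn) > 1L) {
    expect_true(all(epn$end_bp[-nrow(epn)] > epn$start_bp[-1L]))
  }
  expect_lte(sum(epn$start_bp - epn$end_bp), diff(range(noisy$age_bp)) +
               1000)
})

test_that("interval overlap and its permutation null behave correctly", {
  s <- simulate_climate(100000, 1000, baseline = 5,
                        events = list(list(onset_bp = 60000,
                                           amplitude = 16,
                                           ramp_years = 1000)))
  roc <- rate_of_change(resample_series(s), mode = "absolute")
  ep <- detect_episodes(roc, 0.98)
  inside <- interval_episode_overlap(c(ep$start_bp[1] - 100,
                                       ep$end_bp[1] + 100), ep,
                                     n_permutations = 200, seed = 1)
  expect_equal(inside$overlap, 1)
  # no episodes -> overlap 0, p 1
  empty <- structure(ep[0, ], threshold = 1, quantile = 0.9, step = 1000,
                     span = attr(ep, "span"),
                     class = c("episode_set", "data.frame"))
  none <- interval_episode_overlap(c(50000, 40000), empty,
                                   n_permutations = 50, seed = 2)
  expect_equal(none$overlap, 0)
  expect_equal(none$p_value, 1)
  # mean overlap under shifts approximates the episode coverage fraction
  cover_frac <- sum(ep$start_bp - ep$end_bp) / diff(range(attr(ep, "span")))
  ov <- interval_episode_overlap(c(30000, 20000), ep,
                                 n_permutations = 2000, seed = 3)
  expect_lt(abs(ov$null_mean - cover_frac), 3 * 0.02)
  expect_error(interval_episode_overlap(c(2e6, 1e6), ep), "outside")
})
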