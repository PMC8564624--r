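test_that("thinning keeps one record per cell with a hand-checked assignment", {
  pts <- data.frame(lon = c(0, 0.01, 5, 5.01, 10, 0),
                    lat = c(50, 50, 50, 50, 50, 55))
  th <- thin_occurrences(pts, 50, seed = 1)
  expect_equal(nrow(th), 4L)
  # all in distinct cells -> identity
  apart <- data.frame(lon = c(0, 5, 10), lat = c(40, 50, 60))
  expect_equal(nrow(thin_occurrences(apart, 50, seed = 1)), 3L)
  # 10 points over 6 cells, oracle = manual cell indexing
  set.seed(2)
  base <- data.frame(lon = c(0, 0, 3, 3, 6, 6, 9, 9, 12, 15),
                     lat = rep(50, 10))
  km <- 111.320 * cos(50 * pi / 180)
  cells <- floor(base$lon * km / 300)
  th2 <- thin_occurrences(base, 300, seed = 3)
  expect_equal(nrow(th2), length(unique(cells)))
})

test_that("background sampling is uniform, exhaustive and seeded", {
  L <- simulate_landscape(grid_shape = c(10, 10), n_presence = 20,
                          n_background = 20, seed = 1)
  all_cells <- sample_background(L$stack, 100, seed = 2)
  expect_equal(nrow(unique(all_cells)), 100L)
  a <- sample_background(L$stack, 30, seed = 5)
  b <- sample_background(L$stack, 30, seed = 5)
  expect_identical(a, b)
  expect_error(sample_background(L$stack, 101), "exceeds")
  # inclusion frequencies across seeded draws match the binomial band
  counts <- matrix(0, 10, 10)
  for (s in 1:200) {
    pts <- sample_background(L$stack, 30, seed = 1000 + s)
    idx <- cell_index(L$stack, pts$lon, pts$lat)
    counts[idx] <- counts[idx] + 1
  }
  p <- 30 / 100
  se <- sqrt(p * (1 - p) / 200)
  expect_true(all(abs(counts / 200 - p) < 4 * se))
})

test_that("max-TSS scoring is correct at the extremes and under monotone transforms", {
  scores <- c(rep(0.9, 20), rep(0.1, 30))
  labels <- c(rep(1, 20), rep(0, 30))
  expect_equal(max_tss(scores, labels)$tss, 1)
  # inverted scores are useless at any threshold on the raw orientation
  inv <- max_tss(1 - scores, labels)
  expect_lt(inv$tss, 0.1)
  # label-independent scores give TSS near zero on average
  set.seed(6)
  tss0 <- vapply(1:50, function(i) {
    max_tss(runif(80), sample(c(rep(1, 30), rep(0, 50))))$tss
  }, numeric(1))
  expect_lt(mean(tss0), 3 * sd(tss0) / sqrt(50) + 0.15)
  # strictly monotone transforms leave max-TSS unchanged
  set.seed(7)
  sc <- runif(100)
  lb <- rbinom(100, 1, sc)
  if (any(lb == 1) && any(lb == 0)) {
    expect_equal(max_tss(sc, lb)$tss, max_tss(sc^3, lb)$tss)
  }
  expect_error(max_tss(sc, rep(1, 100)), "both classes")
})

test_that("learners recover a known niche and separate a separable one", {
  L <- simulate_landscape(seed = 11)
  mem <- fit_learner("logistic_quadratic", L$presences, L$background,
                     L$stack)
  pred <- predict_learner(mem, L$stack)
  expect_gte(cor(as.vector(pred), as.vector(L$suitability),
                 method = "spearman"), 0.8)
  # a perfectly separable niche reaches validation TSS = 1
  sep <- separable_fixture(12)
  cv <- cross_evaluate("logistic_quadratic", sep$presences,
                       sep$background, sep$stack, seed = 13)
  expect_equal(cv$mean_tss, 1)
  # envelope semantics: presences spanning a box score the inside higher
  env <- fit_learner("range_envelope", L$presences, L$background, L$stack)
  xp <- extract_env(L$stack, L$presences)
  inside <- predict_learner(env, matrix(apply(xp, 2, median), 1,
                                        dimnames = list(NULL,
                                                        colnames(xp))))
  outside <- predict_learner(env, matrix(apply(xp, 2, max) + 10, 1,
                                         dimnames = list(NULL,
                                                         colnames(xp))))
  expect_gt(inside, 0)
  expect_equal(unname(outside), 0)
})

test_that("the ensemble gate and median aggregation behave as specified", {
  mk <- function(tss) list(model = NULL, tss = tss, threshold = 0.5)
  ens <- build_ensemble(list(mk(0.9), mk(0.85), mk(0.4)), gate = 0.8)
  expect_length(ens$members, 2L)
  expect_error(build_ensemble(list(mk(0.5)), gate = 0.8), "no member")
  # cell-wise median of three members, bounded by member extremes
  L <- simulate_landscape(grid_shape = c(8, 8), n_presence = 20,
                          n_background = 40, seed = 21)
  fake_member <- function(const) {
    model <- structure(list(kind = "range_envelope",
                            vars = names(L$stack$vars),
                            model = list(q = NULL)),
                       class = "sdm_learner")
    list(model = model, tss = 0.9, threshold = 0.5, const = const)
  }
  # use real learners fitted on jittered data instead of stubs
  members <- lapply(1:3, function(k) {
    set.seed(30 + k)
    idx <- sample(nrow(L$presences), nrow(L$presences), replace = TRUE)
    m <- fit_learner("logistic_quadratic", L$presences[idx, ],
                     L$background, L$stack)
    list(model = m, tss = 0.9, threshold = 0.5)
  })
  ens3 <- build_ensemble(members, gate = 0.8)
  med <- predict_ensemble(ens3, L$stack)
  each <- lapply(members, function(m) predict_learner(m$model, L$stack))
  lo <- pmin(each[[1]], each[[2]], each[[3]])
  hi <- pmax(each[[1]], each[[2]], each[[3]])
  expect_true(all(med >= lo - 1e-12 & med <= hi + 1e-12))
  expect_equal(med[1, 1], median(c(each[[1]][1, 1], each[[2]][1, 1],
                                   each[[3]][1, 1])))
})

test_that("MESS agrees exactly with brute-force counting and flags extrapolation", {
  set.seed(9)
  for (r in 1:100) {
    ref <- matrix(rnorm(40 * 3), 40, 3)
    pts <- matrix(rnorm(10 * 3, sd = 2), 10, 3)
    a <- mess(pts, ref)
    b <- brute_mess(pts, ref)
    expect_equal(a$per_variable, b$per_variable, ignore_attr = TRUE)
    expect_equal(a$mess, b$mess)
  }
  ref <- matrix(rnorm(200), 50, 4)
  at_median <- matrix(apply(ref, 2, median), 1)
  expect_equal(mess(at_median, ref)$mess, 100)
  below <- matrix(apply(ref, 2, min), 1) - c(10, 0, 0, 0)
  expect_lt(mess(below, ref)$mess, 0)
  # reference points score non-negative against themselves
  expect_true(all(mess(ref, ref)$mess >= 0))
})

test_that("projection detects an engineered mid-series habitat crash", {
  L <- simulate_landscape(seed = 31)
  cv <- cross_evaluate("logistic_quadratic", L$presences, L$background,
                       L$stack, seed = 32)
  mem <- fit_learner("logistic_quadratic", L$presences, L$background,
                     L$stack)
  ens <- build_ensemble(list(list(model = mem, tss = cv$mean_tss,
                                  threshold = cv$mean_threshold)),
                        gate = 0.8)
  stacks <- lapply(1:10, function(s) {
    st <- L$stack
    st$time_bp <- s * 1000
    if (s %in% 5:6) {
      sh <- c(-4, 4, -4, 4)
      st$vars <- stats::setNames(lapply(seq_along(st$vars),
                                        function(j) st$vars[[j]] + sh[j]),
                                 names(st$vars))
    }
    st
  })
  pr <- project_time_slices(ens, stacks,
                            reference = extract_env(L$stack, L$presences))
  # identity slices reproduce the training-period area exactly
  expect_equal(pr$area$area[1], pr$area$area[10])
  expect_equal(which.min(pr$area$area) %in% 5:6, TRUE)
  col <- detect_range_collapse(pr$area)
  expect_equal(nrow(col), 1L)
  expect_equal(c(col$from_slice, col$to_slice), c(5L, 6L))
  # shifted slices are flagged as extrapolated
  expect_gt(pr$area$frac_extrapolated[5], 0.9)
  expect_lt(pr$area$frac_extrapolated[1], 0.5)
  # missing variables are named in the error
  broken <- stacks
  broken[[2]]$vars$temp_mean <- NULL
  expect_error(project_time_slices(ens, broken), "temp_mean")
  # area series invariance to variable order
  reordered <- lapply(stacks, function(st) {
    st$vars <- st$vars[rev(names(st$vars))]
    st
  })
  pr2 <- project_time_slices(ens, reordered)
  expect_equal(pr2$area$area, pr$area$area)
})

test_that("range collapse detection handles flat and single-dip series", {
  expect_equal(nrow(detect_range_collapse(rep(100, 8))), 0L)
  a <- c(100, 95, 100, 10, 100, 98)
  col <- detect_range_collapse(a)
  expect_equal(col$from_slice, 4L)
  expect_equal(col$to_slice, 4L)
  expect_error(detect_range_collapse(c(1, 2)), "3 slices")
})
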