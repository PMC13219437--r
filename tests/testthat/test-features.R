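test_that("moments match hand-computed values and degenerate convention", {
  m <- compute_moments(c(1, 2, 3, 4, 5))
  expect_equal(m$mean, 3)
  expect_equal(m$std, sqrt(2.5))
  expect_equal(m$skew, 0)
  expect_false(m$degenerate)

  const <- compute_moments(rep(7, 10))
  expect_equal(const$mean, 7)
  expect_equal(const$std, 0)
  expect_equal(const$skew, 0)
  expect_equal(const$kurt, 0)
  expect_true(const$degenerate)

  expect_error(compute_moments(3), "length >= 2")
})

test_that("moments converge to Gaussian values (kurtosis is not excess)", {
  set.seed(101)
  x <- rnorm(1e5)
  m <- compute_moments(x)
  expect_lt(abs(m$kurt - 3), 0.1)
  expect_lt(abs(m$skew), 0.05)
})

test_that("extrema features follow the 1-based first-occurrence latency convention", {
  f <- compute_extrema_features(c(0, 3, -1, 2), fs = 1)
  expect_equal(f$amp_max, 3)
  expect_equal(f$amp_min, -1)
  expect_equal(f$lmax, 2)
  expect_equal(f$lmin, 3)
  expect_equal(f$pp, 4)
  expect_equal(f$ppt, 1)
  expect_equal(f$pps, 4)
  expect_equal(f$alar, 1.5)
  expect_equal(f$lar, 2 / 3)

  # constant window: zero-range guards kick in, latencies at first sample
  g <- compute_extrema_features(rep(2, 5), fs = 10)
  expect_equal(g$pp, 0)
  expect_equal(g$ppt, 0)
  expect_equal(g$pps, 0)
  expect_equal(g$lmax, 0.1)
  expect_equal(g$lmin, 0.1)
  expect_true(g$degenerate)

  # maximum at the first sample still gives a strictly positive latency
  h <- compute_extrema_features(c(5, 1, 2), fs = 2)
  expect_equal(h$lmax, 0.5)
  expect_true(is.finite(h$alar))

  expect_error(compute_extrema_features(numeric(0), 1), "non-empty")
})

test_that("difference features use valid-index sums with as-printed divisors", {
  d <- compute_difference_features(c(0, 1, 3))
  expect_equal(d$mdif1, 1)
  expect_equal(d$mdif1norm, 1.5)

  d2 <- compute_difference_features(c(0, 1, 3, 4))
  expect_equal(d2$mdif2, 0.5)
  expect_equal(d2$mdif2norm, 1)

  # difference operators kill any DC offset
  x <- rnorm(50)
  a <- compute_difference_features(x)
  b <- compute_difference_features(x + 17.3)
  expect_equal(a, b)

  expect_error(compute_difference_features(c(1, 2)), "length >= 3")
})

test_that("energy and its normalization satisfy the exact T-scaling identity", {
  e <- compute_energy(c(1, 2, 2))
  expect_equal(e$energy, 9)
  expect_equal(e$energy_norm, 3)
  expect_equal(compute_energy(rep(0, 8))$energy, 0)

  x <- rnorm(40)
  e1 <- compute_energy(x)
  e2 <- compute_energy(3 * x)
  expect_equal(e2$energy, 9 * e1$energy)
  expect_equal(e1$energy, length(x) * e1$energy_norm)
})

test_that("entropy hits its limits and sign convention", {
  expect_equal(compute_entropy(rep(4, 100)), 0)
  # exact 50/50 split across two occupied bins
  expect_equal(compute_entropy(rep(c(0, 1), 50), n_bins = 2), 1)
  set.seed(202)
  u <- runif(1e6)
  expect_lt(abs(compute_entropy(u, n_bins = 64) - 6), 0.01)
  x <- rnorm(100)
  expect_equal(compute_entropy(x, as_printed = TRUE), -compute_entropy(x))
})

test_that("extract_features composes the kernels and matches the loop oracle", {
  x <- c(0, 1, 3, 4, 1)
  fv <- extract_features(x, fs = 1, entropy_bins = 2)
  expect_named(fv, feature_names())
  oracle <- naive_features(x, fs = 1, n_bins = 2)
  expect_equal(unclass(fv), oracle[feature_names()], tolerance = 1e-12,
    ignore_attr = TRUE
  )

  # component-wise agreement with the single-purpose operations
  mo <- compute_moments(x)
  expect_equal(fv[["std"]], mo$std)
  expect_equal(fv[["kurt"]], mo$kurt)
  ex <- compute_extrema_features(x, fs = 1)
  expect_equal(fv[["alar"]], ex$alar)

  const <- extract_features(rep(1, 10), fs = 5)
  expect_true(attr(const, "degenerate"))
  expect_equal(const[["pp"]], 0)
  expect_equal(const[["mdif1"]], 0)
})

test_that("feature kernels match the straight-loop oracle on random vectors", {
  set.seed(303)
  for (i in 1:1000) {
    n <- sample(10:200, 1)
    x <- rnorm(n, sd = runif(1, 0.1, 50))
    fs <- sample(c(1, 100, 250), 1)
    got <- extract_features(x, fs = fs, entropy_bins = 16)
    want <- naive_features(x, fs = fs, n_bins = 16)
    expect_equal(unclass(got), want[feature_names()],
      tolerance = 1e-9, ignore_attr = TRUE
    )
  }
})

test_that("features obey shift, scaling and time-reversal invariances", {
  set.seed(404)
  shift_inv <- c("std", "skew", "kurt", "pp", "ppt", "pps",
    "mdif1", "mdif2", "mdif1norm", "mdif2norm"
  )
  scale_lin <- c("std", "pp", "pps", "mdif1", "mdif2", "mdif1norm", "mdif2norm")
  rev_inv <- c("mean", "std", "skew", "kurt", "pp", "energy", "entropy")
  for (i in 1:25) {
    x <- rnorm(sample(20:100, 1))
    f0 <- extract_features(x, fs = 10)
    fc <- extract_features(x + 3.7, fs = 10)
    expect_equal(fc[shift_inv], f0[shift_inv], tolerance = 1e-9)
    expect_equal(fc[["mean"]], f0[["mean"]] + 3.7)
    a <- 2.5
    fa <- extract_features(a * x, fs = 10)
    expect_equal(fa[scale_lin], a * f0[scale_lin], tolerance = 1e-9)
    expect_equal(fa[["energy"]], a^2 * f0[["energy"]], tolerance = 1e-9)
    expect_equal(fa[c("skew", "kurt", "entropy")], f0[c("skew", "kurt", "entropy")],
      tolerance = 1e-9
    )
    fr <- extract_features(rev(x), fs = 10)
    expect_equal(fr[rev_inv], f0[rev_inv], tolerance = 1e-9)
  }
})

test_that("feature table has the electrode-by-feature column contract", {
  p <- sim_params(n_subjects = 2, fs = 100, duration_s = 20, seed = 5)
  co <- simulate_cohort(p)
  segs <- dplyr::bind_rows(lapply(co$recordings, segment_recording,
    scheme = segmentation_scheme("non_overlapping", window_s = 10)
  ))
  tab <- build_feature_table(segs)
  feat_cols <- setdiff(names(tab), c("subject_id", "degenerate_windows"))
  expect_length(feat_cols, 80)
  expect_true(all(feat_cols == as.vector(outer(
    feature_names(), c("AF7", "AF8", "TP7", "TP8"),
    function(f, ch) paste(ch, f, sep = "_")
  ))))
  expect_false(anyNA(tab))
})

test_that("per-subject mean aggregation is consistent with per-segment rows", {
  rec <- eeg_recording("s1",
    matrix(rnorm(2 * 100), nrow = 2, dimnames = list(c("A", "B"), NULL)),
    fs = 10
  )
  segs1 <- segment_recording(rec, segmentation_scheme("non_overlapping", window_s = 10))
  m1 <- build_feature_table(segs1, aggregation = "per_subject_mean")
  p1 <- build_feature_table(segs1, aggregation = "per_segment")
  expect_equal(nrow(segs1), 2)
  cols <- setdiff(names(m1), c("subject_id", "degenerate_windows"))
  expect_equal(m1[, cols], p1[, cols])

  # duplicated identical windows: the mean is idempotent
  segs2 <- dplyr::bind_rows(segs1, segs1)
  m2 <- build_feature_table(segs2, aggregation = "per_subject_mean")
  expect_equal(m2[, cols], m1[, cols])

  # a subject missing one electrode is a hard, named error
  segs3 <- segs1[segs1$channel == "A", ]
  expect_error(build_feature_table(segs3, channels = c("A", "B")), "s1")
})
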