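test_that("kurtosis is the standardized fourth moment", {
  expect_equal(signal_kurtosis(c(1, 2, 3, 4)), 1.64)

  set.seed(71)
  g <- rnorm(100000)
  expect_gt(signal_kurtosis(g), 2.9)
  expect_lt(signal_kurtosis(g), 3.1)

  x <- rexp(500)
  expect_equal(signal_kurtosis(37.2 * x), signal_kurtosis(x),
               tolerance = 1e-12)
  expect_equal(signal_kurtosis(-2 * x), signal_kurtosis(x),
               tolerance = 1e-12)

  # printed subtractive variant, for comparison only: scale dependent
  expect_equal(signal_kurtosis(c(1, 2, 3, 4), form = "subtractive"),
               2.5625 - 1.25^2)

  expect_error(signal_kurtosis(rep(1, 10)), "zero variance")
})

test_that("energy is the raw sum of squares", {
  expect_identical(signal_energy(numeric(5)), 0)
  expect_identical(signal_energy(c(1, 2)), 5)
  set.seed(72)
  x <- rnorm(300)
  expect_equal(signal_energy(3 * x), 9 * signal_energy(x), tolerance = 1e-12)
})

test_that("kurtosis and energy agree with brute-force implementations", {
  set.seed(73)
  for (i in 1:10) {
    x <- rnorm(sample(50:500, 1), mean = runif(1, -5, 5),
               sd = runif(1, 0.1, 10))
    expect_equal(signal_kurtosis(x), bf_kurtosis(x), tolerance = 1e-10)
    expect_equal(signal_energy(x), bf_energy(x), tolerance = 1e-10)
  }
})

test_that("the blink-carrying component is flagged on contaminated mixtures", {
  mx <- make_mixture(seed = 301, p = 1)
  dec <- cissa(mx$s - mean(mx$s), L = 18, fs = mx$fs)
  mask <- select_artifact_components(dec)
  expect_false(mask$fallback)
  kur <- apply(dec$components, 2, signal_kurtosis)
  en <- apply(dec$components, 2, signal_energy)
  expect_true(which.max(kur) %in% mask$indices)
  expect_true(which.max(en) %in% mask$indices)
  # blinks live in the first one or two low-frequency components
  expect_true(all(mask$indices %in% c(1L, 2L)))
  expect_length(mask$ez, mx$n)
  expect_equal(mask$ez, rowSums(dec$components[, mask$flags, drop = FALSE]))
})

test_that("flagged set contains the component most correlated with the artifact", {
  for (seed in seq(401, by = 1, length.out = 15)) {
    mx <- make_mixture(seed, p = 1)
    dec <- cissa(mx$s - mean(mx$s), L = 18, fs = mx$fs)
    mask <- suppressWarnings(select_artifact_components(dec))
    cors <- apply(dec$components, 2, function(cmp) abs(bf_cc(cmp, mx$k)))
    expect_true(which.max(cors) %in% mask$indices)
  }
})

test_that("fallback flags exactly the lowest-frequency component with a warning", {
  set.seed(75)
  dec <- cissa(rnorm(1000), L = 10)
  expect_warning(mask <- select_artifact_components(dec, kt = 1e12, et = 1e12),
                 "falling back")
  expect_true(mask$fallback)
  expect_identical(mask$indices, 1L)
  expect_identical(mask$ez, dec$components[, 1])
})

test_that("raising a threshold never adds a flag (before fallback)", {
  mx <- make_mixture(seed = 501, p = 1)
  dec <- cissa(mx$s - mean(mx$s), L = 18, fs = mx$fs)
  kur <- apply(dec$components, 2, signal_kurtosis)
  en <- apply(dec$components, 2, signal_energy)
  effective <- function(kt, et) {
    m <- suppressWarnings(select_artifact_components(dec, kt = kt, et = et))
    if (m$fallback) integer(0) else m$indices
  }
  kt_grid <- quantile(kur, c(0, 0.3, 0.6, 0.9))
  et_grid <- quantile(en, c(0, 0.3, 0.6, 0.9))
  for (i in seq_along(kt_grid)) for (j in seq_along(et_grid)) {
    cur <- effective(kt_grid[i], et_grid[j])
    if (i < length(kt_grid))
      expect_true(all(effective(kt_grid[i + 1], et_grid[j]) %in% cur))
    if (j < length(et_grid))
      expect_true(all(effective(kt_grid[i], et_grid[j + 1]) %in% cur))
  }
})

test_that("degenerate component sets are rejected", {
  expect_error(select_artifact_components(matrix(0, 100, 3)),
               "zero variance")
  expect_error(select_artifact_components(matrix(rnorm(100), ncol = 1)),
               "at least 2")
  set.seed(76)
  expect_error(select_artifact_components(cissa(rnorm(100), 8), kt = "high"),
               "must be a finite number")
})
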