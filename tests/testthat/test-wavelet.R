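test_that("the cascade reconstructs perfectly across lengths, modes, wavelets", {
  set.seed(81)
  for (mode in c("symmetric", "zero", "periodic")) {
    for (n in c(64, 100, 101, 333, 1000, 2500, 5000)) {
      x <- rnorm(n)
      rec <- idwt(dwt(x, mode = mode))
      expect_lt(max(abs(rec - x)) / max(abs(x)), 1e-10)
    }
  }
  x <- rnorm(300)
  for (w in c("haar", "db2", "db8"))
    expect_lt(max(abs(idwt(dwt(x, wavelet = w)) - x)), 1e-10)
})

test_that("coefficients of the zero series are zero and the map is linear", {
  z <- dwt(numeric(400))
  expect_true(all(z$approximation == 0))
  expect_true(all(unlist(z$details) == 0))

  set.seed(82)
  a <- rnorm(500)
  b <- rnorm(500)
  da <- dwt(a); db_ <- dwt(b); dab <- dwt(2 * a - 5 * b)
  expect_equal(dab$approximation, 2 * da$approximation - 5 * db_$approximation,
               tolerance = 1e-10)
  for (lev in 1:4)
    expect_equal(dab$details[[lev]],
                 2 * da$details[[lev]] - 5 * db_$details[[lev]],
                 tolerance = 1e-10)
})

test_that("an impulse produces compactly supported coefficients (zero padding)", {
  x <- numeric(512)
  x[100] <- 1
  d <- dwt(x, mode = "zero")
  F <- 8  # db4 support
  for (lev in 1:4) {
    nz <- which(abs(d$details[[lev]]) > 1e-14)
    expect_lte(length(nz), F + 1)           # support stays filter-sized
    expect_lt(max(abs(nz - 100 / 2^lev)), 2 * F)  # and near the impulse
  }
  nz <- which(abs(d$approximation) > 1e-14)
  expect_lte(length(nz), F + 1)
})

test_that("periodized transform conserves energy on dyadic lengths", {
  set.seed(83)
  for (n in c(512, 1024)) {
    x <- rnorm(n)
    d <- dwt(x, mode = "periodic")
    coef_energy <- sum(d$approximation^2) + sum(unlist(d$details)^2)
    expect_equal(coef_energy, sum(x^2), tolerance = 1e-8)
  }
})

test_that("reconstruction splits additively into approximation and detail parts", {
  set.seed(84)
  x <- rnorm(700)
  d <- dwt(x)
  only_a <- d
  for (lev in 1:4) only_a$details[[lev]] <- numeric(length(d$details[[lev]]))
  parts <- idwt(only_a)
  for (lev in 1:4) {
    only_d <- d
    only_d$approximation <- numeric(length(d$approximation))
    for (m in setdiff(1:4, lev))
      only_d$details[[m]] <- numeric(length(d$details[[m]]))
    parts <- parts + idwt(only_d)
  }
  expect_equal(parts, idwt(d), tolerance = 1e-10)
})

test_that("zeroing the approximation is idempotent and detail-preserving", {
  set.seed(85)
  d <- dwt(rnorm(600))
  z <- zero_approximation(d)
  expect_identical(zero_approximation(z), z)
  expect_equal(signal_energy(z$approximation), 0)
  for (lev in 1:4) expect_identical(z$details[[lev]], d$details[[lev]])

  # a slow ramp is approximation-dominated: stripping A4 removes almost all
  ramp <- seq(0, 1, length.out = 2500)
  resid <- idwt(zero_approximation(dwt(ramp)))
  expect_lt(signal_energy(resid) / signal_energy(ramp), 0.05)
})

test_that("low-frequency removal is conservative and band-selective", {
  set.seed(86)
  for (i in 1:10) {
    x <- rnorm(sample(200:3000, 1))
    sp <- remove_low_frequency(x)
    expect_lt(max(abs(sp$residual + sp$removed - x)), 1e-10)
  }

  fs <- 250
  tt <- seq_len(2500) / fs
  slow <- sin(2 * pi * 1 * tt)        # 1 Hz: inside the A4 band (~0-7.8 Hz)
  sp <- remove_low_frequency(slow)
  expect_gte(signal_energy(sp$removed) / signal_energy(slow), 0.95)

  fast <- sin(2 * pi * 40 * tt)       # 40 Hz: far above the A4 band
  sp <- remove_low_frequency(fast)
  expect_lt(signal_energy(sp$removed) / signal_energy(fast), 0.01)

  # white noise: the A4 band holds 1/16 of a flat spectrum (periodized
  # transform, so the coefficient count ratio is exact)
  fr <- replicate(100, {
    w <- rnorm(512)
    sp <- remove_low_frequency(w, mode = "periodic")
    signal_energy(sp$removed) / signal_energy(w)
  })
  expect_equal(mean(fr), 1 / 16, tolerance = 0.15)
})

test_that("a series too short for the cascade fails with guidance", {
  expect_error(dwt(rnorm(8), levels = 4), "reduce 'levels'")
  expect_silent(d <- dwt(rnorm(8), levels = 1))
  expect_error(idwt(list()), "wavelet_decomposition")
  bad <- dwt(rnorm(200))
  bad$approximation <- numeric(3)
  expect_error(idwt(bad), "inconsistent")
})
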