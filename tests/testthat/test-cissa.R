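test_that("trajectory embedding is the Hankel matrix of lagged windows", {
  expect_equal(embed_trajectory(c(1, 2, 3, 4, 5), 2),
               matrix(c(1, 2, 2, 3, 3, 4, 4, 5), nrow = 2))

  A <- embed_trajectory(rep(3.5, 10), 4)
  expect_true(all(A == 3.5))
  expect_equal(dim(A), c(4L, 7L))

  set.seed(11)
  x <- rnorm(2500)
  A <- embed_trajectory(x, 18)
  expect_equal(dim(A), c(18L, 2483L))
  # exhaustive anti-diagonal scan: A[i, j] depends only on i + j
  for (i in 2:18)
    expect_identical(A[i, 1:(2483 - 1)], A[i - 1, 2:2483])

  expect_error(embed_trajectory(1:10, 1), "out of range")
  expect_error(embed_trajectory(1:10, 10), "out of range")
  expect_error(embed_trajectory(c(1, NA, 3, 4), 2), "non-finite")
})

test_that("circulant first row matches the autocovariance convex combination", {
  expect_warning(r0 <- circulant_first_row(rep(2, 50), 5), "zero variance")
  expect_equal(r0, numeric(5))

  set.seed(21)
  x <- rnorm(200)
  L <- 7
  r <- circulant_first_row(x, L)
  # entry 0 carries full weight on lag 0: the biased sample variance
  expect_equal(r[1], bf_autocov(x, 0), tolerance = 1e-12)
  # every entry against the brute-force double-loop autocovariance
  for (n in 1:(L - 1)) {
    expected <- (L - n) / L * bf_autocov(x, n) + n / L * bf_autocov(x, L - n)
    expect_equal(r[n + 1], expected, tolerance = 1e-12)
  }
  # PSD symmetry of the row itself
  expect_equal(r[2:L], rev(r[2:L]), tolerance = 1e-12)

  alt <- rep(c(1, -1), 50)
  r4 <- circulant_first_row(alt, 4)
  for (n in 0:3) {
    expected <- if (n == 0) bf_autocov(alt, 0) else
      (4 - n) / 4 * bf_autocov(alt, n) + n / 4 * bf_autocov(alt, 4 - n)
    expect_equal(r4[n + 1], expected, tolerance = 1e-12)
  }
})

test_that("circulant eigenstructure: Fourier formula vs dense eigensolver", {
  # scaled identity: first row (c, 0, ..., 0)
  sp <- circulant_eigens(c(4.2, 0, 0, 0, 0))
  expect_equal(sp$values, rep(4.2, 5))

  set.seed(31)
  for (L in c(6L, 13L, 18L)) {
    r <- circulant_first_row(rnorm(300), L)
    sp <- circulant_eigens(r)
    expect_length(sp$values, L)
    expect_equal(sp$frequencies, (0:(L - 1)) / L)
    # eigenvalue multiset against a dense symmetric eigensolver
    dense <- eigen(bf_circulant(r), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sort(sp$values), sort(dense), tolerance = 1e-9)
    # conjugate-pair structure: mu_b = mu_{L+2-b}, j_b = conj(j_{L+2-b})
    for (b in 2:ceiling(L / 2)) {
      expect_equal(sp$values[b], sp$values[L + 2 - b], tolerance = 1e-9)
      expect_equal(sp$vectors[, b], Conj(sp$vectors[, L + 2 - b]))
    }
    # unit norm and true eigenvector property C j = mu j
    C <- bf_circulant(r)
    for (b in seq_len(L)) {
      v <- sp$vectors[, b]
      expect_equal(sum(Mod(v)^2), 1, tolerance = 1e-12)
      expect_lt(max(Mod(C %*% v - sp$values[b] * v)), 1e-9 * max(1, abs(sp$values[b])))
    }
  }

  expect_error(circulant_eigens(c(1, Inf, 1)), "non-finite")
})

test_that("group projectors partition the identity with the expected structure", {
  set.seed(41)
  sp18 <- circulant_eigens(circulant_first_row(rnorm(400), 18))
  gp <- group_projectors(sp18)
  expect_length(gp, 10L)
  expect_equal(lapply(gp, `[[`, "indices"),
               c(list(1L), lapply(2:9, function(b) c(b, 20L - b)), list(10L)))
  Ptot <- Reduce(`+`, lapply(gp, `[[`, "projector"))
  expect_equal(Ptot, diag(18), tolerance = 1e-9)
  for (a in seq_along(gp)) {
    P <- gp[[a]]$projector
    expect_equal(P, t(P), tolerance = 1e-9)            # symmetric
    expect_equal(P %*% P, P, tolerance = 1e-9)         # idempotent
    for (b in seq_along(gp)) if (b != a)
      expect_lt(max(abs(P %*% gp[[b]]$projector)), 1e-9)  # orthogonal
  }

  # odd window: groups {1}, {2,5}, {3,4} with ranks 1, 2, 2
  sp5 <- circulant_eigens(circulant_first_row(rnorm(100), 5))
  gp5 <- group_projectors(sp5)
  expect_equal(lapply(gp5, `[[`, "indices"), list(1L, c(2L, 5L), c(3L, 4L)))
  ranks <- vapply(gp5, function(g)
    sum(eigen(g$projector, symmetric = TRUE, only.values = TRUE)$values > 0.5),
    numeric(1))
  expect_equal(ranks, c(1, 2, 2))
})

test_that("hankelization averages anti-diagonals and is linear", {
  expect_equal(hankelize(matrix(c(1, 3, 2, 4), 2)), c(1, 2.5, 4))

  set.seed(51)
  y <- rnorm(40)
  H <- embed_trajectory(y, 7)
  expect_equal(hankelize(H), y, tolerance = 1e-12)   # fixed point

  M1 <- matrix(rnorm(35), 5)
  M2 <- matrix(rnorm(35), 5)
  expect_equal(hankelize(2.5 * M1 - 3 * M2),
               2.5 * hankelize(M1) - 3 * hankelize(M2), tolerance = 1e-12)
})

test_that("cissa yields an exact additive frequency-ordered decomposition", {
  set.seed(61)
  x <- gen_eeg(2500, 250, seed = 6)
  z <- cissa(x, L = 18, fs = 250)
  expect_s3_class(z, "cissa")
  expect_identical(ncol(z$components), 10L)
  expect_equal(rowSums(z$components), x, tolerance = 1e-8)
  expect_true(all(diff(z$frequencies) > 0))
  expect_equal(z$frequencies[1], 0)

  # group-count formula over all windows 2..40 (t fixed, content random)
  y <- rnorm(100)
  for (L in 2:40) {
    G <- ncol(cissa(y, L = L)$components)
    expect_identical(G, if (L %% 2L == 0L) L %/% 2L + 1L else (L + 1L) %/% 2L)
  }

  # randomized additive-reconstruction cases (the full 200-case sweep is
  # exercised in the acceptance suite)
  for (i in 1:25) {
    t <- sample(100:1500, 1)
    L <- sample(4:48, 1)
    v <- rnorm(t, sd = sample(c(0.1, 1, 50), 1))
    comp <- cissa(v, L = L)$components
    expect_lt(max(abs(rowSums(comp) - v)) / max(abs(v)), 1e-8)
  }
})

test_that("a tone at a group frequency is isolated in that group", {
  fs <- 250
  t <- 2500
  L <- 18
  for (b in c(2L, 4L, 9L)) {
    f <- (b - 1) / L * fs
    tone <- sin(2 * pi * f * seq_len(t) / fs + 0.3)
    z <- cissa(tone, L = L, fs = fs)
    en <- colSums(z$components^2)
    grp <- which(vapply(z$groups, function(g) b %in% g, logical(1)))
    expect_gte(en[grp] / sum(en), 0.99)
  }
})

test_that("a constant series decomposes into its constant plus silence", {
  expect_warning(z <- cissa(rep(7, 60), L = 6), "zero variance")
  expect_equal(z$components[, 1], rep(7, 60), tolerance = 1e-10)
  expect_lt(max(abs(z$components[, -1])), 1e-10)
})
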