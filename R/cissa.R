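#' Build the trajectory (Hankel) matrix of a series
#'
#' Stacks lagged windows of `x` into the `L` x `S` trajectory matrix with
#' `S = length(x) - L + 1`, so that every anti-diagonal is constant.
#'
#' @param x Numeric vector, the time series (length `t >= 3`).
#' @param L Integer window (embedding) length, `2 <= L <= t - 1`.
#' @return An `L` x `S` numeric matrix whose `(i, j)` entry is `x[i + j - 1]`.
#' @examples
#' embed_trajectory(1:5, 2)
#' @export
embed_trajectory <- function(x, L) {
  x <- check_series(x)
  t <- length(x)
  L <- check_window(L, t)
  S <- t - L + 1L
  idx <- outer(seq_len(L), seq_len(S) - 1L, `+`)
  matrix(x[idx], nrow = L, ncol = S)
}

#' First row of the circulant second-moment matrix
#'
#' Computes the `L` circulant entries as the convex combination of biased
#' sample autocovariances at complementary lags,
#' `M_n = ((L - n)/L) g(n) + (n/L) g(L - n)` for `n = 0, ..., L - 1`,
#' where `g(m)` is the mean-removed autocovariance at lag `m` divided by the
#' series length.  Entry `n = 0` therefore equals the biased sample variance.
#' A constant (zero-variance) series yields an all-zero row with a warning.
#'
#' @inheritParams embed_trajectory
#' @return Numeric vector of length `L`, symmetric in the sense
#'   `M[n] == M[L - n]`.
#' @export
circulant_first_row <- function(x, L) {
  x <- check_series(x)
  t <- length(x)
  L <- check_window(L, t)
  if (stats::var(x) == 0) {
    warning("series has zero variance; circulant row is identically zero")
    return(numeric(L))
  }
  g <- as.numeric(stats::acf(x, lag.max = L - 1L, type = "covariance",
                             plot = FALSE, demean = TRUE)$acf)
  n <- 0:(L - 1L)
  # g at lag L - n for n = 0 wraps to lag 0 with weight n/L = 0
  gr <- g[(L - n) %% L + 1L]
  (L - n) / L * g + n / L * gr
}

#' Eigenstructure of a circulant matrix from its first row
#'
#' The eigenvalues of a circulant matrix are the discrete Fourier transform
#' of its first row, evaluated at frequencies `(b - 1)/L` cycles/sample; the
#' eigenvector for frequency `f_b` is the unit Fourier vector
#' `L^(-1/2) * exp(-2i * pi * f_b * (0:(L-1)))`.  For the symmetric rows
#' produced by [circulant_first_row()] the eigenvalues are real and satisfy
#' the power-spectral-density pairing `mu[b] == mu[L + 2 - b]`.
#'
#' @param first_row Numeric vector of length `L >= 2`, all entries finite.
#' @return An object of class `"cissa_spectrum"`: a list with elements
#'   `first_row`, `values` (real eigenvalues), `vectors` (complex `L` x `L`
#'   matrix, one unit eigenvector per column) and `frequencies`
#'   (`(b - 1)/L`, cycles per sample).
#' @export
circulant_eigens <- function(first_row) {
  if (!is.numeric(first_row) || length(first_row) < 2L)
    stop("'first_row' must be a numeric vector of length >= 2")
  if (!all(is.finite(first_row)))
    stop("'first_row' contains non-finite values")
  L <- length(first_row)
  lam <- stats::fft(first_row)
  scale <- max(1, max(abs(first_row)) * L)
  if (max(abs(Im(lam))) > 1e-9 * scale)
    stop("circulant first row is not symmetric: complex eigenvalues")
  n <- 0:(L - 1L)
  freqs <- n / L
  vectors <- exp(-2i * pi * outer(n, freqs)) / sqrt(L)
  structure(list(first_row = first_row,
                 values = Re(lam),
                 vectors = vectors,
                 frequencies = freqs),
            class = "cissa_spectrum")
}

#' Frequency-pair grouping of circulant eigenvectors
#'
#' Conjugate eigenvector pairs `{b, L + 2 - b}` share the frequency
#' `(b - 1)/L` and are merged into one real rank-2 projector; the
#' zero-frequency index 1 (and, for even `L`, the Nyquist index `L/2 + 1`)
#' stay as rank-1 singletons.  The projectors are symmetric, idempotent,
#' mutually orthogonal, and sum to the identity.
#'
#' @param spectrum A `"cissa_spectrum"` object from [circulant_eigens()].
#' @return A list with one element per group, each a list holding `indices`
#'   (1-based eigenvector indices), `frequency` (cycles/sample) and
#'   `projector` (`L` x `L` real symmetric matrix).
#' @export
group_projectors <- function(spectrum) {
  if (!inherits(spectrum, "cissa_spectrum"))
    stop("'spectrum' must be a \"cissa_spectrum\" object")
  L <- length(spectrum$first_row)
  lapply(cissa_group_indices(L), function(idx) {
    j <- spectrum$vectors[, idx[1L]]
    P <- if (length(idx) == 2L) 2 * Re(j %o% Conj(j)) else Re(j %o% Conj(j))
    list(indices = idx,
         frequency = spectrum$frequencies[idx[1L]],
         projector = P)
  })
}

# index sets {1}, {2, L}, {3, L-1}, ... (+ Nyquist singleton for even L)
cissa_group_indices <- function(L) {
  half <- if (L %% 2L == 0L) L / 2L + 1L else (L + 1L) / 2L
  lapply(seq_len(half), function(b) {
    if (b == 1L || (L %% 2L == 0L && b == L / 2L + 1L)) b
    else c(b, L + 2L - b)
  })
}

#' Diagonal averaging (hankelization) of a matrix
#'
#' Projects an `L` x `S` matrix back onto a series of length `L + S - 1` by
#' averaging each anti-diagonal, the least-squares Hankel approximation.
#' A matrix that is already Hankel is returned unchanged as its generating
#' series, and the operator is linear.
#'
#' @param M Numeric matrix.
#' @return Numeric vector of length `nrow(M) + ncol(M) - 1`.
#' @examples
#' hankelize(matrix(c(1, 3, 2, 4), 2)) # c(1, 2.5, 4)
#' @export
hankelize <- function(M) {
  if (!is.matrix(M) || !is.numeric(M))
    stop("'M' must be a numeric matrix")
  L <- nrow(M)
  S <- ncol(M)
  t <- L + S - 1L
  out <- numeric(t)
  for (i in seq_len(L)) out[i:(i + S - 1L)] <- out[i:(i + S - 1L)] + M[i, ]
  out / pmin(seq_len(t), L, S, t - seq_len(t) + 1L)
}

#' Circulant singular spectrum analysis of a time series
#'
#' Decomposes `x` into `G` additive components, one per frequency group of
#' the circulant eigenstructure: the trajectory matrix is projected onto
#' each group subspace and hankelized back to a series.  Because the group
#' projectors partition the identity, the components sum to `x` exactly (to
#' rounding), so the inverse transform is plain summation.  With the default
#' window `L = 18` the decomposition has 10 components.
#'
#' @inheritParams embed_trajectory
#' @param L Integer window length (default 18).  `G = L/2 + 1` components
#'   for even `L`, `(L + 1)/2` for odd.
#' @param fs Sampling rate in Hz, used only to label component frequencies.
#' @return An object of class `"cissa"`: a list with
#'   \describe{
#'     \item{components}{`t` x `G` matrix, one reconstructed component per
#'       column, ordered by increasing center frequency.}
#'     \item{frequencies}{center frequencies in Hz (`(b - 1)/L * fs`).}
#'     \item{groups}{the eigenvector index set of each component.}
#'     \item{eigenvalues}{summed circulant eigenvalues per group
#'       (diagnostic energy ordering).}
#'     \item{L, fs, x}{window, sampling rate, and the input series.}
#'   }
#' @examples
#' z <- cissa(gen_eeg(500, fs = 250, seed = 1), L = 18, fs = 250)
#' ncol(z$components) # 10
#' max(abs(rowSums(z$components) - z$x)) < 1e-10
#' @export
cissa <- function(x, L = 18L, fs = 1) {
  x <- check_series(x)
  t <- length(x)
  L <- check_window(L, t)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a positive scalar")
  first_row <- circulant_first_row(x, L)   # warns on zero variance
  spectrum <- circulant_eigens(first_row)
  groups <- group_projectors(spectrum)
  traj <- embed_trajectory(x, L)
  comps <- vapply(groups, function(g) hankelize(g$projector %*% traj),
                  numeric(t))
  structure(list(
    components   = comps,
    frequencies  = vapply(groups, `[[`, numeric(1), "frequency") * fs,
    groups       = lapply(groups, `[[`, "indices"),
    eigenvalues  = vapply(groups, function(g) sum(spectrum$values[g$indices]),
                          numeric(1)),
    spectrum     = spectrum,
    L = L, fs = fs, x = x), class = "cissa")
}

#' @export
print.cissa <- function(x, ...) {
  cat("Circulant SSA decomposition\n")
  cat(sprintf("  series length: %d samples at %g Hz\n", length(x$x), x$fs))
  cat(sprintf("  window L = %d -> %d components\n", x$L,
              ncol(x$components)))
  en <- colSums(x$components^2)
  tab <- data.frame(frequency_hz = round(x$frequencies, 3),
                    energy_share = round(en / sum(en), 4))
  print(tab, ...)
  invisible(x)
}

#' @export
plot.cissa <- function(x, ...) {
  G <- ncol(x$components)
  old <- graphics::par(mfrow = c(G, 1), mar = c(1, 4, 0.5, 1))
  on.exit(graphics::par(old))
  tt <- seq_along(x$x) / x$fs
  for (g in seq_len(G))
    graphics::plot(tt, x$components[, g], type = "l", xlab = "",
                   ylab = sprintf("%.1f Hz", x$frequencies[g]), ...)
  invisible(x)
}

# ---- shared input checks ----

check_series <- function(x, n_min = 3L) {
  if (is.list(x) && !is.null(x$values)) x <- x$values
  if (!is.numeric(x)) stop("series must be numeric")
  x <- as.numeric(x)
  if (length(x) < n_min)
    stop(sprintf("series must have at least %d samples", n_min))
  if (!all(is.finite(x))) stop("series contains non-finite values")
  x
}

check_window <- function(L, t) {
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L != round(L))
    stop("window length 'L' must be a single integer")
  L <- as.integer(L)
  if (L < 2L || L > t - 1L)
    stop(sprintf("window length L = %d out of range [2, %d] for a series of %d samples",
                 L, t - 1L, t))
  L
}
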