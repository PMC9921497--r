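# Orthogonal Daubechies scaling (reconstruction low-pass) filters.
# The three remaining filters of each quadrature-mirror bank are derived
# below; coefficients are exact to double precision.
wavelet_table <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314453416, 0.8365163037378079, 0.2241438680420134,
          -0.12940952255126037),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032),
  db8 = c(0.05441584224310401, 0.31287159091429995, 0.6756307362972898,
          0.5853546836542067, -0.015829105256349306, -0.2840155429615469,
          0.0004724845739132828, 0.12874742662047847, -0.017369301001807547,
          -0.044088253930794755, 0.013981027917398282, 0.008746094047405777,
          -0.004870352993451574, -0.00039174037337694705,
          0.0006754494064505693, -0.00011747678412476953)
)

#' Quadrature-mirror filter bank of an orthogonal wavelet
#'
#' @param wavelet One of `"haar"`, `"db2"`, `"db4"`, `"db8"`.
#' @return List with decomposition/reconstruction low/high-pass filters
#'   (`dec_lo`, `dec_hi`, `rec_lo`, `rec_hi`).
#' @export
wavelet_filters <- function(wavelet = "db4") {
  wavelet <- match.arg(wavelet, names(wavelet_table))
  rec_lo <- wavelet_table[[wavelet]]
  dec_hi <- rec_lo * rep_len(c(-1, 1), length(rec_lo))
  list(dec_lo = rev(rec_lo), dec_hi = dec_hi,
       rec_lo = rec_lo, rec_hi = rev(dec_hi))
}

# ordinary (full) convolution, O(n * F); filters here are short
conv_full <- function(x, h) {
  n <- length(x)
  F <- length(h)
  out <- numeric(n + F - 1L)
  for (m in seq_len(F))
    out[m:(m + n - 1L)] <- out[m:(m + n - 1L)] + h[m] * x
  out
}

# one analysis step with boundary extension (zero or half-point symmetric):
# extend by F-1 each side, convolve, keep the even phase of the valid part
dwt_step_ext <- function(x, flt, mode) {
  F <- length(flt$dec_lo)
  n <- length(x)
  e <- F - 1L
  ext <- switch(mode,
    zero = c(numeric(e), x, numeric(e)),
    symmetric = c(x[pmin(e:1, n)], x, x[pmax(n:(n - e + 1L), 1L)]))
  vl <- conv_full(ext, flt$dec_lo)[F:length(ext)]
  vh <- conv_full(ext, flt$dec_hi)[F:length(ext)]
  keep <- seq(2L, length(vl), by = 2L)
  list(a = vl[keep], d = vh[keep])
}

# inverse of dwt_step_ext: upsample, filter, keep n samples at offset F-2
idwt_step_ext <- function(a, d, flt, n) {
  F <- length(flt$rec_lo)
  up <- function(cf) {
    u <- numeric(2L * length(cf))
    u[seq(1L, length(u), by = 2L)] <- cf
    u
  }
  full <- conv_full(up(a), flt$rec_lo) + conv_full(up(d), flt$rec_hi)
  full[(F - 1L):(F - 2L + n)]
}

# periodized analysis step (orthogonal): circular correlation with even
# shifts; odd input lengths are extended by repeating the last sample
dwt_step_per <- function(x, flt) {
  if (length(x) %% 2L == 1L) x <- c(x, x[length(x)])
  n <- length(x)
  F <- length(flt$dec_lo)
  nc <- n %/% 2L
  a <- numeric(nc)
  d <- numeric(nc)
  base <- 2L * (seq_len(nc) - 1L)
  for (m in seq_len(F)) {
    idx <- (base + m - 1L) %% n + 1L
    a <- a + flt$dec_lo[m] * x[idx]
    d <- d + flt$dec_hi[m] * x[idx]
  }
  list(a = a, d = d)
}

# transpose of the orthogonal periodized analysis operator
idwt_step_per <- function(a, d, flt, n) {
  ne <- n + n %% 2L
  F <- length(flt$dec_lo)
  x <- numeric(ne)
  base <- 2L * (seq_along(a) - 1L)
  for (m in seq_len(F)) {
    idx <- (base + m - 1L) %% ne + 1L
    add <- flt$dec_lo[m] * a + flt$dec_hi[m] * d
    # idx values collide only when ne < 2 * F (wrap); accumulate safely
    for (k in seq_along(idx)) x[idx[k]] <- x[idx[k]] + add[k]
  }
  x[seq_len(n)]
}

#' Multilevel discrete wavelet transform (Mallat cascade)
#'
#' Decomposes a series into a level-`levels` approximation plus detail
#' coefficient sets D1...D`levels` by iterated two-channel filtering and
#' decimation.  The default (`"db4"`, 4 levels) targets the low-frequency
#' eye-blink band: at sampling rate `fs` the level-4 approximation spans
#' roughly 0 to `fs / 32` Hz (7.8 Hz at 250 Hz).
#'
#' Boundary handling: `"symmetric"` (half-point reflection, default) and
#' `"zero"` store slightly redundant coefficients and reconstruct any
#' length exactly; `"periodic"` uses periodization, which is orthogonal
#' (coefficient energies sum to the signal energy) when every intermediate
#' length is even.
#'
#' @param x Numeric series.
#' @param wavelet Orthogonal wavelet name (see [wavelet_filters()]).
#' @param levels Number of cascade levels (default 4).
#' @param mode Boundary extension: `"symmetric"`, `"zero"` or `"periodic"`.
#' @return An object of class `"wavelet_decomposition"`: list with
#'   `approximation` (deepest-level low-band coefficients), `details`
#'   (list, level 1 first), `wavelet`, `mode`, `levels`,
#'   `original_length`, and `input_lengths` (per-level input lengths used
#'   by the inverse).
#' @seealso [idwt()], [zero_approximation()], [remove_low_frequency()]
#' @export
dwt <- function(x, wavelet = "db4", levels = 4L,
                mode = c("symmetric", "zero", "periodic")) {
  x <- check_series(x)
  mode <- match.arg(mode)
  flt <- wavelet_filters(wavelet)
  levels <- as.integer(levels)
  if (levels < 1L) stop("'levels' must be >= 1")
  F <- length(flt$dec_lo)
  # precheck the length chain so failure is explicit, not numeric garbage
  n_chain <- length(x)
  for (lev in seq_len(levels)) {
    if (n_chain < F)
      stop(sprintf(
        "series of length %d is too short for a %d-level '%s' transform; reduce 'levels'",
        length(x), levels, wavelet))
    n_chain <- if (mode == "periodic") (n_chain + n_chain %% 2L) %/% 2L
               else (n_chain + F - 1L) %/% 2L
  }
  details <- vector("list", levels)
  input_lengths <- integer(levels)
  cur <- x
  for (lev in seq_len(levels)) {
    input_lengths[lev] <- length(cur)
    st <- if (mode == "periodic") dwt_step_per(cur, flt)
          else dwt_step_ext(cur, flt, mode)
    details[[lev]] <- st$d
    cur <- st$a
  }
  structure(list(approximation = cur, details = details, wavelet = wavelet,
                 mode = mode, levels = levels,
                 original_length = length(x),
                 input_lengths = input_lengths),
            class = "wavelet_decomposition")
}

#' Inverse multilevel discrete wavelet transform
#'
#' Reverses [dwt()]: coefficients are upsampled, filtered with the
#' reconstruction bank and summed, level by level, trimming each stage to
#' the recorded input length.  An unmodified decomposition reproduces the
#' original series to rounding error.
#'
#' @param decomp A `"wavelet_decomposition"` object.
#' @return Numeric series of length `decomp$original_length`.
#' @export
idwt <- function(decomp) {
  check_wavedec(decomp)
  flt <- wavelet_filters(decomp$wavelet)
  cur <- decomp$approximation
  for (lev in rev(seq_len(decomp$levels))) {
    n_out <- decomp$input_lengths[lev]
    d <- decomp$details[[lev]]
    cur <- if (decomp$mode == "periodic") idwt_step_per(cur, d, flt, n_out)
           else idwt_step_ext(cur, d, flt, n_out)
  }
  cur
}

#' Zero the approximation band of a wavelet decomposition
#'
#' Replaces the deepest-level approximation coefficients (the low-frequency
#' band that carries the eye-blink waveform) with zeros; detail
#' coefficients are untouched.
#'
#' @inheritParams idwt
#' @return The modified `"wavelet_decomposition"`.
#' @export
zero_approximation <- function(decomp) {
  check_wavedec(decomp)
  decomp$approximation <- numeric(length(decomp$approximation))
  decomp
}

#' Split a series into low-frequency and residual parts via the DWT
#'
#' High-pass filters the series by zeroing the level-`levels` approximation
#' and inverting: `residual` keeps only detail-band content, `removed` is
#' the discarded low band, and `residual + removed == x` exactly (to float
#' tolerance) by linearity.  At `fs = 250` Hz with 4 levels the removed
#' band is roughly 0-7.8 Hz, covering the blink spectrum.
#'
#' @inheritParams dwt
#' @return List with numeric elements `residual` and `removed`, each the
#'   length of `x`.
#' @export
remove_low_frequency <- function(x, wavelet = "db4", levels = 4L,
                                 mode = c("symmetric", "zero", "periodic")) {
  x <- check_series(x)
  residual <- idwt(zero_approximation(dwt(x, wavelet, levels, mode)))
  list(residual = residual, removed = x - residual)
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf("%d-level '%s' wavelet decomposition (%s boundary)\n",
              x$levels, x$wavelet, x$mode))
  cat(sprintf("  original length %d; A%d: %d coefficients\n",
              x$original_length, x$levels, length(x$approximation)))
  for (lev in seq_len(x$levels))
    cat(sprintf("  D%d: %d coefficients\n", lev, length(x$details[[lev]])))
  invisible(x)
}

check_wavedec <- function(decomp) {
  if (!inherits(decomp, "wavelet_decomposition"))
    stop("expected a \"wavelet_decomposition\" object")
  expect_a <- decomp$input_lengths[decomp$levels]
  expect_a <- if (decomp$mode == "periodic") (expect_a + expect_a %% 2L) %/% 2L
              else (expect_a + length(wavelet_filters(decomp$wavelet)$dec_lo) - 1L) %/% 2L
  if (length(decomp$approximation) != expect_a)
    stop("inconsistent coefficient lengths in wavelet decomposition")
  invisible(decomp)
}
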