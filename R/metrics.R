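#' Relative root-mean-square error of an artifact estimate
#'
#' `RRMSE = RMS(k - k_hat) / RMS(k) * 100` (percent): 0 for a perfect
#' estimate, 100 for the null estimate `k_hat = 0`.
#'
#' @param k Ground-truth artifact (nonzero energy).
#' @param k_hat Estimated artifact, same length.
#' @return Percentage (nonnegative scalar).
#' @export
rrmse <- function(k, k_hat) {
  check_pair(k, k_hat)
  denom <- sqrt(mean(k^2))
  if (denom == 0) stop("RRMSE undefined: reference signal has zero energy")
  100 * sqrt(mean((k - k_hat)^2)) / denom
}

#' Pearson correlation between artifact and estimate
#'
#' @inheritParams rrmse
#' @return Correlation in `[-1, 1]`; 1 for a perfect estimate.
#' @export
cc <- function(k, k_hat) {
  check_pair(k, k_hat)
  if (stats::var(k) == 0 || stats::var(k_hat) == 0)
    stop("correlation undefined: a signal has zero variance")
  stats::cor(k, k_hat)
}

#' Signal-to-artifact ratio in dB
#'
#' `SAR = 10 * log10(sd(k) / sd(k_hat - k))`: higher means a better
#' artifact estimate.  With real recordings no ground truth exists; the
#' real-data convention is `sar(s, q_hat)` with `s` the raw contaminated
#' signal and `q_hat` the cleaned one, i.e.
#' `10 * log10(sd(s) / sd(q_hat - s))`.
#'
#' @inheritParams rrmse
#' @param k Reference signal (ground-truth artifact, or the raw recording
#'   in real-data mode).
#' @param k_hat Estimate (or the cleaned recording in real-data mode).
#' @return dB value; `Inf` with a warning when the two inputs are
#'   identical.
#' @export
sar <- function(k, k_hat) {
  check_pair(k, k_hat)
  num <- stats::sd(k)
  den <- stats::sd(k_hat - k)
  if (den == 0) {
    warning("signals are identical up to a constant; SAR is infinite")
    return(Inf)
  }
  10 * log10(num / den)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms: the mean-removed series is split into
#' Hann-windowed segments of `nperseg` samples with the given fractional
#' overlap, and one-sided periodograms are averaged.  Used by [mae_band()];
#' exposed because band-power bookkeeping should be reproducible.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length (default 256; shortened to `length(x)`
#'   when the series is shorter).
#' @param overlap Fractional overlap between segments in `[0, 1)`
#'   (default 0.5).
#' @return List with `freq` (Hz) and `power` (density, units^2/Hz).
#' @export
welch_psd <- function(x, fs, nperseg = 256L, overlap = 0.5) {
  x <- check_series(x)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a positive scalar")
  nperseg <- min(as.integer(nperseg), length(x))
  if (nperseg < 8L) stop("'nperseg' too small")
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, length(x) - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0L, nperseg - 1L) / (nperseg - 1L))
  u <- sum(w^2)
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    spec <- abs(stats::fft(seg))[seq_len(nf)]^2
    acc <- acc + spec
  }
  pxx <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist when present)
  dbl <- rep(2, nf)
  dbl[1L] <- 1
  if (nperseg %% 2L == 0L) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, power = pxx * dbl)
}

#' Mean absolute spectral error over a frequency band
#'
#' Mean absolute difference between the Welch power spectra of the
#' contaminated and the cleaned signal over the bins falling in `band`
#' (alpha band, 8-13 Hz, by default).  Near zero when cleaning leaves the
#' band untouched.
#'
#' @param s Contaminated signal.
#' @param q_hat Cleaned signal, same length.
#' @param fs Sampling rate in Hz.
#' @param band Numeric length-2 vector `(a, b)` Hz, inside `(0, fs/2)`.
#' @param nperseg,overlap Welch parameters, see [welch_psd()].
#' @return Nonnegative scalar (power density units).
#' @export
mae_band <- function(s, q_hat, fs, band = c(8, 13), nperseg = 256L,
                     overlap = 0.5) {
  check_pair(s, q_hat)
  if (length(band) != 2L || band[1] >= band[2])
    stop("'band' must be an increasing (a, b) pair")
  if (band[1] <= 0 || band[2] >= fs / 2)
    stop(sprintf("band [%g, %g] Hz must lie inside (0, %g) Hz",
                 band[1], band[2], fs / 2))
  ps <- welch_psd(s, fs, nperseg, overlap)
  pq <- welch_psd(q_hat, fs, nperseg, overlap)
  in_band <- ps$freq >= band[1] & ps$freq <= band[2]
  if (!any(in_band)) stop("no spectral bins fall inside 'band'")
  mean(abs(ps$power[in_band] - pq$power[in_band]))
}

#' Full evaluation report for an artifact-removal run
#'
#' Ground-truth mode (synthetic data, `k` and `k_hat` supplied) reports
#' RRMSE, CC and SAR of the artifact estimate plus alpha-band MAE of the
#' cleaned signal.  Real-data mode (no ground truth) reports the
#' real-data SAR `10 log10(sd(s)/sd(q_hat - s))` and the band MAE only.
#'
#' @inheritParams mae_band
#' @param k,k_hat Optional ground-truth artifact and its estimate.
#' @param nperseg Welch segment length, see [welch_psd()].
#' @return Object of class `"metrics_report"`: list with `rrmse`, `cc`,
#'   `sar`, `mae`, `band`, `mode` (`"ground-truth"` or `"real-data"`) and
#'   `psd_method`.
#' @export
artifact_metrics <- function(s, q_hat, fs, k = NULL, k_hat = NULL,
                             band = c(8, 13), nperseg = 256L) {
  ground_truth <- !is.null(k) && !is.null(k_hat)
  rep <- list(
    rrmse = if (ground_truth) rrmse(k, k_hat) else NA_real_,
    cc    = if (ground_truth) cc(k, k_hat) else NA_real_,
    sar   = if (ground_truth) sar(k, k_hat) else sar(s, q_hat),
    mae   = mae_band(s, q_hat, fs, band, nperseg),
    band  = band,
    mode  = if (ground_truth) "ground-truth" else "real-data",
    psd_method = sprintf("welch(nperseg=%d, overlap=0.5, hann)",
                         min(as.integer(nperseg), length(s))))
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Artifact-removal metrics (%s mode)\n", x$mode))
  if (!is.na(x$rrmse)) cat(sprintf("  RRMSE: %8.4f %%\n", x$rrmse))
  if (!is.na(x$cc))    cat(sprintf("  CC:    %8.4f\n", x$cc))
  cat(sprintf("  SAR:   %8.4f dB%s\n", x$sar,
              if (x$mode == "real-data") " (real-data convention)" else ""))
  cat(sprintf("  MAE:   %8.5f over %g-%g Hz [%s]\n",
              x$mae, x$band[1], x$band[2], x$psd_method))
  invisible(x)
}

check_pair <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b))
    stop("inputs must be numeric vectors")
  if (length(a) != length(b))
    stop(sprintf("length mismatch: %d vs %d", length(a), length(b)))
  if (length(a) < 2L) stop("need at least 2 samples")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("inputs contain non-finite values")
  invisible(NULL)
}
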