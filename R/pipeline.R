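#' Split a recording into consecutive analysis segments
#'
#' Non-overlapping windows of `wd` samples.  A final remainder shorter
#' than `wd` is kept as its own segment when it has at least `min_len`
#' samples, and merged into the previous window otherwise.
#'
#' @param x Numeric series.
#' @param wd Window length in samples (frame duration times sampling
#'   rate).
#' @param min_len Minimum viable segment length (the CiSSA window plus
#'   one; default 19 for `L = 18`).
#' @return List of numeric segments, with a `"starts"` attribute giving
#'   each segment's 1-based offset in `x`.
#' @examples
#' lengths(segment_signal(numeric(6200), 2500)) # 2500 2500 1200
#' @export
segment_signal <- function(x, wd, min_len = 19L) {
  x <- check_series(x, n_min = 2L)
  wd <- check_count(wd, 2L, "wd")
  min_len <- check_count(min_len, 2L, "min_len")
  if (length(x) < min_len)
    stop(sprintf("series of %d samples is shorter than the minimum segment length %d",
                 length(x), min_len))
  n <- length(x)
  n_full <- n %/% wd
  rem <- n - n_full * wd
  starts <- (seq_len(max(n_full, 1L)) - 1L) * wd + 1L
  ends <- pmin(starts + wd - 1L, n)
  if (n_full == 0L) {
    ends <- n                       # whole record shorter than one window
  } else if (rem > 0L) {
    if (rem >= min_len) {
      starts <- c(starts, n_full * wd + 1L)
      ends <- c(ends, n)
    } else {
      ends[n_full] <- n             # merge the short tail into the last window
    }
  }
  segs <- Map(function(s, e) x[s:e], starts, ends)
  attr(segs, "starts") <- starts
  segs
}

#' Clean one EEG segment of ocular artifacts
#'
#' The core per-segment procedure: remove the segment mean, decompose with
#' [cissa()], flag blink components with
#' [select_artifact_components()], high-pass the flagged sum with
#' [remove_low_frequency()] (zeroed level-`levels` approximation), and
#' reassemble.  The clean estimate is the sum of unflagged components
#' plus the detail-band residual of the flagged ones (plus the segment
#' mean); the artifact estimate is the removed approximation band.  By
#' linearity `clean + artifact == s` exactly.
#'
#' A zero-variance segment passes through unchanged (artifact 0) with a
#' warning.
#'
#' @param s Numeric segment (length at least `L + 1` and long enough for
#'   the wavelet cascade).
#' @param fs Sampling rate in Hz (default 250).
#' @param L CiSSA window length (default 18).
#' @param wavelet,levels,mode Wavelet filter settings, see [dwt()].
#' @param kt,et Kurtosis/energy thresholds, numeric or `"auto"`.
#' @return List with `clean`, `artifact` (numeric, same length as `s`),
#'   `mask` (the `"artifact_mask"`), `frequencies` (component centre
#'   frequencies, Hz), and `degenerate` (TRUE for the zero-variance
#'   pass-through).
#' @export
clean_segment <- function(s, fs = 250, L = 18L, wavelet = "db4",
                          levels = 4L, kt = "auto", et = "auto",
                          mode = "symmetric") {
  s <- check_series(s)
  if (stats::var(s) == 0) {
    warning("zero-variance segment passed through unchanged")
    return(list(clean = s, artifact = numeric(length(s)), mask = NULL,
                frequencies = numeric(0), degenerate = TRUE))
  }
  mu <- mean(s)
  dec <- cissa(s - mu, L = L, fs = fs)
  mask <- select_artifact_components(dec, kt = kt, et = et)
  rest <- rowSums(dec$components[, !mask$flags, drop = FALSE])
  split <- remove_low_frequency(mask$ez, wavelet = wavelet, levels = levels,
                                mode = mode)
  list(clean = rest + split$residual + mu,
       artifact = split$removed,
       mask = mask,
       frequencies = dec$frequencies,
       degenerate = FALSE)
}

#' Remove eye-blink artifacts from an EEG recording
#'
#' Segment-wise artifact removal: the recording is cut into frames of
#' `segment_sec` seconds ([segment_signal()]) and each frame is cleaned
#' independently with [clean_segment()]; results are concatenated in
#' order.  Every stage is linear, so the cleaned signal and the artifact
#' estimate add back to the input exactly.
#'
#' @param x Numeric vector: the contaminated single-channel EEG.
#' @param fs Sampling rate in Hz (default 250).
#' @param L CiSSA embedding window (default 18, giving 10 components).
#' @param wavelet Wavelet for the low-frequency filter (default
#'   `"db4"`).
#' @param levels Wavelet decomposition depth (default 4; removed band is
#'   about 0 to `fs / 32` Hz).
#' @param kt,et Kurtosis and energy thresholds for blink-component
#'   selection, a number or `"auto"` (mean + 1 SD across components).
#' @param segment_sec Frame duration in seconds (default 10, i.e. 2500
#'   samples at 250 Hz).
#' @param mode Wavelet boundary mode (default `"symmetric"`).
#' @return An object of class `"eog_clean"`: list with
#'   \describe{
#'     \item{clean}{the artifact-free EEG estimate.}
#'     \item{artifact}{the estimated blink waveform
#'       (`clean + artifact == x`).}
#'     \item{x, fs}{input series and sampling rate.}
#'     \item{segments}{per-segment diagnostics: start, length, flagged
#'       component indices, thresholds, fallback/degenerate status,
#'       component frequencies.}
#'     \item{config}{the parameter set used.}
#'   }
#'   Methods: `print`, `summary`, `plot`, `fitted` (clean signal) and
#'   `residuals` (artifact estimate).
#' @examples
#' q <- gen_eeg(2500, fs = 250, seed = 7)
#' k <- gen_eog(2500, fs = 250, seed = 8)
#' fit <- eog_clean(q + k, fs = 250)
#' cc(residuals(fit), k) # close to 1
#' @export
eog_clean <- function(x, fs = 250, L = 18L, wavelet = "db4", levels = 4L,
                      kt = "auto", et = "auto", segment_sec = 10,
                      mode = c("symmetric", "zero", "periodic")) {
  mode <- match.arg(mode)
  x <- check_series(x)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a positive scalar")
  if (!is.numeric(segment_sec) || length(segment_sec) != 1L ||
      segment_sec <= 0)
    stop("'segment_sec' must be a positive scalar")
  wd <- as.integer(round(segment_sec * fs))
  L <- check_window(L, min(wd, length(x)))
  segs <- segment_signal(x, wd, min_len = L + 1L)
  starts <- attr(segs, "starts")
  clean <- numeric(length(x))
  artifact <- numeric(length(x))
  diags <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    res <- clean_segment(segs[[i]], fs = fs, L = L, wavelet = wavelet,
                         levels = levels, kt = kt, et = et, mode = mode)
    idx <- starts[i] + seq_along(segs[[i]]) - 1L
    clean[idx] <- res$clean
    artifact[idx] <- res$artifact
    diags[[i]] <- list(
      start = starts[i], length = length(segs[[i]]),
      flagged = if (res$degenerate) integer(0) else res$mask$indices,
      kurtosis = if (res$degenerate) numeric(0) else res$mask$kurtosis,
      energy = if (res$degenerate) numeric(0) else res$mask$energy,
      kt = if (res$degenerate) NA_real_ else res$mask$kt,
      et = if (res$degenerate) NA_real_ else res$mask$et,
      fallback = if (res$degenerate) NA else res$mask$fallback,
      degenerate = res$degenerate,
      frequencies = res$frequencies)
  }
  structure(list(clean = clean, artifact = artifact, x = x, fs = fs,
                 segments = diags,
                 config = list(L = L, wavelet = wavelet, levels = levels,
                               kt = kt, et = et, segment_sec = segment_sec,
                               fs = fs, mode = mode)),
            class = "eog_clean")
}

#' @export
print.eog_clean <- function(x, ...) {
  cfg <- x$config
  cat("EOG artifact removal (circulant SSA + wavelet filter)\n")
  cat(sprintf("  %d samples at %g Hz, %d segment(s) of ~%g s\n",
              length(x$x), x$fs, length(x$segments), cfg$segment_sec))
  cat(sprintf("  L = %d, %s, %d levels, thresholds kt = %s, et = %s\n",
              cfg$L, cfg$wavelet, cfg$levels,
              format(cfg$kt), format(cfg$et)))
  nfb <- sum(vapply(x$segments, function(s) isTRUE(s$fallback), logical(1)))
  cat(sprintf("  artifact variance removed: %.3g (%.1f%% of input)\n",
              stats::var(x$artifact),
              100 * stats::var(x$artifact) / stats::var(x$x)))
  if (nfb > 0)
    cat(sprintf("  note: fallback selection used in %d segment(s)\n", nfb))
  invisible(x)
}

#' @export
summary.eog_clean <- function(object, ...) {
  seg <- data.frame(
    start = vapply(object$segments, `[[`, numeric(1), "start"),
    length = vapply(object$segments, `[[`, numeric(1), "length"),
    n_flagged = vapply(object$segments,
                       function(s) length(s$flagged), numeric(1)),
    fallback = vapply(object$segments,
                      function(s) isTRUE(s$fallback), logical(1)),
    degenerate = vapply(object$segments, `[[`, logical(1), "degenerate"))
  out <- list(config = object$config, segments = seg,
              conservation_error = max(abs(object$clean + object$artifact -
                                             object$x)),
              artifact_share = stats::var(object$artifact) /
                stats::var(object$x))
  class(out) <- "summary.eog_clean"
  out
}

#' @export
print.summary.eog_clean <- function(x, ...) {
  cat("Per-segment diagnostics:\n")
  print(x$segments, ...)
  cat(sprintf("Conservation |clean + artifact - input| max: %.3g\n",
              x$conservation_error))
  cat(sprintf("Artifact variance share: %.3f\n", x$artifact_share))
  invisible(x)
}

#' @export
fitted.eog_clean <- function(object, ...) object$clean

#' @export
residuals.eog_clean <- function(object, ...) object$artifact

#' @export
plot.eog_clean <- function(x, ...) {
  old <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  tt <- seq_along(x$x) / x$fs
  graphics::plot(tt, x$x, type = "l", main = "contaminated input",
                 xlab = "", ylab = "amplitude", ...)
  graphics::plot(tt, x$clean, type = "l", main = "cleaned EEG",
                 xlab = "", ylab = "amplitude", ...)
  graphics::plot(tt, x$artifact, type = "l", main = "estimated artifact",
                 xlab = "time (s)", ylab = "amplitude", ...)
  invisible(x)
}
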