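#' Sample kurtosis of a series
#'
#' Classical standardized fourth central moment `m4 / m2^2` with biased
#' (divide-by-n) moments; about 3 for Gaussian data and strongly elevated
#' by sparse, pulse-like waveforms such as eye blinks.  The scale-dependent
#' subtractive variant `m4 - m2^2` is available for comparison experiments
#' via `form = "subtractive"`.
#'
#' @param x Numeric series, length >= 4, nonzero variance.
#' @param form `"ratio"` (default, classical) or `"subtractive"`.
#' @return A single numeric value.
#' @examples
#' signal_kurtosis(c(1, 2, 3, 4)) # 1.64
#' @export
signal_kurtosis <- function(x, form = c("ratio", "subtractive")) {
  form <- match.arg(form)
  x <- check_series(x, n_min = 4L)
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 == 0)
    stop("kurtosis undefined: series has zero variance")
  m4 <- mean(xc^4)
  if (form == "ratio") m4 / m2^2 else m4 - m2^2
}

#' Energy of a series
#'
#' Discrete signal energy: the sum of squared (raw, not mean-removed)
#' samples.
#'
#' @param x Numeric series.
#' @return Nonnegative scalar, zero only for the all-zero series.
#' @examples
#' signal_energy(c(1, 2)) # 5
#' @export
signal_energy <- function(x) {
  if (!is.numeric(x)) stop("series must be numeric")
  sum(as.numeric(x)^2)
}

#' Flag eye-blink-related components by kurtosis and energy
#'
#' Scores every CiSSA component and flags those whose kurtosis exceeds `kt`
#' AND whose energy exceeds `et` as EOG-related.  With the default
#' `"auto"` thresholds each cutoff is the mean plus one standard deviation
#' of the respective score across components, matching the relative notion
#' that blink components stand out from the rest.  If nothing passes both
#' cutoffs the lowest-frequency component is flagged as a fallback (blinks
#' concentrate in the first one or two components) and a warning is
#' emitted, so clean recordings remain auditable.
#'
#' @param components A `"cissa"` object or a numeric matrix with one
#'   component per column (>= 2 components).
#' @param kt,et Kurtosis / energy thresholds: a number, or `"auto"`.
#' @param form Kurtosis form, see [signal_kurtosis()].
#' @return An object of class `"artifact_mask"`: list with `flags`
#'   (logical per component), `indices` (flagged, 1-based, frequency
#'   order), `kurtosis`, `energy`, `kt`, `et` (resolved numeric
#'   thresholds), `fallback` (logical) and `ez` (element-wise sum of the
#'   flagged components, the series passed on to the wavelet filter).
#' @export
select_artifact_components <- function(components, kt = "auto", et = "auto",
                                       form = c("ratio", "subtractive")) {
  form <- match.arg(form)
  comp <- if (inherits(components, "cissa")) components$components
          else components
  if (!is.matrix(comp) || !is.numeric(comp))
    stop("'components' must be a \"cissa\" object or a numeric matrix")
  G <- ncol(comp)
  if (G < 2L) stop("need at least 2 components")
  ok <- apply(comp, 2L, function(cl) stats::var(cl) > 0)
  if (!any(ok)) stop("all components have zero variance")
  kur <- rep(NA_real_, G)
  kur[ok] <- apply(comp[, ok, drop = FALSE], 2L, signal_kurtosis, form = form)
  en <- apply(comp, 2L, signal_energy)
  kt_num <- resolve_threshold(kt, kur, "kt")
  et_num <- resolve_threshold(et, en, "et")
  flags <- !is.na(kur) & kur > kt_num & en > et_num
  fallback <- FALSE
  if (!any(flags)) {
    flags[1L] <- TRUE
    fallback <- TRUE
    warning("no component exceeded both thresholds; falling back to the lowest-frequency component")
  }
  structure(list(flags = flags,
                 indices = which(flags),
                 kurtosis = kur,
                 energy = en,
                 kt = kt_num, et = et_num,
                 fallback = fallback,
                 ez = rowSums(comp[, flags, drop = FALSE])),
            class = "artifact_mask")
}

resolve_threshold <- function(th, scores, name) {
  if (identical(th, "auto")) {
    s <- scores[!is.na(scores)]
    return(mean(s) + stats::sd(s))
  }
  if (!is.numeric(th) || length(th) != 1L || !is.finite(th))
    stop(sprintf("'%s' must be a finite number or \"auto\"", name))
  th
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("Artifact component mask: %d of %d components flagged%s\n",
              sum(x$flags), length(x$flags),
              if (x$fallback) " (fallback)" else ""))
  cat(sprintf("  thresholds: kurtosis > %.4g, energy > %.4g\n", x$kt, x$et))
  tab <- data.frame(kurtosis = round(x$kurtosis, 3),
                    energy = signif(x$energy, 4),
                    flagged = x$flags)
  print(tab, ...)
  invisible(x)
}
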