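# run expr with a temporarily seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate synthetic ground-truth EEG
#'
#' Draws a zero-mean, unit-variance series with the spectral signature of
#' resting EEG: a `1/f^gamma` (pink) background band-limited to
#' `band[1]`-`band[2]` Hz plus a Gaussian alpha resonance centred at
#' `alpha_freq` carrying the fraction `alpha_frac` of the variance
#' (defaults emulate eyes-closed recordings with pronounced occipital
#' alpha).  Synthesis is spectral: amplitudes are shaped deterministically
#' and phases drawn uniformly, so each seed gives one exact realization.
#'
#' @param n Number of samples (>= 100).
#' @param fs Sampling rate in Hz (default 250).
#' @param seed Optional integer seed; the global RNG state is untouched.
#' @param gamma Spectral slope of the background (default 1).
#' @param alpha_freq,alpha_bw Alpha-peak centre and bandwidth in Hz
#'   (defaults 10 and 1.5).
#' @param alpha_frac Fraction of total variance in the alpha resonance
#'   (default 0.8).
#' @param band Pass band of the background in Hz (default 0.5-45).
#' @param noise_frac Fraction of variance in a white measurement-noise
#'   floor spanning the full 0 to `fs/2` band (default 0.01); real
#'   amplifiers never produce spectrally empty bands, and a nonzero floor
#'   keeps out-of-band decomposition components statistically
#'   well-behaved.
#' @return Numeric vector of length `n` (zero mean, unit variance).
#' @export
gen_eeg <- function(n, fs = 250, seed = NULL, gamma = 1,
                    alpha_freq = 10, alpha_bw = 1.5, alpha_frac = 0.8,
                    band = c(0.5, 45), noise_frac = 0.01) {
  n <- check_count(n, 100L, "n")
  if (alpha_frac < 0 || alpha_frac > 1) stop("'alpha_frac' must be in [0, 1]")
  if (noise_frac < 0 || noise_frac >= 1) stop("'noise_frac' must be in [0, 1)")
  nf <- n %/% 2L + 1L
  f <- (seq_len(nf) - 1L) * fs / n
  bg <- numeric(nf)
  sel <- f >= band[1] & f <= band[2]
  bg[sel] <- f[sel]^(-gamma / 2)
  bump <- exp(-0.5 * ((f - alpha_freq) / alpha_bw)^2)
  bg <- bg / sqrt(sum(bg^2))
  bump <- bump / sqrt(sum(bump^2))
  floor_ <- rep(1, nf)
  floor_[1L] <- 0
  floor_ <- floor_ / sqrt(sum(floor_^2))
  amp <- sqrt((1 - noise_frac) * (1 - alpha_frac)) * bg +
    sqrt((1 - noise_frac) * alpha_frac) * bump +
    sqrt(noise_frac) * floor_
  phase <- with_seed(seed, stats::runif(nf, 0, 2 * pi))
  z <- complex(modulus = amp, argument = phase)
  z[1L] <- 0
  full <- c(z, Conj(rev(z[2:(nf - if (n %% 2L == 0L) 1L else 0L)])))
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x)
}

#' Generate a synthetic eye-blink (EOG) artifact train
#'
#' A train of smooth positive pulses: squared half-sine (default) or a
#' gamma-shaped pulse, of `width` seconds, repeated with mean interval
#' `1/rate` at jittered-regular (default) or Poisson times.  The default
#' rate of 0.2 blinks/s reflects spontaneous blinking about every five
#' seconds; pulse energy sits almost entirely below 12 Hz, the usual
#' ocular-artifact band.
#'
#' @param n Number of samples.
#' @param fs Sampling rate in Hz.
#' @param rate Mean blink rate per second (default 0.2).
#' @param width Pulse duration in seconds (default 0.35).
#' @param amplitude Pulse peak amplitude (default 10, in units of the
#'   EEG standard deviation when mixed with [gen_eeg()] output).
#' @param shape `"halfsine2"` (squared half-sine, default) or `"gamma"`.
#' @param timing `"jittered"` (regular grid with Gaussian jitter,
#'   default) or `"poisson"`.
#' @param jitter Timing jitter SD as a fraction of the mean interval
#'   (jittered-regular mode only; default 0.15).
#' @param seed Optional integer seed; global RNG state untouched.
#' @return Numeric vector of length `n`, nonnegative.
#' @export
gen_eog <- function(n, fs = 250, rate = 0.2, width = 0.35, amplitude = 10,
                    shape = c("halfsine2", "gamma"),
                    timing = c("jittered", "poisson"),
                    jitter = 0.15, seed = NULL) {
  shape <- match.arg(shape)
  timing <- match.arg(timing)
  n <- check_count(n, 10L, "n")
  if (amplitude < 0) stop("'amplitude' must be >= 0")
  if (rate <= 0 || rate * width >= 1)
    stop("'rate' must be positive with rate * width < 1")
  w <- max(3L, as.integer(round(width * fs)))
  if (n < w) stop("series shorter than one pulse width")
  u <- seq(0, 1, length.out = w)
  pulse <- switch(shape,
    halfsine2 = sin(pi * u)^2,
    gamma = { g <- (u * 4)^2 * exp(-u * 8); g / max(g) })
  pulse <- amplitude * pulse
  dur <- n / fs
  interval <- 1 / rate
  centers <- with_seed(seed, {
    if (timing == "jittered") {
      if (interval / 2 > dur) numeric(0)
      else {
        grid <- seq(interval / 2, dur, by = interval)
        grid + stats::rnorm(length(grid), 0, jitter * interval)
      }
    } else {
      ct <- cumsum(stats::rexp(max(10L, ceiling(dur * rate * 4)), rate))
      ct[ct < dur]
    }
  })
  x <- numeric(n)
  for (cen in centers) {
    i0 <- as.integer(round(cen * fs - w / 2))
    idx <- i0 + seq_len(w)
    keep <- idx >= 1L & idx <= n
    x[idx[keep]] <- x[idx[keep]] + pulse[keep]
  }
  x
}

#' Mix clean EEG with a scaled artifact
#'
#' The additive contamination model `s = q + p * k`, where `p` controls
#' artifact severity (signal-to-noise of the mixture is low for `p > 1`).
#'
#' @param q Ground-truth EEG series.
#' @param k Artifact series, same length.
#' @param p Nonnegative mixing constant.
#' @return Object of class `"eeg_mixture"`: list with `s`, `q`, `k`, `p`.
#' @export
mix_signals <- function(q, k, p) {
  if (!is.numeric(q) || !is.numeric(k))
    stop("'q' and 'k' must be numeric")
  if (length(q) != length(k))
    stop(sprintf("length mismatch: q has %d samples, k has %d",
                 length(q), length(k)))
  if (!is.numeric(p) || length(p) != 1L || p < 0)
    stop("'p' must be a single nonnegative number")
  structure(list(s = q + p * k, q = q, k = k, p = p),
            class = "eeg_mixture")
}

#' Build a reproducible benchmark corpus of contaminated mixtures
#'
#' Generates `n_trials` independent EEG/blink pairs per mixing constant in
#' `p_values`, with per-trial seeds derived deterministically from the
#' master seed so the corpus is byte-identical across runs.  Optionally
#' writes each mixture as delimited text plus a JSON manifest recording
#' seeds and parameters.
#'
#' @param n_trials Trials per mixing constant (default 50).
#' @param p_values Mixing constants (default `c(0.5, 1, 1.25, 1.5)`).
#' @param n,fs Samples per trial and sampling rate (defaults 2500, 250).
#' @param seed Master seed (default 1).
#' @param dir Optional directory; when given, signals are written as
#'   `.tsv` files with a `manifest.json`.
#' @param ... Further arguments passed to [gen_eeg()] and [gen_eog()]
#'   (matched by name to each generator's formals).
#' @return List of class `"eeg_benchmark"`: `trials` (list of
#'   `"eeg_mixture"` objects with `$seed`, `$trial`), and `manifest`.
#' @export
make_benchmark <- function(n_trials = 50L, p_values = c(0.5, 1, 1.25, 1.5),
                           n = 2500L, fs = 250, seed = 1L, dir = NULL, ...) {
  n_trials <- check_count(n_trials, 1L, "n_trials")
  extra <- list(...)
  eeg_extra <- extra[names(extra) %in% names(formals(gen_eeg))]
  eog_extra <- extra[names(extra) %in% names(formals(gen_eog))]
  n_cases <- n_trials * length(p_values)
  seeds <- with_seed(seed, sample.int(2^30, 2L * n_cases))
  trials <- vector("list", n_cases)
  entries <- vector("list", n_cases)
  i <- 0L
  for (p in p_values) for (tr in seq_len(n_trials)) {
    i <- i + 1L
    q <- do.call(gen_eeg, c(list(n = n, fs = fs, seed = seeds[2L * i - 1L]),
                            eeg_extra))
    k <- do.call(gen_eog, c(list(n = n, fs = fs, seed = seeds[2L * i]),
                            eog_extra))
    m <- mix_signals(q, k, p)
    m$trial <- tr
    m$seed <- c(eeg = seeds[2L * i - 1L], eog = seeds[2L * i])
    trials[[i]] <- m
    entries[[i]] <- list(trial = tr, p = p,
                         seed_eeg = seeds[2L * i - 1L],
                         seed_eog = seeds[2L * i])
  }
  manifest <- list(n_trials = n_trials, p_values = p_values, n = n, fs = fs,
                   master_seed = seed, cases = entries)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (j in seq_along(trials)) {
      m <- trials[[j]]
      path <- file.path(dir, sprintf("mix_p%s_trial%03d.tsv",
                                     gsub("[.]", "_", format(m$p)), m$trial))
      utils::write.table(
        data.frame(s = m$s, q = m$q, k = m$k),
        path, sep = "\t", row.names = FALSE, quote = FALSE)
      entries[[j]]$file <- basename(path)
    }
    manifest$cases <- entries
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(trials = trials, manifest = manifest),
            class = "eeg_benchmark")
}

check_count <- function(n, n_min, name) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n != round(n))
    stop(sprintf("'%s' must be a single integer", name))
  n <- as.integer(n)
  if (n < n_min) stop(sprintf("'%s' must be >= %d", name, n_min))
  n
}
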