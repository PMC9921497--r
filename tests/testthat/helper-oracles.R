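# Independent brute-force oracles used across the suite.  These are kept
# deliberately naive (double loops, textbook formulas) so they share no
# code path with the implementation they check.

# biased autocovariance at lag m, mean removed, divide by length
bf_autocov <- function(x, m) {
  n <- length(x)
  mu <- sum(x) / n
  acc <- 0
  for (i in seq_len(n - m)) acc <- acc + (x[i] - mu) * (x[i + m] - mu)
  acc / n
}

bf_central_moment <- function(x, k) {
  mu <- sum(x) / length(x)
  acc <- 0
  for (v in x) acc <- acc + (v - mu)^k
  acc / length(x)
}

bf_kurtosis <- function(x) bf_central_moment(x, 4) / bf_central_moment(x, 2)^2

bf_energy <- function(x) {
  acc <- 0
  for (v in x) acc <- acc + v * v
  acc
}

bf_rrmse <- function(k, kh) {
  100 * sqrt(sum((k - kh)^2) / length(k)) / sqrt(sum(k^2) / length(k))
}

bf_cc <- function(a, b) {
  am <- a - mean(a)
  bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

bf_sar <- function(k, kh) 10 * log10(sd(k) / sd(kh - k))

# textbook Welch estimate written independently: explicit segment loop,
# hann window from the cosine definition, one-sided density scaling
bf_welch <- function(x, fs, nperseg = 256L, overlap = 0.5) {
  nperseg <- min(nperseg, length(x))
  step <- max(1L, round(nperseg * (1 - overlap)))
  idx <- seq(1L, length(x) - nperseg + 1L, by = step)
  w <- sapply(seq_len(nperseg) - 1L,
              function(j) 0.5 * (1 - cos(2 * pi * j / (nperseg - 1))))
  specs <- sapply(idx, function(s0) {
    seg <- x[s0:(s0 + nperseg - 1L)]
    seg <- seg - mean(seg)
    Mod(fft(seg * w))[1:(nperseg %/% 2 + 1)]^2
  })
  pxx <- rowMeans(as.matrix(specs)) / (fs * sum(w^2))
  mult <- c(1, rep(2, nperseg %/% 2 - 1), if (nperseg %% 2 == 0) 1 else 2)
  list(freq = (seq_len(nperseg %/% 2 + 1) - 1) * fs / nperseg,
       power = pxx * mult)
}

# explicit circulant matrix with first row r (row i is r cycled right by i-1)
bf_circulant <- function(r) {
  L <- length(r)
  M <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L))
    M[i, j] <- r[(j - i) %% L + 1L]
  M
}

# energy fraction of a series below f_hi Hz (rectangular FFT bins)
energy_below <- function(x, fs, f_hi) {
  n <- length(x)
  sp <- Mod(fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                   # two-sided -> folded frequency
  sum(sp[f <= f_hi]) / sum(sp)
}

# one seeded contaminated mixture at the generator's frozen defaults
make_mixture <- function(seed, p = 1, n = 2500L, fs = 250) {
  q <- gen_eeg(n, fs, seed = seed)
  k <- gen_eog(n, fs, seed = seed + 100000L)
  list(q = q, k = k, p = p, s = q + p * k, fs = fs, n = n)
}
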