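# fixed-width ASCII field helpers for the EDF header
edf_pad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) stop(sprintf("EDF field too wide: '%s'", s))
  formatC(s, width = -width)
}

# shortest %g representation fitting an 8-char EDF numeric field
edf_num <- function(v) {
  for (digits in 7:1) {
    s <- sprintf(paste0("%.", digits, "g"), v)
    if (nchar(s) <= 8L && is.finite(as.numeric(s))) return(s)
  }
  stop(sprintf("cannot represent %g in an EDF numeric field", v))
}

#' Write signals to a European Data Format (EDF) file
#'
#' Minimal single-record EDF writer: each column of `x` becomes one
#' channel, quantized to 16-bit integers over a symmetric physical range
#' covering the data.  The quantization error is bounded by the physical
#' range divided by 2^15.
#'
#' @param x Numeric vector or matrix (columns = channels).
#' @param path Output file path.
#' @param fs Sampling rate in Hz (same for all channels).
#' @param labels Channel labels (recycled).
#' @param units Physical dimension string, e.g. `"uV"`.
#' @return `path`, invisibly.
#' @export
write_edf <- function(x, path, fs, labels = NULL, units = "uV") {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1L)
  if (!is.matrix(x) || !is.numeric(x) || nrow(x) == 0L)
    stop("'x' must be a non-empty numeric vector or matrix")
  if (!all(is.finite(x))) stop("signals contain non-finite values")
  if (missing(fs) || !is.numeric(fs) || fs <= 0)
    stop("a positive 'fs' is required")
  ns <- ncol(x)
  n <- nrow(x)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ns))
  labels <- rep_len(labels, ns)
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  # physical range: symmetric, written in ASCII, re-read for exact scaling
  pmax_txt <- vapply(seq_len(ns), function(j) {
    m <- max(abs(x[, j]), 1e-12)
    edf_num(signif(m * 1.001, 6))
  }, character(1))
  pmax_val <- as.numeric(pmax_txt)
  dur <- n / fs
  header <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (ns + 1L), 8), edf_pad("", 44),
    edf_pad(1L, 8), edf_pad(edf_num(dur), 8), edf_pad(ns, 4))
  sig_hdr <- paste0(
    paste(vapply(labels, edf_pad, character(1), width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(units, 8), ns), collapse = ""),
    paste(vapply(vapply(-pmax_val, edf_num, character(1)),
                 edf_pad, character(1), width = 8), collapse = ""),
    paste(vapply(pmax_txt, edf_pad, character(1), width = 8), collapse = ""),
    paste(rep(edf_pad("-32768", 8), ns), collapse = ""),
    paste(rep(edf_pad("32767", 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(n, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = ""))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(header, sig_hdr), con, eos = NULL, useBytes = TRUE)
  for (j in seq_len(ns)) {
    scale <- (2 * pmax_val[j]) / 65535
    dig <- as.integer(round(x[, j] / scale))
    dig <- pmax(pmin(dig, 32767L), -32768L)
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a European Data Format (EDF) file
#'
#' @param path EDF file path.
#' @return List with `signals` (list of numeric vectors, one per
#'   channel), `labels`, `fs` (Hz per channel), `units`, `n_records`,
#'   `record_duration`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop(sprintf("not an EDF file (version '%s')", version))
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                  # header bytes (recomputed below)
  rd(44)
  n_records <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("corrupt EDF header: bad signal count")
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fld(16); fld(80)
  units <- fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  signals <- lapply(seq_len(ns), function(j) numeric(0))
  for (r in seq_len(n_records)) {
    for (j in seq_len(ns)) {
      raw <- readBin(con, integer(), n = spr[j], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- pmin_[j] + (raw - dmin[j]) * (pmax_[j] - pmin_[j]) /
        (dmax[j] - dmin[j])
      signals[[j]] <- c(signals[[j]], phys)
    }
  }
  list(signals = signals, labels = labels, fs = spr / rec_dur,
       units = units, n_records = n_records, record_duration = rec_dur)
}

#' Read a single-channel signal from text or EDF
#'
#' Delimited text expects one sample per row (one numeric column per
#' channel, optional single header row of labels); EDF is detected by the
#' `.edf` extension or forced with `format`.  For text input the sampling
#' rate must be supplied; for EDF it comes from the header unless
#' overridden.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"text"` or `"edf"`.
#' @param channel Column index or channel label.
#' @param fs Sampling rate override in Hz (required for text).
#' @return List with `values` (numeric), `fs`, and `header` (list:
#'   `labels`, `fs`, `units`, `format`).
#' @export
read_signal <- function(path, format = c("auto", "text", "edf"),
                        channel = 1L, fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "text"
  if (format == "edf") {
    edf <- read_edf(path)
    j <- match_channel(channel, edf$labels)
    fs_out <- if (is.null(fs)) edf$fs[j] else fs
    return(list(values = edf$signals[[j]], fs = fs_out,
                header = list(labels = edf$labels, fs = edf$fs,
                              units = edf$units, format = "edf")))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty signal file: %s", path))
  sep <- if (grepl("\t", lines[1L])) "\t"
         else if (grepl(",", lines[1L])) ","
         else if (grepl(";", lines[1L])) ";" else ""
  split1 <- strsplit(trimws(lines[1L]),
                     if (sep == "") "[[:space:]]+" else sep)[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(split1)))
  labels <- if (has_header) trimws(split1)
            else paste0("ch", seq_along(split1))
  body <- if (has_header) lines[-1L] else lines
  cells <- strsplit(trimws(body),
                    if (sep == "") "[[:space:]]+" else sep)
  ncol_ <- length(split1)
  if (any(lengths(cells) != ncol_))
    stop(sprintf("ragged rows in %s: expected %d columns", path, ncol_))
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(cells)), ncol = ncol_, byrow = TRUE))
  if (anyNA(mat)) stop(sprintf("non-numeric cells in %s", path))
  j <- match_channel(channel, labels)
  if (is.null(fs))
    stop("text input carries no sampling rate; supply 'fs'")
  list(values = mat[, j], fs = fs,
       header = list(labels = labels, fs = rep(fs, ncol_),
                     units = rep(NA_character_, ncol_), format = "text"))
}

match_channel <- function(channel, labels) {
  if (is.character(channel)) {
    j <- match(channel, labels)
    if (is.na(j))
      stop(sprintf("channel '%s' not found; available: %s",
                   channel, paste(labels, collapse = ", ")))
    return(j)
  }
  j <- as.integer(channel)
  if (is.na(j) || j < 1L || j > length(labels))
    stop(sprintf("channel index %s out of range 1..%d",
                 format(channel), length(labels)))
  j
}

#' Write a signal to delimited text or EDF
#'
#' Text output stores one sample per row at full double precision (17
#' significant digits), so a text round trip is lossless; EDF output is
#' 16-bit quantized (see [write_edf()]).
#'
#' @param x Numeric vector.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"text"` or `"edf"`.
#' @param fs Sampling rate (required for EDF).
#' @param label Channel label / header name.
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path, format = c("auto", "text", "edf"),
                         fs = NULL, label = "eeg") {
  format <- match.arg(format)
  if (!is.numeric(x) || length(x) == 0L)
    stop("'x' must be a non-empty numeric vector")
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "text"
  if (format == "edf") {
    if (is.null(fs)) stop("EDF output requires 'fs'")
    return(write_edf(x, path, fs = fs, labels = label))
  }
  writeLines(c(label, sprintf("%.17g", x)), path)
  invisible(path)
}
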