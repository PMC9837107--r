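#' @useDynLib musedecode, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif fft cor sd var median quantile dnorm pt cor.test ks.test
#' @importFrom utils head tail write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' z-score a numeric vector
#'
#' Centers and scales to unit variance. Constant input returns all zeros
#' (rather than NaN) so downstream correlation code can flag it explicitly.
#' @param x numeric vector
#' @return numeric vector of the same length
#' @keywords internal
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

## Moore-Penrose pseudo-inverse via SVD (symmetric use cases only need tol)
pinv <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(s$d)
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

## symmetric positive (semi)definite matrix square root via eigen
sym_sqrt <- function(A) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

## 1/f ("pink") noise via spectral shaping of white Gaussian noise;
## computed at a fast FFT length and truncated
pink_noise <- function(n, sd = 1) {
  if (n < 2) return(stats::rnorm(n, sd = sd))
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(m)
  W <- stats::fft(w)
  f <- c(1, seq_len(m - 1))                 # avoid division by zero at DC
  f <- pmin(f, m - f + 1)                   # symmetric frequency index
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE))[seq_len(n)] / m
  x <- x / stats::sd(x) * sd
  x - mean(x)
}

## zero-phase filtering with odd-reflection edge padding (absorbs the
## zero-padding transients of plain filtfilt)
zp_filtfilt <- function(filt, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1, 3 * 34)
  if (pad < 1) return(as.numeric(signal::filtfilt(filt, x)))
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- as.numeric(signal::filtfilt(filt, c(head_pad, x, tail_pad)))
  y[(pad + 1):(pad + n)]
}

## zero-phase Butterworth low-pass (order 4)
lowpass <- function(x, fs, cutoff_hz, order = 4) {
  wn <- cutoff_hz / (fs / 2)
  stopifnot(wn > 0, wn < 1)
  bf <- signal::butter(order, wn, type = "low")
  zp_filtfilt(bf, x)
}

## zero-phase Butterworth band-pass (applied as in rank-accuracy evaluation)
bandpass <- function(x, fs, band, order = 4) {
  wn <- band / (fs / 2)
  stopifnot(all(wn > 0), all(wn < 1), wn[1] < wn[2])
  bf <- signal::butter(order, wn, type = "pass")
  zp_filtfilt(bf, x)
}

#' Welch power spectral density
#'
#' Averaged modified periodograms with a Hann window.
#'
#' @param x numeric series
#' @param fs sampling rate (Hz)
#' @param nperseg segment length in samples (default 1 s)
#' @param overlap fractional overlap between segments (default 0.5)
#' @return list with `freq` (Hz) and `power` vectors
#' @export
welch_psd <- function(x, fs, nperseg = fs, overlap = 0.5) {
  nperseg <- min(as.integer(nperseg), length(x))
  step <- max(1L, as.integer(nperseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  u <- sum(win^2)
  nf <- nperseg %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    P <- abs(stats::fft(seg))^2 / (u * fs)
    acc <- acc + P[seq_len(nf)]
  }
  list(freq = (seq_len(nf) - 1) * fs / nperseg, power = acc / length(starts))
}

## half-open interval membership for trial windows [onset, onset + duration)
in_window <- function(t, onset, duration) t >= onset & t < onset + duration

## deterministic seed derivation, kept below 2^31
derive_seed <- function(seed, k) as.integer((as.numeric(seed) * 1000003 + k) %% 2147483647)
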