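## Similarity, significance, identification, and tempo-confound statistics.

#' Log-power time-frequency spectrogram
#'
#' Short-time Fourier transform with a 1 s Hann window and 50 % overlap;
#' returns 10*log10 power restricted to frequencies up to `fmax_hz`.
#'
#' @param x numeric series
#' @param fs sampling rate (Hz)
#' @param window_s STFT window length in seconds (default 1)
#' @param overlap fractional window overlap (default 0.5)
#' @param fmax_hz highest retained frequency (default 50)
#' @return matrix (frequencies x frames) with attributes `freq` and `time`
#' @export
spectrogram <- function(x, fs, window_s = 1, overlap = 0.5, fmax_hz = 50) {
  n <- round(window_s * fs)
  if (length(x) < n) stop("series shorter than one spectrogram window")
  sg <- signal::specgram(x, n = n, Fs = fs, overlap = round(n * overlap))
  P <- abs(sg$S)^2
  logP <- 10 * log10(P + 1e-12)
  keep <- sg$f <= fmax_hz
  out <- logP[keep, , drop = FALSE]
  attr(out, "freq") <- sg$f[keep]
  attr(out, "time") <- sg$t
  out
}

## separable Gaussian filtering, "valid" region only
.gauss_filter_valid <- function(img, win, sigma) {
  half <- (win - 1) / 2
  g <- exp(-((-half:half)^2) / (2 * sigma^2)); g <- g / sum(g)
  rowf <- apply(img, 2, function(col) as.numeric(stats::filter(col, g, sides = 2)))
  out <- t(apply(rowf, 1, function(row) as.numeric(stats::filter(row, g, sides = 2))))
  out[(half + 1):(nrow(img) - half), (half + 1):(ncol(img) - half), drop = FALSE]
}

#' Structural similarity index of two images
#'
#' Windowed luminance/contrast/structure comparison (Gaussian window,
#' stabilising constants `C1 = (K1*L)^2`, `C2 = (K2*L)^2`), averaged over
#' the window map. Symmetric, bounded by 1, and `ssim(x, x) = 1`.
#'
#' @param imageA,imageB numeric matrices of identical shape
#' @param dynamic_range shared dynamic range `L`; defaults to the joint
#'   range of both images
#' @param K1,K2 stabilising constants (defaults 0.01, 0.03)
#' @param win_size Gaussian window size in bins (odd, default 11)
#' @param sigma Gaussian window sd in bins (default 1.5)
#' @return scalar structural similarity in `[-1, 1]`
#' @export
ssim <- function(imageA, imageB, dynamic_range = NULL, K1 = 0.01, K2 = 0.03,
                 win_size = 11, sigma = 1.5) {
  if (!all(dim(imageA) == dim(imageB))) stop("images must have identical shape")
  if (win_size %% 2 != 1) stop("win_size must be odd")
  if (any(dim(imageA) < win_size))
    stop("images smaller than the SSIM window")
  L <- dynamic_range %||% (max(imageA, imageB) - min(imageA, imageB))
  if (L <= 0) L <- 1
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  f <- function(img) .gauss_filter_valid(img, win_size, sigma)
  muA <- f(imageA); muB <- f(imageB)
  sA <- f(imageA^2) - muA^2
  sB <- f(imageB^2) - muB^2
  sAB <- f(imageA * imageB) - muA * muB
  num <- (2 * muA * muB + C1) * (2 * sAB + C2)
  den <- (muA^2 + muB^2 + C1) * (sA + sB + C2)
  mean(num / den)
}

## min-max normalise a pair of images to a shared [0, 1] range and compare
.ssim_pair <- function(a, b, ...) {
  lo <- min(a, b); hi <- max(a, b)
  if (hi <= lo) return(1)
  ssim((a - lo) / (hi - lo), (b - lo) / (hi - lo), dynamic_range = 1, ...)
}

#' Bootstrap null p-value from a cross-similarity matrix
#'
#' The observed statistic is the mean diagonal (matched original/
#' reconstructed pairs); the null distribution is the mean similarity under
#' random re-pairings (shuffles of the reconstructed trials).
#' `p = (1 + #[null >= observed]) / (n_boot + 1)`.
#'
#' @param cross square matrix: `cross[i, k]` = similarity between original
#'   trial i and reconstructed trial k
#' @param n_boot number of shuffles (default 4000)
#' @param seed integer seed
#' @return scalar p-value with attribute `null` (the null draws)
#' @export
bootstrap_null <- function(cross, n_boot = 4000, seed = 1) {
  stopifnot(nrow(cross) == ncol(cross))
  n <- nrow(cross)
  if (n < 2) stop("need at least 2 trials")
  if (n_boot < 100) warning("n_boot < 100 gives a coarse p-value")
  observed <- mean(diag(cross))
  null <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      perm <- sample(n)
      mean(cross[cbind(seq_len(n), perm)])
    }, 0)
  })
  p <- (1 + sum(null >= observed)) / (n_boot + 1)
  attr(p, "observed") <- observed
  attr(p, "null") <- null
  p
}

## cross matrices of the three similarity measures over trial lists
.similarity_cross <- function(orig, recon, fs, ...) {
  n <- length(orig)
  r_time <- matrix(NA_real_, n, n)
  r_freq <- matrix(NA_real_, n, n)
  s_tf <- matrix(NA_real_, n, n)
  psd_o <- lapply(orig, function(x) welch_psd(x, fs)$power)
  psd_r <- lapply(recon, function(x) welch_psd(x, fs)$power)
  sg_ok <- TRUE
  sg_o <- tryCatch(lapply(orig, spectrogram, fs = fs, ...),
                   error = function(e) { sg_ok <<- FALSE; NULL })
  sg_r <- tryCatch(lapply(recon, spectrogram, fs = fs, ...),
                   error = function(e) { sg_ok <<- FALSE; NULL })
  if (sg_ok && any(dim(sg_o[[1]]) < 11)) sg_ok <- FALSE
  if (!sg_ok)
    message("trials too short for spectrogram SSIM; recorded as missing")
  const <- function(x) stats::sd(x) == 0 || !is.finite(stats::sd(x))
  for (i in seq_len(n)) for (k in seq_len(n)) {
    if (!const(orig[[i]]) && !const(recon[[k]])) {
      r_time[i, k] <- stats::cor(orig[[i]], recon[[k]])
      r_freq[i, k] <- stats::cor(psd_o[[i]], psd_r[[k]])
    }
    if (sg_ok) s_tf[i, k] <- .ssim_pair(sg_o[[i]], sg_r[[k]])
  }
  list(r_time = r_time, r_freq = r_freq, ssim = s_tf)
}

#' Similarity suite: time, frequency and time-frequency agreement
#'
#' Per trial: Pearson correlation between the original and reconstructed
#' series (time domain), Pearson correlation between their Welch power
#' spectra (frequency domain), and the structural similarity of their
#' log-power spectrograms. Bootstrap p-values (trial-shuffling null) are
#' attached per measure. Constant series give undefined correlations; these
#' trials are recorded as missing and excluded from the means with a
#' message.
#'
#' @param orig_trials,recon_trials lists of equal-length numeric series
#'   (aligned trials at a common rate)
#' @param fs sampling rate (default 100)
#' @param n_boot bootstrap resamples (default 4000)
#' @param seed integer seed for the bootstrap
#' @param ... spectrogram settings passed through
#' @return a `similarity_report`: list with `per_trial` (data.frame),
#'   `means`, `p`, and the `cross` matrices
#' @export
similarity_suite <- function(orig_trials, recon_trials, fs = 100,
                             n_boot = 4000, seed = 1, ...) {
  stopifnot(length(orig_trials) == length(recon_trials))
  lens <- c(vapply(orig_trials, length, 0L), vapply(recon_trials, length, 0L))
  if (length(unique(lens)) != 1) stop("trials must be aligned and equal length")
  cross <- .similarity_cross(orig_trials, recon_trials, fs, ...)
  per_trial <- data.frame(trial = seq_along(orig_trials),
                          r_time = diag(cross$r_time),
                          r_freq = diag(cross$r_freq),
                          ssim = diag(cross$ssim))
  if (anyNA(per_trial[, -1]))
    message("constant trial series: correlation undefined for ",
            sum(!stats::complete.cases(per_trial[, -1])),
            " trial(s); excluded from means")
  means <- colMeans(per_trial[, -1], na.rm = TRUE)
  p <- c(r_time = NA_real_, r_freq = NA_real_, ssim = NA_real_)
  for (m in names(p)) {
    cm <- cross[[m]]
    if (!anyNA(cm)) p[m] <- as.numeric(bootstrap_null(cm, n_boot, seed))
  }
  structure(list(per_trial = per_trial, means = means, p = p, cross = cross,
                 n_boot = n_boot),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("Similarity over", nrow(x$per_trial), "trials:\n")
  for (m in names(x$means))
    cat(sprintf("  %-7s mean = %+.3f  (bootstrap p = %.4g)\n",
                m, x$means[[m]], x$p[[m]]))
  invisible(x)
}

#' Per-trial rank accuracies from a similarity matrix
#'
#' `C[k, i]` is the similarity between reconstructed trial k and original
#' trial i. Trial k's comparison set holds all other trials (optionally
#' only those carrying a different piece); its rank accuracy is the
#' fraction of comparisons the matched similarity `C[k, k]` beats, with
#' half credit for ties. 0.5 at chance, 1 for perfect identification.
#'
#' @param C square similarity matrix (reconstructed x original)
#' @param piece_ids piece label per trial (default: all distinct)
#' @param comparison `"different_piece"` (default) excludes same-piece
#'   trials from the comparison set; `"all_other"` excludes only trial k
#' @return numeric vector of per-trial rank accuracies
#' @export
rank_accuracy_from_C <- function(C, piece_ids = seq_len(nrow(C)),
                                 comparison = c("different_piece", "all_other")) {
  comparison <- match.arg(comparison)
  n <- nrow(C)
  stopifnot(ncol(C) == n, length(piece_ids) == n)
  if (!anyDuplicated(piece_ids)) {
    # all pieces distinct: both comparison modes reduce to "all other
    # trials"; vectorised over the matrix
    d <- diag(C)
    wins <- rowSums(C < d)
    ties <- rowSums(C == d) - 1          # self-comparison is not in A
    return((wins + 0.5 * ties) / (n - 1))
  }
  acc <- numeric(n)
  for (k in seq_len(n)) {
    A <- setdiff(seq_len(n), k)
    if (comparison == "different_piece")
      A <- A[piece_ids[A] != piece_ids[k]]
    if (!length(A)) stop("empty comparison set for trial ", k,
                         " (all trials share its piece)")
    acc[k] <- (sum(C[k, k] > C[k, A]) + 0.5 * sum(C[k, k] == C[k, A])) / length(A)
  }
  acc
}

#' Rank-accuracy identification of heard music
#'
#' Both series sets are z-scored, band-pass filtered as continuous
#' concatenated series (zero-phase 4th-order Butterworth; the default band
#' 0.035-4.75 Hz preserves amplitude-envelope structure), re-segmented into
#' trials, and converted to log-power spectrograms. The structural
#' similarity of reconstructed trial k against every original trial fills
#' C; per-trial rank accuracies follow from [rank_accuracy_from_C()].
#'
#' @param orig_trials,recon_trials lists of equal-length series (40 s
#'   trials at `fs`)
#' @param piece_ids piece label per trial
#' @param fs sampling rate (default 100)
#' @param filter_band band-pass edges in Hz (default `c(0.035, 4.75)`)
#' @param comparison see [rank_accuracy_from_C()]
#' @param ... spectrogram settings
#' @return a `rank_result`: list with `C`, `rank_acc`, `mean_rank_acc`,
#'   `piece_ids`, `comparison`
#' @export
rank_accuracy <- function(orig_trials, recon_trials, piece_ids,
                          fs = 100, filter_band = c(0.035, 4.75),
                          comparison = c("different_piece", "all_other"), ...) {
  comparison <- match.arg(comparison)
  n <- length(orig_trials)
  stopifnot(length(recon_trials) == n, length(piece_ids) == n)
  len <- unique(vapply(c(orig_trials, recon_trials), length, 0L))
  if (length(len) != 1) stop("trials must share one length")

  prep <- function(trials) {
    z <- zscore(unlist(trials))
    z <- bandpass(z, fs, filter_band)
    lapply(seq_len(n), function(k) z[((k - 1) * len + 1):(k * len)])
  }
  o <- prep(orig_trials); r <- prep(recon_trials)
  sg_o <- lapply(o, spectrogram, fs = fs, ...)
  sg_r <- lapply(r, spectrogram, fs = fs, ...)
  C <- matrix(0, n, n)
  for (k in seq_len(n)) for (i in seq_len(n))
    C[k, i] <- .ssim_pair(sg_r[[k]], sg_o[[i]])
  acc <- rank_accuracy_from_C(C, piece_ids, comparison)
  structure(list(C = C, rank_acc = acc, mean_rank_acc = mean(acc),
                 piece_ids = piece_ids, comparison = comparison),
            class = "rank_result")
}

#' @export
print.rank_result <- function(x, ...) {
  cat("Rank accuracy over", length(x$rank_acc), "trials: mean =",
      round(x$mean_rank_acc, 3), "(chance 0.5)\n")
  invisible(x)
}

#' Permutation significance of the mean rank accuracy
#'
#' Permutes the trial-to-piece assignment of the similarity matrix columns
#' and recomputes the mean rank accuracy per permutation;
#' `p = (1 + #[null >= observed]) / (n_perm + 1)`.
#'
#' @param rank_result a `rank_result`
#' @param n_perm permutations (default 10000)
#' @param seed integer seed
#' @return scalar p-value with attribute `null`
#' @export
rank_significance <- function(rank_result, n_perm = 10000, seed = 1) {
  C <- rank_result$C
  n <- nrow(C)
  observed <- rank_result$mean_rank_acc
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- sample(n)
      mean(rank_accuracy_from_C(C[, perm, drop = FALSE],
                                rank_result$piece_ids[perm],
                                rank_result$comparison))
    }, 0)
  })
  p <- (1 + sum(null >= observed)) / (n_perm + 1)
  attr(p, "observed") <- observed
  attr(p, "null") <- null
  p
}
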