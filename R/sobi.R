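## Second-order blind identification: whitening followed by joint
## approximate diagonalisation (Jacobi rotations) of a set of time-lagged
## covariance matrices (Belouchrani et al. style). Entirely deterministic:
## the same data and lags always give the same decomposition.

## joint approximate diagonalisation of symmetric matrices, stacked
## horizontally in an n x (n*K) block matrix so Jacobi rotations apply to
## every matrix at once; returns orthogonal V maximising the sum of
## squared diagonals of V' M V
joint_diag <- function(Ms, tol = 1e-8, max_sweeps = 200) {
  n <- nrow(Ms[[1]])
  K <- length(Ms)
  A <- do.call(cbind, Ms)                  # n x (n*K)
  V <- diag(n)
  off <- (seq_len(K) - 1) * n
  for (sweep in seq_len(max_sweeps)) {
    max_theta <- 0
    for (p in 1:(n - 1)) for (q in (p + 1):n) {
      cp <- off + p; cq <- off + q
      h1 <- A[p, cp] - A[q, cq]
      h2 <- A[p, cq] + A[q, cp]
      ton <- sum(h1^2 - h2^2)
      toff <- 2 * sum(h1 * h2)
      theta <- 0.25 * atan2(toff, ton + sqrt(ton^2 + toff^2))
      if (abs(theta) > max_theta) max_theta <- abs(theta)
      if (abs(sin(theta)) > .Machine$double.eps) {
        cs <- cos(theta); sn <- sin(theta)
        rp <- cs * A[p, ] + sn * A[q, ]
        A[q, ] <- -sn * A[p, ] + cs * A[q, ]
        A[p, ] <- rp
        colp <- cs * A[, cp] + sn * A[, cq]
        A[, cq] <- -sn * A[, cp] + cs * A[, cq]
        A[, cp] <- colp
        vp <- cs * V[, p] + sn * V[, q]
        V[, q] <- -sn * V[, p] + cs * V[, q]
        V[, p] <- vp
      }
    }
    if (max_theta < tol) break
  }
  list(V = V, sweeps = sweep, converged = max_theta < tol)
}

#' SOBI decomposition of multichannel EEG
#'
#' Whitens the data and jointly diagonalises the symmetrised lagged
#' covariance matrices with Jacobi rotations. Rank-deficient data yield a
#' reduced-rank decomposition with a warning.
#'
#' @param eeg an `eeg_recording` or a channels x samples matrix
#' @param lags positive sample lags (default `1:100`)
#' @param tol rotation-angle convergence threshold (default 1e-8)
#' @param max_sweeps maximum Jacobi sweeps (default 200)
#' @return an `ica_decomposition`: list with `unmixing`
#'   (components x channels), `mixing` (channels x components), `sources`
#'   (`unmixing %*% data`, exactly), `lags`, `channels`, `fs`
#' @export
sobi <- function(eeg, lags = 1:100, tol = 1e-8, max_sweeps = 200) {
  X <- if (inherits(eeg, "eeg_recording")) eeg$data else as.matrix(eeg)
  fs <- if (inherits(eeg, "eeg_recording")) eeg$fs else NA_real_
  channels <- rownames(X) %||% paste0("ch", seq_len(nrow(X)))
  nc <- nrow(X); N <- ncol(X)
  if (nc >= N) stop("need more samples than channels")
  if (any(lags < 1) || any(lags != round(lags))) stop("lags must be positive integers")
  if (max(lags) >= N) stop("largest lag exceeds the data length")

  Xc <- X - rowMeans(X)
  C0 <- tcrossprod(Xc) / N
  e <- eigen(C0, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-10
  k <- sum(keep)
  if (k < nc) warning("rank-deficient data: retaining ", k, " of ", nc, " components")
  wh <- (1 / sqrt(e$values[seq_len(k)])) * t(e$vectors[, seq_len(k), drop = FALSE])
  Z <- wh %*% Xc

  Ms <- lapply(lags, function(l) {
    M <- tcrossprod(Z[, 1:(N - l), drop = FALSE],
                    Z[, (1 + l):N, drop = FALSE]) / (N - l)
    (M + t(M)) / 2
  })
  jd <- joint_diag(Ms, tol = tol, max_sweeps = max_sweeps)
  W <- t(jd$V) %*% wh                       # components x channels
  # sign convention: largest-magnitude unmixing weight of each component positive
  for (i in seq_len(nrow(W))) {
    j <- which.max(abs(W[i, ]))
    if (W[i, j] < 0) W[i, ] <- -W[i, ]
  }
  A <- if (k == nc) solve(W) else pinv(W)   # channels x components
  structure(list(unmixing = W, mixing = A, sources = W %*% X,
                 lags = lags, channels = channels, fs = fs,
                 sweeps = jd$sweeps, converged = jd$converged),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat("SOBI decomposition:", nrow(x$unmixing), "components x",
      ncol(x$unmixing), "channels (", x$sweeps, "sweeps,",
      if (x$converged) "converged" else "not converged", ")\n")
  invisible(x)
}

#' Back-project one independent component to channel space
#'
#' The channel-space signal that would be observed if only this component
#' were active: the outer product of its mixing column and its source time
#' course. Projections over all components sum to the input data exactly.
#'
#' @param decomp an `ica_decomposition`
#' @param component_index component to project (1-based)
#' @return channels x samples matrix
#' @export
project_component <- function(decomp, component_index) {
  if (component_index < 1 || component_index > nrow(decomp$sources))
    stop("component index out of range")
  outer(decomp$mixing[, component_index], decomp$sources[component_index, ])
}

#' Reconstruct EEG with components removed
#'
#' @param decomp an `ica_decomposition`
#' @param reject_indices components to drop (may be empty)
#' @return channels x samples matrix of the cleaned recording
#' @export
remove_components <- function(decomp, reject_indices = integer(0)) {
  M <- nrow(decomp$sources)
  if (length(reject_indices)) {
    if (any(reject_indices < 1 | reject_indices > M))
      stop("component index out of range")
    if (length(unique(reject_indices)) >= M)
      stop("cannot reject every component")
  }
  keep <- setdiff(seq_len(M), reject_indices)
  decomp$mixing[, keep, drop = FALSE] %*% decomp$sources[keep, , drop = FALSE]
}

#' Simple automated artifact-component heuristics
#'
#' Flags components with excess kurtosis above `kurtosis_max` or with a
#' dominant share of power at the mains frequency. A reproducible stand-in
#' for interactive component inspection; review the result before rejecting.
#'
#' @param decomp an `ica_decomposition` with a known `fs`
#' @param kurtosis_max kurtosis threshold (default 10)
#' @param line_freq_hz mains frequency (default 50)
#' @param line_ratio_max flag when power within 1 Hz of the mains frequency
#'   exceeds this fraction of total power (default 0.5)
#' @return integer vector of suspect component indices
#' @export
suggest_artifact_components <- function(decomp, kurtosis_max = 10,
                                        line_freq_hz = 50, line_ratio_max = 0.5) {
  S <- decomp$sources
  kurt <- apply(S, 1, function(s) {
    s <- s - mean(s); mean(s^4) / mean(s^2)^2 - 3
  })
  flagged <- which(kurt > kurtosis_max)
  if (is.finite(decomp$fs)) {
    for (i in seq_len(nrow(S))) {
      ps <- welch_psd(S[i, ], decomp$fs, nperseg = min(ncol(S), 2 * decomp$fs))
      band <- ps$freq >= line_freq_hz - 1 & ps$freq <= line_freq_hz + 1
      if (any(band) && sum(ps$power[band]) / sum(ps$power) > line_ratio_max)
        flagged <- union(flagged, i)
    }
  }
  sort(flagged)
}
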