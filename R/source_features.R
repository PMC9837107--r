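## eLORETA distributed inverse solution and the per-IC source-projection
## feature matrix.
##
## eLORETA iterates 3x3 block depth weights W_v to the fixed point
## W_v = [ L_v' (L W^-1 L' + alpha H)^+ L_v ]^(1/2), with H the
## average-reference centering matrix, then applies the kernel
## K = W^-1 L' (L W^-1 L' + alpha H)^+. For noiseless single-dipole data
## this solution has zero localisation error.

#' eLORETA inverse operator
#'
#' @param leadfield an average-referenced `leadfield`
#' @param alpha dimensionless regularisation; scales the trace-normalised
#'   sensor gram (default 0.05)
#' @param tol convergence tolerance: maximum relative Frobenius change of
#'   any block weight (default 1e-6)
#' @param max_iter maximum fixed-point iterations (default 100)
#' @return an `inverse_operator`: list with `kernel`
#'   ((sources*3) x channels), `alpha`, `iterations`, `converged`, `grid`,
#'   `spacing_mm`, `channels`, `method`
#' @export
eloreta_kernel <- function(leadfield, alpha = 0.05, tol = 1e-6, max_iter = 100) {
  if (!identical(leadfield$reference_scheme, "average"))
    stop("eLORETA expects an average-referenced leadfield")
  if (alpha < 0) stop("alpha must be >= 0")
  L <- leadfield$gain
  nc <- nrow(L); ns <- ncol(L) / 3
  H <- diag(nc) - matrix(1 / nc, nc, nc)

  Winv <- rep(list(diag(3)), ns)
  iterations <- 0; converged <- FALSE
  Lblocks <- lapply(seq_len(ns), function(v) L[, (v - 1) * 3 + 1:3, drop = FALSE])
  for (it in seq_len(max_iter)) {
    iterations <- it
    G <- matrix(0, nc, nc)
    for (v in seq_len(ns))
      G <- G + Lblocks[[v]] %*% Winv[[v]] %*% t(Lblocks[[v]])
    Minv <- pinv(G + alpha * (sum(diag(G)) / nc) * H)
    delta <- 0
    for (v in seq_len(ns)) {
      Wv <- sym_sqrt(t(Lblocks[[v]]) %*% Minv %*% Lblocks[[v]])
      Wv_inv <- pinv(Wv)
      old <- Winv[[v]]
      rel <- norm(Wv_inv - old, "F") / max(norm(old, "F"), .Machine$double.eps)
      if (rel > delta) delta <- rel
      Winv[[v]] <- Wv_inv
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("eLORETA weights did not converge in ", max_iter, " iterations")

  G <- matrix(0, nc, nc)
  for (v in seq_len(ns))
    G <- G + Lblocks[[v]] %*% Winv[[v]] %*% t(Lblocks[[v]])
  Minv <- pinv(G + alpha * (sum(diag(G)) / nc) * H)
  K <- matrix(0, ns * 3, nc)
  for (v in seq_len(ns))
    K[(v - 1) * 3 + 1:3, ] <- Winv[[v]] %*% t(Lblocks[[v]]) %*% Minv
  structure(list(kernel = K, alpha = alpha, iterations = iterations,
                 converged = converged, grid = leadfield$grid,
                 spacing_mm = leadfield$spacing_mm,
                 channels = leadfield$channels, method = "eloreta"),
            class = "inverse_operator")
}

#' LCMV beamformer inverse operator
#'
#' Secondary source-reconstruction option behind the same interface:
#' per-source spatial filters `(L_v' C^-1 L_v)^-1 L_v' C^-1` from a sensor
#' covariance `C` (regularised by `alpha` times its normalised trace).
#'
#' @param leadfield a `leadfield`
#' @param data_cov channels x channels sensor covariance
#' @param alpha diagonal-loading factor (default 0.05)
#' @return an `inverse_operator` with `method = "lcmv"`
#' @export
lcmv_kernel <- function(leadfield, data_cov, alpha = 0.05) {
  L <- leadfield$gain
  nc <- nrow(L); ns <- ncol(L) / 3
  C <- data_cov + alpha * (sum(diag(data_cov)) / nc) * diag(nc)
  Cinv <- pinv(C)
  K <- matrix(0, ns * 3, nc)
  for (v in seq_len(ns)) {
    Lv <- L[, (v - 1) * 3 + 1:3, drop = FALSE]
    K[(v - 1) * 3 + 1:3, ] <- pinv(t(Lv) %*% Cinv %*% Lv) %*% t(Lv) %*% Cinv
  }
  structure(list(kernel = K, alpha = alpha, iterations = 1L, converged = TRUE,
                 grid = leadfield$grid, spacing_mm = leadfield$spacing_mm,
                 channels = leadfield$channels, method = "lcmv"),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(toupper(x$method), "inverse operator:", nrow(x$kernel) / 3, "sources,",
      "alpha =", x$alpha, "(", x$iterations, "iterations,",
      if (x$converged) "converged" else "not converged", ")\n")
  invisible(x)
}

## snap dipole coordinates to grid rows; error beyond one grid spacing
snap_dipoles <- function(invop, dipoles) {
  coords <- if (inherits(dipoles, "dipole_set")) dipoles$locations else rbind(dipoles)
  idx <- integer(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    d2 <- rowSums(sweep(invop$grid, 2, coords[i, ])^2)
    j <- which.min(d2)
    d <- sqrt(d2[j])
    if (d > invop$spacing_mm)
      stop("dipole (", paste(round(coords[i, ], 1), collapse = ", "),
           ") is farther than one grid spacing from the source grid")
    if (d > 1e-9)
      message("dipole ", i, " snapped to grid point ", j,
              " (", round(d, 2), " mm away)")
    idx[i] <- j
  }
  idx
}

#' Estimate source activity at selected dipole locations
#'
#' Applies the inverse kernel at the dipole grid points and reduces the
#' three orientation time courses per dipole to one via projection onto the
#' principal orientation (leading eigenvector of the 3 x 3 moment
#' covariance; sign fixed so its largest component is positive). A fixed
#' `orientations` matrix may be supplied instead, which makes the estimate
#' exactly linear in the data.
#'
#' @param invop an `inverse_operator`
#' @param recording an `eeg_recording` or channels x samples matrix
#' @param dipoles a `dipole_set` or k x 3 coordinate matrix (snapped to the
#'   nearest grid point; more than one grid spacing away is an error)
#' @param orientations optional k x 3 matrix of fixed unit orientations
#' @return k x samples matrix, rows in dipole order, with attributes
#'   `grid_index` and `orientations`
#' @export
estimate_sources <- function(invop, recording, dipoles, orientations = NULL) {
  X <- if (inherits(recording, "eeg_recording")) recording$data else as.matrix(recording)
  if (ncol(invop$kernel) != nrow(X))
    stop("recording has ", nrow(X), " channels but the kernel expects ",
         ncol(invop$kernel))
  idx <- snap_dipoles(invop, dipoles)
  k <- length(idx)
  out <- matrix(0, k, ncol(X))
  ori <- matrix(0, k, 3)
  for (i in seq_len(k)) {
    Kd <- invop$kernel[(idx[i] - 1) * 3 + 1:3, , drop = FALSE]
    Mom <- Kd %*% X
    if (is.null(orientations)) {
      u <- eigen(tcrossprod(Mom), symmetric = TRUE)$vectors[, 1]
      if (u[which.max(abs(u))] < 0) u <- -u
    } else {
      u <- orientations[i, ]
      u <- u / sqrt(sum(u^2))
    }
    ori[i, ] <- u
    out[i, ] <- as.numeric(crossprod(u, Mom))
  }
  attr(out, "grid_index") <- idx
  attr(out, "orientations") <- ori
  out
}

#' Build the per-IC source-projection feature matrix
#'
#' For each independent component, its channel-space back-projection is
#' passed through the inverse operator at the selected dipole locations,
#' giving a dipoles x samples block; blocks are concatenated in component
#' order into a (dipoles x components) x samples matrix (124 x N_s for 31
#' components and 4 dipoles). Dipole orientations are fixed once from the
#' full reconstruction, so the blocks sum exactly to the source estimate of
#' the full data.
#'
#' @param decomp an `ica_decomposition` with M retained components
#' @param invop an `inverse_operator`
#' @param dipoles a `dipole_set` or coordinate matrix (k dipoles)
#' @param downsample_factor optional integer; when > 1 each feature row is
#'   decimated with [downsample()] after construction
#' @return a `feature_matrix`: list with `values` ((k*M) x N matrix),
#'   `row_map` (data.frame row, ic, dipole), `fs`
#' @export
build_features <- function(decomp, invop, dipoles, downsample_factor = 1) {
  M <- nrow(decomp$sources)
  N <- ncol(decomp$sources)
  if (ncol(decomp$mixing) != M) stop("inconsistent decomposition")
  idx <- suppressMessages(snap_dipoles(invop, dipoles))
  k <- length(idx)

  # fixed orientations from the full reconstruction (mixing %*% sources)
  full <- decomp$mixing %*% decomp$sources
  est_full <- estimate_sources(invop, full, dipoles)
  ori <- attr(est_full, "orientations")

  nsamp <- if (downsample_factor > 1) ceiling(N / downsample_factor) else N
  values <- matrix(0, k * M, nsamp)
  row_map <- data.frame(row = seq_len(k * M),
                        ic = rep(seq_len(M), each = k),
                        dipole = rep(seq_len(k), times = M))
  for (i in seq_len(M)) {
    # rank-1 shortcut: sources of (a_i s_i') at dipole d are
    # (u_d' K_d a_i) * s_i
    gains <- numeric(k)
    for (d in seq_len(k)) {
      Kd <- invop$kernel[(idx[d] - 1) * 3 + 1:3, , drop = FALSE]
      gains[d] <- as.numeric(crossprod(ori[d, ], Kd %*% decomp$mixing[, i]))
    }
    block <- outer(gains, decomp$sources[i, ])
    if (downsample_factor > 1)
      block <- t(apply(block, 1, downsample, factor = downsample_factor))
    values[(i - 1) * k + seq_len(k), ] <- block
  }
  fs <- decomp$fs
  if (is.finite(fs) && downsample_factor > 1) fs <- fs / downsample_factor
  structure(list(values = values, row_map = row_map, fs = fs,
                 n_dipoles = k, n_components = M),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix: (", x$n_dipoles, " dipoles x ", x$n_components,
      " ICs) = ", nrow(x$values), " rows x ", ncol(x$values), " samples @ ",
      x$fs, " Hz\n", sep = "")
  invisible(x)
}
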