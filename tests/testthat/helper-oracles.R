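# Independent oracles and shared fixtures for the test suite.

# Closed-form scalp potential of a dipole in a homogeneous conducting
# sphere (insulating exterior), derived via Legendre generating functions;
# independent of the package's truncated-series + boundary-value solver.
closed_sphere_potential <- function(re, r0, q, R, sigma) {
  b <- sqrt(sum(r0^2))
  f <- b / R
  ur <- r0 / b
  qr <- sum(q * ur)
  qperp <- q - qr * ur
  eu <- re / sqrt(sum(re^2))
  x <- sum(eu * ur)
  d <- sqrt(1 - 2 * f * x + f^2)
  w <- eu - x * ur
  rad <- 2 * (x - f) / d^3 + (1 / f) * (1 / d - 1)
  tang <- 2 / d^3 + (d + 1) / (d * (1 - f * x + d))
  (qr * rad + sum(w * qperp) * tang) / (4 * pi * sigma * R^2)
}

# Amari performance index of a permutation-scaling matrix P = W %*% A;
# 0 for perfect separation up to permutation and scale.
amari_index <- function(P) {
  P <- abs(P)
  n <- nrow(P)
  r <- sum(rowSums(P / apply(P, 1, max)) - 1) / (n * (n - 1))
  cc <- sum(colSums(P / rep(apply(P, 2, max), each = n)) - 1) / (n * (n - 1))
  (r + cc) / 2
}

# Step-by-step reference implementation of the greedy minimum-distance
# selection, written against the procedure directly (no shared code with
# select_dipoles).
greedy_oracle <- function(coords, tvals, cand, m, n_l) {
  V <- integer(0)
  C <- cand
  while (length(V) < n_l && length(C)) {
    # largest T, ties by lowest index
    best <- C[which(tvals[C] == max(tvals[C]))]
    v <- min(best)
    C <- setdiff(C, v)
    ok <- TRUE
    if (length(V)) {
      dd <- sqrt(rowSums((coords[V, , drop = FALSE] -
                            matrix(coords[v, ], length(V), 3, byrow = TRUE))^2))
      ok <- min(dd) > m
    }
    if (ok) V <- c(V, v)
  }
  V
}

# Naive windowed SSIM (double loop over window positions), independent of
# the package's separable-filter implementation.
ssim_oracle <- function(a, b, L, K1 = 0.01, K2 = 0.03, win = 11, sigma = 1.5) {
  half <- (win - 1) / 2
  g1 <- exp(-((-half:half)^2) / (2 * sigma^2))
  G <- outer(g1, g1)
  G <- G / sum(G)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  vals <- c()
  for (i in (half + 1):(nrow(a) - half)) {
    for (j in (half + 1):(ncol(a) - half)) {
      wa <- a[(i - half):(i + half), (j - half):(j + half)]
      wb <- b[(i - half):(i + half), (j - half):(j + half)]
      mua <- sum(G * wa); mub <- sum(G * wb)
      va <- sum(G * wa^2) - mua^2; vb <- sum(G * wb^2) - mub^2
      vab <- sum(G * wa * wb) - mua * mub
      vals <- c(vals, ((2 * mua * mub + C1) * (2 * vab + C2)) /
                  ((mua^2 + mub^2 + C1) * (va + vb + C2)))
    }
  }
  mean(vals)
}

# seeded AR(1) source matrix (samples x k) with well-separated spectra
ar_sources <- function(n, coefs = c(0.05, 0.3, 0.55, 0.75, 0.92), seed = 1) {
  set.seed(seed)
  sapply(coefs, function(a) as.numeric(stats::arima.sim(list(ar = a), n)))
}

# small shared leadfield (coarse 30 mm grid), built once per test session
small_leadfield <- local({
  lf <- NULL
  function() {
    if (is.null(lf))
      lf <<- suppressMessages(build_spherical_leadfield(
        standard_montage(), grid_spacing_mm = 30))
    lf
  }
})

# tiny stimulus/schedule pair for simulator tests
tiny_experiment <- function(n_pieces = 4, duration_s = 8, fs = 500,
                            n_runs = 1, trials_per_run = 3, seed = 5) {
  stim <- generate_music(n_pieces, duration_s, fs, c(60, 180), seed = seed)
  sched <- generate_schedule(
    n_runs, trials_per_run, stim, seed = seed + 1,
    type_mix = c(music_only = 1L, music_reporting = 1L, reporting_only = 1L),
    task_s = duration_s)
  list(stim = stim, sched = sched)
}
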