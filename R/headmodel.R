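## Analytic multishell spherical volume conductor.
##
## The scalp potential of a current dipole inside a set of concentric
## spherical shells is expanded in Legendre harmonics. Per harmonic degree n
## the radial solution in shell j is a_j r^n + b_j r^(-(n+1)); continuity of
## potential and of radial current at every interface plus the insulating
## outer boundary give a small linear system whose solution yields a
## transfer coefficient per degree. Radii are normalised to the scalp radius
## so powers stay within double-precision range.

## transfer coefficients S_n for n = 1..n_terms, for unit primary
## coefficient rho^-(n+1) in the innermost shell (radii normalised to 1)
.shell_transfer <- function(rho, sigma, n_terms) {
  M <- length(rho)           # rho[M] == 1 (scalp)
  S <- numeric(n_terms)
  for (n in seq_len(n_terms)) {
    if (M == 1) {
      # insulating homogeneous sphere: n*a = (n+1)  =>  S = a + 1
      S[n] <- (n + 1) / n + 1
      next
    }
    nm <- 2 * M - 1          # unknowns a_1..a_M, b_2..b_M
    A <- matrix(0, nm, nm)
    rhs <- numeric(nm)
    ai <- function(j) j                    # index of a_j
    bi <- function(j) M + j - 1            # index of b_j (j >= 2)
    row <- 0
    for (j in seq_len(M - 1)) {            # interface at rho[j]
      r <- rho[j]
      # potential continuity
      row <- row + 1
      A[row, ai(j)] <- r^n
      if (j > 1) A[row, bi(j)] <- r^(-(n + 1))
      A[row, ai(j + 1)] <- -r^n
      A[row, bi(j + 1)] <- -r^(-(n + 1))
      if (j == 1) rhs[row] <- -r^(-(n + 1))
      # radial current continuity
      row <- row + 1
      A[row, ai(j)] <- sigma[j] * n * r^(n - 1)
      if (j > 1) A[row, bi(j)] <- -sigma[j] * (n + 1) * r^(-(n + 2))
      A[row, ai(j + 1)] <- -sigma[j + 1] * n * r^(n - 1)
      A[row, bi(j + 1)] <- sigma[j + 1] * (n + 1) * r^(-(n + 2))
      if (j == 1) rhs[row] <- sigma[1] * (n + 1) * r^(-(n + 2))
    }
    row <- row + 1                         # insulating scalp surface, rho = 1
    A[row, ai(M)] <- n
    A[row, bi(M)] <- -(n + 1)
    x <- solve(A, rhs)
    S[n] <- x[ai(M)] + x[bi(M)]
  }
  S
}

## Legendre P_n(x) and P_n'(x), n = 1..N, vectorised over x
.legendre_table <- function(x, N) {
  P <- matrix(0, length(x), N)
  dP <- matrix(0, length(x), N)
  Pm1 <- rep(1, length(x)); P0 <- x
  dPm1 <- rep(0, length(x)); dP0 <- rep(1, length(x))
  P[, 1] <- P0; dP[, 1] <- dP0
  if (N >= 2) for (n in 2:N) {
    Pn <- ((2 * n - 1) * x * P0 - (n - 1) * Pm1) / n
    dPn <- ((2 * n - 1) * (P0 + x * dP0) - (n - 1) * dPm1) / n
    P[, n] <- Pn; dP[, n] <- dPn
    Pm1 <- P0; P0 <- Pn; dPm1 <- dP0; dP0 <- dPn
  }
  list(P = P, dP = dP)
}

#' Analytic multishell spherical leadfield
#'
#' Computes the sensor gain matrix of unit current dipoles on a regular 3D
#' grid inside the innermost shell of a concentric-sphere conductor
#' (default three shells: brain, skull, scalp), via a truncated Legendre
#' series. Gains are returned average-referenced, so every column sums to
#' zero across channels.
#'
#' @param sensors a `sensor_array` (see [standard_montage()]); positions are
#'   projected onto the scalp sphere
#' @param shell_radii_mm strictly increasing shell radii in mm
#'   (default `c(80, 85, 92)`: brain, skull, scalp)
#' @param shell_conductivities conductivity per shell in S/m
#'   (default `c(0.33, 0.01, 0.43)`)
#' @param grid_spacing_mm source grid spacing in mm (default 15)
#' @param n_terms number of Legendre terms (default 100, minimum 60)
#' @return a `leadfield`: list with `gain` (channels x (sources*3), columns
#'   grouped per source as x/y/z unit-dipole orientations), `grid`
#'   (sources x 3, mm), `spacing_mm`, `radii_mm`, `conductivities`,
#'   `channels`, `reference_scheme = "average"`
#' @details A grid point at the exact sphere centre has no defined radial
#'   direction and is dropped with a message.
#' @export
build_spherical_leadfield <- function(sensors,
                                      shell_radii_mm = c(80, 85, 92),
                                      shell_conductivities = c(0.33, 0.01, 0.43),
                                      grid_spacing_mm = 15,
                                      n_terms = 100) {
  if (length(shell_radii_mm) != length(shell_conductivities))
    stop("one conductivity per shell required")
  if (any(diff(shell_radii_mm) <= 0)) stop("shell radii must be strictly increasing")
  if (any(shell_conductivities <= 0)) stop("conductivities must be positive")
  if (n_terms < 60) stop("n_terms must be at least 60")

  R <- shell_radii_mm[length(shell_radii_mm)]
  r_brain <- shell_radii_mm[1]
  grid <- make_source_grid(r_brain, grid_spacing_mm)
  at_centre <- sqrt(rowSums(grid^2)) < 1e-9
  if (any(at_centre)) {
    message("dropping ", sum(at_centre), " grid point(s) at the sphere centre (undefined tangential field)")
    grid <- grid[!at_centre, , drop = FALSE]
  }

  epos <- as.matrix(sensors[, c("x", "y", "z")])
  epos <- epos / sqrt(rowSums(epos^2)) * R       # snap electrodes to scalp sphere
  ne <- nrow(epos); ns <- nrow(grid)

  S <- .shell_transfer(shell_radii_mm / R, shell_conductivities, n_terms)
  n_idx <- seq_len(n_terms)
  scale0 <- 1 / (4 * pi * shell_conductivities[1] * R^2)

  gain <- matrix(0, ne, ns * 3)
  eu <- epos / R                                  # unit electrode directions
  for (s in seq_len(ns)) {
    r0 <- grid[s, ]
    b <- sqrt(sum(r0^2))
    ur <- r0 / b
    f <- b / R
    x <- as.numeric(eu %*% ur)                    # cos(gamma) per electrode
    x <- pmin(pmax(x, -1), 1)
    leg <- .legendre_table(x, n_terms)
    fpow <- f^(n_idx - 1)
    Acoef <- leg$P %*% (S * fpow * n_idx)         # radial pattern
    Bcoef <- leg$dP %*% (S * fpow)                # tangential pattern
    W <- eu - outer(x, ur)                        # electrode vector less axial part
    for (j in 1:3) {
      q <- c(0, 0, 0); q[j] <- 1
      qr <- ur[j]                                 # q . ur for a basis vector
      qperp <- q - qr * ur
      gain[, (s - 1) * 3 + j] <- scale0 * (Acoef * qr + Bcoef * as.numeric(W %*% qperp))
    }
  }
  gain <- sweep(gain, 2, colMeans(gain))          # average reference
  structure(list(gain = gain,
                 grid = grid,
                 spacing_mm = grid_spacing_mm,
                 radii_mm = shell_radii_mm,
                 conductivities = shell_conductivities,
                 channels = sensors$name,
                 reference_scheme = "average"),
            class = "leadfield")
}

#' Regular source grid inside a sphere
#'
#' Grid points at integer multiples of `spacing_mm` (0-based indices from the
#' origin, RAS mm) strictly inside radius `r_mm`.
#' @param r_mm bounding sphere radius (mm)
#' @param spacing_mm grid spacing (mm)
#' @return matrix (points x 3)
#' @export
make_source_grid <- function(r_mm, spacing_mm) {
  ax <- seq(-floor(r_mm / spacing_mm), floor(r_mm / spacing_mm)) * spacing_mm
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  dimnames(g) <- NULL
  g[sqrt(rowSums(g^2)) < r_mm, , drop = FALSE]
}

#' @export
print.leadfield <- function(x, ...) {
  cat("Spherical leadfield:", nrow(x$gain), "channels x",
      nrow(x$grid), "sources (x3 orientations)\n")
  cat("  shell radii (mm):", paste(x$radii_mm, collapse = "/"),
      " conductivities (S/m):", paste(x$conductivities, collapse = "/"), "\n")
  cat("  grid spacing:", x$spacing_mm, "mm; reference:", x$reference_scheme, "\n")
  invisible(x)
}

#' Export / import a leadfield container
#'
#' Portable JSON container with the gain matrix, source grid and metadata.
#' On import all leadfield invariants are re-validated: finite gains,
#' average-reference column sums (when the stored reference scheme is
#' `"average"`), and every source inside the innermost shell.
#'
#' @param leadfield a `leadfield`
#' @param path file path (`.json`)
#' @return `import_leadfield` returns a validated `leadfield`
#' @export
export_leadfield <- function(leadfield, path) {
  obj <- list(gain = leadfield$gain,
              grid = leadfield$grid,
              spacing_mm = leadfield$spacing_mm,
              radii_mm = leadfield$radii_mm,
              conductivities = leadfield$conductivities,
              channels = leadfield$channels,
              reference_scheme = leadfield$reference_scheme)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname export_leadfield
#' @export
import_leadfield <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("gain", "grid", "spacing_mm", "conductivities", "channels")
  if (!all(need %in% names(obj))) stop("leadfield container missing fields: ",
                                       paste(setdiff(need, names(obj)), collapse = ", "))
  gain <- as.matrix(obj$gain); grid <- as.matrix(obj$grid)
  if (length(obj$channels) != nrow(gain))
    stop("leadfield container: gain has ", nrow(gain),
         " rows but ", length(obj$channels), " channel names")
  if (ncol(gain) != nrow(grid) * 3)
    stop("leadfield container: gain columns do not match grid size x 3")
  if (!all(is.finite(gain))) stop("leadfield container: non-finite gains")
  ref <- obj$reference_scheme %||% "average"
  if (identical(ref, "average")) {
    colsum <- colSums(gain)
    if (max(abs(colsum)) > 1e-6 * max(abs(gain)))
      stop("leadfield container: declared average reference but gain columns do not sum to zero")
  }
  radii <- obj$radii_mm %||% rep(NA_real_, 3)
  if (is.finite(radii[1]) && any(sqrt(rowSums(grid^2)) >= radii[1]))
    stop("leadfield container: source outside the innermost shell")
  structure(list(gain = gain, grid = grid,
                 spacing_mm = obj$spacing_mm,
                 radii_mm = radii,
                 conductivities = obj$conductivities,
                 channels = obj$channels,
                 reference_scheme = ref),
            class = "leadfield")
}
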