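# a fabricated square decomposition over the montage channels, for feature
# tests that do not need a real SOBI fit
fake_decomp <- function(n_ch = 31, M = n_ch, N = 200, fs = 1000, seed = 1) {
  set.seed(seed)
  A <- qr.Q(qr(matrix(stats::rnorm(n_ch * M), n_ch, M)))
  S <- matrix(stats::rnorm(M * N), M, N)
  list(unmixing = t(A), mixing = A, sources = S,
       channels = paste0("ch", seq_len(n_ch)), fs = fs)
}

small_invop <- local({
  inv <- NULL
  function() {
    if (is.null(inv)) inv <<- eloreta_kernel(small_leadfield(), alpha = 0.05)
    inv
  }
})

test_that("eLORETA localises every noiseless grid dipole exactly", {
  lf <- small_leadfield()             # 5 points per axis inside the sphere
  inv <- eloreta_kernel(lf, alpha = 1e-3)
  expect_true(inv$converged)
  miss <- 0L
  for (s in seq_len(nrow(lf$grid))) {
    for (j in 1:3) {
      mom <- inv$kernel %*% lf$gain[, (s - 1) * 3 + j, drop = FALSE]
      pow <- rowSums(matrix(mom^2, ncol = 3, byrow = TRUE))
      if (which.max(pow) != s) miss <- miss + 1L
    }
  }
  expect_equal(miss, 0L)
})

test_that("large regularisation approaches the weighted minimum-norm limit", {
  lf <- small_leadfield()
  inv <- eloreta_kernel(lf, alpha = 1e4)
  # alpha-dominant fixed point, coded independently: block weights from the
  # centering matrix alone, kernel shape pinv(sqrt(Lv' H+ Lv)) Lv' H+
  L <- lf$gain; nc <- nrow(L)
  H <- diag(nc) - matrix(1 / nc, nc, nc)
  Ko <- matrix(0, ncol(L), nc)
  for (v in seq_len(ncol(L) / 3)) {
    Lv <- L[, (v - 1) * 3 + 1:3]
    W <- t(Lv) %*% H %*% Lv
    e <- eigen((W + t(W)) / 2, symmetric = TRUE)
    Whalf_inv <- e$vectors %*% ((1 / sqrt(pmax(e$values, 1e-30))) * t(e$vectors))
    Ko[(v - 1) * 3 + 1:3, ] <- Whalf_inv %*% t(Lv) %*% H
  }
  expect_gt(stats::cor(as.numeric(inv$kernel), as.numeric(Ko)), 0.999)
})

test_that("the eLORETA kernel is deterministic and reference-invariant", {
  lf <- small_leadfield()
  i1 <- eloreta_kernel(lf, alpha = 0.05)
  i2 <- eloreta_kernel(lf, alpha = 0.05)
  expect_identical(i1$kernel, i2$kernel)
  # common-mode channel offsets map to (numerically) zero sources
  offs <- matrix(3.7, nrow(lf$gain), 5)
  mom <- i1$kernel %*% offs
  expect_lt(max(abs(mom)), 1e-10 * max(abs(i1$kernel)) * nrow(lf$gain) * 4)
})

test_that("non-convergence is reported on the operator", {
  lf <- small_leadfield()
  expect_warning(inv <- eloreta_kernel(lf, alpha = 0.05, tol = 1e-14,
                                       max_iter = 2), "converge")
  expect_false(inv$converged)
  expect_equal(inv$iterations, 2)
})

test_that("source estimation honours dipole order, snapping and zero input", {
  lf <- small_leadfield()
  inv <- small_invop()
  dip <- lf$grid[c(8, 21, 33, 47), ]
  zero <- matrix(0, nrow(lf$gain), 10)
  est <- estimate_sources(inv, zero, dip)
  expect_equal(est, matrix(0, 4, 10), ignore_attr = TRUE)
  expect_equal(nrow(est), 4)

  # rank-1 recording from one dipole: its row dominates
  set.seed(2)
  s <- stats::rnorm(300)
  x <- lf$gain[, (21 - 1) * 3 + 2, drop = FALSE] %*% t(s)
  est <- estimate_sources(inv, x, dip)
  expect_equal(which.max(apply(est, 1, stats::var)), 2L)

  # snapping: small offsets snap with a message, large offsets error
  expect_message(estimate_sources(inv, zero, dip + 3), "snapped")
  expect_error(suppressMessages(estimate_sources(inv, zero, rbind(c(500, 0, 0)))),
               "grid spacing")
})

test_that("LCMV behind the same interface recovers a strong source", {
  lf <- small_leadfield()
  set.seed(3)
  s <- stats::rnorm(500)
  x <- lf$gain[, (15 - 1) * 3 + 1, drop = FALSE] %*% t(s) +
    matrix(stats::rnorm(nrow(lf$gain) * 500, sd = 1e-4 * max(abs(lf$gain))),
           ncol = 500)
  C <- tcrossprod(x - rowMeans(x)) / ncol(x)
  inv <- lcmv_kernel(lf, C, alpha = 0.05)
  expect_s3_class(inv, "inverse_operator")
  dip <- lf$grid[c(15, 40), ]
  est <- estimate_sources(inv, x, dip)
  expect_gt(stats::var(est[1, ]), stats::var(est[2, ]))
})

test_that("feature matrix has (dipoles x components) rows with a bijective row map", {
  d <- fake_decomp(31, 31, N = 150)
  inv <- small_invop()
  dip <- small_leadfield()$grid[c(8, 21, 33, 47), ]
  fm <- build_features(d, inv, dip)
  expect_equal(nrow(fm$values), 124)          # 4 dipoles x 31 components
  expect_equal(ncol(fm$values), 150)
  expect_equal(nrow(fm$row_map), 124)
  expect_false(any(duplicated(fm$row_map[, c("ic", "dipole")])))
  expect_equal(sort(unique(fm$row_map$ic)), 1:31)
  expect_equal(sort(unique(fm$row_map$dipole)), 1:4)
})

test_that("a single-component feature matrix equals the full-data source estimate", {
  d <- fake_decomp(31, 31, N = 120, seed = 5)
  d$mixing <- d$mixing[, 1, drop = FALSE]
  d$unmixing <- d$unmixing[1, , drop = FALSE]
  d$sources <- d$sources[1, , drop = FALSE]
  inv <- small_invop()
  dip <- small_leadfield()$grid[c(8, 21, 33), ]
  fm <- build_features(d, inv, dip)
  full <- estimate_sources(inv, d$mixing %*% d$sources, dip)
  expect_equal(fm$values, full, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("feature blocks sum to the source estimate of the full data", {
  d <- fake_decomp(31, 31, N = 140, seed = 6)
  inv <- small_invop()
  lf <- small_leadfield()
  dip <- lf$grid[c(8, 21, 33, 47), ]
  fm <- build_features(d, inv, dip)
  full <- estimate_sources(inv, d$mixing %*% d$sources, dip)
  summed <- Reduce(`+`, lapply(1:31, function(i)
    fm$values[(i - 1) * 4 + 1:4, , drop = FALSE]))
  expect_lt(max(abs(summed - full)) / max(abs(full)), 1e-6)
})

test_that("feature construction validates inconsistent inputs", {
  d <- fake_decomp(31, 31, N = 100)
  d$mixing <- d$mixing[, 1:30]
  inv <- small_invop()
  expect_error(build_features(d, inv, small_leadfield()$grid[3, , drop = FALSE]),
               "inconsistent")
})
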