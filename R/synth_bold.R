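## BOLD-like 4D volume: voxel time series are white noise, plus (inside
## active clusters) the music-trial boxcar convolved with a canonical
## double-gamma hemodynamic response, sampled at the repetition time.

#' Canonical double-gamma hemodynamic response function
#'
#' Peak at ~6 s, undershoot at ~16 s, undershoot ratio 1/6.
#'
#' @param t time in seconds (vector)
#' @param peak,undershoot gamma shape parameters (rate 1/s)
#' @param ratio undershoot amplitude ratio
#' @return HRF values at `t`
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot, rate = 1)
  h[t < 0] <- 0
  h
}

## condition boxcar convolved with the HRF, sampled at TR over `dur` seconds
hrf_regressor <- function(onsets, durations, dur_s, tr_s, dt = 0.1) {
  n <- ceiling(dur_s / dt)
  box <- numeric(n)
  tt <- (seq_len(n) - 1) * dt
  for (k in seq_along(onsets))
    box[in_window(tt, onsets[k], durations[k])] <- 1
  h <- hrf_double_gamma(seq(0, 32, by = dt))
  conv <- stats::convolve(box, rev(h), type = "open")[seq_len(n)] * dt
  idx <- round(seq(0, dur_s - tr_s, by = tr_s) / dt) + 1
  conv[pmin(idx, n)]
}

#' Simulate a BOLD-like 4D volume
#'
#' Voxel time series over the schedule's runs at repetition time `tr_s`
#' (default 2 s): white noise everywhere, plus the music-listening regressor
#' (boxcar of music trials convolved with the double-gamma HRF) scaled by
#' `amplitude` inside spheres of `cluster_radius_mm` around the planted
#' cluster centres.
#'
#' @param schedule a `trial_schedule`
#' @param grid voxel coordinates, matrix (n x 3) in mm
#' @param active_cluster_centres matrix (k x 3) of mm coordinates on `grid`
#' @param seed integer seed
#' @param tr_s repetition time (default 2)
#' @param amplitude regressor amplitude inside clusters (default 1)
#' @param noise_sd white noise sd (default 1)
#' @param cluster_radius_mm cluster radius around each centre (default 16)
#' @return a `bold_volume`: list with `ts` (voxels x volumes), `grid`,
#'   `tr_s`, `run` (run index per volume), `active_voxels` (planted indices)
#' @export
simulate_bold <- function(schedule, grid, active_cluster_centres, seed = 1,
                          tr_s = 2, amplitude = 1, noise_sd = 1,
                          cluster_radius_mm = 16) {
  centres <- rbind(active_cluster_centres)
  match_grid_points(grid, centres)   # errors when a centre is off-grid
  active <- rep(FALSE, nrow(grid))
  for (i in seq_len(nrow(centres)))
    active <- active | sqrt(rowSums(sweep(grid, 2, centres[i, ])^2)) <= cluster_radius_mm

  runs <- sort(unique(schedule$run))
  run_len <- attr(schedule, "run_length_s")
  reg <- list(); run_of <- integer(0)
  for (ri in seq_along(runs)) {
    r <- runs[ri]
    sr <- schedule[schedule$run == r, , drop = FALSE]
    dur <- if (!is.null(run_len)) run_len[ri] else
      max(sr$onset_s + sr$duration_s) + 0.5
    mt <- sr[sr$type %in% c("music_only", "music_reporting"), , drop = FALSE]
    reg[[ri]] <- hrf_regressor(mt$onset_s, mt$duration_s, dur, tr_s)
    run_of <- c(run_of, rep(r, length(reg[[ri]])))
  }
  regressor <- unlist(reg)
  nv <- length(regressor)

  with_seed(seed, {
    ts <- matrix(stats::rnorm(nrow(grid) * nv, sd = noise_sd), nrow(grid), nv)
    if (amplitude != 0 && any(active))
      ts[active, ] <- ts[active, ] + rep(amplitude * regressor, each = sum(active))
    structure(list(ts = ts, grid = grid, tr_s = tr_s, run = run_of,
                   active_voxels = which(active)),
              class = "bold_volume")
  })
}

#' @export
print.bold_volume <- function(x, ...) {
  cat("BOLD volume:", nrow(x$ts), "voxels x", ncol(x$ts), "volumes, TR",
      x$tr_s, "s,", length(unique(x$run)), "run(s)\n")
  invisible(x)
}

#' Write / read a BOLD volume as NIfTI-1
#'
#' The sphere-restricted voxel list is embedded in the smallest enclosing
#' cuboid (zeros outside); the affine maps voxel indices to mm (RAS).
#' Reading back returns every cuboid voxel.
#'
#' @param bold a `bold_volume` with a regular grid
#' @param path `.nii` / `.nii.gz` path
#' @param tr_s repetition time stored on read (NIfTI pixdim is used if set)
#' @return `read_bold_nifti` returns a `bold_volume` (without run labels;
#'   supply them from the schedule when fitting the GLM)
#' @export
write_bold_nifti <- function(bold, path) {
  g <- bold$grid
  sp <- apply(g, 2, function(v) {
    u <- sort(unique(v)); if (length(u) > 1) min(diff(u)) else 1
  })
  i0 <- round(sweep(g, 2, apply(g, 2, min)) %*% diag(1 / sp)) + 1
  dims <- apply(i0, 2, max)
  arr <- array(0, c(dims, ncol(bold$ts)))
  for (v in seq_len(nrow(g)))
    arr[i0[v, 1], i0[v, 2], i0[v, 3], ] <- bold$ts[v, ]
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(sp, 1)
  aff <- diag(c(sp, 1))
  aff[1:3, 4] <- apply(g, 2, min)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_bold_nifti <- function(path, tr_s = 2) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4) stop("expected a 4D NIfTI volume")
  aff <- RNifti::xform(img)
  dims <- dim(arr)[1:3]
  idx <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                               k = seq_len(dims[3])))
  mm <- cbind(idx - 1, 1) %*% t(aff)
  ts <- matrix(aperm(arr, c(4, 1, 2, 3)), nrow = dim(arr)[4])
  structure(list(ts = t(ts), grid = mm[, 1:3, drop = FALSE], tr_s = tr_s,
                 run = NULL, active_voxels = NULL),
            class = "bold_volume")
}
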