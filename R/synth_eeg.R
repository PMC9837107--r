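## Forward-modelled synthetic EEG.
##
## Cortical sources at the "active" dipoles track the amplitude envelope of
## the concurrently playing piece (low-passed, lagged) scaled by a coupling
## gain, plus 1/f noise; a set of background grid sources carry 1/f noise
## only; sensor data are leadfield projections plus white sensor noise.

#' Simulation configuration
#'
#' @param seed integer seed fixing every random draw
#' @param n_channels channel count (default 31)
#' @param fs_eeg EEG sampling rate in Hz (default 1000)
#' @param coupling_gain source moment per unit of stimulus envelope
#'   (dimensionless; default 1 gives a strongly coupled recording)
#' @param source_noise_sd sd of 1/f noise added to every simulated source,
#'   in source-moment units (default 0.02, about one sixth of the default
#'   envelope drive's sd)
#' @param sensor_noise_sd sd of white sensor noise, in sensor units
#'   (default 1e-5, the median projected signal sd of the default head
#'   model; gives a strongly coupled recording)
#' @param envelope_lowpass_hz envelope low-pass cutoff (default 8 Hz)
#' @param envelope_lag_s neural lag of the envelope response (default 0.1 s)
#' @param n_background number of background noise sources (default 20)
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1, n_channels = 31, fs_eeg = 1000,
                       coupling_gain = 1, source_noise_sd = 0.02,
                       sensor_noise_sd = 1e-5, envelope_lowpass_hz = 8,
                       envelope_lag_s = 0.1, n_background = 20) {
  if (source_noise_sd < 0 || sensor_noise_sd < 0) stop("noise sds must be >= 0")
  if (fs_eeg <= 0) stop("fs_eeg must be positive")
  structure(list(seed = seed, n_channels = n_channels, fs_eeg = fs_eeg,
                 coupling_gain = coupling_gain,
                 source_noise_sd = source_noise_sd,
                 sensor_noise_sd = sensor_noise_sd,
                 envelope_lowpass_hz = envelope_lowpass_hz,
                 envelope_lag_s = envelope_lag_s,
                 n_background = n_background),
            class = "sim_config")
}

## match dipole coordinates (n x 3 mm) to grid rows; error when off-grid
match_grid_points <- function(grid, coords, tol_mm = 1e-6) {
  coords <- rbind(coords)
  idx <- integer(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    d2 <- rowSums(sweep(grid, 2, coords[i, ])^2)
    j <- which.min(d2)
    if (sqrt(d2[j]) > tol_mm)
      stop("dipole (", paste(round(coords[i, ], 1), collapse = ", "),
           ") is not on the source grid")
    idx[i] <- j
  }
  idx
}

## gain column for a dipole (grid row) with a given unit orientation
gain_for <- function(leadfield, grid_idx, orientation) {
  cols <- (grid_idx - 1) * 3 + 1:3
  as.numeric(leadfield$gain[, cols] %*% orientation)
}

#' Simulate a multichannel EEG recording set
#'
#' One recording per run. During music trials the active dipoles carry the
#' lagged, low-passed amplitude envelope of the scheduled piece times
#' `coupling_gain` plus 1/f noise; during reporting-only trials (and gaps)
#' they carry noise only. Active dipoles use radial orientations.
#'
#' @param stimuli a `stimulus_set`
#' @param schedule a `trial_schedule` referencing `stimuli`
#' @param leadfield a `leadfield` whose grid contains the active dipoles
#' @param active_dipoles matrix (n x 3) of mm coordinates on the grid
#' @param config a [sim_config()]
#' @return named list of `eeg_recording` objects (one per run), each a list
#'   with `data` (channels x samples), `fs`, `channels`, `run`
#' @export
simulate_eeg <- function(stimuli, schedule, leadfield, active_dipoles,
                         config = sim_config()) {
  if (nrow(leadfield$gain) != config$n_channels)
    stop("leadfield has ", nrow(leadfield$gain), " channels but config asks for ",
         config$n_channels)
  act_idx <- match_grid_points(leadfield$grid, active_dipoles)
  fs <- config$fs_eeg
  lag_n <- round(config$envelope_lag_s * fs)

  # envelopes per piece, computed once at the stimulus rate then resampled
  env <- lapply(stimuli$pieces, function(p) {
    e <- amplitude_envelope(p$waveform, p$fs, config$envelope_lowpass_hz)
    if (p$fs != fs) e <- resample_series(e, p$fs, fs)
    e
  })

  runs <- sort(unique(schedule$run))
  run_len <- attr(schedule, "run_length_s")
  out <- vector("list", length(runs))
  names(out) <- paste0("run", runs)

  with_seed(config$seed, {
    # fixed random orientations for background sources, radial for active
    bg_pool <- setdiff(seq_len(nrow(leadfield$grid)), act_idx)
    n_bg <- min(config$n_background, length(bg_pool))
    bg_idx <- if (n_bg > 0) sample(bg_pool, n_bg) else integer(0)
    bg_orient <- matrix(stats::rnorm(3 * n_bg), ncol = 3)
    bg_orient <- bg_orient / sqrt(rowSums(bg_orient^2))
    act_orient <- leadfield$grid[act_idx, , drop = FALSE]
    act_orient <- act_orient / sqrt(rowSums(act_orient^2))

    for (ri in seq_along(runs)) {
      r <- runs[ri]
      dur <- if (!is.null(run_len)) run_len[ri] else
        max(schedule$onset_s[schedule$run == r] +
              schedule$duration_s[schedule$run == r]) + 0.5
      N <- round(dur * fs)
      drive <- numeric(N)                     # shared envelope drive
      mt <- music_trials(schedule)
      mt <- mt[mt$run == r, , drop = FALSE]
      for (k in seq_len(nrow(mt))) {
        e <- env[[mt$piece_id[k]]]
        i0 <- round(mt$onset_s[k] * fs) + 1 + lag_n
        i1 <- min(N, i0 + length(e) - 1)
        if (i0 <= N)
          drive[i0:i1] <- drive[i0:i1] + e[seq_len(i1 - i0 + 1)]
      }
      X <- matrix(0, config$n_channels, N)
      for (d in seq_along(act_idx)) {
        s <- config$coupling_gain * drive
        if (config$source_noise_sd > 0) s <- s + pink_noise(N, config$source_noise_sd)
        X <- X + outer(gain_for(leadfield, act_idx[d], act_orient[d, ]), s)
      }
      for (d in seq_along(bg_idx)) {
        if (config$source_noise_sd > 0) {
          s <- pink_noise(N, config$source_noise_sd)
          X <- X + outer(gain_for(leadfield, bg_idx[d], bg_orient[d, ]), s)
        }
      }
      if (config$sensor_noise_sd > 0)
        X <- X + matrix(stats::rnorm(length(X), sd = config$sensor_noise_sd),
                        nrow = nrow(X))
      rownames(X) <- leadfield$channels
      out[[ri]] <- structure(list(data = X, fs = fs,
                                  channels = leadfield$channels, run = r),
                             class = "eeg_recording")
    }
  })
  out
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("EEG recording: ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (run ", x$run, ")\n", sep = "")
  invisible(x)
}
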