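test_that("music generator meets the study-design contract", {
  stim <- generate_music(36, 40, 1000, c(60, 180), seed = 1)
  expect_length(stim$pieces, 36)
  expect_true(all(vapply(stim$pieces, function(p) length(p$waveform), 0L) == 40000))
  expect_true(all(vapply(stim$pieces, function(p) p$fs, 0) == 1000))
  targets <- vapply(stim$pieces, function(p) paste(p$affect_target, collapse = "/"), "")
  expect_length(unique(targets), 9)
  expect_true(all(table(targets) == 4))
  # waveforms finite and non-constant
  expect_true(all(vapply(stim$pieces, function(p) all(is.finite(p$waveform)), TRUE)))
  expect_true(all(vapply(stim$pieces, function(p) stats::sd(p$waveform) > 0, TRUE)))
})

test_that("music generation is a pure function of config and seed", {
  a <- generate_music(3, 10, 1000, c(90, 90), seed = 7)
  b <- generate_music(3, 10, 1000, c(90, 90), seed = 7)
  expect_identical(a, b)
  c2 <- generate_music(3, 10, 1000, c(90, 90), seed = 8)
  expect_false(identical(a, c2))
})

test_that("fixed 60 bpm with no jitter gives exactly 1 s inter-onset intervals", {
  stim <- generate_music(1, 2.5, 100, c(60, 60), seed = 0, onset_jitter = 0)
  ioi <- diff(stim$pieces[[1]]$onsets_s)
  expect_true(all(ioi == 1))
  expect_equal(stim$pieces[[1]]$tempo_realised_bpm, 60)
})

test_that("invalid music configurations error", {
  expect_error(generate_music(0, 40), "n_pieces")
  expect_error(generate_music(1, -2), "duration")
  expect_error(generate_music(1, 10, 1000, c(10, 400)), "tempo")
  expect_error(generate_music(1, 10, 1000, c(180, 60)), "tempo")
})

test_that("schedule has 36 trials, unique pieces and the fixation-task-break structure", {
  stim <- generate_music(36, 40, 1000, seed = 1)
  sched <- generate_schedule(3, 12, stim, seed = 2)
  expect_equal(nrow(sched), 36)
  expect_equal(sort(unique(sched$run)), 1:3)
  mt <- music_trials(sched)
  expect_true(all(!is.na(mt$piece_id)))
  expect_false(any(duplicated(mt$piece_id)))          # at most once each
  expect_true(all(is.na(sched$piece_id[sched$type == "reporting_only"])))
  for (r in 1:3) {
    on <- sched$onset_s[sched$run == r]
    expect_true(all(diff(on) > 0))                     # strictly increasing
    expect_true(all(diff(on) >= 40 + 0.5 + 1))         # fixation >= 1 s
    expect_true(all(diff(on) <= 40 + 0.5 + 3 + 1e-9))  # fixation <= 3 s
  }
  expect_true(all(sched$fixation_s >= 1 & sched$fixation_s <= 3))
})

test_that("schedule conserves run length as the sum of its intervals", {
  stim <- generate_music(36, 40, 1000, seed = 1)
  sched <- generate_schedule(3, 12, stim, seed = 5)
  run_len <- attr(sched, "run_length_s")
  for (r in 1:3) {
    sr <- sched[sched$run == r, ]
    expect_equal(run_len[r], sum(sr$fixation_s + sr$duration_s + 0.5))
  }
})

test_that("schedule rejects insufficient pieces unless replacement is allowed", {
  stim <- generate_music(4, 5, 200, seed = 1)
  expect_error(generate_schedule(3, 12, stim, seed = 1), "not enough pieces")
  sched <- generate_schedule(3, 12, stim, seed = 1, replace = TRUE, task_s = 5)
  expect_equal(nrow(sched), 36)
})

test_that("single-trial schedule starts after its fixation interval", {
  stim <- generate_music(1, 5, 200, seed = 3)
  sched <- generate_schedule(1, 1, stim, seed = 0,
                             type_mix = c(music_only = 1L), task_s = 5)
  expect_equal(nrow(sched), 1)
  expect_equal(sched$onset_s, sched$fixation_s)
  expect_true(sched$onset_s >= 1 && sched$onset_s <= 3)
})

test_that("zero coupling leaves channels uncorrelated with the envelope", {
  ex <- tiny_experiment()
  lf <- small_leadfield()
  act <- lf$grid[c(10, 30), ]
  cfg <- sim_config(seed = 4, n_channels = 31, fs_eeg = ex$stim$fs,
                    coupling_gain = 0, n_background = 5)
  eeg <- simulate_eeg(ex$stim, ex$sched, lf, act, cfg)
  mt <- music_trials(ex$sched)
  env <- amplitude_envelope(ex$stim$pieces[[mt$piece_id[1]]]$waveform, ex$stim$fs)
  i0 <- round(mt$onset_s[1] * ex$stim$fs) + 1
  seg <- eeg$run1$data[, i0:(i0 + length(env) - 1)]
  rs <- apply(seg, 1, stats::cor, y = env)
  expect_true(all(abs(rs) < 3 / sqrt(length(env))))
})

test_that("noise-free single-dipole recording is a rank-1 forward model", {
  ex <- tiny_experiment()
  lf <- small_leadfield()
  act <- lf$grid[15, , drop = FALSE]
  cfg <- sim_config(seed = 4, fs_eeg = ex$stim$fs, source_noise_sd = 0,
                    sensor_noise_sd = 0, n_background = 0)
  eeg <- simulate_eeg(ex$stim, ex$sched, lf, act, cfg)
  X <- eeg$run1$data
  s <- svd(X, nu = 0, nv = 0)$d
  expect_gt(s[1], 0)
  expect_lt(s[2] / s[1], 1e-8)
})

test_that("the noiseless forward model is linear in the stimulus", {
  ex <- tiny_experiment()
  lf <- small_leadfield()
  act <- lf$grid[c(12, 40), ]
  cfg <- sim_config(seed = 9, fs_eeg = ex$stim$fs, source_noise_sd = 0,
                    sensor_noise_sd = 0, n_background = 0)
  eeg1 <- simulate_eeg(ex$stim, ex$sched, lf, act, cfg)
  stim2 <- ex$stim
  for (i in seq_along(stim2$pieces))
    stim2$pieces[[i]]$waveform <- 2.5 * stim2$pieces[[i]]$waveform
  eeg2 <- simulate_eeg(stim2, ex$sched, lf, act, cfg)
  expect_equal(eeg2$run1$data, 2.5 * eeg1$run1$data, tolerance = 1e-10)
})

test_that("active dipoles carry no stimulus drive outside music trials", {
  ex <- tiny_experiment()
  lf <- small_leadfield()
  act <- lf$grid[15, , drop = FALSE]
  cfg <- sim_config(seed = 4, fs_eeg = ex$stim$fs, source_noise_sd = 0,
                    sensor_noise_sd = 0, n_background = 0)
  eeg <- simulate_eeg(ex$stim, ex$sched, lf, act, cfg)
  ro <- ex$sched[ex$sched$type == "reporting_only", ][1, ]
  i0 <- round(ro$onset_s * ex$stim$fs) + 1
  i1 <- i0 + round(ro$duration_s * ex$stim$fs) - 1
  expect_equal(max(abs(eeg$run1$data[, i0:i1])), 0)
})

test_that("envelope coupling at defaults beats a circular-shift null", {
  ex <- tiny_experiment(duration_s = 10)
  lf <- small_leadfield()
  act <- lf$grid[c(15, 40), ]
  cfg <- sim_config(seed = 3, fs_eeg = ex$stim$fs)
  eeg <- simulate_eeg(ex$stim, ex$sched, lf, act, cfg)
  mt <- music_trials(ex$sched)
  fs <- ex$stim$fs
  env <- amplitude_envelope(ex$stim$pieces[[mt$piece_id[1]]]$waveform, fs)
  lag <- round(cfg$envelope_lag_s * fs)
  i0 <- round(mt$onset_s[1] * fs) + 1 + lag
  seg <- eeg$run1$data[, i0:(i0 + length(env) - 1)]
  rs <- apply(seg, 1, stats::cor, y = env)
  best <- which.max(abs(rs))
  obs <- abs(rs[best])
  null <- vapply(seq_len(200), function(k) {
    shift <- round(k * length(env) / 201)
    abs(stats::cor(seg[best, ], c(env[-seq_len(shift)], env[seq_len(shift)])))
  }, 0)
  expect_gt(obs, stats::quantile(null, 0.95))
})

test_that("simulated EEG is deterministic and off-grid dipoles error", {
  ex <- tiny_experiment()
  lf <- small_leadfield()
  act <- lf$grid[20, , drop = FALSE]
  cfg <- sim_config(seed = 12, fs_eeg = ex$stim$fs)
  e1 <- simulate_eeg(ex$stim, ex$sched, lf, act, cfg)
  e2 <- simulate_eeg(ex$stim, ex$sched, lf, act, cfg)
  expect_identical(e1$run1$data, e2$run1$data)
  expect_error(simulate_eeg(ex$stim, ex$sched, lf, rbind(c(7, 7, 7)), cfg),
               "not on the source grid")
})

test_that("planted BOLD clusters surface in the GLM T-map", {
  ex <- tiny_experiment(n_pieces = 8, duration_s = 8, n_runs = 2,
                        trials_per_run = 3)
  grid <- small_leadfield()$grid
  centres <- grid[c(20, 60), ]
  bold <- simulate_bold(ex$sched, grid, centres, seed = 2, tr_s = 2,
                        amplitude = 3, noise_sd = 1)
  tm <- glm_tmap(bold, ex$sched)
  planted <- bold$active_voxels
  thr <- stats::quantile(tm$t, 0.9)
  expect_true(all(tm$t[musedecode:::match_grid_points(grid, centres)] >= thr))
})

test_that("high-amplitude noiseless BOLD puts the argmax T on a planted centre", {
  ex <- tiny_experiment(n_pieces = 8, duration_s = 8, n_runs = 2,
                        trials_per_run = 3)
  grid <- small_leadfield()$grid
  centres <- grid[33, , drop = FALSE]
  bold <- simulate_bold(ex$sched, grid, centres, seed = 2, amplitude = 5,
                        noise_sd = 1e-9, cluster_radius_mm = 1)
  tm <- glm_tmap(bold, ex$sched)
  expect_equal(which.max(tm$t), 33L)
})

test_that("zero-amplitude BOLD leaves planted and unplanted voxels exchangeable", {
  ex <- tiny_experiment(n_pieces = 8, duration_s = 8, n_runs = 2,
                        trials_per_run = 3)
  grid <- small_leadfield()$grid
  centres <- grid[c(20, 60), ]
  bold <- simulate_bold(ex$sched, grid, centres, seed = 7, amplitude = 0)
  tm <- glm_tmap(bold, ex$sched)
  planted <- bold$active_voxels
  ks <- suppressWarnings(stats::ks.test(tm$t[planted], tm$t[-planted]))
  expect_gt(ks$p.value, 0.01)
})
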