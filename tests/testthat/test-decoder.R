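test_that("downsampling is anti-aliased and length-exact", {
  expect_equal(downsample(rep(2.5, 1000), 10), rep(2.5, 100), tolerance = 1e-9)
  expect_length(downsample(stats::rnorm(1000), 10), 100)
  expect_length(downsample(stats::rnorm(1005), 10), 101)
  # a 45 Hz tone at 1000 Hz must not alias into the 100 Hz output
  t <- (0:9999) / 1000
  tone <- sin(2 * pi * 45 * t)
  out <- downsample(tone, 10)
  expect_lt(mean(out^2) / mean(tone^2), 0.01)
  # and a 2 Hz tone passes essentially untouched
  slow <- sin(2 * pi * 2 * t)
  expect_gt(stats::cor(downsample(slow, 10), slow[seq(1, 10000, 10)]), 0.999)
  expect_error(downsample(1:5, 10), "too short")
  expect_error(downsample(1:100, 2.5), "integer")
  expect_identical(downsample(1:7, 1), 1:7)
})

test_that("a constant target is learned to near-zero error", {
  set.seed(1)
  xs <- lapply(1:4, function(i) matrix(stats::rnorm(5 * 200), 5))
  ys <- lapply(xs, function(x) rep(0, ncol(x)))
  fit <- bilstm(xs, ys, decoder_spec(5, epochs = 50, seed = 3))
  expect_lt(utils::tail(fit$loss_curve, 1), 1e-3)
})

test_that("a linear readout of one feature row is decodable on held-out data", {
  set.seed(7)
  xs <- lapply(1:6, function(i) matrix(stats::rnorm(8 * 400), 8))
  ys <- lapply(xs, function(x) x[3, ])
  fit <- bilstm(xs, ys, decoder_spec(8, epochs = 80, seed = 2))
  xte <- matrix(stats::rnorm(8 * 400), 8)
  expect_gt(stats::cor(predict(fit, xte), xte[3, ]), 0.95)
})

test_that("training is bit-reproducible under a fixed seed", {
  set.seed(4)
  xs <- lapply(1:3, function(i) matrix(stats::rnorm(6 * 150), 6))
  ys <- lapply(xs, function(x) x[1, ] - 0.5 * x[4, ])
  f1 <- bilstm(xs, ys, decoder_spec(6, epochs = 10, seed = 11))
  f2 <- bilstm(xs, ys, decoder_spec(6, epochs = 10, seed = 11))
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$loss_curve, f2$loss_curve)
  xte <- matrix(stats::rnorm(6 * 80), 6)
  expect_identical(predict(f1, xte), predict(f2, xte))
})

test_that("prediction shape and determinism hold over random lengths", {
  set.seed(5)
  fit <- bilstm(matrix(stats::rnorm(4 * 120), 4), stats::rnorm(120),
                decoder_spec(4, epochs = 2, seed = 1))
  for (T_len in sample(20:300, 4)) {
    x <- matrix(stats::rnorm(4 * T_len), 4)
    y1 <- predict(fit, x)
    expect_length(y1, T_len)
    expect_identical(y1, predict(fit, x))
  }
  expect_error(predict(fit, matrix(0, 5, 10)), "expects")
})

test_that("a zero read-out head gives identically zero output", {
  set.seed(6)
  fit <- bilstm(matrix(stats::rnorm(3 * 60), 3), stats::rnorm(60),
                decoder_spec(3, epochs = 1, seed = 2))
  fit$weights$w_out <- rep(0, length(fit$weights$w_out))
  fit$weights$b_out <- 0
  expect_equal(reconstruct(fit, matrix(stats::rnorm(3 * 50), 3)), rep(0, 50))
})

test_that("the fold plan uses each run exactly once as test", {
  plan <- fold_plan(c(1, 2, 3))
  expect_length(plan$folds, 3)
  tests <- vapply(plan$folds, `[[`, 0, "test")
  expect_equal(sort(tests), 1:3)
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), 1:3)
  }
  expect_error(fold_plan(1), "two runs")
})

## shared toy trials: target is a lagged linear functional of the features
toy_trials <- function(n_runs = 3, trials_per_run = 3, T_len = 150, D = 6,
                       seed = 9) {
  set.seed(seed)
  out <- list()
  id <- 1
  for (r in seq_len(n_runs)) for (k in seq_len(trials_per_run)) {
    x <- matrix(stats::rnorm(D * T_len), D)
    out[[id]] <- list(features = x, target = x[2, ] + 0.5 * x[5, ],
                      trial_id = id, run = r, piece_id = id)
    id <- id + 1
  }
  out
}

test_that("cross-fold training reconstructs held-out runs without leakage", {
  trials <- toy_trials()
  spec <- decoder_spec(6, epochs = 30, seed = 3)
  plan <- fold_plan(1:3)
  res <- train_decoder(trials, spec, plan, fs = 100)
  expect_length(res$models, 3)
  expect_length(res$reconstructions, 9)
  for (rec in res$reconstructions) {
    fold <- res$plan$folds[[rec$fold]]
    expect_false(rec$run %in% fold$train)   # hygiene: model never saw its run
    expect_equal(fold$test, rec$run)
    expect_length(rec$yhat, 150)
  }
  # decodes the toy functional on held-out data
  rs <- vapply(res$reconstructions, function(rec) {
    tr <- trials[[rec$trial_id]]
    stats::cor(rec$yhat, tr$target)
  }, 0)
  expect_gt(mean(rs), 0.8)
  # reproducibility of the whole scheme
  res2 <- train_decoder(trials, spec, plan, fs = 100)
  expect_identical(res$reconstructions[[1]]$yhat, res2$reconstructions[[1]]$yhat)
})

test_that("the decoder beats a shuffled-target control on coupled toy data", {
  trials <- toy_trials(seed = 31)
  plan <- fold_plan(1:3)
  spec <- decoder_spec(6, epochs = 30, seed = 5)
  real <- train_decoder(trials, spec, plan, fs = 100)
  r_real <- mean(vapply(real$reconstructions, function(rec)
    stats::cor(rec$yhat, trials[[rec$trial_id]]$target), 0))
  shuffled <- trials
  set.seed(99)
  perm <- sample(length(trials))
  while (any(perm == seq_along(perm))) perm <- sample(length(trials))
  for (i in seq_along(trials)) shuffled[[i]]$target <- trials[[perm[i]]]$target
  ctrl <- train_decoder(shuffled, spec, plan, fs = 100)
  r_ctrl <- mean(vapply(ctrl$reconstructions, function(rec)
    stats::cor(rec$yhat, trials[[rec$trial_id]]$target), 0))
  expect_gt(r_real, 0.5)
  expect_lt(abs(r_ctrl), 0.3)
  expect_gt(r_real, r_ctrl + 0.3)
})

test_that("sequence chunking covers the series without tiny tails", {
  idx <- musedecode:::chunk_sequence(2200, 1000)
  expect_equal(unlist(idx), 1:2200)
  expect_equal(lengths(idx), c(1000, 1200))   # short tail folded into previous
  idx2 <- musedecode:::chunk_sequence(3000, 1000)
  expect_equal(lengths(idx2), rep(1000, 3))
  idx3 <- musedecode:::chunk_sequence(2500, 1000)
  expect_equal(lengths(idx3), c(1000, 1000, 500))  # tail >= chunk/4 kept
  expect_equal(musedecode:::chunk_sequence(80, 1000), list(1:80))
})

test_that("decoder specs validate their inputs", {
  expect_error(decoder_spec(0), "input_dim")
  expect_error(decoder_spec(5, n_bilstm_layers = 0), "layer")
  ps <- full_decoder_spec(124)
  expect_equal(ps$n_bilstm_layers, 4)
  expect_equal(ps$hidden_units, 250)
  expect_equal(ps$input_dim, 124L)
})
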