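test_that("SSIM satisfies identity, symmetry and boundedness", {
  set.seed(1)
  a <- matrix(stats::runif(40 * 30), 40)
  b <- matrix(stats::runif(40 * 30), 40)
  expect_equal(ssim(a, a), 1)
  expect_equal(ssim(a, b), ssim(b, a))
  expect_true(abs(ssim(a, b)) <= 1)
  expect_lt(ssim(a, b), 1)
  expect_error(ssim(a, matrix(0, 5, 5)), "shape")
  expect_error(ssim(matrix(0, 4, 4), matrix(0, 4, 4)), "window")
})

test_that("SSIM matches a naive windowed oracle, including luminance shifts", {
  set.seed(2)
  a <- matrix(stats::runif(20 * 18), 20)
  b <- a + 0.6                                  # large constant shift
  L <- max(a, b) - min(a, b)
  expect_equal(ssim(a, b, dynamic_range = L), ssim_oracle(a, b, L),
               tolerance = 1e-10)
  expect_lt(ssim(a, b, dynamic_range = L), 1)   # luminance term bites
  c2 <- matrix(stats::runif(20 * 18), 20)
  L2 <- max(a, c2) - min(a, c2)
  expect_equal(ssim(a, c2, dynamic_range = L2), ssim_oracle(a, c2, L2),
               tolerance = 1e-10)
})

test_that("similarity suite is exact on identity and sign-flip cases", {
  set.seed(3)
  trials <- lapply(1:4, function(i)
    sin(2 * pi * (i + 1) * (0:1599) / 100) + 0.3 * stats::rnorm(1600))
  rep_id <- similarity_suite(trials, trials, fs = 100, n_boot = 200)
  expect_equal(unname(rep_id$means["r_time"]), 1)
  expect_equal(unname(rep_id$means["r_freq"]), 1)
  expect_equal(unname(rep_id$means["ssim"]), 1)
  rep_neg <- similarity_suite(trials, lapply(trials, `-`), fs = 100, n_boot = 200)
  expect_equal(unname(rep_neg$per_trial$r_time), rep(-1, 4))
  expect_equal(unname(rep_neg$per_trial$r_freq), rep(1, 4))   # power unchanged
})

test_that("time-domain correlation matches the closed-form Pearson on a 4-sample fixture", {
  o <- list(c(1, 2, 3, 4) * 1.0, c(2, 0, 1, 5) * 1.0)
  r <- list(c(1, 3, 2, 4) * 1.0, c(1, 1, 0, 4) * 1.0)
  # hand calculation: r = sum((x-xbar)(y-ybar)) / sqrt(ssx * ssy)
  hand <- function(x, y) {
    xc <- x - mean(x); yc <- y - mean(y)
    sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  }
  cross <- suppressMessages(musedecode:::.similarity_cross(o, r, fs = 4))$r_time
  expect_equal(cross[1, 1], hand(o[[1]], r[[1]]))
  expect_equal(cross[2, 2], hand(o[[2]], r[[2]]))
  expect_equal(cross[1, 2], hand(o[[1]], r[[2]]))
})

test_that("constant trials are flagged missing and excluded from means", {
  trials <- list(stats::rnorm(1600), rep(1, 1600), stats::rnorm(1600))
  expect_message(rep_ <- similarity_suite(trials, trials, fs = 100, n_boot = 150),
                 "constant")
  expect_true(is.na(rep_$per_trial$r_time[2]))
  expect_equal(unname(rep_$means[["r_time"]]), 1)
})

test_that("bootstrap null p-values behave at the extremes and defaults", {
  n <- 12
  cross <- matrix(0, n, n); diag(cross) <- 1    # perfectly matched pairs
  p <- bootstrap_null(cross, n_boot = 4000, seed = 1)
  expect_equal(as.numeric(p), 1 / 4001)
  expect_warning(bootstrap_null(cross, n_boot = 50, seed = 1), "coarse")
  expect_error(bootstrap_null(matrix(0, 1, 1)), "2 trials")
  expect_equal(eval(formals(bootstrap_null)$n_boot), 4000)
  expect_equal(eval(formals(similarity_suite)$n_boot), 4000)
})

test_that("rank accuracies from a small 3x3 matrix match hand enumeration", {
  C <- rbind(c(0.9, 0.2, 0.5),
             c(0.1, 0.4, 0.6),
             c(0.3, 0.3, 0.3))
  # trial 1: 0.9 beats 0.2 and 0.5          -> 2/2 = 1
  # trial 2: 0.4 beats 0.1, loses to 0.6    -> 1/2
  # trial 3: 0.3 ties 0.3 twice             -> (0 + 0.5*2)/2 = 0.5
  acc <- rank_accuracy_from_C(C)
  expect_equal(acc, c(1, 0.5, 0.5))
  # exchangeable-tie matrix: exactly the chance level
  expect_equal(rank_accuracy_from_C(matrix(1, 5, 5)), rep(0.5, 5))
})

test_that("the comparison set can exclude trials sharing the piece", {
  C <- matrix(stats::rnorm(16), 4)
  pieces <- c(1, 1, 2, 3)
  acc_dp <- rank_accuracy_from_C(C, pieces, comparison = "different_piece")
  # trial 1 compares only against trials 3 and 4 (trial 2 shares piece 1)
  hand1 <- (sum(C[1, 1] > C[1, 3:4]) + 0.5 * sum(C[1, 1] == C[1, 3:4])) / 2
  expect_equal(acc_dp[1], hand1)
  acc_all <- rank_accuracy_from_C(C, pieces, comparison = "all_other")
  hand1b <- (sum(C[1, 1] > C[1, 2:4]) + 0.5 * sum(C[1, 1] == C[1, 2:4])) / 3
  expect_equal(acc_all[1], hand1b)
  expect_error(rank_accuracy_from_C(matrix(0, 3, 3), c(1, 1, 1)), "empty")
})

test_that("identical reconstructions identify every distinct piece perfectly", {
  set.seed(4)
  trials <- lapply(1:5, function(i) {
    on <- seq(0.2, 15.8, by = 0.35 + 0.05 * i)
    w <- numeric(1600)
    for (o in on) {
      idx <- round(o * 100):min(1600, round(o * 100) + 60)
      w[idx] <- w[idx] + exp(-(seq_along(idx) - 1) / 20) * sin(2 * pi * 3 * seq_along(idx) / 100)
    }
    w + 0.01 * stats::rnorm(1600)
  })
  rr <- rank_accuracy(trials, trials, piece_ids = 1:5, fs = 100)
  expect_equal(rr$rank_acc, rep(1, 5))
  expect_equal(rr$mean_rank_acc, 1)
})

test_that("rank accuracy rejects degenerate inputs", {
  trials <- lapply(1:3, function(i) stats::rnorm(1600))
  expect_error(rank_accuracy(trials, trials, piece_ids = c(1, 1, 1), fs = 100),
               "empty comparison")
  expect_error(rank_accuracy(trials, trials[1:2], piece_ids = 1:3), "length")
})

test_that("permutation significance is exact for a perfect decoder and monotone", {
  set.seed(5)
  n <- 10
  Cstrong <- matrix(stats::rnorm(n * n, sd = 0.1), n); diag(Cstrong) <- 10
  rr_strong <- list(C = Cstrong, rank_acc = rank_accuracy_from_C(Cstrong),
                    mean_rank_acc = mean(rank_accuracy_from_C(Cstrong)),
                    piece_ids = 1:n, comparison = "different_piece")
  p_strong <- rank_significance(rr_strong, n_perm = 999, seed = 2)
  expect_equal(as.numeric(p_strong), 1 / 1000)
  Cweak <- Cstrong; diag(Cweak) <- stats::rnorm(n, sd = 0.1)
  rr_weak <- list(C = Cweak, rank_acc = rank_accuracy_from_C(Cweak),
                  mean_rank_acc = mean(rank_accuracy_from_C(Cweak)),
                  piece_ids = 1:n, comparison = "different_piece")
  p_weak <- rank_significance(rr_weak, n_perm = 999, seed = 2)
  expect_gt(as.numeric(p_weak), as.numeric(p_strong))
})

test_that("metronome tempi are recovered within a beat per minute", {
  fs <- 500
  mk <- function(bpm, dur = 20, jitter = 0) {
    beat <- 60 / bpm
    on <- seq(0, dur - 0.5, by = beat)
    if (jitter > 0) { set.seed(8); on <- sort(on + stats::rnorm(length(on), 0, jitter)) }
    t <- (0:(dur * fs - 1)) / fs
    w <- numeric(length(t))
    for (o in on) {
      idx <- which(t >= o & t < o + 0.3)
      w[idx] <- w[idx] + exp(-(t[idx] - o) / 0.08) * sin(2 * pi * 8 * (t[idx] - o))
    }
    list(w = w, on = on)
  }
  expect_equal(estimate_tempo(mk(120)$w, fs)$mean_bpm, 120, tolerance = 1 / 120)
  expect_equal(estimate_tempo(mk(60)$w, fs)$mean_bpm, 60, tolerance = 1 / 60)
  jit <- mk(100, jitter = 0.02)
  est <- estimate_tempo(jit$w, fs)
  oracle <- 60 / stats::median(diff(jit$on))
  expect_equal(est$mean_bpm, oracle, tolerance = 0.02)
  expect_true(est$range_bpm[1] <= est$range_bpm[2])
  expect_warning(out <- estimate_tempo(numeric(1000), fs),
                 "tempo undefined")
  expect_true(is.na(out$mean_bpm))
})

test_that("tempo-confound correlations match closed forms and handle nulls", {
  tempos <- c(60, 80, 100, 120, 140, 160)
  acc <- 0.3 + 0.002 * tempos
  rep1 <- tempo_confound(tempos, acc)
  expect_equal(rep1$r_tempo, 1)
  # 6-point hand-computable fixture
  acc2 <- c(0.4, 0.8, 0.5, 0.9, 0.3, 0.6)
  hand <- sum(scale(tempos) * scale(acc2)) / 5
  rep2 <- tempo_confound(tempos, acc2)
  expect_equal(rep2$r_tempo, hand, tolerance = 1e-12)
  expect_equal(rep2$typicality, stats::dnorm(tempos, mean(tempos), stats::sd(tempos)))
  # independent accuracies: no strong association expected
  set.seed(9)
  acc3 <- stats::runif(40, 0.3, 0.7)
  tempos3 <- stats::runif(40, 60, 180)
  rep3 <- tempo_confound(tempos3, acc3)
  expect_lt(abs(rep3$r_tempo), 0.5)
  expect_gt(rep3$p_tempo, 0.001)
  expect_message(rep4 <- tempo_confound(rep(100, 5), stats::runif(5)),
                 "zero-variance")
  expect_true(is.na(rep4$r_tempo))
})

test_that("spectrograms have the expected frequency support and frame count", {
  x <- sin(2 * pi * 10 * (0:3999) / 100)
  sg <- spectrogram(x, fs = 100)
  expect_true(all(attr(sg, "freq") <= 50))
  fpk <- attr(sg, "freq")[apply(sg, 2, which.max)]
  expect_true(all(abs(fpk - 10) <= 1))
  expect_error(spectrogram(x[1:50], fs = 100), "window")
})
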