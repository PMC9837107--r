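## Synthetic monophonic piano-like stimuli.
##
## Each piece is a train of note onsets at the piece tempo (optionally
## jittered), each note an exponentially decaying sinusoid. Fundamentals are
## kept low (a few Hz to a few tens of Hz) so the waveform retains its
## content after the decoder's 1000 -> 100 Hz downsampling.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.affect_levels <- c("low", "neutral", "high")

#' Generate a synthetic music stimulus set
#'
#' Produces monophonic piano-like pieces: a metronome of note onsets at a
#' per-piece tempo (with optional onset jitter), each note an
#' exponential-decay envelope carrying a low-frequency fundamental. Affect
#' targets (valence x arousal over low/neutral/high) are assigned cyclically
#' over the 9 combinations and are metadata only.
#'
#' @param n_pieces number of pieces (default 36)
#' @param duration_s piece duration in seconds (default 40)
#' @param fs sampling rate in Hz (default 1000)
#' @param tempo_range_bpm length-2 tempo range in beats/min, inside (20, 300)
#' @param seed integer seed; same seed gives bit-identical output
#' @param onset_jitter onset jitter as a fraction of the beat period
#'   (Gaussian, default 0.04; 0 gives an exact metronome)
#' @return a `stimulus_set`: list with `pieces` (each holding `piece_id`,
#'   `waveform`, `fs`, `duration_s`, `affect_target`, `tempo_bpm` (target),
#'   `tempo_realised_bpm`, `onsets_s`), plus shared `fs` and `duration_s`
#' @export
generate_music <- function(n_pieces = 36, duration_s = 40, fs = 1000,
                           tempo_range_bpm = c(60, 180), seed = 1,
                           onset_jitter = 0.04) {
  if (n_pieces < 1) stop("n_pieces must be >= 1")
  if (duration_s <= 0) stop("duration_s must be positive")
  if (length(tempo_range_bpm) != 2 || tempo_range_bpm[1] > tempo_range_bpm[2] ||
      tempo_range_bpm[1] <= 20 || tempo_range_bpm[2] >= 300)
    stop("tempo_range_bpm must be an increasing pair within (20, 300)")
  if (onset_jitter < 0) stop("onset_jitter must be >= 0")

  n_samp <- round(duration_s * fs)
  t_axis <- (seq_len(n_samp) - 1) / fs
  affect <- expand.grid(valence = .affect_levels, arousal = .affect_levels,
                        stringsAsFactors = FALSE)

  with_seed(seed, {
    pieces <- vector("list", n_pieces)
    for (p in seq_len(n_pieces)) {
      tempo <- stats::runif(1, tempo_range_bpm[1], tempo_range_bpm[2])
      beat <- 60 / tempo
      k <- seq(0, ceiling(duration_s / beat))
      onsets <- k * beat
      if (onset_jitter > 0)
        onsets <- onsets + c(0, stats::rnorm(length(k) - 1, 0, onset_jitter * beat))
      onsets <- sort(onsets[onsets >= 0 & onsets < duration_s - 0.05])
      f_base <- stats::runif(1, 2, 12)                  # per-piece register (Hz)
      w <- numeric(n_samp)
      for (on in onsets) {
        f_note <- min(max(f_base * 2^(stats::runif(1, -0.5, 0.8)), 1), 30)
        amp <- stats::runif(1, 0.5, 1)
        tau <- stats::runif(1, 0.25, 0.45)
        i0 <- floor(on * fs) + 1
        i1 <- min(n_samp, i0 + ceiling(6 * tau * fs))
        idx <- i0:i1
        tt <- t_axis[idx] - on
        w[idx] <- w[idx] + amp * exp(-tt / tau) * sin(2 * pi * f_note * tt)
      }
      realised <- if (length(onsets) >= 2) 60 / mean(diff(onsets)) else NA_real_
      ai <- ((p - 1) %% nrow(affect)) + 1
      pieces[[p]] <- list(piece_id = p,
                          waveform = w,
                          fs = fs,
                          duration_s = duration_s,
                          affect_target = c(valence = affect$valence[ai],
                                            arousal = affect$arousal[ai]),
                          tempo_bpm = tempo,
                          tempo_realised_bpm = realised,
                          onsets_s = onsets)
    }
    structure(list(pieces = pieces, fs = fs, duration_s = duration_s),
              class = "stimulus_set")
  })
}

#' @export
print.stimulus_set <- function(x, ...) {
  tg <- vapply(x$pieces, function(p) paste(p$affect_target, collapse = "/"), "")
  cat("Stimulus set:", length(x$pieces), "pieces,", x$duration_s, "s at",
      x$fs, "Hz;", length(unique(tg)), "affect targets\n")
  invisible(x)
}

#' Amplitude envelope of a waveform
#'
#' Rectify-and-smooth envelope: absolute value low-passed with a zero-phase
#' Butterworth filter. This is the quantity the simulated cortical sources
#' track.
#'
#' @param waveform numeric vector
#' @param fs sampling rate (Hz)
#' @param cutoff_hz low-pass cutoff (default 8 Hz)
#' @return numeric vector, same length
#' @export
amplitude_envelope <- function(waveform, fs, cutoff_hz = 8) {
  lowpass(abs(waveform), fs, cutoff_hz)
}
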