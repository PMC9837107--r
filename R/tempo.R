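## Tempo estimation and the tempo-confound analysis: is decoding
## performance explained by the stimulus tempo (or its typicality)?

#' Estimate tempo from a monophonic waveform
#'
#' Note onsets are detected as peaks of the positive envelope derivative
#' above an adaptive threshold with a refractory gap (0.2 s, i.e. 300 bpm
#' ceiling); tempo is 60 over the median inter-onset interval, and the
#' range follows from the 10-90 % interval quantiles.
#'
#' @param waveform numeric vector
#' @param fs sampling rate (Hz)
#' @param threshold_frac peak threshold as a fraction of the largest onset
#'   strength (default 0.25)
#' @return list with `mean_bpm`, `range_bpm` (slow, fast), `onsets_s`;
#'   fewer than 3 detected onsets give `NA` tempo with a warning
#' @export
estimate_tempo <- function(waveform, fs, threshold_frac = 0.25) {
  env <- amplitude_envelope(waveform, fs, cutoff_hz = min(10, 0.45 * fs))
  s <- pmax(c(0, diff(env)), 0)
  thr <- threshold_frac * max(s)
  gap <- round(0.2 * fs)
  peaks <- integer(0)
  cand <- which(s > thr)
  last <- -Inf
  for (i in cand) {
    if (i - last < gap) {
      # keep the stronger of the colliding peaks
      if (length(peaks) && s[i] > s[peaks[length(peaks)]]) {
        peaks[length(peaks)] <- i; last <- i
      }
      next
    }
    # local maximum within the refractory window
    lo <- max(1, i - gap %/% 2); hi <- min(length(s), i + gap %/% 2)
    if (s[i] == max(s[lo:hi])) { peaks <- c(peaks, i); last <- i }
  }
  onsets <- (peaks - 1) / fs
  if (length(onsets) < 3) {
    warning("fewer than 3 onsets detected; tempo undefined")
    return(list(mean_bpm = NA_real_, range_bpm = c(NA_real_, NA_real_),
                onsets_s = onsets))
  }
  ioi <- diff(onsets)
  list(mean_bpm = 60 / stats::median(ioi),
       range_bpm = 60 / stats::quantile(ioi, c(0.9, 0.1), names = FALSE),
       onsets_s = onsets)
}

#' Tempo-confound report
#'
#' Pearson correlation (with two-sided p) between per-trial mean tempo and
#' rank accuracy, and between tempo typicality and rank accuracy.
#' Typicality is the Gaussian density of a trial's tempo under the mean and
#' sd of all trial tempos, so unusual tempos score low.
#'
#' @param tempos mean tempo per trial (bpm)
#' @param rank_accs rank accuracy per trial
#' @return a `tempo_report`: list with `r_tempo`, `p_tempo`,
#'   `r_typicality`, `p_typicality`, `typicality`
#' @export
tempo_confound <- function(tempos, rank_accs) {
  stopifnot(length(tempos) == length(rank_accs))
  ok <- is.finite(tempos) & is.finite(rank_accs)
  tempos <- tempos[ok]; rank_accs <- rank_accs[ok]
  if (stats::sd(tempos) == 0) {
    message("zero-variance tempos: correlations undefined")
    return(structure(list(r_tempo = NA_real_, p_tempo = NA_real_,
                          r_typicality = NA_real_, p_typicality = NA_real_,
                          typicality = rep(NA_real_, length(tempos))),
                     class = "tempo_report"))
  }
  ct <- stats::cor.test(tempos, rank_accs)
  typ <- stats::dnorm(tempos, mean(tempos), stats::sd(tempos))
  cty <- if (stats::sd(typ) > 0) stats::cor.test(typ, rank_accs) else
    list(estimate = NA_real_, p.value = NA_real_)
  structure(list(r_tempo = unname(ct$estimate), p_tempo = ct$p.value,
                 r_typicality = unname(cty$estimate), p_typicality = cty$p.value,
                 typicality = typ),
            class = "tempo_report")
}

#' @export
print.tempo_report <- function(x, ...) {
  cat(sprintf("Tempo vs accuracy:      r = %+.3f, p = %.3g\n",
              x$r_tempo, x$p_tempo))
  cat(sprintf("Typicality vs accuracy: r = %+.3f, p = %.3g\n",
              x$r_typicality, x$p_typicality))
  invisible(x)
}
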