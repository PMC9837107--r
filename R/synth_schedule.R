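## Trial schedule: per run, trials follow each other as
## fixation U(1,3) s -> 40 s task -> 0.5 s break. Three trial types:
## music_only and music_reporting carry a piece, reporting_only does not.

.trial_types <- c("music_only", "music_reporting", "reporting_only")

#' Generate a trial schedule
#'
#' Builds a pseudo-random schedule of `n_runs` x `trials_per_run` trials.
#' Each trial is preceded by a uniformly drawn 1-3 s fixation and followed
#' by a 0.5 s break; trial onsets within a run are strictly increasing and
#' non-overlapping. Pieces are assigned to music trials without replacement
#' by default (a piece is heard at most once).
#'
#' @param n_runs number of runs (default 3)
#' @param trials_per_run trials per run (default 12)
#' @param stimuli a `stimulus_set`
#' @param seed integer seed
#' @param type_mix named integer vector giving the per-run count of each
#'   trial type; must sum to `trials_per_run`
#' @param replace logical: allow pieces to repeat across music trials
#'   (default `FALSE`)
#' @param task_s task duration in seconds (default 40)
#' @return a `trial_schedule`: data.frame with columns `trial_id`, `run`,
#'   `type`, `onset_s`, `duration_s`, `piece_id` (NA for reporting_only)
#'   and `fixation_s`; attribute `run_length_s` gives each run's total length
#' @export
generate_schedule <- function(n_runs = 3, trials_per_run = 12, stimuli,
                              seed = 1,
                              type_mix = c(music_only = 5L, music_reporting = 4L,
                                           reporting_only = 3L),
                              replace = FALSE, task_s = 40) {
  if (!all(names(type_mix) %in% .trial_types)) stop("unknown trial type in type_mix")
  if (sum(type_mix) != trials_per_run)
    stop("type_mix must sum to trials_per_run")
  n_music <- n_runs * sum(type_mix[c("music_only", "music_reporting")], na.rm = TRUE)
  n_pieces <- length(stimuli$pieces)
  if (!replace && n_music > n_pieces)
    stop("not enough pieces: ", n_music, " music trials but only ",
         n_pieces, " pieces (set replace = TRUE to reuse pieces)")

  with_seed(seed, {
    piece_pool <- if (replace) sample(n_pieces, n_music, replace = TRUE)
                  else sample(n_pieces, n_music)
    rows <- list(); pi <- 1L; tid <- 1L
    run_len <- numeric(n_runs)
    for (r in seq_len(n_runs)) {
      types <- sample(rep(names(type_mix), times = type_mix))
      t_cur <- 0
      for (ty in types) {
        fix <- stats::runif(1, 1, 3)
        onset <- t_cur + fix
        pid <- NA_integer_
        if (ty != "reporting_only") { pid <- piece_pool[pi]; pi <- pi + 1L }
        rows[[tid]] <- data.frame(trial_id = tid, run = r, type = ty,
                                  onset_s = onset, duration_s = task_s,
                                  piece_id = pid, fixation_s = fix,
                                  stringsAsFactors = FALSE)
        t_cur <- onset + task_s + 0.5
        tid <- tid + 1L
      }
      run_len[r] <- t_cur
    }
    sched <- do.call(rbind, rows)
    structure(sched, run_length_s = run_len, break_s = 0.5,
              class = c("trial_schedule", "data.frame"))
  })
}

#' Music trials of a schedule
#' @param schedule a `trial_schedule`
#' @return the rows whose type carries music
#' @export
music_trials <- function(schedule) {
  schedule[schedule$type %in% c("music_only", "music_reporting"), , drop = FALSE]
}

#' Read / write a trial schedule as TSV
#'
#' Columns: `trial_id`, `run`, `type`, `onset_s`, `duration_s`, `piece_id`.
#' @param schedule a `trial_schedule`
#' @param path file path
#' @return `read_schedule` returns a `trial_schedule`
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(schedule[, c("trial_id", "run", "type", "onset_s",
                                  "duration_s", "piece_id")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("trial_id", "run", "type", "onset_s", "duration_s", "piece_id")
  if (!all(need %in% names(df))) stop("schedule TSV missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  bad <- df$type %in% c("music_only", "music_reporting") & is.na(df$piece_id)
  if (any(bad)) stop("music trials without piece_id: ",
                     paste(df$trial_id[bad], collapse = ", "))
  structure(df, class = c("trial_schedule", "data.frame"))
}
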