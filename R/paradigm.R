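# Block-design paradigm schedules for offline classifier training and online
# neurofeedback runs.  Labels come from a closed alphabet:
#   IAPS  emotional cue image          H  happy-imagery regulation block
#   R     rest/counting block          M  motor-imagery regulation block
#   FIX   fixation (bias estimation)   REST inter-block pause
# Onsets and durations are seconds; blocks are contiguous within a run.

schedule_labels <- c("IAPS", "H", "R", "M", "FIX", "REST")

#' Construct a paradigm schedule
#'
#' @param blocks data.frame with `label`, `onset`, `duration` (seconds) and
#'   `run` columns.
#' @param variant `"offline"` or `"online"`.
#' @return an object of class `paradigm_schedule` (also a data.frame).
#' @export
paradigm_schedule <- function(blocks, variant = c("offline", "online")) {
  variant <- match.arg(variant)
  stopifnot(all(c("label", "onset", "duration", "run") %in% names(blocks)))
  if (!all(blocks$label %in% schedule_labels))
    stopf("unknown block labels: %s",
          paste(setdiff(blocks$label, schedule_labels), collapse = ", "))
  if (any(blocks$duration <= 0)) stopf("block durations must be positive")
  if (is.unsorted(blocks$onset)) stopf("block onsets must be non-decreasing")
  structure(as.data.frame(blocks), variant = variant,
            class = c("paradigm_schedule", "data.frame"))
}

#' @export
print.paradigm_schedule <- function(x, ...) {
  cat(sprintf("%s paradigm: %d blocks, %d runs, %d regulation trials, span %.0f s\n",
              attr(x, "variant"), nrow(x), length(unique(x$run)),
              sum(x$label %in% c("H", "M")), max(x$onset + x$duration)))
  invisible(x)
}

#' Offline training-session schedule
#'
#' Per run, `reps_per_run` deterministic stimulus cycles of
#' IAPS (5 s) - pause (2 s) - H (5 s) - pause (2 s) - R (5 s) - pause (2 s) -
#' M (5 s) - pause (2 s).  The defaults (5 runs of 8 cycles, 4 min per run)
#' give 8 regulation trials per condition per run and 80 regulation trials per
#' session.
#'
#' @param n_runs runs per session (default 5).
#' @param reps_per_run stimulus cycles per run (default 8).
#' @param stim_s,pause_s stimulus and pause durations (defaults 5 and 2 s).
#' @return a [paradigm_schedule()], variant `"offline"`.
#' @export
offline_schedule <- function(n_runs = 5, reps_per_run = 8, stim_s = 5, pause_s = 2) {
  stopifnot(is_count(n_runs), is_count(reps_per_run))
  cyc_labels <- c("IAPS", "REST", "H", "REST", "R", "REST", "M", "REST")
  cyc_durs <- rep(c(stim_s, pause_s), 4L)
  labels <- rep(cyc_labels, times = reps_per_run * n_runs)
  durs <- rep(cyc_durs, times = reps_per_run * n_runs)
  onsets <- cumsum(c(0, durs[-length(durs)]))
  run <- rep(seq_len(n_runs), each = length(cyc_labels) * reps_per_run)
  paradigm_schedule(data.frame(label = labels, onset = onsets,
                               duration = durs, run = run),
                    variant = "offline")
}

#' Online neurofeedback schedule
#'
#' Per run: an opening fixation block, four alternating 20 s regulation blocks
#' (H, M, H, M) each followed by a 10 s rest, a mid-run fixation block (after
#' the 4th regulation block, so the classifier bias can be re-estimated for
#' the second half), then the remaining four regulation blocks with rests.
#' One run spans 280 s and contains 8 regulation blocks; the defaults
#' (3 sessions x 4 runs) give 32 regulation trials per session and 96 total.
#'
#' @param n_sessions sessions (default 3).
#' @param runs_per_session runs per session (default 4).
#' @param reg_s regulation/fixation block duration (default 20 s).
#' @param rest_s rest duration (default 10 s).
#' @return a [paradigm_schedule()], variant `"online"`, with a `session`
#'   column.
#' @export
online_schedule <- function(n_sessions = 3, runs_per_session = 4,
                            reg_s = 20, rest_s = 10) {
  stopifnot(is_count(n_sessions), is_count(runs_per_session))
  half <- c("H", "REST", "M", "REST", "H", "REST", "M", "REST")
  run_labels <- c("FIX", half, "FIX", half)
  run_durs <- ifelse(run_labels %in% c("REST"), rest_s, reg_s)
  n_runs <- n_sessions * runs_per_session
  labels <- rep(run_labels, times = n_runs)
  durs <- rep(run_durs, times = n_runs)
  onsets <- cumsum(c(0, durs[-length(durs)]))
  run <- rep(seq_len(n_runs), each = length(run_labels))
  sch <- paradigm_schedule(data.frame(label = labels, onset = onsets,
                                      duration = durs, run = run),
                           variant = "online")
  sch$session <- rep(seq_len(n_sessions), each = runs_per_session *
                       length(run_labels))
  sch
}
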