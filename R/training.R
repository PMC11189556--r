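training_exercises <- function() {
  c("stop", "flanker", "vs_span", "verbal_span", "switching", "matching")
}

#' Initial per-exercise difficulty state for the training program
#'
#' Difficulty persists across the 20 training sessions: the stop exercise
#' carries its stop-signal delay, the flanker and switching exercises an
#' integer level, the span exercises their current sequence length, and the
#' matching exercise its position on the change-frequency ladder
#' (criterion changes after 12, 8, 6 then 4 consecutive correct responses).
#'
#' @return named list of starting difficulties.
#' @export
training_state_init <- function() {
  list(stop = 500, flanker = 1L, vs_span = 2L, verbal_span = 2L,
       switching = 1L, matching = 1L)
}

# probability of a correct response given ability z and difficulty level
train_p_correct <- function(z, level, base_logit = 2.0, level_slope = 0.35) {
  stats::plogis(base_logit + 0.5 * z - level_slope * (level - 1))
}

run_training_exercise <- function(ex, policies, difficulty, n_trials) {
  z <- policies[[switch(ex,
    stop = "response_inhibition", flanker = "interference_control",
    vs_span = "visuospatial_wm", verbal_span = "verbal_wm",
    switching = "switching", matching = "matching")]]$z
  diff_track <- numeric(n_trials)
  correct <- logical(n_trials)
  if (ex == "stop") {
    p <- policies$response_inhibition$params
    sc <- staircase(start = difficulty)
    tt <- sample(rep(c("go", "stop"), round(c(0.75, 0.25) * n_trials)))
    for (i in seq_len(n_trials)) {
      diff_track[i] <- sc$value
      lift <- stats::rnorm(1, p$go_mean, p$go_sd)
      if (tt[i] == "stop") {
        finish <- sc$value + p$ssrt_true + stats::rnorm(1, 0, p$ssrt_sd)
        inhibited <- lift >= finish
        correct[i] <- inhibited
        sc <- staircase_update(sc, inhibited)
      } else {
        correct[i] <- abs(lift - p$go_mean) <= 150
      }
    }
    difficulty <- sc$value
  } else if (ex %in% c("vs_span", "verbal_span")) {
    p <- policies[[if (ex == "vs_span") "visuospatial_wm" else "verbal_wm"]]$params
    span <- difficulty; consec <- 0L
    for (i in seq_len(n_trials)) {
      diff_track[i] <- span
      ok <- span_correct(span, p$capacity + 0.5, p$lapse)
      correct[i] <- ok
      if (ok) {
        consec <- consec + 1L
        if (consec >= 2L) { span <- min(span + 1L, 9L); consec <- 0L }
      } else {
        span <- max(span - 1L, 2L); consec <- 0L
      }
    }
    difficulty <- span
  } else if (ex == "matching") {
    thresholds <- c(12L, 8L, 6L, 4L)
    pos <- difficulty; consec <- 0L
    pc <- stats::plogis(1.6 + 0.5 * z)
    for (i in seq_len(n_trials)) {
      diff_track[i] <- pos
      ok <- stats::runif(1) < pc
      correct[i] <- ok
      if (ok) {
        consec <- consec + 1L
        if (consec >= thresholds[pos]) {  # sorting dimension changes
          pos <- min(pos + 1L, 4L)
          consec <- 0L
        }
      } else consec <- 0L
    }
    difficulty <- pos
  } else {                                # flanker / switching levels
    level <- difficulty; up <- 0L; down <- 0L
    for (i in seq_len(n_trials)) {
      diff_track[i] <- level
      reversal <- ex == "switching" && level >= 3L &&
        stats::runif(1) < 0.1 * (level - 2L)
      pc <- train_p_correct(z, level) * (if (reversal) 0.8 else 1)
      ok <- stats::runif(1) < pc
      correct[i] <- ok
      if (ok) {
        up <- up + 1L; down <- 0L
        if (up >= 3L) { level <- min(level + 1L, 10L); up <- 0L }
      } else {
        down <- down + 1L; up <- 0L
        if (down >= 2L) { level <- max(level - 1L, 1L); down <- 0L }
      }
    }
    difficulty <- level
  }
  list(log = data.frame(exercise = ex, trial = seq_len(n_trials),
                        difficulty = diff_track, correct = correct,
                        stringsAsFactors = FALSE),
       difficulty = difficulty)
}

#' Run one adaptive training session
#'
#' A session runs the six game exercises (stop-signal, flanker, visuospatial
#' and verbal serial recall, rule switching, and matching) in a seeded
#' random order, three minutes each for 18 active minutes. Each exercise
#' applies its stated adaptation rule (stop: +/- 50 ms delay staircase in
#' [300, 700]; spans: +/- 1 item; flanker/switching: level steps; matching:
#' the 12-8-6-4 consecutive-correct ladder) and difficulty persists across
#' sessions via `state`.
#'
#' @param policies named list of `responder_policy` objects covering the
#'   six training domains (see [make_responder()]).
#' @param state per-exercise difficulty, see [training_state_init()].
#' @param seed integer seed.
#' @param session session index (1-20).
#' @param trial_budget trials per 3-minute exercise block (simulation
#'   parameter; the program fixes minutes, not trial counts).
#' @return list of class `session_log`: `session`, `order`, `minutes`,
#'   `exercises` (per-exercise trial logs), `state` (end-of-session
#'   difficulties), `completed`.
#' @export
run_training_session <- function(policies, state = training_state_init(),
                                 seed = 1L, session = 1L, trial_budget = 40L) {
  bad <- setdiff(names(state), training_exercises())
  if (length(bad)) stop_config("unknown exercise id: %s", paste(bad, collapse = ", "))
  with_seed(seed, {
    ord <- sample(training_exercises())
    logs <- list()
    for (ex in ord) {
      res <- run_training_exercise(ex, policies, state[[ex]], trial_budget)
      logs[[ex]] <- res$log
      state[[ex]] <- res$difficulty
    }
    structure(list(session = session, order = ord, minutes = 18,
                   exercises = logs, state = state, completed = TRUE),
              class = "session_log")
  })
}

#' Run a full training course
#'
#' @param policies as in [run_training_session()].
#' @param n_sessions number of sessions to complete (scheduled: 20).
#' @param seed integer master seed; each session derives its own.
#' @param trial_budget trials per exercise block.
#' @return list of `session_log`s, one per completed session.
#' @export
run_training_course <- function(policies, n_sessions = 20L, seed = 1L,
                                trial_budget = 40L) {
  state <- training_state_init()
  out <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    sl <- run_training_session(policies, state,
                               seed = derive_seed(seed, paste0("session", s)),
                               session = s, trial_budget = trial_budget)
    state <- sl$state
    out[[s]] <- sl
  }
  out
}

#' Serialize trial or session logs as JSONL
#'
#' One JSON record per trial (or per session), with a schema version field.
#'
#' @param log a `trial_log` data.frame or list of `session_log`s.
#' @param path output file.
#' @export
write_log_jsonl <- function(log, path) {
  con <- file(path, "w"); on.exit(close(con))
  if (inherits(log, "trial_log")) {
    for (i in seq_len(nrow(log))) {
      rec <- c(schema = "trial_log/1", as.list(log[i, ]))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null"), con)
    }
  } else {
    for (sl in log) {
      rec <- list(schema = "session_log/1", session = sl$session,
                  order = sl$order, minutes = sl$minutes,
                  completed = sl$completed, state = sl$state)
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}
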