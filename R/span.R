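span_correct <- function(span, capacity, lapse) {
  span <= capacity && (lapse <= 0 || stats::runif(1) >= lapse)
}

#' Simulate a backwards digit span administration
#'
#' Auditory digit sequences start at a span of two and must be recalled in
#' reverse order. Two trials are offered at each span; the span increases
#' by one when at least one of the two is correct, and the task ends when
#' both trials of the same span are answered incorrectly (or the maximum
#' span is passed). The responder recalls a sequence correctly when the
#' span does not exceed its capacity and no attentional lapse occurs.
#'
#' @param policy `responder_policy` for `verbal_wm` (capacity, lapse).
#' @param seed integer seed (drives lapses).
#' @param start_span,max_span schedule bounds (2 and 9).
#' @return `trial_log` data.frame with `span`, `trial`, `correct`.
#' @export
run_digit_span <- function(policy, seed = 1L, start_span = 2L, max_span = 9L) {
  p <- policy$params
  with_seed(seed, {
    rows <- list()
    span <- start_span
    repeat {
      ok <- c(span_correct(span, p$capacity, p$lapse),
              span_correct(span, p$capacity, p$lapse))
      rows[[length(rows) + 1L]] <-
        data.frame(span = span, trial = 1:2, correct = ok)
      if (!any(ok)) break               # two trials of the same span failed
      if (span >= max_span) break
      span <- span + 1L
    }
    log <- do.call(rbind, rows)
    log <- cbind(task = "digit_span", index = seq_len(nrow(log)), log)
    class(log) <- c("trial_log", class(log))
    log
  })
}

#' Simulate a Corsi block-tapping administration
#'
#' Sequences of blocks light up and must be reproduced in order. The
#' sequence length starts at two and increases by one only after two
#' consecutive correct reproductions of the same length, up to nine blocks.
#' The task is discontinued after two trials of the same length are
#' incorrect. When the first two trials of a length split (one correct,
#' one not), a single additional trial is presented to resolve the window
#' (hard cap of three trials per length): a correct third trial following a
#' correct second trial completes the two-consecutive rule, any other
#' outcome discontinues.
#'
#' @inheritParams run_digit_span
#' @param policy `responder_policy` for `visuospatial_wm`.
#' @return `trial_log` data.frame with `span`, `trial`, `correct`.
#' @export
run_corsi <- function(policy, seed = 1L, start_span = 2L, max_span = 9L) {
  p <- policy$params
  with_seed(seed, {
    rows <- list()
    span <- start_span
    done <- FALSE
    while (!done) {
      consec <- 0L; wrong <- 0L; tried <- 0L
      advance <- FALSE
      while (tried < 3L) {
        ok <- span_correct(span, p$capacity, p$lapse)
        tried <- tried + 1L
        rows[[length(rows) + 1L]] <-
          data.frame(span = span, trial = tried, correct = ok)
        if (ok) consec <- consec + 1L else { consec <- 0L; wrong <- wrong + 1L }
        if (consec >= 2L) { advance <- TRUE; break }
        if (wrong >= 2L) break
      }
      if (!advance || span >= max_span) done <- TRUE else span <- span + 1L
    }
    log <- do.call(rbind, rows)
    log <- cbind(task = "corsi", index = seq_len(nrow(log)), log)
    class(log) <- c("trial_log", class(log))
    log
  })
}
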