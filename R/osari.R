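#' One-up one-down stop-signal delay staircase
#'
#' Tracks the stop-signal delay (SSD) used on stop trials: the delay starts
#' at `start` and moves up by `step` after a successful inhibition (making
#' the next stop harder) and down by `step` after a failed one, clipped to
#' `[lower, upper]` after every update. The 1-up-1-down rule converges to
#' the delay at which stopping succeeds half the time.
#'
#' @param start,step,lower,upper milliseconds; trial defaults 500/50/300/700.
#' @return object of class `staircase` with fields `value`, `step`,
#'   `lower`, `upper`, `history`.
#' @export
staircase <- function(start = 500, step = 50, lower = 300, upper = 700) {
  stopifnot(step > 0, lower <= start, start <= upper)
  structure(list(value = start, step = step, lower = lower, upper = upper,
                 history = numeric(0)),
            class = "staircase")
}

staircase_update <- function(sc, inhibited) {
  sc$history <- c(sc$history, sc$value)
  delta <- if (inhibited) sc$step else -sc$step
  sc$value <- min(max(sc$value + delta, sc$lower), sc$upper)
  sc
}

osari_phases <- function() {
  list(practice_go = c(go = 10L, stop = 0L),
       practice_mixed = c(go = 15L, stop = 5L),
       test = c(go = 45L, stop = 15L))   # per test block, 3 blocks
}

#' Simulate an anticipated-response stop-signal task administration
#'
#' The go response is a timed key lift aimed at the 800 ms target on a bar
#' that fills completely at 1000 ms. On stop trials the bar stops filling
#' at the current stop-signal delay and the child must withhold the lift.
#' The responder is a race: a planned lift time drawn from the policy's go
#' distribution races the stop process, which finishes at SSD plus the true
#' stop-signal reaction time; the lift is withheld when the stop process
#' finishes no later than the planned lift (ties count as successful
#' inhibition). Schedule: 10 practice go trials, 20 mixed practice trials
#' (15 go / 5 stop), then three test blocks of 60 trials (45 go / 15 stop),
#' order randomised within block. The SSD staircase starts at 500 ms and
#' moves +/- 50 ms within [300, 700].
#'
#' @param policy `responder_policy` for the `response_inhibition` domain.
#' @param seed integer seed.
#' @param target_ms go target (800); `bar_full_ms` end of trial window (1000).
#' @param sc initial [staircase()].
#' @return data.frame trial log (class `trial_log`): `task`, `phase`,
#'   `block`, `index`, `trial_type`, `ssd`, `rt`, `responded`, `correct`.
#' @export
run_osari <- function(policy, seed = 1L, target_ms = 800, bar_full_ms = 1000,
                      sc = staircase()) {
  p <- policy$params
  need <- c("go_mean", "go_sd", "go_omission", "ssrt_true", "ssrt_sd")
  if (!all(need %in% names(p))) {
    stop_config("policy lacks stop-signal parameters (%s)",
                paste(setdiff(need, names(p)), collapse = ", "))
  }
  with_seed(seed, {
    ph <- osari_phases()
    mk_block <- function(phase, block, counts) {
      tt <- sample(rep(c("go", "stop"), counts))
      data.frame(phase = phase, block = block, trial_type = tt,
                 stringsAsFactors = FALSE)
    }
    sched <- rbind(
      mk_block("practice_go", 0L, ph$practice_go),
      mk_block("practice_mixed", 0L, ph$practice_mixed),
      do.call(rbind, lapply(1:3, function(b) mk_block("test", b, ph$test)))
    )
    n <- nrow(sched)
    lift <- stats::rnorm(n, p$go_mean, p$go_sd)
    omit <- stats::runif(n) < p$go_omission
    stopfin_noise <- stats::rnorm(n, 0, p$ssrt_sd)
    ssd <- rep(NA_real_, n); rt <- rep(NA_real_, n)
    responded <- logical(n); correct <- logical(n)
    for (i in seq_len(n)) {
      if (sched$trial_type[i] == "go") {
        if (!omit[i] && lift[i] <= bar_full_ms) {
          responded[i] <- TRUE
          rt[i] <- lift[i]
          correct[i] <- abs(lift[i] - target_ms) <= 150
        }
      } else {
        ssd[i] <- sc$value
        finish <- ssd[i] + p$ssrt_true + stopfin_noise[i]
        lifts <- !omit[i] && lift[i] < finish && lift[i] <= bar_full_ms
        if (lifts) {
          responded[i] <- TRUE
          rt[i] <- lift[i]
        }
        correct[i] <- !responded[i]
        sc <- staircase_update(sc, inhibited = !responded[i])
      }
    }
    log <- data.frame(task = "osari", phase = sched$phase, block = sched$block,
                      index = seq_len(n), trial_type = sched$trial_type,
                      ssd = ssd, rt = rt, responded = responded,
                      correct = correct, stringsAsFactors = FALSE)
    class(log) <- c("trial_log", class(log))
    attr(log, "staircase") <- sc
    log
  })
}
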