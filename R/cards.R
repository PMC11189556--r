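wcst_dims <- function() c("colour", "shape", "number")

#' Simulate a modified card-sorting administration
#'
#' Exactly 48 non-ambiguous cards are sorted by colour, shape or number.
#' The active criterion is never announced; corrective feedback follows
#' every trial, and after 6 consecutive correct sorts the criterion changes
#' (cycling colour, shape, number). The responder sorts by its currently
#' believed dimension, except on attentional lapses (random dimension).
#' After an error it either perseverates (keeps the now-wrong belief, with
#' the policy's perseveration probability) or shifts belief: to the next
#' dimension in the cycle (`switch_rule = "cycle"`, deterministic) or to a
#' random other dimension (`"random"`).
#'
#' @param policy `responder_policy` for `switching`.
#' @param seed integer seed.
#' @param n_trials number of cards (48).
#' @return `trial_log` data.frame with `criterion`, `prev_criterion`,
#'   `response_dim`, `correct`.
#' @export
run_wcst <- function(policy, seed = 1L, n_trials = 48L) {
  p <- policy$params
  with_seed(seed, {
    dims <- wcst_dims()
    crit_i <- 1L                       # colour first, standard administration
    prev_crit <- NA_character_
    believed <- p$start_dimension %||% "colour"
    consec <- 0L
    out <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      resp <- if (p$lapse > 0 && stats::runif(1) < p$lapse) {
        sample(dims, 1L)
      } else believed
      crit <- dims[crit_i]
      ok <- resp == crit
      out[[i]] <- data.frame(criterion = crit, prev_criterion = prev_crit,
                             response_dim = resp, correct = ok,
                             stringsAsFactors = FALSE)
      if (ok) {
        believed <- resp
        consec <- consec + 1L
        if (consec >= 6L) {            # unannounced criterion change
          prev_crit <- crit
          crit_i <- crit_i %% 3L + 1L
          consec <- 0L
        }
      } else {
        consec <- 0L
        persev <- p$perseveration_prob > 0 &&
          stats::runif(1) < p$perseveration_prob
        if (!persev) {
          believed <- if (identical(p$switch_rule, "random")) {
            sample(setdiff(dims, resp), 1L)
          } else {
            dims[match(resp, dims) %% 3L + 1L]
          }
        }
      }
    }
    log <- do.call(rbind, out)
    log <- cbind(task = "wcst", index = seq_len(n_trials), log)
    class(log) <- c("trial_log", class(log))
    log
  })
}

#' Simulate a dimensional change card sort administration
#'
#' Six pre-switch trials (rule stated each trial), six post-switch trials
#' under the other rule, and — only if at least five of six post-switch
#' trials are correct — an advanced phase of twelve trials in which the
#' rule changes trial-by-trial with a verbal cue. The responder applies
#' the cued rule correctly with a per-phase probability from the policy.
#' The pre-switch pass criterion is taken as at least five of six by
#' analogy with the stated post-switch rule.
#'
#' @param policy `responder_policy` for `matching` (per-phase accuracy
#'   logits).
#' @param seed integer seed.
#' @return `trial_log` data.frame with `phase`, `correct`.
#' @export
run_dccs <- function(policy, seed = 1L) {
  p <- policy$params
  with_seed(seed, {
    acc <- c(pre = stats::plogis(p$acc_pre_logit),
             post = stats::plogis(p$acc_post_logit),
             advanced = stats::plogis(p$acc_adv_logit))
    pre <- stats::runif(6) < acc["pre"]
    post <- stats::runif(6) < acc["post"]
    phases <- data.frame(phase = rep(c("pre", "post"), each = 6),
                         correct = c(pre, post), stringsAsFactors = FALSE)
    if (sum(post) >= 5L) {
      adv <- stats::runif(12) < acc["advanced"]
      phases <- rbind(phases,
                      data.frame(phase = "advanced", correct = adv))
    }
    log <- cbind(task = "dccs", index = seq_len(nrow(phases)), phases)
    class(log) <- c("trial_log", class(log))
    log
  })
}
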