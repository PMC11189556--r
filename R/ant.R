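#' Simulate a child attention-network (flanker) task administration
#'
#' A central target fish points left or right, flanked by congruent or
#' incongruent distractors, preceded by one of four cue conditions (no,
#' centre, double, spatial). The schedule is one 24-trial practice block
#' (12 target-only, 12 flanked) followed by three experimental blocks of 48
#' trials, each balanced 50/50 congruent/incongruent and equally across the
#' four cues. Reaction times are generated additively: base RT, plus the
#' policy's congruency cost on incongruent trials, minus an alerting
#' benefit under centre/double cues and an orienting benefit under spatial
#' cues, plus Gaussian noise. A small anticipation rate produces sub-100 ms
#' responses and an omission rate produces non-responses, exercising the
#' scoring exclusions.
#'
#' @param policy `responder_policy` for the `interference_control` domain.
#' @param seed integer seed.
#' @return `trial_log` data.frame with `phase`, `block`, `cue`,
#'   `congruency`, `rt`, `responded`, `correct`.
#' @export
run_ant <- function(policy, seed = 1L) {
  p <- policy$params
  need <- c("base_rt", "congruency_cost", "alerting_benefit",
            "orienting_benefit", "rt_noise_sd", "error_rate", "omission_rate")
  if (!all(need %in% names(p))) {
    stop_config("policy lacks flanker parameters (%s)",
                paste(setdiff(need, names(p)), collapse = ", "))
  }
  with_seed(seed, {
    cues <- c("none", "centre", "double", "spatial")
    mk_block <- function(phase, block) {
      if (phase == "practice") {
        d <- data.frame(congruency = rep(c("target_only", "congruent",
                                           "incongruent"), c(12, 6, 6)),
                        cue = sample(cues, 24, replace = TRUE))
      } else {
        d <- expand.grid(cue = cues,
                         congruency = c("congruent", "incongruent"),
                         rep = 1:6, stringsAsFactors = FALSE)[, 1:2]
        d <- d[sample(nrow(d)), ]
      }
      d$phase <- phase; d$block <- block
      d
    }
    sched <- rbind(mk_block("practice", 0L),
                   do.call(rbind, lapply(1:3, function(b)
                     mk_block("experimental", b))))
    n <- nrow(sched)
    # any cue alerts; only the spatial cue additionally orients, so the
    # centre-minus-spatial subtraction isolates the orienting benefit
    rt <- p$base_rt +
      p$congruency_cost * (sched$congruency == "incongruent") -
      p$alerting_benefit * (sched$cue != "none") -
      p$orienting_benefit * (sched$cue == "spatial") +
      stats::rnorm(n, 0, p$rt_noise_sd)
    rt <- pmax(rt, 150)
    anticip <- stats::runif(n) < (p$anticipation_rate %||% 0)
    rt[anticip] <- stats::runif(sum(anticip), 0, 99)
    omit <- stats::runif(n) < p$omission_rate
    rt[omit] <- NA_real_
    correct <- !omit & stats::runif(n) >= p$error_rate
    log <- data.frame(task = "ant", phase = sched$phase, block = sched$block,
                      index = seq_len(n), cue = sched$cue,
                      congruency = sched$congruency, rt = rt,
                      responded = !omit, correct = correct,
                      stringsAsFactors = FALSE)
    class(log) <- c("trial_log", class(log))
    rownames(log) <- NULL
    log
  })
}
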