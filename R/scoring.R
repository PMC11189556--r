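#' Integration-method stop-signal reaction time
#'
#' The race-model estimator: let `p` be the observed probability of
#' responding on a stop trial. Omitted go trials are assigned the maximum
#' observed lift time, the `p`-th quantile of the resulting go lift-time
#' distribution is taken (empirical inverse-CDF, type-1 quantile), and the
#' mean stop-signal delay is subtracted. Degenerate respond rates (0 or 1)
#' carry no information about the stop process and are flagged rather than
#' returned as finite estimates.
#'
#' @param go_lift_times numeric, observed go lift times in ms; `NA` marks
#'   an omitted go trial.
#' @param stop_trials data.frame with columns `ssd` (ms) and `responded`
#'   (logical), one row per stop trial.
#' @return list `ssrt` (ms, `NA` when degenerate), `p_respond`,
#'   `mean_ssd`, `degenerate`.
#' @export
ssrt_integration <- function(go_lift_times, stop_trials) {
  if (!length(go_lift_times)) stop_config("need at least one go trial")
  if (!nrow(stop_trials)) stop_config("need at least one stop trial")
  p <- mean(stop_trials$responded)
  mean_ssd <- mean(stop_trials$ssd)
  if (p <= 0 || p >= 1) {
    warning("degenerate stop-respond rate (", p,
            "); SSRT not estimable by the integration method")
    return(list(ssrt = NA_real_, p_respond = p, mean_ssd = mean_ssd,
                degenerate = TRUE))
  }
  lifts <- go_lift_times
  lifts[is.na(lifts)] <- max(lifts, na.rm = TRUE)  # omissions -> max lift
  q <- stats::quantile(lifts, probs = p, type = 1, names = FALSE)
  list(ssrt = q - mean_ssd, p_respond = p, mean_ssd = mean_ssd,
       degenerate = FALSE)
}

#' Score an anticipated-response stop-signal log
#'
#' Summarises the test blocks of a [run_osari()] log: integration-method
#' SSRT, go RT mean/SD, go accuracy (lifts within a tolerance window of the
#' 800 ms target — the anticipated-response convention, window
#' configurable), go response rate, and the mean and maximum stop-signal
#' delay. Quality control fails the administration when the go response
#' rate is below 75%, go accuracy below 60%, or mean go RT below 400 ms;
#' summary fields are computed regardless.
#'
#' @param log a `trial_log` from [run_osari()].
#' @param target_ms go target time (800).
#' @param accuracy_window_ms half-width of the accuracy window (150).
#' @return list of class `osari_scores`.
#' @export
score_osari <- function(log, target_ms = 800, accuracy_window_ms = 150) {
  test <- log[log$phase == "test", , drop = FALSE]
  if (!nrow(test)) stop_config("log has no test-phase trials")
  go <- test[test$trial_type == "go", , drop = FALSE]
  stop_t <- test[test$trial_type == "stop", , drop = FALSE]
  go_response_rate <- mean(go$responded)
  go_rt <- go$rt[go$responded]
  go_accuracy <- mean(go$responded &
                        abs(go$rt - target_ms) <= accuracy_window_ms,
                      na.rm = TRUE)
  est <- suppressWarnings(
    ssrt_integration(ifelse(go$responded, go$rt, NA_real_),
                     data.frame(ssd = stop_t$ssd,
                                responded = stop_t$responded)))
  qc_pass <- go_response_rate >= 0.75 && go_accuracy >= 0.60 &&
    (length(go_rt) > 0 && mean(go_rt) >= 400) && !est$degenerate
  structure(list(
    ssrt = est$ssrt,
    go_rt_mean = if (length(go_rt)) mean(go_rt) else NA_real_,
    go_rt_sd = if (length(go_rt) > 1) stats::sd(go_rt) else NA_real_,
    go_accuracy = go_accuracy,
    go_response_rate = go_response_rate,
    p_respond_stop = est$p_respond,
    mean_ssd = est$mean_ssd,
    max_ssd = max(stop_t$ssd),
    qc_pass = qc_pass
  ), class = "osari_scores")
}

#' Score an attention-network (flanker) log
#'
#' Computed from experimental blocks only. Responses faster than 100 ms
#' are excluded before any mean, omissions are counted and excluded from
#' RT means. Alerting = mean RT(no cue) - mean RT(double cue) and
#' orienting = mean RT(centre cue) - mean RT(spatial cue), both excluding
#' incongruent trials; conflict = mean RT(incongruent) - mean RT(congruent).
#'
#' @param log a `trial_log` from [run_ant()].
#' @return list of class `ant_scores` with `alerting`, `orienting`,
#'   `conflict` (ms), `accuracy`, `omissions`, and a `flagged` field naming
#'   any condition cell left empty after exclusions.
#' @export
score_ant <- function(log) {
  ex <- log[log$phase == "experimental", , drop = FALSE]
  if (!nrow(ex)) stop_config("log has no experimental trials")
  usable <- ex$responded & !is.na(ex$rt) & ex$rt >= 100
  mrt <- function(keep) {
    i <- usable & keep
    if (!any(i)) return(NA_real_)
    mean(ex$rt[i])
  }
  cong <- ex$congruency == "congruent"
  incong <- ex$congruency == "incongruent"
  alerting <- mrt(ex$cue == "none" & !incong) - mrt(ex$cue == "double" & !incong)
  orienting <- mrt(ex$cue == "centre" & !incong) - mrt(ex$cue == "spatial" & !incong)
  conflict <- mrt(incong) - mrt(cong)
  flagged <- character(0)
  if (is.na(alerting)) flagged <- c(flagged, "alerting")
  if (is.na(orienting)) flagged <- c(flagged, "orienting")
  if (is.na(conflict)) flagged <- c(flagged, "conflict")
  structure(list(alerting = alerting, orienting = orienting,
                 conflict = conflict,
                 accuracy = mean(ex$correct),
                 omissions = sum(!ex$responded),
                 flagged = flagged),
            class = "ant_scores")
}

#' Score a serial span log (digit span or Corsi)
#'
#' The longest correctly recalled span and the total number of correctly
#' recalled sequences are recorded and multiplied to give the total score.
#'
#' @param log a `trial_log` from [run_digit_span()] or [run_corsi()].
#' @return list of class `span_scores`: `longest_span`, `n_correct`,
#'   `total` (= longest_span * n_correct).
#' @export
score_span <- function(log) {
  n_correct <- sum(log$correct)
  longest <- if (n_correct) max(log$span[log$correct]) else 0L
  structure(list(longest_span = as.integer(longest),
                 n_correct = as.integer(n_correct),
                 total = as.integer(longest) * as.integer(n_correct)),
            class = "span_scores")
}

#' Score a card-sorting log
#'
#' An error is perseverative when the sorted dimension matches the
#' immediately preceding sorting criterion (defined once a criterion change
#' has occurred); all other errors are non-perseverative. Proportions are
#' relative to the total number of trials.
#'
#' @param log a `trial_log` from [run_wcst()].
#' @return list of class `wcst_scores` with the three error proportions
#'   and `n_criterion_changes`.
#' @export
score_wcst <- function(log) {
  n <- nrow(log)
  err <- !log$correct
  persev <- err & !is.na(log$prev_criterion) &
    log$response_dim == log$prev_criterion
  # a criterion change fires each time 6 consecutive correct are completed
  consec <- 0L; changes <- 0L
  for (ok in log$correct) {
    if (ok) {
      consec <- consec + 1L
      if (consec == 6L) { changes <- changes + 1L; consec <- 0L }
    } else consec <- 0L
  }
  structure(list(
    prop_perseverative = sum(persev) / n,
    prop_nonperseverative = sum(err & !persev) / n,
    prop_total_errors = sum(err) / n,
    n_criterion_changes = changes,
    n_trials = n
  ), class = "wcst_scores")
}

#' Score a dimensional-change card-sort log
#'
#' Total correct advanced-phase responses (0-12; 0 when the advanced phase
#' was not administered) and the 0-3 phase ladder: 0 = failed pre-switch,
#' 1 = passed pre-switch only, 2 = passed post-switch but not advanced,
#' 3 = passed advanced (at least nine of twelve correct).
#'
#' @param log a `trial_log` from [run_dccs()].
#' @return list of class `dccs_scores`: `advanced_total`, `phase_score`.
#' @export
score_dccs <- function(log) {
  n_ok <- function(ph) sum(log$correct[log$phase == ph])
  has_adv <- any(log$phase == "advanced")
  pre_pass <- n_ok("pre") >= 5L
  post_pass <- n_ok("post") >= 5L
  adv_total <- if (has_adv) n_ok("advanced") else 0L
  adv_pass <- has_adv && adv_total >= 9L
  score <- if (!pre_pass) 0L else if (!post_pass) 1L else if (!adv_pass) 2L else 3L
  structure(list(advanced_total = as.integer(adv_total),
                 phase_score = score),
            class = "dccs_scores")
}

#' Score questionnaire subscale inputs
#'
#' Raw composites only: the global executive composite is the sum of the
#' nine executive-function rating subscales; the wellbeing total sums the
#' four deficit-focused subscales (emotional, conduct, hyperactivity,
#' peer), excluding prosocial behaviour; the motivation and
#' family-functioning scales are item means (item sum divided by the number
#' of items).
#'
#' @param brief_subscales numeric vector of 9 executive-function rating
#'   subscale values (each >= 0).
#' @param sdq named numeric length-5 (emotional, conduct, hyperactivity,
#'   peer, prosocial), each in `[0, 10]`.
#' @param dmq_items motivation items, each in `[1, 5]`.
#' @param fad_items family-functioning items, each in `[1, 4]`.
#' @return list of class `rating_scores` with whichever composites the
#'   supplied inputs allow: `brief_gec`, `sdq_total`, `dmq_persistence`,
#'   `fad_general`.
#' @export
score_ratings <- function(brief_subscales = NULL, sdq = NULL,
                          dmq_items = NULL, fad_items = NULL) {
  out <- list()
  if (!is.null(brief_subscales)) {
    if (any(brief_subscales < 0)) stop_config("rating subscales must be >= 0")
    out$brief_gec <- sum(brief_subscales)
  }
  if (!is.null(sdq)) {
    need <- c("emotional", "conduct", "hyperactivity", "peer")
    if (!all(need %in% names(sdq))) stop_config("sdq needs named subscales")
    if (any(sdq < 0 | sdq > 10)) stop_config("sdq subscales must be in [0, 10]")
    out$sdq_total <- sum(sdq[need])     # prosocial excluded
  }
  if (!is.null(dmq_items)) {
    if (any(dmq_items < 1 | dmq_items > 5)) stop_config("dmq items in [1, 5]")
    out$dmq_persistence <- sum(dmq_items) / length(dmq_items)
  }
  if (!is.null(fad_items)) {
    if (any(fad_items < 1 | fad_items > 4)) stop_config("fad items in [1, 4]")
    out$fad_general <- sum(fad_items) / length(fad_items)
  }
  structure(out, class = "rating_scores")
}
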