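#' Population-default behavioural parameters per domain
#'
#' The generative link from latent ability to task behaviour is anchored at
#' these population defaults (a child of exactly average latent ability,
#' z = 0). Values are calibrated to what 6-8 year-olds typically produce on
#' these paradigms: mean anticipated-lift times at the 800 ms target with
#' ~250 ms true stopping latency; flanker conflict costs around 100 ms;
#' backwards verbal span near 3.5 and spatial span near 4.5; substantial
#' perseveration on unannounced rule switches; and raw rating-scale levels
#' near the trial's baseline table.
#'
#' @return named list of per-domain parameter lists.
#' @export
responder_defaults <- function() {
  list(
    response_inhibition = list(
      go_mean = 800, go_sd = 60, go_omission = 0.03,
      ssrt_true = 250, ssrt_sd = 20,
      # per-SD-of-ability slopes (better ability -> faster stopping,
      # tighter timing, fewer omissions)
      slope = c(ssrt_true = -50, go_sd = -10, go_omission_logit = -0.3)
    ),
    interference_control = list(
      base_rt = 650, congruency_cost = 100, alerting_benefit = 40,
      orienting_benefit = 45, rt_noise_sd = 150,
      error_rate = 0.06, omission_rate = 0.04, anticipation_rate = 0.02,
      slope = c(congruency_cost = -30, error_rate_logit = -0.3,
                omission_rate_logit = -0.3)
    ),
    verbal_wm = list(
      capacity = 3.5, lapse = 0.05,
      slope = c(capacity = 1.0, lapse_logit = -0.3)
    ),
    visuospatial_wm = list(
      capacity = 4.5, lapse = 0.05,
      slope = c(capacity = 1.0, lapse_logit = -0.3)
    ),
    switching = list(
      perseveration_prob = 0.45, lapse = 0.20,
      start_dimension = "colour", switch_rule = "cycle",
      slope = c(perseveration_prob_logit = -0.5, lapse_logit = -0.4)
    ),
    matching = list(
      acc_pre_logit = 2.9, acc_post_logit = 2.2, acc_adv_logit = 1.1,
      slope = c(acc_pre_logit = 0.5, acc_post_logit = 0.6,
                acc_adv_logit = 0.6)
    ),
    everyday_ef = list(
      gec_mean = 51, gec_sd = 6, n_subscales = 9,
      slope = c(gec_mean = -9)       # better everyday EF -> lower GEC
    ),
    sewb = list(
      sdq_parent_mean = 9.2, sdq_teacher_mean = 7.4, sdq_sd = 4.5,
      prosocial_mean = 7,
      slope = c(sdq_parent_mean = -2.2, sdq_teacher_mean = -2.2)
    )
  )
}

#' Extract one participant's profile from a cohort
#'
#' @param cohort an `ef_cohort`.
#' @param id participant identifier.
#' @return list with the demographic row and the domain x timepoint latent
#'   ability matrix.
#' @export
participant_profile <- function(cohort, id) {
  i <- match(id, cohort$participants$id)
  if (is.na(i)) stop_config("unknown participant id: %s", id)
  list(demographics = cohort$participants[i, , drop = FALSE],
       ability = cohort$ability[i, , ])
}

#' Map latent ability to a generative task policy
#'
#' The monotone link at the heart of the cohort generator: one standard
#' deviation of latent ability buys a fixed improvement in every
#' ability-linked behavioural parameter of the corresponding task (shorter
#' true stopping latency, smaller conflict cost, larger span capacity,
#' less perseveration, higher rule-application accuracy, better ratings).
#' At z = 0 the policy equals [responder_defaults()].
#'
#' @param profile a [participant_profile()], or `NULL` when `z` is given
#'   directly.
#' @param domain one of [ef_domains()].
#' @param timepoint `"T1"`, `"T2"` or `"T3"` (used with `profile`).
#' @param z latent ability z-score, overrides `profile`.
#' @param defaults parameter anchor, see [responder_defaults()].
#' @return object of class `responder_policy`.
#' @export
make_responder <- function(profile = NULL, domain, timepoint = "T1", z = NULL,
                           defaults = responder_defaults()) {
  if (!domain %in% names(defaults)) stop_config("unknown domain: %s", domain)
  if (is.null(z)) {
    stopifnot(!is.null(profile))
    z <- profile$ability[domain, timepoint]
  }
  d <- defaults[[domain]]
  p <- d[setdiff(names(d), "slope")]
  sl <- d$slope
  adj_logit <- function(val, delta) stats::plogis(stats::qlogis(val) + delta)
  for (nm in names(sl)) {
    if (grepl("_logit$", nm)) {
      base_nm <- sub("_logit$", "", nm)
      if (base_nm %in% names(p)) {
        p[[base_nm]] <- adj_logit(p[[base_nm]], sl[[nm]] * z)
      } else {
        p[[nm]] <- d[[nm]] + sl[[nm]] * z      # stored on the logit scale
      }
    } else {
      p[[nm]] <- p[[nm]] + sl[[nm]] * z
    }
  }
  # physical floors
  if (!is.null(p$ssrt_true)) p$ssrt_true <- max(p$ssrt_true, 80)
  if (!is.null(p$go_sd)) p$go_sd <- max(p$go_sd, 15)
  if (!is.null(p$congruency_cost)) p$congruency_cost <- max(p$congruency_cost, 5)
  if (!is.null(p$capacity)) p$capacity <- max(p$capacity, 0)
  structure(list(domain = domain, z = z, params = p,
                 linked = sub("_logit$", "", names(sl))),
            class = "responder_policy")
}

#' @export
print.responder_policy <- function(x, ...) {
  cat(sprintf("<responder_policy> domain=%s z=%.2f\n", x$domain, x$z))
  utils::str(x$params, give.attr = FALSE)
  invisible(x)
}

#' Generate questionnaire subscale values for a participant
#'
#' Emits raw subscale values for the parent executive-function rating
#' (9 subdomains whose sum is the global executive composite), and the
#' parent- and teacher-rated wellbeing questionnaire (4 deficit subscales
#' plus prosocial). Values are driven by the participant's latent
#' `everyday_ef` and `sewb` abilities with rater noise; normative score
#' conversion is out of scope, raw composites only.
#'
#' @param profile a [participant_profile()].
#' @param timepoint assessment occasion.
#' @param seed integer seed.
#' @return list with `brief_subscales` (length 9), `sdq_parent`,
#'   `sdq_teacher` (each a named length-5 vector: emotional, conduct,
#'   hyperactivity, peer, prosocial).
#' @export
rate_questionnaires <- function(profile, timepoint, seed = 1L) {
  pol_ef <- make_responder(profile, "everyday_ef", timepoint)
  pol_wb <- make_responder(profile, "sewb", timepoint)
  with_seed(seed, {
    pe <- pol_ef$params
    gec <- stats::rnorm(1, pe$gec_mean, pe$gec_sd)
    w <- stats::runif(pe$n_subscales); w <- w / sum(w)
    brief <- pmax(round(gec * w, 1), 0)

    pw <- pol_wb$params
    sdq_one <- function(total_mean) {
      tot <- max(stats::rnorm(1, total_mean, pw$sdq_sd), 0)
      w <- stats::runif(4); w <- w / sum(w)
      sub <- pmin(round(tot * w), 10)
      pros <- min(max(round(stats::rnorm(1, pw$prosocial_mean, 1.5)), 0), 10)
      stats::setNames(c(sub, pros),
                      c("emotional", "conduct", "hyperactivity", "peer",
                        "prosocial"))
    }
    list(brief_subscales = brief,
         sdq_parent = sdq_one(pw$sdq_parent_mean),
         sdq_teacher = sdq_one(pw$sdq_teacher_mean))
  })
}
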