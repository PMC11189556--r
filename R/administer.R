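#' Administer the assessment battery to a cohort
#'
#' Runs every assessment engine (stop-signal, flanker, digit span, Corsi,
#' card sorting, dimensional change card sort) plus the questionnaire
#' generators for each participant at the requested timepoints, scores the
#' logs, and assembles the long-format outcome table that the analysis
#' modules consume. A stop-signal administration that fails quality control
#' (or yields a degenerate respond rate) contributes a missing value, as it
#' would in the real trial.
#'
#' @param cohort an `ef_cohort`.
#' @param timepoints subset of `c("T1", "T2", "T3")`.
#' @param seed integer master seed; every administration derives its own.
#' @return long data.frame: `id`, `arm`, `classroom`, `timepoint`,
#'   `measure`, `value`, `missing`.
#' @export
administer_battery <- function(cohort, timepoints = c("T1", "T2", "T3"),
                               seed = 1L) {
  stopifnot(inherits(cohort, "ef_cohort"))
  parts <- cohort$participants
  out <- vector("list", nrow(parts) * length(timepoints))
  k <- 0L
  for (i in seq_len(nrow(parts))) {
    prof <- list(demographics = parts[i, , drop = FALSE],
                 ability = cohort$ability[i, , ])
    for (tp in timepoints) {
      k <- k + 1L
      s <- derive_seed(seed, paste0(parts$id[i], "_", tp))
      out[[k]] <- administer_one(prof, tp, s)
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}

administer_one <- function(prof, tp, seed) {
  d <- prof$demographics
  pol <- function(dom) make_responder(prof, dom, tp)

  osari <- score_osari(run_osari(pol("response_inhibition"),
                                 seed = derive_seed(seed, "osari")))
  ant <- score_ant(run_ant(pol("interference_control"),
                           seed = derive_seed(seed, "ant")))
  ds <- score_span(run_digit_span(pol("verbal_wm"),
                                  seed = derive_seed(seed, "ds")))
  corsi <- score_span(run_corsi(pol("visuospatial_wm"),
                                seed = derive_seed(seed, "corsi")))
  wcst <- score_wcst(run_wcst(pol("switching"),
                              seed = derive_seed(seed, "wcst")))
  dccs <- score_dccs(run_dccs(pol("matching"),
                              seed = derive_seed(seed, "dccs")))
  q <- rate_questionnaires(prof, tp, seed = derive_seed(seed, "ratings"))
  rs <- score_ratings(brief_subscales = q$brief_subscales)
  sdq_p <- score_ratings(sdq = q$sdq_parent)$sdq_total
  sdq_t <- score_ratings(sdq = q$sdq_teacher)$sdq_total

  vals <- c(osari_ssrt = if (osari$qc_pass) osari$ssrt else NA_real_,
            ant_conflict = ant$conflict,
            ds_total = ds$total,
            corsi_total = corsi$total,
            wcst_prop_err = wcst$prop_total_errors,
            dccs_adv = dccs$advanced_total,
            brief_gec = rs$brief_gec,
            sdq_parent = sdq_p,
            sdq_teacher = sdq_t)
  data.frame(id = d$id, arm = d$arm, classroom = d$classroom,
             timepoint = tp, measure = names(vals), value = unname(vals),
             missing = is.na(vals), row.names = NULL,
             stringsAsFactors = FALSE)
}
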