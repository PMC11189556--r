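#' Tabulate outcomes by arm and timepoint
#'
#' Mean-and-SD summary of every measure per arm per timepoint, plus the
#' between-group difference in change over each interval (intervention
#' change minus control change) with a normal-theory 95% interval — the
#' shape of the trial's descriptive outcome table.
#'
#' @param table long outcome table (scored).
#' @return list of class `summary_table`: `cells` (measure x arm x
#'   timepoint n/mean/sd) and `change` (per measure x interval difference
#'   and CI).
#' @export
tabulate_outcomes <- function(table) {
  cells <- list()
  for (m in unique(table$measure)) for (a in unique(table$arm)) {
    for (tp in unique(table$timepoint)) {
      v <- table$value[table$measure == m & table$arm == a &
                         table$timepoint == tp & !table$missing]
      cells[[length(cells) + 1]] <-
        data.frame(measure = m, arm = a, timepoint = tp,
                   n = length(v),
                   mean = if (length(v)) mean(v) else NA_real_,
                   sd = if (length(v) > 1) stats::sd(v) else NA_real_)
    }
  }
  cells <- do.call(rbind, cells)

  change <- list()
  wide <- outcomes_wide(table)
  for (m in unique(table$measure)) {
    for (iv in list(c("T1", "T2"), c("T1", "T3"))) {
      c1 <- paste(m, iv[1], sep = "_"); c2 <- paste(m, iv[2], sep = "_")
      if (!all(c(c1, c2) %in% names(wide))) next
      ch <- wide[[c2]] - wide[[c1]]
      ok <- !is.na(ch)
      gi <- wide$arm == "intervention" & ok
      gc <- wide$arm == "control" & ok
      if (sum(gi) < 2 || sum(gc) < 2) {
        change[[length(change) + 1]] <-
          data.frame(measure = m, interval = paste(iv, collapse = "-"),
                     diff = NA_real_, ci_lower = NA_real_,
                     ci_upper = NA_real_, n = sum(ok))
        next
      }
      di <- mean(ch[gi]) - mean(ch[gc])
      se <- sqrt(stats::var(ch[gi]) / sum(gi) + stats::var(ch[gc]) / sum(gc))
      change[[length(change) + 1]] <-
        data.frame(measure = m, interval = paste(iv, collapse = "-"),
                   diff = di, ci_lower = di - 1.96 * se,
                   ci_upper = di + 1.96 * se, n = sum(ok))
    }
  }
  structure(list(cells = cells, change = do.call(rbind, change)),
            class = "summary_table")
}

#' Participant flow accounting
#'
#' Conservation-checked flow counts from eligibility screening through
#' analysis, with a plain-text flow diagram.
#'
#' @param assessed number assessed for eligibility.
#' @param excluded number excluded before randomisation.
#' @param allocation an `allocation_record`.
#' @param withdrawals optional data.frame `id`, `reason`.
#' @return list of class `flow_counts`.
#' @export
consort_flow <- function(assessed, excluded, allocation, withdrawals = NULL) {
  enrolled <- assessed - excluded
  if (enrolled != nrow(allocation)) {
    stop_config("flow mismatch: %d enrolled but %d randomised",
                enrolled, nrow(allocation))
  }
  rand <- table(allocation$arm)
  withdrawn <- rep(0L, length(rand))
  if (!is.null(withdrawals) && nrow(withdrawals)) {
    orphans <- setdiff(withdrawals$id, allocation$id)
    if (length(orphans)) {
      stop_config("withdrawal ids not in allocation: %s",
                  paste(orphans, collapse = ", "))
    }
    warm <- allocation$arm[match(withdrawals$id, allocation$id)]
    wt <- table(factor(warm, levels = names(rand)))
    withdrawn <- withdrawn + as.integer(wt)
  }
  analysed <- as.integer(rand) - withdrawn
  out <- structure(list(assessed = assessed, excluded = excluded,
                        enrolled = enrolled,
                        randomised = as.integer(rand),
                        arms = names(rand),
                        withdrawn = withdrawn, analysed = analysed),
                   class = "flow_counts")
  out
}

#' @export
print.flow_counts <- function(x, ...) {
  cat(sprintf("Assessed for eligibility: %d\n", x$assessed))
  cat(sprintf("  |- excluded: %d\n", x$excluded))
  cat(sprintf("Enrolled & randomised: %d\n", x$enrolled))
  for (i in seq_along(x$arms)) {
    cat(sprintf("  |- %s: randomised %d, withdrawn %d, analysed %d\n",
                x$arms[i], x$randomised[i], x$withdrawn[i], x$analysed[i]))
  }
  invisible(x)
}

#' Configuration for a full pipeline run
#'
#' @param cohort a [cohort_config()] (its seed is overridden by the
#'   pipeline's derived stage seed).
#' @param missingness a [missingness_spec()].
#' @param family,interval analysis family and interval for the ladder.
#' @param mcmc an [mcmc_config()].
#' @param fit_ladder fit all four models (TRUE) or only Model 2 (FALSE,
#'   faster; still supports the Bayes factor).
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            missingness = missingness_spec(),
                            family = "inhibitory", interval = "t1t2",
                            mcmc = mcmc_config(), fit_ladder = FALSE,
                            seed = 1L) {
  structure(list(cohort = cohort, missingness = missingness,
                 family = family, interval = interval, mcmc = mcmc,
                 fit_ladder = fit_ladder, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full simulated trial pipeline
#'
#' simulate cohort -> randomise (block + balance check) -> administer the
#' battery at the three occasions -> apply missingness -> summarise
#' missingness -> impute (single completed set) -> tabulate -> fit the
#' latent change score model(s) -> Bayes factor for the arm effect ->
#' compliance and sensitivity analyses. Every stage draws from a seed
#' derived from the master seed and the stage name, logged in
#' `stage_seeds`; a failing stage aborts with its name.
#'
#' @param config a [pipeline_config()].
#' @return list of class `trial_report` with every intermediate artifact.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- list()
  stage <- function(name, fun) {
    s <- derive_seed(config$seed, name)
    seeds[[name]] <<- s
    tryCatch(fun(s), error = function(e) {
      stop_config("pipeline stage '%s' failed (seed %d): %s",
                  name, s, conditionMessage(e))
    })
  }
  cc <- config$cohort
  cohort <- stage("cohort", function(s) {
    cc$seed <- s
    generate_cohort(cc)
  })
  alloc <- stage("randomise", function(s) {
    a <- block_randomise(cohort$participants$id, seed = s)
    balance_check_and_rerandomise(a, cohort$participants, seed = s)
  })
  # the simulated arms follow the cohort's generative allocation; the
  # allocation record documents the procedure on the same ids
  scored <- stage("battery", function(s)
    administer_battery(cohort, seed = s))
  ms <- config$missingness
  observed <- stage("missingness", function(s) {
    ms$seed <- s
    apply_missingness(scored, ms, covariates = cohort$participants)
  })
  miss_summary <- summarise_missingness(
    observed, covariates = cohort$participants[, c("id", "age", "iq")])
  completed <- stage("impute", function(s) {
    wide <- outcomes_wide(observed, cohort$participants[
      , c("id", "age", "iq", "ses_index", "motivation", "family_functioning")])
    imp <- impute_chained(wide,
                          auxiliaries = c("age", "iq", "ses_index",
                                          "motivation", "family_functioning"),
                          seed = s)
    long_from_wide(imp, observed)
  })
  summary_table <- tabulate_outcomes(completed)
  lcs_data <- prepare_lcs_data(completed,
                               lcs_spec(config$family, config$interval, 2L),
                               cohort$participants)
  bf <- stage("bayes_factor", function(s)
    bayes_factor_group_effect(lcs_data, config$family, config$interval,
                              mcmc = config$mcmc, seed = s))
  ladder <- if (config$fit_ladder) {
    stage("ladder", function(s)
      fit_lcs_ladder(lcs_data, config$family, config$interval,
                     mcmc = config$mcmc, seed = s))
  } else NULL
  sessions <- stage("adherence", function(s) simulate_sessions(cohort, s))
  compliance <- classify_compliance(
    stats::setNames(sessions$sessions_completed, sessions$id))
  sens <- sensitivity_suite(completed, compliance, cohort$participants)
  icc <- icc_by_cluster(scored, measures = "ant_conflict")
  # flow is accounted on the cohort's actual arms; `alloc` documents the
  # randomisation procedure on the same ids
  arm_record <- data.frame(id = cohort$participants$id,
                           arm = cohort$participants$arm,
                           block = NA_integer_, blinded = FALSE)
  flow <- consort_flow(nrow(cohort$participants), 0L, arm_record)
  structure(list(config = config, stage_seeds = seeds, cohort = cohort,
                 allocation = alloc, scored = scored, observed = observed,
                 missingness = miss_summary, completed = completed,
                 summary_table = summary_table, bf = bf, ladder = ladder,
                 sessions = sessions, compliance = compliance,
                 sensitivity = sens, icc = icc, flow = flow),
            class = "trial_report")
}

# push imputed wide values back into the long table
long_from_wide <- function(wide, long) {
  out <- long
  for (i in seq_len(nrow(out))) {
    if (out$missing[i]) {
      col <- paste(out$measure[i], out$timepoint[i], sep = "_")
      if (col %in% names(wide)) {
        v <- wide[[col]][match(out$id[i], wide$id)]
        out$value[i] <- v
        out$missing[i] <- is.na(v)
      }
    }
  }
  out
}

#' @export
print.trial_report <- function(x, ...) {
  cat("<trial_report>\n")
  print(x$flow)
  cat(sprintf("Mean sessions completed: %.1f (%.0f%% compliers)\n",
              attr(x$compliance, "mean_sessions"),
              100 * attr(x$compliance, "prop_compliers")))
  cat(sprintf("Arm effect on %s change (%s): BF10 = %.2f, BF01 = %.2f -> %s\n",
              x$config$family, x$config$interval,
              x$bf$bf10, x$bf$bf01,
              switch(x$bf$evidence,
                     H1 = "evidence for a group effect (BF10 >= 3)",
                     H0 = "evidence for the null (BF01 >= 3)",
                     "inconclusive")))
  invisible(x)
}

#' Serialize a trial report bundle
#'
#' Writes the machine-readable artifacts of a pipeline run into a
#' directory: outcome tables as CSV, allocation as CSV, stage seeds,
#' fit summaries and Bayes factor as JSON.
#'
#' @param report a `trial_report`.
#' @param dir output directory (created if needed).
#' @export
write_report_bundle <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_outcomes_csv(report$observed, file.path(dir, "outcomes_observed.csv"))
  write_outcomes_csv(report$completed, file.path(dir, "outcomes_completed.csv"))
  utils::write.csv(report$allocation, file.path(dir, "allocation.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$stage_seeds, file.path(dir, "stage_seeds.json"),
                       auto_unbox = TRUE)
  jsonlite::write_json(list(bf10 = report$bf$bf10, bf01 = report$bf$bf01,
                            evidence = report$bf$evidence,
                            parameter = report$bf$parameter),
                       file.path(dir, "bayes_factor.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$summary_table$cells,
                       file.path(dir, "summary_cells.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
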