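#' Intra-class correlation by classroom
#'
#' One-way random-effects ICC per measure and timepoint, estimated from
#' the between/within mean squares (Searle's formula with the average
#' cluster-size correction for unbalanced designs), floored at zero.
#' Reported at each timepoint to indicate relative variability between
#' and within classrooms.
#'
#' @param table long outcome table with a `classroom` column.
#' @param measures subset of measures (default: all present).
#' @return data.frame `measure`, `timepoint`, `icc`, `n`, `n_clusters`,
#'   `degenerate` (TRUE when all values are identical).
#' @export
icc_by_cluster <- function(table, measures = NULL) {
  measures <- measures %||% unique(table$measure)
  out <- list()
  for (m in measures) for (tp in unique(table$timepoint)) {
    d <- table[table$measure == m & table$timepoint == tp & !table$missing, ]
    if (!nrow(d)) next
    k <- length(unique(d$classroom))
    if (k < 2) stop_config("ICC needs at least two clusters")
    if (stats::var(d$value) == 0) {
      out[[length(out) + 1]] <- data.frame(measure = m, timepoint = tp,
                                           icc = NA_real_, n = nrow(d),
                                           n_clusters = k, degenerate = TRUE)
      next
    }
    fit <- stats::aov(value ~ classroom, data = d)
    ms <- summary(fit)[[1]][["Mean Sq"]]
    ns <- table(d$classroom)
    n0 <- (sum(ns) - sum(ns^2) / sum(ns)) / (k - 1)
    icc <- (ms[1] - ms[2]) / (ms[1] + (n0 - 1) * ms[2])
    out[[length(out) + 1]] <- data.frame(measure = m, timepoint = tp,
                                         icc = max(icc, 0), n = nrow(d),
                                         n_clusters = k, degenerate = FALSE)
  }
  do.call(rbind, out)
}

#' Family-wise error control
#'
#' Step-down Holm adjustment (default) over a family of p-values, with
#' reject flags at the supplied level. A thin, auditable wrapper around
#' [stats::p.adjust()].
#'
#' @param p numeric p-values.
#' @param method any [stats::p.adjust.methods] entry; default `"holm"`.
#' @param alpha rejection level.
#' @return data.frame `p`, `p_adjusted`, `reject`.
#' @export
fwer_adjust <- function(p, method = "holm", alpha = 0.05) {
  if (!length(p)) stop_config("empty family of tests")
  adj <- stats::p.adjust(p, method = method)
  data.frame(p = p, p_adjusted = adj, reject = adj < alpha)
}

#' Thorndike Case 2 range-restriction correction
#'
#' Corrects a correlation observed under direct range restriction on one
#' variable: `r_c = r * u / sqrt(1 - r^2 + r^2 * u^2)` where `u` is the
#' ratio of unrestricted to restricted SD. The result is clipped to the
#' open interval (-1, 1).
#'
#' @param r restricted-sample correlation, `|r| < 1`.
#' @param sd_ratio `u > 0`, unrestricted SD divided by restricted SD.
#' @return corrected correlation.
#' @export
thorndike_case2 <- function(r, sd_ratio) {
  if (abs(r) >= 1) stop_config("|r| must be < 1")
  if (sd_ratio <= 0) stop_config("sd_ratio must be positive")
  rc <- r * sd_ratio / sqrt(1 - r^2 + r^2 * sd_ratio^2)
  max(min(rc, 1 - 1e-12), -1 + 1e-12)
}

#' Compliance sensitivity analyses
#'
#' (a) Complier vs non-complier comparisons (Welch t-tests) on every
#' outcome at baseline and post-intervention; (b) logistic regression of
#' compliance on the five demographic factors (gender, general cognition,
#' motivation, SES, family functioning); (c) Pearson correlation between
#' sessions completed and pre-to-post change in the primary outcome, with
#' the conventional df = n - 2.
#'
#' @param table long outcome table (scored).
#' @param compliance output of [classify_compliance()] with `id`.
#' @param participants participants data.frame.
#' @param primary_measure measure used for the adherence correlation.
#' @return list `group_comparisons`, `logistic` (coefficient table),
#'   `adherence_cor` (`r`, `df`, `p`), `underpowered` flag.
#' @export
sensitivity_suite <- function(table, compliance, participants,
                              primary_measure = "osari_ssrt") {
  comp <- merge(compliance, participants, by = "id")
  underpowered <- min(table(compliance$label)) < 3
  if (underpowered) {
    warning("fewer than 3 participants in a compliance group; ",
            "comparisons are underpowered but still computed")
  }
  rows <- list()
  for (m in unique(table$measure)) for (tp in c("T1", "T2")) {
    d <- table[table$measure == m & table$timepoint == tp & !table$missing, ]
    d <- merge(d, compliance[, c("id", "label")], by = "id")
    if (length(unique(d$label)) < 2 || min(table(d$label)) < 2) next
    tt <- stats::t.test(value ~ label, data = d)
    rows[[length(rows) + 1]] <- data.frame(measure = m, timepoint = tp,
                                           statistic = unname(tt$statistic),
                                           p = tt$p.value)
  }
  group_comparisons <- if (length(rows)) do.call(rbind, rows) else NULL

  comp$complier <- as.integer(comp$label == "complier")
  comp$gender_male <- as.integer(comp$gender == "male")
  lg <- tryCatch({
    fit <- stats::glm(complier ~ gender_male + iq + motivation + ses_index +
                        family_functioning,
                      data = comp, family = stats::binomial())
    as.data.frame(summary(fit)$coefficients)
  }, error = function(e) NULL, warning = function(w) {
    fit <- suppressWarnings(
      stats::glm(complier ~ gender_male + iq + motivation + ses_index +
                   family_functioning,
                 data = comp, family = stats::binomial()))
    as.data.frame(summary(fit)$coefficients)
  })

  t1 <- table[table$measure == primary_measure & table$timepoint == "T1", ]
  t2 <- table[table$measure == primary_measure & table$timepoint == "T2", ]
  chg <- merge(t1[, c("id", "value")], t2[, c("id", "value")], by = "id",
               suffixes = c("_t1", "_t2"))
  chg$change <- chg$value_t2 - chg$value_t1
  chg <- merge(chg, compliance[, c("id", "sessions_completed")], by = "id")
  chg <- chg[stats::complete.cases(chg), ]
  n <- nrow(chg)
  if (n >= 3 && stats::sd(chg$change) > 0 &&
      stats::sd(chg$sessions_completed) > 0) {
    r <- stats::cor(chg$sessions_completed, chg$change)
    df <- n - 2L
    tstat <- r * sqrt(df / (1 - r^2))
    pv <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(tstat), df)
    adherence_cor <- list(r = r, df = df, p = pv, n = n)
  } else {
    adherence_cor <- list(r = NA_real_, df = max(n - 2L, 0L), p = NA_real_,
                          n = n)
  }
  list(group_comparisons = group_comparisons, logistic = lg,
       adherence_cor = adherence_cor, underpowered = underpowered)
}
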