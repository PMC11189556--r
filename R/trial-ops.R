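#' Blocked 1:1 randomisation
#'
#' Computer-generated allocation with a 1:1 ratio within permuted blocks of
#' 10: every complete block contains exactly five participants per arm; a
#' final partial block is balanced to within one. The returned record
#' carries a blinded flag — analysis code should only see the blinded view
#' until [unblind_allocation()] is called.
#'
#' @param ids participant identifiers, in enrolment order.
#' @param block_size even block size (default 10).
#' @param seed integer seed; allocation is deterministic given ids + seed.
#' @return data.frame of class `allocation_record`: `id`, `arm`, `block`,
#'   `blinded` (logical), with attribute `seed`.
#' @export
block_randomise <- function(ids, block_size = 10L, seed = 1L) {
  if (!length(ids)) stop_config("ids must be non-empty")
  if (block_size %% 2L != 0L) stop_config("block size must be even for 1:1 allocation")
  with_seed(seed, {
    n <- length(ids)
    arms <- character(0)
    remaining <- n
    block <- integer(0)
    b <- 0L
    while (remaining > 0L) {
      b <- b + 1L
      k <- min(block_size, remaining)
      half <- block_size %/% 2L
      if (k == block_size) {
        blk <- sample(rep(c("control", "intervention"), each = half))
      } else {
        lo <- floor(k / 2); hi <- ceiling(k / 2)
        counts <- sample(c(lo, hi))   # which arm gets the extra slot
        blk <- sample(rep(c("control", "intervention"), counts))
      }
      arms <- c(arms, blk)
      block <- c(block, rep(b, k))
      remaining <- remaining - k
    }
    rec <- data.frame(id = ids, arm = arms, block = block, blinded = TRUE,
                      stringsAsFactors = FALSE)
    attr(rec, "seed") <- seed
    class(rec) <- c("allocation_record", class(rec))
    rec
  })
}

#' Reveal arm labels on an allocation record
#'
#' Unblinding is explicit and logged via a message; downstream summaries
#' that require arm identity should accept only unblinded records.
#'
#' @param alloc an `allocation_record`.
#' @param reason character, recorded with the unblinding event.
#' @return the record with `blinded = FALSE` and an `unblind_log` attribute.
#' @export
unblind_allocation <- function(alloc, reason = "analysis") {
  alloc$blinded <- FALSE
  attr(alloc, "unblind_log") <- data.frame(time = format(Sys.time()),
                                           reason = reason)
  message("allocation unblinded: ", reason)
  alloc
}

#' Re-randomise until demographic balance criteria are met
#'
#' Mirrors the trial's interim balance check: after allocation, the arms
#' are compared on age (absolute standardized difference) and gender
#' (proportion difference); if either exceeds its threshold the allocation
#' is regenerated with a fresh derived seed until balance is achieved or
#' the iteration cap is hit.
#'
#' @param alloc an `allocation_record`.
#' @param demographics data.frame with `id`, `age`, `gender`.
#' @param age_z_max maximum |standardized age difference| (default 0.2).
#' @param gender_diff_max maximum |proportion difference| (default 0.15).
#' @param seed integer seed for re-randomisation attempts.
#' @param max_iter iteration cap.
#' @return a balanced `allocation_record` with attribute `n_rerandomised`.
#' @export
balance_check_and_rerandomise <- function(alloc, demographics,
                                          age_z_max = 0.2,
                                          gender_diff_max = 0.15,
                                          seed = 1L, max_iter = 1000L) {
  stopifnot(all(c("id", "age", "gender") %in% names(demographics)))
  balanced <- function(a) {
    d <- merge(a[, c("id", "arm")],
               demographics[, c("id", "age", "gender")], by = "id")
    age_c <- d$age[d$arm == "control"]; age_i <- d$age[d$arm == "intervention"]
    sd_pool <- sqrt((stats::var(age_c) + stats::var(age_i)) / 2)
    z <- abs(mean(age_c) - mean(age_i)) / sd_pool
    pm <- abs(mean(d$gender[d$arm == "control"] == "male") -
                mean(d$gender[d$arm == "intervention"] == "male"))
    z <= age_z_max && pm <= gender_diff_max
  }
  it <- 0L
  while (!balanced(alloc)) {
    it <- it + 1L
    if (it > max_iter) {
      stop_config(paste("balance criteria not attainable in %d re-randomisations",
                        "(age_z_max=%.3g, gender_diff_max=%.3g)"),
                  max_iter, age_z_max, gender_diff_max)
    }
    alloc <- block_randomise(alloc$id, seed = derive_seed(seed, paste0("rr", it)))
  }
  attr(alloc, "n_rerandomised") <- it
  alloc
}

#' Two-sample t-test power analysis
#'
#' Power under the noncentral-t distribution for a two-sided two-sample
#' t-test with equal group sizes. Solves for whichever of `n_per_group` or
#' `power` is missing; solving for n returns the smallest integer per
#' group meeting the target power.
#'
#' @param d standardized effect size (>= 0).
#' @param alpha two-sided significance level.
#' @param power target power (when solving for n).
#' @param n_per_group group size (when solving for power).
#' @param solve_for `"n"` or `"power"`.
#' @return list with `d`, `alpha`, `n_per_group`, `n_total`, `power`.
#' @export
power_two_sample <- function(d, alpha = 0.05, power = NULL,
                             n_per_group = NULL,
                             solve_for = c("n", "power")) {
  solve_for <- match.arg(solve_for)
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  if (d < 0) stop_config("d must be non-negative")
  pow_at <- function(n) {
    df <- 2 * n - 2
    tc <- stats::qt(1 - alpha / 2, df)
    ncp <- d * sqrt(n / 2)
    stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp)
  }
  if (solve_for == "power") {
    if (is.null(n_per_group)) stop_config("n_per_group required to solve for power")
    power <- pow_at(n_per_group)
  } else {
    if (is.null(power)) stop_config("power required to solve for n")
    if (power <= 0 || power >= 1) stop_config("power must be in (0, 1)")
    if (d == 0) stop_config("no finite sample size achieves power > alpha at d = 0")
    n <- 2L
    while (pow_at(n) < power) n <- n + 1L
    n_per_group <- n
    power <- pow_at(n)
  }
  list(d = d, alpha = alpha, n_per_group = as.integer(n_per_group),
       n_total = 2L * as.integer(n_per_group), power = power)
}

#' Classify training compliance
#'
#' Compliers completed at least 16 of the 20 scheduled training sessions.
#'
#' @param session_counts named or plain integer vector in `[0, 20]`.
#' @param threshold complier cut-off (16 sessions).
#' @return data.frame `sessions_completed`, `label`, with attribute
#'   `mean_sessions`.
#' @export
classify_compliance <- function(session_counts, threshold = 16L) {
  if (any(session_counts < 0 | session_counts > 20)) {
    stop_config("session counts must be in [0, 20]")
  }
  lab <- ifelse(session_counts >= threshold, "complier", "non-complier")
  out <- data.frame(id = names(session_counts) %||%
                      as.character(seq_along(session_counts)),
                    sessions_completed = as.integer(session_counts),
                    label = lab, stringsAsFactors = FALSE)
  attr(out, "mean_sessions") <- mean(session_counts)
  attr(out, "prop_compliers") <- mean(lab == "complier")
  out
}

#' Summarise missingness in an outcome table
#'
#' Per measure and timepoint missing fractions, flags for measures
#' exceeding the 20% retention threshold, and a covariate-comparison test
#' of the missing-completely-at-random assumption: for each measure the
#' missingness indicator is regressed (logistic) on the supplied
#' covariates and the likelihood-ratio test against the null model is
#' reported; under MCAR these p-values are uniform.
#'
#' @param table long outcome table.
#' @param covariates optional data.frame (`id` + numeric covariates, e.g.
#'   age and IQ) for the MCAR test.
#' @return list `fractions` (measure x timepoint), `flagged` (measures over
#'   20% at any timepoint), `mcar` (per-measure LR test data.frame or NULL).
#' @export
summarise_missingness <- function(table, covariates = NULL) {
  tp <- sort(unique(table$timepoint))
  meas <- unique(table$measure)
  fr <- sapply(tp, function(t) sapply(meas, function(m) {
    i <- table$measure == m & table$timepoint == t
    if (!any(i)) NA_real_ else mean(table$missing[i])
  }))
  fr <- matrix(fr, nrow = length(meas), dimnames = list(meas, tp))
  flagged <- rownames(fr)[apply(fr > 0.20, 1, any, na.rm = TRUE)]
  mcar <- NULL
  if (!is.null(covariates)) {
    covs <- setdiff(names(covariates), "id")
    res <- lapply(meas, function(m) {
      sub <- table[table$measure == m, c("id", "missing")]
      d <- merge(sub, covariates, by = "id")
      if (length(unique(d$missing)) < 2) {
        return(data.frame(measure = m, statistic = NA_real_,
                          df = NA_integer_, p = NA_real_))
      }
      f1 <- stats::as.formula(paste("missing ~", paste(covs, collapse = "+")))
      m1 <- stats::glm(f1, data = d, family = stats::binomial())
      m0 <- stats::glm(missing ~ 1, data = d, family = stats::binomial())
      lr <- as.numeric(2 * (stats::logLik(m1) - stats::logLik(m0)))
      df <- length(covs)
      data.frame(measure = m, statistic = lr, df = df,
                 p = stats::pchisq(lr, df, lower.tail = FALSE))
    })
    mcar <- do.call(rbind, res)
  }
  list(fractions = fr, flagged = flagged, mcar = mcar)
}

# Bayesian-draw normal regression imputation for one variable (the standard
# fully-conditional-specification building block)
impute_norm_draw <- function(y, X) {
  obs <- !is.na(y)
  Xo <- cbind(1, X[obs, , drop = FALSE])
  yo <- y[obs]
  # ridge escalates until the (possibly near-singular) normal equations
  # factorize; with p close to n this behaves like a light ridge regression
  lam <- 1e-6 * (mean(diag(crossprod(Xo))) + 1)
  repeat {
    XtX <- crossprod(Xo) + diag(lam, ncol(Xo))
    Vi <- tryCatch(chol2inv(chol(XtX)), error = function(e) NULL)
    if (!is.null(Vi)) break
    lam <- lam * 100
  }
  bhat <- Vi %*% crossprod(Xo, yo)
  res <- yo - Xo %*% bhat
  df <- max(length(yo) - ncol(Xo), 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  L <- tryCatch(chol(Vi), error = function(e) chol(Vi + diag(1e-8, ncol(Vi))))
  beta <- bhat + sqrt(sigma2) * t(L) %*% stats::rnorm(ncol(Xo))
  Xm <- cbind(1, X[!obs, , drop = FALSE])
  as.numeric(Xm %*% beta + stats::rnorm(sum(!obs), 0, sqrt(sigma2)))
}

#' Multiple imputation by chained equations
#'
#' Fully-conditional-specification loop over the incomplete numeric
#' columns of a wide data.frame: each incomplete variable is regressed on
#' all other variables plus the auxiliaries with Bayesian parameter draws,
#' cycling `max_iterations` times per imputed set. Observed cells are never
#' altered. The trial's analysis used a single completed set (m = 1);
#' `n_imputations > 1` returns a list of completed sets for pooling.
#'
#' @param data wide data.frame; columns to impute must be numeric.
#' @param auxiliaries character, names of complete auxiliary columns (e.g.
#'   demographics) used as predictors but never imputed.
#' @param n_imputations number of completed data sets (m).
#' @param max_iterations chained-equation cycles per set.
#' @param seed integer seed.
#' @return a completed data.frame (m = 1) or list of them (m > 1), with an
#'   `audit` attribute logging imputed counts per variable.
#' @export
impute_chained <- function(data, auxiliaries = character(0),
                           n_imputations = 1L, max_iterations = 10L,
                           seed = 1L) {
  num_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  targets <- num_cols[vapply(num_cols, function(v) anyNA(data[[v]]), logical(1))]
  targets <- setdiff(targets, auxiliaries)
  all_missing <- targets[vapply(targets, function(v) all(is.na(data[[v]])),
                                logical(1))]
  if (length(all_missing)) {
    stop_config("variable(s) 100%% missing, cannot impute: %s",
                paste(all_missing, collapse = ", "))
  }
  if (!length(targets)) {
    attr(data, "audit") <- data.frame(variable = character(0),
                                      n_imputed = integer(0))
    return(data)
  }
  preds <- unique(c(setdiff(num_cols, character(0)), auxiliaries))
  preds <- preds[vapply(preds, function(v) is.numeric(data[[v]]), logical(1))]
  one_set <- function(s) {
    with_seed(s, {
      d <- data
      # initialise missing cells by resampling observed values
      for (v in targets) {
        miss <- is.na(d[[v]])
        d[[v]][miss] <- sample(d[[v]][!miss], sum(miss), replace = TRUE)
      }
      for (it in seq_len(max_iterations)) {
        for (v in targets) {
          others <- setdiff(preds, v)
          X <- as.matrix(d[, others, drop = FALSE])
          y <- data[[v]]                       # original missingness pattern
          d[[v]][is.na(y)] <- impute_norm_draw(
            replace(d[[v]], is.na(y), NA), X)
        }
      }
      audit <- data.frame(variable = targets,
                          n_imputed = vapply(targets, function(v)
                            sum(is.na(data[[v]])), integer(1)))
      attr(d, "audit") <- audit
      d
    })
  }
  if (n_imputations == 1L) {
    one_set(seed)
  } else {
    lapply(seq_len(n_imputations), function(m)
      one_set(derive_seed(seed, paste0("imp", m))))
  }
}

#' Pivot a long outcome table to wide measure-by-timepoint columns
#'
#' Column names take the form `measure_T1` etc.; participant covariates
#' can be merged in for use as imputation auxiliaries.
#'
#' @param table long outcome table.
#' @param participants optional participants data.frame to merge by `id`.
#' @return wide data.frame, one row per participant.
#' @export
outcomes_wide <- function(table, participants = NULL) {
  table$col <- paste(table$measure, table$timepoint, sep = "_")
  w <- stats::reshape(table[, c("id", "col", "value")],
                      idvar = "id", timevar = "col", direction = "wide")
  names(w) <- sub("^value\\.", "", names(w))
  ids <- unique(table[, c("id", "arm", "classroom")])
  w <- merge(ids, w, by = "id")
  if (!is.null(participants)) {
    w <- merge(w, participants, by = "id",
               suffixes = c("", ".participant"))
  }
  w
}
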