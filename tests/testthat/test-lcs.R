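test_that("the invariance ladder frees parameters in the stated order", {
  n_free <- sapply(1:4, function(m)
    nrow(build_lcs_model(lcs_spec("inhibitory", "t1t2", m))))
  expect_equal(n_free[2] - n_free[1], 2L)   # two change intercepts
  expect_equal(n_free[3] - n_free[2], 4L)   # four crossed/lagged regressions
  expect_equal(n_free[4] - n_free[3], 1L)   # the coupled-change regression
  m1 <- build_lcs_model(lcs_spec("working_memory", "t1t3", 1))
  expect_false(any(m1$group_specific))      # fully invariant over groups
  expect_error(lcs_spec("inhibitory", "t1t2", 5), "model_id")
})

test_that("model-implied moments match simulation at scale", {
  spec <- lcs_spec("inhibitory", "t1t2", 2, covariates = FALSE)
  par <- lcs_true_params(spec, c(dN = 0.4))
  dat <- simulate_lcs_data(spec, par, n_per_group = 30000, seed = 1)
  for (g in 0:1) {
    imp <- lcs_implied(par, g, covariates = FALSE)
    Yg <- dat$Y[dat$group == g, ]
    expect_lt(max(abs(colMeans(Yg) - imp$mu0)), 0.03)
    expect_lt(max(abs(cov(Yg) - imp$Sigma)), 0.05)
  }
  # the arm offset shifts only the occasion-2 means
  i0 <- lcs_implied(par, 0, covariates = FALSE)
  i1 <- lcs_implied(par, 1, covariates = FALSE)
  expect_equal(i0$mu0[1:4], i1$mu0[1:4])
  expect_false(isTRUE(all.equal(i0$mu0[5:6], i1$mu0[5:6])))
})

test_that("posterior sampling recovers generating parameters", {
  spec <- lcs_spec("inhibitory", "t1t2", 2)
  truth <- lcs_true_params(spec, c(dN = 0.5, dF = 0))
  dat <- simulate_lcs_data(spec, truth, n_per_group = 200, seed = 11)
  fit <- fit_lcs(spec, dat, seed = 2)
  expect_true(fit$converged)
  expect_s3_class(fit, "lcs_fit")
  key <- c(aN = 0.2, dN = 0.5, cNF = 0.3, lamN = 0.7, lamF = 0.7)
  for (p in names(key)) {
    row <- fit$summary[fit$summary$parameter == p, ]
    expect_lt(abs(row$mean - key[[p]]), 4 * row$sd)
  }
  expect_true(all(fit$summary$ci_lower <= fit$summary$mean &
                    fit$summary$mean <= fit$summary$ci_upper))
  expect_gte(fit$ppp, 0); expect_lte(fit$ppp, 1)
})

test_that("degenerate inputs raise specification errors", {
  spec <- lcs_spec("inhibitory", "t1t2", 1)
  dat <- simulate_lcs_data(spec, n_per_group = 30, seed = 1)
  dat$Y[, 2] <- 1
  expect_error(fit_lcs(spec, dat), "zero-variance")
})

test_that("leave-one-out comparison is antisymmetric with zero self-difference", {
  spec <- lcs_spec("inhibitory", "t1t2", 1)
  dat <- simulate_lcs_data(spec, n_per_group = 60, seed = 3)
  fit1 <- suppressWarnings(fit_lcs(spec, dat, seed = 4))
  expect_equal(compare_loo(fit1, fit1)$loo_diff, 0)
  spec2 <- lcs_spec("inhibitory", "t1t2", 2)
  fit2 <- suppressWarnings(fit_lcs(spec2, dat, seed = 5))
  ab <- compare_loo(fit1, fit2)
  ba <- compare_loo(fit2, fit1)
  expect_equal(ab$loo_diff, -ba$loo_diff)
  expect_equal(ab$se, ba$se)
  dat2 <- simulate_lcs_data(spec, n_per_group = 50, seed = 9)
  fit3 <- suppressWarnings(fit_lcs(spec, dat2, seed = 6))
  expect_error(compare_loo(fit1, fit3), "identical observation")
})

test_that("leave-one-out favours the generating model over a misspecified one", {
  # model-recovery: data carry a strong arm effect; Model 1 (which cannot
  # represent it) must lose to Model 2 decisively at n = 400
  spec2 <- lcs_spec("inhibitory", "t1t2", 2)
  wins <- sapply(1:3, function(s) {
    dat <- simulate_lcs_data(spec2, lcs_true_params(spec2, c(dN = 0.8)),
                             n_per_group = 200, seed = 100 + s)
    f2 <- suppressWarnings(fit_lcs(spec2, dat, seed = s))
    f1 <- suppressWarnings(fit_lcs(lcs_spec("inhibitory", "t1t2", 1), dat,
                                   seed = s))
    cmp <- compare_loo(f2, f1)
    cmp$loo_diff > 2 * cmp$se
  })
  expect_gte(mean(wins), 2 / 3)
})

test_that("Bayes factors are reciprocal and track the generating effect", {
  spec <- lcs_spec("inhibitory", "t1t2", 2)
  dat_null <- simulate_lcs_data(spec, lcs_true_params(spec, c(dN = 0)),
                                n_per_group = 200, seed = 21)
  bf0 <- suppressWarnings(bayes_factor_group_effect(dat_null, seed = 1))
  expect_equal(bf0$bf10 * bf0$bf01, 1)
  expect_gte(bf0$bf01, 3)
  expect_equal(bf0$evidence, "H0")

  dat_eff <- simulate_lcs_data(spec, lcs_true_params(spec, c(dN = 0.8)),
                               n_per_group = 200, seed = 22)
  bf1 <- suppressWarnings(bayes_factor_group_effect(dat_eff, seed = 1))
  expect_gte(bf1$bf10, 3)
  expect_equal(bf1$evidence, "H1")
})

test_that("ICC estimation flags degenerate clusters and needs two of them", {
  d <- data.frame(id = 1:40, measure = "m", timepoint = "T1",
                  value = 5, missing = FALSE,
                  classroom = rep(c("A", "B"), 20))
  out <- icc_by_cluster(d, "m")
  expect_true(out$degenerate)
  d1 <- d; d1$classroom <- "A"; d1$value <- rnorm(40)
  expect_error(icc_by_cluster(d1, "m"), "two clusters")
})

test_that("Holm adjustment matches its closed form", {
  out <- fwer_adjust(c(0.01, 0.04))
  expect_equal(out$p_adjusted, c(0.02, 0.04))
  expect_equal(fwer_adjust(0.03)$p_adjusted, 0.03)
  all_one <- fwer_adjust(rep(1, 5))
  expect_false(any(all_one$reject))
  expect_error(fwer_adjust(numeric(0)), "empty")
})

test_that("range-restriction correction matches its closed form", {
  expect_equal(thorndike_case2(0.5, 2), 1 / sqrt(1.75), tolerance = 1e-12)
  expect_equal(round(thorndike_case2(0.5, 2), 3), 0.756)
  expect_equal(thorndike_case2(0, 5), 0)
  expect_equal(thorndike_case2(0.42, 1), 0.42)
  expect_error(thorndike_case2(1, 2), "< 1")
  expect_error(thorndike_case2(0.5, 0), "positive")
})

test_that("sensitivity suite reports the n - 2 correlation convention", {
  co <- generate_cohort(cohort_config(seed = 13))
  tab <- administer_battery(co, timepoints = c("T1", "T2"), seed = 13)
  sess <- simulate_sessions(co, seed = 13)
  compl <- classify_compliance(setNames(sess$sessions_completed, sess$id))
  out <- suppressWarnings(
    sensitivity_suite(tab, compl, co$participants))
  n_pairs <- out$adherence_cor$n
  expect_equal(out$adherence_cor$df, n_pairs - 2L)
  expect_true(is.data.frame(out$group_comparisons))
  expect_true(is.data.frame(out$logistic))

  # perfect collinearity: r = 1
  tab2 <- tab[tab$measure == "osari_ssrt", ]
  tab2$value[tab2$timepoint == "T1"] <- 0
  sess_ids <- compl$id
  tab2$value[tab2$timepoint == "T2"] <-
    compl$sessions_completed[match(tab2$id[tab2$timepoint == "T2"], compl$id)]
  tab2$missing <- FALSE
  out2 <- suppressWarnings(sensitivity_suite(tab2, compl, co$participants))
  expect_equal(out2$adherence_cor$r, 1)
})

test_that("complier comparisons reject at the nominal rate under the null", {
  # labels independent of outcomes: calibration of the sensitivity t-tests
  ps <- unlist(lapply(1:60, function(s) {
    set.seed(s)
    n <- 80
    tab <- data.frame(id = sprintf("P%03d", 1:n), arm = "intervention",
                      classroom = "C01", timepoint = "T1", measure = "m",
                      value = rnorm(n), missing = FALSE)
    compl <- classify_compliance(
      setNames(sample(c(10, 18), n, TRUE), tab$id))
    d <- merge(tab, compl[, c("id", "label")], by = "id")
    t.test(value ~ label, data = d)$p.value
  }))
  rej <- mean(ps < 0.05)
  expect_gt(rej, 0.005)
  expect_lt(rej, 0.12)
})
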