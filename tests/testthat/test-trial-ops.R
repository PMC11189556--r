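test_that("blocked randomisation is 5/5 within complete blocks of 10", {
  ids <- sprintf("P%03d", 1:10)
  a <- block_randomise(ids, seed = 1)
  expect_equal(sum(a$arm == "intervention"), 5L)
  expect_equal(sum(a$arm == "control"), 5L)
  expect_true(all(a$blinded))
  expect_error(block_randomise(ids, block_size = 9), "even")
  expect_error(block_randomise(character(0)), "non-empty")
})

test_that("a partial final block is balanced to within one", {
  a <- block_randomise(sprintf("P%03d", 1:115), seed = 3)
  tb <- table(a$arm)
  expect_lte(abs(tb[["control"]] - tb[["intervention"]]), 1L)
  full_blocks <- table(a$block[a$block <= 11], a$arm[a$block <= 11])
  expect_true(all(full_blocks == 5L))
  expect_identical(block_randomise(sprintf("P%03d", 1:115), seed = 3), a)
})

test_that("re-randomisation enforces the demographic balance criteria", {
  set.seed(10)
  demo <- data.frame(id = sprintf("P%03d", 1:60),
                     age = rnorm(60, 7.5, 0.6),
                     gender = sample(c("male", "female"), 60, TRUE))
  a <- block_randomise(demo$id, seed = 1)
  b <- balance_check_and_rerandomise(a, demo, seed = 1)
  d <- merge(b[, c("id", "arm")], demo, by = "id")
  ages <- split(d$age, d$arm)
  z <- abs(mean(ages[[1]]) - mean(ages[[2]])) /
    sqrt((var(ages[[1]]) + var(ages[[2]])) / 2)
  expect_lte(z, 0.2)
  gm <- sapply(split(d$gender == "male", d$arm), mean)
  expect_lte(abs(diff(gm)), 0.15)

  # infinite thresholds accept the first allocation unchanged
  c0 <- balance_check_and_rerandomise(a, demo, age_z_max = Inf,
                                      gender_diff_max = Inf, seed = 1)
  expect_equal(attr(c0, "n_rerandomised"), 0L)
  expect_identical(c0$arm, a$arm)

  # rejection-sampling oracle: adversarial ages that are imbalanced for
  # the first many seeds still end balanced
  demo2 <- demo
  demo2$age <- sort(demo2$age)           # enrolment order confounded with age
  b2 <- balance_check_and_rerandomise(block_randomise(demo2$id, seed = 2),
                                      demo2, seed = 2)
  d2 <- merge(b2[, c("id", "arm")], demo2, by = "id")
  ages2 <- split(d2$age, d2$arm)
  z2 <- abs(mean(ages2[[1]]) - mean(ages2[[2]])) /
    sqrt((var(ages2[[1]]) + var(ages2[[2]])) / 2)
  expect_lte(z2, 0.2)

  expect_error(balance_check_and_rerandomise(a, demo, age_z_max = 1e-9,
                                             gender_diff_max = 1e-9,
                                             seed = 1, max_iter = 5),
               "not attainable")
})

test_that("unblinding is explicit and logged", {
  a <- block_randomise(sprintf("P%02d", 1:10), seed = 1)
  expect_message(u <- unblind_allocation(a, "interim balance check"),
                 "unblinded")
  expect_false(any(u$blinded))
  expect_equal(attr(u, "unblind_log")$reason, "interim balance check")
})

test_that("power analysis reproduces the trial's published sample sizes", {
  m <- power_two_sample(d = 0.5, power = 0.95, solve_for = "n")
  expect_equal(m$n_per_group, 105L)
  expect_equal(m$n_total, 210L)
  l <- power_two_sample(d = 0.8, power = 0.95, solve_for = "n")
  expect_equal(l$n_per_group, 42L)
  expect_equal(l$n_total, 84L)
  p70m <- power_two_sample(d = 0.5, n_per_group = 70, solve_for = "power")
  expect_equal(round(100 * p70m$power, 1), 83.6)
  p70l <- power_two_sample(d = 0.8, n_per_group = 70, solve_for = "power")
  expect_equal(round(100 * p70l$power, 1), 99.7)
})

test_that("power function agrees with the base-R oracle and is monotone", {
  # independent route: stats::power.t.test on a grid (that oracle drops
  # the opposite-tail rejection term, so agreement is to ~1e-3)
  for (d in c(0.3, 0.5, 0.8)) for (n in c(20, 70, 150)) {
    expect_lt(abs(power_two_sample(d = d, n_per_group = n,
                                   solve_for = "power")$power -
                    stats::power.t.test(n = n, delta = d)$power), 2.5e-3)
  }
  pows <- sapply(c(10, 30, 60, 120), function(n)
    power_two_sample(d = 0.4, n_per_group = n, solve_for = "power")$power)
  expect_true(all(diff(pows) > 0))
  pows_d <- sapply(c(0.2, 0.4, 0.6, 0.9), function(d)
    power_two_sample(d = d, n_per_group = 50, solve_for = "power")$power)
  expect_true(all(diff(pows_d) > 0))
})

test_that("null effect gives power equal to alpha; solve-evaluate round-trips", {
  p0 <- power_two_sample(d = 0, n_per_group = 70, solve_for = "power")
  expect_equal(p0$power, 0.05, tolerance = 1e-9)
  expect_error(power_two_sample(d = 0, power = 0.8, solve_for = "n"),
               "no finite")
  for (d in c(0.35, 0.6)) {
    n <- power_two_sample(d = d, power = 0.9, solve_for = "n")$n_per_group
    expect_gte(power_two_sample(d = d, n_per_group = n,
                                solve_for = "power")$power, 0.9)
    expect_lt(power_two_sample(d = d, n_per_group = n - 1,
                               solve_for = "power")$power, 0.9)
  }
})

test_that("compliance threshold sits exactly at 16 sessions", {
  lab <- classify_compliance(c(a = 16, b = 15, c = 20, d = 0))
  expect_equal(lab$label, c("complier", "non-complier", "complier",
                            "non-complier"))
  expect_equal(attr(classify_compliance(rep(20, 5)), "prop_compliers"), 1)
  expect_error(classify_compliance(c(3, 21)), "\\[0, 20\\]")
})

test_that("missingness summary flags measures over the 20% threshold", {
  co <- generate_cohort(cohort_config(seed = 4))
  tab <- administer_battery(co, timepoints = "T1", seed = 4)
  tab$missing <- FALSE; tab$value[is.na(tab$value)] <- 0
  s0 <- summarise_missingness(tab)
  expect_true(all(s0$fractions == 0))
  expect_length(s0$flagged, 0L)

  sp <- missingness_spec(rates = c(ds_total = 0.30), seed = 2)
  tab2 <- apply_missingness(tab, sp)
  s1 <- summarise_missingness(tab2,
                              covariates = co$participants[, c("id", "age", "iq")])
  expect_true("ds_total" %in% s1$flagged)
  expect_gt(s1$fractions["ds_total", "T1"], 0.20)
  expect_true(is.data.frame(s1$mcar))
})

test_that("MCAR covariate test is calibrated under the null", {
  # with truly MCAR missingness the likelihood-ratio p-values reject at
  # about the nominal 5% rate
  ps <- sapply(1:150, function(s) {
    n <- 300
    tab <- data.frame(id = sprintf("P%03d", 1:n), arm = "control",
                      classroom = "C01", timepoint = "T1",
                      measure = "ds_total", value = rnorm(n),
                      missing = FALSE, stringsAsFactors = FALSE)
    cov <- data.frame(id = tab$id, age = rnorm(n, 7.5), iq = rnorm(n, 100, 15))
    sp <- missingness_spec(rates = c(ds_total = 0.3), seed = s)
    out <- apply_missingness(tab, sp)
    summarise_missingness(out, cov)$mcar$p[1]
  })
  rej <- mean(ps < 0.05)
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.11)
})

test_that("imputation leaves complete data and observed cells untouched", {
  set.seed(1)
  d <- data.frame(id = 1:50, x = rnorm(50), y = rnorm(50))
  out <- impute_chained(d, seed = 1)
  expect_equal(out$x, d$x)
  expect_equal(nrow(attr(out, "audit")), 0L)

  d$y[1:10] <- NA
  out2 <- impute_chained(d, seed = 1)
  expect_equal(out2$y[11:50], d$y[11:50])     # observed cells never altered
  expect_false(anyNA(out2$y))
  expect_identical(impute_chained(d, seed = 1), out2)   # seed-deterministic

  d$z <- NA_real_
  expect_error(impute_chained(d, seed = 1), "100% missing")
})

test_that("chained imputation is unbiased under MCAR", {
  # Monte-Carlo oracle: MCAR implies the completed-data mean tracks the
  # complete-data mean, and the completed-data correlation tracks r = 0.7
  dev_mean <- dev_cor <- numeric(10)
  for (s in 1:10) {
    set.seed(s)
    n <- 1000
    x <- rnorm(n)
    y <- 0.7 * x + sqrt(1 - 0.49) * rnorm(n)
    aux <- 0.5 * x + rnorm(n)
    d <- data.frame(x = x, y = y, aux = aux)
    miss <- sample(n, 0.3 * n)
    d$y[miss] <- NA
    out <- impute_chained(d, auxiliaries = "aux", max_iterations = 5,
                          seed = s)
    dev_mean[s] <- mean(out$y) - mean(y)
    dev_cor[s] <- cor(out$x, out$y) - 0.7
  }
  expect_lt(abs(mean(dev_mean)), 0.1)
  expect_lt(abs(mean(dev_cor)), 0.1)
  expect_lt(max(abs(dev_cor)), 0.15)
})

test_that("multiple imputations differ but share observed data", {
  set.seed(2)
  d <- data.frame(x = rnorm(40), y = rnorm(40))
  d$y[1:8] <- NA
  sets <- impute_chained(d, n_imputations = 3, seed = 5)
  expect_length(sets, 3L)
  expect_false(identical(sets[[1]]$y[1:8], sets[[2]]$y[1:8]))
  expect_equal(sets[[1]]$y[9:40], sets[[2]]$y[9:40])
})
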