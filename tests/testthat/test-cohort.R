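test_that("cohort has requested arm sizes and valid covariates", {
  co <- generate_cohort(cohort_config(seed = 3))
  p <- co$participants
  expect_equal(nrow(p), 115L)
  expect_equal(sum(p$arm == "control"), 60L)
  expect_equal(sum(p$arm == "intervention"), 55L)
  expect_true(all(p$iq > 70))
  expect_true(all(p$age >= 6 & p$age <= 9))
  expect_true(all(p$adherence_propensity > 0 & p$adherence_propensity < 1))
  expect_equal(dim(co$ability), c(115L, 8L, 3L))
  expect_false(anyNA(co$ability))
})

test_that("cohorts are byte-identical given config and seed", {
  cc <- cohort_config(effect_sizes = c(verbal_wm = 0.4), seed = 77)
  expect_identical(generate_cohort(cc), generate_cohort(cc))
  cc2 <- cohort_config(effect_sizes = c(verbal_wm = 0.4), seed = 78)
  expect_false(identical(generate_cohort(cc)$ability,
                         generate_cohort(cc2)$ability))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_control = 0), "positive")
  expect_error(cohort_config(iq_floor = 120), "iq_floor")
  expect_error(cohort_config(classroom_icc = 1), "classroom_icc")
  expect_error(cohort_config(effect_sizes = c(nonsense = 0.3)), "unknown")
  expect_error(cohort_config(effect_sizes = c(verbal_wm = Inf)), "finite")
})

test_that("null effect leaves baseline and follow-up abilities symmetric", {
  co <- generate_cohort(cohort_config(n_control = 1000, n_intervention = 1000,
                                      classroom_icc = 0, seed = 5))
  arm <- co$participants$arm
  for (d in dimnames(co$ability)[[2]]) {
    for (tp in c("T1", "T2")) {
      diff <- mean(co$ability[arm == "intervention", d, tp]) -
        mean(co$ability[arm == "control", d, tp])
      expect_lt(abs(diff), 0.2)
    }
  }
})

test_that("injected latent effect is recovered at T2 in the treated arm only", {
  # Monte-Carlo oracle: with d = 0.8 on one domain the standardized arm
  # difference at T2 approaches 0.8 as n grows, stays 0 at T1
  diffs_t1 <- diffs_t2 <- other_t2 <- numeric(4)
  for (i in 1:4) {
    co <- generate_cohort(cohort_config(
      n_control = 500, n_intervention = 500,
      effect_sizes = c(response_inhibition = 0.8), seed = i))
    arm <- co$participants$arm
    std_diff <- function(d, tp) {
      x <- co$ability[arm == "intervention", d, tp]
      y <- co$ability[arm == "control", d, tp]
      (mean(x) - mean(y)) / sqrt((var(x) + var(y)) / 2)
    }
    diffs_t1[i] <- std_diff("response_inhibition", "T1")
    diffs_t2[i] <- std_diff("response_inhibition", "T2")
    other_t2[i] <- std_diff("verbal_wm", "T2")
  }
  expect_lt(abs(mean(diffs_t2) - 0.8), 0.1)
  expect_lt(abs(mean(diffs_t1)), 0.1)
  expect_lt(abs(mean(other_t2)), 0.1)
})

test_that("follow-up retention scales the sustained latent effect", {
  co <- generate_cohort(cohort_config(
    n_control = 500, n_intervention = 500,
    effect_sizes = c(switching = 0.6), retention_t3 = 0.5, seed = 9))
  arm <- co$participants$arm
  d_t3 <- mean(co$ability[arm == "intervention", "switching", "T3"]) -
    mean(co$ability[arm == "control", "switching", "T3"])
  expect_lt(abs(d_t3 - 0.3), 0.12)
})

test_that("classroom clustering induces the requested intra-class correlation", {
  est_icc <- function(icc, seed) {
    co <- generate_cohort(cohort_config(n_control = 500, n_intervention = 500,
                                        n_classrooms = 50,
                                        classroom_icc = icc, seed = seed))
    d <- data.frame(value = co$ability[, "verbal_wm", "T1"],
                    classroom = co$participants$classroom,
                    measure = "m", timepoint = "T1", missing = FALSE)
    icc_by_cluster(d, "m")$icc
  }
  expect_lt(est_icc(0, 21), 0.05)
  expect_lt(abs(est_icc(0.2, 22) - 0.2), 0.07)
})

test_that("simulated adherence is calibrated near 12 of 20 sessions", {
  means <- sapply(1:10, function(s) {
    co <- generate_cohort(cohort_config(n_control = 5, n_intervention = 200,
                                        seed = s))
    mean(simulate_sessions(co, seed = s)$sessions_completed)
  })
  expect_lt(abs(mean(means) - 12), 1)
})

test_that("missingness is applied at the requested MCAR rates", {
  co <- generate_cohort(cohort_config(n_control = 500, n_intervention = 500,
                                      seed = 2))
  tab <- data.frame(id = co$participants$id, arm = co$participants$arm,
                    classroom = co$participants$classroom, timepoint = "T1",
                    measure = "ds_total", value = rnorm(1000),
                    missing = FALSE, stringsAsFactors = FALSE)
  spec0 <- missingness_spec(rates = c(ds_total = 0), seed = 1)
  expect_identical(apply_missingness(tab, spec0), tab)

  spec30 <- missingness_spec(rates = c(ds_total = 0.30), seed = 1)
  out <- apply_missingness(tab, spec30)
  expect_lt(abs(mean(out$missing) - 0.30), 0.04)
  expect_true(all(is.na(out$value[out$missing])))
  expect_identical(out$id, tab$id)

  # MCAR: covariate means of missing vs observed rows agree
  iq <- co$participants$iq[match(out$id, co$participants$id)]
  gap <- abs(mean(iq[out$missing]) - mean(iq[!out$missing])) / sd(iq)
  expect_lt(gap, 0.15)

  expect_error(missingness_spec(rates = c(ds_total = 1)), "\\[0, 1\\)")
})

test_that("cohort serializes to JSON and outcome tables round-trip CSV", {
  co <- generate_cohort(cohort_config(n_control = 4, n_intervention = 4,
                                      seed = 1))
  f <- tempfile(fileext = ".json")
  write_cohort_json(co, f)
  expect_true(file.exists(f))
  obj <- jsonlite::read_json(f)
  expect_length(obj$participants, 8)

  tab <- administer_battery(co, timepoints = "T1", seed = 1)
  f2 <- tempfile(fileext = ".csv")
  write_outcomes_csv(tab, f2)
  back <- read_outcomes_csv(f2)
  expect_equal(back$value, tab$value, tolerance = 1e-12)
  expect_identical(back$missing, tab$missing)
})
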