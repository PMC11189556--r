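test_that("integration-method SSRT matches the hand-computed median case", {
  go <- c(700, 750, 800, 850, 900)
  stops <- data.frame(ssd = rep(500, 4), responded = c(TRUE, TRUE, FALSE, FALSE))
  est <- ssrt_integration(go, stops)
  expect_equal(est$p_respond, 0.5)
  expect_equal(est$ssrt, 300)          # type-1 median 800 minus mean SSD 500
  expect_false(est$degenerate)
})

test_that("degenerate stop-respond rates are flagged, not estimated", {
  go <- c(700, 800, 900)
  all_inhibited <- data.frame(ssd = c(500, 500), responded = c(FALSE, FALSE))
  expect_warning(est <- ssrt_integration(go, all_inhibited), "degenerate")
  expect_true(est$degenerate)
  expect_true(is.na(est$ssrt))
  all_responded <- data.frame(ssd = c(500, 500), responded = c(TRUE, TRUE))
  expect_warning(est2 <- ssrt_integration(go, all_responded), "degenerate")
  expect_true(est2$degenerate)
  expect_error(ssrt_integration(numeric(0), all_inhibited), "go trial")
})

test_that("omitted go trials take the maximum observed lift time", {
  go <- c(700, 750, NA, 850, 900)       # omission -> treated as 900
  stops <- data.frame(ssd = rep(500, 5),
                      responded = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  est <- ssrt_integration(go, stops)
  # p = 0.8 -> 4th order statistic of (700, 750, 900, 850, 900) = 900
  expect_equal(est$ssrt, 900 - 500)
})

test_that("integration estimator recovers a known simulated SSRT", {
  # generative-model recovery oracle on the full schedule
  ests <- sapply(1:120, function(s) {
    p <- policy_at("response_inhibition", go_mean = 800, go_sd = 50,
                   go_omission = 0, ssrt_true = 200, ssrt_sd = 0)
    score_osari(run_osari(p, seed = s))$ssrt
  })
  expect_lt(abs(mean(ests, na.rm = TRUE) - 200), 20)
})

test_that("estimator identity: mean SSD plus SSRT equals the respond quantile", {
  p <- policy_at("response_inhibition")
  log <- run_osari(p, seed = 31)
  sc <- score_osari(log)
  test <- log[log$phase == "test", ]
  go <- test[test$trial_type == "go", ]
  lifts <- ifelse(go$responded, go$rt, NA)
  lifts[is.na(lifts)] <- max(lifts, na.rm = TRUE)
  q <- quantile(lifts, sc$p_respond_stop, type = 1, names = FALSE)
  expect_equal(sc$mean_ssd + sc$ssrt, q)
})

test_that("quality control applies the three stated cut-offs", {
  p <- policy_at("response_inhibition")
  base <- run_osari(p, seed = 5)
  expect_true(score_osari(base)$qc_pass)

  low_resp <- base
  gi <- which(low_resp$phase == "test" & low_resp$trial_type == "go")
  drop <- gi[1:35]                       # 100/135 responses = 74%
  low_resp$responded[drop] <- FALSE
  low_resp$rt[drop] <- NA
  s <- score_osari(low_resp)
  expect_lt(s$go_response_rate, 0.75)
  expect_false(s$qc_pass)

  inaccurate <- base
  inaccurate$rt[gi] <- inaccurate$rt[gi] - 450   # lifts far from target
  s2 <- score_osari(inaccurate)
  expect_lt(s2$go_accuracy, 0.60)
  expect_false(s2$qc_pass)
  expect_lt(s2$go_rt_mean, 400)          # also trips the mean RT rule
})

test_that("degrading a log can only flip quality control from pass to fail", {
  p <- policy_at("response_inhibition")
  log <- run_osari(p, seed = 6)
  gi <- which(log$phase == "test" & log$trial_type == "go")
  passes <- logical(6)
  for (k in 0:5) {
    deg <- log
    drop <- gi[seq_len(k * 12)]
    deg$responded[drop] <- FALSE
    deg$rt[drop] <- NA
    passes[k + 1] <- score_osari(deg)$qc_pass
  }
  expect_false(any(diff(passes) > 0))    # monotone: no fail -> pass
})

test_that("flanker scoring identities hold on constructed logs", {
  means <- list("none.congruent" = 820, "centre.congruent" = 790,
                "double.congruent" = 780, "spatial.congruent" = 760,
                "none.incongruent" = 900, "centre.incongruent" = 880,
                "double.incongruent" = 870, "spatial.incongruent" = 860)
  log <- ant_log_from_means(means)
  s <- score_ant(log)
  expect_equal(s$conflict, mean(unlist(means[5:8])) - mean(unlist(means[1:4])))
  expect_equal(s$alerting, 820 - 780)
  expect_equal(s$orienting, 790 - 760)

  flat <- ant_log_from_means(lapply(means, function(x) 800))
  sf <- score_ant(flat)
  expect_equal(sf$alerting, 0)
  expect_equal(sf$orienting, 0)
  expect_equal(sf$conflict, 0)
})

test_that("sub-100 ms responses are excluded from every mean", {
  means <- list("none.congruent" = 820, "centre.congruent" = 790,
                "double.congruent" = 780, "spatial.congruent" = 760,
                "none.incongruent" = 900, "centre.incongruent" = 880,
                "double.incongruent" = 870, "spatial.incongruent" = 860)
  log <- ant_log_from_means(means)
  with_fast <- rbind(log, transform(log[1, ], rt = 50, index = nrow(log) + 1))
  class(with_fast) <- class(log)
  expect_equal(score_ant(with_fast)$conflict, score_ant(log)$conflict)
  expect_equal(score_ant(with_fast)$alerting, score_ant(log)$alerting)
})

test_that("rating composites follow their summation rules", {
  s <- score_ratings(sdq = c(emotional = 2, conduct = 3, hyperactivity = 4,
                             peer = 1, prosocial = 9))
  expect_equal(s$sdq_total, 10)          # prosocial excluded
  expect_equal(score_ratings(dmq_items = rep(3, 6))$dmq_persistence, 3)
  expect_equal(score_ratings(fad_items = rep(c(1, 3), 6))$fad_general, 2)
  expect_equal(score_ratings(brief_subscales = rep(5, 9))$brief_gec, 45)
  expect_error(score_ratings(dmq_items = c(3, 6)), "\\[1, 5\\]")
  expect_error(score_ratings(sdq = c(emotional = 2, conduct = 3,
                                     hyperactivity = 11, peer = 1,
                                     prosocial = 2)), "\\[0, 10\\]")
})

test_that("scorers are deterministic functions of their logs", {
  p <- policy_at("response_inhibition")
  log <- run_osari(p, seed = 9)
  expect_identical(score_osari(log), score_osari(log))
  lg2 <- run_wcst(policy_at("switching"), seed = 9)
  expect_identical(score_wcst(lg2), score_wcst(lg2))
})
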