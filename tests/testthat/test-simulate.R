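test_that("cumulative MLE is the sample-size weighted mean", {
  expect_equal(cumulative_mle(c(1, 2, 3), c(100, 50, 25), 3), 275 / 175)
  expect_equal(cumulative_mle(c(1, 2, 3), c(100, 50, 25), 1), 1)
  expect_equal(cumulative_mle(c(0.2, 0.8), c(50, 50), 2), 0.5)
  expect_error(cumulative_mle(c(1, 2), c(50, 50), 3), "outside")
  expect_error(cumulative_mle(c(1, NA), c(50, 50), 2), "not active")
})

test_that("the selection rule keeps the top arms by cumulative MLE", {
  d <- dtl_design(c(3, 2, 1), 50, 50)
  # stage-1 means (0.5, 0.9, 0.1): arm 3 dropped after stage 1
  Y <- matrix(c(0.5, 0.9, 0.1, 0.9, 0.1, NA, 0.4, NA, NA), nrow = 3)
  out <- rank_and_select(Y, d)
  expect_equal(out$survivors_per_stage[[2]], c(1L, 2L))
  expect_equal(out$ranking[3], 3L)
  expect_equal(out$thresholds[1], 0.1)

  # stage-2 reversal: kept stage-1 means (0.5, 0.9), stage-2 (1.5, 0.1)
  # -> cumulative (1.0, 0.5): the arm that trailed at stage 1 wins
  Y2 <- matrix(c(0.5, 0.9, 0.1, 1.5, 0.1, NA, 2.0, NA, NA), nrow = 3)
  out2 <- rank_and_select(Y2, d)
  expect_equal(out2$selected_arm, 1L)
  expect_equal(out2$thresholds[2], 0.5)
  expect_equal(out2$relabeled_means[1, ], c(0.5, 1.5, 2.0))
  expect_equal(out2$relabeled_means[2, 1:2], c(0.9, 0.1))
  expect_equal(out2$relabeled_means[3, 1], 0.1)
})

test_that("exact ties break in favour of the lower original arm index", {
  d <- dtl_design(c(3, 2, 1), 50, 50)
  Y <- matrix(c(0.7, 0.9, 0.7, 0.1, 0.1, NA, NA, 0.0, NA), nrow = 3)
  out <- rank_and_select(Y, d)
  expect_equal(out$survivors_per_stage[[2]], c(1L, 2L))  # arm 3 loses the tie
  # stage-2 cumulative tie between arms 1 and 2 -> arm 1 selected
  Y2 <- matrix(c(0.5, 0.5, 0.1, 0.5, 0.5, NA, 0.3, NA, NA), nrow = 3)
  expect_equal(rank_and_select(Y2, d)$selected_arm, 1L)
})

test_that("simulation is reproducible per (seed, replicate)", {
  sc <- dtl_scenario(dtl_design(c(3, 2, 1), 50, 50), c(0, 0.5, 1),
                     seed = 42, patient_level = TRUE)
  a <- simulate_trial(sc, 7)
  b <- simulate_trial(sc, 7)
  expect_identical(a$trial$stage_means, b$trial$stage_means)
  expect_identical(a$trial$patient_responses, b$trial$patient_responses)
  expect_identical(a$outcome$selected_arm, b$outcome$selected_arm)
  c_ <- simulate_trial(sc, 8)
  expect_false(identical(a$trial$stage_means, c_$trial$stage_means))
})

test_that("patient-level stage means equal the means of the raw responses", {
  sc <- dtl_scenario(dtl_design(c(3, 2, 1), c(20, 10, 5), 50), c(0, 0, 0),
                     seed = 3, patient_level = TRUE)
  run <- simulate_trial(sc, 1)
  Y <- run$trial$stage_means
  pr <- run$trial$patient_responses
  for (k in 1:3) for (j in 1:3) {
    if (!is.na(Y[k, j])) expect_equal(Y[k, j], mean(pr[[k]][[j]]))
  }
})

test_that("with vanishing variance the truly best arm is always selected", {
  sc <- dtl_scenario(dtl_design(c(3, 2, 1), 50, 1e-12), c(1, 1.5, 2),
                     seed = 9)
  for (i in 1:20) {
    expect_equal(simulate_trial(sc, i)$outcome$selected_arm, 3L)
  }
})

test_that("every simulated outcome satisfies its own Q inequalities", {
  designs <- list(dtl_design(c(3, 2, 1), 50, 50),
                  dtl_design(c(5, 3, 1), c(30, 20, 10), 20),
                  dtl_design(c(4, 3, 2, 1), 25, 10),
                  dtl_design(c(3, 1), c(100, 100), 50))
  for (d in designs) {
    sc <- dtl_scenario(d, seq(0, 1, length.out = d$arms_per_stage[1]),
                       seed = 17)
    for (i in 1:50) {
      out <- simulate_trial(sc, i)$outcome
      expect_true(q_satisfied(out))
      # the observed final-stage mean never exceeds its truncation bound
      ctx <- rb1_conditioning(out, d)
      expect_lte(out$relabeled_means[1, d$J], ctx$t + 1e-10)
    }
  }
})

test_that("exchangeable arms are each selected with probability 1/K", {
  sc <- dtl_scenario(dtl_design(c(3, 2, 1), 50, 50), c(0, 0, 0),
                     reps = 100000L, seed = 21)
  sims <- simulate_trials(sc)
  freq <- tabulate(sims$selected, 3) / nrow(sims)
  se <- sqrt((1 / 3) * (2 / 3) / nrow(sims))
  expect_true(all(abs(freq - 1 / 3) < 3 * se))
})

test_that("batch and single-trial paths agree on the selection logic", {
  # identical stage-mean matrices must select the same arm either way
  sc <- dtl_scenario(dtl_design(c(4, 2, 1), 10, 25), c(0, 0.2, 0.4, 0.6),
                     reps = 200L, seed = 33)
  sims <- simulate_trials(sc)
  expect_true(all(sims$selected %in% 1:4))
  # selected arm's mle column is consistent with its stage means
  n <- sc$design$n_per_stage
  expect_equal(sims$mle,
               (n[1] * sims$y1 + n[2] * sims$y2 + n[3] * sims$y3) / sum(n))
  # thresholds never exceed the selected arm's own cumulative MLE
  expect_true(all(sims$c1 <= (sims$y1) + 1e-10))
  cum2 <- (n[1] * sims$y1 + n[2] * sims$y2) / (n[1] + n[2])
  expect_true(all(sims$c2 <= cum2 + 1e-10))
})

test_that("selection power increases with per-stage sample size", {
  powers <- vapply(c(5L, 25L, 125L), function(n) {
    sc <- dtl_scenario(dtl_design(c(3, 2, 1), n, 50), c(0, 0, 1),
                       reps = 20000L, seed = 55)
    mean(simulate_trials(sc)$selected == 3L)
  }, numeric(1))
  se <- sqrt(powers * (1 - powers) / 20000)
  mc_slack <- 3 * sqrt(se[-3]^2 + se[-1]^2)
  expect_true(all(diff(powers) > -mc_slack))
  expect_gt(powers[3], powers[1])
})

test_that("tidy export has one row per active arm-stage cell", {
  d <- dtl_design(c(3, 2, 1), c(20, 10, 5), 50)
  sc <- dtl_scenario(d, c(0, 0, 0), seed = 2)
  run <- simulate_trial(sc, 1)
  df <- tidy_trial(run$trial, run$outcome, d)
  expect_named(df, c("replicate", "arm", "stage", "n", "mean", "selected"))
  expect_equal(nrow(df), 3 + 2 + 1)
  expect_equal(sum(df$selected), 3)  # selected arm appears in all stages
  expect_equal(df$n, c(20, 20, 20, 10, 10, 5))
})
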