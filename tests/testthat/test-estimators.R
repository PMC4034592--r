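test_that("the RB1 conditioning context matches the hand-worked example", {
  # 3:2:1, n = (50, 50, 50), v2 = 50; selected arm stage means chosen so
  # z = 85, y12 = 0.5; dropped arm at 0.3; runner-up cumulative at 0.25
  d <- null_design()
  out <- make_321_outcome(y1 = c(0.8, 0.5, 0.4), y21 = 0.4, y22 = 0.1,
                          y31 = 0.3, d)
  expect_equal(out$selected_arm, 1L)
  ctx <- rb1_conditioning(out, d)
  expect_equal(ctx$z, 85)
  expect_equal(ctx$mu_tilde, 0.6)
  expect_equal(ctx$sigma_tilde, sqrt(0.5))
  expect_equal(ctx$t, min((85 - 25 - 15) / 50, (85 - 100 * 0.25) / 50))
  expect_equal(ctx$t, 0.9)
})

test_that("RB1 matches the rejection-sampling conditional expectation", {
  d <- null_design()
  out <- make_321_outcome(y1 = c(0.8, 0.5, 0.4), y21 = 0.4, y22 = 0.1,
                          y31 = 0.3, d)
  rb1 <- rb1_estimate(out, d)
  set.seed(61)
  or <- rb1_oracle_full(z = 85, y12 = 0.5, y31 = 0.3, x22 = 0.25,
                        n = rep(50, 3), v2 = 50, centre = 0.55)
  expect_gt(or$n, 1000)
  expect_lt(abs(rb1 - or$mean), 4 * or$se)
  # the empirical support boundary sits at the computed bound t
  expect_lt(abs(or$max - 0.9), 0.1)

  # oracle recentred at a different true mean: same conditional law
  set.seed(62)
  or2 <- rb1_oracle_full(z = 85, y12 = 0.5, y31 = 0.3, x22 = 0.25,
                         n = rep(50, 3), v2 = 50, centre = 0.2)
  expect_lt(abs(rb1 - or2$mean), 4 * or2$se)
})

test_that("RB2 matches its conditional oracle and refuses J != 3", {
  d <- null_design()
  out <- make_321_outcome(y1 = c(0.8, 0.5, 0.4), y21 = 0.4, y22 = 0.1,
                          y31 = 0.3, d)
  rb2 <- rb2_estimate(out, d)
  set.seed(63)
  or <- rb2_oracle_full(z = 85, x22 = 0.25, n = rep(50, 3), v2 = 50,
                        centre = 0.55)
  expect_gt(or$n, 1000)
  expect_lt(abs(rb2 - or$mean), 4 * or$se)

  d2 <- dtl_design(c(3, 1), c(100, 100), 50)
  out2 <- rank_and_select(matrix(c(1, 0, -1, 0.5, NA, NA), nrow = 3), d2)
  expect_error(rb2_estimate(out2, d2), "three-stage")
})

test_that("RB1 and RB2 match the pair oracle on a sweep of conditioning points", {
  d <- null_design()
  pts <- list(list(y1 = c(0.8, 0.5, 0.4), y21 = 0.4, y22 = 0.1, y31 = 0.3),
              list(y1 = c(1.2, -0.3, 0.6), y21 = 1.0, y22 = -0.2, y31 = 0.9),
              list(y1 = c(0.1, 0.4, 0.0), y21 = 0.0, y22 = 0.1, y31 = -0.2),
              list(y1 = c(2.0, 1.0, -1.0), y21 = 1.5, y22 = 0.0, y31 = 1.2),
              list(y1 = c(0.6, 0.6, 0.6), y21 = 0.5, y22 = 0.6, y31 = 0.4))
  set.seed(64)
  for (p in pts) {
    out <- make_321_outcome(p$y1, p$y21, p$y22, p$y31, d)
    expect_equal(out$selected_arm, 1L)
    z <- 50 * sum(p$y1)
    x22 <- (50 * p$y21 + 50 * p$y22) / 100
    or <- rb1_oracle_pair(z, p$y1[2], p$y31, x22, n = rep(50, 3), v2 = 50,
                          centre = mean(p$y1))
    expect_gt(or$n, 500)
    expect_lt(abs(rb1_estimate(out, d) - or$mean), 4 * or$se)
  }
})

test_that("conditional moments are free of the true means", {
  d <- null_design()
  args <- list(y1 = c(0.8, 0.5, 0.4), y21 = 0.4, y22 = 0.1, y31 = 0.3)
  a <- rb1_conditioning(do.call(make_321_outcome,
                                c(args, list(design = d,
                                             means = c(0, 0, 0)))), d)
  b <- rb1_conditioning(do.call(make_321_outcome,
                                c(args, list(design = d,
                                             means = c(5, -2, 1)))), d)
  expect_identical(a[c("mu_tilde", "sigma_tilde", "t")],
                   b[c("mu_tilde", "sigma_tilde", "t")])
})

test_that("distant competitors remove the truncation", {
  d <- null_design()
  out <- make_321_outcome(y1 = c(0.8, 0.5, 0.4), y21 = -100, y22 = -100,
                          y31 = -120, d)
  ctx <- rb1_conditioning(out, d)
  expect_gt(ctx$w, 8)
  expect_equal(rb1_estimate(out, d), ctx$mu_tilde, tolerance = 1e-8)
  expect_equal(rb2_estimate(out, d), mle_estimate(out, d), tolerance = 1e-8)
})

test_that("a two-stage design reproduces the two-stage UMVCUE", {
  # independent implementation of the two-stage truncated-mean formula:
  # condition the selected arm's stage-2 mean on Z1 and on beating the
  # best competitor's stage-1 mean
  d2 <- dtl_design(c(3, 1), c(100, 100), 50)
  two_stage_umvcue <- function(y11, y12, c1, n1, n2, v2) {
    z <- n1 * y11 + n2 * y12
    mu <- z / (n1 + n2)
    sg <- sqrt(v2 * n1 / (n2 * (n1 + n2)))
    t <- (z - n1 * c1) / n2
    mu - sg * dnorm((t - mu) / sg) / pnorm((t - mu) / sg)
  }
  sc <- dtl_scenario(d2, c(0, 0.3, 0.6), seed = 71)
  for (i in 1:25) {
    out <- simulate_trial(sc, i)$outcome
    ctx <- rb1_conditioning(out, d2)
    y1 <- out$relabeled_means[1, ]
    # J = 2: the conditional mean is the two-stage MLE of the selected arm
    expect_equal(ctx$mu_tilde, cumulative_mle(y1, d2$n_per_stage, 2))
    expect_equal(rb1_estimate(out, d2),
                 two_stage_umvcue(y1[1], y1[2], out$thresholds[1],
                                  100, 100, 50))
  }
})

test_that("MLE and final-stage estimators are simple statistics", {
  d <- dtl_design(c(3, 2, 1), c(100, 50, 25), 50)
  Y <- matrix(c(1, -5, -6, 2, -5, NA, 3, NA, NA), nrow = 3)
  out <- rank_and_select(Y, d)
  expect_equal(mle_estimate(out, d), 275 / 175)
  expect_equal(final_stage_estimate(out), 3)
  est <- dtl_estimates(out, d, estimators = c("mle", "rb1", "rb2", "final"))
  expect_named(est, c("mle", "rb1", "rb2", "final"))
  expect_true(all(vapply(est, is.finite, logical(1))))
})

test_that("an outcome violating Q is rejected", {
  d <- null_design()
  out <- make_321_outcome(y1 = c(0.8, 0.5, 0.4), y21 = 0.4, y22 = 0.1,
                          y31 = 0.3, d)
  bad <- out
  # lowering the recorded stage-1 mean below the dropped arm's pushes the
  # observed final-stage mean past the recomputed bound
  bad$relabeled_means[1, 1] <- 0.2
  expect_error(rb1_conditioning(bad, d), "inconsistent with event Q")
})
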