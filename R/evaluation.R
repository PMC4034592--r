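# closed-form estimator columns for a batch of simulated trials
estimates_from_sims <- function(sims, design,
                                estimators = c("mle", "rb1", "rb2", "final"),
                                bcmle_reps = NULL) {
  J <- design$J
  n <- as.numeric(design$n_per_stage)
  N <- design$N
  R <- nrow(sims)
  y <- as.matrix(sims[paste0("y", seq_len(J))])
  cj <- as.matrix(sims[paste0("c", seq_len(J - 1L))])
  z <- sims$z
  est <- matrix(NA_real_, R, length(estimators),
                dimnames = list(NULL, estimators))
  inter <- if (J > 2L) {
    as.vector(y[, 2:(J - 1L), drop = FALSE] %*% n[2:(J - 1L)])
  } else 0
  if ("mle" %in% estimators) est[, "mle"] <- sims$mle
  if ("final" %in% estimators) est[, "final"] <- y[, J]
  if ("rb1" %in% estimators) {
    sigma_tilde <- sqrt(design$v2 * n[1L] / (n[J] * (n[1L] + n[J])))
    tb <- rep(Inf, R)
    for (j in seq_len(J - 1L)) {
      partial <- if (j >= 2L) {
        as.vector(y[, 2:j, drop = FALSE] %*% n[2:j])
      } else 0
      tb <- pmin(tb, (z - inter - (N[j] * cj[, j] - partial)) / n[J])
    }
    est[, "rb1"] <- upper_truncated_normal_mean((z - inter) / (n[1L] + n[J]),
                                                sigma_tilde, tb)
  }
  if ("rb2" %in% estimators) {
    if (J != 3L) stop("RB2 requires a three-stage design", call. = FALSE)
    sd2 <- sqrt(design$v2 * (1 / n[3L] - 1 / N[3L]))
    est[, "rb2"] <- upper_truncated_normal_mean(
      sims$mle, sd2, (z - N[2L] * cj[, 2L]) / n[3L])
  }
  if ("bcmle" %in% estimators) {
    check_321(design)
    nb <- if (is.null(bcmle_reps)) R else min(bcmle_reps, R)
    vars <- c(design$v2 / N[3L], design$v2 / N[2L], design$v2 / n[1L])
    for (i in seq_len(nb)) {
      ld <- structure(list(stats = c(x13 = sims$mle[i], x22 = cj[i, 2L],
                                     y31 = cj[i, 1L]),
                           vars = vars),
                      class = "dtl_likelihood_data")
      fit <- try(bcmle_estimate(ld, design), silent = TRUE)
      if (!inherits(fit, "try-error")) est[i, "bcmle"] <- fit[1L]
    }
  }
  est
}

#' Operating characteristics of the point estimators
#'
#' Simulates replicate trials and reports, per estimator, the Monte-Carlo
#' extended bias (mean of estimate minus the true mean of whichever arm
#' was selected) and mean squared error, together with per-selected-arm
#' conditional summaries.  The extended-bias notion treats the estimand as
#' random: averaging the deviation over replicates is the Monte-Carlo form
#' of the selection-probability-weighted sum of conditional biases.
#'
#' @param scenario a [dtl_scenario()].
#' @param estimators subset of `c("mle", "rb1", "rb2", "bcmle", "final")`.
#' @param bcmle_reps number of leading replicates on which the (expensive)
#'   bias-corrected conditional MLE is evaluated; other estimators use all
#'   replicates.
#' @return An object of class `dtl_oc` with components `summary` (one row
#'   per estimator: `bias`, `mse`, `variance`, Monte-Carlo standard
#'   errors, `n_reps`), `conditional` (per selected arm: selection
#'   frequency and conditional bias), and the raw `estimates`, `truth` and
#'   `selected` vectors.
#' @examples
#' sc <- dtl_scenario(dtl_design(c(3, 2, 1), 50, 50), c(0, 0, 0),
#'                    reps = 2000, seed = 1)
#' oc_study(sc, estimators = c("mle", "rb1", "final"))$summary
#' @export
oc_study <- function(scenario,
                     estimators = c("mle", "rb1", "rb2", "final"),
                     bcmle_reps = 2000L) {
  design <- scenario$design
  sims <- simulate_trials(scenario)
  est <- estimates_from_sims(sims, design, estimators, bcmle_reps)
  truth <- sims$mu_selected
  summ <- do.call(rbind, lapply(estimators, function(e) {
    dev <- est[, e] - truth
    dev <- dev[!is.na(dev)]
    m <- length(dev)
    data.frame(estimator = e,
               bias = mean(dev),
               mse = mean(dev^2),
               variance = stats::var(dev),
               mc_se_bias = stats::sd(dev) / sqrt(m),
               mc_se_mse = stats::sd(dev^2) / sqrt(m),
               n_reps = m)
  }))
  cond <- do.call(rbind, lapply(sort(unique(sims$selected)), function(k) {
    rows <- sims$selected == k
    data.frame(arm = k,
               p_selected = mean(rows),
               do.call(cbind, stats::setNames(lapply(estimators, function(e) {
                 mean(est[rows, e] - truth[rows], na.rm = TRUE)
               }), paste0("bias_", estimators))))
  }))
  structure(list(summary = summ, conditional = cond, estimates = est,
                 truth = truth, selected = sims$selected,
                 n_reps = scenario$reps, seed = scenario$seed),
            class = "dtl_oc")
}

#' @export
print.dtl_oc <- function(x, ...) {
  cat(sprintf("operating characteristics over %d replicates\n", x$n_reps))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Proportion of replicates overestimating the selected treatment mean
#'
#' @inheritParams oc_study
#' @param oc optionally, a precomputed [oc_study()] result for the same
#'   scenario (avoids resimulation).
#' @return Named vector of fractions of replicates with
#'   estimate > true mean of the selected arm.
#' @export
overestimation_rate <- function(scenario,
                                estimators = c("mle", "rb1", "rb2"),
                                oc = NULL) {
  if (is.null(oc)) oc <- oc_study(scenario, estimators)
  vapply(estimators, function(e) {
    dev <- oc$estimates[, e] - oc$truth
    mean(dev[!is.na(dev)] > 0)
  }, numeric(1))
}

#' Coverage study for the interval methods
#'
#' Simulates patient-level trials and, per replicate, builds the requested
#' confidence intervals and scores whether each contains the true mean of
#' the selected arm, lies entirely above it, or entirely below.
#'
#' @param scenario a [dtl_scenario()] with `patient_level = TRUE` when any
#'   bootstrap method is requested.
#' @param methods subset of `c("bootstrap_rb1", "bootstrap_rb2",
#'   "profile_bcmle", "wald_mle", "wald_final")`.
#' @param settings a [bootstrap_settings()]; its `level` is used for every
#'   method.
#' @return An object of class `dtl_coverage`: data.frame `summary` with
#'   one row per method (`coverage`, `mean_width`, `prop_above`,
#'   `prop_below`, `n`, `failures`).  Coverage, above and below partition
#'   the successful replicates.
#' @export
coverage_study <- function(scenario,
                           methods = c("bootstrap_rb1", "bootstrap_rb2",
                                       "profile_bcmle", "wald_mle",
                                       "wald_final"),
                           settings = bootstrap_settings(B = 500L)) {
  methods <- match.arg(methods, several.ok = TRUE)
  design <- scenario$design
  needs_boot <- any(grepl("^bootstrap", methods))
  if (needs_boot && !scenario$patient_level) {
    stop("bootstrap methods need a patient-level scenario", call. = FALSE)
  }
  R <- scenario$reps
  hit <- above <- matrix(0, R, length(methods),
                         dimnames = list(NULL, methods))
  below <- width <- hit
  ok <- matrix(TRUE, R, length(methods), dimnames = list(NULL, methods))
  sd_mle <- sqrt(design$v2 / design$N[design$J])
  sd_final <- design$sigma[design$J]
  boot_set <- settings
  boot_set$seed <- NULL       # draws continue the per-replicate substream
  for (i in seq_len(R)) {
    run <- simulate_trial(scenario, i)
    outcome <- run$outcome
    mu1 <- outcome$mu_selected
    cis <- list()
    if (needs_boot) {
      reps <- try(bootstrap_replicates(run$trial, outcome, design, boot_set),
                  silent = TRUE)
      if (inherits(reps, "try-error")) {
        ok[i, grepl("^bootstrap", methods)] <- FALSE
      } else {
        if ("bootstrap_rb1" %in% methods) {
          cis$bootstrap_rb1 <- percentile_interval(reps$rb1, settings$level)
        }
        if ("bootstrap_rb2" %in% methods) {
          cis$bootstrap_rb2 <- percentile_interval(reps$rb2, settings$level)
        }
      }
    }
    if ("profile_bcmle" %in% methods) {
      ci <- try({
        ld <- likelihood_data(outcome, design)
        pl <- profile_likelihood_ci(ld, design, level = settings$level)
        c(pl$lower, pl$upper)
      }, silent = TRUE)
      if (inherits(ci, "try-error")) ok[i, "profile_bcmle"] <- FALSE
      else cis$profile_bcmle <- ci
    }
    if ("wald_mle" %in% methods) {
      w <- wald_ci(mle_estimate(outcome, design), sd_mle, settings$level)
      cis$wald_mle <- c(w$lower, w$upper)
    }
    if ("wald_final" %in% methods) {
      w <- wald_ci(final_stage_estimate(outcome), sd_final, settings$level)
      cis$wald_final <- c(w$lower, w$upper)
    }
    for (m in names(cis)) {
      ci <- cis[[m]]
      hit[i, m] <- ci[1L] <= mu1 && mu1 <= ci[2L]
      above[i, m] <- ci[1L] > mu1
      below[i, m] <- ci[2L] < mu1
      width[i, m] <- ci[2L] - ci[1L]
    }
  }
  summ <- do.call(rbind, lapply(methods, function(m) {
    use <- ok[, m]
    data.frame(method = m,
               coverage = mean(hit[use, m]),
               mean_width = mean(width[use, m]),
               prop_above = mean(above[use, m]),
               prop_below = mean(below[use, m]),
               n = sum(use),
               failures = sum(!use))
  }))
  structure(list(summary = summ, level = settings$level,
                 n_sims = R, seed = scenario$seed),
            class = "dtl_coverage")
}

#' @export
print.dtl_coverage <- function(x, ...) {
  cat(sprintf("interval coverage over %d simulated trials (level %g%%)\n",
              x$n_sims, 100 * x$level))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tail proportions of the confidence intervals in K:2:1 trials
#'
#' For each `K` in `K_grid`, simulates a `K:2:1` trial with all true means
#' zero and reports the percentage of 95% intervals lying entirely above
#' or entirely below the selected arm's true mean.  The cheap Wald
#' interval around the MLE is evaluated on `reps` replicates at summary
#' level; the bootstrap intervals for RB1 and RB2 on `boot_sims`
#' patient-level trials.
#'
#' @param K_grid integer vector of initial arm counts (all at least 3).
#' @param n_per_stage,v2 design parameters shared by every `K`.
#' @param reps replicates for the Wald/MLE columns.
#' @param boot_sims patient-level trials for the bootstrap columns
#'   (0 skips them).
#' @param settings [bootstrap_settings()] for the bootstrap columns.
#' @param seed master seed.
#' @param level interval level.
#' @return A data.frame with one row per `K` and percent columns
#'   `mle_above`, `mle_below`, `rb1_above`, `rb1_below`, `rb2_above`,
#'   `rb2_below`.
#' @export
tail_proportions <- function(K_grid, n_per_stage = c(50L, 50L, 50L),
                             v2 = 50, reps = 50000L, boot_sims = 1000L,
                             settings = bootstrap_settings(B = 500L),
                             seed = NULL, level = 0.95) {
  rows <- lapply(seq_along(K_grid), function(gi) {
    K <- K_grid[gi]
    design <- dtl_design(c(K, 2L, 1L), n_per_stage, v2)
    sub <- if (is.null(seed)) NULL else replicate_seed(seed, gi)
    sc <- dtl_scenario(design, rep(0, K), reps = reps, seed = sub)
    sims <- simulate_trials(sc)
    zq <- stats::qnorm(1 - (1 - level) / 2)
    half <- zq * sqrt(v2 / design$N[3L])
    dev <- sims$mle - sims$mu_selected
    out <- data.frame(K = K,
                      mle_above = 100 * mean(dev - half > 0),
                      mle_below = 100 * mean(dev + half < 0),
                      rb1_above = NA_real_, rb1_below = NA_real_,
                      rb2_above = NA_real_, rb2_below = NA_real_)
    if (boot_sims > 0L) {
      scb <- dtl_scenario(design, rep(0, K), reps = boot_sims,
                          seed = if (is.null(sub)) NULL else sub + 1L,
                          patient_level = TRUE)
      cov <- coverage_study(scb, c("bootstrap_rb1", "bootstrap_rb2"),
                            settings)
      s <- cov$summary
      out$rb1_above <- 100 * s$prop_above[s$method == "bootstrap_rb1"]
      out$rb1_below <- 100 * s$prop_below[s$method == "bootstrap_rb1"]
      out$rb2_above <- 100 * s$prop_above[s$method == "bootstrap_rb2"]
      out$rb2_below <- 100 * s$prop_below[s$method == "bootstrap_rb2"]
    }
    out
  })
  do.call(rbind, rows)
}

#' Power to select the truly best treatment
#'
#' For each design and each value of the shifting mean `Delta`, reports
#' the proportion of simulated trials in which the truly best arm ends up
#' selected.  The `means` template contains exactly one `NA`, the slot
#' `Delta` fills.
#'
#' @param designs a named list of [dtl_design()] objects sharing the same
#'   initial arm count.
#' @param means numeric template with one `NA` entry.
#' @param delta_grid values substituted for the `NA`.
#' @param reps replicates per design per grid point.
#' @param seed master seed (substreams per grid cell).
#' @return A data.frame of class `dtl_power` with columns `design`,
#'   `delta`, `power`, `best_arm`, `best_unique` and `n_reps`.
#' @examples
#' ds <- list(`3:2:1` = dtl_design(c(3, 2, 1), 60, 50),
#'            `3:1` = dtl_design(c(3, 1), c(100, 100), 50))
#' selection_power(ds, c(1, NA, 2), delta_grid = c(0, 1), reps = 500,
#'                 seed = 1)
#' @export
selection_power <- function(designs, means, delta_grid, reps = 10000L,
                            seed = NULL) {
  slot <- which(is.na(means))
  if (length(slot) != 1L) {
    stop("'means' must contain exactly one NA for Delta", call. = FALSE)
  }
  grid <- expand.grid(design = seq_along(designs), delta = delta_grid)
  labels <- if (is.null(names(designs))) {
    vapply(designs, function(d) paste(d$arms_per_stage, collapse = ":"),
           character(1))
  } else names(designs)
  rows <- lapply(seq_len(nrow(grid)), function(gi) {
    design <- validate_design(designs[[grid$design[gi]]])
    mu <- means
    mu[slot] <- grid$delta[gi]
    best <- which.max(mu)
    unique_best <- sum(mu == max(mu)) == 1L
    if (!unique_best) {
      warning("best arm not unique at Delta = ", grid$delta[gi],
              "; reporting the lowest-index maximizer", call. = FALSE)
    }
    sub <- if (is.null(seed)) NULL else replicate_seed(seed, gi)
    sims <- simulate_trials(dtl_scenario(design, mu, reps = reps,
                                         seed = sub))
    data.frame(design = labels[grid$design[gi]], delta = grid$delta[gi],
               power = mean(sims$selected == best), best_arm = best,
               best_unique = unique_best, n_reps = reps)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dtl_power", "data.frame")
  out
}
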