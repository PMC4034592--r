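#' Settings for the conditional bootstrap
#'
#' @param B target number of accepted bootstrap replicates (at least 100
#'   for reportable intervals).
#' @param level coverage level in (0, 1).
#' @param max_attempts cap on total resampling attempts; the default,
#'   `1000 * B`, makes the run fail once the acceptance rate drops below
#'   0.1 percent.
#' @param seed optional seed for the resampling stream; when `NULL` the
#'   ambient RNG state is used (so a bootstrap following a seeded
#'   [simulate_trial()] is still fully reproducible).
#' @return A list of class `dtl_bootstrap_settings`.
#' @export
bootstrap_settings <- function(B = 1000L, level = 0.95,
                               max_attempts = NULL, seed = NULL) {
  B <- as.integer(B)
  if (B < 1L) stop("'B' must be positive", call. = FALSE)
  if (B < 100L) warning("fewer than 100 bootstrap replicates; ",
                        "interval quantiles will be unstable")
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)",
                                     call. = FALSE)
  if (is.null(max_attempts)) max_attempts <- 1000 * B
  if (max_attempts < B) stop("'max_attempts' must be at least B",
                             call. = FALSE)
  structure(list(B = B, level = level, max_attempts = max_attempts,
                 seed = seed),
            class = "dtl_bootstrap_settings")
}

percentile_interval <- function(values, level) {
  alpha <- (1 - level) / 2
  stats::quantile(values, c(alpha, 1 - alpha), names = FALSE)
}

# Conditional resampling engine.  Resamples the selected arm's per-stage
# patient responses with replacement; a replicate is accepted only if its
# bootstrap cumulative MLEs clear the original observed competitor
# thresholds at every selection stage.  RB1/RB2 are then evaluated at the
# bootstrap means with the truncation bounds recomputed from the bootstrap
# statistics (thresholds stay frozen at their original observed values).
# Accepting a replicate is equivalent to its final-stage mean lying below
# the recomputed RB1 bound, mirroring how Q restricts the real data.
bootstrap_replicates <- function(trial, outcome, design, settings,
                                 keep_samples = FALSE) {
  design <- validate_design(design)
  J <- design$J
  n <- as.numeric(design$n_per_stage)
  N <- design$N
  sel <- outcome$selected_arm
  x <- trial$patient_responses[[sel]]
  if (is.null(x) || any(vapply(x, is.null, logical(1)))) {
    stop("patient-level responses for the selected arm are required ",
         "for the bootstrap", call. = FALSE)
  }
  cj <- outcome$thresholds
  sigma_tilde <- sqrt(design$v2 * n[1L] / (n[J] * (n[1L] + n[J])))
  sd2 <- if (J == 3L) sqrt(design$v2 * (1 / n[3L] - 1 / N[3L]))
  if (!is.null(settings$seed)) set.seed(settings$seed)
  rb1 <- rb2 <- numeric(0)
  samples <- if (keep_samples) matrix(numeric(0), 0L, J)
  attempts <- 0L
  resample_means <- function(xj, nj, M) {
    colMeans(matrix(sample(xj, nj * M, replace = TRUE), nj, M))
  }
  while (length(rb1) < settings$B && attempts < settings$max_attempts) {
    M <- min(max(2L * (settings$B - length(rb1)), 200L),
             settings$max_attempts - attempts)
    attempts <- attempts + M
    bm <- matrix(NA_real_, M, J)
    bm[, 1L] <- resample_means(x[[1L]], n[1L], M)
    alive <- bm[, 1L] >= cj[1L]
    if (J > 2L) {
      for (j in 2:(J - 1L)) {
        idx <- which(alive)
        if (!length(idx)) break
        bm[idx, j] <- resample_means(x[[j]], n[j], length(idx))
        cumj <- as.vector(bm[idx, 1:j, drop = FALSE] %*% n[1:j]) / N[j]
        alive[idx] <- cumj >= cj[j]
      }
    }
    idx <- which(alive)
    if (!length(idx)) next
    bm[idx, J] <- resample_means(x[[J]], n[J], length(idx))
    b <- bm[idx, , drop = FALSE]
    z <- as.vector(b %*% n)
    inter <- if (J > 2L) {
      as.vector(b[, 2:(J - 1L), drop = FALSE] %*% n[2:(J - 1L)])
    } else 0
    tb <- rep(Inf, length(idx))
    for (j in seq_len(J - 1L)) {
      partial <- if (j >= 2L) {
        as.vector(b[, 2:j, drop = FALSE] %*% n[2:j])
      } else 0
      tb <- pmin(tb, (z - inter - (N[j] * cj[j] - partial)) / n[J])
    }
    rb1 <- c(rb1, upper_truncated_normal_mean((z - inter) / (n[1L] + n[J]),
                                              sigma_tilde, tb))
    if (J == 3L) {
      tprime <- (z - N[2L] * cj[2L]) / n[3L]
      rb2 <- c(rb2, upper_truncated_normal_mean(z / N[3L], sd2, tprime))
    }
    if (keep_samples) samples <- rbind(samples, b)
  }
  if (length(rb1) < settings$B) {
    stop(sprintf(paste0("bootstrap acceptance rate too low: %d of %d ",
                        "attempts accepted (%.3f%%); need B = %d"),
                 length(rb1), attempts, 100 * length(rb1) / attempts,
                 settings$B), call. = FALSE)
  }
  keep <- seq_len(settings$B)
  list(rb1 = rb1[keep],
       rb2 = if (J == 3L) rb2[keep],
       attempts = attempts,
       acceptance_rate = length(rb1) / attempts,
       samples = if (keep_samples) samples[keep, , drop = FALSE])
}

#' Conditional nonparametric bootstrap confidence interval
#'
#' Percentile interval for the RB1 or RB2 estimate of the selected
#' treatment mean.  The selected arm's stage-wise patient responses are
#' resampled with replacement; a resample is accepted only if it would
#' have survived the trial's original selection — its bootstrap cumulative
#' MLE must clear the original observed competitor threshold at every
#' selection stage.  The estimator is then evaluated at the bootstrap
#' means, with the competitor thresholds entering the truncation bound
#' frozen at their original observed values.
#'
#' @param trial a `dtl_trial` carrying `patient_responses` for the
#'   selected arm.
#' @param outcome the matching `dtl_selection`.
#' @param design the [dtl_design()].
#' @param estimator `"rb1"` or `"rb2"` (the latter needs a three-stage
#'   design).
#' @param settings a [bootstrap_settings()] object.
#' @param keep_samples if `TRUE`, the accepted bootstrap stage means are
#'   attached as attribute `"samples"` (diagnostics/testing).
#' @return A list of class `dtl_interval` with fields `lower`, `upper`,
#'   `method = "bootstrap-percentile"`, `estimator`, `level`,
#'   `n_accepted` and `acceptance_rate`.  The bootstrap estimates
#'   themselves are attached as attribute `"replicates"`.
#' @export
bootstrap_ci <- function(trial, outcome, design,
                         estimator = c("rb1", "rb2"),
                         settings = bootstrap_settings(),
                         keep_samples = FALSE) {
  estimator <- match.arg(estimator)
  design <- validate_design(design)
  if (estimator == "rb2" && design$J != 3L) {
    stop("the RB2 estimator is defined for three-stage designs only",
         call. = FALSE)
  }
  reps <- bootstrap_replicates(trial, outcome, design, settings,
                               keep_samples = keep_samples)
  values <- reps[[estimator]]
  ci <- percentile_interval(values, settings$level)
  out <- structure(list(lower = ci[1L], upper = ci[2L],
                        method = "bootstrap-percentile",
                        estimator = estimator, level = settings$level,
                        n_accepted = length(values),
                        acceptance_rate = reps$acceptance_rate),
                   class = "dtl_interval")
  attr(out, "replicates") <- values
  if (keep_samples) attr(out, "samples") <- reps$samples
  out
}

#' Profile-likelihood confidence interval for the bias-corrected MLE
#'
#' The profile statistic `Lambda(mu_1)` is twice the gap between the
#' selection-conditioned log-likelihood at the joint conditional MLE and
#' its maximum over `(mu_2, mu_3)` with `mu_1` held fixed.  The interval
#' is the set where `Lambda` does not exceed the chi-square(1) quantile;
#' endpoints are located by root bisection to 1e-4, warm-starting each
#' profile maximization from its neighbour.
#'
#' @param data a [likelihood_data()] object.
#' @param design a 3:2:1 [dtl_design()].
#' @param level coverage level.
#' @param fit optional precomputed [bcmle_estimate()] result.
#' @return A `dtl_interval` with `method = "profile-likelihood"`.
#' @export
profile_likelihood_ci <- function(data, design, level = 0.95, fit = NULL) {
  design <- validate_design(design)
  check_321(design)
  if (is.null(fit)) fit <- bcmle_estimate(data, design)
  lmax <- attr(fit, "loglik")
  crit <- stats::qchisq(level, df = 1L)
  sd1 <- sqrt(data$vars[1L])
  warm <- fit[2:3]
  profile_gap <- function(mu1) {
    o <- stats::optim(warm, function(q) neg_cloglik(c(mu1, q), data, design),
                      method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-9))
    if (o$value < 1e9) warm <<- o$par
    2 * (lmax + o$value) - crit      # 2 * (lmax - profile loglik) - crit
  }
  find_root <- function(direction) {
    warm <<- fit[2:3]
    step <- 1.5
    bound <- fit[1L] + direction * step * sd1
    g <- profile_gap(bound)
    tries <- 0L
    while (g < 0 && tries < 10L) {
      bound <- bound + direction * sd1
      g <- profile_gap(bound)
      tries <- tries + 1L
    }
    if (g < 0) stop("profile statistic failed to cross its threshold",
                    call. = FALSE)
    interval <- sort(c(fit[1L], bound))
    stats::uniroot(profile_gap, interval, tol = 1e-4)$root
  }
  lower <- find_root(-1)
  upper <- find_root(+1)
  structure(list(lower = lower, upper = upper,
                 method = "profile-likelihood", estimator = "bcmle",
                 level = level),
            class = "dtl_interval")
}

#' Wald confidence interval
#'
#' The standard symmetric normal-theory interval
#' `estimate +/- z_(1 - alpha/2) * sd`, ignoring selection.  Exact for the
#' unbiased final-stage estimator (its sampling distribution really is
#' normal around the selected arm's mean); anti-conservative for the
#' selection-biased MLE.
#'
#' @param estimate point estimate.
#' @param sd its standard deviation (positive).
#' @param level coverage level.
#' @return A `dtl_interval` with `method = "wald"`.
#' @examples
#' wald_ci(0, 1, 0.95)  # width 3.92
#' @export
wald_ci <- function(estimate, sd, level = 0.95) {
  if (sd <= 0) stop("'sd' must be positive", call. = FALSE)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(lower = estimate - zq * sd, upper = estimate + zq * sd,
                 method = "wald", level = level),
            class = "dtl_interval")
}

#' @export
print.dtl_interval <- function(x, ...) {
  cat(sprintf("%s %g%% interval: [%.5f, %.5f]\n", x$method, 100 * x$level,
              x$lower, x$upper))
  if (!is.null(x$n_accepted)) {
    cat(sprintf("  accepted replicates: %d (acceptance rate %.2f%%)\n",
                x$n_accepted, 100 * x$acceptance_rate))
  }
  invisible(x)
}
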