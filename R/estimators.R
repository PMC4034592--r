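#' Conditioning context for the RB1 estimator
#'
#' The RB1 estimator is the conditional expectation of the selected arm's
#' unbiased final-stage mean `Y_1J` given the arm's sufficient total
#' `Z_1 = sum(n_j * Y_1j)`, its intermediate stage means
#' `Y_12, ..., Y_1(J-1)`, and the selection event Q.  Multivariate-normal
#' conditioning makes the unrestricted conditional law of `Y_1J` normal
#' with moments that are free of every mean parameter:
#' `mu_tilde = (z - sum_{i=2}^{J-1} n_i y_1i) / (n_1 + n_J)` and
#' `sigma_tilde^2 = v2 * n_1 / (n_J * (n_1 + n_J))`.  Event Q then
#' truncates `Y_1J` above: each selection-stage constraint
#' `Xbar_1j >= c_j` (with `c_j` the largest dropped cumulative MLE at
#' stage `j`) is solved for `Y_1J` after substituting
#' `Y_11 = (Z_1 - sum_{i >= 2} n_i Y_1i) / n_1`, and the bound `t` is
#' their minimum.
#'
#' @param outcome a `dtl_selection` from a trial satisfying Q.
#' @param design the [dtl_design()].
#' @return A list of class `dtl_truncation` with fields `mu_tilde`,
#'   `sigma_tilde`, `t`, `w = (t - mu_tilde) / sigma_tilde` and `z`.
#' @seealso [rb1_estimate()]
#' @export
rb1_conditioning <- function(outcome, design) {
  design <- validate_design(design)
  J <- design$J
  n <- as.numeric(design$n_per_stage)
  y1 <- outcome$relabeled_means[1L, ]
  z <- sum(n * y1)
  inter <- if (J > 2L) sum(n[2:(J - 1L)] * y1[2:(J - 1L)]) else 0
  mu_tilde <- (z - inter) / (n[1L] + n[J])
  sigma_tilde <- sqrt(design$v2 * n[1L] / (n[J] * (n[1L] + n[J])))
  cj <- outcome$thresholds
  bounds <- vapply(seq_len(J - 1L), function(j) {
    partial <- if (j >= 2L) sum(n[2:j] * y1[2:j]) else 0
    (z - inter - (design$N[j] * cj[j] - partial)) / n[J]
  }, numeric(1))
  t <- min(bounds)
  if (y1[J] > t + 1e-8) {
    stop("selection outcome inconsistent with event Q: observed final-stage ",
         "mean exceeds its truncation bound", call. = FALSE)
  }
  structure(list(mu_tilde = mu_tilde, sigma_tilde = sigma_tilde, t = t,
                 w = (t - mu_tilde) / sigma_tilde, z = z),
            class = "dtl_truncation")
}

#' RB1: Rao-Blackwellized unbiased estimate of the selected treatment mean
#'
#' Unbiased under the selection event Q (indeed conditionally on each arm
#' being the selected one), with smaller variance than the final-stage
#' mean alone by the Rao-Blackwell theorem.  Valid for any number of
#' stages `J >= 2`.
#'
#' @inheritParams rb1_conditioning
#' @return The truncated-normal conditional expectation
#'   `upper_truncated_normal_mean(mu_tilde, sigma_tilde, t)`.
#' @examples
#' sc <- dtl_scenario(dtl_design(c(3, 2, 1), 50, 50), c(0, 0, 0), seed = 1)
#' run <- simulate_trial(sc)
#' rb1_estimate(run$outcome, sc$design)
#' @export
rb1_estimate <- function(outcome, design) {
  ctx <- rb1_conditioning(outcome, design)
  upper_truncated_normal_mean(ctx$mu_tilde, ctx$sigma_tilde, ctx$t)
}

#' RB2: Rao-Blackwellized estimate under the stage-two condition only
#'
#' Conditions on the sufficient total `Z_1` alone and on the final
#' selection rule (the stage-two comparison in a three-stage trial) rather
#' than the full event Q.  The unrestricted conditional mean of `Y_13`
#' given `Z_1` is the MLE `z / N_3` with variance
#' `v2 * (1 / n_3 - 1 / N_3)`, truncated above at
#' `t' = (z - N_2 * Xbar_22) / n_3` where `Xbar_22` is the runner-up's
#' stage-two cumulative MLE.  Slightly biased (the conditioning event is
#' not the full Q) but with a much smaller mean squared error than RB1.
#'
#' @inheritParams rb1_conditioning
#' @return The RB2 estimate; only defined for three-stage designs.
#' @export
rb2_estimate <- function(outcome, design) {
  design <- validate_design(design)
  if (design$J != 3L) {
    stop("the RB2 estimator is defined for three-stage designs only",
         call. = FALSE)
  }
  n <- as.numeric(design$n_per_stage)
  y1 <- outcome$relabeled_means[1L, ]
  z <- sum(n * y1)
  mle <- z / design$N[3L]
  sd2 <- sqrt(design$v2 * (1 / n[3L] - 1 / design$N[3L]))
  tprime <- (z - design$N[2L] * outcome$thresholds[2L]) / n[3L]
  upper_truncated_normal_mean(mle, sd2, tprime)
}

#' Naive maximum likelihood estimate of the selected treatment mean
#'
#' The selected arm's all-stage cumulative MLE.  Efficient but biased
#' upward under selection, because the interim stage means that earned the
#' arm its selection are conditionally biased.
#'
#' @inheritParams rb1_conditioning
#' @return `sum(n_j * Y_1j) / N_J`.
#' @export
mle_estimate <- function(outcome, design) {
  design <- validate_design(design)
  n <- as.numeric(design$n_per_stage)
  sum(n * outcome$relabeled_means[1L, ]) / design$N[design$J]
}

#' Final-stage estimate of the selected treatment mean
#'
#' The selected arm's stage-`J` sample mean.  Unbiased — the final stage
#' happens after all selection — but inefficient, ignoring all earlier
#' data on the arm.
#'
#' @param outcome a `dtl_selection`.
#' @return `Y_1J`.
#' @export
final_stage_estimate <- function(outcome) {
  y1 <- outcome$relabeled_means[1L, ]
  y1[length(y1)]
}

#' All point estimates for one realized trial
#'
#' @inheritParams rb1_conditioning
#' @param estimators subset of `c("mle", "rb1", "rb2", "bcmle", "final")`.
#'   `"rb2"` requires a three-stage design and `"bcmle"` a 3:2:1 design.
#' @return A named list of class `dtl_estimates`.
#' @examples
#' sc <- dtl_scenario(dtl_design(c(3, 2, 1), 50, 50), c(0, 0, 0), seed = 1)
#' run <- simulate_trial(sc)
#' dtl_estimates(run$outcome, sc$design)
#' @export
dtl_estimates <- function(outcome, design,
                          estimators = c("mle", "rb1", "rb2", "bcmle",
                                         "final")) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  design <- validate_design(design)
  out <- list()
  if ("mle" %in% estimators) out$mle <- mle_estimate(outcome, design)
  if ("rb1" %in% estimators) out$rb1 <- rb1_estimate(outcome, design)
  if ("rb2" %in% estimators && design$J == 3L) {
    out$rb2 <- rb2_estimate(outcome, design)
  }
  if ("bcmle" %in% estimators && identical(design$arms_per_stage,
                                           c(3L, 2L, 1L))) {
    fit <- bcmle_estimate(likelihood_data(outcome, design), design)
    out$bcmle <- unname(fit[1L])
  }
  if ("final" %in% estimators) out$final <- final_stage_estimate(outcome)
  structure(out, class = "dtl_estimates")
}

#' @export
print.dtl_estimates <- function(x, ...) {
  cat("selected-treatment mean estimates\n")
  for (nm in names(x)) cat(sprintf("  %-6s %10.5f\n", nm, x[[nm]]))
  invisible(x)
}
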