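#' Statistics entering the selection-conditioned likelihood
#'
#' For a 3:2:1 trial the conditional likelihood of the three arm means
#' given the selection event uses one statistic per (relabeled) arm: the
#' selected arm's full cumulative MLE `Xbar_13` (variance `v2 / N_3`), the
#' runner-up's stage-two cumulative MLE `Xbar_22` (variance `v2 / N_2`),
#' and the stage-one mean `Y_31` of the arm dropped at stage one
#' (variance `v2 / n_1`).
#'
#' @param outcome a `dtl_selection` from a 3:2:1 trial.
#' @param design the [dtl_design()].
#' @return A list of class `dtl_likelihood_data` with fields `stats`
#'   (named numeric 3-vector) and `vars`.
#' @export
likelihood_data <- function(outcome, design) {
  design <- validate_design(design)
  check_321(design)
  n <- as.numeric(design$n_per_stage)
  y1 <- outcome$relabeled_means[1L, ]
  stats <- c(x13 = sum(n * y1) / design$N[3L],
             x22 = outcome$thresholds[2L],
             y31 = outcome$relabeled_means[3L, 1L])
  vars <- c(design$v2 / design$N[3L], design$v2 / design$N[2L],
            design$v2 / n[1L])
  structure(list(stats = stats, vars = vars),
            class = "dtl_likelihood_data")
}

check_321 <- function(design) {
  if (!identical(design$arms_per_stage, c(3L, 2L, 1L))) {
    stop("this operation is implemented for the 3:2:1 design only",
         call. = FALSE)
  }
  invisible(design)
}

#' Positive-orthant probability of a multivariate normal vector
#'
#' `P(X_1 > 0, ..., X_d > 0)` for `X ~ N(mean, sigma)`.  Diagonal
#' covariances factor into a product of marginal `pnorm` terms; otherwise
#' the deterministic Genz algorithms of \pkg{mvtnorm} are used (TVPACK
#' for 2-3 dimensions), so repeated calls give identical values.
#'
#' @param mean mean vector.
#' @param sigma covariance matrix.
#' @param abseps absolute tolerance of the rectangle algorithm.
#' @return A probability.
#' @export
orthant_prob <- function(mean, sigma, abseps = 1e-6) {
  d <- length(mean)
  if (d == 1L) return(stats::pnorm(mean / sqrt(sigma[1L])))
  off <- sigma; diag(off) <- 0
  if (all(off == 0)) {
    return(prod(stats::pnorm(mean / sqrt(diag(sigma)))))
  }
  alg <- if (d <= 3L) mvtnorm::TVPACK(abseps) else
    mvtnorm::Miwa(steps = 512)
  as.numeric(mvtnorm::pmvnorm(lower = rep(0, d), upper = rep(Inf, d),
                              mean = mean, sigma = sigma, algorithm = alg))
}

# Mean and covariance of the Q-defining difference vector for a 3:2:1
# design.  membership: D = (Y11 - Y31, Y21 - Y31, Xbar12 - Xbar22);
# full:       D = (Y11 - Y21, Y21 - Y31, Xbar12 - Xbar22).
q_difference_moments <- function(means, design,
                                 q_ordering = c("membership", "full")) {
  q_ordering <- match.arg(q_ordering)
  a <- design$v2 / design$n_per_stage[1L]   # var of a stage-1 mean
  b <- design$v2 / design$N[2L]             # var of a stage-2 cumulative MLE
  m <- as.numeric(means)
  if (q_ordering == "membership") {
    list(mean = c(m[1L] - m[3L], m[2L] - m[3L], m[1L] - m[2L]),
         sigma = matrix(c(2 * a,     a,      b,
                              a, 2 * a,     -b,
                              b,    -b,  2 * b), 3L, 3L))
  } else {
    list(mean = c(m[1L] - m[2L], m[2L] - m[3L], m[1L] - m[2L]),
         sigma = matrix(c(2 * a,    -a,  2 * b,
                             -a, 2 * a,     -b,
                          2 * b,    -b,  2 * b), 3L, 3L))
  }
}

#' Probability of the selection event in a 3:2:1 trial
#'
#' The probability, given true means `(mu_1, mu_2, mu_3)` (labeled by
#' final rank), that arm 3 is dropped at stage one and arm 1 beats arm 2
#' on stage-two cumulative MLEs — i.e. that the Q-defining differences
#' `(Y11 - Y31, Y21 - Y31, Xbar12 - Xbar22)` are all positive.  Computed
#' as a deterministic trivariate-normal orthant probability.  With
#' `q_ordering = "full"` the stage-one ordering between the two kept arms
#' is also imposed (`Y11 >= Y21`), giving 1/12 instead of 1/6 under equal
#' means.
#'
#' @param means true means in Q-labeling, length 3.
#' @param design a 3:2:1 [dtl_design()].
#' @param q_ordering `"membership"` (default) conditions only on which
#'   arms were kept at stage one; `"full"` additionally orders the kept
#'   arms.
#' @param abseps absolute tolerance of the orthant-probability algorithm.
#' @return A probability in (0, 1).
#' @examples
#' d <- dtl_design(c(3, 2, 1), 50, 50)
#' selection_probability(c(0, 0, 0), d)       # 1/6
#' @export
selection_probability <- function(means, design,
                                  q_ordering = c("membership", "full"),
                                  abseps = 1e-6) {
  design <- validate_design(design)
  check_321(design)
  qm <- q_difference_moments(means, design, q_ordering)
  orthant_prob(qm$mean, qm$sigma, abseps)
}

#' Selection-conditioned log-likelihood for a 3:2:1 trial
#'
#' The log-likelihood of `(mu_1, mu_2, mu_3)` given the observed
#' statistics and the selection event: three Gaussian log-density terms
#' minus the log selection probability (the normalizing penalty that makes
#' the restricted density integrate to one).
#'
#' @param mu_vec numeric 3-vector of candidate means (Q-labeling).
#' @param data a [likelihood_data()] object.
#' @param design a 3:2:1 [dtl_design()].
#' @return The conditional log-likelihood; `-Inf` (with a warning) where
#'   the selection probability underflows.
#' @export
conditional_loglik <- function(mu_vec, data, design) {
  design <- validate_design(design)
  check_321(design)
  p <- selection_probability(mu_vec, design)
  if (!is.finite(p) || p <= 0) {
    warning("selection probability underflow; log-likelihood is -Inf")
    return(-Inf)
  }
  sum(stats::dnorm(data$stats, mu_vec, sqrt(data$vars), log = TRUE)) - log(p)
}

# objective used by the optimizers: negative conditional log-likelihood
# without the underflow warning (large finite penalty keeps line searches
# inside the region where the orthant probability is positive)
neg_cloglik <- function(mu_vec, data, design) {
  p <- selection_probability(mu_vec, design)
  if (!is.finite(p) || p <= 0) return(1e10)
  -(sum(stats::dnorm(data$stats, mu_vec, sqrt(data$vars), log = TRUE)) -
      log(p))
}

num_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

#' Bias-corrected conditional MLE for a 3:2:1 trial
#'
#' Maximizes the selection-conditioned likelihood jointly over the three
#' arm means, starting from the naive statistics
#' `(Xbar_13, Xbar_22, Y_31)`.  A Nelder-Mead pass is polished by
#' box-constrained quasi-Newton (bounds: each naive statistic plus or
#' minus 10 of its standard deviations, which keeps the search away from
#' orthant-probability underflow); jittered restarts are tried if the
#' finite-difference gradient at the reported optimum is not small.
#'
#' @param data a [likelihood_data()] object.
#' @param design a 3:2:1 [dtl_design()].
#' @param start optional starting 3-vector (default: the naive statistics).
#' @param grad_tol largest acceptable absolute gradient component at the
#'   optimum.
#' @param restarts number of jittered restarts before giving up.
#' @return A named numeric 3-vector `(mu1, mu2, mu3)` of conditional MLEs
#'   with attributes `loglik` (maximized conditional log-likelihood) and
#'   `gradient`.  Errors if no restart converges.
#' @export
bcmle_estimate <- function(data, design, start = NULL, grad_tol = 1e-4,
                           restarts = 3L) {
  design <- validate_design(design)
  check_321(design)
  stat <- as.numeric(data$stats)
  sds <- sqrt(data$vars)
  lower <- stat - 10 * sds
  upper <- stat + 10 * sds
  obj <- function(m) neg_cloglik(m, data, design)
  st <- if (is.null(start)) stat else as.numeric(start)
  for (r in 0:restarts) {
    fit <- stats::optim(st, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    polish <- try(stats::optim(fit$par, obj, method = "L-BFGS-B",
                               lower = lower, upper = upper,
                               control = list(factr = 1e4)), silent = TRUE)
    if (!inherits(polish, "try-error") && polish$value <= fit$value) {
      fit <- polish
    }
    g <- num_gradient(obj, fit$par)
    interior <- all(fit$par > lower + 1e-6) && all(fit$par < upper - 1e-6)
    if (max(abs(g)) < grad_tol && interior) {
      out <- fit$par
      names(out) <- c("mu1", "mu2", "mu3")
      attr(out, "loglik") <- -fit$value
      attr(out, "gradient") <- g
      return(out)
    }
    st <- stat + stats::rnorm(3L, 0, 0.25 * sds)
  }
  # a maximum pinned to the search box (non-zero gradient) means the
  # conditional likelihood drifts without an interior mode for these data;
  # the conditional MLE does not exist and we refuse to report a value
  stop("bias-corrected MLE did not converge after ", restarts,
       " restarts; the conditional likelihood appears to have no ",
       "interior maximum for these data", call. = FALSE)
}
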