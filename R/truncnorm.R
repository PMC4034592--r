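#' Inverse Mills ratio
#'
#' `phi(w) / Phi(w)`, the hazard-type correction factor in the mean of a
#' normal distribution truncated above.  Evaluated on the log scale,
#' `exp(log phi(w) - log Phi(w))`, which stays accurate arbitrarily far
#' into the lower tail where `Phi(w)` itself underflows (there the ratio
#' approaches `-w`).
#'
#' @param w numeric vector of standardized bounds.
#' @return `dnorm(w) / pnorm(w)`, computed stably.
#' @examples
#' mills_ratio(0)            # sqrt(2/pi)
#' mills_ratio(-40) + (-40)  # close to 1/40
#' @export
mills_ratio <- function(w) {
  exp(stats::dnorm(w, log = TRUE) - stats::pnorm(w, log.p = TRUE))
}

#' Mean of a normal distribution truncated above
#'
#' `E[X | X <= t]` for `X ~ N(mu, sd^2)`, the closed form at the heart of
#' the Rao-Blackwellized estimators:
#' `mu - sd * phi(w) / Phi(w)` with `w = (t - mu) / sd`.
#'
#' @param mu mean of the untruncated normal.
#' @param sd standard deviation (positive).
#' @param t upper truncation bound; `+Inf` means no truncation.
#' @return The truncated mean; vectorized over its arguments.
#' @examples
#' upper_truncated_normal_mean(0, 1, 0)      # -sqrt(2/pi), half-normal
#' upper_truncated_normal_mean(0.6, 0.7, Inf)  # 0.6, untruncated
#' @export
upper_truncated_normal_mean <- function(mu, sd, t) {
  if (any(sd <= 0)) stop("'sd' must be positive", call. = FALSE)
  w <- (t - mu) / sd
  out <- mu - sd * mills_ratio(w)
  # no truncation: keep the identity exact even if t - mu overflows
  untrunc <- rep_len(is.infinite(t) & t > 0, length(out))
  if (any(untrunc)) out[untrunc] <- rep_len(mu, length(out))[untrunc]
  out
}
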