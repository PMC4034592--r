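#' Define a multistage drop-the-losers design
#'
#' A J-stage drop-the-losers trial starts with `K1 = arms_per_stage[1]`
#' experimental arms and drops poorly performing arms at each interim
#' analysis, so that `arms_per_stage[j]` arms are active at the start of
#' stage `j` and a single arm remains in the final stage.  At each stage
#' every active arm recruits `n_per_stage[j]` patients whose responses are
#' normal with common within-arm variance `v2`; higher responses are better.
#'
#' @param arms_per_stage integer vector `(K1, ..., KJ)`, strictly decreasing
#'   with `KJ = 1`.
#' @param n_per_stage integer vector of per-arm per-stage sample sizes, all
#'   at least 1.  Recycled to length `J` if a single value is given.
#' @param v2 positive within-arm response variance.
#'
#' @return An object of class `dtl_design` with derived fields:
#'   `J` (stage count), `sigma` (stage-wise standard errors
#'   `sqrt(v2 / n_j)` of a single arm's stage mean) and `N` (cumulative
#'   per-arm sample sizes `N_j = n_1 + ... + n_j`).
#'
#' @examples
#' d <- dtl_design(c(3, 2, 1), n_per_stage = 50, v2 = 50)
#' d$sigma  # all 1
#' @seealso [parse_design_string()], [dtl_scenario()]
#' @export
dtl_design <- function(arms_per_stage, n_per_stage, v2) {
  if (length(n_per_stage) == 1L) {
    n_per_stage <- rep(n_per_stage, length(arms_per_stage))
  }
  validate_design(structure(
    list(arms_per_stage = as.integer(arms_per_stage),
         n_per_stage = as.integer(n_per_stage),
         v2 = as.numeric(v2)),
    class = "dtl_design"))
}

#' Validate a drop-the-losers design and populate derived fields
#'
#' Checks the design invariants (strictly decreasing arm schedule ending in a
#' single arm, positive sample sizes, positive variance) and fills in the
#' derived quantities `J`, `sigma` and `N`.
#'
#' @param design a `dtl_design`, or a bare list with fields
#'   `arms_per_stage`, `n_per_stage` and `v2`.
#' @return The validated `dtl_design` with derived fields populated.
#' @export
validate_design <- function(design) {
  a <- design$arms_per_stage
  n <- design$n_per_stage
  v2 <- design$v2
  J <- length(a)
  if (J < 2L) {
    stop("a drop-the-losers design needs at least two stages", call. = FALSE)
  }
  if (length(n) != J) {
    stop("'n_per_stage' must have one entry per stage", call. = FALSE)
  }
  if (any(diff(a) >= 0L)) {
    stop("'arms_per_stage' must be strictly decreasing", call. = FALSE)
  }
  if (a[J] != 1L) {
    stop("the final stage must have exactly one experimental arm",
         call. = FALSE)
  }
  if (any(n < 1L) || anyNA(n)) {
    stop("'n_per_stage' entries must be positive integers", call. = FALSE)
  }
  if (!is.finite(v2) || v2 <= 0) {
    stop("'v2' must be a positive variance", call. = FALSE)
  }
  design$J <- J
  design$sigma <- sqrt(v2 / n)
  design$N <- cumsum(as.numeric(n))
  class(design) <- "dtl_design"
  design
}

#' Parse a "K:L:...:1" design label
#'
#' Designs are conventionally named by their arm schedule, e.g. `"3:2:1"`
#' for a three-stage trial keeping two of three arms after stage one.
#'
#' @param s a string of colon-separated positive integers.
#' @param n_per_stage,v2 passed on to [dtl_design()]; when omitted the
#'   returned fragment is a bare list holding only the arm schedule.
#' @return A `dtl_design` when `n_per_stage` and `v2` are supplied,
#'   otherwise a list with fields `arms_per_stage` and `J`.
#' @examples
#' parse_design_string("6:2:1")$arms_per_stage
#' parse_design_string("3:2:1", n_per_stage = 50, v2 = 50)
#' @export
parse_design_string <- function(s, n_per_stage = NULL, v2 = NULL) {
  tokens <- strsplit(trimws(s), ":", fixed = TRUE)[[1]]
  a <- suppressWarnings(as.integer(tokens))
  if (length(a) < 2L || anyNA(a) || any(a < 1L)) {
    stop("design string must be colon-separated positive integers, e.g. \"3:2:1\"",
         call. = FALSE)
  }
  if (any(diff(a) >= 0L)) {
    stop("design string must be strictly decreasing, e.g. \"3:2:1\"",
         call. = FALSE)
  }
  if (a[length(a)] != 1L) {
    stop("design string must end in 1 (single final-stage arm)", call. = FALSE)
  }
  if (is.null(n_per_stage) || is.null(v2)) {
    return(list(arms_per_stage = a, J = length(a)))
  }
  dtl_design(a, n_per_stage, v2)
}

#' @export
print.dtl_design <- function(x, ...) {
  cat(sprintf("%s drop-the-losers design (%d stages)\n",
              paste(x$arms_per_stage, collapse = ":"), x$J))
  cat("  n per arm per stage:", paste(x$n_per_stage, collapse = ", "), "\n")
  cat(sprintf("  within-arm variance v2 = %g; stage-mean sd: %s\n",
              x$v2, paste(signif(x$sigma, 4), collapse = ", ")))
  invisible(x)
}
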