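#' Define a simulation scenario
#'
#' Couples a design with a vector of true arm means and replication
#' settings.  Patient responses are `Y ~ N(mu_k, v2)` so that the stage-j
#' mean of an arm is `N(mu_k, v2 / n_j)`.
#'
#' @param design a [dtl_design()].
#' @param means numeric vector of true means, one per initial arm.
#' @param reps number of replicate trials.
#' @param seed master seed; each replicate uses an independent substream
#'   derived from `(seed, replicate_index)` so any single replicate is
#'   reproducible in isolation.
#' @param patient_level if `TRUE`, [simulate_trial()] draws and stores raw
#'   patient responses (required for the conditional bootstrap); otherwise
#'   only stage-wise means are drawn.
#' @return An object of class `dtl_scenario`.
#' @examples
#' d <- dtl_design(c(3, 2, 1), 50, 50)
#' sc <- dtl_scenario(d, means = c(0, 0, 0), reps = 1000, seed = 1)
#' @export
dtl_scenario <- function(design, means, reps = 1L, seed = NULL,
                         patient_level = FALSE) {
  design <- validate_design(design)
  if (length(means) != design$arms_per_stage[1]) {
    stop("'means' must have one entry per initial arm", call. = FALSE)
  }
  if (reps < 1L) stop("'reps' must be at least 1", call. = FALSE)
  structure(list(design = design, means = as.numeric(means),
                 reps = as.integer(reps),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 patient_level = isTRUE(patient_level)),
            class = "dtl_scenario")
}

# Substream seed for one replicate; kept below 2^31.
replicate_seed <- function(seed, replicate_index) {
  as.integer((as.double(seed) * 69069 + as.double(replicate_index)) %%
               2147483629 + 1)
}

#' Cumulative maximum likelihood estimate of an arm mean
#'
#' The cumulative MLE through stage `j` is the sample-size weighted mean
#' `sum(n_i * Y_i) / N_j` of the arm's stage-wise means, the statistic by
#' which active arms are ranked at each interim analysis.
#'
#' @param stage_means numeric vector of the arm's stage-wise means.
#' @param n_per_stage per-stage sample sizes.
#' @param through_stage last stage to include.
#' @return The weighted mean through `through_stage`.
#' @examples
#' cumulative_mle(c(1, 2, 3), c(100, 50, 25), 3)  # 275/175
#' @export
cumulative_mle <- function(stage_means, n_per_stage, through_stage) {
  j <- as.integer(through_stage)
  if (j < 1L || j > length(stage_means) || j > length(n_per_stage)) {
    stop("'through_stage' outside the arm's activity", call. = FALSE)
  }
  y <- stage_means[seq_len(j)]
  n <- n_per_stage[seq_len(j)]
  if (anyNA(y)) stop("arm not active through the requested stage", call. = FALSE)
  sum(n * y) / sum(n)
}

#' Apply the drop-the-losers selection rule to observed stage means
#'
#' At each interim stage `j < J` the active arms are ranked by their
#' cumulative MLEs; the top `arms_per_stage[j + 1]` are kept and the rest
#' dropped.  Exact ties are broken in favour of the lower original arm
#' index (a probability-zero event for continuous data).  The realized set
#' of selection inequalities is the conditioning event Q of the estimators.
#'
#' @param trial a `dtl_trial` from [simulate_trial()], or a bare
#'   `K1 x J` matrix of stage means with `NA` for inactive arm-stage cells.
#' @param design the [dtl_design()].
#' @param means optional true arm means; when supplied, the true mean of
#'   the selected arm is recorded for simulation bookkeeping.
#' @return An object of class `dtl_selection` with fields
#'   `selected_arm` (original index), `ranking` (final rank of each
#'   original arm; 1 = selected), `relabeled_means` (stage means with row
#'   `k` the rank-`k` arm, so that row 1 satisfies the Q inequalities),
#'   `cumulative_mles`, `survivors_per_stage` (original indices active at
#'   the start of each stage), `thresholds` (for each selection stage, the
#'   largest cumulative MLE among the arms dropped there — the value the
#'   surviving arms had to match or beat) and `mu_selected`.
#' @examples
#' d <- dtl_design(c(3, 2, 1), 50, 50)
#' m <- matrix(c(0.5, 0.9, 0.1, 1.5, 0.1, NA, 0.7, NA, NA), 3, 3)
#' rank_and_select(m, d)$selected_arm
#' @export
rank_and_select <- function(trial, design, means = NULL) {
  design <- validate_design(design)
  Y <- if (inherits(trial, "dtl_trial")) trial$stage_means else as.matrix(trial)
  K1 <- design$arms_per_stage[1]
  J <- design$J
  if (nrow(Y) != K1 || ncol(Y) != J) {
    stop("stage-mean matrix must be K1 x J", call. = FALSE)
  }
  n <- design$n_per_stage
  cum <- matrix(NA_real_, K1, J)
  active <- seq_len(K1)
  survivors <- vector("list", J)
  dropped_at <- integer(K1)        # selection stage at which each arm was dropped
  drop_rank_stat <- rep(NA_real_, K1)
  thresholds <- numeric(J - 1L)
  S <- numeric(K1)                 # running sum n_i * Y_i per arm
  for (j in seq_len(J)) {
    survivors[[j]] <- active
    if (anyNA(Y[active, j])) {
      stop("stage means missing for active arms at stage ", j, call. = FALSE)
    }
    S[active] <- S[active] + n[j] * Y[active, j]
    cum[active, j] <- S[active] / design$N[j]
    if (j < J) {
      keep_m <- design$arms_per_stage[j + 1L]
      ord <- active[order(-cum[active, j], active)]
      kept <- ord[seq_len(keep_m)]
      gone <- ord[-seq_len(keep_m)]
      thresholds[j] <- max(cum[gone, j])
      dropped_at[gone] <- j
      drop_rank_stat[gone] <- cum[gone, j]
      active <- sort(kept)
    }
  }
  selected <- active
  dropped_at[selected] <- J        # "dropped" last, i.e. never
  drop_rank_stat[selected] <- cum[selected, J]
  # rank 1 = selected; later-dropped arms rank ahead of earlier-dropped;
  # within a drop stage, by cumulative MLE at drop time (ties: lower index)
  ord_all <- order(-dropped_at, -drop_rank_stat, seq_len(K1))
  ranking <- integer(K1)
  ranking[ord_all] <- seq_len(K1)
  structure(list(
    selected_arm = selected,
    ranking = ranking,
    relabeled_means = Y[ord_all, , drop = FALSE],
    cumulative_mles = cum,
    survivors_per_stage = survivors,
    thresholds = thresholds,
    mu_selected = if (is.null(means)) NA_real_ else as.numeric(means[selected])),
    class = "dtl_selection")
}

#' Check that a selection outcome satisfies its own Q inequalities
#'
#' @param outcome a `dtl_selection`.
#' @param tol numeric slack for floating-point comparison.
#' @return `TRUE` if at every selection stage each kept arm's cumulative
#'   MLE is at least every dropped arm's, and the selected arm leads the
#'   final interim ranking.
#' @export
q_satisfied <- function(outcome, tol = 1e-10) {
  cum <- outcome$cumulative_mles
  sv <- outcome$survivors_per_stage
  J <- length(sv)
  for (j in seq_len(J - 1L)) {
    kept <- sv[[j + 1L]]
    gone <- setdiff(sv[[j]], kept)
    if (min(cum[kept, j]) < max(cum[gone, j]) - tol) return(FALSE)
  }
  TRUE
}

#' Simulate one drop-the-losers trial
#'
#' Draws stage-wise arm means (or patient-level responses when the
#' scenario requests them), applying the selection rule between stages so
#' that only surviving arms are observed later.  The same
#' `(seed, replicate_index)` pair always reproduces the same trial.
#'
#' @param scenario a [dtl_scenario()].
#' @param replicate_index replicate number, used to derive the RNG
#'   substream.
#' @return A list with components `trial` (class `dtl_trial`: the
#'   `stage_means` matrix and, if requested, `patient_responses`, a list
#'   indexed `[[arm]][[stage]]`) and `outcome` (a `dtl_selection`).
#' @examples
#' sc <- dtl_scenario(dtl_design(c(3, 2, 1), 50, 50), c(0, 0, 0), seed = 7)
#' simulate_trial(sc, 1)$outcome$selected_arm
#' @export
simulate_trial <- function(scenario, replicate_index = 1L) {
  design <- scenario$design
  if (!is.null(scenario$seed)) {
    set.seed(replicate_seed(scenario$seed, replicate_index))
  }
  K1 <- design$arms_per_stage[1]
  J <- design$J
  n <- design$n_per_stage
  mu <- scenario$means
  Y <- matrix(NA_real_, K1, J)
  patient <- if (scenario$patient_level) {
    lapply(seq_len(K1), function(k) vector("list", J))
  }
  active <- seq_len(K1)
  S <- numeric(K1)
  for (j in seq_len(J)) {
    for (k in active) {
      if (scenario$patient_level) {
        x <- stats::rnorm(n[j], mu[k], sqrt(design$v2))
        patient[[k]][[j]] <- x
        Y[k, j] <- mean(x)
      } else {
        Y[k, j] <- stats::rnorm(1L, mu[k], design$sigma[j])
      }
    }
    S[active] <- S[active] + n[j] * Y[active, j]
    if (j < J) {
      keep_m <- design$arms_per_stage[j + 1L]
      cumj <- S[active] / design$N[j]
      active <- sort(active[order(-cumj, active)][seq_len(keep_m)])
    }
  }
  trial <- structure(list(stage_means = Y, patient_responses = patient),
                     class = "dtl_trial")
  list(trial = trial,
       outcome = rank_and_select(trial, design, means = mu))
}

#' Simulate many trials at summary level (vectorized)
#'
#' Fast batch engine used by the operating-characteristics functions: all
#' replicates are advanced through the stages together, drawing stage
#' means directly as `N(mu_k, v2 / n_j)`.  A single RNG stream seeded by
#' `scenario$seed` drives the whole batch.
#'
#' @param scenario a [dtl_scenario()].
#' @return A data.frame of class `dtl_sims` with one row per replicate:
#'   `replicate`, `selected` (original arm index), `mu_selected`, the
#'   selected arm's stage means `y1 ... yJ`, its sufficient total
#'   `z = sum(n_j * y_j)`, `mle`, and the selection thresholds
#'   `c1 ... c(J-1)` (largest dropped cumulative MLE per selection stage).
#' @examples
#' sc <- dtl_scenario(dtl_design(c(3, 2, 1), 50, 50), c(0, 0, 0),
#'                    reps = 100, seed = 1)
#' head(simulate_trials(sc))
#' @export
simulate_trials <- function(scenario) {
  design <- scenario$design
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  R <- scenario$reps
  K1 <- design$arms_per_stage[1]
  J <- design$J
  n <- design$n_per_stage
  mu <- scenario$means
  active <- matrix(TRUE, R, K1)
  S <- matrix(0, R, K1)
  ymeans <- matrix(NA_real_, R, J)       # selected arm's stage means (filled later)
  ystage <- vector("list", J)            # all drawn stage means
  thr <- matrix(NA_real_, R, J - 1L)
  for (j in seq_len(J)) {
    Yj <- matrix(stats::rnorm(R * K1, rep(mu, each = R), design$sigma[j]), R, K1)
    Yj[!active] <- NA_real_
    ystage[[j]] <- Yj
    S <- S + ifelse(active, n[j] * Yj, 0)
    if (j < J) {
      keep_m <- design$arms_per_stage[j + 1L]
      X <- S / design$N[j]
      X[!active] <- -Inf
      # within-row descending order; stable, so ties favour lower arm index
      li <- matrix(order(row(X), -X), nrow = R, byrow = TRUE)
      colidx <- (li - 1L) %/% R + 1L
      thr[, j] <- X[cbind(seq_len(R), colidx[, keep_m + 1L])]
      active[] <- FALSE
      active[cbind(rep(seq_len(R), keep_m),
                   as.vector(colidx[, seq_len(keep_m)]))] <- TRUE
    }
  }
  selected <- max.col(active, ties.method = "first")
  idx <- cbind(seq_len(R), selected)
  for (j in seq_len(J)) ymeans[, j] <- ystage[[j]][idx]
  z <- as.vector(ymeans %*% n)
  out <- data.frame(replicate = seq_len(R), selected = selected,
                    mu_selected = mu[selected])
  colnames(ymeans) <- paste0("y", seq_len(J))
  colnames(thr) <- paste0("c", seq_len(J - 1L))
  out <- cbind(out, ymeans, z = z, mle = z / design$N[J], thr)
  class(out) <- c("dtl_sims", "data.frame")
  out
}

#' Tidy per-arm per-stage view of a simulated trial
#'
#' @param trial a `dtl_trial`.
#' @param outcome the matching `dtl_selection`.
#' @param design the [dtl_design()].
#' @param replicate replicate label for the `replicate` column.
#' @return A data.frame with columns `replicate`, `arm`, `stage`, `n`,
#'   `mean` and `selected`, one row per active arm-stage cell — suitable
#'   for writing as tidy CSV via [write_results()].
#' @export
tidy_trial <- function(trial, outcome, design, replicate = 1L) {
  Y <- trial$stage_means
  act <- which(!is.na(Y), arr.ind = TRUE)
  data.frame(replicate = replicate,
             arm = act[, 1L],
             stage = act[, 2L],
             n = design$n_per_stage[act[, 2L]],
             mean = Y[act],
             selected = act[, 1L] == outcome$selected_arm)[
    order(act[, 2L], act[, 1L]), , drop = FALSE]
}

#' @export
print.dtl_selection <- function(x, ...) {
  cat("drop-the-losers selection outcome\n")
  cat("  selected arm:", x$selected_arm,
      sprintf(" (true mean %s)\n",
              ifelse(is.na(x$mu_selected), "unknown", x$mu_selected)))
  cat("  final ranking (per original arm):",
      paste(x$ranking, collapse = ", "), "\n")
  invisible(x)
}
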