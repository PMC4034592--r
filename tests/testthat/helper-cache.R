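# shared fixtures and one-shot heavy simulation runs (computed on first use,
# reused by the property and acceptance tests in the same session)

null_design <- function() dtl_design(c(3L, 2L, 1L), 50L, 50)
unequal_design <- function() dtl_design(c(3L, 2L, 1L), c(100L, 50L, 25L), 50)

.cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) {
    assign(name, force(expr), envir = .cache)
  }
  get(name, envir = .cache)
}

# Table-1 scenario: 3:2:1, all means 0, 50 patients/arm/stage, v2 = 50
cached_null_oc <- function() cached("null_oc", {
  sc <- dtl_scenario(null_design(), c(0, 0, 0), reps = 50000L, seed = 101L)
  oc_study(sc, estimators = c("mle", "rb1", "rb2", "final"))
})

cached_null_bcmle <- function() cached("null_bcmle", {
  sc <- dtl_scenario(null_design(), c(0, 0, 0), reps = 2000L, seed = 102L)
  oc_study(sc, estimators = "bcmle", bcmle_reps = 2000L)
})

# unequal-allocation scenario: n = (100, 50, 25), v2 = 50, means 0
cached_unequal_oc <- function() cached("unequal_oc", {
  sc <- dtl_scenario(unequal_design(), c(0, 0, 0), reps = 100000L,
                     seed = 103L)
  oc_study(sc, estimators = c("mle", "rb1", "rb2", "final"))
})

cached_unequal_bcmle <- function() cached("unequal_bcmle", {
  sc <- dtl_scenario(unequal_design(), c(0, 0, 0), reps = 2000L,
                     seed = 104L)
  oc_study(sc, estimators = "bcmle", bcmle_reps = 2000L)
})

# interval study at reduced scale: 1,000 trials x 500 accepted resamples
cached_coverage <- function() cached("coverage", {
  sc <- dtl_scenario(null_design(), c(0, 0, 0), reps = 1000L, seed = 105L,
                     patient_level = TRUE)
  coverage_study(sc,
                 methods = c("bootstrap_rb1", "bootstrap_rb2",
                             "profile_bcmle", "wald_final"),
                 settings = bootstrap_settings(B = 500L))
})

oc_row <- function(oc, estimator) {
  oc$summary[oc$summary$estimator == estimator, , drop = FALSE]
}

cov_row <- function(cov, method) {
  cov$summary[cov$summary$method == method, , drop = FALSE]
}

# tolerance for comparing two Monte-Carlo estimates of the same quantity at
# matched replication (ours and a published one), floored at half the
# published value's printed precision
mc_tol <- function(se, printed_unit = 0) {
  max(3 * sqrt(2) * se, printed_unit / 2)
}
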