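# Shared fixtures, built lazily once per test run and cached, so the
# expensive hierarchical fits are reused across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

base_bias <- c("extrinsic-win" = 0.35, "extrinsic-loss" = 0.45,
               "intrinsic-win" = 0.55, "intrinsic-loss" = 0.65)

one_group <- function(n, ...) {
  list(group_spec("HC", n, bias_mean = base_bias, ...))
}

# n = 40 subjects, 228 trials each, sigmoid truth: used for the
# parameter-recovery, shrinkage and evidence-trace checks.
recovery_fixture <- function() fixture("recovery", function() {
  cohort <- generate_cohort(one_group(40), seed = 101L)
  st <- fit_settings(max_rounds = 5L, tol = 0.01, n_starts = 2L, seed = 7L)
  full <- suppressWarnings(fit_hierarchical(cohort, "sigmoid", st))
  st1 <- fit_settings(max_rounds = 1L, tol = 0.01, n_starts = 2L, seed = 7L)
  round1 <- suppressWarnings(fit_hierarchical(cohort, "sigmoid", st1))
  list(cohort = cohort, fit = full, fit_round1 = round1, settings = st)
})

# n = 30 subjects generated from the sigmoid family, all three families
# fitted: used for model comparison.
bms_fixture <- function() fixture("bms", function() {
  cohort <- generate_cohort(one_group(30), seed = 202L)
  st <- fit_settings(max_rounds = 3L, tol = 0.01, n_starts = 2L, seed = 7L)
  fits <- lapply(c(linear = "linear", sigmoid = "sigmoid",
                   weibull = "weibull"),
                 function(fam)
                   suppressWarnings(fit_hierarchical(cohort, fam, st)))
  L <- evidence_matrix(fits)
  bms <- protected_ep(rfx_bms(L, n_samples = 1e5, seed = 9L))
  list(cohort = cohort, fits = fits, evidence = L, bms = bms)
})

# merge fitted and true parameters per subject x condition
recovery_merge <- function(fit, cohort) {
  merge(fit$estimates_table, truth_table(cohort),
        by = c("subject_id", "condition"),
        suffixes = c("_hat", "_true"))
}
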