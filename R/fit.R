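# Hierarchical empirical-Bayes curve fitting. Subject-level MAP estimation
# with a Laplace approximation to the model evidence, alternated with a
# population-prior update (parametric empirical Bayes): the Gaussian prior
# over transformed parameters is re-estimated from the subject posteriors and
# fed into the next round, until the summed log evidence stops improving.
#
# Positivity-constrained parameters (sigma, asymptotes, latency, abruptness,
# noise) are fit on the log scale; bias is fit untransformed so it can sit
# outside (0, 1) for never/always-motivated subjects.

.fit_par_names <- function(family, control) {
  noise <- if (control == "extrinsic") "log_tau" else "log_sigma_obs"
  switch(family,
         linear  = c("m", "c", noise),
         sigmoid = c("bias", "log_sigma", "log_c", noise),
         weibull = c("log_A", "log_L", "log_S", noise))
}

# transformed parameter vector -> natural-scale named list
.to_natural <- function(theta) {
  nm <- names(theta)
  logp <- startsWith(nm, "log_")
  out <- as.list(ifelse(logp, exp(theta), theta))
  names(out) <- ifelse(logp, substring(nm, 5), nm)
  out
}

# fast unclassed curve evaluation used inside the optimizer
.curve_y <- function(family, nat, x) {
  switch(family,
         linear  = nat$m * x + nat$c,
         sigmoid = nat$c / (1 + exp(-(x - nat$bias) / nat$sigma)),
         weibull = nat$A * (1 - 2^(-(x * nat$L)^nat$S)))
}

# summed data log-likelihood of one subject-condition block
.block_loglik <- function(theta, family, control, tr, effort_cap) {
  nat <- .to_natural(theta)
  y <- .clamp_effort(.curve_y(family, nat, tr$outcome_norm), effort_cap)
  if (control == "extrinsic") {
    z <- (y - tr$offered_effort) / nat$tau
    sum(plogis(ifelse(tr$accepted, z, -z), log.p = TRUE))
  } else {
    sum(dnorm(tr$reported_effort, mean = y, sd = nat$sigma_obs, log = TRUE))
  }
}

#' Fitting settings
#'
#' @param max_rounds maximum empirical-Bayes rounds.
#' @param tol convergence tolerance on the change in group log evidence
#'   (nats).
#' @param n_starts optimizer multi-starts per fit (prior mean plus jittered
#'   starts).
#' @param jitter_sd start jitter, in units of the prior sd.
#' @param seed integer seed for the deterministic start jitter.
#' @param effort_cap press cap used at the observation stage.
#' @return List of class `"fit_settings"`.
#' @export
fit_settings <- function(max_rounds = 16L, tol = 0.01, n_starts = 4L,
                         jitter_sd = 0.5, seed = 1L, effort_cap = 70) {
  stopifnot(max_rounds >= 1, tol > 0, n_starts >= 1)
  structure(list(max_rounds = as.integer(max_rounds), tol = tol,
                 n_starts = as.integer(n_starts), jitter_sd = jitter_sd,
                 seed = as.integer(seed), effort_cap = effort_cap),
            class = "fit_settings")
}

#' Initial (round-1) population prior for one family and control condition
#'
#' Weakly informative Gaussian in transformed space: bias centred at 0.5,
#' sigma at 0.2, asymptotes at 0.75 x effort cap, noise at 5 presses, with
#' sd 1 on each transformed coordinate (sd 25 for the linear family's
#' untransformed press-scale gradient and intercept).
#'
#' @param family curve family.
#' @param control `"extrinsic"` or `"intrinsic"`.
#' @param effort_cap press cap.
#' @return List with `mean` (named) and `cov`.
#' @export
initial_prior <- function(family, control, effort_cap = 70) {
  nm <- .fit_par_names(family, control)
  mu <- vapply(nm, function(p) switch(p,
    bias = 0.5, log_sigma = log(0.2), log_c = log(0.75 * effort_cap),
    log_A = log(0.75 * effort_cap), log_L = log(2), log_S = 0,
    log_tau = log(5), log_sigma_obs = log(5),
    m = 0.5 * effort_cap, c = 10), numeric(1))
  sd <- vapply(nm, function(p) if (p %in% c("m", "c")) 25 else 1, numeric(1))
  S <- diag(sd^2, length(nm))
  dimnames(S) <- list(nm, nm)
  list(mean = mu, cov = S)
}

#' Fit one subject-condition block under a Gaussian prior
#'
#' MAP estimation in transformed parameter space by quasi-Newton (BFGS)
#' optimization with deterministic multi-start, posterior covariance from
#' the Hessian at the optimum, and log evidence by the Laplace approximation
#' `log p(D|th) + log p(th) + (d/2) log 2pi - 0.5 log |H|`.
#'
#' @param trials data.frame of one subject's trials for one condition
#'   (single control and valence), with response columns. An empty block
#'   returns the prior unchanged with zero log evidence (useful in tests).
#' @param family curve family.
#' @param prior list with `mean` and `cov` over the transformed parameters.
#' @param settings a [fit_settings()].
#' @param subject_id,condition identifiers carried into the result and any
#'   error message.
#' @return List of class `"posterior_estimate"`: `subject_id`, `condition`,
#'   `family`, `mean`, `cov`, `log_evidence`, `natural` (natural-scale
#'   parameter list), `hessian_ok`.
#' @export
fit_subject_condition <- function(trials, family, prior, settings =
                                    fit_settings(), subject_id = "subject",
                                  condition = NULL) {
  if (is.null(condition)) {
    condition <- if (nrow(trials)) .condition_of(trials$control[1],
                                                 trials$valence[1])
                 else "extrinsic-win"
  }
  control <- .control_of(condition)
  nm <- names(prior$mean)
  d <- length(nm)
  if (nrow(trials) == 0L) {
    return(structure(list(subject_id = subject_id, condition = condition,
                          family = family, mean = prior$mean,
                          cov = prior$cov, log_evidence = 0,
                          natural = .to_natural(prior$mean),
                          hessian_ok = TRUE),
                     class = "posterior_estimate"))
  }
  if (length(unique(trials$control)) != 1L)
    stop("a subject-condition block must contain a single control condition")
  cap <- settings$effort_cap
  nlj <- function(theta) {
    names(theta) <- nm
    ll <- .block_loglik(theta, family, control, trials, cap)
    if (!is.finite(ll)) return(1e10)
    -(ll + .dmvnorm_log(theta, prior$mean, prior$cov))
  }
  prior_sd <- sqrt(diag(prior$cov))
  starts <- .with_seed(.hash_seed(settings$seed, subject_id, condition, family), {
    s <- matrix(rep(prior$mean, settings$n_starts), nrow = settings$n_starts,
                byrow = TRUE)
    if (settings$n_starts > 1L)
      s[-1, ] <- s[-1, , drop = FALSE] +
        matrix(rnorm((settings$n_starts - 1L) * d, 0, settings$jitter_sd),
               ncol = d) %*% diag(prior_sd, d)
    s
  })
  best <- NULL
  for (k in seq_len(settings$n_starts)) {
    fit <- tryCatch(optim(starts[k, ], nlj, method = "BFGS",
                          control = list(maxit = 300)),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("non-finite likelihood at all starts for ", subject_id, " / ",
         condition, " (", family, ")")
  theta <- best$par
  names(theta) <- nm
  H <- tryCatch(optimHess(theta, nlj), error = function(e) NULL)
  hessian_ok <- !is.null(H) && all(is.finite(H)) &&
    inherits(tryCatch(chol((H + t(H)) / 2), error = function(e) e),
             "matrix")
  if (hessian_ok) {
    H <- (H + t(H)) / 2
    cov <- .make_spd(solve(H))
    logdetH <- as.numeric(determinant(H, logarithm = TRUE)$modulus)
  } else {
    warning("singular Hessian for ", subject_id, " / ", condition,
            "; using prior covariance", call. = FALSE)
    cov <- prior$cov
    logdetH <- -as.numeric(determinant(prior$cov, logarithm = TRUE)$modulus)
  }
  log_ev <- -best$value + 0.5 * d * log(2 * pi) - 0.5 * logdetH
  dimnames(cov) <- list(nm, nm)
  structure(list(subject_id = subject_id, condition = condition,
                 family = family, mean = theta, cov = cov,
                 log_evidence = log_ev, natural = .to_natural(theta),
                 hessian_ok = hessian_ok),
            class = "posterior_estimate")
}

#' Update the population prior from subject posteriors
#'
#' Parametric empirical-Bayes update, computed per condition: the new prior
#' mean is the mean of the posterior means, and the new prior covariance is
#' the between-subject covariance of posterior means plus the average
#' within-subject posterior covariance, regularized to symmetric positive
#' definite.
#'
#' @param estimates list of `"posterior_estimate"` objects (>= 2 per
#'   condition).
#' @param round_index stored on the result.
#' @return Named list of class `"population_prior"`, one `(mean, cov)` pair
#'   per condition, with attribute `round_index`.
#' @export
update_population_prior <- function(estimates, round_index = 1L) {
  conds <- unique(vapply(estimates, `[[`, character(1), "condition"))
  out <- list()
  for (cd in conds) {
    es <- Filter(function(e) e$condition == cd, estimates)
    if (length(es) < 2L)
      stop("need >= 2 estimates per condition; condition ", cd, " has ",
           length(es))
    M <- do.call(rbind, lapply(es, `[[`, "mean"))
    mu <- colMeans(M)
    within <- Reduce(`+`, lapply(es, `[[`, "cov")) / length(es)
    between <- cov(M)
    out[[cd]] <- list(mean = mu, cov = .make_spd(between + within, 1e-6))
  }
  structure(out, round_index = as.integer(round_index),
            class = "population_prior")
}

#' Fit one curve family to a whole cohort (mixed-effects loop)
#'
#' Alternates subject-level MAP fits ([fit_subject_condition()], all
#' subjects and all four conditions) with the population-prior update
#' ([update_population_prior()]) until the group log evidence (the sum over
#' all fits) gains less than `settings$tol` nats, or `settings$max_rounds`
#' is reached (in which case the convergence flag is `FALSE`, no error).
#' Subjects making the same extrinsic button response on every trial are
#' flagged as deterministic responders and excluded before fitting.
#'
#' @param dataset an `"imt_cohort"` or a list with a `trials` data.frame
#'   (multi-subject trial table with response columns).
#' @param family curve family to fit.
#' @param settings a [fit_settings()].
#' @return List of class `"hier_fit"`: `estimates` (list of posterior
#'   estimates from the final round), `estimates_table` (tidy data.frame:
#'   subject, condition, family, natural-scale parameters, log evidence),
#'   `prior` (final population prior), `trace` (per-round group log
#'   evidence, convergence flag, rounds, excluded subjects).
#' @export
fit_hierarchical <- function(dataset, family = "sigmoid",
                             settings = fit_settings()) {
  trials <- dataset$trials
  stopifnot(!is.null(trials), nrow(trials) > 0)
  excluded <- flag_deterministic(trials)
  if (length(excluded)) {
    warning("excluding ", length(excluded), " deterministic responder(s): ",
            paste(excluded, collapse = ", "), call. = FALSE)
    trials <- trials[!trials$subject_id %in% excluded, , drop = FALSE]
  }
  ids <- unique(trials$subject_id)
  if (length(ids) < 2L) stop("need >= 2 subjects after exclusions")
  trials$condition <- .condition_of(trials$control, trials$valence)
  blocks <- split(trials, list(trials$subject_id, trials$condition),
                  drop = TRUE)
  conds <- unique(trials$condition)
  prior <- structure(
    lapply(stats::setNames(conds, conds), function(cd)
      initial_prior(family, .control_of(cd), settings$effort_cap)),
    round_index = 0L, class = "population_prior")
  trace_le <- numeric(0)
  converged <- FALSE
  estimates <- NULL
  for (r in seq_len(settings$max_rounds)) {
    estimates <- lapply(blocks, function(b)
      fit_subject_condition(b, family, prior[[b$condition[1]]], settings,
                            subject_id = b$subject_id[1],
                            condition = b$condition[1]))
    total <- sum(vapply(estimates, `[[`, numeric(1), "log_evidence"))
    trace_le <- c(trace_le, total)
    if (r > 1L && abs(total - trace_le[r - 1L]) < settings$tol) {
      converged <- TRUE
      break
    }
    if (r < settings$max_rounds)
      prior <- update_population_prior(estimates, round_index = r)
  }
  all_pars <- unique(unlist(lapply(estimates,
                                   function(e) names(e$natural))))
  tab <- do.call(rbind, lapply(estimates, function(e) {
    df <- data.frame(subject_id = e$subject_id, condition = e$condition,
                     family = e$family, log_evidence = e$log_evidence,
                     stringsAsFactors = FALSE)
    for (p in all_pars) df[[p]] <- e$natural[[p]] %||% NA_real_
    df
  }))
  rownames(tab) <- NULL
  structure(list(estimates = estimates, estimates_table = tab, prior = prior,
                 trace = list(group_log_evidence = trace_le,
                              converged = converged,
                              rounds = length(trace_le),
                              excluded = excluded)),
            class = "hier_fit")
}

#' Subjects-by-families log-evidence matrix
#'
#' Sums each subject's per-condition log evidence within each fitted family,
#' producing the input to [rfx_bms()].
#'
#' @param fits named list of `"hier_fit"` results (names = families).
#' @return Numeric matrix, rows = subjects, columns = families.
#' @export
evidence_matrix <- function(fits) {
  stopifnot(length(fits) >= 2, !is.null(names(fits)))
  cols <- lapply(fits, function(f) {
    tab <- f$estimates_table
    tapply(tab$log_evidence, tab$subject_id, sum)
  })
  ids <- sort(Reduce(intersect, lapply(cols, names)))
  M <- vapply(cols, function(v) v[ids], numeric(length(ids)))
  rownames(M) <- ids
  M
}

#' @export
print.hier_fit <- function(x, ...) {
  tr <- x$trace
  cat("Hierarchical fit:", x$estimates_table$family[1], "|",
      length(unique(x$estimates_table$subject_id)), "subjects |",
      tr$rounds, "round(s), converged:", tr$converged, "\n")
  cat("Group log evidence:",
      paste(signif(tr$group_log_evidence, 6), collapse = " -> "), "\n")
  invisible(x)
}
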