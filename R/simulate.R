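# Synthetic cohorts: subjects with sigmoid discount-curve parameters per
# condition, clinical-group structure, symptom scores coupled to parameters,
# and trial-level responses simulated from the observation models.

.instrument_ranges <- data.frame(
  scale = c("teps_anticipatory", "teps_consummatory", "sticsa_cognitive",
            "sticsa_somatic", "pss", "qids"),
  min = c(10, 8, 10, 11, 0, 0),
  max = c(60, 48, 40, 44, 40, 27),
  stringsAsFactors = FALSE)

#' Specify one synthetic group
#'
#' Defines the generating distribution for one clinical group: per-condition
#' sigmoid curve parameters (bias, sigma, asymptote), observation noise,
#' symptom-score distributions with optional linear couplings to the curve
#' parameters, and covariates. Bias for subject i in condition c is
#' `bias_mean[c] + a_i + e_ic` with `a_i ~ N(0, bias_subject_sd)` (a shared
#' subject intercept) and `e_ic ~ N(0, bias_cond_sd)`; log sigma is Gaussian
#' per condition around `sigma_log_mean[c]`.
#'
#' @param label group label, e.g. `"HC"`, `"MDD"`, `"ANX"`.
#' @param n_subjects number of subjects, >= 1.
#' @param bias_mean named numeric over the four conditions
#'   (`extrinsic-win`, `extrinsic-loss`, `intrinsic-win`, `intrinsic-loss`).
#' @param bias_subject_sd,bias_cond_sd between-subject and within-subject
#'   (condition-level) sd of bias.
#' @param sigma_log_mean named numeric, log-scale sigma means per condition.
#' @param sigma_log_sd sd of log sigma.
#' @param asym_mean,asym_sd effort asymptote distribution (shared across
#'   conditions, truncated to (5, effort_cap]).
#' @param tau,sigma_obs observation noise (presses).
#' @param symptoms data.frame with columns `scale`, `mean`, `sd` (one row per
#'   instrument named in `.instrument_ranges`); scores are truncated-normal
#'   within the instrument's range.
#' @param couplings data.frame with columns `scale`, `condition`, `measure`
#'   (`"bias"` or `"sigma"`), `r`: target correlation between the symptom
#'   score and the (standardized) parameter. Per scale, `sum(r^2)` must be
#'   <= 1.
#' @param age_mean,age_sd,p_female,p_medication covariate model.
#' @param rt_log_offset group offset on the log reaction-time scale.
#' @return A list of class `"group_spec"`.
#' @export
group_spec <- function(label, n_subjects,
                       bias_mean,
                       bias_subject_sd = 0.20, bias_cond_sd = 0.15,
                       sigma_log_mean = stats::setNames(rep(log(0.15), 4),
                                                        .conditions),
                       sigma_log_sd = 0.40,
                       asym_mean = 58, asym_sd = 6,
                       tau = 5, sigma_obs = 5,
                       symptoms = NULL, couplings = NULL,
                       age_mean = 32, age_sd = 10,
                       p_female = 0.5, p_medication = 0,
                       rt_log_offset = 0) {
  stopifnot(n_subjects >= 1, bias_subject_sd >= 0, bias_cond_sd >= 0,
            sigma_log_sd >= 0, asym_sd >= 0, tau > 0, sigma_obs > 0)
  bias_mean <- bias_mean[.conditions]
  sigma_log_mean <- sigma_log_mean[.conditions]
  if (anyNA(bias_mean) || anyNA(sigma_log_mean))
    stop("bias_mean and sigma_log_mean must name all four conditions")
  if (is.null(symptoms)) {
    symptoms <- .instrument_ranges[, "scale", drop = FALSE]
    symptoms$mean <- c(42, 37, 18, 16, 16, 5)
    symptoms$sd <- c(8, 7, 7, 6, 8, 5)
  }
  if (!is.null(couplings) && nrow(couplings)) {
    stopifnot(all(couplings$measure %in% c("bias", "sigma")),
              all(couplings$condition %in% .conditions),
              all(abs(couplings$r) < 1))
    r2 <- tapply(couplings$r^2, couplings$scale, sum)
    if (any(r2 > 1))
      stop("per-scale sum of squared couplings exceeds 1")
  }
  structure(list(label = label, n_subjects = as.integer(n_subjects),
                 bias_mean = bias_mean, bias_subject_sd = bias_subject_sd,
                 bias_cond_sd = bias_cond_sd,
                 sigma_log_mean = sigma_log_mean, sigma_log_sd = sigma_log_sd,
                 asym_mean = asym_mean, asym_sd = asym_sd,
                 tau = tau, sigma_obs = sigma_obs,
                 symptoms = symptoms, couplings = couplings,
                 age_mean = age_mean, age_sd = age_sd,
                 p_female = p_female, p_medication = p_medication,
                 rt_log_offset = rt_log_offset),
            class = "group_spec")
}

#' Default three-group cohort specification
#'
#' HC (n = 74), MDD (n = 63) and ANX (n = 44) groups. Curve-parameter means
#' encode the qualitative group effects the analysis is designed to detect —
#' extrinsic control more motivating than intrinsic, wins more motivating
#' than losses, MDD with higher extrinsic bias (lower extrinsic motivation)
#' and lower loss motivation, ANX with the opposite pattern plus higher
#' intrinsic sigma (outcome insensitivity) — at roughly 0.4-SD group
#' separations (offsets of 0.1 against a total bias sd of 0.25). Symptom
#' means/sds and covariates follow the in-person sample characteristics;
#' default couplings link anticipatory anhedonia negatively to extrinsic
#' bias, consummatory anhedonia negatively to intrinsic sigma, and perceived
#' stress positively to intrinsic-win bias.
#'
#' @return List of three [group_spec()] objects.
#' @export
default_cohort_spec <- function() {
  base_bias <- c("extrinsic-win" = 0.35, "extrinsic-loss" = 0.45,
                 "intrinsic-win" = 0.55, "intrinsic-loss" = 0.65)
  off <- function(extr, loss) {
    b <- base_bias
    b[c("extrinsic-win", "extrinsic-loss")] <-
      b[c("extrinsic-win", "extrinsic-loss")] + extr
    b[c("extrinsic-loss", "intrinsic-loss")] <-
      b[c("extrinsic-loss", "intrinsic-loss")] + loss
    b
  }
  sig <- function(intr = 0) stats::setNames(
    log(0.15) + c(0, 0, intr, intr), .conditions)
  symp <- function(means, sds) {
    s <- .instrument_ranges[, "scale", drop = FALSE]
    s$mean <- means; s$sd <- sds
    s
  }
  coup <- data.frame(
    scale = c("teps_anticipatory", "teps_anticipatory",
              "teps_consummatory", "teps_consummatory", "pss"),
    condition = c("extrinsic-win", "extrinsic-loss",
                  "intrinsic-win", "intrinsic-loss", "intrinsic-win"),
    measure = c("bias", "bias", "sigma", "sigma", "bias"),
    r = c(-0.20, -0.21, -0.30, -0.25, 0.30),
    stringsAsFactors = FALSE)
  list(
    group_spec("HC", 74, bias_mean = off(0, 0),
               symptoms = symp(c(46.52, 38.60, 11.17, 11.82, 9.55, 1.55),
                               c(7.18, 6.96, 2.21, 1.51, 5.24, 1.84)),
               couplings = coup, age_mean = 31.5, age_sd = 9.5,
               p_female = 0.554, p_medication = 0.01, rt_log_offset = 0),
    group_spec("MDD", 63, bias_mean = off(+0.1, +0.1),
               symptoms = symp(c(34.12, 32.45, 25.32, 20.55, 26.16, 13.86),
                               c(8.61, 8.72, 6.44, 7.59, 6.24, 4.65)),
               couplings = coup, age_mean = 32.7, age_sd = 10.6,
               p_female = 0.574, p_medication = 0.51, rt_log_offset = +0.12),
    group_spec("ANX", 44, bias_mean = off(-0.1, -0.1),
               sigma_log_mean = sig(intr = 0.4),
               symptoms = symp(c(43.18, 37.94, 24.84, 18.79, 22.10, 8.27),
                               c(7.74, 6.78, 7.22, 6.37, 7.22, 4.70)),
               couplings = coup, age_mean = 33.0, age_sd = 10.5,
               p_female = 0.727, p_medication = 0.43, rt_log_offset = -0.12))
}

#' Draw one subject's true parameters, covariates and symptom scores
#'
#' Samples per-condition sigmoid [curve_params()] and [observation_params()]
#' from a [group_spec()], plus age, sex, medication status and the six
#' symptom scores. Symptom scores are generated on a standardized scale as
#' `z = sum_j r_j * z_param_j + sqrt(1 - sum r^2) * noise`, so the configured
#' coupling `r` is the population correlation between the score and the
#' coupled parameter, then mapped to instrument units and truncated to the
#' instrument range.
#'
#' @param group a [group_spec()].
#' @param effort_cap press cap bounding the asymptote.
#' @param seed optional integer seed (RNG state restored afterwards).
#' @return List with `params` (named list of 4 sigmoid curves), `obs`,
#'   `group`, `age`, `sex`, `medication`, `symptoms` (named numeric),
#'   `rt_log_offset`.
#' @export
draw_subject <- function(group, effort_cap = 70, seed = NULL) {
  stopifnot(inherits(group, "group_spec"))
  .with_seed(seed, {
    a <- rnorm(1, 0, group$bias_subject_sd)
    e <- rnorm(4, 0, group$bias_cond_sd)
    bias <- as.numeric(group$bias_mean) + a + e
    log_sigma <- rnorm(4, as.numeric(group$sigma_log_mean),
                       group$sigma_log_sd)
    asym <- .rtruncnorm(1, group$asym_mean, group$asym_sd, 5, effort_cap)
    params <- lapply(seq_len(4), function(k)
      curve_params("sigmoid", c = asym, bias = bias[k],
                   sigma = exp(log_sigma[k]), effort_cap = effort_cap))
    names(params) <- .conditions

    # standardized parameter deviations used by the symptom couplings
    tot_bias_sd <- sqrt(group$bias_subject_sd^2 + group$bias_cond_sd^2)
    z_of <- function(measure, condition) {
      k <- match(condition, .conditions)
      if (measure == "bias") {
        if (tot_bias_sd == 0) 0 else (bias[k] - group$bias_mean[k]) / tot_bias_sd
      } else {
        if (group$sigma_log_sd == 0) 0
        else (log_sigma[k] - group$sigma_log_mean[k]) / group$sigma_log_sd
      }
    }
    symptoms <- numeric(nrow(group$symptoms))
    names(symptoms) <- group$symptoms$scale
    for (i in seq_len(nrow(group$symptoms))) {
      sc <- group$symptoms$scale[i]
      cp <- group$couplings
      cp <- if (is.null(cp)) NULL else cp[cp$scale == sc, , drop = FALSE]
      z <- 0; r2 <- 0
      if (!is.null(cp) && nrow(cp)) {
        for (j in seq_len(nrow(cp)))
          z <- z + cp$r[j] * z_of(cp$measure[j], cp$condition[j])
        r2 <- sum(cp$r^2)
      }
      z <- z + sqrt(max(0, 1 - r2)) * rnorm(1)
      rng <- .instrument_ranges[.instrument_ranges$scale == sc, ]
      score <- group$symptoms$mean[i] + group$symptoms$sd[i] * z
      symptoms[i] <- min(max(score, rng$min), rng$max)
    }
    list(params = params,
         obs = observation_params(group$tau, group$sigma_obs),
         group = group$label,
         age = round(.rtruncnorm(1, group$age_mean, group$age_sd, 18, 65)),
         sex = if (runif(1) < group$p_female) "female" else "male",
         medication = runif(1) < group$p_medication,
         symptoms = symptoms,
         rt_log_offset = group$rt_log_offset + rnorm(1, 0, 0.05))
  })
}

#' Simulate one subject's trial-level responses
#'
#' Generative twin of the task: extrinsic trials are accepted with the
#' logistic probability of [loglik_extrinsic()]; intrinsic trials yield the
#' Gaussian-perturbed curve value, clamped to `[0, effort_cap]` and rounded
#' to integer presses; reaction times are lognormal with intrinsic trials
#' slower than extrinsic and loss trials slower than wins.
#'
#' @param true a subject as returned by [draw_subject()] (needs `params`,
#'   `obs`, optionally `rt_log_offset`).
#' @param schedule a `"task_schedule"`.
#' @param seed optional integer seed.
#' @return The schedule's trial data.frame with added columns `accepted`
#'   (logical, `NA` on intrinsic trials), `reported_effort` (integer, `NA` on
#'   extrinsic trials) and `reaction_time` (seconds).
#' @export
simulate_responses <- function(true, schedule, seed = NULL) {
  tr <- schedule$trials
  cap <- schedule$effort_cap
  .with_seed(seed, {
    cond <- .condition_of(tr$control, tr$valence)
    y <- vapply(seq_len(nrow(tr)), function(i)
      eval_curve(true$params[[cond[i]]], tr$outcome_norm[i]), numeric(1))
    y <- .clamp_effort(y, cap)
    ext <- tr$control == "extrinsic"
    accepted <- rep(NA, nrow(tr))
    p_acc <- plogis((y[ext] - tr$offered_effort[ext]) /
                      true$obs$choice_temperature)
    accepted[ext] <- runif(sum(ext)) < p_acc
    reported <- rep(NA_integer_, nrow(tr))
    raw <- y[!ext] + rnorm(sum(!ext), 0, true$obs$intrinsic_sd)
    reported[!ext] <- as.integer(round(.clamp_effort(raw, cap)))
    mu <- log(0.9) + 0.45 * (!ext) + 0.08 * (tr$valence == "loss") +
      (true$rt_log_offset %||% 0)
    rt <- rlnorm(nrow(tr), meanlog = mu, sdlog = 0.35)
    out <- tr
    out$accepted <- as.logical(accepted)
    out$reported_effort <- reported
    out$reaction_time <- rt
    out
  })
}

#' Generate a full synthetic cohort
#'
#' Draws every subject from the group specifications, simulates their trial
#' responses on a common schedule, and returns the two standard tables plus
#' a manifest of the true generating parameters for recovery testing. The
#' schedule (design columns) depends only on `schedule_cfg$seed`; the master
#' `seed` drives subjects and responses, so two cohorts with different seeds
#' share identical design columns.
#'
#' @param groups list of [group_spec()] objects (default
#'   [default_cohort_spec()]).
#' @param schedule_cfg a [schedule_config()].
#' @param seed master integer seed.
#' @param simulate if `FALSE`, skip response simulation (subject table and
#'   truth manifest only); used for fast design-level studies.
#' @return List of class `"imt_cohort"`: `subjects` (one row per subject with
#'   group, covariates, symptom scores, `deterministic` flag), `trials` (one
#'   row per subject x trial with responses; `NULL` when `simulate = FALSE`),
#'   `truth` (per-subject generating parameters), `schedule`, `seed`.
#' @export
generate_cohort <- function(groups = default_cohort_spec(),
                            schedule_cfg = schedule_config(),
                            seed = 1L, simulate = TRUE) {
  if (inherits(groups, "group_spec")) groups <- list(groups)
  schedule <- build_schedule(schedule_cfg)
  n_total <- sum(vapply(groups, function(g) g$n_subjects, integer(1)))
  ids <- sprintf("S%03d", seq_len(n_total))
  subj_rows <- vector("list", n_total)
  trial_rows <- if (simulate) vector("list", n_total) else NULL
  truth <- vector("list", n_total)
  names(truth) <- ids
  i <- 0L
  for (g in groups) {
    for (k in seq_len(g$n_subjects)) {
      i <- i + 1L
      sub <- draw_subject(g, effort_cap = schedule$effort_cap,
                          seed = .hash_seed(seed, "subject", ids[i]))
      truth[[i]] <- list(
        params = lapply(sub$params, function(p) p[setdiff(names(p), "family")]),
        tau = sub$obs$choice_temperature,
        sigma_obs = sub$obs$intrinsic_sd,
        group = sub$group)
      det <- NA
      if (simulate) {
        resp <- simulate_responses(sub, schedule,
                                   seed = .hash_seed(seed, "resp", ids[i]))
        resp <- cbind(subject_id = ids[i], resp, stringsAsFactors = FALSE)
        trial_rows[[i]] <- resp
        acc <- resp$accepted[resp$control == "extrinsic"]
        det <- length(unique(acc)) == 1L
      }
      subj_rows[[i]] <- data.frame(
        subject_id = ids[i], group = sub$group, age = sub$age, sex = sub$sex,
        medication = sub$medication, t(sub$symptoms),
        deterministic = det, stringsAsFactors = FALSE)
    }
  }
  cohort <- list(subjects = do.call(rbind, subj_rows),
                 trials = if (simulate) do.call(rbind, trial_rows) else NULL,
                 truth = truth, schedule = schedule, seed = as.integer(seed))
  class(cohort) <- "imt_cohort"
  cohort
}

#' True-parameter long table from a cohort manifest
#'
#' Convenience accessor: one row per subject x condition with the generating
#' bias, sigma and asymptote, for parameter-recovery comparisons and
#' design-level statistics.
#'
#' @param cohort an `"imt_cohort"`.
#' @return data.frame with columns `subject_id`, `group`, `condition`,
#'   `control`, `valence`, `bias`, `sigma`, `c`.
#' @export
truth_table <- function(cohort) {
  rows <- lapply(names(cohort$truth), function(id) {
    tt <- cohort$truth[[id]]
    do.call(rbind, lapply(.conditions, function(cd) {
      p <- tt$params[[cd]]
      data.frame(subject_id = id, group = tt$group, condition = cd,
                 control = .control_of(cd), valence = .valence_of(cd),
                 bias = p$bias, sigma = p$sigma, c = p$c,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
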