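# Dataset I/O and end-to-end orchestration: generate (or read) a cohort,
# fit every curve family hierarchically, select the winning family by
# protected exceedance probability, and run the parameter-level group and
# symptom statistics, writing every stage artifact to an output directory.

.trial_columns <- c("subject_id", "trial_index", "control", "valence",
                    "outcome_type", "outcome_magnitude", "outcome_norm",
                    "offered_effort", "executes_effort", "accepted",
                    "reported_effort", "reaction_time")
.subject_columns <- c("subject_id", "group", "age", "sex", "medication",
                      "teps_anticipatory", "teps_consummatory",
                      "sticsa_cognitive", "sticsa_somatic", "pss", "qids")

#' Flag deterministic responders
#'
#' Subjects who make the same accept/reject button response on every
#' extrinsic trial carry no choice information and are excluded before
#' fitting.
#'
#' @param trials multi-subject trial table with `subject_id`, `control`,
#'   `accepted`.
#' @return Character vector of flagged subject ids (possibly empty).
#' @export
flag_deterministic <- function(trials) {
  ext <- trials[trials$control == "extrinsic", , drop = FALSE]
  if (!nrow(ext) || is.null(ext$accepted)) return(character(0))
  det <- tapply(ext$accepted, ext$subject_id,
                function(a) length(unique(a[!is.na(a)])) <= 1L)
  names(det)[det]
}

#' Write / read a cohort dataset
#'
#' `write_dataset` writes `subjects.csv`, `trials.csv` and (when present)
#' the true-parameter manifest `truth.json`. `read_dataset` restores the
#' dataset, validates the schemas, range-checks efforts against the press
#' cap, and re-derives the deterministic-responder flags.
#'
#' @param cohort an `"imt_cohort"` (or compatible list).
#' @param dir directory to write to / read from.
#' @param effort_cap press cap used for range checks on reading.
#' @return `read_dataset` returns a list of class `"imt_cohort"` with
#'   `subjects`, `trials`, `truth` (or `NULL`) and `effort_cap`.
#' @export
write_dataset <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sub <- cohort$subjects
  utils::write.csv(sub[, intersect(c(.subject_columns, "deterministic"),
                                   names(sub))],
                   file.path(dir, "subjects.csv"), row.names = FALSE)
  utils::write.csv(cohort$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$truth))
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir, effort_cap = 70) {
  tpath <- file.path(dir, "trials.csv")
  spath <- file.path(dir, "subjects.csv")
  if (!file.exists(tpath) || !file.exists(spath))
    stop("dataset directory must contain trials.csv and subjects.csv")
  trials <- utils::read.csv(tpath, stringsAsFactors = FALSE)
  if (!nrow(trials)) stop("empty trials file: ", tpath)
  subjects <- utils::read.csv(spath, stringsAsFactors = FALSE)
  miss_t <- setdiff(.trial_columns, names(trials))
  extra_t <- setdiff(names(trials), .trial_columns)
  if (length(miss_t) || length(extra_t))
    stop("trials.csv schema mismatch; missing: [",
         paste(miss_t, collapse = ", "), "] extra: [",
         paste(extra_t, collapse = ", "), "]")
  miss_s <- setdiff(.subject_columns, names(subjects))
  if (length(miss_s))
    stop("subjects.csv schema mismatch; missing: [",
         paste(miss_s, collapse = ", "), "]")
  eff <- c(trials$offered_effort, trials$reported_effort)
  eff <- eff[!is.na(eff)]
  if (length(eff) && (min(eff) < 0 || max(eff) > effort_cap))
    stop("effort values outside [0, ", effort_cap, "]")
  trials$accepted <- as.logical(trials$accepted)
  trials$executes_effort <- as.logical(trials$executes_effort)
  subjects$medication <- as.logical(subjects$medication)
  subjects$deterministic <- subjects$subject_id %in%
    flag_deterministic(trials)
  truth <- NULL
  jp <- file.path(dir, "truth.json")
  if (file.exists(jp)) truth <- jsonlite::read_json(jp, simplifyVector = FALSE)
  structure(list(subjects = subjects, trials = trials, truth = truth,
                 effort_cap = effort_cap),
            class = "imt_cohort")
}

#' Pipeline configuration
#'
#' Bundles every stage's settings. `groups`, `schedule_cfg` and `fit` take
#' the package defaults when not supplied; `data_dir` switches the pipeline
#' from simulation to reading an existing dataset.
#'
#' @param seed master seed (mandatory; drives simulation, fitting jitter and
#'   the BMS Monte-Carlo draw).
#' @param out_dir output directory for stage artifacts.
#' @param groups list of [group_spec()]s, or `NULL` for the default cohort.
#' @param schedule_cfg a [schedule_config()].
#' @param fit a [fit_settings()].
#' @param families curve families to fit and compare.
#' @param bms_samples Monte-Carlo samples for the exceedance probability.
#' @param data_dir optional directory with an existing dataset (skips
#'   simulation).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(seed, out_dir, groups = NULL,
                       schedule_cfg = schedule_config(),
                       fit = fit_settings(seed = seed),
                       families = c("linear", "sigmoid", "weibull"),
                       bms_samples = 1e6, data_dir = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (fit$max_rounds < 1) stop("fit max_rounds must be >= 1")
  stopifnot(length(families) >= 2)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 groups = groups, schedule_cfg = schedule_cfg, fit = fit,
                 families = families, bms_samples = bms_samples,
                 data_dir = data_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes generate (or read) -> hierarchical fit per family -> model
#' comparison -> group and symptom statistics, writing `subjects.csv`,
#' `trials.csv`, `truth.json`, `estimates.csv`, `trace.json`, `bms.json`,
#' `bms_summary.csv`, `anova_<dv>.csv`, `posthoc_group.csv`,
#' `correlations.csv` and `manifest.json` under `config$out_dir`. Identical
#' config and seed reproduce identical numeric outputs. Group-level
#' statistics run only when the subject table carries more than one group
#' label.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the cohort, per-family fits, `bms`,
#'   `winning_family`, `anova` tables, `posthoc`, `correlations`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- stage("data", {
    if (!is.null(config$data_dir)) {
      read_dataset(config$data_dir, config$schedule_cfg$effort_cap)
    } else {
      generate_cohort(config$groups %||% default_cohort_spec(),
                      config$schedule_cfg, seed = config$seed)
    }
  })
  write_dataset(cohort, out)

  fits <- stage("fit", {
    fs <- lapply(config$families, function(fam)
      suppressWarnings(fit_hierarchical(cohort, fam, config$fit)))
    names(fs) <- config$families
    fs
  })
  est_all <- do.call(rbind, lapply(fits, function(f) {
    t <- f$estimates_table
    base <- c("subject_id", "condition", "family", "log_evidence")
    pars <- setdiff(names(t), base)
    t$parameters <- vapply(seq_len(nrow(t)), function(i)
      paste(pars, signif(unlist(t[i, pars]), 8), sep = "=", collapse = ";"),
      character(1))
    t[, c(base, "parameters")]
  }))
  utils::write.csv(est_all, file.path(out, "estimates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(lapply(fits, `[[`, "trace"),
                       file.path(out, "trace.json"), auto_unbox = TRUE,
                       digits = NA)

  bms <- stage("compare", {
    L <- evidence_matrix(fits)
    protected_ep(rfx_bms(L, n_samples = config$bms_samples,
                         seed = config$seed))
  })
  jsonlite::write_json(list(alpha = as.list(bms$alpha),
                            expected_freq = as.list(bms$expected_freq),
                            ep = as.list(bms$ep), bor = bms$bor,
                            pxp = as.list(bms$pxp),
                            settings = list(alpha0 = bms$alpha0,
                                            n_samples = bms$n_samples,
                                            seed = bms$seed)),
                       file.path(out, "bms.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(attribute_models(bms), file.path(out, "bms_summary.csv"),
                   row.names = FALSE)
  winner <- bms$families[which.max(bms$pxp)]

  stats_out <- stage("stats", {
    tab <- fits[[winner]]$estimates_table
    subj <- cohort$subjects
    multi_group <- length(unique(subj$group)) > 1L
    between <- if (multi_group) "group" else NULL
    anovas <- list()
    for (dvn in intersect(c("bias", "sigma"), names(tab))) {
      lt <- long_table(tab, subj, dv = dvn)
      anovas[[dvn]] <- rm_anova(lt, between = between)
      utils::write.csv(anovas[[dvn]],
                       file.path(out, paste0("anova_", dvn, ".csv")),
                       row.names = FALSE)
    }
    # reaction-time ANOVA on subject x condition means
    rtm <- aggregate(reaction_time ~ subject_id + control + valence,
                     data = cohort$trials, FUN = mean)
    names(rtm)[names(rtm) == "reaction_time"] <- "value"
    rtm <- merge(rtm, subj[, c("subject_id", "group")], by = "subject_id")
    anovas$reaction_time <- rm_anova(rtm, between = between)
    utils::write.csv(anovas$reaction_time,
                     file.path(out, "anova_reaction_time.csv"),
                     row.names = FALSE)
    posthoc <- NULL
    if (multi_group) {
      pv <- intersect(c("bias", "sigma"), names(tab))
      src <- if (length(pv)) long_table(tab, subj, dv = pv[1]) else rtm
      posthoc <- tukey_posthoc(src, dv = "value", factor = "group",
                               subject = "subject_id")
      utils::write.csv(posthoc, file.path(out, "posthoc_group.csv"),
                       row.names = FALSE)
    }
    correlations <- NULL
    if ("bias" %in% names(tab)) {
      correlations <- symptom_correlations(tab, subj)
      utils::write.csv(correlations, file.path(out, "correlations.csv"),
                       row.names = FALSE)
    }
    list(anova = anovas, posthoc = posthoc, correlations = correlations)
  })

  cfg_str <- paste(deparse(config[setdiff(names(config), "out_dir")]),
                   collapse = "")
  manifest <- list(seed = config$seed,
                   config_hash = sum(utf8ToInt(cfg_str) *
                                       seq_along(utf8ToInt(cfg_str))),
                   families = config$families,
                   winning_family = winner,
                   n_subjects = nrow(cohort$subjects),
                   n_trials = length(unique(cohort$trials$trial_index)),
                   package_version =
                     as.character(utils::packageVersion("effortdm")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, fits = fits, bms = bms,
                 winning_family = winner, anova = stats_out$anova,
                 posthoc = stats_out$posthoc,
                 correlations = stats_out$correlations, out_dir = out))
}

#' Read a pipeline configuration from YAML
#'
#' Supports the scalar knobs a run typically varies: `seed`, `out_dir`,
#' `n_trials`, `effort_cap`, `effort_execution_fraction`,
#' `extrinsic_fraction`, `families`, `bms_samples`, `max_rounds`, `tol`,
#' `n_starts`, `data_dir`, and per-group sizes as `group_sizes: {HC: ...,
#' MDD: ..., ANX: ...}` applied to the default cohort spec.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config YAML must set seed")
  sc <- schedule_config(
    n_trials = y$n_trials %||% 228L,
    effort_cap = y$effort_cap %||% 70L,
    effort_execution_fraction = y$effort_execution_fraction %||% 0.30,
    extrinsic_fraction = y$extrinsic_fraction %||% 0.75,
    seed = y$schedule_seed %||% 1L)
  groups <- NULL
  if (!is.null(y$group_sizes)) {
    groups <- default_cohort_spec()
    for (g in seq_along(groups)) {
      nz <- y$group_sizes[[groups[[g]]$label]]
      if (!is.null(nz)) groups[[g]]$n_subjects <- as.integer(nz)
    }
  }
  run_config(seed = y$seed, out_dir = y$out_dir %||% "effortdm-run",
             groups = groups, schedule_cfg = sc,
             fit = fit_settings(max_rounds = y$max_rounds %||% 16L,
                                tol = y$tol %||% 0.01,
                                n_starts = y$n_starts %||% 4L,
                                seed = y$seed,
                                effort_cap = y$effort_cap %||% 70),
             families = unlist(y$families) %||%
               c("linear", "sigmoid", "weibull"),
             bms_samples = y$bms_samples %||% 1e6,
             data_dir = y$data_dir)
}
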