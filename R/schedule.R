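#' Configure a task schedule
#'
#' Builds the configuration object consumed by [build_schedule()]. The
#' defaults reproduce the task as run: 228 trials split evenly across the
#' four valence-by-outcome-type cells (win/loss crossed with money/social),
#' money outcomes from $0.25 to $2.00, social outcomes from 25 to 200 points,
#' button-press effort capped at 70 per trial, and 30% of trials randomly
#' selected for actual effort execution. Three out of four trials are under
#' extrinsic control (an offered effort level to accept or reject); the rest
#' are intrinsic (the subject self-sets the effort level).
#'
#' @param n_trials total number of trials.
#' @param effort_cap maximum button presses per trial.
#' @param effort_execution_fraction proportion of trials that lead to actual
#'   effort performance.
#' @param extrinsic_fraction proportion of trials under extrinsic control.
#' @param money_levels,social_levels outcome magnitudes on each native scale.
#' @param effort_levels offered effort levels (extrinsic trials), in presses.
#' @param even_split require equal counts in every valence-by-outcome-type
#'   cell. `NULL` (default) requires it exactly when `n_trials` is divisible
#'   by 4; `TRUE` errors when an even split is impossible.
#' @param seed integer seed controlling trial ordering and effort assignment.
#' @return A list of class `"schedule_config"`.
#' @seealso [build_schedule()], [validate_schedule()]
#' @export
schedule_config <- function(n_trials = 228L,
                            effort_cap = 70L,
                            effort_execution_fraction = 0.30,
                            extrinsic_fraction = 0.75,
                            money_levels = seq(0.25, 2.00, by = 0.25),
                            social_levels = seq(25, 200, by = 25),
                            effort_levels = round(seq(10, 70, length.out = 6)),
                            even_split = NULL,
                            seed = 1L) {
  stopifnot(n_trials >= 1, effort_cap >= 1,
            effort_execution_fraction >= 0, effort_execution_fraction <= 1,
            extrinsic_fraction >= 0, extrinsic_fraction <= 1)
  if (length(money_levels) == 0 || length(social_levels) == 0 ||
      length(effort_levels) == 0)
    stop("outcome and effort level lists must be non-empty")
  if (any(money_levels <= 0) || any(social_levels <= 0))
    stop("outcome magnitudes must be positive")
  if (any(effort_levels < 1) || any(effort_levels > effort_cap))
    stop("effort levels must lie in [1, effort_cap]; got max ",
         max(effort_levels), " with cap ", effort_cap)
  cfg <- list(n_trials = as.integer(n_trials),
              effort_cap = as.integer(effort_cap),
              effort_execution_fraction = effort_execution_fraction,
              extrinsic_fraction = extrinsic_fraction,
              money_levels = money_levels,
              social_levels = social_levels,
              effort_levels = as.integer(effort_levels),
              even_split = even_split,
              seed = as.integer(seed))
  class(cfg) <- "schedule_config"
  cfg
}

# Largest-remainder allocation of `total` items over weights.
.allocate <- function(total, weights) {
  raw <- total * weights / sum(weights)
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Build a task schedule
#'
#' Constructs the trial list for one task run: the valence-by-outcome-type
#' cells are filled evenly (or by largest remainder when an even split is not
#' requested), extrinsic/intrinsic control is allocated within cells at the
#' configured ratio, outcome magnitudes cycle through the configured levels,
#' offered efforts are assigned to extrinsic trials, the effort-execution
#' subset is drawn, and the whole schedule is shuffled. Deterministic under
#' `config$seed`.
#'
#' @param config a [schedule_config()] object.
#' @return A list of class `"task_schedule"` with elements `trials` (one row
#'   per trial: `trial_index`, `control`, `valence`, `outcome_type`,
#'   `outcome_magnitude`, `outcome_norm`, `offered_effort`,
#'   `executes_effort`), `effort_cap`, `effort_execution_fraction`, `config`.
#' @export
build_schedule <- function(config = schedule_config()) {
  stopifnot(inherits(config, "schedule_config"))
  n <- config$n_trials
  cells <- expand.grid(valence = c("win", "loss"),
                       outcome_type = c("money", "social"),
                       stringsAsFactors = FALSE)
  want_even <- config$even_split %||% (n %% 4L == 0L)
  if (want_even && n %% 4L != 0L) {
    alloc <- .allocate(n, rep(1, 4))
    stop("even split across the 4 valence x outcome-type cells impossible ",
         "for ", n, " trials; cell counts would be ",
         paste(alloc, collapse = "/"))
  }
  cell_n <- if (want_even) rep(n %/% 4L, 4L) else .allocate(n, rep(1, 4))
  n_ext_total <- round(n * config$extrinsic_fraction)
  # distribute extrinsic trials over the non-empty cells as evenly as possible
  ext_per_cell <- .allocate(n_ext_total, pmax(cell_n, 1e-9))
  ext_per_cell <- pmin(ext_per_cell, cell_n)

  rows <- .with_seed(config$seed, {
    out <- vector("list", 4L)
    for (k in seq_len(4L)) {
      nk <- cell_n[k]
      if (nk == 0L) next
      levs <- sort(if (cells$outcome_type[k] == "money") config$money_levels
                   else config$social_levels)
      n_ext <- ext_per_cell[k]
      n_int <- nk - n_ext
      # deterministic cell contents: magnitudes cycle through the levels
      # within each control condition, offers cycle through the effort
      # levels; only the trial order and the execution subset are random,
      # so every seed permutes the same trial multiset
      control <- rep(c("extrinsic", "intrinsic"), c(n_ext, n_int))
      mags <- c(rep_len(levs, n_ext), rep_len(levs, n_int))
      offered <- rep(NA_integer_, nk)
      if (n_ext > 0)
        offered[seq_len(n_ext)] <- rep_len(sort(config$effort_levels), n_ext)
      out[[k]] <- data.frame(control = control,
                             valence = cells$valence[k],
                             outcome_type = cells$outcome_type[k],
                             outcome_magnitude = mags,
                             offered_effort = offered,
                             stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, out)
    n_exec <- round(config$effort_execution_fraction * n)
    exec <- rep(FALSE, n)
    if (n_exec > 0) exec[sample.int(n, n_exec)] <- TRUE
    df$executes_effort <- exec
    df <- df[sample.int(n), , drop = FALSE]
    df
  })
  rows$outcome_norm <- normalize_outcome(rows$outcome_magnitude,
                                         rows$outcome_type, config)
  rows$trial_index <- seq_len(n)
  rownames(rows) <- NULL
  rows <- rows[, c("trial_index", "control", "valence", "outcome_type",
                   "outcome_magnitude", "outcome_norm", "offered_effort",
                   "executes_effort")]
  sched <- list(trials = rows,
                effort_cap = config$effort_cap,
                effort_execution_fraction = config$effort_execution_fraction,
                config = config)
  class(sched) <- "task_schedule"
  sched
}

#' Normalize outcome magnitudes to a common (0, 1] scale
#'
#' Money and social outcomes live on different native scales; curves are fit
#' against a common outcome axis obtained by dividing each magnitude by the
#' maximum of its own type, so the top of each scale maps to 1.
#'
#' @param magnitude outcome magnitude(s) on the native scale.
#' @param outcome_type `"money"` or `"social"`, recycled against `magnitude`.
#' @param config a [schedule_config()] providing the configured level ranges.
#' @return Numeric vector in (0, 1].
#' @export
normalize_outcome <- function(magnitude, outcome_type,
                              config = schedule_config()) {
  outcome_type <- rep_len(outcome_type, length(magnitude))
  if (!all(outcome_type %in% c("money", "social")))
    stop("outcome_type must be 'money' or 'social'")
  lo <- ifelse(outcome_type == "money", min(config$money_levels),
               min(config$social_levels))
  hi <- ifelse(outcome_type == "money", max(config$money_levels),
               max(config$social_levels))
  bad <- which(magnitude < lo | magnitude > hi)
  if (length(bad))
    stop("outcome magnitude outside configured range: ",
         paste(magnitude[bad], collapse = ", "))
  magnitude / hi
}

#' Validate a task schedule
#'
#' Checks every structural invariant of a schedule and reports violations;
#' never raises. An empty report means the schedule is valid.
#'
#' @param schedule a `"task_schedule"` object.
#' @return Character vector of violation messages (length 0 if valid).
#' @export
validate_schedule <- function(schedule) {
  bad <- character(0)
  tr <- schedule$trials
  ext <- tr$control == "extrinsic"
  if (any(ext & is.na(tr$offered_effort)))
    bad <- c(bad, "extrinsic trial(s) missing offered_effort")
  if (any(!ext & !is.na(tr$offered_effort)))
    bad <- c(bad, "intrinsic trial(s) carrying offered_effort")
  if (any(!is.na(tr$offered_effort) &
          tr$offered_effort > schedule$effort_cap))
    bad <- c(bad, paste0("offered_effort above effort_cap ",
                         schedule$effort_cap))
  if (any(tr$outcome_norm <= 0 | tr$outcome_norm > 1))
    bad <- c(bad, "outcome_norm outside (0, 1]")
  cfg <- schedule$config
  if (!is.null(cfg)) {
    expect_norm <- tryCatch(
      normalize_outcome(tr$outcome_magnitude, tr$outcome_type, cfg),
      error = function(e) NULL)
    if (is.null(expect_norm) ||
        max(abs(expect_norm - tr$outcome_norm)) > 1e-12)
      bad <- c(bad, "outcome_norm inconsistent with magnitude / scale maximum")
  }
  n <- nrow(tr)
  n_exec <- sum(tr$executes_effort)
  if (n_exec != round(schedule$effort_execution_fraction * n))
    bad <- c(bad, paste0("executes_effort count ", n_exec, " != round(",
                         schedule$effort_execution_fraction, " * ", n, ")"))
  if (n %% 4L == 0L) {
    counts <- table(tr$valence, tr$outcome_type)
    if (length(unique(as.vector(counts))) != 1L)
      bad <- c(bad, paste0("uneven valence x outcome-type cells: ",
                           paste(as.vector(counts), collapse = "/")))
  }
  bad
}

#' Write / read a schedule as CSV
#'
#' One row per trial, with the documented column set. `read_schedule`
#' restores a `"task_schedule"`; the configuration is carried alongside as
#' attributes in a small YAML side string only when written via the pipeline,
#' so a schedule read back from bare CSV has `config = NULL` (validation then
#' skips the config-dependent checks).
#'
#' @param schedule a `"task_schedule"`.
#' @param path CSV file path.
#' @param effort_cap,effort_execution_fraction metadata used when reading
#'   bare CSV.
#' @return `read_schedule` returns a `"task_schedule"`.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(schedule$trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path, effort_cap = 70L,
                          effort_execution_fraction = NULL) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_index", "control", "valence", "outcome_type",
            "outcome_magnitude", "outcome_norm", "offered_effort",
            "executes_effort")
  miss <- setdiff(need, names(tr))
  if (length(miss)) stop("schedule CSV missing columns: ",
                         paste(miss, collapse = ", "))
  frac <- effort_execution_fraction %||%
    (sum(tr$executes_effort) / nrow(tr))
  sched <- list(trials = tr[, need], effort_cap = as.integer(effort_cap),
                effort_execution_fraction = frac, config = NULL)
  class(sched) <- "task_schedule"
  sched
}

#' @export
print.task_schedule <- function(x, ...) {
  tr <- x$trials
  cat("Task schedule:", nrow(tr), "trials |",
      sum(tr$control == "extrinsic"), "extrinsic,",
      sum(tr$control == "intrinsic"), "intrinsic | effort cap",
      x$effort_cap, "\n")
  print(table(tr$valence, tr$outcome_type))
  invisible(x)
}
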