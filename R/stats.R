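# Parameter-level group inference: repeated-measures ANOVA over control and
# valence (with an optional between-subject group factor), Tukey post-hoc
# contrasts, covariate-adjusted partial correlations with scale-wise
# Bonferroni correction, dependent-correlation Z tests, internal consistency
# and paired test-retest comparisons.

#' Long table of fitted parameters for group statistics
#'
#' Joins a [fit_hierarchical()] estimates table with a subject table and
#' splits the condition label into the two within-subject factors.
#'
#' @param estimates_table data.frame with `subject_id`, `condition` and the
#'   parameter columns (e.g. `bias`, `sigma`).
#' @param subjects optional subject table (`subject_id`, `group`,
#'   covariates, symptom scores) to join.
#' @param dv which parameter column becomes `value`.
#' @return data.frame with `subject_id`, `control`, `valence`, `value` and
#'   any joined subject columns.
#' @export
long_table <- function(estimates_table, subjects = NULL, dv = "bias") {
  stopifnot(dv %in% names(estimates_table))
  out <- data.frame(subject_id = estimates_table$subject_id,
                    control = .control_of(estimates_table$condition),
                    valence = .valence_of(estimates_table$condition),
                    value = estimates_table[[dv]],
                    stringsAsFactors = FALSE)
  if (!is.null(subjects))
    out <- merge(out, subjects, by = "subject_id", sort = FALSE)
  out
}

#' Repeated-measures ANOVA
#'
#' Univariate sums-of-squares repeated-measures ANOVA with fully-crossed
#' within-subject factors and an optional between-subject factor, via
#' `stats::aov` with `Error()` strata. With 2-level within factors
#' sphericity holds automatically, so no correction is applied. Within
#' effects are tested against their subject-by-factor stratum; with a
#' between factor of g levels and N subjects the within-effect error df is
#' N - g.
#'
#' @param data long-format data.frame, one row per subject x within-cell.
#' @param dv name of the dependent-variable column.
#' @param subject name of the subject-id column.
#' @param within character vector of within-subject factor columns.
#' @param between optional between-subject factor column (e.g. `"group"`).
#' @return data.frame: `effect`, `df1`, `df2`, `F`, `p`, `stratum`.
#' @export
rm_anova <- function(data, dv = "value", subject = "subject_id",
                     within = c("control", "valence"), between = NULL) {
  need <- c(dv, subject, within, between)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- data
  d$.subj <- factor(d[[subject]])
  for (w in within) d[[w]] <- factor(d[[w]])
  if (!is.null(between)) d[[between]] <- factor(d[[between]])
  d$.y <- d[[dv]]
  # complete crossing check
  cells <- interaction(d[within], drop = FALSE)
  tab <- table(d$.subj, cells)
  bad <- rownames(tab)[apply(tab, 1, function(r) any(r != r[1]) || r[1] < 1)]
  if (length(bad))
    stop("incomplete within-factor crossing for subject(s): ",
         paste(bad, collapse = ", "))
  if (!is.null(between)) {
    g <- tapply(as.character(d[[between]]), d$.subj,
                function(x) length(unique(x)))
    if (any(g > 1)) stop("subjects with multiple group labels")
    if (min(table(unique(d[, c(".subj", between)])[[between]])) < 2)
      stop("need >= 2 subjects per group")
  }
  fixed <- paste(c(between, within), collapse = " * ")
  err <- paste0("Error(.subj/(", paste(within, collapse = " * "), "))")
  form <- as.formula(paste(".y ~", fixed, "+", err))
  fit <- aov(form, data = d)
  sm <- summary(fit)
  rows <- list()
  for (s in seq_along(sm)) {
    stratum <- names(sm)[s]
    t <- as.data.frame(sm[[s]][[1]])
    t$effect <- trimws(rownames(t))
    resid_df <- t$Df[t$effect == "Residuals"]
    t <- t[t$effect != "Residuals", , drop = FALSE]
    if (!nrow(t)) next
    rows[[length(rows) + 1L]] <- data.frame(
      effect = t$effect, df1 = t$Df,
      df2 = if (length(resid_df)) resid_df else NA_real_,
      F = t[["F value"]], p = t[["Pr(>F)"]],
      stratum = trimws(sub("^Error: ", "", stratum)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tukey post-hoc contrasts
#'
#' All pairwise contrasts on one factor, adjusted with the studentized range
#' distribution. When a subject column is supplied, values are first
#' averaged within subject x level (so a repeated-measures factor is tested
#' on subject means).
#'
#' @param data long-format data.frame.
#' @param dv dependent-variable column name.
#' @param factor factor column name (>= 2 levels).
#' @param subject optional subject-id column for pre-averaging.
#' @return data.frame: `contrast`, `difference`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_posthoc <- function(data, dv = "value", factor = "group",
                          subject = NULL) {
  d <- data.frame(y = data[[dv]], f = base::factor(data[[factor]]))
  if (nlevels(d$f) < 2L) stop("factor must have >= 2 levels")
  if (!is.null(subject)) {
    d$s <- data[[subject]]
    d <- aggregate(y ~ s + f, data = d, FUN = mean)
  }
  hsd <- TukeyHSD(aov(y ~ f, data = d))$f
  out <- data.frame(contrast = rownames(hsd), difference = hsd[, "diff"],
                    lwr = hsd[, "lwr"], upr = hsd[, "upr"],
                    p_adj = hsd[, "p adj"], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Partial correlation with covariate adjustment
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing each
#' on the covariates (with intercept); the p value uses a t distribution
#' with `n - 2 - k` degrees of freedom for k covariates. With no covariates
#' this reduces to the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates optional data.frame/matrix of covariates; logical or
#'   character/factor columns (e.g. sex, medication status) are converted to
#'   numeric indicators.
#' @return List with `r`, `p`, `n`, `df`.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  keep <- is.finite(x) & is.finite(y)
  Z <- NULL
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    Z <- as.data.frame(covariates)
    for (j in seq_along(Z)) {
      if (is.logical(Z[[j]])) Z[[j]] <- as.numeric(Z[[j]])
      if (is.character(Z[[j]]) || is.factor(Z[[j]]))
        Z[[j]] <- as.numeric(factor(Z[[j]])) - 1
    }
    keep <- keep & stats::complete.cases(Z)
  }
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  k <- if (is.null(Z)) 0L else ncol(Z)
  if (n <= k + 2L) stop("need n > number of covariates + 2")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input variable")
  if (k > 0) {
    M <- cbind(1, as.matrix(Z[keep, , drop = FALSE]))
    x <- lm.fit(M, x)$residuals
    y <- lm.fit(M, y)$residuals
  }
  r <- cor(x, y)
  df <- n - 2L - k
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df), n = n, df = df)
}

#' Difference between two dependent correlations sharing one variable
#'
#' Meng-Rosenthal-Rubin Z test for `r_xy` versus `r_xz` measured in the same
#' sample, where y and z are correlated `r_yz`. Positive Z means
#' `r_xy > r_xz`. The one-sided p is the tail beyond |Z|.
#'
#' @param r_xy,r_xz the two correlations being compared, each in (-1, 1).
#' @param r_yz correlation between the two non-shared variables.
#' @param n sample size, > 3.
#' @return List with `Z`, `p_one_sided`, `p_two_sided`.
#' @references Meng, Rosenthal & Rubin (1992) Psychological Bulletin
#'   111:172-175.
#' @export
dependent_corr_diff <- function(r_xy, r_xz, r_yz, n) {
  if (any(abs(c(r_xy, r_xz, r_yz)) >= 1))
    stop("correlations must lie strictly in (-1, 1)")
  if (n <= 3) stop("need n > 3")
  rbar2 <- (r_xy^2 + r_xz^2) / 2
  f <- min((1 - r_yz) / (2 * (1 - rbar2)), 1)
  h <- (1 - f * rbar2) / (1 - rbar2)
  Z <- (atanh(r_xy) - atanh(r_xz)) *
    sqrt((n - 3) / (2 * (1 - r_yz) * h))
  list(Z = Z, p_one_sided = pnorm(-abs(Z)), p_two_sided = 2 * pnorm(-abs(Z)))
}

#' Bonferroni per-test alpha
#'
#' @param alpha family-wise alpha in (0, 1).
#' @param n_tests number of tests, >= 1.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests = 1L) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Cronbach's alpha
#'
#' Internal consistency of a set of items:
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total score))`.
#'
#' @param items numeric matrix or data.frame, subjects x items (>= 2 each).
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(items) {
  X <- as.matrix(items)
  k <- ncol(X)
  if (k < 2L || nrow(X) < 2L) stop("need >= 2 items and >= 2 subjects")
  vt <- var(rowSums(X))
  if (vt == 0) stop("zero total-score variance")
  k / (k - 1) * (1 - sum(apply(X, 2, var)) / vt)
}

#' Paired-samples t test
#'
#' Standard paired t with `df = n - 1`. Degenerate difference vectors are
#' handled by convention: zero variance with a nonzero mean difference gives
#' infinite t and p = 0; an identically-zero difference gives t = 0, p = 1.
#'
#' @param session1,session2 numeric vectors of equal length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
paired_ttest <- function(session1, session2) {
  stopifnot(length(session1) == length(session2), length(session1) >= 2)
  d <- session2 - session1
  n <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1L, p = 1))
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0))
  }
  tt <- t.test(session2, session1, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Symptom-parameter partial correlations with scale-wise Bonferroni
#'
#' For every symptom scale, parameter and condition, computes the partial
#' correlation between the subject-level parameter estimate and the symptom
#' score, controlling for age, sex and medication status. The Bonferroni
#' correction is applied scale-wise: within one scale and parameter, the
#' per-test alpha is `alpha / number of conditions` (0.0125 for four
#' conditions at alpha = 0.05).
#'
#' @param estimates_table tidy fit table with `subject_id`, `condition` and
#'   parameter columns.
#' @param subjects subject table with the symptom and covariate columns.
#' @param scales symptom-scale column names.
#' @param measures parameter columns to correlate.
#' @param covariates covariate column names.
#' @param alpha family-wise alpha.
#' @return data.frame: `scale`, `measure`, `condition`, `r`, `p`, `n`,
#'   `alpha_bonferroni`, `pass_bonferroni`.
#' @export
symptom_correlations <- function(estimates_table, subjects,
                                 scales = c("teps_anticipatory",
                                            "teps_consummatory",
                                            "sticsa_cognitive",
                                            "sticsa_somatic", "pss"),
                                 measures = c("bias", "sigma"),
                                 covariates = c("age", "sex", "medication"),
                                 alpha = 0.05) {
  conds <- unique(estimates_table$condition)
  thr <- bonferroni_threshold(alpha, length(conds))
  rows <- list()
  for (sc in scales) for (m in measures) for (cd in conds) {
    sub <- estimates_table[estimates_table$condition == cd, ]
    j <- merge(sub, subjects, by = "subject_id")
    pc <- partial_corr(j[[m]], j[[sc]], j[, covariates, drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      scale = sc, measure = m, condition = cd, r = pc$r, p = pc$p,
      n = pc$n, alpha_bonferroni = thr, pass_bonferroni = pc$p < thr,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
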