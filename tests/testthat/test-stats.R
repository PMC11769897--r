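make_long <- function(n_per_group, groups = c("HC", "MDD", "ANX"),
                      effects = list(), sd_s = 0.2, sd_e = 0.15, seed = 1) {
  set.seed(seed)
  rows <- list()
  sid <- 0
  for (g in groups) for (i in seq_len(n_per_group[[g]])) {
    sid <- sid + 1
    a <- rnorm(1, 0, sd_s)
    for (ctrl in c("extrinsic", "intrinsic")) for (val in c("win", "loss")) {
      mu <- 0.5 + (effects[[g]]$extr %||% 0) * (ctrl == "extrinsic") +
        (effects[[g]]$loss %||% 0) * (val == "loss")
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = sprintf("S%03d", sid), group = g, control = ctrl,
        valence = val, value = mu + a + rnorm(1, 0, sd_e))
    }
  }
  do.call(rbind, rows)
}

test_that("repeated-measures ANOVA matches a hand-worked sums-of-squares
           partition on a 4-subject toy", {
  d <- data.frame(subject_id = rep(paste0("s", 1:4), each = 2),
                  control = rep(c("extrinsic", "intrinsic"), 4),
                  valence = "win",
                  value = c(10, 12, 14, 13, 9, 12, 11, 14))
  out <- rm_anova(d, within = "control")
  # explicit partitioning: SS_total = SS_subject + SS_within + SS_error
  y <- matrix(d$value, 4, 2, byrow = TRUE)
  grand <- mean(y)
  ss_subj <- 2 * sum((rowMeans(y) - grand)^2)
  ss_w <- 4 * sum((colMeans(y) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_w
  f_oracle <- (ss_w / 1) / (ss_err / 3)
  row <- out[out$effect == "control", ]
  expect_equal(row$F, f_oracle, tolerance = 1e-9)
  expect_equal(row$df1, 1)
  expect_equal(row$df2, 3)
  expect_equal(row$p, pf(f_oracle, 1, 3, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("within-effect error degrees of freedom follow the design size", {
  d181 <- make_long(list(HC = 74, MDD = 63, ANX = 44), seed = 2)
  out <- rm_anova(d181, between = "group")
  expect_equal(out$df2[out$effect == "control"], 178)
  expect_equal(out$df2[out$effect == "group:control"], 178)
  expect_equal(out$df2[out$effect == "group"], 178)

  d258 <- make_long(list(HC = 258), groups = "HC", seed = 3)
  out2 <- rm_anova(d258)
  expect_equal(out2$df2[out2$effect == "control"], 257)
})

test_that("ANOVA F values are invariant to affine rescaling of the DV and
           p values stay in [0, 1]", {
  d <- make_long(list(HC = 10, MDD = 10, ANX = 10),
                 effects = list(MDD = list(extr = 0.2)), seed = 4)
  o1 <- rm_anova(d, between = "group")
  d2 <- d
  d2$value <- 100 * d2$value - 7
  o2 <- rm_anova(d2, between = "group")
  expect_equal(o1$F, o2$F, tolerance = 1e-9)
  expect_true(all(o1$p >= 0 & o1$p <= 1))
})

test_that("incomplete crossings and inconsistent groups are rejected", {
  d <- make_long(list(HC = 4), groups = "HC", seed = 5)
  expect_error(rm_anova(d[-1, ]), "S001")
  d$group[1:4] <- c("HC", "MDD", "HC", "HC")
  expect_error(rm_anova(d, between = "group"), "multiple group labels")
})

test_that("Tukey post-hoc p values match a studentized-range oracle", {
  set.seed(6)
  d <- data.frame(value = c(rnorm(5, 0), rnorm(5, 0.5), rnorm(5, 10)),
                  group = rep(c("A", "B", "C"), each = 5))
  out <- tukey_posthoc(d, factor = "group")
  fit <- aov(value ~ group, data = d)
  mse <- sum(residuals(fit)^2) / fit$df.residual
  means <- tapply(d$value, d$group, mean)
  for (i in seq_len(nrow(out))) {
    pair <- strsplit(out$contrast[i], "-")[[1]]
    q <- abs(means[pair[1]] - means[pair[2]]) / sqrt(mse / 5)
    p_oracle <- ptukey(q, nmeans = 3, df = fit$df.residual,
                       lower.tail = FALSE)
    expect_equal(out$p_adj[i], unname(p_oracle), tolerance = 1e-6)
  }
  # the far group separates; the near pair does not
  cvc <- out[grepl("C", out$contrast), ]
  expect_true(all(cvc$p_adj < 0.001))
  expect_gt(out$p_adj[out$contrast == "B-A"], 0.05)
  expect_error(tukey_posthoc(d[d$group == "A", ], factor = "group"),
               ">= 2 levels")
})

test_that("identical group means give Tukey p near 1", {
  d <- data.frame(value = rep(c(1, 2, 3), 3),
                  group = rep(c("A", "B", "C"), each = 3))
  out <- tukey_posthoc(d, factor = "group")
  expect_true(all(out$p_adj > 0.999))
})

test_that("partial correlation matches an explicit residualization oracle", {
  set.seed(7)
  n <- 20
  cov <- data.frame(age = rnorm(n, 40, 10),
                    sex = sample(c("female", "male"), n, TRUE),
                    medication = sample(c(TRUE, FALSE), n, TRUE))
  x <- rnorm(n) + 0.05 * cov$age
  y <- 0.5 * x + rnorm(n) - 0.03 * cov$age
  pc <- partial_corr(x, y, cov)
  Z <- cbind(age = cov$age, sex = as.numeric(factor(cov$sex)) - 1,
             medication = as.numeric(cov$medication))
  rx <- residuals(lm(x ~ Z))
  ry <- residuals(lm(y ~ Z))
  r_oracle <- cor(rx, ry)
  expect_equal(pc$r, r_oracle, tolerance = 1e-12)
  t_oracle <- r_oracle * sqrt((n - 5) / (1 - r_oracle^2))
  expect_equal(pc$p, 2 * pt(-abs(t_oracle), n - 5), tolerance = 1e-12)
  # reductions and degenerate cases
  expect_equal(partial_corr(x, y)$r, cor(x, y), tolerance = 1e-12)
  expect_equal(partial_corr(x, x, cov["age"])$r, 1, tolerance = 1e-10)
  expect_error(partial_corr(rep(1, n), y), "constant")
  expect_error(partial_corr(x[1:4], y[1:4], cov[1:4, ]), "covariates")
})

test_that("dependent-correlation Z test is antisymmetric, zero at equality,
           and matches an independent formula implementation", {
  z0 <- dependent_corr_diff(0.4, 0.4, 0.2, 50)
  expect_equal(z0$Z, 0)
  expect_equal(z0$p_one_sided, 0.5)
  za <- dependent_corr_diff(0.5, 0.2, 0.3, 100)
  zb <- dependent_corr_diff(0.2, 0.5, 0.3, 100)
  expect_equal(za$Z, -zb$Z, tolerance = 1e-12)
  # independent re-derivation
  r_xy <- 0.5; r_xz <- 0.2; r_yz <- 0.3; n <- 100
  rb2 <- mean(c(r_xy^2, r_xz^2))
  f <- min(1, (1 - r_yz) / (2 * (1 - rb2)))
  h <- (1 - f * rb2) / (1 - rb2)
  z_oracle <- (0.5 * log((1 + r_xy) / (1 - r_xy)) -
                 0.5 * log((1 + r_xz) / (1 - r_xz))) *
    sqrt((n - 3) / (2 * (1 - r_yz) * h))
  expect_equal(za$Z, z_oracle, tolerance = 1e-9)
  expect_error(dependent_corr_diff(1, 0.2, 0.3, 50), "strictly")
  expect_error(dependent_corr_diff(0.5, 0.2, 0.3, 3), "n > 3")
})

test_that("Bonferroni threshold divides the family-wise alpha", {
  expect_equal(bonferroni_threshold(0.05, 4), 0.0125)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
})

test_that("Cronbach's alpha follows its variance-ratio definition", {
  set.seed(8)
  base <- rnorm(6)
  expect_equal(cronbach_alpha(matrix(rep(base, 4), 6, 4)), 1)
  X <- matrix(c(2, 4, 3, 5, 1, 6,
                3, 5, 4, 6, 2, 7,
                2, 5, 5, 4, 1, 6,
                4, 4, 3, 6, 2, 5), 6, 4)
  k <- 4
  oracle <- k / (k - 1) * (1 - sum(apply(X, 2, var)) / var(rowSums(X)))
  expect_equal(cronbach_alpha(X), oracle, tolerance = 1e-12)
  # independent items: alpha near zero at large n
  Y <- matrix(rnorm(4000), 1000, 4)
  expect_lt(abs(cronbach_alpha(Y)), 0.15)
  expect_error(cronbach_alpha(matrix(1, 5, 3)), "zero total")
})

test_that("paired t test handles standard and degenerate inputs", {
  s1 <- c(3, 5, 2, 8, 6, 4, 7, 5, 6, 3)
  expect_equal(paired_ttest(s1, s1), list(t = 0, df = 9L, p = 1))
  shift <- paired_ttest(s1, s1 + 2)
  expect_true(is.infinite(shift$t) && shift$t > 0)
  expect_equal(shift$p, 0)
  set.seed(9)
  s2 <- s1 + rnorm(10, 0.5)
  out <- paired_ttest(s1, s2)
  d <- s2 - s1
  t_oracle <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(out$t, t_oracle, tolerance = 1e-12)
  expect_equal(out$df, 9)
  expect_equal(out$p, 2 * pt(-abs(t_oracle), 9), tolerance = 1e-12)
})

test_that("symptom correlation table applies the scale-wise Bonferroni
           threshold consistently", {
  co <- generate_cohort(seed = 12, simulate = FALSE)
  tt <- truth_table(co)
  tab <- data.frame(subject_id = tt$subject_id, condition = tt$condition,
                    bias = tt$bias, sigma = tt$sigma)
  out <- symptom_correlations(tab, co$subjects,
                              scales = c("teps_anticipatory", "pss"))
  expect_equal(unique(out$alpha_bonferroni), 0.0125)
  expect_identical(out$pass_bonferroni, out$p < out$alpha_bonferroni)
  expect_true(all(out$p >= 0 & out$p <= 1))
  # the generator's anticipatory-anhedonia coupling shows up negative
  r_ew <- out$r[out$scale == "teps_anticipatory" & out$measure == "bias" &
                  out$condition == "extrinsic-win"]
  expect_lt(r_ew, 0)
})
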