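test_that("an empty block returns the prior untouched with zero evidence", {
  pr <- initial_prior("sigmoid", "extrinsic")
  est <- fit_subject_condition(data.frame(), "sigmoid", pr,
                               condition = "extrinsic-win")
  expect_equal(est$mean, pr$mean)
  expect_equal(est$cov, pr$cov)
  expect_equal(est$log_evidence, 0)
})

test_that("a near-delta prior dominates the data", {
  g <- group_spec("HC", 1, bias_mean = base_bias)
  sub <- draw_subject(g, seed = 3)
  sched <- build_schedule()
  tr <- simulate_responses(sub, sched, seed = 3)
  blk <- tr[tr$control == "extrinsic" & tr$valence == "win", ]
  pr <- initial_prior("sigmoid", "extrinsic")
  pr$mean["bias"] <- 0.9
  pr$cov <- diag(1e-8, 4)
  dimnames(pr$cov) <- dimnames(initial_prior("sigmoid", "extrinsic")$cov)
  est <- fit_subject_condition(blk, "sigmoid", pr,
                               fit_settings(n_starts = 1L))
  expect_equal(unname(est$mean["bias"]), 0.9, tolerance = 1e-3)
})

test_that("subject-level MAP recovers a known sigmoid bias from dense data", {
  # dense extrinsic sampling, low noise, true bias 0.5
  cfg <- schedule_config(n_trials = 500, extrinsic_fraction = 1,
                         even_split = FALSE, seed = 8)
  sched <- build_schedule(cfg)
  true <- list(params = stats::setNames(rep(list(
    curve_params("sigmoid", c = 60, bias = 0.5, sigma = 0.12)), 4),
    c("extrinsic-win", "extrinsic-loss", "intrinsic-win", "intrinsic-loss")),
    obs = observation_params(choice_temperature = 1, intrinsic_sd = 1),
    rt_log_offset = 0)
  tr <- simulate_responses(true, sched, seed = 17)
  blk <- tr[tr$control == "extrinsic" & tr$valence == "win", ]
  est <- fit_subject_condition(blk, "sigmoid",
                               initial_prior("sigmoid", "extrinsic"),
                               fit_settings(n_starts = 2L, seed = 2L))
  expect_lt(abs(est$natural$bias - 0.5), 0.05)
  expect_true(est$hessian_ok)
  expect_true(is.finite(est$log_evidence))
  # grid-search ML oracle over (bias, sigma) with c and tau at truth
  # confirms the likelihood peaks where the optimizer says it does
  grid <- expand.grid(bias = seq(0.2, 0.8, by = 0.02),
                      sigma = exp(seq(log(0.05), log(0.5), length.out = 15)))
  obs1 <- observation_params(choice_temperature = 1, intrinsic_sd = 1)
  ll <- vapply(seq_len(nrow(grid)), function(i) {
    p <- curve_params("sigmoid", c = 60, bias = grid$bias[i],
                      sigma = grid$sigma[i])
    loglik_extrinsic(p, obs1, blk, blk$accepted)
  }, numeric(1))
  expect_lt(abs(grid$bias[which.max(ll)] - 0.5), 0.05)
})

test_that("the population-prior update matches an explicit two-pass oracle", {
  mk <- function(id, cond, mean, cov) {
    structure(list(subject_id = id, condition = cond, family = "sigmoid",
                   mean = mean, cov = cov, log_evidence = 0),
              class = "posterior_estimate")
  }
  nm <- c("bias", "log_sigma")
  # degenerate: identical estimates
  same <- lapply(1:3, function(i)
    mk(i, "extrinsic-win", stats::setNames(c(0.4, -1), nm), diag(0.1, 2)))
  pr <- update_population_prior(same)
  expect_equal(unname(pr[["extrinsic-win"]]$mean), c(0.4, -1))
  # symmetry: means symmetric about zero
  sym <- list(mk(1, "intrinsic-win", stats::setNames(c(0.3, 1), nm),
                 diag(0.1, 2)),
              mk(2, "intrinsic-win", stats::setNames(c(-0.3, -1), nm),
                 diag(0.1, 2)))
  expect_equal(unname(update_population_prior(sym)[["intrinsic-win"]]$mean),
               c(0, 0))
  # 50 simulated estimates vs an explicit loop-based moment oracle
  set.seed(33)
  means <- matrix(rnorm(100), 50, 2)
  covs <- lapply(1:50, function(i) {A <- matrix(rnorm(4), 2); A %*% t(A) + diag(2)})
  ests <- lapply(1:50, function(i)
    mk(i, "extrinsic-loss", stats::setNames(means[i, ], nm), covs[[i]]))
  pr <- update_population_prior(ests)
  mbar <- c(mean(means[, 1]), mean(means[, 2]))
  between <- matrix(0, 2, 2)
  for (i in 1:50) {
    d <- means[i, ] - mbar
    between <- between + outer(d, d)
  }
  between <- between / 49
  within <- Reduce(`+`, covs) / 50
  expect_equal(unname(pr[["extrinsic-loss"]]$mean), mbar)
  expect_equal(unname(pr[["extrinsic-loss"]]$cov), between + within,
               tolerance = 1e-8)
  expect_error(update_population_prior(same[1]), ">= 2 estimates")
})

test_that("a single-round hierarchical fit equals independent subject fits
           under the initial prior", {
  co <- generate_cohort(one_group(3), schedule_config(n_trials = 60),
                        seed = 44)
  st <- fit_settings(max_rounds = 1L, n_starts = 1L, seed = 5L)
  f <- suppressWarnings(fit_hierarchical(co, "sigmoid", st))
  tr <- co$trials
  tr$condition <- paste(tr$control, tr$valence, sep = "-")
  for (e in f$estimates[1:4]) {
    blk <- tr[tr$subject_id == e$subject_id & tr$condition == e$condition, ]
    solo <- fit_subject_condition(
      blk, "sigmoid",
      initial_prior("sigmoid", sub("-.*", "", e$condition)), st,
      subject_id = e$subject_id, condition = e$condition)
    expect_equal(e$mean, solo$mean, tolerance = 1e-8)
    expect_equal(e$log_evidence, solo$log_evidence, tolerance = 1e-6)
  }
})

test_that("bias recovery improves with trials per subject", {
  counts <- c(56, 112, 228)
  r_by_count <- sapply(counts, function(nt) {
    mean(sapply(1:5, function(s) {
      co <- generate_cohort(one_group(10),
                            schedule_config(n_trials = nt, seed = s),
                            seed = 300 + s)
      st <- fit_settings(max_rounds = 2L, n_starts = 1L, seed = s)
      f <- suppressWarnings(fit_hierarchical(co, "sigmoid", st))
      m <- recovery_merge(f, co)
      cor(m$bias_hat, m$bias_true)
    }))
  })
  expect_gt(r_by_count[3], r_by_count[1])
  expect_gt(r_by_count[2], r_by_count[1] - 0.02)
  expect_gt(r_by_count[3], r_by_count[2] - 0.02)
})

test_that("log-transform reparameterization agrees with direct constrained
           optimization on an easy instance", {
  g <- group_spec("HC", 1, bias_mean = base_bias, tau = 3)
  sub <- draw_subject(g, seed = 9)
  sched <- build_schedule(schedule_config(seed = 2))
  tr <- simulate_responses(sub, sched, seed = 9)
  blk <- tr[tr$control == "intrinsic" & tr$valence == "win", ]
  pr <- initial_prior("sigmoid", "intrinsic")
  est <- fit_subject_condition(blk, "sigmoid", pr,
                               fit_settings(n_starts = 2L, seed = 3L))
  # direct box-constrained optimization on the natural scale of the same
  # penalized objective (prior still on the transformed scale)
  nlj_nat <- function(p) {
    th <- c(bias = p[1], log_sigma = log(p[2]), log_c = log(p[3]),
            log_sigma_obs = log(p[4]))
    cp <- curve_params("sigmoid", c = p[3], bias = p[1], sigma = p[2])
    ob <- observation_params(choice_temperature = 1, intrinsic_sd = p[4])
    ll <- loglik_intrinsic(cp, ob, blk, blk$reported_effort)
    pen <- -0.5 * sum((th - pr$mean)^2 / diag(pr$cov)) -
      0.5 * sum(log(2 * pi * diag(pr$cov)))
    -(ll + pen)
  }
  direct <- optim(c(0.5, 0.2, 52.5, 5), nlj_nat, method = "L-BFGS-B",
                  lower = c(-2, 1e-3, 1, 0.1), upper = c(3, 5, 70, 40))
  expect_equal(est$natural$bias, direct$par[1], tolerance = 0.02)
  expect_equal(est$natural$sigma, direct$par[2], tolerance = 0.05)
})
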