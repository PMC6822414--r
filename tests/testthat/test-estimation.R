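test_that("equal-shares log-likelihood is N log(1/J)", {
  pa <- pilot_attrs()
  des <- optimize_design(pa, n_tasks = 8, seed = 1, n_starts = 1,
                         max_passes = 2)$design
  sim <- simulate_choices(des, prior_vector(pa), 31, seed = 2)
  expect_equal(mnl_loglik(rep(0, 6), sim), 248 * log(1 / 3),
               tolerance = 1e-10)
})

test_that("log-likelihood matches a hand-computed toy oracle", {
  # 2 respondents, 1 task, alternatives (0,0) and (1,2), beta = (0.3, -0.1):
  # resp 1 chooses alt 2, resp 2 chooses alt 1; frozen from the explicit
  # log-softmax sum
  df <- data.frame(
    respondent_id = c(1L, 1L, 2L, 2L), task_id = 1L, alt_id = c(1:2, 1:2),
    is_optout = 0L, chosen = c(0L, 1L, 1L, 0L),
    a = c(0, 1, 0, 1), b = c(0, 2, 0, 2))
  data <- as_choice_data(df, c("a", "b"))
  expect_equal(mnl_loglik(c(0.3, -0.1), data), -1.388793320147,
               tolerance = 1e-10)
})

test_that("log-likelihood is invariant to within-task utility shifts", {
  des <- toy_design()
  sim <- simulate_choices(des, c(0.5, -0.25), 20, seed = 3)
  beta <- c(0.4, -0.2)
  shifted <- as.data.frame(sim)
  # add a task-specific constant vector to every alternative's encoded row
  shifted$a <- shifted$a + ifelse(shifted$task_id == 1L, 2, -1)
  shifted$b <- shifted$b + ifelse(shifted$task_id == 1L, -3, 0.5)
  shifted <- as_choice_data(shifted, c("a", "b"))
  expect_equal(mnl_loglik(beta, sim), mnl_loglik(beta, shifted),
               tolerance = 1e-10)
})

test_that("fit satisfies the first-order condition and improves on the start", {
  pa <- pilot_attrs()
  des <- optimize_design(pa, n_tasks = 8, seed = 4, n_starts = 1,
                         max_passes = 3)$design
  sim <- simulate_choices(des, prior_vector(pa), 100, seed = 5)
  fit <- fit_mnl(sim, tol = 1e-8)
  expect_true(fit$converged)
  expect_lte(fit$grad_norm, 1e-8)
  expect_gte(fit$ll_final, mnl_loglik(rep(0, 6), sim))
  expect_identical(fit$n_obs, 800L)
  expect_identical(fit$n_respondents, 100L)
  expect_true(all(diag(fit$cov_classical) >= 0))
  expect_true(all(diag(fit$cov_robust) >= 0))
  expect_equal(fit$cov_robust, t(fit$cov_robust))
})

test_that("MNL estimation is start-point invariant (global concavity)", {
  pa <- pilot_attrs()
  des <- optimize_design(pa, n_tasks = 8, seed = 6, n_starts = 1,
                         max_passes = 3)$design
  sim <- simulate_choices(des, prior_vector(pa), 60, seed = 7)
  f0 <- fit_mnl(sim, start = rep(0, 6))
  f1 <- fit_mnl(sim, start = c(0.5, -0.5, 0.001, 0.3, -0.4, 1))
  expect_true(f0$converged && f1$converged)
  expect_lt(max(abs(f0$beta_hat - f1$beta_hat)), 1e-6)
})

test_that("parameters are recovered within 3 robust SEs at 500 respondents", {
  pa <- pilot_attrs()
  des <- optimize_design(pa, n_tasks = 8, seed = 8, n_starts = 2)$design
  beta_true <- c(-0.09, 0.48, 3e-4, -0.04, 0.05, -0.23)
  sim <- simulate_choices(des, beta_true, 500, seed = 9)
  fit <- fit_mnl(sim)
  expect_true(fit$converged)
  se <- sqrt(diag(fit$cov_robust))
  expect_true(all(abs(fit$beta_hat - beta_true) < 3 * se))
})

test_that("a no-contrast attribute makes the fit non-identified, flagged", {
  ta <- toy_attrs()
  # b constant within every task: no within-task contrast anywhere
  des <- dce_design(list(rbind(c(1L, 1L), c(2L, 1L)),
                         rbind(c(2L, 1L), c(1L, 1L))),
                    ta, optout = FALSE)
  sim <- simulate_choices(des, c(0.5, 0), 50, seed = 10)
  fit <- fit_mnl(sim)
  expect_false(fit$converged)
  expect_match(fit$note, "singular")
})

test_that("clustered and unclustered sandwiches agree with one task per respondent", {
  des1 <- dce_design(toy_design()$tasks[1L], toy_attrs(), optout = FALSE)
  sim <- simulate_choices(des1, c(0.5, -0.25), 400, seed = 11)
  fc <- fit_mnl(sim, cluster = TRUE)
  fu <- fit_mnl(sim, cluster = FALSE)
  expect_equal(fc$cov_robust, fu$cov_robust, tolerance = 1e-10)
})

test_that("forced-choice fit equals the fit on manually reduced data", {
  pa <- pilot_attrs()
  des <- optimize_design(pa, n_tasks = 8, seed = 12, n_starts = 1,
                         max_passes = 3)$design
  # ASC at -50: the opt-out is never chosen
  beta_true <- c(-0.09, 0.48, 3e-4, -0.04, 0.05, -50)
  sim <- simulate_choices(des, beta_true, 80, seed = 13)
  expect_identical(sum(sim$chosen[sim$is_optout == 1L]), 0L)
  forced <- fit_mnl(sim, include_optout = FALSE)
  expect_identical(forced$dropped_optout_tasks, 0L)
  manual <- as.data.frame(sim)[sim$is_optout == 0L,
                               setdiff(names(sim), "optout")]
  manual$rank <- NULL  # ranks no longer a 1..J permutation after the drop
  manual <- as_choice_data(manual, setdiff(attr(sim, "params"), "optout"))
  ref <- fit_mnl(manual)
  expect_equal(forced$beta_hat, ref$beta_hat, tolerance = 1e-8)
  expect_equal(forced$ll_final, ref$ll_final, tolerance = 1e-8)
})

test_that("forced choice drops and counts tasks where the opt-out won", {
  pa <- pilot_attrs()
  des <- optimize_design(pa, n_tasks = 8, seed = 14, n_starts = 1,
                         max_passes = 2)$design
  sim <- simulate_choices(des, c(0, 0, 0, 0, 0, 0), 30, seed = 15)
  n_oo <- sum(sim$chosen[sim$is_optout == 1L])
  expect_gt(n_oo, 0L)  # with equal shares some opt-outs are chosen
  forced <- fit_mnl(sim, include_optout = FALSE)
  expect_identical(forced$dropped_optout_tasks, as.integer(n_oo))
  expect_identical(forced$n_obs, 240L - as.integer(n_oo))
  expect_identical(length(forced$beta_hat), 5L)
})

test_that("fit statistics reproduce their defining identities", {
  res <- list(ll_final = -222.5633, K = 6L, n_obs = 248L,
              ll_null = 248 * log(1 / 3))
  fs <- fit_stats(res, baseline = -250.6159)
  expect_equal(round(fs$aic, 2), 457.13)
  expect_equal(round(fs$bic, 2), 478.21)
  expect_equal(round(fs$adj_rho2, 2), 0.09)
  expect_identical(fs$baseline_used, "user_supplied")
  # degenerate: ll_final equal to baseline with K = 0 gives rho2 = 0
  fs0 <- fit_stats(list(ll_final = -100, K = 0L, n_obs = 10L, ll_null = -99),
                   baseline = -100)
  expect_equal(fs0$adj_rho2, 0)
  expect_error(fit_stats(list(ll_final = -1, K = 1L, n_obs = 0L)), "positive")
})

test_that("mixed logit with zero variances equals the MNL log-likelihood", {
  pa <- pilot_attrs()
  des <- optimize_design(pa, n_tasks = 8, seed = 16, n_starts = 1,
                         max_passes = 2)$design
  sim <- simulate_choices(des, prior_vector(pa), 40, seed = 17)
  beta <- c(-0.05, 0.4, 2e-4, -0.1, 0.1, -0.3)
  sds <- setNames(rep(0, 5), setdiff(param_names(pa), "optout"))
  expect_equal(mmnl_loglik(sim, beta, sds, n_draws = 50),
               mnl_loglik(beta, sim), tolerance = 1e-12)
})

test_that("simulated likelihood is bit-for-bit reproducible", {
  des <- toy_design()
  sim <- simulate_choices(des, c(0.5, -0.25), 30, seed = 18)
  sds <- c(a = 0.2)
  l1 <- mmnl_loglik(sim, c(0.4, -0.2), sds, n_draws = 100)
  l2 <- mmnl_loglik(sim, c(0.4, -0.2), sds, n_draws = 100)
  expect_identical(l1, l2)
  r1 <- mmnl_loglik(sim, c(0.4, -0.2), sds, n_draws = 100,
                    draw_type = "pseudorandom", seed = 5)
  r2 <- mmnl_loglik(sim, c(0.4, -0.2), sds, n_draws = 100,
                    draw_type = "pseudorandom", seed = 5)
  expect_identical(r1, r2)
  expect_error(mmnl_loglik(sim, c(0.4, -0.2), sds, n_draws = 0), "n_draws")
})

test_that("mixed logit recovers a normal random coefficient", {
  ta <- toy_attrs()
  des <- dce_design(list(rbind(c(1L, 1L), c(2L, 2L)),
                         rbind(c(1L, 2L), c(2L, 1L)),
                         rbind(c(2L, 1L), c(1L, 2L)),
                         rbind(c(2L, 2L), c(1L, 1L))),
                    ta, optout = FALSE)
  # respondent-level normal heterogeneity on a: mean 0.5, sd 0.3
  sim <- simulate_choices(des, c(0.5, -0.25), 500, seed = 19,
                          random_sds = c(0.3, 0))
  fit <- fit_mmnl(sim, random_coefs = "a", n_draws = 200, seed = 20)
  expect_true(fit$converged)
  expect_lt(abs(fit$means[["a"]] - 0.5), 3 * fit$se_means[["a"]])
  expect_lt(abs(fit$sds[["a"]] - 0.3), 3 * fit$se_sds[["a"]])
})

test_that("halton draws are uniform enough and reproducible", {
  z <- halton_normal(500, 2)
  expect_identical(dim(z), c(500L, 2L))
  expect_identical(z, halton_normal(500, 2))
  expect_lt(abs(mean(z[, 1L])), 0.05)
  expect_lt(abs(mean(z[, 2L])), 0.05)
  expect_gt(cor(z[, 1L], z[, 2L]), -0.1)
  expect_lt(cor(z[, 1L], z[, 2L]), 0.1)
})
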