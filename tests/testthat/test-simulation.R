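test_that("analytic probabilities match closed forms", {
  pa <- pilot_attrs()
  des <- optimize_design(pa, n_tasks = 2, seed = 4, n_starts = 1,
                         max_passes = 2)$design
  # beta = 0: equal shares over the 3 alternatives
  p0 <- analytic_choice_probabilities(des, rep(0, 6))
  for (p in p0) expect_equal(unname(p), rep(1 / 3, 3), tolerance = 1e-12)
  # every vector sums to one at arbitrary beta
  pb <- analytic_choice_probabilities(des, c(-0.09, 0.48, 3e-4, -0.04, 0.05, -0.23))
  for (p in pb) expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("two-alternative task reduces to the logistic closed form", {
  des <- toy_design()
  beta <- c(0.7, -0.3)
  p <- analytic_choice_probabilities(des, beta)
  X <- rbind(c(0, 0), c(1, 2))
  expect_equal(p[[1L]][1L],
               1 / (1 + exp(-sum((X[1L, ] - X[2L, ]) * beta))),
               tolerance = 1e-12)
})

test_that("identical alternatives split evenly when the opt-out is killed", {
  ta <- toy_attrs(optout = TRUE)
  # two identical non-opt-out alternatives are forbidden in a design, so
  # make them utility-identical instead: a differs but carries zero weight
  des <- dce_design(list(rbind(c(1L, 1L), c(2L, 1L))), ta, optout = TRUE)
  p <- analytic_choice_probabilities(des, c(0, -0.25, -50))  # ASC -> -50
  expect_equal(p[[1L]][1L], 0.5, tolerance = 1e-10)
  expect_equal(p[[1L]][2L], 0.5, tolerance = 1e-10)
  expect_lt(p[[1L]][3L], 1e-20)
})

test_that("probabilities are invariant to a common utility shift", {
  des <- toy_design()
  beta <- c(0.7, -0.3)
  p1 <- analytic_choice_probabilities(des, beta)
  # shifting both alternatives' rows by the same vector shifts all utilities
  # in a task by a constant; probabilities must not move
  shifted <- des
  shifted$attrs$attributes$a$codes <- shifted$attrs$attributes$a$codes + 5
  p2 <- analytic_choice_probabilities(shifted, beta)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("pilot-shaped simulation has the pilot's observation structure", {
  pa <- pilot_attrs()
  des <- optimize_design(pa, n_tasks = 8, seed = 1, n_starts = 1,
                         max_passes = 3)$design
  sim <- simulate_choices(des, prior_vector(pa), n_respondents = 31, seed = 2)
  expect_identical(nrow(sim), 744L)                     # 31 * 8 * 3
  expect_identical(sum(sim$chosen), 248L)               # 31 * 8
  expect_identical(length(unique(sim$respondent_id)), 31L)
  # ranks are a 1..3 permutation per task and rank 1 is the chosen row
  grp <- paste(sim$respondent_id, sim$task_id)
  expect_true(all(tapply(sim$rank, grp, function(r) setequal(r, 1:3))))
  expect_true(all(sim$chosen[sim$rank == 1L] == 1L))
})

test_that("seed determinism: identical config gives identical data", {
  des <- toy_design()
  a <- simulate_choices(des, c(0.5, -0.25), 10, seed = 42)
  b <- simulate_choices(des, c(0.5, -0.25), 10, seed = 42)
  expect_identical(a, b)
  c <- simulate_choices(des, c(0.5, -0.25), 10, seed = 43)
  expect_false(identical(a$chosen, c$chosen))
})

test_that("beta = 0 gives uniform empirical shares", {
  pa <- pilot_attrs()
  des <- optimize_design(pa, n_tasks = 1, seed = 6, n_starts = 1,
                         max_passes = 2)$design
  sim <- simulate_choices(des, rep(0, 6), n_respondents = 10000, seed = 3,
                          ranks = FALSE)
  shares <- tapply(sim$chosen, sim$alt_id, mean)
  # 99% binomial interval around 1/3 at n = 10,000
  half <- qnorm(0.995) * sqrt((1 / 3) * (2 / 3) / 10000)
  expect_true(all(abs(shares - 1 / 3) < half))
})

test_that("a strictly dominant alternative is chosen in the noiseless limit", {
  ta <- toy_attrs()
  des <- dce_design(list(rbind(c(2L, 1L), c(1L, 2L))), ta, optout = FALSE)
  sim <- simulate_choices(des, 1e6 * c(0.5, -0.25), 5000, seed = 4,
                          ranks = FALSE)
  expect_gt(mean(sim$chosen[sim$alt_id == 1L]), 0.999)
})

test_that("empirical first-choice shares match MNL probabilities", {
  pa <- pilot_attrs()
  des <- optimize_design(pa, n_tasks = 2, seed = 8, n_starts = 1,
                         max_passes = 2)$design
  beta <- c(-0.09, 0.48, 3e-4, -0.04, 0.05, -0.23)
  p <- analytic_choice_probabilities(des, beta)
  sim <- simulate_choices(des, beta, n_respondents = 10000, seed = 5,
                          ranks = FALSE)
  for (s in seq_along(p)) {
    rows <- sim$task_id == s
    shares <- tapply(sim$chosen[rows], sim$alt_id[rows], mean)
    tol <- 3 * sqrt(p[[s]] * (1 - p[[s]]) / 10000)
    expect_true(all(abs(shares - p[[s]]) < tol))
  }
})

test_that("rankings are exploded-logit consistent", {
  pa <- pilot_attrs()
  des <- optimize_design(pa, n_tasks = 1, seed = 10, n_starts = 1,
                         max_passes = 2)$design
  beta <- c(-0.09, 0.48, 3e-4, -0.04, 0.05, -0.23)
  p <- analytic_choice_probabilities(des, beta)[[1L]]
  n <- 20000
  sim <- simulate_choices(des, beta, n_respondents = n, seed = 6)
  # conditional rank-2 shares given each rank-1 winner match MNL on the
  # reduced choice set: p_k / (1 - p_j)
  r1 <- sim$alt_id[sim$rank == 1L]
  r2 <- sim$alt_id[sim$rank == 2L]
  for (j in 1:3) {
    sel <- r1 == j
    nj <- sum(sel)
    for (k in setdiff(1:3, j)) {
      cond <- p[k] / (1 - p[j])
      share <- mean(r2[sel] == k)
      expect_lt(abs(share - cond), 3 * sqrt(cond * (1 - cond) / nj))
    }
  }
})

test_that("dataset validation enforces the choice invariants", {
  des <- toy_design()
  sim <- simulate_choices(des, c(0.5, -0.25), 3, seed = 1)
  bad <- as.data.frame(sim)
  bad$chosen[bad$respondent_id == 1 & bad$task_id == 1] <- 1L
  expect_error(as_choice_data(bad, attr(sim, "params")), "exactly one chosen")
  dup <- rbind(as.data.frame(sim), as.data.frame(sim)[1L, ])
  expect_error(as_choice_data(dup, attr(sim, "params")), "duplicate")
  badrank <- as.data.frame(sim)
  badrank$rank[1:2] <- c(2L, 2L)
  expect_error(as_choice_data(badrank, attr(sim, "params")), "rank")
})
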