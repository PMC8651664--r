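# The artificial radiotherapy environment: learned biomarker transitions,
# the alternating mu/T outcome estimator, step/episode mechanics, JSONL
# trace logs, and the fitted end-to-end environment.

test_that("biomarker transition net recovers a linear dose response", {
  set.seed(11)
  n <- 400
  x <- cbind(a = stats::runif(n), b = stats::runif(n))
  dose <- stats::runif(n, 1, 4)
  y <- cbind(y1 = 2 + 0.8 * dose + 0.3 * x[, "a"] + stats::rnorm(n, 0, 0.05),
             y2 = 1 - 0.4 * dose + 0.5 * x[, "b"] + stats::rnorm(n, 0, 0.05))
  m <- fit_biomarker_transition(x, dose, y, seed = 3)
  x0 <- matrix(0.5, 50, 2, dimnames = list(NULL, c("a", "b")))
  slope1 <- mean(predict_biomarker_transition(m, x0, 3.0)[, 1] -
                 predict_biomarker_transition(m, x0, 2.0)[, 1])
  slope2 <- mean(predict_biomarker_transition(m, x0, 3.0)[, 2] -
                 predict_biomarker_transition(m, x0, 2.0)[, 2])
  expect_equal(slope1, 0.8, tolerance = 0.1)
  expect_equal(slope2, -0.4, tolerance = 0.15)
  # refitting under the same seed is bit-identical
  m2 <- fit_biomarker_transition(x, dose, y, seed = 3)
  expect_identical(m$net, m2$net)
})

test_that("biomarker prediction rejects untrained models and off-grid doses", {
  set.seed(1)
  x <- matrix(stats::runif(40), 20, 2)
  m <- fit_biomarker_transition(x, stats::runif(20, 1, 4),
                                matrix(stats::rnorm(40), 20, 2),
                                epochs = 5L, seed = 1)
  expect_error(predict_biomarker_transition(m, x, 9),
               class = "qdrlart_domain_error")
  fake <- m
  fake$trained <- FALSE
  expect_error(predict_biomarker_transition(fake, x, 2),
               class = "qdrlart_domain_error")
  expect_error(fit_biomarker_transition(x, 1:3, matrix(0, 20, 2)),
               class = "qdrlart_domain_error")
})

test_that("outcome estimator recovers a known logistic dose response", {
  set.seed(42)
  n <- 2000
  states <- cbind(ip10 = stats::rlnorm(n, 5, 0.5),
                  zsv = stats::rlnorm(n, 4, 0.6),
                  genotype = stats::rbinom(n, 2, 0.3))
  g <- stats::runif(n, 40, 90)
  y <- stats::rbinom(n, 1, stats::plogis((60 - g) / (-5)))
  est <- fit_outcome_estimator(states, g, y, weight_decay = 1e-3, seed = 7)
  # independent oracle: the logistic MLE on the same draw
  mle <- stats::glm(y ~ g, family = stats::binomial)
  gs <- seq(40, 90, by = 1)
  idx <- sample(n, 50)
  curve_err <- vapply(gs, function(gg) {
    p_net <- mean(predict_outcome(est, states[idx, ], rep(gg, 50)))
    p_mle <- stats::plogis(sum(stats::coef(mle) * c(1, gg)))
    abs(p_net - p_mle)
  }, numeric(1))
  expect_lt(max(curve_err), 0.05)
  truth_err <- vapply(gs, function(gg) {
    abs(mean(predict_outcome(est, states[idx, ], rep(gg, 50))) -
        stats::plogis((60 - gg) / (-5)))
  }, numeric(1))
  expect_lt(max(truth_err), 0.1)
  # monotone nondecreasing over the reachable g range
  p_curve <- vapply(gs, function(gg) {
    mean(predict_outcome(est, states[idx, ], rep(gg, 50)))
  }, numeric(1))
  expect_true(all(diff(p_curve) >= -1e-9))
})

test_that("outcome estimator is deterministic and rejects one-class labels", {
  set.seed(3)
  n <- 120
  states <- cbind(ip10 = stats::rlnorm(n, 5, 0.5),
                  zsv = stats::rlnorm(n, 4, 0.6),
                  genotype = stats::rbinom(n, 2, 0.3))
  g <- stats::runif(n, 40, 90)
  y <- stats::rbinom(n, 1, stats::plogis((60 - g) / (-5)))
  a <- fit_outcome_estimator(states, g, y, max_rounds = 3L, seed = 5)
  b <- fit_outcome_estimator(states, g, y, max_rounds = 3L, seed = 5)
  expect_identical(a$mu_net, b$mu_net)
  expect_identical(a$t_net, b$t_net)
  expect_error(fit_outcome_estimator(states, g, rep(1, n)),
               class = "qdrlart_domain_error")
  expect_error(fit_outcome_estimator(states, g, c(rep(0, n - 1), 2)),
               class = "qdrlart_domain_error")
})

test_that("environment step composes the three stage functions", {
  env <- make_toy_env("clinical")
  state <- c(ip10 = 150, zsv = 50, tumor_geud = 45, lung_geud = 10,
             genotype = 1)
  res <- arte_step(env, state, 2.0)
  # hand-composition of the stages
  g_t <- 45 + 10 * 2 * (1 + 2 / 10)
  g_l <- 10 + 3 * 2 * (1 + 2 / 4)
  p_lc <- outcome_probability(g_t, 60, -5)
  p_rp2 <- outcome_probability(g_l, 25, -4)
  expect_equal(res$next_state[["tumor_geud"]], g_t)
  expect_equal(res$next_state[["lung_geud"]], g_l)
  expect_equal(res$p_lc, p_lc)
  expect_equal(res$p_rp2, p_rp2)
  expect_equal(res$reward, outcome_reward(p_lc, p_rp2))
  expect_equal(res$done, clinically_desirable(p_lc, p_rp2))
  # determinism
  expect_identical(res, arte_step(env, state, 2.0))
  # a patient already implying the clinical region terminates on any dose
  good <- c(ip10 = 150, zsv = 50, tumor_geud = 80, lung_geud = 2, genotype = 0)
  expect_true(arte_step(env, good, env$params$alpha_beta_lung / 100)$done)
  # low dose on a high-mu patient: fails the region, reward = P+ - 1
  bad <- c(ip10 = 150, zsv = 50, tumor_geud = 10, lung_geud = 2, genotype = 0)
  res_bad <- arte_step(env, bad, 1.0)
  expect_false(res_bad$done)
  expect_equal(res_bad$reward, res_bad$p_lc * (1 - res_bad$p_rp2) - 1)
})

test_that("episodes stop at the clinical region or the step cap", {
  never <- make_toy_env("never", max_steps = 10L)
  state <- c(ip10 = 150, zsv = 50, tumor_geud = 30, lung_geud = 8, genotype = 1)
  tr <- run_episode(never, state, function(s) 2.0)
  expect_equal(nrow(tr), 10L)
  expect_false(any(tr$done))
  term <- make_toy_env("terminal")
  expect_equal(nrow(run_episode(term, state, function(s) 2.0)), 1L)
})

test_that("episode traces round-trip through JSONL", {
  env <- make_toy_env("never", max_steps = 3L)
  state <- c(ip10 = 150, zsv = 50, tumor_geud = 30, lung_geud = 8, genotype = 1)
  tr <- run_episode(env, state, function(s) 2.5)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_episode_log(list(tr, tr), path)
  back <- read_episode_log(path)
  expect_equal(nrow(back), 6L)
  expect_equal(back$reward[1:3], tr$reward, tolerance = 1e-12)
  expect_equal(unique(back$episode), c(1L, 2L))
})

test_that("fitted environment keeps outcomes monotone in dose", {
  co <- generate_cohort(cohort_config(n_patients = 120L, seed = 2L))
  fit <- fit_arte(co, seed = 3L, max_rounds = 8L)
  st <- cohort_states(co)
  doses <- seq(1, 4, by = 0.5)
  for (i in c(1L, 5L, 9L)) {
    p_lc <- vapply(doses, function(d) arte_step(fit$env, st[i, ], d)$p_lc,
                   numeric(1))
    p_rp2 <- vapply(doses, function(d) arte_step(fit$env, st[i, ], d)$p_rp2,
                    numeric(1))
    expect_true(all(diff(p_lc) >= -1e-9))
    expect_true(all(diff(p_rp2) >= -1e-9))
    expect_true(all(p_lc >= 0 & p_lc <= 1 & p_rp2 >= 0 & p_rp2 <= 1))
  }
})
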