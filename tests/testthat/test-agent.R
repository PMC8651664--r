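# The deep-Q agent: double-Q bootstrap targets, epsilon-greedy action
# through the quantum layer, tabular equivalence with dynamic programming,
# and ensemble recommendation.

test_that("double-Q target decouples selection from evaluation", {
  expect_equal(double_q_target(10, 0.99, c(1, 2), c(3, 4), done = TRUE), 10)
  expect_equal(double_q_target(5.42, 0, c(1, 2), c(3, 4), done = FALSE), 5.42)
  # online argmax is index 2; the target net evaluates it at 0.1
  expect_equal(double_q_target(-0.88, 0.99, c(1, 3, 2), c(0.5, 0.1, 0.9),
                               done = FALSE), -0.88 + 0.99 * 0.1)
  expect_error(double_q_target(0, 0.9, c(1, 2), c(1, 2, 3), FALSE),
               class = "qdrlart_domain_error")
})

test_that("epsilon-greedy policy explores uniformly and exploits the argmax", {
  grid <- build_dose_grid(3, 1, 4.1)
  qnet <- qdrlart:::mlp_init(c(2, 8, 8), seed = 4)
  set.seed(9)
  draws <- vapply(1:4000, function(i) {
    agent_act(c(0, 0), qnet, epsilon = 1, grid)$index
  }, integer(1))
  tab <- table(factor(draws, levels = 0:7))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
  q <- qdrlart:::mlp_predict(qnet, matrix(c(0, 0), 1))[1, ]
  set.seed(9)
  greedy <- agent_act(c(0, 0), qnet, epsilon = 0, grid)
  expect_equal(greedy$index, which.max(q) - 1L)
  # reproducible action sequence under a fixed seed
  set.seed(5)
  a <- vapply(1:20, function(i) agent_act(c(0, 0), qnet, 0.5, grid)$index,
              integer(1))
  set.seed(5)
  b <- vapply(1:20, function(i) agent_act(c(0, 0), qnet, 0.5, grid)$index,
              integer(1))
  expect_identical(a, b)
})

test_that("tabular double-Q sweeps match value iteration on a 2-state MDP", {
  # deterministic 2-state, 2-action MDP
  trans <- matrix(c(2L, 1L, 1L, 2L), 2, 2)  # trans[s, a] -> s'
  rew <- matrix(c(1, 0, -1, 2), 2, 2)       # rew[s, a]
  gamma <- 0.9
  # oracle: exact value iteration
  Q_star <- matrix(0, 2, 2)
  repeat {
    Q_new <- Q_star
    for (s in 1:2) for (a in 1:2) {
      Q_new[s, a] <- rew[s, a] + gamma * max(Q_star[trans[s, a], ])
    }
    if (max(abs(Q_new - Q_star)) < 1e-12) break
    Q_star <- Q_new
  }
  # synchronous sweeps driven by double_q_target (previous iterate as the
  # frozen target table)
  Q <- matrix(0, 2, 2)
  for (k in 1:400) {
    Q_prev <- Q
    for (s in 1:2) for (a in 1:2) {
      s2 <- trans[s, a]
      Q[s, a] <- double_q_target(rew[s, a], gamma, Q_prev[s2, ], Q_prev[s2, ],
                                 done = FALSE)
    }
  }
  expect_equal(Q, Q_star, tolerance = 1e-3)
})

test_that("trained agent recovers the enumeration-oracle dose on a toy", {
  env <- make_toy_env("terminal")
  grid <- build_dose_grid(3, 1.0, 4.1)
  train_states <- toy_states(60, seed = 1)
  test_states <- toy_states(40, seed = 2)
  oracle <- apply(test_states, 1, function(s) oracle_best_index(env, grid, s))
  agent <- train_agent(train_states, env, grid,
                       train_config(episodes = 1000L, max_steps = 1L,
                                    eps_end = 0.3, eps_decay_steps = 500L,
                                    seed = 5L))
  pred <- max.col(agent_q_values(agent, test_states), ties.method = "first") - 1L
  expect_gte(mean(abs(pred - oracle) <= 1), 0.95)
})

test_that("training respects the step cap and is seed-reproducible", {
  env <- make_toy_env("never")
  grid <- build_dose_grid(3, 1.0, 4.1)
  states <- toy_states(10, seed = 3)
  cfg <- train_config(episodes = 6L, max_steps = 10L, seed = 11L)
  agent <- train_agent(states, env, grid, cfg)
  steps_per_episode <- table(agent$traces$episode)
  expect_true(all(steps_per_episode == 10L))
  agent2 <- train_agent(states, env, grid, cfg)
  expect_identical(agent$qnet, agent2$qnet)
  expect_identical(agent$traces, agent2$traces)
  expect_error(train_agent(states[0, , drop = FALSE], env, grid, cfg),
               class = "qdrlart_domain_error")
})

test_that("terminal training episodes end inside the clinical region", {
  env <- make_toy_env("clinical")
  grid <- build_dose_grid(3, 1.0, 4.1)
  agent <- train_agent(toy_states(20, seed = 4), env, grid,
                       train_config(episodes = 40L, seed = 2L))
  by_ep <- split(agent$traces, agent$traces$episode)
  for (tr in by_ep) {
    expect_lte(nrow(tr), 10L)
    if (any(tr$done)) {
      last <- tr[nrow(tr), ]
      expect_true(clinically_desirable(last$p_lc, last$p_rp2))
    }
  }
})

test_that("ensemble recommendation reports mean, SEM and member q-values", {
  env <- make_toy_env("terminal")
  grid <- build_dose_grid(3, 1.0, 4.1)
  states <- toy_states(6, seed = 6)
  agent <- train_agent(states, env, grid,
                       train_config(episodes = 30L, max_steps = 1L, seed = 1L))
  # identical members: SEM exactly 0
  rec <- recommend_dose(structure(list(agent, agent, agent, agent, agent),
                                  class = "qdrl_ensemble"), states)
  expect_equal(rec$dose_sem, rep(0, 6))
  expect_equal(dim(attr(rec, "member_doses")), c(6L, 5L))
  # single member: SEM 0 by convention
  rec1 <- recommend_dose(list(agent), states)
  expect_equal(rec1$dose_sem, rep(0, 6))
  expect_equal(rec1$dose_mean, rec$dose_mean)
  expect_error(recommend_dose(list(), states), class = "qdrlart_domain_error")
  # hand-checked SEM for member doses {2.0, 2.0, 2.5, 2.5, 2.0}
  doses <- c(2.0, 2.0, 2.5, 2.5, 2.0)
  expect_equal(stats::sd(doses) / sqrt(5), 0.1224745, tolerance = 1e-6)
})

test_that("agent checkpoints round-trip through serialization", {
  env <- make_toy_env("terminal")
  grid <- build_dose_grid(3, 1.0, 4.1)
  states <- toy_states(5, seed = 8)
  agent <- train_agent(states, env, grid,
                       train_config(episodes = 10L, max_steps = 1L, seed = 2L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_agent(agent, path, config_hash = "abc")
  back <- load_agent(path)
  expect_equal(back$config_hash, "abc")
  expect_identical(back$qnet, agent$qnet)
  expect_equal(agent_q_values(back, states), agent_q_values(agent, states))
})
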