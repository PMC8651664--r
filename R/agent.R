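# The clinical AI agent: a deep Q-net over the dose grid trained with double
# Q-learning from a replay buffer, an epsilon-greedy policy whose greedy arm
# routes through the quantum decision layer, and ensemble-averaged
# recommendation with SEM uncertainty.

#' Training configuration for the deep-Q agent
#'
#' @param gamma Discount factor in `[0, 1)`.
#' @param eps_start,eps_end Linear epsilon annealing endpoints.
#' @param eps_decay_steps Environment steps over which epsilon anneals.
#' @param lr Adam learning rate.
#' @param batch Minibatch size.
#' @param buffer_capacity Replay buffer capacity (FIFO).
#' @param target_sync Gradient updates between target-network syncs.
#' @param episodes Training episodes (one patient rollout each).
#' @param max_steps Step cap per episode (default 10).
#' @param hidden Q-net hidden widths.
#' @param ensemble_size Members trained by [train_ensemble()] (default 5).
#' @param backend Quantum selection backend for the greedy arm
#'   (`"controller-sim"` or `"grover-sim"`).
#' @param shots Measurement shots per selection.
#' @param seed Base RNG seed.
#' @return A list of class `train_config`.
#' @export
train_config <- function(gamma = 0.99, eps_start = 1.0, eps_end = 0.05,
                         eps_decay_steps = 1000L, lr = 1e-3, batch = 64L,
                         buffer_capacity = 10000L, target_sync = 100L,
                         episodes = 300L, max_steps = 10L,
                         hidden = c(64, 64, 64), ensemble_size = 5L,
                         backend = "controller-sim", shots = 256L, seed = 1L) {
  if (gamma < 0 || gamma >= 1) stop_config("gamma must lie in [0, 1)")
  if (max_steps < 1L) stop_config("max_steps must be >= 1")
  structure(as.list(environment()), class = "train_config")
}

#' Double Q-learning bootstrap target
#'
#' `y = r` on terminal transitions, else
#' `y = r + gamma * q_target_next[argmax(q_online_next)]`: the online network
#' selects the next action, the target network evaluates it, decoupling
#' selection from evaluation to curb overestimation.
#'
#' @param r Reward.
#' @param gamma Discount factor.
#' @param q_online_next,q_target_next Next-state q-value vectors (equal
#'   length).
#' @param done Logical terminal flag.
#' @return Scalar target.
#' @examples
#' double_q_target(-0.88, 0.99, c(1, 3, 2), c(0.5, 0.1, 0.9), FALSE) # -0.781
#' @export
double_q_target <- function(r, gamma, q_online_next, q_target_next, done) {
  if (length(q_online_next) != length(q_target_next)) {
    stop_domain("q-value vectors must have equal length")
  }
  if (isTRUE(done)) return(r)
  r + gamma * q_target_next[which.max(q_online_next)]
}

#' Epsilon-greedy action through the quantum layer
#'
#' With probability `epsilon` a uniformly random grid dose; otherwise the
#' greedy dose selected by [select_dose()] on the q-net's output.
#'
#' @param state_std Standardized state vector (the q-net's input).
#' @param qnet The q-network (an `mlp`).
#' @param epsilon Exploration probability.
#' @param grid A [build_dose_grid()].
#' @param backend,shots Forwarded to [select_dose()].
#' @return A `dose_decision` (random picks have `greedy_index = NA`).
#' @export
agent_act <- function(state_std, qnet, epsilon, grid,
                      backend = "controller-sim", shots = 256L) {
  N <- length(grid$levels)
  if (stats::runif(1) < epsilon) {
    idx <- sample.int(N, 1L) - 1L
    structure(
      list(index = idx, bits = index_to_bits(idx, grid$n_qubits),
           dose = grid$levels[idx + 1L], greedy_index = NA_integer_,
           counts = NULL),
      class = "dose_decision"
    )
  } else {
    q <- mlp_predict(qnet, matrix(state_std, nrow = 1L))[1, ]
    select_dose(q, grid, backend = backend, shots = shots)
  }
}

# gather q[cbind(row, col)] for a batch
gather <- function(Q, cols) Q[cbind(seq_len(nrow(Q)), cols)]

#' Train the deep-Q agent in the environment
#'
#' Per episode a patient start state is sampled; the agent rolls out at most
#' `config$max_steps` decisions, storing `(s, a, r, s', done)` transitions in
#' the FIFO replay buffer; after every environment step one minibatch
#' double-Q update is applied, and the target network syncs every
#' `config$target_sync` updates. Deterministic given `config$seed` (the
#' noiseless controller backend consumes RNG draws reproducibly).
#'
#' @param states Matrix of start states (one patient per row, columns
#'   `ip10, zsv, tumor_geud, lung_geud, genotype`).
#' @param env An [arte_env()].
#' @param grid A [build_dose_grid()].
#' @param config A [train_config()].
#' @return A list of class `qdrl_agent`: `qnet`, `scaler`, `grid`, `config`,
#'   per-episode returns, and the episode traces.
#' @export
train_agent <- function(states, env, grid = build_dose_grid(),
                        config = train_config()) {
  states <- as.matrix(states)
  if (nrow(states) == 0L) stop_domain("cannot train on an empty cohort")
  N <- length(grid$levels)
  set.seed(config$seed)
  scaler <- make_scaler(states)
  qnet <- mlp_init(c(ncol(states), config$hidden, N), activation = "relu")
  target <- qnet
  opt <- adam_init(qnet)

  cap <- config$buffer_capacity
  buf_s <- matrix(0, cap, ncol(states))
  buf_s2 <- matrix(0, cap, ncol(states))
  buf_a <- integer(cap)
  buf_r <- numeric(cap)
  buf_done <- logical(cap)
  buf_n <- 0L
  buf_pos <- 0L

  step_count <- 0L
  update_count <- 0L
  traces <- vector("list", config$episodes)
  returns <- numeric(config$episodes)

  for (ep in seq_len(config$episodes)) {
    pid <- sample.int(nrow(states), 1L)
    state <- states[pid, ]
    ep_rows <- vector("list", config$max_steps)
    for (t in seq_len(config$max_steps)) {
      eps <- max(config$eps_end,
                 config$eps_start - (config$eps_start - config$eps_end) *
                   step_count / config$eps_decay_steps)
      s_std <- as.numeric(scale_apply(scaler, matrix(state, nrow = 1L)))
      decision <- agent_act(s_std, qnet, eps, grid,
                            backend = config$backend, shots = config$shots)
      res <- arte_step(env, state, decision$dose)
      s2_std <- as.numeric(scale_apply(scaler, matrix(res$next_state, nrow = 1L)))

      buf_pos <- (buf_pos %% cap) + 1L
      buf_s[buf_pos, ] <- s_std
      buf_s2[buf_pos, ] <- s2_std
      buf_a[buf_pos] <- decision$index + 1L
      buf_r[buf_pos] <- res$reward
      buf_done[buf_pos] <- res$done
      buf_n <- min(buf_n + 1L, cap)
      step_count <- step_count + 1L
      returns[ep] <- returns[ep] + res$reward
      ep_rows[[t]] <- data.frame(
        episode = ep, step = t, dose_index = decision$index,
        dose = decision$dose, p_lc = res$p_lc, p_rp2 = res$p_rp2,
        reward = res$reward, done = res$done, epsilon = eps
      )

      if (buf_n >= config$batch) {
        rows <- sample.int(buf_n, config$batch)
        Qs <- mlp_forward(qnet, buf_s[rows, , drop = FALSE])
        Qo2 <- mlp_predict(qnet, buf_s2[rows, , drop = FALSE])
        Qt2 <- mlp_predict(target, buf_s2[rows, , drop = FALSE])
        a_star <- max.col(Qo2, ties.method = "first")
        y <- buf_r[rows] +
          config$gamma * ifelse(buf_done[rows], 0, gather(Qt2, a_star))
        d_out <- matrix(0, config$batch, N)
        pred <- gather(Qs$out, buf_a[rows])
        d_out[cbind(seq_len(config$batch), buf_a[rows])] <-
          2 * (pred - y) / config$batch
        gr <- mlp_backward(qnet, Qs, d_out)
        st <- adam_step(qnet, opt, gr$gW, gr$gb, lr = config$lr)
        qnet <- st$net
        opt <- st$opt
        update_count <- update_count + 1L
        if (update_count %% config$target_sync == 0L) target <- qnet
      }

      state <- res$next_state
      if (res$done) break
    }
    traces[[ep]] <- do.call(rbind, ep_rows[!vapply(ep_rows, is.null, logical(1))])
  }
  structure(
    list(qnet = qnet, scaler = scaler, grid = grid, config = config,
         returns = returns, traces = do.call(rbind, traces)),
    class = "qdrl_agent"
  )
}

#' @export
print.qdrl_agent <- function(x, ...) {
  cat(sprintf(
    "<qdrl_agent> %d episodes, %d-level grid, mean return (last 20%%) %.2f\n",
    length(x$returns), length(x$grid$levels),
    mean(utils::tail(x$returns, max(1L, length(x$returns) %/% 5L)))))
  invisible(x)
}

#' Q-values of an agent for a batch of states
#'
#' @param agent A trained `qdrl_agent`.
#' @param states State matrix (unstandardized).
#' @return Matrix of q-values (rows = states, columns = grid doses).
#' @export
agent_q_values <- function(agent, states) {
  mlp_predict(agent$qnet, scale_apply(agent$scaler, as.matrix(states)))
}

#' Train an ensemble of identically configured agents
#'
#' Members differ only in seed (`config$seed + 0:(m-1)`), mirroring the
#' repeat-and-average protocol used for reporting.
#'
#' @param states,env,grid,config As in [train_agent()].
#' @param n_members Ensemble size (default `config$ensemble_size`).
#' @return A list of class `qdrl_ensemble` of trained agents.
#' @export
train_ensemble <- function(states, env, grid = build_dose_grid(),
                           config = train_config(),
                           n_members = config$ensemble_size) {
  members <- lapply(seq_len(n_members) - 1L, function(k) {
    cfg <- config
    cfg$seed <- config$seed + k
    train_agent(states, env, grid, cfg)
  })
  structure(members, class = "qdrl_ensemble")
}

#' Ensemble dose recommendation with SEM uncertainty
#'
#' Each member recommends its greedy dose per state (noiseless selection is
#' exactly the argmax); the report is the ensemble mean dose with the
#' standard error of the mean (`sd / sqrt(m)`; 0 by convention for a single
#' member) and each member's q-value at its recommended dose, the confidence
#' proxy.
#'
#' @param ensemble A `qdrl_ensemble` (or a list of `qdrl_agent`s).
#' @param states State matrix, one row per patient.
#' @return A data frame: `dose_mean`, `dose_sem`, `q_mean`, plus matrices of
#'   member doses and q-values in attributes `member_doses`, `member_q`.
#' @export
recommend_dose <- function(ensemble, states) {
  if (length(ensemble) == 0L) stop_domain("ensemble must be nonempty")
  states <- as.matrix(states)
  m <- length(ensemble)
  doses <- matrix(0, nrow(states), m)
  qmax <- matrix(0, nrow(states), m)
  for (k in seq_len(m)) {
    agent <- ensemble[[k]]
    Q <- agent_q_values(agent, states)
    idx <- max.col(Q, ties.method = "first")
    doses[, k] <- agent$grid$levels[idx]
    qmax[, k] <- gather(Q, idx)
  }
  sem <- if (m == 1L) rep(0, nrow(states)) else apply(doses, 1L, stats::sd) / sqrt(m)
  out <- data.frame(
    dose_mean = rowMeans(doses),
    dose_sem = sem,
    q_mean = rowMeans(qmax)
  )
  if (!is.null(rownames(states))) out$patient_id <- rownames(states)
  attr(out, "member_doses") <- doses
  attr(out, "member_q") <- qmax
  out
}

#' Save / load a trained agent checkpoint
#'
#' Checkpoints are serialized R objects embedding the training configuration
#' and, when supplied, the run configuration hash, so a recommendation can
#' always be traced to the configuration that trained it.
#'
#' @param agent A `qdrl_agent`.
#' @param path File path (`.rds`).
#' @param config_hash Optional hash string embedded in the checkpoint.
#' @return `save_agent` returns `path` invisibly; `load_agent` the agent.
#' @export
save_agent <- function(agent, path, config_hash = NULL) {
  agent$config_hash <- config_hash
  saveRDS(agent, path)
  invisible(path)
}

#' @rdname save_agent
#' @export
load_agent <- function(path) {
  agent <- readRDS(path)
  if (!inherits(agent, "qdrl_agent")) stop_domain(path, " is not an agent checkpoint")
  agent
}
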