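# The artificial radiotherapy environment (ARTE): a model-based RL
# environment over the 5-tuple (patient states, dose register, transition
# function, outcome estimator, reward). Biomarker transitions are learned
# regression nets; tumor/lung gEUD advance by the process-driven monotone
# rule; outcomes come from logistic heads whose midpoint and slope are the
# outputs of two alternately trained networks.

state_features <- c("ip10", "zsv", "tumor_geud", "lung_geud", "genotype")

make_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  # a feature without training variance carries no information: mapping it
  # to 0 regardless of input makes downstream models invariant to it
  sd[sd < 1e-12] <- Inf
  list(mu = mu, sd = sd)
}

scale_apply <- function(scaler, X) {
  sweep(sweep(X, 2L, scaler$mu, "-"), 2L, scaler$sd, "/")
}

# Biomarker transition --------------------------------------------------------

#' Fit a biomarker transition network
#'
#' Trains a dense regression net mapping (state features, dose per fraction)
#' to the next-period biomarker values, minimizing mean squared error on
#' standardized inputs and outputs with Adam. Used in the environment for the
#' IP10 and GLSZM-ZSV features, whose dynamics have no process-driven form.
#'
#' @param x Numeric matrix of input features (one row per record).
#' @param dose Numeric vector of doses (Gy/frac) delivered over the period.
#' @param y Numeric matrix of next-period target values.
#' @param dose_range Length-2 numeric: doses accepted at prediction time
#'   (default the training range). Predictions outside it raise a domain
#'   error.
#' @param hidden Hidden-layer widths.
#' @param epochs Adam passes over the data.
#' @param batch Minibatch size.
#' @param lr Learning rate.
#' @param seed RNG seed; fits are deterministic given it.
#' @return A list of class `biomarker_model`.
#' @export
fit_biomarker_transition <- function(x, dose, y, dose_range = NULL,
                                     hidden = c(32, 32), epochs = 300L,
                                     batch = 32L, lr = 1e-3, seed = 1L) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) != length(dose) || nrow(x) != nrow(y)) {
    stop_domain("x, dose and y must have matching row counts")
  }
  if (is.null(dose_range)) dose_range <- range(dose)
  X <- cbind(x, dose = dose)
  sx <- make_scaler(X)
  sy <- make_scaler(y)
  Xs <- scale_apply(sx, X)
  Ys <- scale_apply(sy, y)
  set.seed(seed)
  net <- mlp_init(c(ncol(Xs), hidden, ncol(Ys)), activation = "tanh")
  opt <- adam_init(net)
  n <- nrow(Xs)
  bs <- min(batch, n)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    for (start in seq(1L, n, by = bs)) {
      rows <- idx[start:min(start + bs - 1L, n)]
      fwd <- mlp_forward(net, Xs[rows, , drop = FALSE])
      err <- fwd$out - Ys[rows, , drop = FALSE]
      g <- mlp_backward(net, fwd, 2 * err / length(err))
      st <- adam_step(net, opt, g$gW, g$gb, lr = lr)
      net <- st$net
      opt <- st$opt
    }
  }
  structure(
    list(net = net, scaler_x = sx, scaler_y = sy, dose_range = dose_range,
         trained = TRUE),
    class = "biomarker_model"
  )
}

#' Predict next-period biomarkers
#'
#' @param model A fitted [fit_biomarker_transition()] model.
#' @param x Input feature matrix (rows = records).
#' @param dose Dose per fraction (Gy), recycled to `nrow(x)`; must lie inside
#'   the model's `dose_range`.
#' @return Matrix of predictions on the original scale.
#' @export
predict_biomarker_transition <- function(model, x, dose) {
  if (!inherits(model, "biomarker_model") || !isTRUE(model$trained)) {
    stop_domain("model must be a fitted biomarker_model")
  }
  x <- as.matrix(x)
  dose <- rep_len(dose, nrow(x))
  tol <- 1e-9
  if (any(dose < model$dose_range[1] - tol | dose > model$dose_range[2] + tol)) {
    stop_domain("dose outside the trained range [",
                model$dose_range[1], ", ", model$dose_range[2], "]")
  }
  Xs <- scale_apply(model$scaler_x, cbind(x, dose = dose))
  Ys <- mlp_predict(model$net, Xs)
  sweep(sweep(Ys, 2L, model$scaler_y$sd, "*"), 2L, model$scaler_y$mu, "+")
}

# Outcome estimator ------------------------------------------------------------

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Fit a logistic outcome estimator with alternating mu/T networks
#'
#' Models a binary outcome as `p = 1 / (1 + exp((g - mu(s)) / T(s)))` where
#' `g` is the end-of-treatment gEUD and the patient-specific midpoint
#' `mu(s)` and slope `T(s)` are the scalar outputs of two networks over the
#' post-irradiation state `s`. `T` is constrained negative through a
#' softplus reparameterization so the probability rises with `g` (and hence
#' with dose) for every patient. The two networks are tuned one after the
#' other — the mu-net with the T-net frozen, then the reverse — under
#' binary cross-entropy, until the loss improves by less than `tol` over a
#' round or `max_rounds` is reached.
#'
#' @param states Numeric matrix of post-irradiation patient states.
#' @param g End-of-treatment gEUD (Gy) per record.
#' @param labels Binary outcome labels (both classes must occur).
#' The state matrix passed here should exclude the endpoint's own gEUD
#' (which enters through `g`); feeding it to the heads as well makes the
#' pair (mu, T) unidentified and lets `T` collapse toward zero.
#'
#' @param hidden Hidden width of each head network.
#' @param max_rounds Maximum alternation rounds.
#' @param epochs_per_round Adam steps per half-round.
#' @param tol Absolute loss-change tolerance for stopping.
#' @param lr Learning rate.
#' @param t_init Initial magnitude of the negative slope (Gy).
#' @param t_min Floor (Gy) on `|T|`; keeps the fitted curves from
#'   degenerating into step functions.
#' @param weight_decay L2 penalty on the head-network weights.
#' @param seed RNG seed.
#' @return A list of class `outcome_estimator`.
#' @export
fit_outcome_estimator <- function(states, g, labels, hidden = 16L,
                                  max_rounds = 25L, epochs_per_round = 60L,
                                  tol = 1e-5, lr = 5e-3, t_init = 5,
                                  t_min = 0.5, weight_decay = 1e-4, seed = 1L) {
  states <- as.matrix(states)
  if (nrow(states) != length(g) || length(g) != length(labels)) {
    stop_domain("states, g and labels must have matching lengths")
  }
  if (!all(labels %in% c(0, 1))) stop_domain("labels must be binary 0/1")
  if (length(unique(labels)) < 2L) {
    stop_domain("labels contain a single class; the logistic fit is unidentified")
  }
  sx <- make_scaler(states)
  Xs <- scale_apply(sx, states)
  y <- as.numeric(labels)
  set.seed(seed)
  mu_net <- mlp_init(c(ncol(Xs), hidden, 1L), activation = "tanh")
  t_net <- mlp_init(c(ncol(Xs), hidden, 1L), activation = "tanh")
  mu_offset <- mean(g)
  # t_min + softplus(u0) = t_init so training starts at T = -t_init
  if (t_init <= t_min) stop_config("t_init must exceed t_min")
  u0 <- log(expm1(t_init - t_min))
  mu_opt <- adam_init(mu_net)
  t_opt <- adam_init(t_net)
  n <- length(y)

  eval_model <- function() {
    mu <- mlp_predict(mu_net, Xs)[, 1] + mu_offset
    u <- mlp_predict(t_net, Xs)[, 1] + u0
    t_val <- -(t_min + softplus(u))
    z <- (mu - g) / t_val
    p <- stats::plogis(z)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    list(mu = mu, u = u, t_val = t_val, p = p,
         loss = -mean(y * log(p) + (1 - y) * log(1 - p)))
  }

  last_loss <- eval_model()$loss
  rounds_used <- 0L
  for (round in seq_len(max_rounds)) {
    rounds_used <- round
    for (which_net in c("mu", "t")) {
      for (step in seq_len(epochs_per_round)) {
        ev <- eval_model()
        dz <- (ev$p - y) / n                       # d(BCE)/dz, mean form
        if (which_net == "mu") {
          d_out <- matrix(dz / ev$t_val, ncol = 1L)
          fwd <- mlp_forward(mu_net, Xs)
          gr <- mlp_backward(mu_net, fwd, d_out)
          gW <- Map(function(gw, w) gw + weight_decay * w, gr$gW, mu_net$W)
          st <- adam_step(mu_net, mu_opt, gW, gr$gb, lr = lr)
          mu_net <- st$net; mu_opt <- st$opt
        } else {
          # dz/dT = -(mu - g)/T^2, dT/du = -sigmoid(u)
          d_out <- matrix(dz * (ev$mu - g) / ev$t_val^2 * stats::plogis(ev$u),
                          ncol = 1L)
          fwd <- mlp_forward(t_net, Xs)
          gr <- mlp_backward(t_net, fwd, d_out)
          gW <- Map(function(gw, w) gw + weight_decay * w, gr$gW, t_net$W)
          st <- adam_step(t_net, t_opt, gW, gr$gb, lr = lr)
          t_net <- st$net; t_opt <- st$opt
        }
      }
    }
    loss <- eval_model()$loss
    if (abs(last_loss - loss) < tol) break
    last_loss <- loss
  }
  structure(
    list(mu_net = mu_net, t_net = t_net, mu_offset = mu_offset, u0 = u0,
         t_min = t_min, scaler = sx, rounds = rounds_used,
         loss = eval_model()$loss),
    class = "outcome_estimator"
  )
}

#' Predict outcome probabilities from a fitted estimator
#'
#' @param est An [fit_outcome_estimator()] fit.
#' @param states Post-irradiation state matrix.
#' @param g End-of-treatment gEUD (Gy) per row.
#' @return Probability vector in (0, 1), nondecreasing in `g` row-wise.
#' @export
predict_outcome <- function(est, states, g) {
  states <- as.matrix(states)
  Xs <- scale_apply(est$scaler, states)
  mu <- mlp_predict(est$mu_net, Xs)[, 1] + est$mu_offset
  t_val <- -(est$t_min + softplus(mlp_predict(est$t_net, Xs)[, 1] + est$u0))
  outcome_probability(g, mu, t_val)
}

# Environment ------------------------------------------------------------------

#' Construct an artificial radiotherapy environment
#'
#' Bundles the three stage functions of the environment — the biomarker and
#' gEUD transitions, the outcome estimator, and the reward — behind a single
#' step interface. The component functions are supplied explicitly so that
#' fitted models ([fit_arte()]) and analytic toys share one API.
#'
#' @param biomarker_fn `function(state, dose) -> c(ip10, zsv)` for the next
#'   period.
#' @param p_lc_fn,p_rp2_fn `function(state) -> probability`, evaluated on the
#'   next state.
#' @param params A [radiobio_params()].
#' @param max_steps Episode step cap (default 10).
#' @param dt Adaptation periods advanced per step (default 1).
#' @param done_fn `function(p_lc, p_rp2) -> logical` deciding episode
#'   termination; defaults to membership of the clinically desirable region
#'   ([clinically_desirable()]).
#' @return A list of class `arte_env`.
#' @export
arte_env <- function(biomarker_fn, p_lc_fn, p_rp2_fn,
                     params = radiobio_params(), max_steps = 10L, dt = 1,
                     done_fn = clinically_desirable) {
  if (max_steps < 1L) stop_config("max_steps must be >= 1")
  structure(
    list(biomarker_fn = biomarker_fn, p_lc_fn = p_lc_fn, p_rp2_fn = p_rp2_fn,
         params = params, max_steps = as.integer(max_steps), dt = dt,
         done_fn = done_fn),
    class = "arte_env"
  )
}

#' Advance the environment by one decision step
#'
#' Applies, in succession, the biomarker transition, the monotone gEUD
#' transitions for tumor and lung, the outcome estimator on the resulting
#' state, and the reward. The step terminates the episode (`done = TRUE`)
#' exactly when the outcome estimate enters the clinically desirable region.
#'
#' @param env An [arte_env()].
#' @param state Named numeric state vector with elements
#'   `ip10, zsv, tumor_geud, lung_geud, genotype`.
#' @param dose Dose per fraction (Gy) for the step.
#' @return A list: `next_state`, `p_lc`, `p_rp2`, `reward`, `done`.
#' @export
arte_step <- function(env, state, dose) {
  bm <- env$biomarker_fn(state, dose)
  next_state <- state
  next_state[["ip10"]] <- bm[[1]]
  next_state[["zsv"]] <- bm[[2]]
  next_state[["tumor_geud"]] <- geud_transition(
    state[["tumor_geud"]], dose, env$dt, env$params, "tumor")
  next_state[["lung_geud"]] <- geud_transition(
    state[["lung_geud"]], dose, env$dt, env$params, "lung")
  p_lc <- env$p_lc_fn(next_state)
  p_rp2 <- env$p_rp2_fn(next_state)
  list(
    next_state = next_state,
    p_lc = p_lc, p_rp2 = p_rp2,
    reward = outcome_reward(p_lc, p_rp2),
    done = env$done_fn(p_lc, p_rp2)
  )
}

#' Roll out one episode under a policy
#'
#' Starts from the mid-treatment decision point and repeatedly applies the
#' policy and [arte_step()] until the clinically desirable region is reached
#' or the step cap is hit.
#'
#' @param env An [arte_env()].
#' @param state Initial named state vector.
#' @param policy `function(state) -> dose (Gy/frac)`.
#' @param max_steps Step cap; default the environment's.
#' @return A data frame of transitions (one row per step) with the state,
#'   dose, outcome estimates, reward and `done` flag.
#' @export
run_episode <- function(env, state, policy, max_steps = env$max_steps) {
  rows <- vector("list", max_steps)
  for (t in seq_len(max_steps)) {
    dose <- policy(state)
    res <- arte_step(env, state, dose)
    rows[[t]] <- data.frame(
      step = t,
      ip10 = state[["ip10"]], zsv = state[["zsv"]],
      tumor_geud = state[["tumor_geud"]], lung_geud = state[["lung_geud"]],
      genotype = state[["genotype"]],
      dose = dose, p_lc = res$p_lc, p_rp2 = res$p_rp2,
      reward = res$reward, done = res$done
    )
    state <- res$next_state
    if (res$done) break
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Write / read episode traces as JSONL
#'
#' One JSON object per transition per line.
#'
#' @param traces Data frame of transitions (as from [run_episode()]), or a
#'   list of such frames.
#' @param path File path.
#' @return `write_episode_log` returns `path` invisibly; `read_episode_log`
#'   returns a data frame.
#' @export
write_episode_log <- function(traces, path) {
  if (is.data.frame(traces)) traces <- list(traces)
  con <- file(path, open = "w")
  on.exit(close(con))
  for (ep in seq_along(traces)) {
    tr <- traces[[ep]]
    for (i in seq_len(nrow(tr))) {
      row <- as.list(tr[i, , drop = FALSE])
      row$episode <- ep
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' @rdname write_episode_log
#' @export
read_episode_log <- function(path) {
  lines <- readLines(path)
  do.call(rbind, lapply(lines, function(ln) {
    as.data.frame(jsonlite::fromJSON(ln))
  }))
}

#' Fit the full environment from a cohort
#'
#' Trains the biomarker transition net on (baseline state, first-phase
#' protocol dose) to mid-treatment IP10/ZSV values (log scale), computes each
#' patient's end-of-treatment gEUDs from the clinical dose of the final
#' third, fits the two logistic outcome estimators, and assembles an
#' [arte_env()] whose step starts from the mid-treatment decision point.
#'
#' @param cohort A cohort data frame ([cohort_columns]).
#' @param grid A [build_dose_grid()]; its range bounds admissible doses.
#' @param params A [radiobio_params()].
#' @param protocol_dose Dose per fraction (Gy) of the first two treatment
#'   thirds used as the transition net's training dose (standard
#'   fractionation, 2 Gy/frac).
#' @param max_steps Episode step cap.
#' @param seed RNG seed for both fits.
#' @param ... Passed to [fit_outcome_estimator()].
#' @return A list of class `arte_fit`: the `env`, plus the fitted
#'   `biomarker_model`, `lc_estimator`, `rp2_estimator`.
#' @export
fit_arte <- function(cohort, grid = build_dose_grid(),
                     params = radiobio_params(), protocol_dose = 2.0,
                     max_steps = 10L, seed = 1L, ...) {
  cohort <- validate_cohort(cohort)
  pre <- as.matrix(cohort[, c("ip10_pre", "zsv_pre", "tumor_geud_pre",
                              "lung_geud_pre", "genotype")])
  colnames(pre) <- state_features
  bm_targets <- cbind(log_ip10 = log(cohort$ip10_mid),
                      log_zsv = log(cohort$zsv_mid))
  bm <- fit_biomarker_transition(
    cbind(pre[, 1:4], genotype = pre[, 5]),
    dose = rep(protocol_dose, nrow(pre)),
    y = bm_targets,
    dose_range = c(min(grid$d_min, protocol_dose), max(grid$d_max, protocol_dose)),
    seed = seed
  )
  g6_tumor <- geud_transition(cohort$tumor_geud_mid, cohort$clinical_dose,
                              1, params, "tumor")
  g6_lung <- geud_transition(cohort$lung_geud_mid, cohort$clinical_dose,
                             1, params, "lung")
  # the heads see only the dose-independent biology: feeding either gEUD to
  # them would let mu(s) proxy the dose and break the monotone dose
  # response that the logistic argument g is meant to carry
  lc_feats <- c("ip10", "zsv", "genotype")
  rp2_feats <- c("ip10", "zsv", "genotype")
  post <- cbind(ip10 = cohort$ip10_mid, zsv = cohort$zsv_mid,
                tumor_geud = g6_tumor, lung_geud = g6_lung,
                genotype = cohort$genotype)
  lc_est <- fit_outcome_estimator(post[, lc_feats, drop = FALSE], g6_tumor,
                                  cohort$lc, seed = seed, ...)
  rp2_est <- fit_outcome_estimator(post[, rp2_feats, drop = FALSE], g6_lung,
                                   cohort$rp2, seed = seed + 1L, ...)

  biomarker_fn <- function(state, dose) {
    pred <- predict_biomarker_transition(
      bm, matrix(state[state_features], nrow = 1L,
                 dimnames = list(NULL, state_features)), dose)
    c(exp(pred[1, 1]), exp(pred[1, 2]))
  }
  state_row <- function(state, feats) {
    matrix(state[feats], nrow = 1L, dimnames = list(NULL, feats))
  }
  p_lc_fn <- function(state) {
    predict_outcome(lc_est, state_row(state, lc_feats), state[["tumor_geud"]])
  }
  p_rp2_fn <- function(state) {
    predict_outcome(rp2_est, state_row(state, rp2_feats), state[["lung_geud"]])
  }
  structure(
    list(
      env = arte_env(biomarker_fn, p_lc_fn, p_rp2_fn, params,
                     max_steps = max_steps),
      biomarker_model = bm, lc_estimator = lc_est, rp2_estimator = rp2_est,
      grid = grid, params = params
    ),
    class = "arte_fit"
  )
}

#' Mid-treatment decision states of a cohort
#'
#' @param cohort Cohort data frame.
#' @return Matrix with one named state row per patient (columns
#'   `ip10, zsv, tumor_geud, lung_geud, genotype`).
#' @export
cohort_states <- function(cohort) {
  m <- as.matrix(cohort[, c("ip10_mid", "zsv_mid", "tumor_geud_mid",
                            "lung_geud_mid", "genotype")])
  colnames(m) <- state_features
  rownames(m) <- cohort$patient_id
  m
}
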