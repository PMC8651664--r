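# Shared fixtures: analytic toy environments and state samplers used across
# the agent, environment and acceptance tests.

# Deterministic toy environment with fixed logistic outcomes on the gEUDs.
# `terminal` makes every step terminal (contextual-bandit setting), `never`
# makes no step terminal (exercises the step cap).
make_toy_env <- function(mode = c("clinical", "terminal", "never"),
                         max_steps = 10L) {
  mode <- match.arg(mode)
  done_fn <- switch(mode,
    clinical = clinically_desirable,
    terminal = function(p_lc, p_rp2) TRUE,
    never = function(p_lc, p_rp2) FALSE
  )
  arte_env(
    biomarker_fn = function(state, dose) c(state[["ip10"]], state[["zsv"]]),
    p_lc_fn = function(s) outcome_probability(s[["tumor_geud"]], 60, -5),
    p_rp2_fn = function(s) outcome_probability(s[["lung_geud"]], 25, -4),
    params = radiobio_params(),
    max_steps = max_steps,
    done_fn = done_fn
  )
}

# Patient start states in the regime where the toy environment's optimum is
# interior to the dose grid.
toy_states <- function(n, seed) {
  set.seed(seed)
  cbind(
    ip10 = stats::rlnorm(n, 5, 0.4),
    zsv = stats::rlnorm(n, 4, 0.5),
    tumor_geud = stats::runif(n, 30, 55),
    lung_geud = stats::runif(n, 6, 18),
    genotype = stats::rbinom(n, 2, 0.3)
  )
}

# Enumeration oracle: the grid dose maximizing the one-step reward.
oracle_best_index <- function(env, grid, state) {
  r <- vapply(grid$levels, function(d) arte_step(env, state, d)$reward,
              numeric(1))
  which.max(r) - 1L
}

tiny_cohort <- function(n = 3L) {
  data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    ip10_pre = seq(100, 100 + 10 * (n - 1), by = 10),
    zsv_pre = seq(40, 40 + 5 * (n - 1), by = 5),
    tumor_geud_pre = rep(25, n),
    lung_geud_pre = rep(6, n),
    genotype = rep_len(c(0L, 1L, 2L), n),
    ip10_mid = seq(90, 90 + 10 * (n - 1), by = 10),
    zsv_mid = seq(35, 35 + 5 * (n - 1), by = 5),
    tumor_geud_mid = rep(43, n),
    lung_geud_mid = rep(12, n),
    clinical_dose = seq(2, 2 + 0.25 * (n - 1), by = 0.25),
    lc = rep_len(c(1L, 0L), n),
    rp2 = rep_len(c(0L, 1L), n),
    stringsAsFactors = FALSE
  )
}
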