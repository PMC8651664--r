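# Radiobiological dose math and the reward function of the artificial
# radiotherapy environment: EQD2 fractionation correction, generalized
# equivalent uniform dose, the monotone process-driven gEUD transition, the
# logistic outcome estimator, and the bonus-structured reward on
# (p_LC, p_RP2).

#' Equivalent dose in 2 Gy fractions
#'
#' Converts a physical dose of `n_frac` fractions of `d` Gy into the
#' isoeffective total dose delivered at the standard 2 Gy per fraction, under
#' the linear-quadratic model:
#' `EQD2 = n_frac * d * (d + alpha/beta) / (2 + alpha/beta)`.
#' The conversion has its nonzero fixed point at `d = 2` Gy for every
#' `alpha/beta`: a 2 Gy/frac schedule is its own equivalent.
#'
#' @param d Dose per fraction (Gy), nonnegative.
#' @param n_frac Number of fractions, nonnegative.
#' @param alpha_beta Fractionation-sensitivity ratio alpha/beta (Gy),
#'   positive; 10 Gy for tumor, 4 Gy for lung.
#' @return EQD2 in Gy.
#' @examples
#' compute_eqd2(2, 30, 10) # 60
#' @export
compute_eqd2 <- function(d, n_frac, alpha_beta) {
  if (any(d < 0) || any(n_frac < 0)) stop_domain("d and n_frac must be nonnegative")
  if (any(alpha_beta <= 0)) stop_domain("alpha_beta must be positive")
  n_frac * d * (d + alpha_beta) / (2 + alpha_beta)
}

#' Generalized equivalent uniform dose
#'
#' The generalized mean `(sum(v_i * e_i^a))^(1/a)` of per-voxel EQD2 values
#' `e_i` with volume fractions `v_i`, using the organ-specific exponent `a`
#' (-10 for tumor, emphasizing cold spots; 1 for lung, the volume-weighted
#' mean dose).
#'
#' @param volumes Positive volume fractions summing to 1 (tolerance 1e-6).
#' @param eqd2 Per-voxel EQD2 values (Gy); must be positive when `a < 0`.
#' @param a Nonzero organ-specific exponent.
#' @return gEUD in Gy.
#' @examples
#' compute_geud(c(0.5, 0.5), c(40, 60), a = 1) # 50
#' @export
compute_geud <- function(volumes, eqd2, a) {
  if (length(volumes) != length(eqd2) || length(volumes) == 0L) {
    stop_domain("volumes and eqd2 must be nonempty vectors of equal length")
  }
  if (a == 0) stop_domain("a must be nonzero")
  if (any(volumes <= 0)) stop_domain("volume fractions must be positive")
  if (abs(sum(volumes) - 1) > 1e-6) {
    stop_domain("volume fractions must sum to 1, got ", sum(volumes))
  }
  if (any(eqd2 < 0)) stop_domain("eqd2 values must be nonnegative")
  if (a < 0 && any(eqd2 == 0)) {
    stop_domain("zero dose is undefined under a negative gEUD exponent")
  }
  sum(volumes * eqd2^a)^(1 / a)
}

#' Radiobiological parameter set
#'
#' Tissue constants of the environment: alpha/beta ratios, gEUD exponents and
#' the accrual constants `kappa` that scale the gEUD transition per
#' adaptation period.
#'
#' @param alpha_beta_tumor,alpha_beta_lung alpha/beta (Gy); defaults 10 and 4.
#' @param a_tumor,a_lung gEUD exponents; defaults -10 and 1.
#' @param kappa_tumor,kappa_lung Proportionality constants of the gEUD
#'   transition (Gy accrued per unit of `d * (1 + d / ab)` per period).
#' @return A list of class `radiobio_params`.
#' @export
radiobio_params <- function(alpha_beta_tumor = 10, alpha_beta_lung = 4,
                            a_tumor = -10, a_lung = 1,
                            kappa_tumor = 10, kappa_lung = 3) {
  if (alpha_beta_tumor <= 0 || alpha_beta_lung <= 0) {
    stop_config("alpha/beta ratios must be positive")
  }
  if (a_tumor == 0 || a_lung == 0) stop_config("gEUD exponents must be nonzero")
  structure(
    list(alpha_beta_tumor = alpha_beta_tumor, alpha_beta_lung = alpha_beta_lung,
         a_tumor = a_tumor, a_lung = a_lung,
         kappa_tumor = kappa_tumor, kappa_lung = kappa_lung),
    class = "radiobio_params"
  )
}

#' Process-driven gEUD transition
#'
#' Advances a scalar gEUD state by one adaptation period under dose `d` per
#' fraction: the accrual rate is proportional to `d * (1 + d / (alpha/beta))`,
#' so `g_next = g_prev + kappa * dt * d * (1 + d / ab)`. The update is
#' monotone nondecreasing in `d` and additive over consecutive equal-dose
#' periods.
#'
#' @param g_prev Current gEUD (Gy), nonnegative.
#' @param d Dose per fraction (Gy), nonnegative.
#' @param dt Duration of the period (adaptation periods; default 1).
#' @param params A [radiobio_params()].
#' @param tissue `"tumor"` or `"lung"`; selects alpha/beta and kappa.
#' @return Next gEUD (Gy), `>= g_prev`.
#' @export
geud_transition <- function(g_prev, d, dt = 1, params = radiobio_params(),
                            tissue = c("tumor", "lung")) {
  tissue <- match.arg(tissue)
  if (any(g_prev < 0)) stop_domain("g_prev must be nonnegative")
  if (any(d < 0)) stop_domain("d must be nonnegative")
  if (dt <= 0) stop_domain("dt must be positive")
  ab <- if (tissue == "tumor") params$alpha_beta_tumor else params$alpha_beta_lung
  kappa <- if (tissue == "tumor") params$kappa_tumor else params$kappa_lung
  g_prev + kappa * dt * d * (1 + d / ab)
}

#' Logistic outcome probability
#'
#' The generic logistic dose-response `p = 1 / (1 + exp((g - mu) / T))` on
#' the end-of-treatment gEUD `g`. With `T < 0` (the convention enforced when
#' fitting) the probability increases with `g`, so a higher delivered dose
#' raises both the chance of local control and the risk of pneumonitis.
#'
#' @param g End-of-treatment gEUD (Gy).
#' @param mu Midpoint (Gy): `p = 0.5` at `g = mu`.
#' @param t_slope Slope/temperature (Gy), nonzero.
#' @return Probability in (0, 1).
#' @examples
#' outcome_probability(70, mu = 60, t_slope = -5) # 1 / (1 + exp(-2))
#' @export
outcome_probability <- function(g, mu, t_slope) {
  if (any(t_slope == 0)) stop_domain("t_slope must be nonzero")
  if (any(!is.finite(g)) || any(!is.finite(mu))) {
    stop_domain("g and mu must be finite")
  }
  stats::plogis(-(g - mu) / t_slope)
}

#' Reward for an outcome-probability pair
#'
#' The base utility is `P+ = p_lc * (1 - p_rp2)`; a bonus is added by an
#' ordered rule over the outcome plane: +10 inside the clinically desirable
#' region (`p_lc > 0.7` and `p_rp2 < 0.172`), else +5 inside the
#' computationally desirable region (`p_lc > 0.5` and `p_rp2 < 0.5`), else
#' -1. Every point of the unit square receives exactly one reward in
#' `[-1, 11]`.
#'
#' @param p_lc,p_rp2 Probabilities in `[0, 1]` (vectorized).
#' @return Numeric reward(s).
#' @examples
#' outcome_reward(0.9, 0.1) # 10.81
#' @export
outcome_reward <- function(p_lc, p_rp2) {
  if (any(p_lc < 0 | p_lc > 1) || any(p_rp2 < 0 | p_rp2 > 1)) {
    stop_domain("outcome probabilities must lie in [0, 1]")
  }
  base <- p_lc * (1 - p_rp2)
  bonus <- ifelse(p_lc > 0.7 & p_rp2 < 0.172, 10,
                  ifelse(p_lc > 0.5 & p_rp2 < 0.5, 5, -1))
  base + bonus
}

#' Is an outcome pair in the clinically desirable region?
#'
#' @param p_lc,p_rp2 Probabilities.
#' @return Logical: `p_lc > 0.7 & p_rp2 < 0.172`.
#' @export
clinically_desirable <- function(p_lc, p_rp2) {
  p_lc > 0.7 & p_rp2 < 0.172
}
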