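#' T-cell acid inactivation probability
#'
#' Logistic in local pH with half-max `H_p` and steepness `sigma_p`:
#' `P_AI = 1 / (1 + exp(sigma_p * (pH - H_p)))`. Monotone decreasing in pH;
#' approaches 1 in deep acid and 0 at physiological pH.
#'
#' @param pH Local pH (finite).
#' @param H_p Half-max pH (default 6.6).
#' @param sigma_p Steepness (default 6).
#' @return `P_AI` in \[0, 1\], vectorized.
#' @export
acid_inactivation_prob <- function(pH, H_p = 6.6, sigma_p = 6) {
  1 / (1 + exp(sigma_p * (pH - H_p)))
}

#' T-cell engagement duration
#'
#' `d_e * (1 + 1/(1 + exp(sigma_e * (pH - H_e))))`: the baseline engagement
#' time `d_e` at physiological pH, rising to twice that in deep acid, half-way
#' elevated at the half-max pH `H_e`.
#'
#' @param pH Local pH (finite).
#' @param d_e Baseline engagement duration (days).
#' @param H_e Half-max pH.
#' @param sigma_e Steepness.
#' @return Engagement duration in days, vectorized.
#' @export
engagement_duration <- function(pH, d_e = 0.042, H_e = 6.6, sigma_e = 4) {
  d_e * (1 + 1 / (1 + exp(sigma_e * (pH - H_e))))
}

#' Probability a T-cell kill succeeds
#'
#' Linear in effective (drug-unbound) PD-L1, clamped to \[0, 1\]:
#' `P_k = 1 - p_P_eff / p_P_max`. A cell at maximal PD-L1 expression is never
#' killed; a fully drug-blocked cell is always killed.
#'
#' @param p_P_eff Effective PD-L1 expression (>= 0).
#' @param p_P_max Maximal PD-L1 expression (default 5).
#' @return `P_k` in \[0, 1\], vectorized.
#' @export
kill_probability <- function(p_P_eff, p_P_max = 5) {
  stopifnot(all(p_P_eff >= 0))
  pmin(pmax(1 - p_P_eff / p_P_max, 0), 1)
}

#' T-cell survival versus local glucose
#'
#' Log-linear in glucose below blood level: `S(g) = L_i + L_g * log10(G_0/g)`,
#' clamped to the floor `L_0` and capped at `L_i` for `g >= G_0`. The floor of
#' the argument avoids a log of zero.
#'
#' @param g Local glucose (mmol/L, >= 0).
#' @param L_i Survival (percent) at blood glucose.
#' @param L_0 Survival floor (percent).
#' @param L_g Change in survival per decade of glucose (negative).
#' @param G_0 Blood glucose (mmol/L).
#' @param g_floor Glucose floor inside the log.
#' @return Survival percentage in `[L_0, L_i]`, vectorized, monotone
#'   non-decreasing in `g`.
#' @export
glucose_survival <- function(g, L_i = 65.35, L_0 = 21.78, L_g = -16.67,
                             G_0 = 5, g_floor = 1e-4) {
  stopifnot(all(g >= 0), L_0 < L_i, L_g < 0)
  s <- L_i + L_g * log10(G_0 / pmax(g, g_floor))
  pmin(pmax(s, L_0), L_i)
}

#' Glucose-scaled T-cell death rate
#'
#' The baseline per-day decay `1/beta_T` of a non-activated T-cell, scaled by
#' relative non-survival `(1 - S(g)/100) / (1 - L_i/100)`: exactly the
#' baseline at blood glucose and about 2.26x the baseline as glucose vanishes
#' (with the published survival parameters).
#'
#' @param g Local glucose (mmol/L).
#' @param cfg An [sim_config()].
#' @return Per-day death rate, vectorized.
#' @export
tcell_death_rate <- function(g, cfg) {
  s <- glucose_survival(g, cfg$L_i, cfg$L_0, cfg$L_g, cfg$G_0, cfg$g_floor)
  (1 / cfg$beta_T) * (1 - s / 100) / (1 - cfg$L_i / 100)
}

#' Recruit T-cells at vessel sites
#'
#' After the response delay `tau_T`, `Poisson(alpha_T * n_tumor * dt)` recruits
#' arrive per step and enter at uniformly chosen vessel sites that are free of
#' cells and other T-cells. Recruits that cannot be placed (no vessels, or all
#' vessel sites occupied) are deferred, not dropped.
#'
#' @param n_tumor Current tumor-cell count.
#' @param t Current time (days, >= 0).
#' @param free_vessel_sites Integer sites of vessels available for entry.
#' @param cfg An [sim_config()].
#' @param dt Timestep (days).
#' @param carried Recruits deferred from earlier steps.
#' @return A list: `sites` (entry sites of the new T-cells) and `deferred`
#'   (recruits carried to the next step).
#' @export
recruit_tcells <- function(n_tumor, t, free_vessel_sites, cfg, dt,
                           carried = 0L) {
  stopifnot(t >= 0)
  n_new <- 0L
  if (t >= cfg$tau_T && cfg$alpha_T > 0 && n_tumor > 0) {
    n_new <- stats::rpois(1L, cfg$alpha_T * n_tumor * dt)
  }
  pending <- carried + n_new
  if (pending == 0L) return(list(sites = integer(), deferred = 0L))
  k <- min(pending, length(free_vessel_sites))
  sites <- if (k > 0L) {
    as.integer(sample(as.character(free_vessel_sites), k))
  } else integer()
  list(sites = sites, deferred = pending - k)
}

#' Convenience immune-susceptibility score
#'
#' A display-level summary of how killable a tumor cell currently is:
#' the probability an approaching T-cell both escapes acid inactivation and
#' succeeds in its kill, `(1 - P_AI(pH)) * P_k(p_P_eff)`. This is a derived
#' convenience layer for map overlays, not one of the seven metaphenotype
#' expressions.
#'
#' @param pH Local pH.
#' @param p_P_eff Effective PD-L1 expression.
#' @param H_p,sigma_p Acid-inactivation curve parameters.
#' @param p_P_max Maximal PD-L1 expression.
#' @return Susceptibility in \[0, 1\], vectorized.
#' @export
immune_susceptibility <- function(pH, p_P_eff, H_p = 6.6, sigma_p = 6,
                                  p_P_max = 5) {
  (1 - acid_inactivation_prob(pH, H_p, sigma_p)) *
    kill_probability(p_P_eff, p_P_max)
}
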