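#' Metabolism parameters
#'
#' Bundles the metabolic constants and derives `A_0`, the baseline ATP
#' production rate of a metabolically normal cell (`p_G = 1`) under blood
#' conditions. `A_0 = (29/5) * V_O`: one glucose yields 2 ATP glycolytically
#' and 27 oxidatively while consuming 5 O2-equivalents, so a fully fueled
#' normal cell producing ATP at the oxidative optimum runs at 29/5 ATP per
#' unit of maximal oxygen consumption. The realized ATP rate at blood
#' conditions equals `A_0` up to the (tiny) glucose half-saturation correction.
#'
#' @param cfg An [sim_config()].
#' @return A list with `V_O`, `k_O`, `k_G`, `k_H`, `ox_yield` (= 27/5) and
#'   `A_0`.
#' @export
metabolism_params <- function(cfg) {
  list(V_O = cfg$V_O, k_O = cfg$k_O, k_G = cfg$k_G, k_H = cfg$k_H,
       ox_yield = 27 / 5, A_0 = (29 / 5) * cfg$V_O)
}

#' Cellular metabolic fluxes
#'
#' Oxygen consumption is Michaelis-Menten in local oxygen; glucose uptake
#' meets the cell's `p_G`-scaled ATP demand net of the oxidative yield
#' (2 ATP per glucose glycolytically, 27/5 ATP per O2-equivalent oxidatively);
#' proton production is proportional to glycolytic flux via the buffering
#' coefficient `k_H`. All arguments are vectorized over cells.
#'
#' @param p_G Glycolytic phenotype multiplier (>= 1; 1 = metabolically normal).
#' @param O,G Local oxygen and glucose (mmol/L, >= 0).
#' @param params A [metabolism_params()] list.
#' @return A tibble with columns `f_O` (oxygen consumption, mmol/L/s), `f_G`
#'   (glucose consumption), `f_A` (ATP production rate), `f_H` (proton
#'   production flux); all non-negative.
#' @export
metabolize <- function(p_G, O, G, params) {
  stopifnot(all(O >= 0), all(G >= 0), all(p_G >= 0))
  f_O <- params$V_O * O / (O + params$k_O)
  f_G <- pmax(0, (p_G * params$A_0 - params$ox_yield * f_O) / 2) *
    G / (G + params$k_G)
  f_A <- 2 * f_G + params$ox_yield * f_O
  f_H <- params$k_H * f_G
  tibble::tibble(f_O = f_O, f_G = f_G, f_A = f_A, f_H = f_H)
}

#' ATP- and acid-gated cell fate
#'
#' Poor conditions are an ATP rate below the death fraction `A_d` of baseline
#' or a local pH below the cell's acid-resistance threshold; cells in poor
#' conditions die with per-day probability `p_delta` (compounded for sub-day
#' steps). Survivors are quiescent when the ATP fraction lies in
#' `[A_d, A_q)` and proliferating otherwise. Normal cells additionally die at
#' the baseline rate `p_D` per day. Vectorized over cells; consumes one
#' uniform draw per cell per hazard from the active RNG stream.
#'
#' @param f_A_ratio ATP rate as a fraction of the normoxic baseline `A_0`.
#' @param pH_local Local pH at the cell's site.
#' @param acid_threshold The cell's acid-resistance threshold `p_H`.
#' @param is_normal Logical; normal (non-tumor) cells get the baseline hazard.
#' @param dt Timestep (days, > 0).
#' @param cfg An [sim_config()].
#' @return A character vector: `"die"`, `"quiescent"`, or `"proliferate"`.
#' @export
update_fate <- function(f_A_ratio, pH_local, acid_threshold, is_normal,
                        dt, cfg) {
  stopifnot(dt > 0)
  n <- length(f_A_ratio)
  poor <- f_A_ratio < cfg$A_d | pH_local < acid_threshold
  p_die <- ifelse(poor, 1 - (1 - cfg$p_delta)^dt, 0)
  dies <- stats::runif(n) < p_die
  base <- is_normal & (stats::runif(n) < 1 - (1 - cfg$p_D)^dt)
  dies <- dies | base
  out <- ifelse(f_A_ratio < cfg$A_q, "quiescent", "proliferate")
  out[dies] <- "die"
  out
}

#' Heritable phenotype drift at division
#'
#' Each trait of a daughter cell independently shifts by `+delta`, `-delta`,
#' or `0` with equal probability and is clamped to its admissible interval:
#' glycolysis to `[1, p_G_max]`, acid resistance to `[p_H_min, p_H_norm]`,
#' PD-L1 to `[p_P_norm, p_P_min]`. Vectorized over daughters.
#'
#' @param p_G,p_H,p_P Parent phenotypes.
#' @param cfg An [sim_config()].
#' @return A tibble with drifted, clamped `p_G`, `p_H`, `p_P`.
#' @export
inherit_phenotypes <- function(p_G, p_H, p_P, cfg) {
  n <- length(p_G)
  step3 <- function(n) sample(c(-1, 0, 1), n, replace = TRUE)
  tibble::tibble(
    p_G = pmin(pmax(p_G + step3(n) * cfg$delta_G, 1), cfg$p_G_max),
    p_H = pmin(pmax(p_H + step3(n) * cfg$delta_H, cfg$p_H_min), cfg$p_H_norm),
    p_P = pmin(pmax(p_P + step3(n) * cfg$delta_P, cfg$p_P_norm), cfg$p_P_min))
}

#' Necrotic debris turnover
#'
#' Necrotic cells are removed with probability `1 - (1 - p_n)^dt`, freeing
#' their site. With the default `p_n = 5e-4` the expected debris lifetime
#' (~2000 days) far exceeds simulated horizons, so necrosis occupies space on
#' simulation timescales.
#'
#' @param n Number of necrotic cells.
#' @param dt Timestep (days).
#' @param cfg An [sim_config()].
#' @return A logical vector: `TRUE` where the debris is removed this step.
#' @export
necrotic_turnover <- function(n, dt, cfg) {
  stats::runif(n) < 1 - (1 - cfg$p_n)^dt
}
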