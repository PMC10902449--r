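#' Advance the anti-PD-L1 drug field
#'
#' While the anti-PD-L1 window is active, vessel sites are held at the source
#' concentration and the field is relaxed to its quasi-steady diffusion/decay
#' profile (the drug equilibrates much faster than cellular events). Outside
#' the window the field undergoes pure first-order decay at `gamma_A` per day,
#' so total drug mass decays exactly exponentially once the source is off.
#'
#' @param drug Current drug concentration matrix.
#' @param vessel_sites Integer column-major vessel site indices.
#' @param active Is the anti-PD-L1 window active at the current time?
#' @param cfg An [sim_config()].
#' @param dt Timestep (days, > 0).
#' @return The updated drug matrix (non-negative everywhere).
#' @export
step_antipdl1_field <- function(drug, vessel_sites, active, cfg, dt) {
  stopifnot(dt > 0)
  if (active && length(vessel_sites)) {
    out <- solve_field(drug, cfg$D_A, cfg$dx, vessel_sites,
                       cfg$treatment$anti_pdl1$source,
                       decay = cfg$gamma_A / 86400, # per-day -> per-second
                       settings = cfg$solver)
    out$field
  } else {
    drug * exp(-cfg$gamma_A * dt)
  }
}

#' Update drug-bound PD-L1 on a cell
#'
#' Bound PD-L1 `b` relaxes toward the saturating occupancy target
#' `p_P * A/(A + K_A)` at the fast binding rate `k_on` while drug is present,
#' and decays at `gamma_P` per day in drug-free medium. The effective PD-L1
#' feeding [kill_probability()] is `p_P_eff = max(p_P - b, 0)`.
#'
#' @param b Current bound level (>= 0), vectorized over cells.
#' @param p_P PD-L1 phenotype of each cell.
#' @param A Local drug concentration at each cell's site (>= 0).
#' @param cfg An [sim_config()].
#' @param dt Timestep (days).
#' @return A tibble with updated `bound` and `p_P_eff`.
#' @export
update_bound_pdl1 <- function(b, p_P, A, cfg, dt) {
  stopifnot(all(A >= 0))
  n <- max(length(b), length(p_P), length(A))
  b <- rep_len(b, n); p_P <- rep_len(p_P, n); A <- rep_len(A, n)
  target <- p_P * A / (A + cfg$K_A)
  present <- A > 0
  b_new <- b * exp(-cfg$gamma_P * dt)
  b_new[present] <- b[present] +
    (target[present] - b[present]) * (1 - exp(-cfg$k_on * dt))
  b_new <- pmax(b_new, 0)
  tibble::tibble(bound = b_new, p_P_eff = pmax(p_P - b_new, 0))
}

antipdl1_active <- function(schedule, t) {
  a <- schedule$anti_pdl1
  a$on && t >= a$start && t < a$end
}
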