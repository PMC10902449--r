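#' Solver settings for the steady-state field solver
#'
#' @param tolerance Relative-change convergence threshold per sweep
#'   (dimensionless, > 0).
#' @param max_iterations Maximum red-black sweeps (>= 1).
#' @param tracking_sweeps Sweep cap used for the warm-started in-loop solves
#'   of [run_simulation()]: each step relaxes the fields toward the current
#'   steady state by at most this many sweeps (they converge long before the
#'   cap whenever the cell configuration has settled). Standalone solves are
#'   unaffected and always iterate to tolerance.
#' @param omega Over-relaxation factor in (0, 2).
#' @param boundary Domain-edge condition tag; only `"zero-flux"` is supported
#'   (the tumor is embedded in tissue with no external reservoir).
#' @return A list of class `mp_solver_settings`.
#' @export
solver_settings <- function(tolerance = 3e-6, max_iterations = 20000,
                            omega = 1.82, tracking_sweeps = 40,
                            boundary = "zero-flux") {
  stopifnot(is.numeric(tolerance), tolerance > 0,
            max_iterations >= 1, tracking_sweeps >= 1, omega > 0, omega < 2)
  if (!identical(boundary, "zero-flux")) {
    stop("unsupported boundary condition: ", boundary)
  }
  structure(list(tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 tracking_sweeps = as.integer(tracking_sweeps),
                 omega = omega, boundary = boundary),
            class = "mp_solver_settings")
}

#' Treatment schedule for anti-PD-L1 and buffer therapy
#'
#' Two independent treatment windows: a diffusible anti-PD-L1 antibody released
#' from vessel sites, and a systemic pH buffer that scales every cell's proton
#' output by `(1 - B)`.
#'
#' @param anti_pdl1_on,buffer_on Logical flags enabling each arm.
#' @param anti_pdl1_start,anti_pdl1_end Anti-PD-L1 window (days, start < end).
#' @param anti_pdl1_source Drug concentration held at vessel sites while the
#'   window is active (arbitrary concentration units; the binding half-max
#'   `K_A` shares them).
#' @param buffer_start,buffer_end Buffer window (days, start < end).
#' @param buffer_B Buffer level B in \[0, 1\] during the window.
#' @return A list of class `mp_schedule`.
#' @export
treatment_schedule <- function(anti_pdl1_on = FALSE,
                               anti_pdl1_start = 100, anti_pdl1_end = 160,
                               anti_pdl1_source = 1,
                               buffer_on = FALSE,
                               buffer_start = 100, buffer_end = 160,
                               buffer_B = 0.8) {
  stopifnot(anti_pdl1_start < anti_pdl1_end, buffer_start < buffer_end,
            buffer_B >= 0, buffer_B <= 1, anti_pdl1_source >= 0)
  structure(list(
    anti_pdl1 = list(on = isTRUE(anti_pdl1_on), start = anti_pdl1_start,
                     end = anti_pdl1_end, source = anti_pdl1_source),
    buffer = list(on = isTRUE(buffer_on), start = buffer_start,
                  end = buffer_end, B = buffer_B)),
    class = "mp_schedule")
}

#' Instantaneous systemic buffer level B(t)
#'
#' @param schedule An [treatment_schedule()] object.
#' @param t Time in days.
#' @return B in \[0, 1\]: the configured level inside the buffer window, 0
#'   outside or when the buffer arm is off.
#' @export
buffer_level <- function(schedule, t) {
  b <- schedule$buffer
  ifelse(b$on & t >= b$start & t < b$end, b$B, 0)
}

# Printed parameter ranges; values outside are rejected at construction.
.mp_ranges <- list(
  nu_mean = c(5, 100), p_ang = c(0, 1), delta_P = c(0, 1)
)

#' Simulation configuration
#'
#' Single source of truth for every model parameter plus run controls. Defaults
#' are the published parameterization of the metabolism/immune hybrid model;
#' rates are per day unless noted, diffusion coefficients in um^2/s,
#' concentrations in mmol/L (protons in mol/L, reported as pH), lengths in um.
#'
#' @param grid_width,grid_height Lattice size in sites (site side `dx` um).
#' @param dx Lattice spacing (um).
#' @param duration Simulated days.
#' @param dt Cell-scale timestep (days); must not exceed the T-cell engagement
#'   duration `d_e` so engagements resolve on the step grid.
#' @param record_every Recording interval (days).
#' @param field_solve_every Re-solve the diffusible fields every this many
#'   cell steps (default 1, i.e. every step). The fields equilibrate in
#'   seconds while cell events unfold over hours, so a coarser cadence also
#'   tracks the quasi-steady state; the default keeps the fields exactly in
#'   step with the cells.
#' @param seed Integer RNG seed; every stochastic element draws from this one
#'   stream.
#' @param p_D Normal-tissue baseline death rate (1/d).
#' @param p_delta Death probability per day in poor conditions (ATP below the
#'   death threshold or pH below the cell's acid-resistance threshold).
#' @param p_n Necrotic turnover rate (1/d).
#' @param D_O,D_g,D_H Diffusion coefficients of oxygen, glucose, protons
#'   (um^2/s).
#' @param O_0,G_0,pH_0 Blood oxygen (mmol/L), glucose (mmol/L) and pH, held at
#'   vessel sites.
#' @param V_O Maximal oxygen consumption (mmol/L/s).
#' @param k_O,k_G Half-max oxygen/glucose concentrations (mmol/L).
#' @param k_H Proton buffering coefficient converting glycolytic flux to proton
#'   source.
#' @param A_d,A_q ATP fractions (of the normoxic baseline) below which a cell
#'   dies / becomes quiescent.
#' @param p_H_min,p_H_norm Maximal and normal acid-resistance thresholds (pH).
#' @param delta_H,delta_G,delta_P Per-division phenotype drift magnitudes for
#'   acid resistance, glycolysis, PD-L1.
#' @param p_G_max Maximal glycolytic phenotype multiplier.
#' @param tau_min Minimum cell-cycle time (days).
#' @param p_P_min,p_P_norm Maximal and normal PD-L1 phenotype (the symbol
#'   `p_P_min` follows the published table; it is the *maximal* expression).
#' @param sigma_min,sigma_mean Minimum / mean vessel spacing (um).
#' @param nu_mean Vessel stability: mean days before collapse, in \[5, 100\].
#' @param p_ang Angiogenesis (renewal) rate in \[0, 1\]: expected number of
#'   new vessels sprouting per day at hypoxic sites while hypoxia persists
#'   (see [update_vessels()]).
#' @param T_M Probability a free T-cell moves each step.
#' @param tau_T T-cell response delay (days).
#' @param alpha_T T-cell recruitment rate (recruits per tumor cell per day);
#'   0 or within \[1e-4, 1e-1\].
#' @param beta_T Non-activated T-cell mean lifespan at blood glucose (days).
#' @param d_e,H_e,sigma_e T-cell engagement duration (days), its pH half-max
#'   and steepness.
#' @param H_p,sigma_p Half-max pH and steepness of T-cell acid inactivation.
#' @param L_i,L_0,L_g T-cell survival (percent) at blood glucose, its floor,
#'   and the change per decade of glucose (negative).
#' @param inactivation_permanent If `TRUE` (default) acid-inactivated T-cells
#'   never recover; set `FALSE` to let them re-test on later contacts.
#' @param D_A Anti-PD-L1 diffusion coefficient (um^2/s).
#' @param gamma_A Anti-PD-L1 natural decay rate (1/d).
#' @param gamma_P Bound-PD-L1 decay rate in drug-free medium (1/d).
#' @param K_A Binding half-saturation of the drug-occupancy target (drug
#'   concentration units).
#' @param k_on Rate (1/d) at which bound PD-L1 relaxes toward its occupancy
#'   target while drug is present (fast binding).
#' @param proton_yield Conversion from glycolytic proton flux (`f_H`,
#'   mmol/L/s units) to the molar proton source of the pH field (mol/L/s per
#'   unit `f_H`). Together with the clearance rates it sets the absolute pH
#'   scale; calibrated so avascular tissue patches acidify to the published
#'   tumor range while perfused tissue holds blood pH.
#' @param proton_clearance Background tissue buffering/washout rate (1/s)
#'   returning protons toward blood pH far from vessels.
#' @param proton_clearance_peri Perivascular clearance rate (1/s) applied
#'   within `peri_radius` sites of a vessel, where perfusion removes acid
#'   efficiently.
#' @param peri_radius Chebyshev radius (sites) of the perivascular clearance
#'   shell around each vessel.
#' @param g_floor Glucose floor (mmol/L) used inside the log of the T-cell
#'   glucose-survival curve.
#' @param T_w Interaction-memory window (days) of the tumor-immune interaction
#'   grid.
#' @param normal_regrowth Homeostatic regrowth rate of normal tissue (1/d):
#'   probability per day that a normal cell with an empty Moore neighbor
#'   divides into it, maintaining the tissue against baseline turnover.
#' @param init_tumor_radius Radius (sites) of the initial central tumor disc.
#' @param treatment A [treatment_schedule()].
#' @param solver A [solver_settings()].
#' @return A validated list of class `mp_config`.
#' @export
sim_config <- function(grid_width = 100, grid_height = 100, dx = 20,
                       duration = 150, dt = 1 / 24, record_every = 1,
                       field_solve_every = 1L,
                       seed = 1L,
                       p_D = 0.005, p_delta = 0.7, p_n = 5e-4,
                       D_O = 1820, D_g = 500, D_H = 1080,
                       O_0 = 0.0556, G_0 = 5, pH_0 = 7.4,
                       V_O = 0.012, k_O = 0.005, k_G = 0.04, k_H = 2.5e-4,
                       A_d = 0.35, A_q = 0.8,
                       p_H_min = 6.1, p_H_norm = 6.65, delta_H = 0.003,
                       p_G_max = 50, delta_G = 0.15,
                       tau_min = 0.95,
                       p_P_min = 5, p_P_norm = 2.7, delta_P = 0.1,
                       sigma_min = 80, sigma_mean = 150,
                       nu_mean = 20, p_ang = 0.9,
                       T_M = 1, tau_T = 4, alpha_T = 0, beta_T = 10,
                       d_e = 0.042, H_e = 6.6, sigma_e = 4,
                       H_p = 6.6, sigma_p = 6,
                       L_i = 65.35, L_0 = 21.78, L_g = -16.67,
                       inactivation_permanent = TRUE,
                       D_A = 100, gamma_A = 0.5, gamma_P = 0.001,
                       K_A = 0.1, k_on = 100,
                       proton_yield = 0.005,
                       proton_clearance = 0.002, proton_clearance_peri = 0.05,
                       peri_radius = 2L, g_floor = 1e-4,
                       T_w = 1,
                       normal_regrowth = 0.1,
                       init_tumor_radius = 5,
                       treatment = treatment_schedule(),
                       solver = solver_settings()) {
  cfg <- structure(list(
    grid_width = as.integer(grid_width), grid_height = as.integer(grid_height),
    dx = dx, duration = duration, dt = dt, record_every = record_every,
    field_solve_every = as.integer(field_solve_every),
    seed = as.integer(seed),
    p_D = p_D, p_delta = p_delta, p_n = p_n,
    D_O = D_O, D_g = D_g, D_H = D_H,
    O_0 = O_0, G_0 = G_0, pH_0 = pH_0,
    V_O = V_O, k_O = k_O, k_G = k_G, k_H = k_H,
    A_d = A_d, A_q = A_q,
    p_H_min = p_H_min, p_H_norm = p_H_norm, delta_H = delta_H,
    p_G_max = p_G_max, delta_G = delta_G,
    tau_min = tau_min,
    p_P_min = p_P_min, p_P_norm = p_P_norm, delta_P = delta_P,
    sigma_min = sigma_min, sigma_mean = sigma_mean,
    nu_mean = nu_mean, p_ang = p_ang,
    T_M = T_M, tau_T = tau_T, alpha_T = alpha_T, beta_T = beta_T,
    d_e = d_e, H_e = H_e, sigma_e = sigma_e,
    H_p = H_p, sigma_p = sigma_p,
    L_i = L_i, L_0 = L_0, L_g = L_g,
    inactivation_permanent = isTRUE(inactivation_permanent),
    D_A = D_A, gamma_A = gamma_A, gamma_P = gamma_P,
    K_A = K_A, k_on = k_on,
    proton_yield = proton_yield,
    proton_clearance = proton_clearance,
    proton_clearance_peri = proton_clearance_peri,
    peri_radius = as.integer(peri_radius), g_floor = g_floor,
    T_w = T_w,
    normal_regrowth = normal_regrowth,
    init_tumor_radius = as.integer(init_tumor_radius),
    treatment = treatment, solver = solver),
    class = "mp_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks every field against its admissible range (including the published
#' sweep ranges for vessel stability, renewal, recruitment, and PD-L1 drift)
#' and reports all violations at once.
#'
#' @param cfg An `mp_config`.
#' @return `cfg`, invisibly; errors with a field-by-field report otherwise.
#' @export
validate_sim_config <- function(cfg) {
  bad <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(cfg$grid_width >= 3 && cfg$grid_height >= 3, "grid must be at least 3x3")
  chk(cfg$dx > 0, "dx must be positive")
  chk(cfg$duration >= 0, "duration must be >= 0")
  chk(cfg$dt > 0, "dt must be positive")
  chk(cfg$field_solve_every >= 1, "field_solve_every must be >= 1")
  chk(cfg$dt <= cfg$d_e + 1e-12,
      sprintf("dt (%g) must not exceed the engagement duration d_e (%g)",
              cfg$dt, cfg$d_e))
  for (nm in c("p_D", "p_delta", "p_n", "T_M")) {
    chk(cfg[[nm]] >= 0 && cfg[[nm]] <= 1, paste(nm, "must lie in [0, 1]"))
  }
  for (nm in c("D_O", "D_g", "D_H", "O_0", "G_0", "V_O", "k_O", "k_G",
               "k_H", "tau_min", "sigma_min", "sigma_mean", "beta_T", "d_e",
               "D_A", "K_A", "k_on", "proton_yield", "proton_clearance",
               "proton_clearance_peri", "peri_radius", "g_floor", "T_w")) {
    chk(cfg[[nm]] > 0, paste(nm, "must be positive"))
  }
  for (nm in c("gamma_A", "gamma_P", "tau_T", "delta_H", "delta_G",
               "normal_regrowth")) {
    chk(cfg[[nm]] >= 0, paste(nm, "must be >= 0"))
  }
  chk(cfg$A_d > 0 && cfg$A_d < cfg$A_q && cfg$A_q <= 1,
      "need 0 < A_d < A_q <= 1")
  chk(cfg$p_H_min < cfg$p_H_norm, "need p_H_min < p_H_norm")
  chk(cfg$p_G_max >= 1, "p_G_max must be >= 1")
  chk(cfg$p_P_norm <= cfg$p_P_min, "need p_P_norm <= p_P_min")
  chk(cfg$sigma_min < cfg$sigma_mean, "need sigma_min < sigma_mean")
  for (nm in names(.mp_ranges)) {
    r <- .mp_ranges[[nm]]
    chk(cfg[[nm]] >= r[1] && cfg[[nm]] <= r[2],
        sprintf("%s = %g outside printed range [%g, %g]", nm, cfg[[nm]],
                r[1], r[2]))
  }
  chk(cfg$alpha_T == 0 || (cfg$alpha_T >= 1e-4 && cfg$alpha_T <= 1e-1),
      "alpha_T must be 0 or within [1e-4, 1e-1]")
  chk(cfg$L_0 < cfg$L_i, "need L_0 < L_i")
  chk(cfg$L_g < 0, "L_g must be negative")
  chk(inherits(cfg$treatment, "mp_schedule"), "treatment must be a schedule")
  chk(inherits(cfg$solver, "mp_solver_settings"),
      "solver must be solver_settings()")
  if (length(bad)) {
    stop("invalid simulation configuration:\n  - ",
         paste(bad, collapse = "\n  - "), call. = FALSE)
  }
  invisible(cfg)
}

#' Write / read a configuration as YAML
#'
#' Configurations round-trip losslessly: `read_sim_config(write_sim_config(x))`
#' reproduces every numeric field exactly (values are serialized at full
#' precision).
#'
#' @param cfg An `mp_config`.
#' @param path File path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a validated `mp_config`.
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$treatment <- unclass(x$treatment)
  x$solver <- unclass(x$solver)
  # full-precision doubles so the round trip is bit exact
  writeLines(yaml::as.yaml(x, precision = 22), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  tr <- x$treatment; so <- x$solver
  x$treatment <- NULL; x$solver <- NULL
  cfg <- do.call(sim_config, c(x, list(
    treatment = treatment_schedule(
      anti_pdl1_on = tr$anti_pdl1$on, anti_pdl1_start = tr$anti_pdl1$start,
      anti_pdl1_end = tr$anti_pdl1$end, anti_pdl1_source = tr$anti_pdl1$source,
      buffer_on = tr$buffer$on, buffer_start = tr$buffer$start,
      buffer_end = tr$buffer$end, buffer_B = tr$buffer$B),
    solver = solver_settings(tolerance = so$tolerance,
                             max_iterations = so$max_iterations,
                             omega = so$omega,
                             tracking_sweeps = so$tracking_sweeps,
                             boundary = so$boundary))))
  cfg
}

#' @export
print.mp_config <- function(x, ...) {
  cat("<mp_config> ", x$grid_width, "x", x$grid_height,
      " lattice (", x$dx, " um sites), ", x$duration, " days, dt = ",
      signif(x$dt, 3), " d, seed = ", x$seed, "\n", sep = "")
  cat("  vasculature: nu_mean = ", x$nu_mean, " d, p_ang = ", x$p_ang,
      "; immune: alpha_T = ", x$alpha_T, "\n", sep = "")
  tr <- x$treatment
  arms <- c(if (tr$anti_pdl1$on) sprintf("anti-PD-L1 [%g, %g)",
                                         tr$anti_pdl1$start, tr$anti_pdl1$end),
            if (tr$buffer$on) sprintf("buffer B = %g [%g, %g)", tr$buffer$B,
                                      tr$buffer$start, tr$buffer$end))
  cat("  treatment: ", if (length(arms)) paste(arms, collapse = " + ")
      else "none", "\n", sep = "")
  invisible(x)
}
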