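#' Create a field set
#'
#' Gridded oxygen, glucose, proton, and anti-PD-L1 concentrations on the
#' `grid_width` x `grid_height` lattice, initialized at blood values (drug at
#' zero). Oxygen and glucose are in mmol/L; protons in mol/L (report with
#' [pH_of()]).
#'
#' @param cfg An [sim_config()].
#' @return A list of class `mp_fields` with matrices `oxygen`, `glucose`,
#'   `protons`, `drug`.
#' @export
make_fields <- function(cfg) {
  nx <- cfg$grid_width; ny <- cfg$grid_height
  structure(list(
    oxygen  = matrix(cfg$O_0, nx, ny),
    glucose = matrix(cfg$G_0, nx, ny),
    protons = matrix(protons_of(cfg$pH_0), nx, ny),
    drug    = matrix(0, nx, ny)),
    class = "mp_fields")
}

#' Convert between proton concentration and pH
#'
#' @param protons Proton concentration (mol/L, > 0).
#' @param pH pH value.
#' @return `pH_of` returns `-log10(protons)`; `protons_of` its inverse.
#' @export
pH_of <- function(protons) {
  if (any(protons <= 0)) stop("proton concentration must be positive")
  -log10(protons)
}

#' @rdname pH_of
#' @export
protons_of <- function(pH) 10^(-pH)

#' Per-cell proton source under buffer therapy
#'
#' The proton output of a glycolytic cell, `f_H`, is scaled down by the
#' systemic buffer level: `p_R = f_H * (1 - B)`.
#'
#' @param f_H Proton production flux of the cell (>= 0).
#' @param B Buffer level in \[0, 1\].
#' @return The effective per-site proton source `p_R`.
#' @export
proton_source_rate <- function(f_H, B) {
  if (any(B < 0 | B > 1)) stop("buffer level B must lie in [0, 1]")
  if (any(f_H < 0)) stop("f_H must be >= 0")
  f_H * (1 - B)
}

#' Solve one reaction-diffusion field to steady state
#'
#' Solves `D lap(C) - decay*C - vmax*C/(C + km) + source = 0` on the lattice
#' with zero-flux edges and Dirichlet values at vessel sites, by red-black
#' successive over-relaxation with the Michaelis-Menten denominator lagged.
#' The input field is used as the starting guess and is not modified.
#'
#' @param field Starting matrix (also sets the grid shape).
#' @param D Diffusion coefficient (um^2/s).
#' @param dx Lattice spacing (um).
#' @param vessel_sites Integer column-major site indices held at `dirichlet`.
#' @param dirichlet Concentration at vessel sites.
#' @param decay Per-site linear decay rate (1/s); scalar or length-n vector.
#' @param source Per-site source (concentration/s); scalar or vector.
#' @param vmax Per-site Michaelis-Menten maximal sink rate; scalar or vector.
#' @param km Michaelis-Menten half-max concentration (scalar).
#' @param settings A [solver_settings()].
#' @param strict If `TRUE` (default), non-convergence within `max_iterations`
#'   is an error carrying the residual. `FALSE` enables tracking mode: the
#'   relaxed field is returned after at most `max_iterations` sweeps, the
#'   warm-started quasi-steady-state tracking used inside the simulation
#'   loop.
#' @return A list: `field` (solved matrix), `iterations`, `residual`,
#'   `converged`.
#' @export
solve_field <- function(field, D, dx, vessel_sites = integer(),
                        dirichlet = 0, decay = 0, source = 0,
                        vmax = 0, km = 1,
                        settings = solver_settings(), strict = TRUE) {
  n <- length(field)
  expand <- function(v) if (length(v) == 1L) rep(v, n) else {
    stopifnot(length(v) == n); as.numeric(v)
  }
  decay <- expand(decay); source <- expand(source); vmax <- expand(vmax)
  if (any(!is.finite(decay)) || any(!is.finite(source)) ||
      any(!is.finite(vmax))) {
    stop("sink/source rates must be finite")
  }
  vs <- as.integer(vessel_sites)
  if (length(vs) && (min(vs) < 1L || max(vs) > n)) {
    stop("vessel sites outside the grid")
  }
  out <- solve_rd_cpp(field, D, dx, vs, dirichlet, decay, source, vmax, km,
                      settings$tolerance, settings$max_iterations,
                      settings$omega)
  if (strict && !out$converged) {
    stop(sprintf(
      "field solver did not converge in %d iterations (residual %.3g)",
      settings$max_iterations, out$residual))
  }
  out[c("field", "iterations", "residual", "converged")]
}

#' Perivascular proton-clearance map
#'
#' Acid is cleared efficiently only where perfusion reaches: sites within
#' `peri_radius` (Chebyshev) of a vessel get the perivascular rate, all other
#' tissue the small background buffering rate. The contrast between the two
#' is what lets avascular patches acidify while perfused tissue holds blood
#' pH.
#'
#' @param vessel_sites Integer column-major vessel sites.
#' @param cfg An [sim_config()].
#' @return A numeric vector of per-site clearance rates (1/s).
#' @export
proton_clearance_field <- function(vessel_sites, cfg) {
  nx <- cfg$grid_width; ny <- cfg$grid_height
  lam <- rep(cfg$proton_clearance, nx * ny)
  nv <- length(vessel_sites)
  if (nv) {
    r <- cfg$peri_radius
    vx <- ((vessel_sites - 1L) %% nx) + 1L
    vy <- ((vessel_sites - 1L) %/% nx) + 1L
    off <- as.matrix(expand.grid(dx = -r:r, dy = -r:r))
    px <- rep(vx, each = nrow(off)) + off[, 1]
    py <- rep(vy, each = nrow(off)) + off[, 2]
    ok <- px >= 1L & px <= nx & py >= 1L & py <= ny
    lam[px[ok] + (py[ok] - 1L) * nx] <- cfg$proton_clearance_peri
  }
  lam
}

#' Solve all diffusible fields to steady state
#'
#' Quasi-steady-state treatment: diffusion equilibrates in seconds while cell
#' events occur over hours, so each field is relaxed to its steady state given
#' the current cell consumption/production map. Oxygen and glucose use
#' Michaelis-Menten sinks; protons have a per-site source plus the
#' perivascular/background clearance of [proton_clearance_field()] returning
#' pH toward blood values where perfusion reaches.
#'
#' @param fields An `mp_fields` (used as the warm start; not modified).
#' @param vessel_sites Integer sites held at blood values.
#' @param sinks A list of per-site vectors (length `n` or scalar):
#'   `oxygen_vmax` (maximal O2 consumption), `glucose_vmax` (glucose demand
#'   numerator of the Michaelis-Menten sink), `proton_source` (proton source in
#'   mol/L/s).
#' @param cfg An [sim_config()].
#' @param settings Optional [solver_settings()] (defaults to `cfg$solver`).
#' @return A new `mp_fields` with solved `oxygen`, `glucose`, `protons`
#'   (`drug` is carried through unchanged; see [step_antipdl1_field()]).
#' @export
solve_steady_state <- function(fields, vessel_sites, sinks, cfg,
                               settings = cfg$solver) {
  H0 <- protons_of(cfg$pH_0)
  o <- solve_field(fields$oxygen, cfg$D_O, cfg$dx, vessel_sites, cfg$O_0,
                   vmax = sinks$oxygen_vmax %||% 0, km = cfg$k_O,
                   settings = settings)
  g <- solve_field(fields$glucose, cfg$D_g, cfg$dx, vessel_sites, cfg$G_0,
                   vmax = sinks$glucose_vmax %||% 0, km = cfg$k_G,
                   settings = settings)
  lam <- proton_clearance_field(vessel_sites, cfg)
  h <- solve_field(fields$protons, cfg$D_H, cfg$dx, vessel_sites, H0,
                   decay = lam,
                   source = (sinks$proton_source %||% 0) + lam * H0,
                   settings = settings)
  structure(list(oxygen = o$field, glucose = g$field, protons = h$field,
                 drug = fields$drug),
            class = "mp_fields")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
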