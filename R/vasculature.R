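#' Initialize the vascular point process
#'
#' Hard-core sequential placement: uniformly random candidate sites are
#' accepted iff they lie at least `sigma_min` (um) from every accepted vessel,
#' targeting a density of one vessel per `sigma_mean^2` of tissue. Each vessel
#' draws an exponential lifetime with mean `nu_mean` days at creation; the
#' lifetime clock runs only while the vessel is tumor-exposed (see
#' [update_vessels()]).
#'
#' @param cfg An [sim_config()].
#' @return A tibble with columns `site` (column-major index), `x`, `y`
#'   (1-based lattice coordinates), `age` (days of tumor exposure) and
#'   `lifetime` (days until collapse).
#' @export
initialize_vessels <- function(cfg) {
  nx <- cfg$grid_width; ny <- cfg$grid_height
  area <- (nx * cfg$dx) * (ny * cfg$dx)
  n_target <- max(1L, round(area / cfg$sigma_mean^2))
  min_sites <- cfg$sigma_min / cfg$dx
  if (nx < 1 || ny < 1) stop("grid too small to hold a vessel")
  xs <- integer(0); ys <- integer(0)
  attempts <- 0L; max_attempts <- 200L * n_target
  while (length(xs) < n_target && attempts < max_attempts) {
    attempts <- attempts + 1L
    cx <- sample.int(nx, 1L); cy <- sample.int(ny, 1L)
    if (length(xs) == 0L ||
        min((xs - cx)^2 + (ys - cy)^2) >= min_sites^2) {
      xs <- c(xs, cx); ys <- c(ys, cy)
    }
  }
  if (length(xs) == 0L) stop("grid too small to hold a vessel at sigma_min")
  n <- length(xs)
  tibble::tibble(site = xs + (ys - 1L) * nx, x = xs, y = ys,
                 age = 0, lifetime = stats::rexp(n, 1 / cfg$nu_mean))
}

#' Vessel collapse and hypoxia-triggered angiogenesis
#'
#' Collapse: each vessel carries an exponential lifetime with mean `nu_mean`
#' (vessel stability) drawn at creation. The clock advances only while the
#' vessel is tumor-exposed (a tumor cell within its Moore neighborhood):
#' tumor-associated vasculature is unstable, while vessels in undisturbed
#' normal tissue are homeostatic. Vessels whose exposure age exceeds their
#' lifetime are removed.
#'
#' Renewal: while hypoxia persists, new vessels form at the renewal rate
#' `p_ang` per day -- `Poisson(p_ang * dt)` candidate sprouts per step, each
#' at a uniformly chosen hypoxic site, accepted iff it keeps the minimum
#' spacing `sigma_min` to all vessels (including ones accepted earlier in the
#' same update; rejected sprouts are lost).
#'
#' @param vessels A vessel tibble (as from [initialize_vessels()]).
#' @param hypoxic_sites Integer column-major indices of hypoxic sites
#'   (local oxygen below the half-max constant `k_O`).
#' @param cfg An [sim_config()].
#' @param dt Timestep (days, > 0).
#' @param tumor_adjacent Logical, one per vessel: is the vessel tumor-exposed
#'   this step? Defaults to all exposed (every vessel ages), the right choice
#'   when using this operation outside the full simulation.
#' @return The updated vessel tibble.
#' @export
update_vessels <- function(vessels, hypoxic_sites, cfg, dt,
                           tumor_adjacent = NULL) {
  stopifnot(dt > 0)
  nx <- cfg$grid_width
  min_sites2 <- (cfg$sigma_min / cfg$dx)^2
  if (nrow(vessels)) {
    exposed <- tumor_adjacent %||% rep(TRUE, nrow(vessels))
    vessels$age <- vessels$age + dt * exposed
    vessels <- vessels[vessels$age <= vessels$lifetime, , drop = FALSE]
  }
  nh <- length(hypoxic_sites)
  if (nh && cfg$p_ang > 0) {
    n_cand <- stats::rpois(1L, cfg$p_ang * dt)
    if (n_cand > 0L) {
      cand <- hypoxic_sites[sample.int(nh, min(n_cand, nh))]
      cand <- setdiff(cand, vessels$site)
      for (s in cand) {
        cx <- ((s - 1L) %% nx) + 1L
        cy <- ((s - 1L) %/% nx) + 1L
        if (!nrow(vessels) ||
            min((vessels$x - cx)^2 + (vessels$y - cy)^2) >= min_sites2) {
          vessels <- tibble::add_row(
            vessels, site = s, x = cx, y = cy, age = 0,
            lifetime = stats::rexp(1, 1 / cfg$nu_mean))
        }
      }
    }
  }
  vessels
}
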