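#' Tumor-immune interaction grid
#'
#' `Tlast` holds, per site, the time of the most recent T-cell traversal of
#' the site's Moore neighborhood (`-Inf` for never). The interaction indicator
#' is `I(x,y) = 1` iff `Tlast(x,y) >= t - T_w`.
#'
#' @param Tlast Numeric vector/matrix of last-interaction times.
#' @param t Current time (days).
#' @param T_w Interaction-memory window (days).
#' @return `interaction_indicator`: numeric 0/1 of the same shape;
#'   `update_interaction_grid`: the updated `Tlast`.
#' @export
interaction_indicator <- function(Tlast, t, T_w) {
  as.numeric(Tlast >= t - T_w)
}

#' @rdname interaction_indicator
#' @param sites Integer indices of sites contacted at time `t`.
#' @export
update_interaction_grid <- function(Tlast, sites, t) {
  if (length(sites)) Tlast[sites] <- pmax(Tlast[sites], t)
  Tlast
}

#' Normalized proton production
#'
#' Scales a cell's proton source by the calibrated buffering capability of a
#' vessel: production at or above `p_R_vessel` is taken as fully self-acidify,
#' production near zero as fully moochable, with a linear clamp between.
#'
#' @param p_R Per-cell proton source (same units as `f_H`).
#' @param p_R_vessel Calibrated vessel buffering capacity (> 0).
#' @return `p_R / p_R_vessel` clamped to \[0, 1\], vectorized.
#' @export
normalized_production <- function(p_R, p_R_vessel) {
  stopifnot(p_R_vessel > 0)
  pmin(pmax(p_R / p_R_vessel, 0), 1)
}

#' Calibrate the vessel buffering capacity
#'
#' Bisection on the glycolytic phenotype of a lone cell placed adjacent to a
#' single vessel on a small quiet lattice: the calibrated capacity is the
#' proton source of the weakest phenotype that first drives its own local
#' steady-state pH below the acid-inactivation half-max `H_p`. If no
#' admissible phenotype (up to `p_G_max`) can acidify its own site that far --
#' single cells typically cannot; acidification is collective -- the capacity
#' falls back to the production of the maximal phenotype, so that normalized
#' production still spans \[0, 1\] over the admissible range.
#'
#' @param cfg An [sim_config()].
#' @param grid_size Side of the calibration lattice (sites).
#' @param tol Bisection tolerance on `p_G`.
#' @return `p_R_vessel`, in the units of `f_H`.
#' @export
calibrate_vessel_buffering <- function(cfg, grid_size = 21, tol = 1e-3) {
  params <- metabolism_params(cfg)
  nx <- grid_size
  H0 <- protons_of(cfg$pH_0)
  cx <- (nx + 1L) %/% 2L
  vessel_site <- cx + (cx - 1L) * nx
  cell_site <- (cx + 1L) + (cx - 1L) * nx
  cal_cfg <- cfg
  cal_cfg$grid_width <- nx; cal_cfg$grid_height <- nx
  lam <- proton_clearance_field(vessel_site, cal_cfg)
  pH_at <- function(p_G) {
    f <- metabolize(p_G, cfg$O_0, cfg$G_0, params)
    src <- lam * H0
    src[cell_site] <- src[cell_site] + f$f_H * cfg$proton_yield
    out <- solve_field(matrix(H0, nx, nx), cfg$D_H, cfg$dx, vessel_site, H0,
                       decay = lam, source = src,
                       settings = cfg$solver)
    pH_of(out$field[cell_site])
  }
  p_R_of <- function(p_G) metabolize(p_G, cfg$O_0, cfg$G_0, params)$f_H
  if (pH_at(cfg$p_G_max) > cfg$H_p) {
    return(p_R_of(cfg$p_G_max))
  }
  lo <- 1; hi <- cfg$p_G_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pH_at(mid) > cfg$H_p) lo <- mid else hi <- mid
  }
  p_R_of((lo + hi) / 2)
}

#' Classify metaphenotypes
#'
#' The seven graded collective-phenotype expressions of a tumor cell, each in
#' \[0, 1\], from precomputed per-cell dynamic quantities (all vectorized):
#'
#' * `MP1` Immune Desert: `1 - I`
#' * `MP2` PD-L1 Attack: `(1 - P_k) * I`
#' * `MP3` Mooch PD-L1: `P_k * (1 - I) * max_j PDL1_j` over the Moore
#'   neighborhood (neighbor PD-L1 normalized to \[0, 1\])
#' * `MP4` Self-Acidify: `P_AI * pbar_R * I`
#' * `MP5` Mooch Acid: `P_AI * (1 - pbar_R) * I`
#' * `MP6` Proliferate Fast: `(1 - D/T_m) * I`
#' * `MP7` Starve Glucose: `P_g * I`
#'
#' The classifier is a pure function: identical inputs yield identical
#' vectors. Note the complementarity `MP4 + MP5 = P_AI * I`, and that the
#' `(1 - I)` factor makes `MP2` and `MP3` mutually exclusive per cell.
#'
#' @param I Interaction indicator (0/1) at the cell's site.
#' @param P_k Kill probability given the cell's effective PD-L1.
#' @param P_AI Acid-inactivation probability at the cell's site.
#' @param pbar_R Normalized proton production in \[0, 1\].
#' @param P_g Probability a T-cell dies in low glucose at the cell's site
#'   (`1 - S(g)/100`).
#' @param D Time until next division (days), clamped to `[0, T_m]`.
#' @param T_m Inter-mitotic time of a metabolically normal cell (days).
#' @param max_nb_pdl1 Maximum normalized PD-L1 among Moore neighbors (0 when
#'   the cell has no cellular neighbor).
#' @return A tibble with columns `MP1` ... `MP7`.
#' @export
classify_metaphenotypes <- function(I, P_k, P_AI, pbar_R, P_g, D, T_m,
                                    max_nb_pdl1) {
  D <- pmin(pmax(D, 0), T_m)
  tibble::tibble(
    MP1 = 1 - I,
    MP2 = (1 - P_k) * I,
    MP3 = P_k * (1 - I) * max_nb_pdl1,
    MP4 = P_AI * pbar_R * I,
    MP5 = P_AI * (1 - pbar_R) * I,
    MP6 = (1 - D / T_m) * I,
    MP7 = P_g * I)
}

#' Summarize a metaphenotype table
#'
#' Population expression mass and fraction per metaphenotype. Metaphenotypes
#' are graded and overlapping, so masses are sums of expressions, not cell
#' counts; fractions are relative to the total retained expression mass.
#'
#' @param mp A tibble with columns `MP1` ... `MP7` (one row per cell).
#' @param exclude_immune_desert Drop `MP1` before computing fractions
#'   (the usual convention for end-of-run distributions).
#' @return A tibble `(MP, expression_sum, fraction)`.
#' @export
summarize_metaphenotypes <- function(mp, exclude_immune_desert = FALSE) {
  keep <- paste0("MP", if (exclude_immune_desert) 2:7 else 1:7)
  sums <- vapply(keep, function(k) sum(mp[[k]]), numeric(1))
  total <- sum(sums)
  tibble::tibble(MP = keep, expression_sum = unname(sums),
                 fraction = if (total > 0) unname(sums) / total
                 else rep(0, length(sums)))
}

mp_labels <- c(MP1 = "Immune Desert", MP2 = "PD-L1 Attack",
               MP3 = "Mooch PD-L1", MP4 = "Self-Acidify",
               MP5 = "Mooch Acid", MP6 = "Proliferate Fast",
               MP7 = "Starve Glucose")
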