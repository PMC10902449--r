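# Deterministic frozen snapshots for unit testing: prescribed fields,
# phenotypes, and interaction histories, validated on construction, so every
# classifier and response function is testable without running the full loop.

#' Validate a frozen snapshot
#'
#' Checks internal consistency: at most one cell per site, phenotype bounds,
#' finite positive proton field, vessel spacing, sites within the grid.
#'
#' @param snap An `mp_snapshot`.
#' @return `snap`, invisibly; errors on any violation.
#' @export
validate_snapshot <- function(snap) {
  cfg <- snap$config
  n <- cfg$grid_width * cfg$grid_height
  cells <- snap$cells
  stopifnot(all(cells$site >= 1), all(cells$site <= n),
            !anyDuplicated(cells$site),
            all(snap$fields$protons > 0),
            all(is.finite(snap$fields$protons)),
            all(snap$fields$oxygen >= 0), all(snap$fields$glucose >= 0))
  tum <- cells[cells$kind == "tumor", ]
  if (nrow(tum)) {
    stopifnot(all(tum$p_G >= 1), all(tum$p_G <= cfg$p_G_max),
              all(tum$p_H >= cfg$p_H_min), all(tum$p_H <= cfg$p_H_norm),
              all(tum$p_P >= cfg$p_P_norm), all(tum$p_P <= cfg$p_P_min))
  }
  if (length(snap$tcell_sites)) {
    stopifnot(all(snap$tcell_sites >= 1), all(snap$tcell_sites <= n),
              !any(snap$tcell_sites %in% cells$site))
  }
  invisible(snap)
}

new_snapshot <- function(cfg, fields, cells, Tlast, t,
                         tcell_sites = integer(), vessels = NULL) {
  snap <- structure(list(config = cfg, fields = fields, cells = cells,
                         Tlast = Tlast, t = t, tcell_sites = tcell_sites,
                         vessels = vessels %||%
                           tibble::tibble(site = integer(), x = integer(),
                                          y = integer(), age = numeric(),
                                          lifetime = numeric())),
                    class = "mp_snapshot")
  validate_snapshot(snap)
}

#' Linear-gradient world
#'
#' A frozen snapshot whose pH and glucose vary linearly across columns
#' (constant down rows); no agents unless cells are supplied. Useful for
#' probing the monotone response functions along a controlled gradient.
#'
#' @param cfg An [sim_config()] giving the lattice shape.
#' @param pH_range Length-2 pH range (left to right column).
#' @param glucose_range Length-2 glucose range (mmol/L).
#' @param cells Optional cells tibble (`site`, `kind`, `p_G`, `p_H`, `p_P`).
#' @return An `mp_snapshot`.
#' @export
make_gradient_world <- function(cfg, pH_range = c(6, 7.4),
                                glucose_range = c(0.05, 5), cells = NULL) {
  stopifnot(all(is.finite(pH_range)), all(is.finite(glucose_range)))
  nx <- cfg$grid_width; ny <- cfg$grid_height
  colv <- function(rng) matrix(rep(seq(rng[1], rng[2], length.out = ny),
                                   each = nx), nx, ny)
  fields <- structure(list(
    oxygen = matrix(cfg$O_0, nx, ny),
    glucose = colv(glucose_range),
    protons = protons_of(colv(pH_range)),
    drug = matrix(0, nx, ny)), class = "mp_fields")
  if (is.null(cells)) {
    cells <- tibble::tibble(site = integer(), kind = character(),
                            p_G = numeric(), p_H = numeric(),
                            p_P = numeric())
  }
  new_snapshot(cfg, fields, cells, Tlast = rep(-Inf, nx * ny), t = 0)
}

#' Metaphenotype testbench
#'
#' Nine tumor cells on a quiet 9x9 lattice covering the classifier's corner
#' cases, with hand-set interaction stamps and fields: a never-contacted cell;
#' contacted cells at maximal, normal, and zero effective PD-L1; a
#' high-glycolysis cell in its own acid plume; a low-glycolysis cell in acid
#' beside that producer; a just-divided and a division-ready cell; and a cell
#' on a glucose-starved site. The snapshot records, per cell, every dynamic
#' input the classifier needs, so expressions can be hand-computed.
#'
#' @param cfg An [sim_config()]; the grid shape is overridden to 9x9.
#' @param t Snapshot time (days).
#' @return An `mp_snapshot` with a `bench` tibble describing each case
#'   (`site`, `label`, `stamped`, plus phenotype and environment columns).
#' @export
make_mp_testbench <- function(cfg = sim_config(), t = 10) {
  cfg$grid_width <- 9L; cfg$grid_height <- 9L
  nx <- 9L
  site <- function(x, y) x + (y - 1L) * nx
  acid_pH <- 6.3
  starved_g <- 0.01
  bench <- tibble::tibble(
    label = c("never_contacted", "max_pdl1", "normal_pdl1", "zero_eff_pdl1",
              "self_acidifier", "acid_moocher", "just_divided",
              "division_ready", "glucose_starved"),
    x = c(2L, 4L, 6L, 8L, 2L, 3L, 6L, 8L, 2L),
    y = c(2L, 2L, 2L, 2L, 5L, 5L, 5L, 5L, 8L),
    p_G = c(1, 1, 1, 1, cfg$p_G_max, 1, 1, 1, 1),
    p_H = cfg$p_H_norm,
    p_P = c(rep(cfg$p_P_norm, 1), cfg$p_P_min, cfg$p_P_norm, cfg$p_P_norm,
            rep(cfg$p_P_norm, 5)),
    bound = c(0, 0, 0, cfg$p_P_norm, 0, 0, 0, 0, 0),
    D = c(rep(cfg$tau_min / 2, 6), cfg$tau_min, 0, cfg$tau_min / 2),
    stamped = c(FALSE, rep(TRUE, 8)),
    pH_env = c(rep(cfg$pH_0, 4), acid_pH, acid_pH, cfg$pH_0, cfg$pH_0,
               cfg$pH_0),
    glucose_env = c(rep(cfg$G_0, 8), starved_g))
  bench$site <- site(bench$x, bench$y)
  fields <- structure(list(
    oxygen = matrix(cfg$O_0, nx, nx),
    glucose = matrix(cfg$G_0, nx, nx),
    protons = matrix(protons_of(cfg$pH_0), nx, nx),
    drug = matrix(0, nx, nx)), class = "mp_fields")
  fields$glucose[bench$site] <- bench$glucose_env
  fields$protons[bench$site] <- protons_of(bench$pH_env)
  Tlast <- rep(-Inf, nx * nx)
  Tlast[bench$site[bench$stamped]] <- t
  cells <- tibble::tibble(site = bench$site, kind = "tumor",
                          p_G = bench$p_G, p_H = bench$p_H, p_P = bench$p_P,
                          bound = bench$bound, D = bench$D)
  snap <- new_snapshot(cfg, fields, cells, Tlast, t)
  snap$bench <- bench
  snap
}

#' Classify the tumor cells of a frozen snapshot
#'
#' Computes every dynamic classifier input (interaction indicator, kill
#' probability from effective PD-L1, acid-inactivation probability, normalized
#' proton production at the snapshot's fields, glucose-death probability,
#' cycle position, neighborhood PD-L1 maximum) and applies
#' [classify_metaphenotypes()]. Pure: the same snapshot always yields the same
#' table.
#'
#' @param snap An `mp_snapshot` whose cells carry `p_G`, `p_P`, `bound`, `D`.
#' @param p_R_vessel Normalization for proton production; calibrated from the
#'   snapshot's configuration when omitted.
#' @return The snapshot's cells tibble with `I`, `P_k`, `P_AI`, `pbar_R`,
#'   `P_g` and `MP1` ... `MP7` columns appended.
#' @export
classify_snapshot <- function(snap, p_R_vessel = NULL) {
  cfg <- snap$config
  params <- metabolism_params(cfg)
  if (is.null(p_R_vessel)) p_R_vessel <- calibrate_vessel_buffering(cfg)
  cells <- snap$cells[snap$cells$kind == "tumor", ]
  nx <- cfg$grid_width
  n <- nx * cfg$grid_height
  pHs <- -log10(as.vector(snap$fields$protons)[cells$site])
  gs <- as.vector(snap$fields$glucose)[cells$site]
  os <- as.vector(snap$fields$oxygen)[cells$site]
  I <- interaction_indicator(snap$Tlast[cells$site], snap$t, cfg$T_w)
  p_P_eff <- pmax(cells$p_P - (cells$bound %||% 0), 0)
  P_k <- kill_probability(p_P_eff, cfg$p_P_min)
  P_AI <- acid_inactivation_prob(pHs, cfg$H_p, cfg$sigma_p)
  fl <- metabolize(cells$p_G, os, gs, params)
  B <- buffer_level(cfg$treatment, snap$t)
  pbar <- normalized_production(proton_source_rate(fl$f_H, B), p_R_vessel)
  P_g <- 1 - glucose_survival(gs, cfg$L_i, cfg$L_0, cfg$L_g, cfg$G_0,
                              cfg$g_floor) / 100
  eff_pad <- numeric(n + 1L)
  eff_pad[cells$site] <- p_P_eff / cfg$p_P_min
  NB <- moore_matrix(nx, cfg$grid_height)
  mx <- row_max_nb(c(eff_pad[seq_len(n)], 0), NB[cells$site, , drop = FALSE])
  mx[!is.finite(mx)] <- 0
  mp <- classify_metaphenotypes(I, P_k, P_AI, pbar, P_g, cells$D,
                                cfg$tau_min, mx)
  dplyr::bind_cols(cells,
                   tibble::tibble(I = I, P_k = P_k, P_AI = P_AI,
                                  pbar_R = pbar, P_g = P_g),
                   mp)
}
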