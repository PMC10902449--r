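#' Evolutionary bottleneck statistic of an area trajectory
#'
#' The relative depth of the immune-driven contraction: with the nadir at the
#' trajectory minimum, `(max pre-nadir area - nadir) / max pre-nadir area`.
#' A monotone trajectory (no contraction) scores 0.
#'
#' @param area Numeric trajectory of tumor area (or count).
#' @return The bottleneck statistic in \[0, 1\].
#' @export
bottleneck_statistic <- function(area) {
  if (!length(area)) return(0)
  nadir <- which.min(area)
  pre_max <- max(area[seq_len(nadir)])
  if (pre_max <= 0) return(0)
  (pre_max - area[nadir]) / pre_max
}

with_seed_cfg <- function(cfg, seed, ...) {
  mods <- list(...)
  for (nm in names(mods)) cfg[[nm]] <- mods[[nm]]
  cfg$seed <- as.integer(seed)
  validate_sim_config(cfg)
  cfg
}

#' Sweep vascular stability and renewal
#'
#' Runs `n_reps` seeded replicates per `(nu_mean, p_ang)` grid point and
#' summarizes final tumor area and mean phenotypes. Replicate `r` of every
#' grid point shares seed `seed + r`, giving common random numbers for paired
#' comparisons across conditions.
#'
#' @param cfg Base [sim_config()].
#' @param nu_values Vessel-stability values (days).
#' @param p_ang_values Renewal values in \[0, 1\].
#' @param n_reps Replicates per grid point.
#' @param seed Base seed.
#' @return A tibble with one row per run (`nu_mean`, `p_ang`, `rep`, `seed`,
#'   final area, mean phenotypes, bottleneck) plus per-condition means joined
#'   on demand via [dplyr::summarise()].
#' @export
sweep_vasculature <- function(cfg, nu_values, p_ang_values, n_reps = 5,
                              seed = cfg$seed) {
  grid <- tidyr::expand_grid(nu_mean = nu_values, p_ang = p_ang_values,
                             rep = seq_len(n_reps))
  purrr::pmap_dfr(grid, function(nu_mean, p_ang, rep) {
    run_cfg <- with_seed_cfg(cfg, seed + rep, nu_mean = nu_mean,
                             p_ang = p_ang)
    g <- glance(run_simulation(run_cfg))
    tibble::tibble(nu_mean = nu_mean, p_ang = p_ang, rep = rep,
                   seed = run_cfg$seed,
                   final_area_mm2 = g$final_area_mm2,
                   final_n_tumor = g$final_n_tumor,
                   mean_pG = g$mean_pG, mean_pH = g$mean_pH,
                   mean_pP = g$mean_pP)
  })
}

#' Sweep the immune response rate
#'
#' Runs `n_reps` seeded replicates per recruitment rate `alpha_T` and returns
#' both per-run summaries (with the bottleneck statistic and regrowth above
#' the nadir) and full area / T-cell trajectories. Replicates share seeds
#' across arms (common random numbers).
#'
#' @param cfg Base [sim_config()].
#' @param alpha_values Recruitment rates (0 or within \[1e-4, 1e-1\]).
#' @param n_reps Replicates per arm.
#' @param seed Base seed.
#' @return A list with `summary` (one row per run) and `trajectories`
#'   (`alpha_T`, `rep`, time series columns).
#' @export
sweep_immune <- function(cfg, alpha_values, n_reps = 5, seed = cfg$seed) {
  grid <- tidyr::expand_grid(alpha_T = alpha_values, rep = seq_len(n_reps))
  runs <- purrr::pmap(grid, function(alpha_T, rep) {
    run_cfg <- with_seed_cfg(cfg, seed + rep, alpha_T = alpha_T)
    sim <- run_simulation(run_cfg)
    ts <- sim$timeseries
    area <- ts$tumor_area_mm2
    nadir <- which.min(area)
    list(summary = dplyr::bind_cols(
      tibble::tibble(alpha_T = alpha_T, rep = rep, seed = run_cfg$seed),
      dplyr::select(glance(sim), -"seed"),
      tibble::tibble(regrowth = area[length(area)] - area[nadir])),
      traj = dplyr::bind_cols(tibble::tibble(alpha_T = alpha_T, rep = rep),
                              ts))
  })
  list(summary = dplyr::bind_rows(purrr::map(runs, "summary")),
       trajectories = dplyr::bind_rows(purrr::map(runs, "traj")))
}

#' Treatment factorial: untreated, anti-PD-L1, buffer, combination
#'
#' Runs the four treatment arms from one base configuration on shared seeds
#' and collects area trajectories and horizon metaphenotype distributions
#' (Immune Desert excluded by convention).
#'
#' @param cfg Base [sim_config()]; its `treatment` windows define when each
#'   active arm is on.
#' @param seeds Integer seeds; each seed runs all four arms.
#' @param exclude_immune_desert Drop the Immune Desert expression from the
#'   horizon distributions.
#' @return A list: `summary` (per arm x seed glance rows), `trajectories`,
#'   `mp_distribution` (per arm x seed per-MP mass and fraction at the
#'   horizon), and `results` (the four `mp_sim` lists per seed).
#' @export
treatment_factorial <- function(cfg, seeds = cfg$seed,
                                exclude_immune_desert = TRUE) {
  arms <- c("untreated", "anti_pdl1", "buffer", "combo")
  sched <- cfg$treatment
  arm_schedule <- function(arm) {
    treatment_schedule(
      anti_pdl1_on = arm %in% c("anti_pdl1", "combo"),
      anti_pdl1_start = sched$anti_pdl1$start,
      anti_pdl1_end = sched$anti_pdl1$end,
      anti_pdl1_source = sched$anti_pdl1$source,
      buffer_on = arm %in% c("buffer", "combo"),
      buffer_start = sched$buffer$start, buffer_end = sched$buffer$end,
      buffer_B = sched$buffer$B)
  }
  out <- list()
  for (sd in seeds) {
    for (arm in arms) {
      run_cfg <- with_seed_cfg(cfg, sd, treatment = arm_schedule(arm))
      sim <- run_simulation(run_cfg)
      mp <- summarize_metaphenotypes(
        sim$mp_final[paste0("MP", 1:7)],
        exclude_immune_desert = exclude_immune_desert)
      out[[paste(arm, sd, sep = "_")]] <- list(
        arm = arm, seed = sd, sim = sim,
        summary = dplyr::bind_cols(tibble::tibble(arm = arm, seed = sd),
                                   dplyr::select(glance(sim), -"seed")),
        traj = dplyr::bind_cols(tibble::tibble(arm = arm, seed = sd),
                                sim$timeseries),
        mp = dplyr::bind_cols(tibble::tibble(arm = arm, seed = sd), mp))
    }
  }
  list(summary = dplyr::bind_rows(purrr::map(out, "summary")),
       trajectories = dplyr::bind_rows(purrr::map(out, "traj")),
       mp_distribution = dplyr::bind_rows(purrr::map(out, "mp")),
       results = purrr::map(out, "sim"))
}
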