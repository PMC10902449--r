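test_that("identical configuration and seed reproduce the run exactly", {
  cfg <- sim_config(grid_width = 20, grid_height = 20, duration = 3,
                    seed = 5, alpha_T = 1e-2, nu_mean = 20, p_ang = 0.5,
                    tau_T = 1)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a, b)
  # a different seed gives a different trajectory
  cfg2 <- cfg; cfg2$seed <- 6L
  c <- run_simulation(cfg2)
  expect_false(identical(a$timeseries, c$timeseries))
})

test_that("zero duration returns only the initial state", {
  cfg <- sim_config(grid_width = 18, grid_height = 18, duration = 0, seed = 3)
  sim <- run_simulation(cfg)
  expect_equal(nrow(sim$timeseries), 1)
  expect_equal(sim$timeseries$time, 0)
  expect_equal(sim$timeseries$n_tumor, nrow(sim$cells[sim$cells$kind ==
                                                        "tumor", ]))
  # initial phenotypes are normal; all metaphenotype mass is Immune Desert
  expect_true(all(sim$cells$p_G[sim$cells$kind == "tumor"] == 1))
  expect_equal(sum(sim$mp_final$MP1), sim$timeseries$n_tumor)
  # with no interactions ever, only Immune Desert and Mooch PD-L1 (which
  # carries the (1 - I) factor) can be expressed
  expect_equal(sum(as.matrix(sim$mp_final[paste0("MP", c(2, 4:7))])), 0)
  expect_true(all(sim$mp_final$MP3 >= 0))
})

test_that("state invariants hold at the end of a stochastic run", {
  cfg <- sim_config(grid_width = 24, grid_height = 24, duration = 6,
                    seed = 11, alpha_T = 1e-2, tau_T = 1, nu_mean = 15,
                    p_ang = 0.7)
  sim <- run_simulation(cfg)
  cells <- sim$cells
  # occupancy: one cell per site; T-cells never co-occupy with cells
  expect_equal(anyDuplicated(cells$site), 0)
  expect_equal(anyDuplicated(sim$tcells$site), 0)
  # T-cells migrate through stroma but never share a site with a tumor cell
  expect_length(intersect(sim$tcells$site,
                          cells$site[cells$kind == "tumor"]), 0)
  # phenotype bounds for every tumor cell
  tum <- cells[cells$kind == "tumor", ]
  expect_true(all(tum$p_G >= 1 & tum$p_G <= cfg$p_G_max))
  expect_true(all(tum$p_H >= cfg$p_H_min & tum$p_H <= cfg$p_H_norm))
  expect_true(all(tum$p_P >= cfg$p_P_norm & tum$p_P <= cfg$p_P_min))
  expect_true(all(tum$D >= 0 & tum$D <= cfg$tau_min + 1e-9))
  # normal cells never drift
  nrm <- cells[cells$kind == "normal", ]
  expect_true(all(nrm$p_G == 1 & nrm$p_H == cfg$p_H_norm &
                    nrm$p_P == cfg$p_P_norm))
  # area bookkeeping
  expect_equal(sim$timeseries$tumor_area_mm2,
               sim$timeseries$n_tumor * (cfg$dx / 1000)^2)
  # vessel spacing maintained through the whole run
  v <- sim$vessels
  if (nrow(v) > 1) {
    d2 <- as.matrix(stats::dist(cbind(v$x, v$y)))^2
    diag(d2) <- Inf
    expect_gte(min(d2) * cfg$dx^2, cfg$sigma_min^2)
  }
  # fields positive and finite; pH finite everywhere
  expect_true(all(sim$fields$protons > 0))
  expect_true(all(is.finite(pH_of(sim$fields$protons))))
})

test_that("the lineage table is a forest rooted in the seed clones", {
  cfg <- sim_config(grid_width = 20, grid_height = 20, duration = 8,
                    seed = 21)
  sim <- run_simulation(cfg)
  lin <- sim$lineage
  expect_gt(nrow(lin), 0)
  first_seen <- tapply(lin$time, lin$clone_id, min)
  seeds <- sim$timeseries$n_tumor[1]
  for (cl in unique(lin$clone_id)) {
    p <- lin$parent_id[lin$clone_id == cl][1]
    if (cl <= seeds) {
      expect_equal(p, 0L)                   # roots
    } else {
      # parent clone appeared no later than the daughter
      expect_true(p %in% names(first_seen) ||
                    p <= seeds || p %in% lin$clone_id)
    }
  }
  # counts are consistent with the time series at matching times
  by_time <- tapply(lin$n_cells, lin$time, sum)
  ts <- sim$timeseries
  expect_equal(as.vector(by_time[as.character(ts$time[ts$n_tumor > 0])]),
               as.numeric(ts$n_tumor[ts$n_tumor > 0]))
})

test_that("immune predation kills tumor cells within days when recruitment is high", {
  cfg <- sim_config(grid_width = 30, grid_height = 30, duration = 12,
                    seed = 9, alpha_T = 1e-2, tau_T = 1, nu_mean = 100,
                    p_ang = 1)
  sim <- run_simulation(cfg)
  expect_gt(max(sim$timeseries$n_kills_cum), 0)
  expect_gt(nrow(sim$kill_log), 0)
  # T-cell states are only the three admissible ones
  expect_true(all(sim$tcells$state %in% c("free", "engaged", "inactivated")))
  # stamped interactions produce non-desert metaphenotype mass somewhere
  # along the run (the interaction window may have lapsed by the horizon)
  nondesert <- sum(as.matrix(sim$mp_timeseries[paste0("MP", c(2, 4:7))]))
  expect_gt(nondesert, 0)
})

test_that("neutral conditions produce negligible phenotype drift", {
  # fully stable, fully vascularized world with no immune system: no
  # directional selection, so mean phenotypes stay near their initial values
  cfg <- sim_config(grid_width = 30, grid_height = 30, duration = 25,
                    seed = 14, alpha_T = 0, nu_mean = 100, p_ang = 1)
  sim <- run_simulation(cfg)
  ts <- sim$timeseries
  expect_lt(abs(ts$mean_pG[nrow(ts)] - 1), 1.5)
  expect_lt(abs(ts$mean_pH[nrow(ts)] - cfg$p_H_norm), 0.02)
  expect_equal(ts$n_tcell_free + ts$n_tcell_engaged + ts$n_tcell_inactivated,
               rep(0L, nrow(ts)))
})
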