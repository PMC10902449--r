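test_that("the bottleneck statistic measures pre-nadir contraction", {
  expect_equal(bottleneck_statistic(c(1, 2, 3, 4)), 0)     # monotone growth
  expect_equal(bottleneck_statistic(c(2, 4, 1, 3)), 0.75)
  expect_equal(bottleneck_statistic(c(5, 5, 5)), 0)
  expect_equal(bottleneck_statistic(numeric(0)), 0)
  expect_equal(bottleneck_statistic(c(0, 0, 2)), 0)        # zero pre-max
})

test_that("sweeps carry full provenance and honor trivial shapes", {
  cfg <- sim_config(grid_width = 16, grid_height = 16, duration = 1,
                    seed = 30)
  tab <- sweep_vasculature(cfg, nu_values = 20, p_ang_values = 0.5,
                           n_reps = 1)
  expect_equal(nrow(tab), 1)
  expect_named(tab, c("nu_mean", "p_ang", "rep", "seed", "final_area_mm2",
                      "final_n_tumor", "mean_pG", "mean_pH", "mean_pP"))
  expect_equal(tab$seed, 31L)
  sw <- sweep_immune(cfg, alpha_values = c(0, 1e-3), n_reps = 1)
  expect_equal(nrow(sw$summary), 2)
  # the summary bottleneck is exactly the statistic of the stored trajectory
  tr0 <- sw$trajectories[sw$trajectories$alpha_T == 0, ]
  expect_equal(sw$summary$bottleneck[sw$summary$alpha_T == 0],
               bottleneck_statistic(tr0$tumor_area_mm2))
  # and a never-contracting trajectory scores 0 by definition
  expect_equal(bottleneck_statistic(cummax(tr0$tumor_area_mm2)), 0)
  expect_true(all(c("alpha_T", "rep", "time",
                    "tumor_area_mm2") %in% names(sw$trajectories)))
})

test_that("the treatment factorial shares seeds across its four arms", {
  cfg <- sim_config(grid_width = 16, grid_height = 16, duration = 2,
                    seed = 40,
                    treatment = treatment_schedule(
                      anti_pdl1_on = TRUE, anti_pdl1_start = 0.5,
                      anti_pdl1_end = 1.5, buffer_on = TRUE,
                      buffer_start = 0.5, buffer_end = 1.5, buffer_B = 0.8))
  fac <- treatment_factorial(cfg, seeds = 40)
  expect_setequal(unique(fac$summary$arm),
                  c("untreated", "anti_pdl1", "buffer", "combo"))
  expect_equal(nrow(fac$summary), 4)
  expect_true(all(fac$summary$seed == 40))
  # arms only differ by schedule: untreated run ignores both windows
  unt <- fac$results$untreated_40
  expect_false(unt$config$treatment$anti_pdl1$on)
  expect_false(unt$config$treatment$buffer$on)
  cmb <- fac$results$combo_40
  expect_true(cmb$config$treatment$anti_pdl1$on &&
                cmb$config$treatment$buffer$on)
  # MP distributions exclude Immune Desert by default
  expect_false("MP1" %in% fac$mp_distribution$MP)
  # identical pre-treatment trajectories under common random numbers
  tr <- fac$trajectories
  pre <- tr[tr$time < 0.5, c("arm", "time", "n_tumor")]
  wide <- tidyr::pivot_wider(pre, names_from = "arm",
                             values_from = "n_tumor")
  expect_equal(wide$untreated, wide$combo)
  expect_equal(wide$anti_pdl1, wide$buffer)
})

test_that("tidy, glance and plots expose the result surfaces", {
  cfg <- sim_config(grid_width = 16, grid_height = 16, duration = 1,
                    seed = 50)
  sim <- run_simulation(cfg)
  expect_identical(tidy(sim), sim$timeseries)
  g <- glance(sim)
  expect_equal(nrow(g), 1)
  expect_equal(g$seed, 50L)
  p <- autoplot(sim)
  expect_s3_class(p, "ggplot")
  s <- summarize_metaphenotypes(sim$mp_final[paste0("MP", 1:7)])
  expect_s3_class(plot_mp_distribution(s), "ggplot")
})
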