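test_that("drug field: off stays zero, off decays exponentially, on is monotone from the vessel", {
  cfg <- tiny_cfg()
  zero <- matrix(0, 15, 15)
  out <- step_antipdl1_field(zero, vessel_sites = 8L + 7L * 15L,
                             active = FALSE, cfg, dt = 1)
  expect_equal(out, zero)
  # pure exponential mass decay once the source is off
  f <- matrix(2, 15, 15)
  out1 <- step_antipdl1_field(f, integer(), active = FALSE, cfg, dt = 1)
  expect_equal(sum(out1), sum(f) * exp(-cfg$gamma_A), tolerance = 1e-12)
  out2 <- step_antipdl1_field(out1, integer(), active = FALSE, cfg, dt = 2.5)
  expect_equal(sum(out2), sum(f) * exp(-cfg$gamma_A * 3.5), tolerance = 1e-12)
  expect_true(all(out2 >= 0))
  # active source: concentration decreases with distance from the vessel
  cfg2 <- tiny_cfg(treatment = treatment_schedule(anti_pdl1_on = TRUE))
  center <- 8L + 7L * 15L
  on <- step_antipdl1_field(zero, center, active = TRUE, cfg2, dt = 1)
  xs <- rep(1:15, 15); ys <- rep(1:15, each = 15)
  d <- sqrt((xs - 8)^2 + (ys - 8)^2)
  v <- as.vector(on)
  ord <- order(d)
  # max principle: value at larger distance never exceeds nearer rings
  expect_equal(which.max(v), center)
  expect_true(all(diff(sapply(split(v, round(d)), max)) <= 1e-9))
  expect_true(all(v > 0))
})

test_that("bound PD-L1 saturates under drug and decays without it", {
  cfg <- tiny_cfg()
  # no drug, ever: identity
  u <- update_bound_pdl1(b = 0, p_P = 2.7, A = 0, cfg, dt = 1)
  expect_equal(u$bound, 0)
  expect_equal(u$p_P_eff, 2.7)
  # sustained saturating drug drives effective PD-L1 to ~0 and P_k to ~1
  b <- rep(0, 3)
  for (i in 1:200) {
    u <- update_bound_pdl1(b, p_P = c(2.7, 4, 5), A = 100 * cfg$K_A, cfg,
                           dt = 1 / 24)
    b <- u$bound
  }
  expect_lt(max(u$p_P_eff / c(2.7, 4, 5)), 0.02)
  expect_gt(min(kill_probability(u$p_P_eff)), 0.95)
  # closed-form decay after drug removal
  b0 <- u$bound
  u2 <- update_bound_pdl1(b0, p_P = c(2.7, 4, 5), A = 0, cfg, dt = 7)
  expect_equal(u2$bound, b0 * exp(-cfg$gamma_P * 7), tolerance = 1e-12)
})

test_that("buffer level follows its window and shuts off acidification", {
  sch <- treatment_schedule(buffer_on = TRUE, buffer_start = 100,
                            buffer_end = 160, buffer_B = 0.8)
  expect_equal(buffer_level(sch, 50), 0)
  expect_equal(buffer_level(sch, 100), 0.8)
  expect_equal(buffer_level(sch, 159.99), 0.8)
  expect_equal(buffer_level(sch, 160), 0)
  expect_equal(proton_source_rate(0.5, buffer_level(sch, 120)),
               0.1, tolerance = 1e-12)
  # B = 1: no cell acidifies, the acid pair is pure mooch
  mp <- classify_metaphenotypes(1, 0.5, 0.8, normalized_production(
    proton_source_rate(0.7, 1), 1), 0.4, 0.5, 0.95, 0)
  expect_equal(mp$MP4, 0)
  expect_equal(mp$MP5, 0.8)
})

test_that("raising the buffer never lowers steady-state pH anywhere", {
  cfg <- tiny_cfg()
  n <- 15L
  set.seed(13)
  src_cells <- runif(n * n, 0, 4e-7)   # frozen per-site proton production
  H0 <- protons_of(cfg$pH_0)
  solveH <- function(B) {
    solve_field(matrix(H0, n, n), cfg$D_H, cfg$dx, 113L, H0,
                decay = cfg$proton_clearance,
                source = src_cells * (1 - B) + cfg$proton_clearance * H0,
                settings = solver_settings(tolerance = 1e-11))$field
  }
  h0 <- solveH(0); h8 <- solveH(0.8)
  expect_true(all(pH_of(h8) >= pH_of(h0) - 1e-9))
})
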