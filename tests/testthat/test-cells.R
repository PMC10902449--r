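test_that("metabolic fluxes follow the stated closed forms", {
  cfg <- tiny_cfg()
  p <- metabolism_params(cfg)
  # blood conditions, normal phenotype
  m <- metabolize(1, cfg$O_0, cfg$G_0, p)
  expect_equal(m$f_O, 0.012 * 0.0556 / (0.0556 + 0.005), tolerance = 1e-12)
  expect_equal(m$f_O, 0.01101, tolerance = 1e-3)
  # baseline ATP: realized blood-condition rate equals A_0 up to the
  # glucose half-saturation correction
  expect_gt(p$A_0, 0)
  expect_equal(m$f_A / p$A_0, 1, tolerance = 1e-2)
  # anoxia: ATP from glycolysis alone
  m0 <- metabolize(c(1, 10), 0, 5, p)
  expect_equal(m0$f_O, c(0, 0))
  expect_equal(m0$f_A, 2 * m0$f_G)
  # no glucose: no glycolysis, no acid
  mg <- metabolize(c(1, 50), cfg$O_0, 0, p)
  expect_equal(mg$f_G, c(0, 0))
  expect_equal(mg$f_H, c(0, 0))
  # all fluxes non-negative across a parameter sweep
  grid <- expand.grid(p_G = c(1, 5, 50), O = c(0, 1e-4, cfg$O_0),
                      G = c(0, 0.01, 5))
  mm <- metabolize(grid$p_G, grid$O, grid$G, p)
  expect_true(all(as.matrix(mm) >= 0))
  # Warburg cells make more acid
  expect_gt(metabolize(50, cfg$O_0, cfg$G_0, p)$f_H,
            metabolize(1, cfg$O_0, cfg$G_0, p)$f_H)
})

test_that("fate gating follows the ATP and acid thresholds", {
  cfg <- tiny_cfg()
  # well-fed tumor cell at blood pH survives and proliferates, always
  f <- update_fate(rep(1, 200), rep(7.4, 200), rep(6.65, 200),
                   rep(FALSE, 200), dt = 1, cfg)
  expect_true(all(f == "proliferate"))
  # acid below threshold: death probability p_delta per day
  set.seed(1)
  n <- 20000
  f <- update_fate(rep(1, n), rep(6.3, n), rep(6.65, n), rep(FALSE, n),
                   dt = 1, cfg)
  expect_equal(mean(f == "die"), 0.7, tolerance = 0.02)
  # sub-day compounding: two half-day draws ~ one day
  set.seed(2)
  p_half <- 1 - (1 - cfg$p_delta)^0.5
  f2 <- update_fate(rep(1, n), rep(6.3, n), rep(6.65, n), rep(FALSE, n),
                    dt = 0.5, cfg)
  expect_equal(mean(f2 == "die"), p_half, tolerance = 0.02)
  # maximally acid-resistant cell with adequate ATP survives deterministically
  f <- update_fate(rep(1, 500), rep(6.3, 500), rep(6.1, 500),
                   rep(FALSE, 500), dt = 1, cfg)
  expect_true(all(f != "die"))
  # quiescence band
  f <- update_fate(0.5, 7.4, 6.65, FALSE, dt = 1, cfg)
  expect_equal(f, "quiescent")
})

test_that("phenotype inheritance drifts symmetrically and clamps", {
  cfg <- tiny_cfg()
  # zero variation: daughters identical to parents
  cfg0 <- tiny_cfg(delta_G = 0, delta_H = 0, delta_P = 0)
  d <- inherit_phenotypes(rep(3, 10), rep(6.4, 10), rep(3.5, 10), cfg0)
  expect_equal(d$p_G, rep(3, 10))
  expect_equal(d$p_H, rep(6.4, 10))
  expect_equal(d$p_P, rep(3.5, 10))
  # boundary clamps
  set.seed(3)
  d <- inherit_phenotypes(rep(1, 3000), rep(cfg$p_H_min, 3000),
                          rep(cfg$p_P_min, 3000), cfg)
  expect_true(all(d$p_G >= 1))
  expect_true(all(d$p_H >= cfg$p_H_min))
  expect_true(all(d$p_P <= cfg$p_P_min))
  # symmetric three-outcome drift away from boundaries
  set.seed(4)
  n <- 10000
  d <- inherit_phenotypes(rep(25, n), rep(6.4, n), rep(3.5, n), cfg)
  shifts <- round((d$p_G - 25) / cfg$delta_G)
  tab <- table(factor(shifts, levels = c(-1, 0, 1)))
  expect_gt(stats::chisq.test(tab, p = rep(1 / 3, 3))$p.value, 0.01)
})

test_that("necrotic turnover matches its geometric rate", {
  cfg <- tiny_cfg()
  set.seed(5)
  n <- 2e5
  expect_equal(mean(necrotic_turnover(n, 1, cfg)), cfg$p_n, tolerance = 0.1)
  cfg0 <- tiny_cfg(p_n = 0)
  expect_equal(sum(necrotic_turnover(1e4, 1, cfg0)), 0)
})
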