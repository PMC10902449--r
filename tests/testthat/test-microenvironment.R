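test_that("steady-state fields match a dense direct solve of the same system", {
  cfg <- tiny_cfg()
  tight <- solver_settings(tolerance = 1e-12)
  for (n in c(9L, 15L)) {
    set.seed(n)
    vessel <- sample.int(n * n, 2)
    lam <- runif(n * n, 0, 0.02)            # linear oxygen sink lambda*O
    got <- solve_field(matrix(cfg$O_0, n, n), cfg$D_O, cfg$dx, vessel,
                       cfg$O_0, decay = lam, settings = tight)$field
    want <- dense_solve(n, cfg$D_O, cfg$dx, vessel, cfg$O_0, decay = lam)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-6)
  }
  # with a per-site source and decay (the proton configuration)
  n <- 11L
  src <- runif(n * n, 0, 1e-7)
  got <- solve_field(matrix(1e-7, n, n), cfg$D_H, cfg$dx, 61L, 10^-7.4,
                     decay = 0.05, source = src, settings = tight)$field
  want <- dense_solve(n, cfg$D_H, cfg$dx, 61L, 10^-7.4, decay = 0.05,
                      source = src)
  expect_lt(max(abs(got - want)) / max(abs(want)), 1e-6)
})

test_that("no cells and one vessel give blood values everywhere", {
  cfg <- sim_config(grid_width = 21, grid_height = 21)
  f <- make_fields(cfg)
  center <- 11L + 10L * 21L
  out <- solve_steady_state(f, center, list(), cfg,
                            settings = solver_settings(tolerance = 1e-10))
  expect_equal(range(out$oxygen), rep(cfg$O_0, 2), tolerance = 1e-8)
  expect_equal(range(out$glucose), rep(cfg$G_0, 2), tolerance = 1e-8)
  expect_equal(range(pH_of(out$protons)), rep(cfg$pH_0, 2), tolerance = 1e-8)
})

test_that("a uniform field with no sources or vessels is a fixed point", {
  cfg <- tiny_cfg()
  f <- matrix(0.3, 8, 8)
  out <- solve_field(f, cfg$D_O, cfg$dx)
  expect_equal(out$field, f)
  expect_equal(out$iterations, 1L)
})

test_that("increasing consumption never raises any site's concentration", {
  cfg <- tiny_cfg()
  n <- 13L
  set.seed(7)
  vessel <- sample.int(n * n, 2)
  base <- runif(n * n, 0, cfg$V_O)
  tight <- solver_settings(tolerance = 1e-11)
  lo <- solve_field(matrix(cfg$O_0, n, n), cfg$D_O, cfg$dx, vessel, cfg$O_0,
                    vmax = base, km = cfg$k_O, settings = tight)$field
  hi <- solve_field(matrix(cfg$O_0, n, n), cfg$D_O, cfg$dx, vessel, cfg$O_0,
                    vmax = base * 2, km = cfg$k_O, settings = tight)$field
  expect_true(all(hi <= lo + 1e-9))
})

test_that("a central vessel with symmetric sinks yields 4-fold symmetric fields", {
  cfg <- tiny_cfg()
  n <- 11L
  center <- 6L + 5L * n
  vmax <- rep(cfg$V_O, n * n)
  out <- solve_field(matrix(cfg$O_0, n, n), cfg$D_O, cfg$dx, center, cfg$O_0,
                     vmax = vmax, km = cfg$k_O,
                     settings = solver_settings(tolerance = 1e-11))$field
  rot <- out[n:1, ][, n:1]
  expect_equal(out, t(out), tolerance = 1e-7)
  expect_equal(out, rot, tolerance = 1e-7)
})

test_that("solver errors carry context and reject bad inputs", {
  cfg <- tiny_cfg()
  expect_error(
    solve_field(matrix(0, 5, 5), cfg$D_O, cfg$dx, 13L, 1,
                settings = solver_settings(tolerance = 1e-14,
                                           max_iterations = 2)),
    "did not converge")
  expect_error(solve_field(matrix(1, 5, 5), cfg$D_O, cfg$dx, 99L, 1),
               "outside the grid")
  expect_error(solve_field(matrix(1, 5, 5), cfg$D_O, cfg$dx,
                           source = rep(NaN, 25)), "finite")
})

test_that("pH conversion is exact and round-trips", {
  expect_equal(pH_of(10^-7.4), 7.4)
  expect_equal(pH_of(10^-6.6), 6.6)
  expect_equal(pH_of(protons_of(6.1)), 6.1, tolerance = 1e-12)
  expect_error(pH_of(0), "positive")
  expect_error(pH_of(-1), "positive")
})

test_that("proton source scales with buffer level", {
  expect_equal(proton_source_rate(0.3, 0), 0.3)
  expect_equal(proton_source_rate(0.3, 1), 0)
  expect_equal(proton_source_rate(0.004, 0.5), 0.002)
  expect_error(proton_source_rate(0.1, 1.2), "\\[0, 1\\]")
  expect_error(proton_source_rate(-0.1, 0), ">= 0")
})
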