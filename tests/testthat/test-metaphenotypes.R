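test_that("interaction indicator implements the memory window exactly", {
  Tlast <- c(-Inf, 10, 10 - 1, 10 - 1 - 1e-9, 0)
  I <- interaction_indicator(Tlast, t = 10, T_w = 1)
  expect_equal(I, c(0, 1, 1, 0, 0))
  # stamping takes the max of existing and new times
  Tl <- update_interaction_grid(rep(-Inf, 5), c(2, 4), 3)
  expect_equal(Tl, c(-Inf, 3, -Inf, 3, -Inf))
  Tl2 <- update_interaction_grid(Tl, 2, 1)   # older contact cannot rewind
  expect_equal(Tl2[2], 3)
})

test_that("testbench expressions match hand-computed values to machine precision", {
  snap <- make_mp_testbench()
  cfg <- snap$config
  p_R_vessel <- calibrate_vessel_buffering(cfg)
  got <- classify_snapshot(snap, p_R_vessel)
  got <- got[match(snap$bench$site, got$site), ]
  b <- snap$bench
  params <- metabolism_params(cfg)

  # hand-computed dynamic inputs, written out term by term
  I <- as.numeric(b$stamped)                      # stamps set at t, window 1 d
  p_P_eff <- b$p_P - b$bound
  P_k <- pmin(pmax(1 - p_P_eff / 5, 0), 1)
  P_AI <- 1 / (1 + exp(6 * (b$pH_env - 6.6)))
  f_O <- 0.012 * cfg$O_0 / (cfg$O_0 + 0.005)
  f_G <- pmax(0, (b$p_G * params$A_0 - 5.4 * f_O) / 2) *
    b$glucose_env / (b$glucose_env + 0.04)
  pbar <- pmin(2.5e-4 * f_G / p_R_vessel, 1)
  S <- pmax(21.78, pmin(65.35, 65.35 - 16.67 * log10(5 / pmax(b$glucose_env,
                                                              1e-4))))
  P_g <- 1 - S / 100
  nbmax <- c(0, 0, 0, 0,                           # isolated cells
             (b$p_P[6] - b$bound[6]) / 5,          # producer's neighbor
             (b$p_P[5] - b$bound[5]) / 5,          # moocher's neighbor
             0, 0, 0)

  expect_equal(got$MP1, 1 - I)
  expect_equal(got$MP2, (1 - P_k) * I)
  expect_equal(got$MP3, P_k * (1 - I) * nbmax)
  expect_equal(got$MP4, P_AI * pbar * I)
  expect_equal(got$MP5, P_AI * (1 - pbar) * I)
  expect_equal(got$MP6, (1 - b$D / cfg$tau_min) * I)
  expect_equal(got$MP7, P_g * I)

  # the published boundary cases
  expect_equal(unlist(got[1, paste0("MP", c(1:2, 4:7))], use.names = FALSE),
               c(1, 0, 0, 0, 0, 0))                # never contacted
  expect_equal(got$MP2[2], 1)                      # maximal PD-L1, contacted
  expect_equal(got$MP6[7], 0)                      # just divided
  expect_equal(got$MP6[8], 1)                      # division ready
  # acid pair: producer mostly self-acidify, moocher mostly mooch
  expect_gt(got$MP4[5], got$MP5[5])
  expect_gt(got$MP5[6], got$MP4[6])
  expect_lt(got$MP4[6], 0.05 * got$MP5[6])         # "not due to self-acid"
})

test_that("metaphenotype invariants hold on random inputs", {
  set.seed(11)
  n <- 500
  I <- sample(0:1, n, replace = TRUE)
  P_k <- runif(n); P_AI <- runif(n); pbar <- runif(n); P_g <- runif(n)
  D <- runif(n, -0.2, 1.2); mx <- runif(n)
  mp <- classify_metaphenotypes(I, P_k, P_AI, pbar, P_g, D, 0.95, mx)
  m <- as.matrix(mp)
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(mp$MP1 %in% c(0, 1)))
  expect_equal(mp$MP4 + mp$MP5, P_AI * I)          # acid complementarity
  expect_true(all(mp$MP2 * mp$MP3 == 0))           # mutually exclusive
  # purity
  mp2 <- classify_metaphenotypes(I, P_k, P_AI, pbar, P_g, D, 0.95, mx)
  expect_identical(mp, mp2)
})

test_that("normalized production clamps to the unit interval", {
  expect_equal(normalized_production(0, 2), 0)
  expect_equal(normalized_production(2, 2), 1)
  expect_equal(normalized_production(5, 2), 1)
  expect_equal(normalized_production(0.5, 2), 0.25)
  expect_error(normalized_production(1, 0))
})

test_that("summaries are permutation invariant and correct on one cell", {
  v <- tibble::tibble(MP1 = 0, MP2 = 0.2, MP3 = 0, MP4 = 0.3, MP5 = 0.2,
                      MP6 = 0.1, MP7 = 0.4)
  s <- summarize_metaphenotypes(v)
  expect_equal(s$expression_sum, c(0, 0.2, 0, 0.3, 0.2, 0.1, 0.4))
  expect_equal(sum(s$fraction), 1)
  set.seed(12)
  big <- tibble::as_tibble(matrix(runif(700), 100, 7,
                                  dimnames = list(NULL, paste0("MP", 1:7))))
  s1 <- summarize_metaphenotypes(big, exclude_immune_desert = TRUE)
  s2 <- summarize_metaphenotypes(big[sample.int(100), ],
                                 exclude_immune_desert = TRUE)
  expect_equal(s1, s2)
  expect_false("MP1" %in% s1$MP)
})
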