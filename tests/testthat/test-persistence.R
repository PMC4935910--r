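test_that("region maxima reproduce the bilinear closed forms exactly", {
  cs <- bilinear_case()
  # f = S I: the two derivative functionals are constant (0 and 1) and f/S = I
  for (eps in c(0, 1)) {
    mx <- region_maxima(cs$p, cs$m, epsilon = eps, grid_n = 101)
    expect_equal(mx$M1, 0, tolerance = 1e-8)
    expect_equal(mx$M2, 1, tolerance = 1e-8)
    expect_equal(mx$M_S, cs$p$S0 + eps, tolerance = 1e-8)
  }
})

test_that("standard incidence has f/S bounded by one on the region", {
  sd <- standard_case()
  mx <- region_maxima(sd$p, sd$m, epsilon = 1, grid_n = 201)
  expect_lte(mx$M_S, 1 + 1e-12)
  expect_gte(mx$M_S, 0.9)
  # closed forms at the region's lower edge q = S_low - eps:
  # M1 = max S/(S+I)^2 = 1/q, M2 = max I/(S+I)^2 = 1/q
  q <- sd$p$S_low - 1
  expect_equal(mx$M1, 1 / q, tolerance = 2e-2)
  expect_equal(mx$M2, 1 / q, tolerance = 2e-2)
})

test_that("region maxima converge under grid refinement", {
  p <- model_params(Lambda = 100, beta = 0.05, mu = 1, gamma = 1, alpha = 0.5,
                    sigma = 0.01)
  for (m in list(make_incidence("standard"),
                 make_incidence("beddington_deangelis",
                                list(omega1 = 0.2, omega2 = 0.1)))) {
    a <- region_maxima(p, m, epsilon = 1, grid_n = 201)
    b <- region_maxima(p, m, epsilon = 1, grid_n = 402)
    for (nm in c("M1", "M2", "M_S")) {
      expect_lt(abs(b[[nm]] - a[[nm]]) / max(abs(a[[nm]]), 1e-12), 0.01)
    }
  }
})

test_that("region padding contracts are enforced", {
  cs <- bilinear_case()
  expect_error(region_maxima(cs$p, cs$m, epsilon = 100), "epsilon")
  expect_error(region_maxima(cs$p, cs$m, epsilon = 1, grid_n = 10),
               "grid_n")
})

test_that("permanence bounds reproduce the bilinear arithmetic", {
  cs <- bilinear_case(sigma = 0.01)
  b <- persistence_bounds(cs$p, cs$m, epsilon = 0, grid_n = 101)
  # theta = beta k - (mu+gamma) - sigma^2 k^2 / 2 = 5 - 2 - 0.5
  expect_equal(b$theta, 2.5, tolerance = 1e-12)
  expect_equal(b$theta0, 0.05, tolerance = 1e-8)
  expect_equal(b$m_I, 50, tolerance = 1e-8)
  # m_S = Lambda / (beta M_S + mu)
  expect_equal(b$m_S, 100 / (0.05 * 100 + 1), tolerance = 1e-8)
})

test_that("theta reduces to the deterministic growth margin at zero noise", {
  set.seed(31)
  m <- make_incidence("bilinear")
  for (i in 1:10) {
    p <- random_params(R0_range = c(1.1, 3), sigma_max = 0)
    b <- persistence_bounds(p, m, epsilon = 0, grid_n = 101)
    D <- p$mu + p$gamma
    R0 <- basic_reproduction_number(p, m)
    expect_equal(b$theta, D * (R0 - 1), tolerance = 1e-10)
    expect_gt(b$m_S, 0)
  }
})

test_that("an unattainable bound is reported with its diagnostic", {
  p <- model_params(Lambda = 100, beta = 0.05, mu = 1, gamma = 1, sigma = 0.05)
  m <- make_incidence("bilinear")  # noise penalty 12.5 overwhelms theta
  b <- persistence_bounds(p, m, epsilon = 0, grid_n = 101)
  expect_true(is.na(b$m_I))
  expect_match(attr(b$m_I, "reason"), "theta")
  expect_output(print(b), "m_I:")
})

test_that("extinction probability summarises an ensemble with a Wilson interval", {
  p <- model_params(Lambda = 100, beta = 0.015, mu = 1, gamma = 1, sigma = 0.02)
  m <- make_incidence("bilinear")
  cfg <- sim_config(dt = 0.01, n_steps = 2000, seed = 11, n_replicates = 20,
                    extinction_threshold = 0.05)
  ens <- simulate_ensemble(p, m, 50, 50, cfg)
  ep <- extinction_probability(ens)
  expect_identical(ep$fraction, 1)       # far subcritical: all extinct
  expect_identical(ep$n, 20L)
  expect_true(ep$ci[["lower"]] > 0.8 && ep$ci[["upper"]] == 1)
  # at an impossible threshold nothing is extinct
  expect_identical(extinction_probability(ens, threshold = -1)$fraction, 0)
})

test_that("stationary summaries have unit mass and sane moments", {
  tr_const <- stochsis:::new_trajectory(times = seq(0, 10, 0.1),
                                        S = rep(2, 101), I = rep(6, 101),
                                        dt = 0.1, scheme = "t", seed = 1L)
  st <- stationary_estimate(tr_const, burn_in = 2, n_bins = 10)
  expect_equal(sum(st$bin_masses), 1)
  expect_identical(sum(st$bin_masses > 0), 1L)  # single occupied bin
  expect_equal(st$mean_I, 6)
  expect_equal(st$var_I, 0)

  cs <- bilinear_case()
  cfg <- sim_config(dt = 0.01, n_steps = 20000, seed = 13)
  tr <- simulate_sis(cs$p, cs$m, 50, 50, cfg)
  st2 <- stationary_estimate(tr, burn_in = 50, n_bins = 30)
  expect_equal(sum(st2$bin_masses), 1)
  expect_gte(st2$mean_I, min(tr$I))
  expect_lte(st2$mean_I, max(tr$I))
  # persistent regime: the stationary mean sits near the oscillation level
  expect_equal(st2$mean_I, xi_level(cs$p, cs$m), tolerance = 0.15)

  expect_error(stationary_estimate(tr, burn_in = 150), "degenerate window")
  expect_error(stationary_estimate(tr, burn_in = 10, n_bins = 2), "n_bins")
})

test_that("time-averaged classes respect the permanence lower bounds", {
  cs <- bilinear_case(sigma = 0.01)
  b <- persistence_bounds(cs$p, cs$m)
  cfg <- sim_config(dt = 0.01, n_steps = 20000, seed = 17, n_replicates = 10)
  ens <- simulate_ensemble(cs$p, cs$m, 50, 50, cfg)
  expect_gte(mean(ens$mean_I > b$m_I), 0.9)
  expect_true(all(ens$mean_S > b$m_S))
})
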