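test_that("eta follows its closed form and its numerical root oracle", {
  cs0 <- bilinear_case(sigma = 0)
  expect_equal(eta_value(cs0$p, cs0$m), 2 / 0.05)  # (mu+gamma)/beta = 40

  cs <- bilinear_case(sigma = 0.01)
  eta <- eta_value(cs$p, cs$m)
  expect_equal(eta, 4 / (0.05 + sqrt(0.05^2 - 2 * 0.01^2 * 2)),
               tolerance = 1e-14)
  # independent oracle: positive root of g(u) = beta u - (sigma^2/2) u^2 - (mu+gamma)
  g <- function(u) 0.05 * u - (0.01^2 / 2) * u^2 - 2
  eta_oracle <- uniroot(g, c(1e-6, 0.05 / 0.01^2), tol = 1e-12)$root
  expect_equal(eta, eta_oracle, tolerance = 1e-9)
})

test_that("eta stays below the parabola vertex beta/sigma^2", {
  set.seed(17)
  m <- make_incidence("bilinear")
  for (i in 1:25) {
    p <- random_params(R0_range = c(1.2, 4), sigma_max = 0)
    p$sigma <- 0.5 * critical_sigmas(p, m)$sigma_bar
    expect_lt(eta_value(p, m), p$beta / p$sigma^2)
  }
})

test_that("eta errors name the violated hypothesis", {
  m <- make_incidence("bilinear")
  p_alpha <- model_params(Lambda = 100, beta = 0.05, mu = 1, gamma = 1,
                          alpha = 1, sigma = 0.01)
  expect_error(eta_value(p_alpha, m), "alpha = 0")
  p_sub <- model_params(Lambda = 100, beta = 0.015, mu = 1, gamma = 1,
                        sigma = 0.001)  # R0 < 1
  expect_error(eta_value(p_sub, m), "threshold > 1")
})

test_that("the oscillation level matches closed forms for bilinear and standard incidence", {
  # bilinear: u(I) = S0 - I, so xi = S0 - eta
  cs <- bilinear_case(sigma = 0.01)
  expect_equal(xi_level(cs$p, cs$m), 100 - eta_value(cs$p, cs$m),
               tolerance = 1e-8)
  # dense grid scan of u as an independent oracle
  I_grid <- seq(1e-3, 100 - 1e-3, length.out = 100001)
  u <- (100 - I_grid) * I_grid / I_grid
  xi_scan <- I_grid[which.min(abs(u - eta_value(cs$p, cs$m)))]
  expect_equal(xi_level(cs$p, cs$m), xi_scan, tolerance = 1e-3)

  # standard: u(I) = (S0 - I)/S0, so xi = S0 (1 - eta)
  sd <- standard_case(sigma = 0.1)
  eta <- eta_value(sd$p, sd$m)
  expect_equal(xi_level(sd$p, sd$m), 100 * (1 - eta), tolerance = 1e-8)
})

test_that("as noise vanishes the oscillation level reaches the endemic equilibrium", {
  cs0 <- bilinear_case(sigma = 0)
  expect_equal(xi_level(cs0$p, cs0$m),
               endemic_equilibrium(cs0$p, cs0$m)$I_star, tolerance = 1e-8)
  # near-zero noise: gap shrinks like sigma^2 (second-order in sigma)
  sd <- standard_case(sigma = 1e-4)
  expect_equal(xi_level(sd$p, sd$m),
               endemic_equilibrium(sd$p, sd$m)$I_star, tolerance = 1e-6)
})

test_that("the oscillation level decreases in sigma and collapses at sigma_hat", {
  cs <- bilinear_case(sigma = 0)
  curve <- xi_curve(cs$p, cs$m, c(0.005, 0.01, 0.015))
  expect_true(all(diff(curve$xi) < 0))

  # 1 < R0 <= 2: xi -> 0 at the upper end of its domain
  p <- model_params(Lambda = 100, beta = 0.03, mu = 1, gamma = 1)  # R0 = 1.5
  m <- cs$m
  sh <- critical_sigmas(p, m)$sigma_hat
  p$sigma <- 0.999 * sh
  expect_lt(xi_level(p, m), 0.01 * p$S0)

  expect_error(xi_curve(cs$p, cs$m, c(0.005, 2)), "sigma_hat")
  expect_error(xi_curve(cs$p, cs$m, c(0.01, 0.005)), "strictly increasing")
})

test_that("the limiting level xi2 exists exactly when R0 exceeds 2", {
  # bilinear closed form: xi2 = S0 (R0 - 2)/(R0 - 1)
  cs <- bilinear_case(sigma = 0)  # R0 = 2.5
  xi2 <- xi2_limit(cs$p, cs$m)
  expect_equal(xi2, 100 * 0.5 / 1.5, tolerance = 1e-8)

  # boundary R0 = 2: absent, the limit is 0
  p2 <- model_params(Lambda = 100, beta = 0.04, mu = 1, gamma = 1)
  out <- xi2_limit(p2, cs$m)
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "<= 2")

  # always below the endemic level
  set.seed(23)
  for (i in 1:15) {
    p <- random_params(R0_range = c(2.1, 5), sigma_max = 0)
    expect_lt(xi2_limit(p, cs$m), endemic_equilibrium(p, cs$m)$I_star)
  }
})

test_that("long-run simulated prevalence oscillates about xi", {
  cs <- bilinear_case(sigma = 0.01)
  xi <- xi_level(cs$p, cs$m)
  cfg <- sim_config(dt = 0.01, n_steps = 50000, seed = 3, n_replicates = 5)
  ens <- simulate_ensemble(cs$p, cs$m, 50, 50, cfg)
  expect_equal(mean(ens$mean_I), xi, tolerance = 0.15)
})

test_that("the oscillation report bundles all levels consistently", {
  cs <- bilinear_case(sigma = 0.01)
  rep <- oscillation_report(cs$p, cs$m, sigma_grid = c(0.005, 0.01))
  expect_equal(rep$xi, xi_level(cs$p, cs$m))
  expect_gt(rep$I_star, rep$xi)       # 0 < xi < I* for sigma > 0
  expect_lt(rep$xi2, rep$I_star)      # R0 = 2.5 > 2 here
  expect_identical(nrow(rep$curve), 2L)
  expect_output(print(rep), "xi2")
})
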