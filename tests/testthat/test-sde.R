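test_that("the zero-noise step is an explicit Euler step of the deterministic model", {
  cs <- bilinear_case(sigma = 0)
  p <- cs$p; m <- cs$m; dt <- 1e-3
  S <- 50; I <- 50
  f <- m$evaluate(S, I)
  euler <- c(S + (p$Lambda - p$beta * f + p$gamma * I - p$mu * S) * dt,
             I + (p$beta * f - (p$mu + p$gamma) * I) * dt)
  for (variant in c("generalized", "published")) {
    st <- sde_step(S, I, z = 1.7, p, m, dt, variant = variant)
    expect_equal(unname(st), euler)
  }
})

test_that("the disease-free state is invariant under the stochastic step", {
  cs <- bilinear_case(sigma = 0.05)
  st <- sde_step(80, 0, z = -2.1, cs$p, cs$m, dt = 1e-3)
  expect_identical(unname(st[2]), 0)
  expect_equal(unname(st[1]), 80 + (100 - 1 * 80) * 1e-3)
})

test_that("noise cancels in the population total for the generalized scheme", {
  # alpha = 0: S' + I' equals the deterministic N-recursion up to round-off
  cs <- bilinear_case(sigma = 0.04)
  set.seed(5)
  for (i in 1:50) {
    S <- runif(1, 1, 150); I <- runif(1, 1, 150); z <- rnorm(1)
    st <- sde_step(S, I, z, cs$p, cs$m, dt = 1e-3)
    N_exact <- (S + I) + (cs$p$Lambda - cs$p$mu * (S + I)) * 1e-3
    expect_equal(unname(st[1] + st[2]), N_exact, tolerance = 1e-12)
  }
  # the published variant adds the same noise to both equations: no cancelling
  st77 <- sde_step(50, 50, 1.3, cs$p, cs$m, dt = 1e-3, variant = "published")
  expect_gt(abs(st77[1] + st77[2] - (100 + (100 - 100) * 1e-3)), 1e-6)
})

test_that("trajectories are reproducible and ensembles extend simulate", {
  cs <- bilinear_case()
  cfg <- sim_config(dt = 0.01, n_steps = 500, seed = 33)
  t1 <- simulate_sis(cs$p, cs$m, 50, 50, cfg)
  t2 <- simulate_sis(cs$p, cs$m, 50, 50, cfg)
  expect_identical(t1$I, t2$I)
  expect_identical(t1$S, t2$S)

  cfg1 <- sim_config(dt = 0.01, n_steps = 500, seed = 33, n_replicates = 1)
  ens <- simulate_ensemble(cs$p, cs$m, 50, 50, cfg1)
  n <- length(t1$I)
  expect_identical(ens$final_I, t1$I[n])
  expect_identical(ens$final_S, t1$S[n])

  cfg3 <- sim_config(dt = 0.01, n_steps = 500, seed = 33, n_replicates = 3)
  ens3 <- simulate_ensemble(cs$p, cs$m, 50, 50, cfg3)
  expect_identical(ens3$seed, 33:35)
  expect_identical(ens3$final_I[1], t1$I[n])
})

test_that("the zero-noise simulation tracks the ODE solution", {
  cs <- bilinear_case(sigma = 0)
  dt <- 1e-3; T <- 10
  cfg <- sim_config(dt = dt, n_steps = T / dt, seed = 1)
  tr <- simulate_sis(cs$p, cs$m, 50, 50, cfg)
  ode <- integrate_ode(cs$p, cs$m, 50, 50, T = T, dt = dt)
  # explicit Euler vs RK4: global gap O(dt)
  expect_equal(tr$I[length(tr$I)], ode$I[length(ode$I)], tolerance = 10 * dt)
  expect_equal(tr$S[length(tr$S)], ode$S[length(ode$S)], tolerance = 10 * dt)
})

test_that("the population total follows its exact recursion under noise", {
  cs <- bilinear_case(sigma = 0.03)
  cfg <- sim_config(dt = 1e-3, n_steps = 10000, seed = 8)
  tr <- simulate_sis(cs$p, cs$m, 60, 40, cfg)
  N <- tr$S + tr$I
  N_exact <- numeric(length(N))
  N_exact[1] <- 100
  for (k in seq_len(length(N) - 1)) {
    N_exact[k + 1] <- N_exact[k] + (cs$p$Lambda - cs$p$mu * N_exact[k]) * 1e-3
  }
  expect_equal(N, N_exact, tolerance = 1e-10)
})

test_that("with disease-induced death the total stays within its confinement band", {
  p <- model_params(Lambda = 100, beta = 0.05, mu = 1, gamma = 1, alpha = 1,
                    sigma = 0.015)
  m <- make_incidence("bilinear")
  cfg <- sim_config(dt = 0.01, n_steps = 20000, seed = 9)
  tr <- simulate_sis(p, m, p$S0 - 10, 10, cfg)
  N <- tr$S + tr$I
  after <- tr$times > 50
  tol <- 0.01 * p$S0
  inside <- N[after] >= p$S_low - tol & N[after] <= p$S0 + tol
  expect_gte(mean(inside), 0.99)
})

test_that("paired refinements contract at the strong order-one rate", {
  # halving dt roughly halves the gap to a shared-noise finer path
  cs <- bilinear_case()
  p <- cs$p; m <- cs$m
  run_path <- function(z, dt) {
    S <- 50; I <- 50
    for (zk in z) {
      st <- sde_step(S, I, zk, p, m, dt)
      S <- max(st[[1]], 0); I <- max(st[[2]], 0)
    }
    c(S, I)
  }
  T <- 1; dt <- 0.02; n4 <- 4 * T / dt
  set.seed(99)
  g1 <- g2 <- numeric(200)
  for (j in 1:200) {
    zf <- rnorm(n4)
    zh <- (zf[seq(1, n4, 2)] + zf[seq(2, n4, 2)]) / sqrt(2)
    zc <- (zh[seq(1, length(zh), 2)] + zh[seq(2, length(zh), 2)]) / sqrt(2)
    xf <- run_path(zf, dt / 4)
    xh <- run_path(zh, dt / 2)
    xc <- run_path(zc, dt)
    g1[j] <- sum((xc - xh)^2)
    g2[j] <- sum((xh - xf)^2)
  }
  ratio <- sqrt(mean(g1)) / sqrt(mean(g2))
  expect_gte(ratio, 1.5)
  expect_lte(ratio, 2.8)
})

test_that("time averages have the stated elementary properties", {
  tr_const <- stochsis:::new_trajectory(times = 0:10, S = rep(3, 11),
                                        I = rep(7, 11), dt = 1, scheme = "t",
                                        seed = 1L)
  expect_equal(time_average(tr_const), c(mean_S = 3, mean_I = 7))

  # linear series on a uniform grid averages to its midpoint value
  tr_lin <- stochsis:::new_trajectory(times = 0:10, S = 2 * (0:10),
                                      I = 5 + 0:10, dt = 1, scheme = "t",
                                      seed = 1L)
  expect_equal(time_average(tr_lin), c(mean_S = 10, mean_I = 10))
  expect_error(time_average(tr_lin, burn_in = 99), "empty averaging window")
})

test_that("extinction times and positivity policies behave sensibly", {
  # strong noise + subcritical transmission: certain extinction, recorded once
  p <- model_params(Lambda = 100, beta = 0.015, mu = 1, gamma = 1, sigma = 0.02)
  m <- make_incidence("bilinear")
  cfg <- sim_config(dt = 0.01, n_steps = 2000, seed = 2,
                    extinction_threshold = 0.05)
  tr <- simulate_sis(p, m, 50, 50, cfg)
  expect_false(is.na(tr$extinction_time))
  expect_lte(min(tr$I), 0.05)
  expect_true(all(tr$I >= 0) && all(tr$S >= 0))

  cfg_rs <- sim_config(dt = 0.01, n_steps = 2000, seed = 2,
                       extinction_threshold = 0.05,
                       positivity_policy = "reject_resample")
  tr_rs <- simulate_sis(p, m, 50, 50, cfg_rs)
  expect_true(all(tr_rs$I >= 0) && all(tr_rs$S >= 0))

  expect_error(simulate_sis(p, m, 50, 0.01, cfg),
               "below the initial infectious level")
})
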