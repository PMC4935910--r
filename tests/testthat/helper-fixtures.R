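# Shared fixtures: small parameter sets with closed-form references.

# Bilinear reference case: S0 = 100, R0 = 2.5; with sigma = 0.01 the
# oscillation level is xi = 100 - eta.
bilinear_case <- function(sigma = 0.01, beta = 0.05) {
  list(p = model_params(Lambda = 100, beta = beta, mu = 1, gamma = 1,
                        sigma = sigma),
       m = make_incidence("bilinear"))
}

# Standard-incidence case with R0 = beta/(mu+gamma) > 1.
standard_case <- function(sigma = 0, beta = 3) {
  list(p = model_params(Lambda = 100, beta = beta, mu = 1, gamma = 1,
                        sigma = sigma),
       m = make_incidence("standard"))
}

# Random admissible parameter draw (seeded by the caller).
random_params <- function(R0_range = c(0.2, 4), sigma_max = 0.05) {
  Lambda <- runif(1, 50, 500)
  mu <- runif(1, 0.5, 5)
  gamma <- runif(1, 0, 5)
  alpha <- 0
  S0 <- Lambda / mu
  R0 <- runif(1, R0_range[1], R0_range[2])
  beta <- R0 * (mu + gamma + alpha) / S0  # bilinear: k = S0
  model_params(Lambda = Lambda, beta = beta, mu = mu, gamma = gamma,
               alpha = alpha, sigma = runif(1, 0, sigma_max))
}

all_builtin_models <- function() {
  list(
    bilinear = make_incidence("bilinear"),
    standard = make_incidence("standard"),
    saturated = make_incidence("saturated", list(omega = 0.1)),
    beddington_deangelis = make_incidence("beddington_deangelis",
                                          list(omega1 = 1, omega2 = 1))
  )
}
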