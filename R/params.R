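#' Parameter set for the stochastic SIS model
#'
#' Bundles the six rate constants of the SIS model with noisy transmission:
#' susceptibles obey
#' \eqn{dS = (\Lambda - \beta f(S,I) + \gamma I - \mu S)\,dt - \sigma f(S,I)\,dB}
#' and infectives
#' \eqn{dI = (\beta f(S,I) - (\mu+\gamma+\alpha) I)\,dt + \sigma f(S,I)\,dB},
#' where \eqn{f} is a nonlinear incidence function (see [make_incidence()]).
#'
#' Two derived population levels are attached: the disease-free susceptible
#' level `S0 = Lambda/mu` and the lower population bound
#' `S_low = Lambda/(mu+alpha)`; the total population is eventually confined
#' to `[S_low, S0]` (exactly `S0` when `alpha = 0`).
#'
#' @param Lambda recruitment rate of susceptibles (> 0), individuals/time.
#' @param beta transmission coefficient (> 0).
#' @param mu natural death rate (> 0), 1/time.
#' @param gamma recovery (disease contact) rate (>= 0), 1/time.
#' @param alpha disease-induced death rate (>= 0), 1/time.
#' @param sigma intensity of the white-noise perturbation of `beta` (>= 0).
#'
#' @return An object of class `"sis_params"`: a list with the six rates plus
#'   `S0` and `S_low`.
#' @examples
#' p <- model_params(Lambda = 100, beta = 0.05, mu = 1, gamma = 1, sigma = 0.01)
#' p$S0
#' @export
model_params <- function(Lambda, beta, mu, gamma = 0, alpha = 0, sigma = 0) {
  check_scalar(Lambda, "Lambda", 0, strict = TRUE)
  check_scalar(beta, "beta", 0, strict = TRUE)
  check_scalar(mu, "mu", 0, strict = TRUE)
  check_scalar(gamma, "gamma", 0)
  check_scalar(alpha, "alpha", 0)
  check_scalar(sigma, "sigma", 0)
  p <- list(
    Lambda = Lambda, beta = beta, mu = mu, gamma = gamma,
    alpha = alpha, sigma = sigma,
    S0 = Lambda / mu,
    S_low = Lambda / (mu + alpha)
  )
  class(p) <- "sis_params"
  p
}

#' @export
print.sis_params <- function(x, ...) {
  cat("Stochastic SIS model parameters\n")
  cat(sprintf("  Lambda = %g, beta = %g, mu = %g, gamma = %g, alpha = %g, sigma = %g\n",
              x$Lambda, x$beta, x$mu, x$gamma, x$alpha, x$sigma))
  cat(sprintf("  S0 = Lambda/mu = %g;  S_low = Lambda/(mu+alpha) = %g\n",
              x$S0, x$S_low))
  invisible(x)
}

as_sis_params <- function(p) {
  if (inherits(p, "sis_params")) return(p)
  if (is.list(p)) {
    return(model_params(
      Lambda = p$Lambda, beta = p$beta, mu = p$mu,
      gamma = if (is.null(p$gamma)) 0 else p$gamma,
      alpha = if (is.null(p$alpha)) 0 else p$alpha,
      sigma = if (is.null(p$sigma)) 0 else p$sigma
    ))
  }
  stop("'p' must be an 'sis_params' object or a named list", call. = FALSE)
}
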