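#' Integrate the deterministic SIS model
#'
#' Fixed-step 4th-order Runge-Kutta integration (via \pkg{deSolve}) of
#' \deqn{dS/dt = \Lambda - \beta f(S,I) + \gamma I - \mu S,\qquad
#'       dI/dt = \beta f(S,I) - (\mu+\gamma+\alpha) I,}
#' the zero-noise reference for the stochastic model. A fixed step (no
#' adaptivity) keeps runs exactly reproducible and the error contract simple.
#' Any component that undershoots zero is clamped at zero with a warning.
#'
#' @inheritParams basic_reproduction_number
#' @param S_init,I_init initial levels (> 0; `I_init = 0` is allowed and
#'   stays on the disease-free manifold).
#' @param T horizon (> dt).
#' @param dt time step (> 0).
#' @return A `"sis_trajectory"` object (see [simulate_sis()]): list with
#'   `times`, `S`, `I`, `dt` and `scheme = "rk4"`.
#' @examples
#' p <- model_params(Lambda = 100, beta = 0.05, mu = 1, gamma = 1)
#' m <- make_incidence("bilinear")
#' tr <- integrate_ode(p, m, S_init = 50, I_init = 50, T = 200, dt = 0.01)
#' tail(as.data.frame(tr), 1)  # approaches the endemic equilibrium (40, 60)
#' @export
integrate_ode <- function(p, m, S_init, I_init, T, dt) {
  p <- as_sis_params(p)
  stopifnot(inherits(m, "incidence_model"))
  check_scalar(S_init, "S_init", 0, strict = TRUE)
  check_scalar(I_init, "I_init", 0)
  check_scalar(dt, "dt", 0, strict = TRUE)
  if (T <= dt) stop("'T' must exceed 'dt'", call. = FALSE)

  deriv <- function(t, y, parms) {
    f <- m$evaluate(y[1], y[2])
    list(c(
      p$Lambda - p$beta * f + p$gamma * y[2] - p$mu * y[1],
      p$beta * f - (p$mu + p$gamma + p$alpha) * y[2]
    ))
  }
  times <- seq(0, T, by = dt)
  sol <- deSolve::ode(y = c(S = S_init, I = I_init), times = times,
                      func = deriv, parms = NULL, method = "rk4")
  if (any(!is.finite(sol[, -1]))) {
    bad <- which(!is.finite(rowSums(sol[, -1, drop = FALSE])))[1]
    stop(sprintf("integration produced a non-finite state at step %d (t = %g)",
                 bad, sol[bad, 1]), call. = FALSE)
  }
  S <- sol[, "S"]; I <- sol[, "I"]
  if (any(S < 0) || any(I < 0)) {
    warning("trajectory undershot zero; clamping negative values to 0")
    S <- pmax(S, 0); I <- pmax(I, 0)
  }
  new_trajectory(times = sol[, 1], S = S, I = I, dt = dt,
                 scheme = "rk4", seed = NA_integer_)
}

#' Endemic equilibrium of the deterministic model
#'
#' Locates the positive equilibrium \eqn{(S^*, I^*)} of the deterministic
#' model. The 2-D stationarity system is reduced to one dimension through the
#' population balance \eqn{\Lambda - \mu N - \alpha I = 0}, giving
#' \eqn{S(I) = (\Lambda - \alpha I)/\mu - I}; the scalar residual
#' \eqn{\beta f(S(I), I) - (\mu+\gamma+\alpha) I} is then monotone through
#' its root on \eqn{(0, S_{low})} (a consequence of the incidence
#' admissibility conditions), so plain bisection with relative tolerance
#' `1e-10` is reliable. No equilibrium exists when \eqn{R_0 \le 1}.
#'
#' @inheritParams basic_reproduction_number
#' @return An `"equilibrium_result"`: list with `S_star`, `I_star`, `exists`,
#'   and `residual` (absolute value of the stationarity defect at the root).
#' @examples
#' p <- model_params(Lambda = 100, beta = 0.05, mu = 1, gamma = 1)
#' endemic_equilibrium(p, make_incidence("bilinear"))  # S* = 40, I* = 60
#' @export
endemic_equilibrium <- function(p, m) {
  p <- as_sis_params(p)
  stopifnot(inherits(m, "incidence_model"))
  R0 <- basic_reproduction_number(p, m)
  D <- p$mu + p$gamma + p$alpha
  if (R0 <= 1) {
    out <- list(S_star = NA_real_, I_star = NA_real_, exists = FALSE,
                residual = NA_real_, R0 = R0)
    class(out) <- "equilibrium_result"
    return(out)
  }
  S_of_I <- function(I) (p$Lambda - p$alpha * I) / p$mu - I
  # phi(I) = beta * f(S(I), I)/I - D: decreasing, phi(0+) = D (R0 - 1) > 0.
  phi <- function(I) p$beta * m$evaluate(S_of_I(I), I) / I - D
  eps <- 1e-12 * p$S_low
  lo <- eps
  hi <- p$S_low * (1 - 1e-12)
  if (phi(lo) <= 0 || phi(hi) >= 0) {
    stop(sprintf(
      "endemic equilibrium: residual does not bracket a root on (%g, %g) although R0 = %g > 1",
      lo, hi, R0), call. = FALSE)
  }
  I_star <- bisect_decreasing(phi, lo, hi, rel_tol = 1e-10)
  S_star <- S_of_I(I_star)
  out <- list(
    S_star = S_star, I_star = I_star, exists = TRUE,
    residual = abs(p$beta * m$evaluate(S_star, I_star) - D * I_star),
    R0 = R0
  )
  class(out) <- "equilibrium_result"
  out
}

#' @export
print.equilibrium_result <- function(x, ...) {
  if (!x$exists) {
    cat(sprintf("No endemic equilibrium (R0 = %g <= 1)\n", x$R0))
  } else {
    cat(sprintf("Endemic equilibrium: S* = %.8g, I* = %.8g (residual %.3g)\n",
                x$S_star, x$I_star, x$residual))
  }
  invisible(x)
}
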