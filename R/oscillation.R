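# Stochastic oscillation level of the infectious class (no disease-induced
# death). With alpha = 0 the total population settles at S0 = Lambda/mu, the
# infectious dynamics reduce to a scalar problem, and when the noise-modified
# threshold exceeds 1 the trajectory oscillates about the level xi solving
# u(xi) = f(S0 - xi, xi)/xi = eta, where eta is the positive root of
# g(u) = beta*u - (sigma^2/2)*u^2 - (mu + gamma).

check_oscillation_context <- function(p, m) {
  if (p$alpha != 0) {
    stop(paste("oscillation level is only defined for alpha = 0",
               "(no disease-induced death); no formula is available for alpha > 0"),
         call. = FALSE)
  }
  R0t <- stochastic_threshold(p, m, include_alpha = TRUE)
  if (R0t <= 1) {
    stop(sprintf(
      "oscillation level requires the noise-modified threshold > 1 (got %g)",
      R0t), call. = FALSE)
  }
  invisible(R0t)
}

#' Incidence-slope level eta about which log-growth of I vanishes
#'
#' The positive root of \eqn{g(u) = \beta u - (\sigma^2/2)u^2 - (\mu+\gamma)}:
#' \deqn{\eta = \frac{\mu+\gamma}{\beta} \;(\sigma = 0),\qquad
#'       \eta = \frac{2(\mu+\gamma)}{\beta+\sqrt{\beta^2-2\sigma^2(\mu+\gamma)}}
#'       \;(\sigma > 0).}
#' Requires `alpha = 0` and noise-modified threshold > 1 (which also keeps
#' the discriminant positive on the admissible sigma range).
#'
#' @inheritParams basic_reproduction_number
#' @return eta (numeric scalar); satisfies `eta < beta/sigma^2` when
#'   `sigma > 0`.
#' @examples
#' p <- model_params(Lambda = 100, beta = 0.05, mu = 1, gamma = 1, sigma = 0.01)
#' eta_value(p, make_incidence("bilinear"))  # 41.742...
#' @export
eta_value <- function(p, m) {
  p <- as_sis_params(p)
  check_oscillation_context(p, m)
  if (p$sigma == 0) return((p$mu + p$gamma) / p$beta)
  disc <- p$beta^2 - 2 * p$sigma^2 * (p$mu + p$gamma)
  if (disc < 0) {
    stop(sprintf(
      "eta undefined: beta^2 - 2 sigma^2 (mu+gamma) = %g < 0 (sigma too large)",
      disc), call. = FALSE)
  }
  2 * (p$mu + p$gamma) / (p$beta + sqrt(disc))
}

u_of_I <- function(m, S0) {
  function(I) m$evaluate(S0 - I, I) / I
}

xi_root <- function(m, S0, target) {
  u <- u_of_I(m, S0)
  lo <- 1e-12 * S0
  hi <- S0 * (1 - 1e-12)
  if (u(lo) <= target || u(hi) >= target) {
    stop(sprintf(
      "u(I) = f(S0-I, I)/I does not bracket the target level %g on (0, S0): u(0+) = %g, u(S0-) = %g",
      target, u(lo), u(hi)), call. = FALSE)
  }
  bisect_decreasing(function(I) u(I) - target, lo, hi, rel_tol = 1e-10)
}

#' Stochastic oscillation level of the infectious class
#'
#' The unique \eqn{\xi \in (0, S^0)} with
#' \eqn{f(S^0-\xi, \xi)/\xi = \eta} (see [eta_value()]): with no
#' disease-induced death and noise-modified threshold > 1, the infectious
#' class oscillates about \eqn{\xi} (its limsup is >= xi and liminf <= xi
#' almost surely). \eqn{u(I) = f(S^0-I, I)/I} is strictly decreasing on
#' \eqn{(0, S^0)} under the incidence admissibility conditions, so the root
#' is found by bisection on \eqn{(10^{-12}S^0,\,S^0(1-10^{-12}))} to
#' relative tolerance \eqn{10^{-10}}. As \eqn{\sigma \to 0}, \eqn{\xi}
#' increases to the deterministic endemic level \eqn{I^*}.
#'
#' @inheritParams basic_reproduction_number
#' @return xi (numeric scalar in `(0, S0)`).
#' @examples
#' p <- model_params(Lambda = 100, beta = 0.05, mu = 1, gamma = 1, sigma = 0.01)
#' xi_level(p, make_incidence("bilinear"))  # 100 - 41.742 = 58.258
#' @export
xi_level <- function(p, m) {
  p <- as_sis_params(p)
  eta <- eta_value(p, m)
  xi_root(m, p$S0, eta)
}

#' Oscillation level as a function of the noise intensity
#'
#' Evaluates [xi_level()] on a grid of noise intensities; every sigma must
#' lie in \eqn{(0, \hat\sigma)}, the interval on which \eqn{\xi(\sigma)} is
#' defined, and the output is checked to be strictly decreasing (it always
#' is, analytically).
#'
#' @inheritParams basic_reproduction_number
#' @param sigmas increasing vector of noise intensities in `(0, sigma_hat)`.
#' @return data frame with columns `sigma` and `xi`.
#' @export
xi_curve <- function(p, m, sigmas) {
  p <- as_sis_params(p)
  if (p$alpha != 0) check_oscillation_context(p, m)  # uniform error message
  cs <- critical_sigmas(p, m)
  if (is.na(cs$sigma_hat)) {
    stop("xi(sigma) undefined: basic reproduction number (alpha = 0) <= 1",
         call. = FALSE)
  }
  if (any(sigmas <= 0) || any(sigmas >= cs$sigma_hat)) {
    stop(sprintf("all sigma values must lie in (0, sigma_hat = %g)",
                 cs$sigma_hat), call. = FALSE)
  }
  if (is.unsorted(sigmas, strictly = TRUE)) {
    stop("'sigmas' must be strictly increasing", call. = FALSE)
  }
  xi <- vapply(sigmas, function(s) {
    ps <- p; ps$sigma <- s
    xi_level(ps, m)
  }, numeric(1))
  if (any(diff(xi) >= 0)) {
    stop("computed xi(sigma) is not strictly decreasing; numerical failure",
         call. = FALSE)
  }
  data.frame(sigma = sigmas, xi = xi)
}

#' Limiting oscillation level at the upper noise intensity
#'
#' As \eqn{\sigma} increases to \eqn{\hat\sigma}, the oscillation level
#' \eqn{\xi(\sigma)} decreases to 0 when \eqn{1 \le R_0 \le 2}, but to a
#' positive floor \eqn{\xi_2} when \eqn{R_0 > 2}
#' (here \eqn{R_0 = \beta k/(\mu+\gamma)}, \eqn{k = \partial f(S^0,0)/\partial I};
#' alpha = 0 context): \eqn{\xi_2} solves
#' \eqn{f(S^0-\xi_2, \xi_2)/\xi_2 = k/(R_0-1)}. Always \eqn{0 < \xi_2 < I^*}.
#'
#' @inheritParams basic_reproduction_number
#' @return xi2 (numeric scalar), or `NA` with attribute `"reason"` when
#'   `R0 <= 2` (the limit is 0 there).
#' @examples
#' p <- model_params(Lambda = 100, beta = 0.05, mu = 1, gamma = 1)  # R0 = 2.5
#' xi2_limit(p, make_incidence("bilinear"))  # 100 * (2.5-2)/(2.5-1)
#' @export
xi2_limit <- function(p, m) {
  p <- as_sis_params(p)
  if (p$alpha != 0) {
    stop("xi2 is only defined for alpha = 0", call. = FALSE)
  }
  k <- df_dI_at_disease_free(m, p$S0)
  R0 <- p$beta * k / (p$mu + p$gamma)
  if (R0 <= 2) {
    out <- NA_real_
    attr(out, "reason") <-
      sprintf("R0 = %g <= 2: xi(sigma) -> 0 as sigma -> sigma_hat", R0)
    return(out)
  }
  xi_root(m, p$S0, k / (R0 - 1))
}

#' Full oscillation report
#'
#' Bundles [eta_value()], [xi_level()], the deterministic endemic level
#' \eqn{I^*}, the upper noise intensity \eqn{\hat\sigma}, the limiting level
#' \eqn{\xi_2} (when \eqn{R_0 > 2}), and optionally the \eqn{\xi(\sigma)}
#' curve on a grid.
#'
#' @inheritParams basic_reproduction_number
#' @param sigma_grid optional increasing vector in `(0, sigma_hat)` for the
#'   curve.
#' @return An `"oscillation_report"`: list with `eta`, `xi`, `I_star`,
#'   `xi2`, `sigma_hat` and (optionally) `curve`.
#' @export
oscillation_report <- function(p, m, sigma_grid = NULL) {
  p <- as_sis_params(p)
  eta <- eta_value(p, m)
  xi <- xi_level(p, m)
  eq <- endemic_equilibrium(p, m)
  cs <- critical_sigmas(p, m)
  out <- list(
    eta = eta, xi = xi,
    I_star = eq$I_star,
    xi2 = xi2_limit(p, m),
    sigma_hat = cs$sigma_hat,
    sigma = p$sigma,
    curve = if (!is.null(sigma_grid)) xi_curve(p, m, sigma_grid)
  )
  class(out) <- "oscillation_report"
  out
}

#' @export
print.oscillation_report <- function(x, ...) {
  cat("Stochastic oscillation report (alpha = 0)\n")
  cat(sprintf("  eta = %.8g;  xi = %.8g at sigma = %g\n", x$eta, x$xi, x$sigma))
  cat(sprintf("  I* (sigma -> 0 limit) = %.8g;  sigma_hat = %.8g\n",
              x$I_star, x$sigma_hat))
  if (is.na(x$xi2)) {
    cat(sprintf("  xi2: %s\n", attr(x$xi2, "reason")))
  } else {
    cat(sprintf("  xi2 (sigma -> sigma_hat limit) = %.8g\n", x$xi2))
  }
  if (!is.null(x$curve)) {
    cat(sprintf("  xi(sigma) curve: %d points, strictly decreasing\n",
                nrow(x$curve)))
  }
  invisible(x)
}
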