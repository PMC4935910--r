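# Permanence-in-mean lower bounds. The long-run time average of I is bounded
# below by m_I = theta/theta0 whenever the noise-modified threshold exceeds 1,
# where theta collects the linearized growth rate at the disease-free state
# minus the noise penalty, and theta0 involves maxima over the attracting
# region D_eps = {S, I > 0, S_low - eps <= S + I <= S0 + eps} of two
# derivative functionals of the incidence. The time average of S is bounded
# below by m_S = Lambda/(beta*M_S + mu) with M_S the region maximum of f/S.

#' Region maxima of the incidence derivative functionals
#'
#' Maximizes, over a grid of the attracting region
#' \eqn{D_\epsilon = \{S, I > 0,\; S_{low}-\epsilon \le S+I \le S^0+\epsilon\}},
#' the three functionals
#' \deqn{M_1 = \max\left|\frac1I\frac{\partial f}{\partial I}-\frac{f}{I^2}\right|,
#'  \quad M_2 = \max \frac1I \frac{\partial f}{\partial S},
#'  \quad M_S = \max \frac{f}{S}.}
#' All three are finite for admissible incidences (the integrands extend
#' continuously to the boundary). The \eqn{I = 0} edge is handled by
#' evaluation at \eqn{I = 10^{-6} S^0} (equivalent, to that tolerance, to the
#' second-derivative limit values and applicable to opaque custom
#' incidences); the \eqn{S = 0} edge of \eqn{f/S} uses the analytic limit
#' \eqn{f/S \to \partial f(0,I)/\partial S} when analytic derivatives are
#' available, small-S evaluation otherwise.
#'
#' Grid maximization (default 401 x 401) is used instead of symbolic
#' optimization so that custom incidences are supported; closed forms for the
#' built-in families serve as test oracles.
#'
#' @inheritParams basic_reproduction_number
#' @param epsilon region padding (>= 0, with `S_low - epsilon > 0`).
#' @param grid_n grid resolution per axis (>= 50).
#' @return list with `M1`, `M2`, `M_S`.
#' @examples
#' p <- model_params(Lambda = 100, beta = 0.05, mu = 1, gamma = 1)
#' region_maxima(p, make_incidence("bilinear"), epsilon = 0)  # M1=0, M2=1, M_S=100
#' @export
region_maxima <- function(p, m, epsilon = 0.01 * p$S0, grid_n = 401L) {
  p <- as_sis_params(p)
  stopifnot(inherits(m, "incidence_model"))
  check_scalar(epsilon, "epsilon", 0)
  if (grid_n < 50L) stop("'grid_n' must be >= 50", call. = FALSE)
  if (p$S_low - epsilon <= 0) {
    stop(sprintf("'epsilon' too large: S_low - epsilon = %g must be positive",
                 p$S_low - epsilon), call. = FALSE)
  }

  upper <- p$S0 + epsilon
  lower <- p$S_low - epsilon
  i_small <- 1e-6 * p$S0
  s_small <- 1e-6 * p$S0

  s_grid <- seq(0, upper, length.out = grid_n)
  i_grid <- seq(0, upper, length.out = grid_n)
  i_grid[1L] <- i_small                      # small-I boundary row
  s_interior <- replace(s_grid, 1L, s_small) # S > 0 version for f/I terms

  G <- expand.grid(S = s_interior, I = i_grid)
  keep <- (G$S + G$I >= lower * (1 - 1e-12)) & (G$S + G$I <= upper * (1 + 1e-12))
  G <- G[keep, ]

  fI <- m$dI(G$S, G$I)
  fS <- m$dS(G$S, G$I)
  fv <- m$evaluate(G$S, G$I)
  h1 <- abs(fI / G$I - fv / G$I^2)
  h2 <- fS / G$I
  bad <- !is.finite(h1) | !is.finite(h2)
  if (any(bad)) {
    j <- which(bad)[1]
    stop(sprintf("non-finite derivative functional at grid point S = %g, I = %g",
                 G$S[j], G$I[j]), call. = FALSE)
  }
  M1 <- max(h1)
  M2 <- max(h2)

  # f/S, including the S = 0 edge via the derivative limit where possible
  GS <- expand.grid(S = s_grid, I = i_grid)
  keep <- (GS$S + GS$I >= lower * (1 - 1e-12)) & (GS$S + GS$I <= upper * (1 + 1e-12))
  GS <- GS[keep, ]
  on_edge <- GS$S == 0
  ratio <- numeric(nrow(GS))
  if (any(!on_edge)) {
    ratio[!on_edge] <- m$evaluate(GS$S[!on_edge], GS$I[!on_edge]) / GS$S[!on_edge]
  }
  if (any(on_edge)) {
    ratio[on_edge] <- if (m$has_analytic_derivatives) {
      m$dS(0, GS$I[on_edge])
    } else {
      m$evaluate(s_small, GS$I[on_edge]) / s_small
    }
  }
  if (any(!is.finite(ratio))) {
    j <- which(!is.finite(ratio))[1]
    stop(sprintf("non-finite f/S at grid point S = %g, I = %g",
                 GS$S[j], GS$I[j]), call. = FALSE)
  }
  M_S <- max(ratio)

  list(M1 = M1, M2 = M2, M_S = M_S)
}

#' Permanence-in-mean lower bounds
#'
#' Computes the almost-sure lower bounds on long-run time averages:
#' \deqn{m_I = \theta/\theta_0,\qquad
#'       \theta = \beta k - (\mu+\gamma+\alpha) - \tfrac12\sigma^2 k_\epsilon^2,
#'       \qquad \theta_0 = \beta\left(M_1 + M_2\,\frac{\mu+\alpha}{\mu}\right),}
#' with \eqn{k = \partial f(S^0,0)/\partial I},
#' \eqn{k_\epsilon = \partial f(S^0+\epsilon,0)/\partial I} and
#' \eqn{M_1, M_2} from [region_maxima()]; and
#' \deqn{m_S = \Lambda/(\beta M_S + \mu).}
#' `m_I` is meaningful only when \eqn{\theta > 0}, which for small
#' \eqn{\epsilon} is the permanence condition (noise-modified threshold > 1);
#' at \eqn{\sigma = 0}, \eqn{\theta = (\mu+\gamma+\alpha)(R_0-1)}. The proof
#' region padding \eqn{\epsilon} is exposed as a parameter since \eqn{\theta}
#' shrinks with it; its sensitivity `d_theta_d_epsilon_penalty` (the noise
#' penalty gap between \eqn{k_\epsilon} and \eqn{k}) is reported.
#'
#' @inheritParams region_maxima
#' @return A `"persistence_bounds"` object: list with `epsilon`, `M1`, `M2`,
#'   `M_S`, `theta`, `theta0`, `m_I` (`NA` with reason if `theta <= 0`),
#'   `m_S`, `grid_n`.
#' @examples
#' p <- model_params(Lambda = 100, beta = 0.05, mu = 1, gamma = 1, sigma = 0.01)
#' persistence_bounds(p, make_incidence("bilinear"), epsilon = 0)$m_I  # 50
#' @export
persistence_bounds <- function(p, m, epsilon = 0.01 * p$S0, grid_n = 401L) {
  p <- as_sis_params(p)
  mx <- region_maxima(p, m, epsilon = epsilon, grid_n = grid_n)
  k <- df_dI_at_disease_free(m, p$S0)
  k_eps <- df_dI_at_disease_free(m, p$S0 + epsilon)
  D <- p$mu + p$gamma + p$alpha
  theta <- p$beta * k - D - 0.5 * p$sigma^2 * k_eps^2
  theta0 <- p$beta * (mx$M1 + mx$M2 * (p$mu + p$alpha) / p$mu)
  m_I <- if (theta > 0) theta / theta0 else {
    x <- NA_real_
    attr(x, "reason") <- sprintf(
      "theta = %g <= 0: noise-modified threshold <= 1 or epsilon too large",
      theta)
    x
  }
  out <- list(
    epsilon = epsilon,
    M1 = mx$M1, M2 = mx$M2, M_S = mx$M_S,
    theta = theta, theta0 = theta0,
    m_I = m_I,
    m_S = p$Lambda / (p$beta * mx$M_S + p$mu),
    d_theta_d_epsilon_penalty = 0.5 * p$sigma^2 * (k_eps^2 - k^2),
    grid_n = as.integer(grid_n)
  )
  class(out) <- "persistence_bounds"
  out
}

#' @export
print.persistence_bounds <- function(x, ...) {
  cat(sprintf("Permanence-in-mean bounds (epsilon = %g, grid %d x %d)\n",
              x$epsilon, x$grid_n, x$grid_n))
  cat(sprintf("  M1 = %.8g, M2 = %.8g, M_S = %.8g\n", x$M1, x$M2, x$M_S))
  cat(sprintf("  theta = %.8g, theta0 = %.8g\n", x$theta, x$theta0))
  if (is.na(x$m_I)) {
    cat(sprintf("  m_I: %s\n", attr(x$m_I, "reason")))
  } else {
    cat(sprintf("  m_I = %.8g (lower bound on time-averaged I)\n", x$m_I))
  }
  cat(sprintf("  m_S = %.8g (lower bound on time-averaged S)\n", x$m_S))
  invisible(x)
}

#' Empirical extinction probability of an ensemble
#'
#' Fraction of replicates whose final infectious level is at or below a
#' threshold, with a 95% Wilson score interval.
#'
#' @param ens an `"ensemble_summary"` from [simulate_ensemble()].
#' @param threshold extinction level; defaults to the ensemble's own
#'   threshold.
#' @return list with `fraction`, `n`, `ci` (Wilson 95% bounds).
#' @export
extinction_probability <- function(ens, threshold = NULL) {
  stopifnot(inherits(ens, "ensemble_summary"))
  if (nrow(ens) == 0L) stop("empty ensemble", call. = FALSE)
  if (is.null(threshold)) threshold <- attr(ens, "extinction_threshold")
  k <- sum(ens$final_I <= threshold)
  list(fraction = k / nrow(ens), n = nrow(ens),
       ci = wilson_interval(k, nrow(ens)))
}

#' Empirical stationary summary of the infectious class
#'
#' Normalized histogram and moments of I over the post-burn-in window of a
#' trajectory: the empirical analogue of the stationary distribution that
#' exists whenever the noise-modified threshold exceeds 1 (the time average
#' of any functional converges to its stationary expectation).
#'
#' @param traj a `"sis_trajectory"`.
#' @param burn_in discarded initial time span; the horizon must be at least
#'   `2 * burn_in`.
#' @param n_bins histogram resolution (>= 5).
#' @return A `"stationary_estimate"`: list with `bin_edges`, `bin_masses`
#'   (summing to 1), `mean_I`, `var_I`, `burn_in`, `horizon`.
#' @export
stationary_estimate <- function(traj, burn_in, n_bins = 50L) {
  stopifnot(inherits(traj, "sis_trajectory"))
  horizon <- max(traj$times)
  if (horizon < 2 * burn_in) {
    stop(sprintf("degenerate window: horizon %g < 2 * burn_in = %g",
                 horizon, 2 * burn_in), call. = FALSE)
  }
  if (n_bins < 5L) stop("'n_bins' must be >= 5", call. = FALSE)
  I <- traj$I[traj$times >= burn_in]
  rng <- range(I)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) * max(1e-8, abs(rng[1]) * 1e-8)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(I, edges, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  out <- list(
    bin_edges = edges,
    bin_masses = counts / length(I),
    mean_I = mean(I),
    var_I = stats::var(I),
    burn_in = burn_in,
    horizon = horizon
  )
  class(out) <- "stationary_estimate"
  out
}

#' @export
print.stationary_estimate <- function(x, ...) {
  cat(sprintf("Stationary summary of I over t in [%g, %g]\n",
              x$burn_in, x$horizon))
  cat(sprintf("  mean_I = %.6g, var_I = %.6g, %d bins on [%.6g, %.6g]\n",
              x$mean_I, x$var_I, length(x$bin_masses),
              min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}
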