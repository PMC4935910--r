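#' Simulation configuration
#'
#' Settings for the Milstein-type discretization of the stochastic model.
#'
#' @param dt time step (> 0; default `1e-3`).
#' @param n_steps number of steps (>= 1).
#' @param seed integer seed; replicate `r` of an ensemble uses `seed + r - 1`
#'   so that a one-replicate ensemble reproduces [simulate_sis()] exactly.
#' @param n_replicates ensemble size (>= 1).
#' @param extinction_threshold level at/below which the infectious class is
#'   recorded as extinct; `NULL` (default) resolves to `1e-6 * I_init` at
#'   simulation time.
#' @param scheme_variant `"generalized"` (default) or `"published"`.
#'   The generalized scheme follows the model equations: noise enters with
#'   opposite signs on S and I (so the total population N = S + I feels no
#'   noise) and the I drift includes the disease-induced death rate `alpha`.
#'   `"published"` is the published discretization kept verbatim for
#'   replication: the same noise increment is *added* to both equations and
#'   `alpha` is omitted from the I drift.
#' @param positivity_policy `"clamp"` (default: a negative component is set
#'   to 0, matching the absorbing interpretation of extinction) or
#'   `"reject_resample"` (redraw the normal deviate up to 100 times, then
#'   clamp with a warning).
#' @return A `"sim_config"` list.
#' @export
sim_config <- function(dt = 1e-3, n_steps, seed = 1L, n_replicates = 1L,
                       extinction_threshold = NULL,
                       scheme_variant = c("generalized", "published"),
                       positivity_policy = c("clamp", "reject_resample")) {
  check_scalar(dt, "dt", 0, strict = TRUE)
  check_scalar(n_steps, "n_steps", 1)
  check_scalar(seed, "seed")
  check_scalar(n_replicates, "n_replicates", 1)
  if (!is.null(extinction_threshold)) {
    check_scalar(extinction_threshold, "extinction_threshold", 0)
  }
  cfg <- list(
    dt = dt, n_steps = as.integer(n_steps), seed = as.integer(seed),
    n_replicates = as.integer(n_replicates),
    extinction_threshold = extinction_threshold,
    scheme_variant = match.arg(scheme_variant),
    positivity_policy = match.arg(positivity_policy)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' One step of the Milstein-type discretization
#'
#' Advances the state by one step of the order-1 scheme. With
#' \eqn{F = f(S_k, I_k)} and noise increment
#' \eqn{W_k = \sigma z_k \sqrt{\Delta t} + \tfrac12 \sigma^2 (z_k^2-1)\Delta t}
#' (the \eqn{\tfrac12\sigma^2(z^2-1)\Delta t} term is the Milstein
#' correction), the `"generalized"` variant computes
#' \deqn{S_{k+1} = S_k + (\Lambda - \beta F + \gamma I_k - \mu S_k)\Delta t - F W_k,}
#' \deqn{I_{k+1} = I_k + (\beta F - (\mu+\gamma+\alpha) I_k)\Delta t + F W_k,}
#' so for `alpha = 0` the noise cancels exactly in \eqn{N = S + I} and
#' \eqn{N_{k+1} = N_k + (\Lambda - \mu N_k)\Delta t}. The `"published"`
#' variant adds \eqn{+F W_k} to both equations and omits `alpha` from the I
#' drift, as printed in the source discretization.
#'
#' @param S,I current state (>= 0; the incidence is 0 when `S + I = 0`).
#' @param z standard normal draw.
#' @inheritParams basic_reproduction_number
#' @param dt time step (> 0).
#' @param variant `"generalized"` or `"published"`.
#' @return numeric vector `c(S_next, I_next)` (possibly negative; positivity
#'   policies are applied by [simulate_sis()], not here).
#' @examples
#' p <- model_params(Lambda = 100, beta = 0.05, mu = 1, gamma = 1, sigma = 0.01)
#' sde_step(50, 50, z = 0.3, p, make_incidence("bilinear"), dt = 1e-3)
#' @export
sde_step <- function(S, I, z, p, m, dt,
                     variant = c("generalized", "published")) {
  p <- as_sis_params(p)
  variant <- match.arg(variant)
  f <- m$evaluate(S, I)
  W <- p$sigma * z * sqrt(dt) + 0.5 * p$sigma^2 * (z^2 - 1) * dt
  if (variant == "generalized") {
    S_next <- S + (p$Lambda - p$beta * f + p$gamma * I - p$mu * S) * dt - f * W
    I_next <- I + (p$beta * f - (p$mu + p$gamma + p$alpha) * I) * dt + f * W
  } else {
    S_next <- S + (p$Lambda - p$beta * f + p$gamma * I - p$mu * S) * dt + f * W
    I_next <- I + (p$beta * f - (p$mu + p$gamma) * I) * dt + f * W
  }
  if (!is.finite(S_next) || !is.finite(I_next)) {
    stop(sprintf("sde_step produced a non-finite state (S = %g, I = %g, z = %g)",
                 S, I, z), call. = FALSE)
  }
  c(S_next = S_next, I_next = I_next)
}

#' Simulate one trajectory of the stochastic SIS model
#'
#' Iterates [sde_step()] with i.i.d. standard normal draws from a seeded
#' generator. Trajectories are reproducible bit-for-bit given
#' `(seed, cfg, params)`. The first time the infectious class falls to or
#' below the extinction threshold is recorded (simulation continues past it).
#'
#' @inheritParams basic_reproduction_number
#' @param S_init,I_init positive initial levels.
#' @param cfg a [sim_config()].
#' @return A `"sis_trajectory"`: list with `times`, `S`, `I`, `dt`, `seed`,
#'   `scheme`, `extinction_time` (`NA` if never reached) and
#'   `extinction_threshold`. Convert with `as.data.frame()` (columns
#'   `time, S, I, N`).
#' @examples
#' p <- model_params(Lambda = 100, beta = 0.05, mu = 1, gamma = 1, sigma = 0.01)
#' cfg <- sim_config(dt = 0.01, n_steps = 1000, seed = 7)
#' tr <- simulate_sis(p, make_incidence("bilinear"), 50, 50, cfg)
#' time_average(tr, burn_in = 5)
#' @export
simulate_sis <- function(p, m, S_init, I_init, cfg) {
  p <- as_sis_params(p)
  stopifnot(inherits(m, "incidence_model"), inherits(cfg, "sim_config"))
  check_scalar(S_init, "S_init", 0, strict = TRUE)
  check_scalar(I_init, "I_init", 0, strict = TRUE)
  threshold <- if (is.null(cfg$extinction_threshold)) 1e-6 * I_init
               else cfg$extinction_threshold
  if (threshold >= I_init) {
    stop("extinction_threshold must be below the initial infectious level",
         call. = FALSE)
  }

  n <- cfg$n_steps
  dt <- cfg$dt
  sqdt <- sqrt(dt)
  sig <- p$sigma
  Lam <- p$Lambda; bet <- p$beta; gam <- p$gamma; mu <- p$mu
  DI <- mu + gam + if (cfg$scheme_variant == "generalized") p$alpha else 0
  noise_sign_S <- if (cfg$scheme_variant == "generalized") -1 else 1
  feval <- if (!is.null(m$evaluate1)) m$evaluate1 else m$evaluate
  resample <- cfg$positivity_policy == "reject_resample"

  S <- numeric(n + 1L); I <- numeric(n + 1L)
  S[1L] <- S_init; I[1L] <- I_init
  set.seed(cfg$seed)
  z <- stats::rnorm(n)
  extinction_idx <- NA_integer_
  clamped <- FALSE

  for (k in seq_len(n)) {
    s <- S[k]; i <- I[k]
    zk <- z[k]
    for (attempt in 0:100) {
      f <- feval(s, i)
      W <- sig * zk * sqdt + 0.5 * sig^2 * (zk * zk - 1) * dt
      s2 <- s + (Lam - bet * f + gam * i - mu * s) * dt + noise_sign_S * f * W
      i2 <- i + (bet * f - DI * i) * dt + f * W
      if ((s2 >= 0 && i2 >= 0) || !resample || attempt == 100L) break
      zk <- stats::rnorm(1)
    }
    if (!is.finite(s2) || !is.finite(i2)) {
      stop(sprintf("simulation produced a non-finite state at step %d (S = %g, I = %g, z = %g)",
                   k, s, i, zk), call. = FALSE)
    }
    if (s2 < 0) { s2 <- 0; clamped <- TRUE }
    if (i2 < 0) { i2 <- 0; clamped <- TRUE }
    S[k + 1L] <- s2; I[k + 1L] <- i2
    if (is.na(extinction_idx) && i2 <= threshold) extinction_idx <- k + 1L
  }
  if (clamped && resample) {
    warning("resampling exhausted at some steps; state clamped at 0")
  }

  times <- dt * (0:n)
  new_trajectory(times = times, S = S, I = I, dt = dt,
                 scheme = cfg$scheme_variant, seed = cfg$seed,
                 extinction_time = if (is.na(extinction_idx)) NA_real_
                                   else times[extinction_idx],
                 extinction_threshold = threshold)
}

#' Simulate a seeded ensemble of trajectories
#'
#' Runs `cfg$n_replicates` independent trajectories; replicate `r` uses seed
#' `cfg$seed + r - 1`, making the whole ensemble deterministic given `cfg`.
#'
#' @inheritParams simulate_sis
#' @param avg_window_start start of the time-averaging window; default half
#'   the horizon.
#' @return An `"ensemble_summary"`: data frame with one row per replicate
#'   (`seed`, `final_S`, `final_I`, `extinct`, `extinction_time`, `mean_S`,
#'   `mean_I`), with the configuration and threshold in attributes.
#' @examples
#' p <- model_params(Lambda = 100, beta = 0.05, mu = 1, gamma = 1, sigma = 0.01)
#' cfg <- sim_config(dt = 0.01, n_steps = 500, seed = 1, n_replicates = 4)
#' simulate_ensemble(p, make_incidence("bilinear"), 50, 50, cfg)
#' @export
simulate_ensemble <- function(p, m, S_init, I_init, cfg,
                              avg_window_start = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  horizon <- cfg$dt * cfg$n_steps
  if (is.null(avg_window_start)) avg_window_start <- horizon / 2
  rows <- vector("list", cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r - 1L
    cfg_r$n_replicates <- 1L
    tr <- simulate_sis(p, m, S_init, I_init, cfg_r)
    avg <- time_average(tr, burn_in = avg_window_start)
    nfin <- length(tr$I)
    rows[[r]] <- data.frame(
      seed = cfg_r$seed,
      final_S = tr$S[nfin],
      final_I = tr$I[nfin],
      extinct = tr$I[nfin] <= tr$extinction_threshold,
      extinction_time = tr$extinction_time,
      mean_S = avg[["mean_S"]],
      mean_I = avg[["mean_I"]]
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- cfg
  attr(out, "extinction_threshold") <-
    if (is.null(cfg$extinction_threshold)) 1e-6 * I_init
    else cfg$extinction_threshold
  attr(out, "avg_window_start") <- avg_window_start
  class(out) <- c("ensemble_summary", "data.frame")
  out
}

#' Time average of a trajectory after a burn-in
#'
#' Discrete analogue of \eqn{(1/t)\int_0^t X(s)\,ds} restricted to times
#' `>= burn_in`: the arithmetic mean of the stored series over the window.
#'
#' @param traj a `"sis_trajectory"`.
#' @param burn_in window start (must leave a nonempty window).
#' @return named numeric vector `c(mean_S = ..., mean_I = ...)`.
#' @export
time_average <- function(traj, burn_in = 0) {
  stopifnot(inherits(traj, "sis_trajectory"))
  keep <- traj$times >= burn_in
  if (!any(keep)) {
    stop(sprintf("empty averaging window: burn_in = %g exceeds the horizon %g",
                 burn_in, max(traj$times)), call. = FALSE)
  }
  c(mean_S = mean(traj$S[keep]), mean_I = mean(traj$I[keep]))
}

new_trajectory <- function(times, S, I, dt, scheme, seed,
                           extinction_time = NA_real_,
                           extinction_threshold = NA_real_) {
  stopifnot(length(times) == length(S), length(S) == length(I))
  out <- list(times = as.numeric(times), S = as.numeric(S), I = as.numeric(I),
              dt = dt, scheme = scheme, seed = seed,
              extinction_time = extinction_time,
              extinction_threshold = extinction_threshold)
  class(out) <- "sis_trajectory"
  out
}

#' @export
as.data.frame.sis_trajectory <- function(x, ...) {
  data.frame(time = x$times, S = x$S, I = x$I, N = x$S + x$I)
}

#' @export
print.sis_trajectory <- function(x, ...) {
  cat(sprintf("SIS trajectory: %d points, dt = %g, scheme = %s, seed = %s\n",
              length(x$times), x$dt, x$scheme,
              ifelse(is.na(x$seed), "-", x$seed)))
  cat(sprintf("  final state: S = %.6g, I = %.6g\n",
              x$S[length(x$S)], x$I[length(x$I)]))
  if (!is.na(x$extinction_time)) {
    cat(sprintf("  I first reached the extinction threshold (%.3g) at t = %g\n",
                x$extinction_threshold, x$extinction_time))
  }
  invisible(x)
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("SIS ensemble: %d replicates, %d steps of dt = %g (%s scheme)\n",
              nrow(x), cfg$n_steps, cfg$dt, cfg$scheme_variant))
  cat(sprintf("  extinct: %d/%d; mean final I = %.6g; mean time-averaged I = %.6g\n",
              sum(x$extinct), nrow(x), mean(x$final_I), mean(x$mean_I)))
  invisible(x)
}
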