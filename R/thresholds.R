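#' Basic reproduction number of the deterministic SIS model
#'
#' \eqn{R_0 = \beta\,\partial f(S^0,0)/\partial I\,/\,(\mu+\gamma+\alpha)}
#' with \eqn{S^0 = \Lambda/\mu}: the expected number of secondary cases per
#' case at the disease-free state. For the noise-free model the disease dies
#' out when \eqn{R_0 \le 1} and persists when \eqn{R_0 > 1}.
#'
#' @param p an `sis_params` object ([model_params()]).
#' @param m an `incidence_model` ([make_incidence()]).
#' @return `R0` (numeric scalar).
#' @examples
#' p <- model_params(Lambda = 2000, beta = 0.60, mu = 11, gamma = 13, alpha = 2)
#' m <- make_incidence("saturated", list(omega = 0.1))
#' basic_reproduction_number(p, m)  # 4.1958...
#' @export
basic_reproduction_number <- function(p, m) {
  p <- as_sis_params(p)
  k <- df_dI_at_disease_free(m, p$S0)
  p$beta * k / (p$mu + p$gamma + p$alpha)
}

#' Noise-modified reproduction threshold
#'
#' The stochastic threshold
#' \deqn{\tilde R_0 = \frac{\beta k}{D} - \frac{\sigma^2 k^2}{2 D},\qquad
#'       k = \partial f(S^0,0)/\partial I,\; D = \mu+\gamma+\alpha,}
#' which replaces \eqn{R_0} once the transmission coefficient carries white
#' noise of intensity \eqn{\sigma}: \eqn{\tilde R_0 > 1} gives permanence in
#' the mean, \eqn{\tilde R_0 < 1} (with the side condition
#' \eqn{\sigma^2 \le \beta/k}) gives extinction with probability one.
#' `include_alpha = FALSE` drops \eqn{\alpha} from `D` in both terms; this
#' variant exists to reproduce reported example values computed without the
#' disease-induced death rate in the denominators.
#'
#' @inheritParams basic_reproduction_number
#' @param include_alpha include `alpha` in the rate denominator (default TRUE).
#' @return the threshold (numeric scalar). Equals `R0` when `sigma = 0`.
#' @examples
#' p <- model_params(Lambda = 2000, beta = 0.9, mu = 30, gamma = 12, sigma = 0.09)
#' stochastic_threshold(p, make_incidence("saturated", list(omega = 0.1)))  # 1
#' @export
stochastic_threshold <- function(p, m, include_alpha = TRUE) {
  p <- as_sis_params(p)
  k <- df_dI_at_disease_free(m, p$S0)
  D <- p$mu + p$gamma + if (include_alpha) p$alpha else 0
  p$beta * k / D - p$sigma^2 * k^2 / (2 * D)
}

#' Critical noise intensities
#'
#' Computes the noise intensities at which the qualitative behaviour of the
#' model changes (`k` denotes \eqn{\partial f(S^0,0)/\partial I}):
#' \describe{
#'   \item{`sigma_bar`}{\eqn{\bar\sigma = \sqrt{2(\mu+\gamma+\alpha)(R_0-1)}/k},
#'     the root of \eqn{\tilde R_0 = 1}; defined only when \eqn{R_0 > 1}.}
#'   \item{`sigma1`}{\eqn{\beta/\sqrt{2(\mu+\gamma+\alpha)}}; above it the
#'     noise alone forces extinction.}
#'   \item{`sigma2`}{\eqn{\beta/k}; the level entering extinction condition
#'     (a), which requires \eqn{\sigma^2 \le \beta/k}.}
#'   \item{`sigma_hat`}{\eqn{\hat\sigma = \sqrt{2(\mu+\gamma)(R_0^{(\alpha=0)}-1)}/k}
#'     with \eqn{R_0^{(\alpha=0)} = \beta k/(\mu+\gamma)}: the upper end of the
#'     interval on which the oscillation level \eqn{\xi(\sigma)} is defined
#'     (no disease-induced death context); defined only when that
#'     reproduction number exceeds 1.}
#' }
#' One has \eqn{\sigma_1 \le \sigma_2} iff \eqn{R_0 \le 2}, and
#' \eqn{\bar\sigma} always lies between them.
#'
#' @inheritParams basic_reproduction_number
#' @return list with `sigma_bar`, `sigma1`, `sigma2`, `sigma_hat`; undefined
#'   entries are `NA` with an explanatory attribute `"reason"`.
#' @examples
#' p <- model_params(Lambda = 2000, beta = 0.9, mu = 30, gamma = 12, sigma = 0.09)
#' critical_sigmas(p, make_incidence("saturated", list(omega = 1)))$sigma_bar  # 0.09
#' @export
critical_sigmas <- function(p, m) {
  p <- as_sis_params(p)
  k <- df_dI_at_disease_free(m, p$S0)
  D <- p$mu + p$gamma + p$alpha
  R0 <- p$beta * k / D

  sigma_bar <- if (R0 > 1) sqrt(2 * D * (R0 - 1)) / k else {
    x <- NA_real_
    attr(x, "reason") <- "sigma_bar undefined: R0 <= 1"
    x
  }
  if (R0 == 1) sigma_bar <- 0

  R0_no_alpha <- p$beta * k / (p$mu + p$gamma)
  sigma_hat <- if (R0_no_alpha > 1) {
    sqrt(2 * (p$mu + p$gamma) * (R0_no_alpha - 1)) / k
  } else {
    x <- NA_real_
    attr(x, "reason") <- "sigma_hat undefined: beta*k/(mu+gamma) <= 1"
    x
  }

  list(
    sigma_bar = sigma_bar,
    sigma1 = p$beta / sqrt(2 * D),
    sigma2 = p$beta / k,
    sigma_hat = sigma_hat
  )
}

#' Classify the dynamical regime of the stochastic SIS model
#'
#' Evaluates the extinction and permanence conditions and returns a labelled
#' report. With \eqn{k = \partial f(S^0,0)/\partial I} and
#' \eqn{D = \mu+\gamma+\alpha}, the two sufficient extinction conditions are
#' (a) \eqn{\sigma^2 \le \beta/k} together with \eqn{\tilde R_0 < 1}, and
#' (b) \eqn{\sigma^2 > \beta^2/(2D)}; \eqn{\tilde R_0 > 1} gives permanence
#' in the mean and (by positive recurrence) a unique stationary distribution.
#' Labels:
#' \describe{
#'   \item{`extinct_any_sigma`}{\eqn{R_0 \le 1}: extinction for every noise
#'     intensity.}
#'   \item{`permanent_in_mean`}{\eqn{\tilde R_0 > 1} (stationary-distribution
#'     flag set).}
#'   \item{`certain_extinction_a` / `certain_extinction_b`}{condition (a)
#'     resp. (b) holds.}
#'   \item{`conjectured_extinction_band`}{\eqn{R_0 > 2} with
#'     \eqn{\bar\sigma \le \sigma \le \sigma_1} but neither (a) nor (b):
#'     extinction is conjectured (supported numerically), not proved.}
#'   \item{`boundary`}{\eqn{\tilde R_0 = 1} (equivalently
#'     \eqn{\sigma = \bar\sigma}) to relative tolerance `1e-9`.}
#'   \item{`indeterminate`}{none of the above.}
#' }
#'
#' @inheritParams basic_reproduction_number
#' @return An object of class `"threshold_report"`: list with `R0`,
#'   `R0_tilde`, `R0_tilde_no_alpha`, the critical sigmas, `regime`,
#'   `stationary_distribution` flag and a named `margins` list of signed
#'   condition margins (`beta/k - sigma^2`, `sigma^2 - beta^2/(2D)`, the
#'   alpha-excluded variant of the latter, `R0_tilde - 1`,
#'   `sigma - sigma_bar`, `sigma1 - sigma`).
#' @examples
#' p <- model_params(Lambda = 2000, beta = 0.60, mu = 11, gamma = 13,
#'                   alpha = 2, sigma = 0.075)
#' classify_regime(p, make_incidence("saturated", list(omega = 0.1)))
#' @export
classify_regime <- function(p, m) {
  p <- as_sis_params(p)
  k <- df_dI_at_disease_free(m, p$S0)
  D <- p$mu + p$gamma + p$alpha
  R0 <- basic_reproduction_number(p, m)
  R0t <- stochastic_threshold(p, m, include_alpha = TRUE)
  R0t_na <- stochastic_threshold(p, m, include_alpha = FALSE)
  cs <- critical_sigmas(p, m)

  margins <- list(
    cond_a_sigma = p$beta / k - p$sigma^2,             # >= 0 part of (a)
    cond_b = p$sigma^2 - p$beta^2 / (2 * D),           # > 0 is (b)
    cond_b_no_alpha = p$sigma^2 - p$beta^2 / (2 * (p$mu + p$gamma)),
    R0_tilde_minus_1 = R0t - 1,
    sigma_minus_sigma_bar = if (is.na(cs$sigma_bar)) NA_real_ else p$sigma - cs$sigma_bar,
    sigma1_minus_sigma = cs$sigma1 - p$sigma
  )

  cond_a <- (p$sigma^2 <= p$beta / k) && (R0t < 1)
  cond_b <- p$sigma^2 > p$beta^2 / (2 * D)
  at_boundary <- rel_close(R0t, 1) ||
    (!is.na(cs$sigma_bar) && cs$sigma_bar > 0 && rel_close(p$sigma, cs$sigma_bar))

  regime <-
    if (R0 <= 1) "extinct_any_sigma"
    else if (at_boundary) "boundary"
    else if (R0t > 1) "permanent_in_mean"
    else if (cond_a) "certain_extinction_a"
    else if (cond_b) "certain_extinction_b"
    else if (R0 > 2 && !is.na(cs$sigma_bar) &&
             p$sigma >= cs$sigma_bar && p$sigma <= cs$sigma1)
      "conjectured_extinction_band"
    else "indeterminate"

  out <- list(
    R0 = R0,
    R0_tilde = R0t,
    R0_tilde_no_alpha = R0t_na,
    sigma_bar = cs$sigma_bar, sigma1 = cs$sigma1,
    sigma2 = cs$sigma2, sigma_hat = cs$sigma_hat,
    regime = regime,
    stationary_distribution = (regime == "permanent_in_mean"),
    margins = margins,
    params = p, incidence_kind = m$kind
  )
  class(out) <- "threshold_report"
  out
}

#' @export
print.threshold_report <- function(x, digits = 6, ...) {
  cat("Stochastic SIS threshold report\n")
  cat(sprintf("  R0        = %.*g\n", digits, x$R0))
  cat(sprintf("  R0_tilde  = %.*g   (alpha excluded: %.*g)\n",
              digits, x$R0_tilde, digits, x$R0_tilde_no_alpha))
  fmt <- function(v) if (is.na(v)) paste0("NA (", attr(v, "reason"), ")") else
    sprintf("%.*g", digits, v)
  cat(sprintf("  sigma_bar = %s, sigma1 = %s, sigma2 = %s, sigma_hat = %s\n",
              fmt(x$sigma_bar), fmt(x$sigma1), fmt(x$sigma2), fmt(x$sigma_hat)))
  cat(sprintf("  regime: %s%s\n", x$regime,
              if (x$stationary_distribution) " (unique stationary distribution)" else ""))
  cat("  margins:\n")
  for (nm in names(x$margins)) {
    cat(sprintf("    %-22s %s\n", nm,
                ifelse(is.na(x$margins[[nm]]), "NA",
                       sprintf("%.*g", digits, x$margins[[nm]]))))
  }
  invisible(x)
}

#' Truncate a value to a fixed number of decimals
#'
#' Truncation (toward zero), not rounding: some reported example values are
#' truncated at the printed precision (e.g. 4.1958... printed as 4.195).
#'
#' @param x numeric.
#' @param digits decimal places kept.
#' @return truncated numeric.
#' @examples
#' truncate_decimals(4.19580, 3)  # 4.195
#' @export
truncate_decimals <- function(x, digits) {
  trunc(x * 10^digits) / 10^digits
}
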