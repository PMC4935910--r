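# Internal numerical helpers shared across modules.

#' Bisection for a monotone decreasing function
#'
#' Locates the root of `fn` on `(lo, hi)` assuming `fn(lo) > 0 > fn(hi)`
#' (monotone decrease). Used for the endemic equilibrium and the oscillation
#' level, where monotonicity is guaranteed by the incidence assumptions.
#'
#' @param fn function of one numeric argument.
#' @param lo,hi bracket endpoints.
#' @param rel_tol relative tolerance on the root.
#' @param max_iter iteration cap.
#' @return the root (numeric scalar).
#' @noRd
bisect_decreasing <- function(fn, lo, hi, rel_tol = 1e-10, max_iter = 200L) {
  flo <- fn(lo)
  fhi <- fn(hi)
  if (!is.finite(flo) || !is.finite(fhi)) {
    stop("bisection: non-finite function value at bracket endpoint",
         call. = FALSE)
  }
  if (flo < 0 || fhi > 0) {
    stop(sprintf(
      "bisection: bracket [%g, %g] does not enclose a sign change (f(lo)=%g, f(hi)=%g)",
      lo, hi, flo, fhi), call. = FALSE)
  }
  for (iter in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- fn(mid)
    if (!is.finite(fm)) {
      stop(sprintf("bisection: non-finite value at x = %g", mid),
           call. = FALSE)
    }
    if (fm > 0) lo <- mid else hi <- mid
    if ((hi - lo) <= rel_tol * max(abs(lo), abs(hi), 1e-300)) break
  }
  (lo + hi) / 2
}

#' Check a scalar is a finite number satisfying a predicate
#' @noRd
check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    cmp <- if (strict) ">" else ">="
    stop(sprintf("'%s' must be %s %g (got %g)", name, cmp, lower, x),
         call. = FALSE)
  }
  invisible(x)
}

# Relative closeness used for boundary detection in regime classification.
rel_close <- function(x, y, tol = 1e-9) {
  abs(x - y) <= tol * max(abs(x), abs(y), 1)
}

#' Wilson score interval for a binomial proportion
#' @noRd
wilson_interval <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}
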