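#' Construct a nonlinear incidence model
#'
#' Builds the incidence function \eqn{f(S,I)} used by the SIS model together
#' with its partial derivatives. The admissible incidence class is the usual
#' one for SIS-type models: \eqn{f} is twice continuously differentiable for
#' \eqn{S,I \ge 0}, \eqn{S+I>0}, vanishes on both axes
#' (\eqn{f(S,0)=f(0,I)=0}), is nondecreasing in \eqn{S} at fixed \eqn{I},
#' and \eqn{f(S,I)/I} is nonincreasing in \eqn{I} at fixed \eqn{S}. These
#' conditions imply \eqn{0 \le f(S,I) \le I\,\partial f(S,0)/\partial I} and
#' make the threshold and root-finding machinery of the package well posed;
#' [validate_assumption_H()] checks them on a grid.
#'
#' Built-in kinds:
#' \describe{
#'   \item{`bilinear`}{\eqn{f = S I} (mass action).}
#'   \item{`standard`}{\eqn{f = S I / (S+I)} (frequency dependent).}
#'   \item{`saturated`}{\eqn{f = S I / (1+\omega I)}, `params$omega >= 0`.}
#'   \item{`beddington_deangelis`}{\eqn{f = S I / (1+\omega_1 I+\omega_2 S)},
#'     `params$omega1, params$omega2 >= 0`.}
#'   \item{`product`}{\eqn{f = h(S) g(I)}; `params$h` and `params$g` are
#'     functions or arithmetic expression strings in `S` resp. `I`.}
#'   \item{`custom`}{`params$f` is a function of `(S, I)`.}
#' }
#' Built-in kinds carry closed-form derivatives; `product` and `custom`
#' fall back to central differences with step \eqn{10^{-6}\max(1,x)}.
#'
#' @param kind one of `"bilinear"`, `"standard"`, `"saturated"`,
#'   `"beddington_deangelis"`, `"product"`, `"custom"`.
#' @param params named list of constants / callables for the kind (see above).
#'
#' @return An object of class `"incidence_model"`: a list with elements
#'   `kind`, `params`, `evaluate(S, I)`, `dI_at_zero(S)` (the slope
#'   \eqn{\partial f(S,0)/\partial I}), `dI(S, I)`, `dS(S, I)` and
#'   `has_analytic_derivatives`.
#' @examples
#' m <- make_incidence("saturated", list(omega = 0.1))
#' m$evaluate(10, 5)            # 10*5 / (1 + 0.5)
#' m$dI_at_zero(2000 / 11)      # equals S for the saturated family
#' @export
make_incidence <- function(kind, params = list()) {
  kinds <- c("bilinear", "standard", "saturated", "beddington_deangelis",
             "product", "custom")
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% kinds)) {
    stop(sprintf("unknown incidence kind %s; must be one of: %s",
                 deparse(kind), paste(kinds, collapse = ", ")),
         call. = FALSE)
  }

  m <- switch(kind,
    bilinear = list(
      evaluate = function(S, I) S * I,
      dI = function(S, I) S + 0 * I,
      dS = function(S, I) I + 0 * S,
      dI_at_zero = function(S) S,
      has_analytic_derivatives = TRUE
    ),
    standard = list(
      evaluate = function(S, I) {
        N <- S + I
        ifelse(N > 0, S * I / pmax(N, .Machine$double.xmin), 0)
      },
      dI = function(S, I) {
        N <- S + I
        ifelse(N > 0, (S / pmax(N, .Machine$double.xmin))^2, 0)
      },
      dS = function(S, I) {
        N <- S + I
        ifelse(N > 0, (I / pmax(N, .Machine$double.xmin))^2, 0)
      },
      dI_at_zero = function(S) ifelse(S > 0, 1, 0),
      has_analytic_derivatives = TRUE
    ),
    saturated = {
      w <- params$omega
      if (is.null(w)) stop("saturated incidence requires params$omega",
                           call. = FALSE)
      check_scalar(w, "omega", 0)
      list(
        evaluate = function(S, I) S * I / (1 + w * I),
        dI = function(S, I) S / (1 + w * I)^2,
        dS = function(S, I) I / (1 + w * I),
        dI_at_zero = function(S) S,
        has_analytic_derivatives = TRUE
      )
    },
    beddington_deangelis = {
      w1 <- params$omega1
      w2 <- params$omega2
      if (is.null(w1) || is.null(w2)) {
        stop("beddington_deangelis incidence requires params$omega1 and params$omega2",
             call. = FALSE)
      }
      check_scalar(w1, "omega1", 0)
      check_scalar(w2, "omega2", 0)
      list(
        evaluate = function(S, I) S * I / (1 + w1 * I + w2 * S),
        dI = function(S, I) S * (1 + w2 * S) / (1 + w1 * I + w2 * S)^2,
        dS = function(S, I) I * (1 + w1 * I) / (1 + w1 * I + w2 * S)^2,
        dI_at_zero = function(S) S / (1 + w2 * S),
        has_analytic_derivatives = TRUE
      )
    },
    product = {
      h <- as_component_fn(params$h, "S")
      g <- as_component_fn(params$g, "I")
      if (is.null(h) || is.null(g)) {
        stop("product incidence requires params$h and params$g", call. = FALSE)
      }
      f <- function(S, I) h(S) * g(I)
      numeric_derivative_set(f)
    },
    custom = {
      f <- params$f
      if (!is.function(f)) stop("custom incidence requires params$f (a function)",
                                call. = FALSE)
      numeric_derivative_set(f)
    }
  )

  # continuity extension: f := 0 where S + I = 0 or either class is 0
  raw_eval <- m$evaluate
  m$evaluate <- function(S, I) {
    out <- ifelse(S > 0 & I > 0, raw_eval(pmax(S, 0), pmax(I, 0)), 0)
    as.numeric(out)
  }
  # scalar fast path for the step-by-step simulation loop
  m$evaluate1 <- switch(kind,
    bilinear = function(S, I) if (S > 0 && I > 0) S * I else 0,
    standard = function(S, I) if (S > 0 && I > 0) S * I / (S + I) else 0,
    saturated = {
      w <- params$omega
      function(S, I) if (S > 0 && I > 0) S * I / (1 + w * I) else 0
    },
    beddington_deangelis = {
      w1 <- params$omega1; w2 <- params$omega2
      function(S, I) if (S > 0 && I > 0) S * I / (1 + w1 * I + w2 * S) else 0
    },
    function(S, I) if (S > 0 && I > 0) raw_eval(S, I) else 0
  )
  m$kind <- kind
  m$params <- params
  class(m) <- "incidence_model"
  m
}

# Central-difference derivative machinery for product/custom incidences.
# Step h = 1e-6 * max(1, x): scale-invariant truncation error.
numeric_derivative_set <- function(f) {
  eval0 <- function(S, I) ifelse(S > 0 & I > 0, f(S, I), 0)
  list(
    evaluate = eval0,
    dI = function(S, I) {
      h <- 1e-6 * pmax(1, I)
      (eval0(S, I + h) - eval0(S, pmax(I - h, 0))) / (h + pmin(I, h))
    },
    dS = function(S, I) {
      h <- 1e-6 * pmax(1, S)
      (eval0(S + h, I) - eval0(pmax(S - h, 0), I)) / (h + pmin(S, h))
    },
    dI_at_zero = function(S) {
      # f(S,0) = 0, so a one-sided difference at I -> 0+ with step
      # h = 1e-8 * max(1, S) approximates the slope directly.
      h <- 1e-8 * pmax(1, S)
      val <- eval0(S, h) / h
      if (any(!is.finite(val))) {
        stop("numeric derivative dI_at_zero is non-finite", call. = FALSE)
      }
      val
    },
    has_analytic_derivatives = FALSE
  )
}

# Accept a function, or an arithmetic expression string in one variable,
# evaluated in a restricted environment (basic arithmetic/math only).
as_component_fn <- function(x, var) {
  if (is.null(x)) return(NULL)
  if (is.function(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    expr <- parse(text = x)[[1]]
    allowed <- c("+", "-", "*", "/", "^", "(", "exp", "log", "sqrt", "abs",
                 "pmin", "pmax", "min", "max", var)
    check_syms <- function(e) {
      if (is.call(e)) {
        fn <- as.character(e[[1]])
        if (!(fn %in% allowed)) {
          stop(sprintf("expression uses disallowed function '%s'", fn),
               call. = FALSE)
        }
        lapply(as.list(e)[-1], check_syms)
      } else if (is.symbol(e)) {
        if (!(as.character(e) %in% allowed)) {
          stop(sprintf("expression uses unknown symbol '%s' (only '%s' allowed)",
                       as.character(e), var), call. = FALSE)
        }
      }
      invisible(NULL)
    }
    check_syms(expr)
    env_fns <- mget(setdiff(allowed, var),
                    envir = baseenv(), ifnotfound = list(NULL))
    function(v) {
      e <- new.env(parent = emptyenv())
      for (nm in names(env_fns)) if (!is.null(env_fns[[nm]])) assign(nm, env_fns[[nm]], e)
      assign(var, v, e)
      eval(expr, e)
    }
  } else {
    stop(sprintf("component '%s' must be a function or an expression string", var),
         call. = FALSE)
  }
}

#' @export
print.incidence_model <- function(x, ...) {
  cat(sprintf("Incidence model: kind = '%s'%s\n", x$kind,
              if (x$has_analytic_derivatives) " (analytic derivatives)"
              else " (numeric derivatives)"))
  cst <- x$params[vapply(x$params, is.numeric, logical(1))]
  if (length(cst)) {
    cat("  constants:",
        paste(sprintf("%s = %g", names(cst), unlist(cst)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Slope of the incidence in I at the disease-free state
#'
#' Returns \eqn{\partial f(S, 0)/\partial I}, the per-infective incidence
#' slope in a wholly susceptible population of size `S`. Evaluated at
#' `S = S0 = Lambda/mu` this slope is the ingredient of the reproduction
#' numbers and all critical noise intensities.
#'
#' @param m an `incidence_model` from [make_incidence()].
#' @param S susceptible level (> 0).
#' @return the slope (numeric scalar, or vector for vector `S`).
#' @examples
#' df_dI_at_disease_free(make_incidence("standard"), 50)  # always 1
#' @export
df_dI_at_disease_free <- function(m, S) {
  stopifnot(inherits(m, "incidence_model"))
  if (any(S <= 0)) stop("'S' must be > 0", call. = FALSE)
  val <- m$dI_at_zero(S)
  if (any(!is.finite(val))) {
    stop("derivative at the disease-free state is non-finite", call. = FALSE)
  }
  as.numeric(val)
}

#' Validate the incidence admissibility assumptions on a grid
#'
#' Checks, on a `grid_n` x `grid_n` grid over `(0, S_max]^2`, the four
#' clauses required of an admissible incidence: (i) `f(S,0) = f(0,I) = 0`;
#' (ii) `f` nondecreasing in `S` at fixed `I`; (iii) `f/I` nonincreasing in
#' `I` at fixed `S`; (iv) positive slope `dI_at_zero(S_max) > 0`. Grid
#' checking (rather than symbolic analysis) is deliberate: custom incidences
#' are opaque callables.
#'
#' @param m an `incidence_model`.
#' @param S_max upper edge of the validation square (> 0).
#' @param grid_n grid resolution per axis (>= 3).
#' @return An object of class `"H_report"`: list with `pass` (overall),
#'   `clauses` (per-clause pass flag and first violating grid point, if any).
#' @examples
#' validate_assumption_H(make_incidence("standard"), S_max = 100)$pass
#' @export
validate_assumption_H <- function(m, S_max, grid_n = 41L) {
  stopifnot(inherits(m, "incidence_model"))
  check_scalar(S_max, "S_max", 0, strict = TRUE)
  if (grid_n < 3L) stop("'grid_n' must be >= 3", call. = FALSE)

  g <- S_max * seq_len(grid_n) / grid_n
  tol <- 1e-9 * max(1, abs(m$evaluate(S_max, S_max)))

  clauses <- list()
  first_bad <- function(cond, Sv, Iv) {
    idx <- which(cond)[1]
    list(S = Sv[idx], I = Iv[idx])
  }

  # (i) vanishing boundaries
  v1 <- m$evaluate(g, rep(0, grid_n))
  v2 <- m$evaluate(rep(0, grid_n), g)
  bad <- c(abs(v1) > tol, abs(v2) > tol)
  clauses$vanishing_boundaries <- list(
    pass = !any(bad),
    violation = if (any(bad)) {
      first_bad(bad, c(g, rep(0, grid_n)), c(rep(0, grid_n), g))
    }
  )

  # (ii) nondecreasing in S at fixed I
  G <- expand.grid(S = g, I = g)
  FM <- matrix(m$evaluate(G$S, G$I), nrow = grid_n)  # rows: S, cols: I
  dS_steps <- diff(FM)                               # along S
  bad <- dS_steps < -tol
  clauses$nondecreasing_in_S <- list(
    pass = !any(bad),
    violation = if (any(bad)) {
      ij <- which(bad, arr.ind = TRUE)[1, ]
      list(S = g[ij[1] + 1L], I = g[ij[2]])
    }
  )

  # (iii) f/I nonincreasing in I at fixed S
  ratio <- sweep(FM, 2, g, "/")
  dI_steps <- t(diff(t(ratio)))                      # along I
  bad <- dI_steps > tol
  clauses$ratio_nonincreasing_in_I <- list(
    pass = !any(bad),
    violation = if (any(bad)) {
      ij <- which(bad, arr.ind = TRUE)[1, ]
      list(S = g[ij[1]], I = g[ij[2] + 1L])
    }
  )

  # (iv) positive slope at the disease-free edge
  slope <- tryCatch(m$dI_at_zero(S_max), error = function(e) NA_real_)
  clauses$positive_slope_at_disease_free <- list(
    pass = is.finite(slope) && slope > 0,
    violation = if (!(is.finite(slope) && slope > 0)) list(S = S_max, I = 0)
  )

  out <- list(pass = all(vapply(clauses, `[[`, logical(1), "pass")),
              clauses = clauses, S_max = S_max, grid_n = grid_n)
  class(out) <- "H_report"
  out
}

#' @export
print.H_report <- function(x, ...) {
  cat(sprintf("Incidence admissibility check on (0, %g]^2 (grid %d x %d): %s\n",
              x$S_max, x$grid_n, x$grid_n, if (x$pass) "PASS" else "FAIL"))
  for (nm in names(x$clauses)) {
    cl <- x$clauses[[nm]]
    cat(sprintf("  %-34s %s", nm, if (cl$pass) "pass" else "FAIL"))
    if (!cl$pass && !is.null(cl$violation)) {
      cat(sprintf("  (first violation near S = %g, I = %g)",
                  cl$violation$S, cl$violation$I))
    }
    cat("\n")
  }
  invisible(x)
}
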