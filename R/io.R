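# Configuration files, trajectory/report I/O and the worked examples.

config_top_keys <- c("model", "incidence", "simulation", "initial",
                     "outputs", "log_level")
config_model_keys <- c("Lambda", "beta", "mu", "gamma", "alpha", "sigma")
config_sim_keys <- c("dt", "n_steps", "seed", "n_replicates",
                     "extinction_threshold", "scheme_variant",
                     "positivity_policy")

#' Read and validate a run configuration
#'
#' Parses a JSON (`.json`) or YAML (`.yaml`/`.yml`) configuration with
#' sections `model` (the six rate constants; `Lambda`, `beta`, `mu` required),
#' `incidence` (`kind` + `params`), and optionally `simulation`
#' (see [sim_config()]), `initial` (`S`, `I`), `outputs` and `log_level`.
#' Unknown keys are rejected with a message naming the key.
#'
#' @param path file path.
#' @return A `"run_config"`: list with constructed `params`
#'   (`sis_params`), `incidence` (`incidence_model`), `simulation`
#'   (`sim_config` or `NULL`), `initial`, `outputs`, `log_level`, and the
#'   original parsed list as `raw`.
#' @examples
#' cfg <- read_config(system.file("extdata", "example2.json", package = "stochsis"))
#' cfg$params$S0
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop(sprintf("unsupported config extension '.%s' (use .json or .yaml)", ext),
         call. = FALSE)
  )
  validate_config(raw)
}

validate_config <- function(raw) {
  if (!is.list(raw)) stop("config must parse to a named list", call. = FALSE)
  unknown <- setdiff(names(raw), config_top_keys)
  if (length(unknown)) {
    stop(sprintf("unknown config key '%s' (allowed: %s)", unknown[1],
                 paste(config_top_keys, collapse = ", ")), call. = FALSE)
  }
  if (is.null(raw$model)) stop("config section 'model' is required", call. = FALSE)
  unknown <- setdiff(names(raw$model), config_model_keys)
  if (length(unknown)) {
    stop(sprintf("unknown key 'model.%s'", unknown[1]), call. = FALSE)
  }
  for (req in c("Lambda", "beta", "mu")) {
    if (is.null(raw$model[[req]])) {
      stop(sprintf("config validation: missing required field 'model.%s'", req),
           call. = FALSE)
    }
  }
  params <- as_sis_params(raw$model)

  inc_spec <- if (is.null(raw$incidence)) list(kind = "bilinear") else raw$incidence
  if (is.null(inc_spec$kind)) {
    stop("config validation: missing required field 'incidence.kind'",
         call. = FALSE)
  }
  unknown <- setdiff(names(inc_spec), c("kind", "params"))
  if (length(unknown)) {
    stop(sprintf("unknown key 'incidence.%s'", unknown[1]), call. = FALSE)
  }
  incidence <- make_incidence(inc_spec$kind,
                              if (is.null(inc_spec$params)) list()
                              else as.list(inc_spec$params))

  simulation <- NULL
  if (!is.null(raw$simulation)) {
    unknown <- setdiff(names(raw$simulation), config_sim_keys)
    if (length(unknown)) {
      stop(sprintf("unknown key 'simulation.%s'", unknown[1]), call. = FALSE)
    }
    simulation <- do.call(sim_config, raw$simulation)
  }

  initial <- raw$initial
  if (!is.null(initial)) {
    unknown <- setdiff(names(initial), c("S", "I"))
    if (length(unknown)) {
      stop(sprintf("unknown key 'initial.%s'", unknown[1]), call. = FALSE)
    }
  }

  out <- list(params = params, incidence = incidence, simulation = simulation,
              initial = initial, outputs = raw$outputs,
              log_level = if (is.null(raw$log_level)) "info" else raw$log_level,
              raw = raw)
  class(out) <- "run_config"
  out
}

#' Write a run configuration
#'
#' Serializes the raw configuration list back to JSON or YAML (by file
#' extension); a write/read round trip reproduces the configuration.
#'
#' @param cfg a `"run_config"` (or a plain list in the config schema).
#' @param path destination (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  raw <- if (inherits(cfg, "run_config")) cfg$raw else cfg
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    yaml = ,
    yml = yaml::write_yaml(raw, path),
    stop(sprintf("unsupported config extension '.%s'", ext), call. = FALSE)
  )
  invisible(path)
}

#' Write a trajectory as CSV
#'
#' Columns `time,S,I,N`, one row per stored step, full double precision
#' (`%.17g`). An empty trajectory produces a header-only file.
#'
#' @param traj a `"sis_trajectory"`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "sis_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time,S,I,N", con)
  if (length(traj$times)) {
    writeLines(sprintf("%.17g,%.17g,%.17g,%.17g",
                       traj$times, traj$S, traj$I, traj$S + traj$I), con)
  }
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path CSV path with columns `time,S,I` (+ optional `N`).
#' @return a `"sis_trajectory"` (seed unknown, `dt` inferred from the grid).
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time", "S", "I")
  if (!all(need %in% names(df))) {
    stop(sprintf("trajectory file %s lacks columns %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  dt <- if (nrow(df) > 1) df$time[2] - df$time[1] else NA_real_
  new_trajectory(times = df$time, S = df$S, I = df$I, dt = dt,
                 scheme = "file", seed = NA_integer_)
}

#' Write an analysis report as JSON
#'
#' Serializes threshold, oscillation, persistence or stationary reports
#' (any list-like object) with a `schema_version` stamp; `NA` values carrying
#' a `"reason"` attribute are written as `null` with the reason alongside.
#'
#' @param report a report object.
#' @param path destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(c(list(schema_version = "1.0"),
                         report_to_list(report)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

report_to_list <- function(x) {
  if (inherits(x, "sis_params")) return(unclass(x))
  if (is.list(x)) {
    out <- lapply(unclass(x), report_to_list)
    return(out[!vapply(out, is.null, logical(1))])
  }
  if (is.function(x)) return(NULL)
  if (length(x) == 1L && is.na(x) && !is.null(attr(x, "reason"))) {
    return(list(value = NULL, reason = attr(x, "reason")))
  }
  x
}

#' Regime sweep over noise intensities
#'
#' Classifies the regime on a grid of noise intensities at otherwise fixed
#' parameters.
#'
#' @inheritParams basic_reproduction_number
#' @param sigmas vector of noise intensities (>= 0).
#' @return data frame with columns `sigma`, `R0_tilde`, `regime`.
#' @export
regime_sweep <- function(p, m, sigmas) {
  p <- as_sis_params(p)
  rows <- lapply(sigmas, function(s) {
    ps <- p; ps$sigma <- s
    rep <- classify_regime(ps, m)
    data.frame(sigma = s, R0_tilde = rep$R0_tilde, regime = rep$regime)
  })
  do.call(rbind, rows)
}

# ---- worked examples ------------------------------------------------------

#' Parameter sets of the three worked examples
#'
#' The three published example parameterizations, each with the saturated
#' incidence \eqn{f = SI/(1+\omega I)}. The saturation constant was never
#' stated with the examples; `omega = 0.1` is used here — every threshold
#' quantity reproduced from the examples depends on the incidence only
#' through \eqn{\partial f(S^0,0)/\partial I = S^0} and is therefore
#' omega-independent.
#'
#' @param name `"example1"`, `"example2"` or `"example3"`.
#' @return list with `params` (`sis_params`), `incidence`
#'   (`incidence_model`), `I0` (initial infectious level used in the
#'   published figures) and `name`.
#' @export
example_params <- function(name = c("example1", "example2", "example3")) {
  name <- match.arg(name)
  preset <- switch(name,
    example1 = list(Lambda = 2000, beta = 0.60, mu = 11, gamma = 13,
                    alpha = 2, sigma = 0.075),
    example2 = list(Lambda = 2000, beta = 0.9, mu = 30, gamma = 12,
                    alpha = 0, sigma = 0.09),
    example3 = list(Lambda = 2000, beta = 0.5, mu = 30, gamma = 20,
                    alpha = 2, sigma = 0.02)
  )
  list(params = do.call(model_params, preset),
       incidence = make_incidence("saturated", list(omega = 0.1)),
       I0 = 0.5, name = name)
}

#' Run a worked example end to end
#'
#' Computes the threshold report for one of the three published example
#' parameter sets, renders the values in the printed style of the source
#' (truncation where the source truncated), and optionally simulates a small
#' ensemble. Example 3's printed threshold and oscillation values
#' (R0 = 1.2500, modified threshold 1.200, xi = 0.1037) cannot be derived
#' from its stated parameters (the reproduction number computed from them is
#' about 0.64, and the oscillation level is undefined for `alpha > 0`); they
#' are flagged as not reproducible while the simulation still runs.
#'
#' @param name `"example1"`, `"example2"` or `"example3"`.
#' @param simulate run the ensemble (default TRUE).
#' @param n_replicates ensemble size (default 50).
#' @param T horizon; defaults to 2 (example 1), 5 (example 2), 50 (example 3).
#' @param dt step (default 1e-3).
#' @param seed base seed (default 1).
#' @return list with `name`, `thresholds` (a `"threshold_report"`),
#'   `printed_style` (character renditions at the source's precision),
#'   `not_reproducible` (character vector of flagged printed values, if any),
#'   and `ensemble` (an `"ensemble_summary"` or `NULL`).
#' @examples
#' ex <- run_example("example2", simulate = FALSE)
#' ex$thresholds$regime  # "boundary"
#' @export
run_example <- function(name = c("example1", "example2", "example3"),
                        simulate = TRUE, n_replicates = 50L, T = NULL,
                        dt = 1e-3, seed = 1L) {
  name <- match.arg(name)
  ex <- example_params(name)
  p <- ex$params
  rep <- classify_regime(p, ex$incidence)

  printed <- switch(name,
    example1 = list(
      R0 = sprintf("%.3f", truncate_decimals(rep$R0, 3)),
      R0_tilde = sprintf("%.4f", round(rep$R0_tilde_no_alpha, 4)),
      # the source prints beta/S0 - sigma^2 (condition (a) margin) and
      # sigma^2 - beta^2/(2(mu+gamma)) (condition (b), alpha excluded)
      cond_a_margin = sprintf("%.4f", round(rep$margins$cond_a_sigma, 4)),
      cond_b_margin = sprintf("%.4f", round(rep$margins$cond_b_no_alpha, 4))
    ),
    example2 = list(R0_tilde = sprintf("%.0f", rep$R0_tilde)),
    example3 = list()
  )

  not_reproducible <- if (name == "example3") {
    c("R0 = 1.2500", "modified threshold = 1.200", "xi = 0.1037")
  } else {
    character(0)
  }

  ensemble <- NULL
  if (simulate) {
    if (is.null(T)) T <- switch(name, example1 = 2, example2 = 5, example3 = 50)
    cfg <- sim_config(dt = dt, n_steps = round(T / dt), seed = seed,
                      n_replicates = n_replicates,
                      extinction_threshold = 1e-3 * ex$I0)
    ensemble <- simulate_ensemble(p, ex$incidence,
                                  S_init = p$S0 - ex$I0, I_init = ex$I0,
                                  cfg = cfg)
  }

  list(name = name, thresholds = rep, printed_style = printed,
       not_reproducible = not_reproducible, ensemble = ensemble)
}
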