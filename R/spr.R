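#' 1:1 binding kinetic parameters
#'
#' @param k_on association rate constant, M^-1 s^-1.
#' @param k_off dissociation rate constant, s^-1.
#' @param rmax analyte binding capacity of the surface, response units.
#' @return one-row tibble of class `kinetic_params`.
#' @export
kinetic_params <- function(k_on, k_off, rmax) {
  if (any(c(k_on, k_off, rmax) <= 0)) {
    abort("k_on, k_off and rmax must be strictly positive")
  }
  structure(tibble(k_on = k_on, k_off = k_off, rmax = rmax),
            class = c("kinetic_params", class(tibble())))
}

#' Serial dilution series
#'
#' `top, top/fold, ..., top/fold^(n_points-1)` - e.g. a 10-point 2-fold
#' series from 50 mM ends at 50/2^9 mM, about 98 uM.
#'
#' @param top highest concentration, molar.
#' @param fold dilution factor per step (> 1).
#' @param n_points number of concentrations (>= 1).
#' @return numeric vector, molar, strictly decreasing.
#' @export
dilution_series <- function(top, fold = 2, n_points = 10) {
  if (top <= 0 || fold <= 1 || n_points < 1) {
    abort("need top > 0, fold > 1, n_points >= 1")
  }
  top / fold^(0:(n_points - 1))
}

#' Multi-cycle injection series
#'
#' @param concentrations strictly decreasing positive analyte
#'   concentrations, molar (one cycle each).
#' @param contact_time association (injection) time, s.
#' @param dissociation_time buffer-flow dissociation time, s.
#' @return list of class `injection_series`.
#' @export
injection_series <- function(concentrations, contact_time,
                             dissociation_time) {
  if (any(concentrations <= 0)) abort("concentrations must be positive")
  if (length(concentrations) > 1 && any(diff(concentrations) >= 0)) {
    abort("concentrations must be strictly decreasing")
  }
  if (contact_time <= 0 || dissociation_time <= 0) {
    abort("contact and dissociation times must be positive")
  }
  structure(list(concentrations = concentrations,
                 contact_time = contact_time,
                 dissociation_time = dissociation_time),
            class = "injection_series")
}

#' Binary-format injection series
#'
#' Small-molecule vs immobilised protein: 120 s contact, 180 s
#' dissociation; running-buffer concentrations are a 10-point 2-fold
#' series (50 uM to ~98 nM by default).
#'
#' @param top top concentration, molar.
#' @param fold,n_points dilution design.
#' @return an [injection_series].
#' @export
binary_injection_series <- function(top = 50e-6, fold = 2, n_points = 10) {
  injection_series(dilution_series(top, fold, n_points),
                   contact_time = 120, dissociation_time = 180)
}

#' Ternary-format injection series
#'
#' Pre-mixed PROTAC:target complex vs captured E3 ligase: 400 s
#' contact, 600 s dissociation. The default concentration list spans
#' 1 uM to 62.5 nM in 2-fold steps; honouring both printed endpoints
#' requires five concentrations (four 2-fold steps).
#'
#' @param top top PROTAC concentration, molar.
#' @param fold,n_points dilution design.
#' @return an [injection_series].
#' @export
ternary_injection_series <- function(top = 1e-6, fold = 2, n_points = 5) {
  injection_series(dilution_series(top, fold, n_points),
                   contact_time = 400, dissociation_time = 600)
}

#' Simulate a 1:1 Langmuir sensorgram
#'
#' Association follows `R(t) = R_eq (1 - exp(-(k_on C + k_off) t))`
#' with `R_eq = Rmax C / (C + K_D)`; dissociation decays from the end
#' of contact as `R(t_c) exp(-k_off (t - t_c))`. Optional i.i.d.
#' Gaussian noise is added reproducibly from `seed`; with
#' `noise_sd = 0` the exact model curve is returned.
#'
#' @param params a [kinetic_params] row.
#' @param conc analyte concentration, molar (>= 0).
#' @param contact_time,dissociation_time phase durations, s.
#' @param dt sampling interval, s.
#' @param noise_sd Gaussian noise standard deviation, RU.
#' @param seed integer seed for the noise (required if noise_sd > 0).
#' @return tibble of class `sensorgram`: `time`, `response`,
#'   `concentration`, `phase`; the contact time is kept in the
#'   `contact_time` attribute.
#' @export
simulate_sensorgram <- function(params, conc, contact_time = 400,
                                dissociation_time = 600, dt = 1,
                                noise_sd = 0, seed = NULL) {
  if (conc < 0) abort("concentration must be non-negative")
  time <- seq(0, contact_time + dissociation_time, by = dt)
  response <- sensorgram_model(time, params$k_on, params$k_off, params$rmax,
                               conc, contact_time)
  if (noise_sd > 0) {
    if (is.null(seed)) abort("a seed is required for noisy simulation")
    noise <- withr::with_seed(seed, stats::rnorm(length(time), 0, noise_sd))
    response <- response + noise
  }
  out <- tibble(time = time, response = response, concentration = conc,
                phase = ifelse(time <= contact_time,
                               "association", "dissociation"))
  structure(out, class = c("sensorgram", class(tibble())),
            contact_time = contact_time)
}

# closed-form 1:1 model, vectorised over time
sensorgram_model <- function(time, k_on, k_off, rmax, conc, contact_time) {
  kd <- k_off / k_on
  req <- if (conc == 0) 0 else rmax * conc / (conc + kd)
  kobs <- k_on * conc + k_off
  r_assoc <- req * (1 - exp(-kobs * pmin(time, contact_time)))
  r_tc <- req * (1 - exp(-kobs * contact_time))
  ifelse(time <= contact_time, r_assoc,
         r_tc * exp(-k_off * (time - contact_time)))
}

#' Derive equilibrium and half-life constants
#'
#' `K_D = k_off / k_on` and, for first-order dissociation,
#' `t_1/2 = ln 2 / k_off`.
#'
#' @param params a [kinetic_params] row.
#' @return one-row tibble with `K_D` (molar) and `t_half` (s).
#' @export
derive_constants <- function(params) {
  tibble(K_D = params$k_off / params$k_on,
         t_half = log(2) / params$k_off)
}

#' Cooperativity of ternary complex formation
#'
#' `alpha = K_D(binary) / K_D(ternary)`. alpha > 1 means the pre-formed
#' binary complex binds the third partner more tightly than the free
#' ligand does (positive cooperativity); alpha < 1 is negative;
#' alpha = 1 neutral.
#'
#' @param kd_binary,kd_ternary dissociation constants, molar (any
#'   common unit works: alpha is scale-invariant).
#' @return one-row tibble of class `cooperativity_result` with
#'   `kd_binary`, `kd_ternary`, `alpha`, `classification`.
#' @export
cooperativity <- function(kd_binary, kd_ternary) {
  if (kd_binary <= 0 || kd_ternary <= 0) {
    abort("dissociation constants must be strictly positive")
  }
  alpha <- kd_binary / kd_ternary
  cls <- if (abs(alpha - 1) < 1e-12) "neutral" else
    if (alpha > 1) "positive" else "negative"
  structure(tibble(kd_binary = kd_binary, kd_ternary = kd_ternary,
                   alpha = alpha, classification = cls),
            class = c("cooperativity_result", class(tibble())))
}

#' Globally fit 1:1 kinetics across a multi-cycle series
#'
#' Levenberg-Marquardt nonlinear least squares of the 1:1 Langmuir
#' model over all cycles simultaneously, sharing `k_on`, `k_off` and
#' `Rmax`. Parameters are fitted on the log scale to enforce
#' positivity. Initialisation is deterministic: `k_off` from a
#' log-linear regression of the pooled dissociation tails, `k_on` from
#' the slope of the per-cycle observed rate versus concentration.
#' Standard errors come from the residual variance and the Jacobian at
#' the optimum.
#'
#' @param data tibble with columns `time`, `response`,
#'   `concentration`, and optionally `cycle` (defaults to one cycle per
#'   distinct concentration) and `phase`.
#' @param contact_time end of the association phase, s; taken from the
#'   `phase` column or the `contact_time` attribute when absent.
#' @return object of class `kinetic_fit`; see [tidy.kinetic_fit] and
#'   [glance.kinetic_fit].
#' @export
fit_kinetics <- function(data, contact_time = NULL) {
  data <- as_tibble(data)
  if (is.null(data[["cycle"]])) {
    data$cycle <- match(data$concentration, unique(data$concentration))
  }
  if (is.null(contact_time)) {
    contact_time <- attr(data, "contact_time")
    if (is.null(contact_time) && !is.null(data[["phase"]])) {
      contact_time <- max(data$time[data$phase == "association"])
    }
    if (is.null(contact_time)) {
      abort("contact_time not given and not recoverable from the data")
    }
  }
  concs <- vapply(split(data$concentration, data$cycle), `[`, numeric(1), 1)
  pos <- concs[concs > 0]
  if (length(pos) < 2 || max(pos) / min(pos) <= 4) {
    warn("fewer than 2 concentrations spanning a > 4-fold range: the global fit may be poorly conditioned")
  }
  if (max(data$response) - min(data$response) < 1e-9) {
    abort("degenerate data: responses are flat")
  }

  init <- init_kinetics(data, contact_time)
  model_resp <- function(p) {
    k_on <- exp(p[1]); k_off <- exp(p[2]); rmax <- exp(p[3])
    unlist(lapply(split(data, data$cycle), function(d) {
      sensorgram_model(d$time, k_on, k_off, rmax, d$concentration[1],
                       contact_time)
    }), use.names = FALSE)
  }
  obs <- unlist(lapply(split(data, data$cycle), `[[`, "response"),
                use.names = FALSE)
  fit <- minpack.lm::nls.lm(
    par = log(c(init$k_on, init$k_off, init$rmax)),
    fn = function(p) obs - model_resp(p),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info %in% c(0, 5, 9)) {
    abort(sprintf(
      "kinetic fit did not converge (lmder info %d, residual norm %.3g)",
      fit$info, sqrt(fit$deviance)))
  }
  p <- fit$par
  params <- kinetic_params(exp(p[1]), exp(p[2]), exp(p[3]))
  dof <- length(obs) - 3
  s2 <- fit$deviance / max(dof, 1)
  vcov_log <- tryCatch(s2 * solve(fit$hessian), error = function(e) {
    matrix(NA_real_, 3, 3)
  })
  se_log <- sqrt(pmax(diag(vcov_log), 0))
  # delta method: se on the natural scale
  se <- se_log * c(params$k_on, params$k_off, params$rmax)
  fitted <- model_resp(p)
  structure(list(params = params,
                 std_errors = tibble(term = c("k_on", "k_off", "rmax"),
                                     estimate = c(params$k_on, params$k_off,
                                                  params$rmax),
                                     std.error = se),
                 residual_norm = sqrt(fit$deviance),
                 n_obs = length(obs),
                 n_cycles = length(concs),
                 contact_time = contact_time,
                 converged = TRUE,
                 init = init,
                 data = data,
                 fitted = fitted),
            class = "kinetic_fit")
}

# deterministic initial values for the global fit
init_kinetics <- function(data, contact_time) {
  dis <- data[data$time > contact_time &
                data$response > 1e-3 * max(data$response), ]
  k_off <- 0.01
  if (nrow(dis) > 5) {
    slopes <- vapply(split(dis, dis$cycle), function(d) {
      if (nrow(d) < 3) return(NA_real_)
      stats::coef(stats::lm(log(pmax(d$response, 1e-9)) ~ d$time))[2]
    }, numeric(1))
    slopes <- slopes[is.finite(slopes) & slopes < 0]
    if (length(slopes) > 0) k_off <- -stats::median(slopes)
  }
  cyc <- split(data[data$time <= contact_time, ],
               data$cycle[data$time <= contact_time])
  kobs <- vapply(cyc, function(d) {
    req <- 1.02 * max(d$response)
    y <- log(pmax(1 - d$response / req, 1e-6))
    sl <- stats::coef(stats::lm(y ~ d$time))[2]
    if (is.finite(sl) && sl < 0) -sl else NA_real_
  }, numeric(1))
  cc <- vapply(cyc, function(d) d$concentration[1], numeric(1))
  ok <- is.finite(kobs) & cc > 0
  k_on <- if (sum(ok) >= 2) {
    sl <- stats::coef(stats::lm(kobs[ok] ~ cc[ok]))[2]
    if (is.finite(sl) && sl > 0) sl else k_off / stats::median(cc[ok])
  } else {
    k_off / stats::median(cc[cc > 0])
  }
  kd <- k_off / k_on
  rmax <- max(vapply(cyc, function(d) {
    max(d$response) * (d$concentration[1] + kd) /
      max(d$concentration[1], 1e-12)
  }, numeric(1)))
  list(k_on = max(k_on, 1e-3), k_off = max(k_off, 1e-6),
       rmax = max(rmax, 1e-3))
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> %d cycles, %d points; k_on %.3g /M/s, k_off %.3g /s, Rmax %.3g RU\n",
    x$n_cycles, x$n_obs, x$params$k_on, x$params$k_off, x$params$rmax))
  dc <- derive_constants(x$params)
  cat(sprintf("K_D %.3g M, t1/2 %.1f s, residual norm %.3g RU\n",
              dc$K_D, dc$t_half, x$residual_norm))
  invisible(x)
}

#' Tidy a kinetic fit
#'
#' @param x a `kinetic_fit`.
#' @param ... unused.
#' @return tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
#' @method tidy kinetic_fit
tidy.kinetic_fit <- function(x, ...) x$std_errors

#' One-row summary of a kinetic fit
#'
#' @param x a `kinetic_fit`.
#' @param ... unused.
#' @return one-row tibble: parameters, derived `K_D` and `t_half`,
#'   residual norm, sizes.
#' @export
#' @method glance kinetic_fit
glance.kinetic_fit <- function(x, ...) {
  dplyr::bind_cols(as_tibble(x$params), derive_constants(x$params),
                   tibble(residual_norm = x$residual_norm,
                          n_obs = x$n_obs, n_cycles = x$n_cycles,
                          converged = x$converged))
}

# ---- sensorgram I/O -----------------------------------------------------

#' Write stacked sensorgrams as delimited text
#'
#' Tab-separated columns `time_s`, `response_RU`, `concentration_M`,
#' `cycle_id`.
#'
#' @param data stacked sensorgram tibble (`time`, `response`,
#'   `concentration`, `cycle`).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sensorgrams <- function(data, path) {
  if (is.null(data[["cycle"]])) {
    data$cycle <- match(data$concentration, unique(data$concentration))
  }
  utils::write.table(
    data.frame(time_s = data$time, response_RU = data$response,
               concentration_M = data$concentration, cycle_id = data$cycle),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sensorgrams from delimited text
#'
#' Expects the layout written by [write_sensorgrams]; malformed numeric
#' fields are reported with their line number.
#'
#' @param path input path.
#' @return tibble with `time`, `response`, `concentration`, `cycle`.
#' @export
read_sensorgrams <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read sensorgrams '%s'", path))
  tab <- utils::read.delim(path, colClasses = "character")
  need <- c("time_s", "response_RU", "concentration_M", "cycle_id")
  if (!all(need %in% names(tab))) {
    abort(sprintf("sensorgram table '%s' lacks columns: %s", path,
                  paste(setdiff(need, names(tab)), collapse = ", ")))
  }
  num <- lapply(tab[need], function(col) suppressWarnings(as.numeric(col)))
  bad <- which(Reduce(`|`, lapply(num, is.na)))
  if (length(bad) > 0) {
    abort(sprintf("sensorgram table '%s': malformed value at line %d",
                  path, bad[1] + 1))
  }
  tibble(time = num$time_s, response = num$response_RU,
         concentration = num$concentration_M, cycle = num$cycle_id)
}
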