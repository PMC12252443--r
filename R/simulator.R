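#' Kinetic parameters of the fermentation simulator
#'
#' Defaults reproduce a typical white-wine alcoholic fermentation: biomass
#' rises from `X0` through a sigmoidal exponential phase to `Xmax` ~ U(3, 4)
#' g/L, sugar falls from `S0` ~ U(200, 220) g/L towards `Send` = 20 g/L, pH
#' drops sigmoidally from 4.5 and recovers slightly, CO2 production peaks
#' during exponential growth, and temperature is held at the 15 degrees C
#' setpoint.  Per-fermentation variability enters through the uniform ranges
#' (`Xmax_range`, `r_range`, `S0_range`, `ke_range`); per-sample noise is
#' Gaussian for biomass/sugar/pH/temperature and exponential (mean = scale)
#' for CO2, with phase-specific scales.
#'
#' @param X0 Initial biomass, g/L.
#' @param tau Lag-phase time constant, h.
#' @param Xmax_range Uniform range of the maximum biomass, g/L.
#' @param r_range Uniform range of the exponential growth rate, 1/h.
#' @param tm Exponential-phase midpoint, h.
#' @param decline_alpha Stationary-phase linear decline rate, g/L/h.
#' @param death_beta Death-phase exponential decay rate, 1/h.
#' @param S0_range Uniform range of the initial sugar concentration, g/L.
#' @param ke_range Uniform range of the sugar consumption rate, 1/h.
#' @param Smin Residual sugar at the stationary plateau, g/L.
#' @param deltaS Stationary-phase transition amplitude, g/L.
#' @param ks Stationary-phase stabilisation rate, 1/h.
#' @param Send Final sugar concentration, g/L.
#' @param temp_setpoint Controlled fermentation temperature, degrees C.
#' @param yield_YXS Biomass yield on sugar, g/g (used by the rate-equation
#'   diagnostic only).
#' @param noise_sd Named list of per-phase Gaussian noise standard deviations
#'   for `biomass`, `sugar`, `pH` (each length-4: lag/exp/stat/death) and a
#'   scalar for `temp`.
#' @param co2_noise_scale Per-phase exponential noise scales (means) for the
#'   CO2 channel.
#' @param noise_mult Scalar multiplier applied to every noise scale
#'   (1 = nominal; used for noise-inflation studies).
#' @return A list of class `kinetic_params`.
#' @export
kinetic_params <- function(X0 = 0.5, tau = 10,
                           Xmax_range = c(3.0, 4.0), r_range = c(0.25, 0.35),
                           tm = 45, decline_alpha = 0.01, death_beta = 0.005,
                           S0_range = c(200, 220), ke_range = c(0.01, 0.02),
                           Smin = 30, deltaS = 50, ks = 0.02, Send = 20,
                           temp_setpoint = 15, yield_YXS = 0.5,
                           noise_sd = list(
                             biomass = c(lag = 0.02, exp = 0.05,
                                         stat = 0.03, death = 0.05),
                             sugar = c(lag = 0.5, exp = 1, stat = 0.8,
                                       death = 0.3),
                             pH = c(lag = 0.05, exp = 0.05, stat = 0.1,
                                    death = 0.05),
                             temp = 0.05),
                           co2_noise_scale = c(lag = 0.1, exp = 0.3,
                                               stat = 0.2, death = 0.1),
                           noise_mult = 1) {
  stopifnot(X0 > 0, tau > 0, tm > 0, decline_alpha > 0, death_beta > 0,
            Smin > 0, deltaS > 0, ks > 0, Send > 0, temp_setpoint > 0,
            yield_YXS > 0, noise_mult >= 0,
            Xmax_range[1] <= Xmax_range[2], r_range[1] <= r_range[2],
            S0_range[1] <= S0_range[2], ke_range[1] <= ke_range[2])
  structure(list(X0 = X0, tau = tau, Xmax_range = Xmax_range,
                 r_range = r_range, tm = tm, decline_alpha = decline_alpha,
                 death_beta = death_beta, S0_range = S0_range,
                 ke_range = ke_range, Smin = Smin, deltaS = deltaS, ks = ks,
                 Send = Send, temp_setpoint = temp_setpoint,
                 yield_YXS = yield_YXS, noise_sd = noise_sd,
                 co2_noise_scale = co2_noise_scale, noise_mult = noise_mult),
            class = "kinetic_params")
}

#' Fermentation-phase memberships
#'
#' Degrees to which a time point (hours) belongs to the lag, exponential,
#' stationary and death phases of alcoholic fermentation:
#' lag = trimf(t; 0, 0, 20), exponential = trapmf(t; 15, 20, 70, 80),
#' stationary = trapmf(t; 70, 80, 150, 170), death = smf(t; 150, 336).
#'
#' @param t Time in hours (vectorised, >= 0).
#' @return A data.frame with columns `lag`, `exp`, `stat`, `death`.
#' @export
#' @examples
#' phase_memberships(c(10, 45, 100, 336))
phase_memberships <- function(t) {
  if (any(t < 0)) stop("t must be non-negative")
  data.frame(
    lag = trimf(t, 0, 0, 20),
    exp = trapmf(t, 15, 20, 70, 80),
    stat = trapmf(t, 70, 80, 150, 170),
    death = smf(t, 150, 336)
  )
}

# Per-fermentation random kinetic parameter draws (uniform ranges).
draw_ferment_params <- function(params) {
  list(Xmax = runif(1, params$Xmax_range[1], params$Xmax_range[2]),
       r = runif(1, params$r_range[1], params$r_range[2]),
       S0 = runif(1, params$S0_range[1], params$S0_range[2]),
       ke = runif(1, params$ke_range[1], params$ke_range[2]))
}

#' Per-phase attribute values of the fermentation rule chain
#'
#' Evaluates, for one attribute, the four phase-specific closed-form
#' expressions of the simulator's rule chain at times `t`.  The CO2 and
#' alcohol expressions are driven by the concurrently generated biomass
#' (passed via `state`).  With `noise_on = FALSE` all stochastic terms are
#' dropped, giving the deterministic reference curves.
#'
#' @param attribute One of `"biomass_gL"`, `"sugar_gL"`, `"co2"`, `"pH"`,
#'   `"temp_C"`, `"alcohol_gL"`.
#' @param t Time in hours (vectorised).
#' @param state Biomass values at `t` (required for CO2 and alcohol).
#' @param params A [kinetic_params()] object.
#' @param draws Per-fermentation parameter draws (list with `Xmax`, `r`,
#'   `S0`, `ke`); defaults to the midpoints of the uniform ranges.
#' @param noise_on Unused here (per-phase values are returned noise-free;
#'   noise is applied after phase blending).  Kept for interface clarity.
#' @return A matrix `length(t)` by 4, columns `lag`, `exp`, `stat`, `death`.
#' @export
phase_value <- function(attribute, t, state = NULL, params = kinetic_params(),
                        draws = NULL, noise_on = FALSE) {
  if (is.null(draws)) {
    draws <- list(Xmax = mean(params$Xmax_range), r = mean(params$r_range),
                  S0 = mean(params$S0_range), ke = mean(params$ke_range))
  }
  n <- length(t)
  v <- switch(attribute,
    biomass_gL = cbind(
      lag = params$X0 * (1 - exp(-t / params$tau)),
      exp = params$X0 + draws$Xmax / (1 + exp(-draws$r * (t - params$tm))),
      stat = draws$Xmax - params$decline_alpha * (t - 100),
      death = 3.0 * exp(-params$death_beta * (t - 200))
    ),
    sugar_gL = cbind(
      lag = rep(draws$S0, n),
      exp = draws$S0 * exp(-draws$ke * t),
      stat = params$Smin + params$deltaS * exp(-params$ks * (t - 100)),
      death = rep(params$Send, n)
    ),
    pH = cbind(
      lag = rep(4.5, n),
      exp = 4.5 - 1.8 / (1 + exp(-0.15 * (t - 50))),
      stat = rep(3.2, n),
      death = 3.0 + 0.5 * exp(-0.01 * (t - 150))
    ),
    temp_C = matrix(params$temp_setpoint, n, 4,
                    dimnames = list(NULL, c("lag", "exp", "stat", "death"))),
    co2 = {
      if (is.null(state)) stop("co2 phase values require the biomass state")
      cbind(
        lag = 0.1 * state,
        exp = 12 * state * exp(-0.008 * (t - 60)^2),
        stat = 4 * state * exp(-0.01 * (t - 120)^2),
        death = 0.5 * state
      )
    },
    alcohol_gL = {
      if (is.null(state)) stop("alcohol phase values require the biomass state")
      cbind(
        lag = rep(0, n),
        exp = 0.15 * state * (1 - 0.3 * sin(t / 50)),
        stat = 0.9 * state * (1 - 0.1 * sin(t / 30)),
        death = 0.8 * state
      )
    },
    stop("unknown attribute: ", attribute)
  )
  colnames(v) <- c("lag", "exp", "stat", "death")
  v
}

# Membership-weighted blend of per-phase values: sum(mu * v) / sum(mu).
blend_phases <- function(values, mu) {
  tot <- rowSums(mu)
  if (any(tot <= 0)) stop("zero total phase membership at some time point")
  rowSums(values * mu) / tot
}

#' Generate one synthetic fermentation curve
#'
#' Draws per-fermentation kinetic parameters from their uniform ranges, then
#' evaluates every attribute on a uniform time grid as the normalised
#' membership-weighted blend of the four phase-specific expressions, adding
#' noise after blending (Gaussian for biomass, sugar, pH, temperature;
#' exponential for CO2, with the per-phase scales blended by the same
#' memberships).  The alcohol channel comes from the deterministic rule-chain
#' expressions unless a trained soft-sensor `controller` is supplied, in which
#' case alcohol is inferred from the other five channels and smoothed.
#'
#' @param params A [kinetic_params()] object.
#' @param seed Integer seed; the curve is bit-reproducible given the seed.
#' @param duration_h Total duration in hours (default 504 = 21 days).
#' @param step_min Sampling interval in minutes (default 5).
#' @param noise Logical; FALSE gives the deterministic reference curve.
#' @param controller Optional `alcohol_controller` used to infer the alcohol
#'   channel.
#' @return A data.frame of class `fermentation_curve` with columns
#'   `time_h, biomass_gL, sugar_gL, co2, pH, temp_C, alcohol_gL` and
#'   attributes `seed`, `params`, `draws`, `alcohol_source`.
#' @export
#' @examples
#' curve <- generate_curve(seed = 1, duration_h = 48, step_min = 60)
#' head(curve)
generate_curve <- function(params = kinetic_params(), seed = NULL,
                           duration_h = 504, step_min = 5,
                           noise = TRUE, controller = NULL) {
  stopifnot(duration_h > 0, step_min > 0)
  n <- duration_h * 60 / step_min
  if (abs(n - round(n)) > 1e-9) stop("step_min must divide the duration")
  n <- as.integer(round(n))
  t <- (seq_len(n) - 1) * step_min / 60

  with_seed(seed, {
    draws <- draw_ferment_params(params)
    mu <- as.matrix(phase_memberships(t))
    nm <- params$noise_mult

    blend_noise_sd <- function(per_phase) {
      blend_phases(matrix(per_phase, n, 4, byrow = TRUE), mu)
    }

    xbio <- blend_phases(phase_value("biomass_gL", t, params = params,
                                     draws = draws), mu)
    sugar <- blend_phases(phase_value("sugar_gL", t, params = params,
                                      draws = draws), mu)
    ph <- blend_phases(phase_value("pH", t, params = params, draws = draws), mu)
    co2 <- blend_phases(phase_value("co2", t, state = xbio, params = params,
                                    draws = draws), mu)
    alc <- blend_phases(phase_value("alcohol_gL", t, state = xbio,
                                    params = params, draws = draws), mu)
    temp <- rep(params$temp_setpoint, n)

    biomass_out <- xbio
    if (noise && nm > 0) {
      biomass_out <- xbio + rnorm(n, 0, blend_noise_sd(params$noise_sd$biomass) * nm)
      sugar <- sugar + rnorm(n, 0, blend_noise_sd(params$noise_sd$sugar) * nm)
      ph <- ph + rnorm(n, 0, blend_noise_sd(params$noise_sd$pH) * nm)
      temp <- temp + rnorm(n, 0, params$noise_sd$temp * nm)
      co2 <- co2 + rexp(n, rate = 1 / (blend_phases(
        matrix(params$co2_noise_scale, n, 4, byrow = TRUE), mu) * nm))
    }

    curve <- data.frame(time_h = t, biomass_gL = biomass_out, sugar_gL = sugar,
                        co2 = co2, pH = ph, temp_C = temp, alcohol_gL = alc)
    alcohol_source <- "rule_chain"
    if (!is.null(controller)) {
      curve$alcohol_gL <- infer_series(controller, curve)
      alcohol_source <- "controller"
    }
    structure(curve, seed = seed, params = params, draws = draws,
              noisy = noise, alcohol_source = alcohol_source,
              class = c("fermentation_curve", "data.frame"))
  })
}

#' Generate a dataset of independent fermentation curves
#'
#' Each curve gets its own per-fermentation parameter draws under a child
#' seed derived reproducibly from `seed`; the collection is bit-reproducible
#' for a fixed master seed and can be partitioned into chunks for continual
#' training.
#'
#' @param n_fermentations Number of curves (>= 1).
#' @param seed Master seed.
#' @param params A [kinetic_params()] object.
#' @param ... Passed to [generate_curve()] (`duration_h`, `step_min`,
#'   `noise`, `controller`).
#' @return A list of `fermentation_curve` objects.
#' @export
generate_dataset <- function(n_fermentations, seed = NULL,
                             params = kinetic_params(), ...) {
  stopifnot(n_fermentations >= 1)
  seeds <- child_seeds(seed, n_fermentations)
  lapply(seq_len(n_fermentations), function(i) {
    generate_curve(params = params, seed = seeds[i], ...)
  })
}

#' Rate-equation consistency diagnostic
#'
#' Compares finite-difference derivatives of a noise-free curve against the
#' growth/consumption rate equations dX/dt = mu X and
#' dS/dt = -(1/Y) mu X (maintenance term set to zero), with the specific
#' growth rate mu backed out from dX/dt.  By construction the biomass
#' residual is ~0; the sugar residual measures how far the closed-form sugar
#' trajectory departs from strict yield-coupled consumption.  Reported for
#' inspection only; no pass/fail.
#'
#' @param curve A noise-free `fermentation_curve`.
#' @param params The [kinetic_params()] used to generate it.
#' @return List with `mu` (implied growth rate series), and mean absolute
#'   residuals `biomass_residual`, `sugar_residual`.
#' @export
ode_consistency_check <- function(curve, params = attr(curve, "params")) {
  if (is.null(params)) params <- kinetic_params()
  if (isTRUE(attr(curve, "noisy"))) {
    warning("curve appears noisy; residuals will be dominated by noise")
  }
  t <- curve$time_h
  dt <- diff(t)
  dX <- diff(curve$biomass_gL) / dt
  dS <- diff(curve$sugar_gL) / dt
  Xmid <- (head(curve$biomass_gL, -1) + tail(curve$biomass_gL, -1)) / 2
  mu <- dX / pmax(Xmid, 1e-12)
  sugar_pred <- -(1 / params$yield_YXS) * mu * Xmid
  list(mu = mu,
       biomass_residual = mean(abs(dX - mu * Xmid)),
       sugar_residual = mean(abs(dS - sugar_pred)))
}

#' @export
print.fermentation_curve <- function(x, ...) {
  cat(sprintf("<fermentation_curve: %d points, %.1f h at %.3g-min step; alcohol: %s>\n",
              nrow(x), max(x$time_h),
              if (nrow(x) > 1) (x$time_h[2] - x$time_h[1]) * 60 else NA,
              attr(x, "alcohol_source") %||% "rule_chain"))
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
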