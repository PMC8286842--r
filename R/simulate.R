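# Synthetic-data generators: forward models plus measurement noise, so the
# whole pipeline is testable without any experimental download.

#' Measurement-noise model
#'
#' Multiplicative Gaussian noise (relative error, the default with a 3%
#' coefficient of variation, motivated by the few-percent standard errors
#' typical of fitted steady-state parameters), additive Gaussian noise (an
#' absolute AU floor, the default for titration absorbances), or both.
#'
#' @param kind `"multiplicative"`, `"additive"` or `"mixed"`.
#' @param cv Coefficient of variation of the multiplicative component
#'   (default 0.03).
#' @param sigma_abs Standard deviation of the additive component
#'   (default 1e-4 AU).
#' @param seed Integer seed recorded in the provenance of every generated
#'   dataset.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative", "additive", "mixed"),
                        cv = 0.03, sigma_abs = 1e-4, seed = 1L) {
  kind <- match.arg(kind)
  check_scalar(cv, "cv", nonneg = TRUE)
  check_scalar(sigma_abs, "sigma_abs", nonneg = TRUE)
  check_scalar(seed, "seed")
  structure(list(kind = kind, cv = cv, sigma_abs = sigma_abs,
                 seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(truth, noise) {
  n <- length(truth)
  switch(noise$kind,
         multiplicative = truth * (1 + noise$cv * stats::rnorm(n)),
         additive = truth + noise$sigma_abs * stats::rnorm(n),
         mixed = truth * (1 + noise$cv * stats::rnorm(n)) +
           noise$sigma_abs * stats::rnorm(n))
}

#' Concentration design grid for simulated rate measurements
#'
#' @param conc_A_levels,conc_B_levels Substrate levels (µM), all >= 0.
#' @param conc_I_levels Inhibitor levels (µM), default 0 (no inhibitor).
#' @param conc_E Enzyme concentration (µM), default 0.01 (10 nM, a typical
#'   catalytic amount).
#' @param replicates Replicates per grid point (default 1).
#' @return An object of class `design_grid`.
#' @export
design_grid <- function(conc_A_levels, conc_B_levels, conc_I_levels = 0,
                        conc_E = 0.01, replicates = 1L) {
  check_conc(conc_A_levels, "conc_A_levels")
  check_conc(conc_B_levels, "conc_B_levels")
  check_conc(conc_I_levels, "conc_I_levels")
  check_scalar(conc_E, "conc_E", positive = TRUE)
  if (length(conc_A_levels) == 0L || length(conc_B_levels) == 0L) {
    nk_stop("design grid has an empty concentration axis",
            "nitrokin_design_error")
  }
  structure(list(conc_A_levels = conc_A_levels,
                 conc_B_levels = conc_B_levels,
                 conc_I_levels = conc_I_levels,
                 conc_E = conc_E, replicates = as.integer(replicates)),
            class = "design_grid")
}

# Default factorial grid: each substrate at 0.25-8x its Km.  This brackets
# both Km values symmetrically in log space, the information-rich region of
# the rate surface.
default_kinetics_grid <- function(params) {
  mult <- 2^(-2:3)
  design_grid(conc_A_levels = params$Km_A * mult,
              conc_B_levels = params$Km_B * mult)
}

default_inhibition_grid <- function(iparams) {
  mult <- 2^(-2:3)
  ki <- if (is.finite(iparams$Ki_A)) iparams$Ki_A else iparams$Ki_B
  if (!is.finite(ki)) {
    nk_stop("cannot choose inhibitor levels: both Ki values are unbounded",
            "nitrokin_design_error")
  }
  design_grid(conc_A_levels = iparams$Km_A * mult,
              conc_B_levels = iparams$Km_B * mult,
              conc_I_levels = c(0, ki, 2.5 * ki))
}

provenance_attrs <- function(df, truth, noise, design = NULL) {
  attr(df, "provenance") <- list(truth = unclass(truth),
                                 noise = unclass(noise), design = design)
  df
}

#' Simulate initial-rate measurements from the ping-pong rate law
#'
#' Generates the full factorial of the grid's substrate levels, evaluates
#' the ping-pong rate law, multiplies by the enzyme concentration and
#' applies the noise model.  With the default grid each substrate spans
#' 0.25–8 times its Michaelis constant.
#'
#' @param params [kinetic_params()] generating truth.
#' @param grid A [design_grid()]; `NULL` (default) uses the Km-anchored
#'   factorial grid.
#' @param noise A [noise_model()].
#' @return Data frame of observations (`conc_A`, `conc_B`, `conc_I`,
#'   `conc_E`, `rate`, `label`) with a `provenance` attribute recording
#'   truth, grid and seed.
#' @examples
#' obs <- simulate_kinetics(kinetic_params(81, 20.6, 10.9))
#' fit_pingpong_global(obs)
#' @export
simulate_kinetics <- function(params, grid = NULL,
                              noise = noise_model()) {
  params <- as_kinetic_params(params)
  if (is.null(grid)) grid <- default_kinetics_grid(params)
  stopifnot(inherits(grid, "design_grid"), inherits(noise, "noise_model"))
  d <- expand.grid(conc_A = grid$conc_A_levels,
                   conc_B = grid$conc_B_levels,
                   rep = seq_len(grid$replicates))
  d$rep <- NULL
  set.seed(noise$seed)
  truth <- pingpong_rate(params, d$conc_A, d$conc_B) * grid$conc_E
  out <- data.frame(conc_A = d$conc_A, conc_B = d$conc_B, conc_I = 0,
                    conc_E = grid$conc_E,
                    rate = apply_noise(truth, noise),
                    label = "pingpong", stringsAsFactors = FALSE)
  provenance_attrs(out, params, noise, unclass(grid))
}

#' Simulate the mixed-inhibition assay design
#'
#' Reproduces the experimental design used for inhibitor studies: each
#' substrate is varied over the grid's levels while the co-substrate is
#' held fixed (at the top of its grid range), and the two series are
#' crossed with every inhibitor level.  Defaults place the inhibitor at
#' 0, Ki and 2.5 Ki.  The grid must include an inhibitor-free level.
#'
#' @param iparams [inhibition_params()] generating truth (at least one
#'   finite Ki).
#' @inheritParams simulate_kinetics
#' @return Data frame of observations with `label` marking the varied
#'   substrate (`"varyA"`/`"varyB"`).
#' @export
simulate_inhibition <- function(iparams, grid = NULL,
                                noise = noise_model()) {
  stopifnot(inherits(iparams, "inhibition_params"))
  if (is.null(grid)) grid <- default_inhibition_grid(iparams)
  stopifnot(inherits(grid, "design_grid"), inherits(noise, "noise_model"))
  if (!any(grid$conc_I_levels == 0)) {
    nk_stop("inhibition designs must include the inhibitor-free level conc_I = 0",
            "nitrokin_design_error")
  }
  fixed_A <- max(grid$conc_A_levels)
  fixed_B <- max(grid$conc_B_levels)
  series <- rbind(
    expand.grid(conc_A = grid$conc_A_levels, conc_B = fixed_B,
                conc_I = grid$conc_I_levels, label = "varyA",
                stringsAsFactors = FALSE),
    expand.grid(conc_A = fixed_A, conc_B = grid$conc_B_levels,
                conc_I = grid$conc_I_levels, label = "varyB",
                stringsAsFactors = FALSE))
  series <- series[rep(seq_len(nrow(series)), each = grid$replicates), ]
  set.seed(noise$seed)
  truth <- pingpong_inhibited_rate(iparams, series$conc_A, series$conc_B,
                                   series$conc_I) * grid$conc_E
  out <- data.frame(conc_A = series$conc_A, conc_B = series$conc_B,
                    conc_I = series$conc_I, conc_E = grid$conc_E,
                    rate = apply_noise(truth, noise),
                    label = series$label, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  provenance_attrs(out, iparams, noise, unclass(grid))
}

#' Simulate a potentiometric titration
#'
#' Evaluates the chosen Nernst model at the given potentials (by default
#' the stepped down-then-up schedule of [titration_schedule()]), maps the
#' oxidised fraction onto absorbances through the endpoints, and applies
#' the noise model (additive by default: absorbance noise does not scale
#' with signal).  Oxidative and reductive cycles share the same underlying
#' curve — no hysteresis is simulated; an optional endpoint drift knob
#' exists purely for robustness testing.
#'
#' @param truth A [redox_two_step_params()] or [redox_concerted_params()].
#' @param potentials Either a data frame with `potential` and `cycle`
#'   columns (as from [titration_schedule()]) or a numeric vector of
#'   potentials (mV); `NULL` uses the default schedule.
#' @param endpoints `c(A_ox, A_red)` absorbances (AU), distinct; the
#'   defaults (0.8, 0.1) are arbitrary but recorded in provenance.
#' @param noise A [noise_model()] (default additive, sigma 1e-4 AU).
#' @param cycles Passed to [titration_schedule()] when `potentials` is
#'   `NULL`.
#' @param endpoint_drift Fractional endpoint offset applied to the
#'   oxidative cycle only (default 0 — cycles overlay).
#' @return Data frame of titration points (`potential`, `absorbance`,
#'   `cycle`, `replicate`) with provenance.
#' @export
simulate_titration <- function(truth, potentials = NULL,
                               endpoints = c(A_ox = 0.8, A_red = 0.1),
                               noise = noise_model(kind = "additive"),
                               cycles = "both", endpoint_drift = 0) {
  if (!(inherits(truth, "redox_two_step_params") ||
        inherits(truth, "redox_concerted_params"))) {
    nk_stop("truth must be a redox_two_step_params or redox_concerted_params",
            "nitrokin_input_error")
  }
  if (is.null(potentials)) potentials <- titration_schedule(cycles)
  if (is.numeric(potentials)) {
    potentials <- data.frame(potential = potentials, cycle = "cycle1",
                             stringsAsFactors = FALSE)
  }
  if (nrow(potentials) == 0L) {
    nk_stop("no potentials supplied", "nitrokin_input_error")
  }
  A_ox <- endpoints[[1]]
  A_red <- endpoints[[2]]
  if (A_ox == A_red) {
    nk_stop("degenerate endpoints: A_ox must differ from A_red",
            "nitrokin_degenerate_endpoints")
  }
  y <- if (inherits(truth, "redox_two_step_params")) {
    fraction_oxidised_two_step(truth, potentials$potential)
  } else {
    fraction_oxidised_concerted(truth, potentials$potential)
  }
  drift <- ifelse(potentials$cycle == "oxidative", 1 + endpoint_drift, 1)
  set.seed(noise$seed)
  absorbance <- apply_noise((A_red + y * (A_ox - A_red)) * drift, noise)
  out <- data.frame(potential = potentials$potential,
                    absorbance = absorbance,
                    cycle = potentials$cycle, replicate = 1L,
                    stringsAsFactors = FALSE)
  provenance_attrs(out, truth, noise,
                   list(endpoints = c(A_ox = A_ox, A_red = A_red),
                        endpoint_drift = endpoint_drift))
}

#' Simulate a linear absorbance-vs-time assay trace
#'
#' Forward model of the Beer–Lambert conversion: a linear absorbance ramp
#' with slope `sign * rate * Δε * path / 1e6` AU/s plus noise.
#'
#' @param molar_rate Reaction rate (µM s⁻¹), >= 0.
#' @param entry An [extinction_entry()].
#' @param duration,dt Trace length and sampling interval (s),
#'   `duration > dt > 0`.
#' @param noise A [noise_model()] (additive component used).
#' @param a0 Starting absorbance (AU).
#' @param sign `+1` for an increasing trace, `-1` for a decreasing one.
#' @param path_length_cm Optical path (cm).
#' @return An [assay_trace()].
#' @export
simulate_assay_trace <- function(molar_rate, entry, duration = 60, dt = 0.5,
                                 noise = noise_model(kind = "additive"),
                                 a0 = 1, sign = 1, path_length_cm = 1) {
  check_scalar(molar_rate, "molar_rate", nonneg = TRUE)
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  if (duration <= dt) {
    nk_stop("'duration' must exceed 'dt'", "nitrokin_input_error")
  }
  times <- seq(0, duration, by = dt)
  slope <- sign * molar_rate * 1e-6 * entry$delta_eps * path_length_cm
  set.seed(noise$seed)
  absorbance <- apply_noise(a0 + slope * times, noise)
  assay_trace(times, absorbance, wavelength_nm = entry$wavelength_nm,
              path_length_cm = path_length_cm)
}
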