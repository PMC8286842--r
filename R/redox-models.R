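#' Nernst slope constants
#'
#' The titration models use the conventional printed slopes of 59 mV/decade
#' for a one-electron couple and 29.5 mV/decade for a concerted two-electron
#' couple (25°C values, fixed rather than recomputed from temperature so the
#' fitted equations match the published form exactly).  A
#' temperature-parameterised mode is available but off by default.
#'
#' @param temperature_K If supplied, slopes are computed as
#'   `ln(10)*R*T/(n*F)` in mV at this temperature instead of the fixed
#'   printed values.
#' @return List with `slope_1e` and `slope_2e` (mV/decade).
#' @export
nernst_constants <- function(temperature_K = NULL) {
  if (is.null(temperature_K)) {
    return(list(slope_1e = 59, slope_2e = 29.5))
  }
  check_scalar(temperature_K, "temperature_K", positive = TRUE)
  s1 <- log(10) * 8.31446261815324 * temperature_K / 96485.33212 * 1000
  list(slope_1e = s1, slope_2e = s1 / 2)
}

#' Two-step (sequential one-electron) Nernst parameter set
#'
#' Parameters of the two sequential one-electron Nernst waves fitted to the
#' oxidised fraction of the flavin: the two transition potentials `E1` and
#' `E2` (mV vs NHE) and `b`, the relative absorbance contribution of the
#' semiquinone intermediate (dimensionless, >= 0).
#'
#' Note the parametrisation follows the fitted equation as published:
#' `E1` enters the term that grows with oxidising potential and `E2` the
#' term that grows with reducing potential, so a strongly stabilised
#' semiquinone corresponds to `E1 > E2` under this labelling.  For the
#' nearly equal potentials typical of NfsA the distinction is immaterial.
#'
#' @param E1,E2 Transition potentials (mV vs NHE), finite.
#' @param b Relative semiquinone absorbance (>= 0).
#' @return An object of class `redox_two_step_params`.
#' @export
redox_two_step_params <- function(E1, E2, b) {
  check_scalar(E1, "E1")
  check_scalar(E2, "E2")
  check_scalar(b, "b", nonneg = TRUE)
  structure(list(E1 = E1, E2 = E2, b = b), class = "redox_two_step_params")
}

#' Concerted two-electron Nernst parameter set
#'
#' @param Em Midpoint potential of the quinone/hydroquinone transition
#'   (mV vs NHE), finite.
#' @return An object of class `redox_concerted_params`.
#' @export
redox_concerted_params <- function(Em) {
  check_scalar(Em, "Em")
  structure(list(Em = Em), class = "redox_concerted_params")
}

#' Oxidised fraction under the two sequential one-electron Nernst waves
#'
#' Evaluates
#' \deqn{y = \frac{10^{(x-E_1)/59} + b}{1 + 10^{(x-E_1)/59} + 10^{(E_2-x)/59}}}
#' exactly in the published form.  `y -> 1` as the potential becomes very
#' oxidising and `y -> 0` as it becomes very reducing; exponents are clamped
#' in log-space so the curve is numerically stable over at least ±1000 mV
#' around the transition.
#'
#' @param params A [redox_two_step_params()].
#' @param potential Applied potential x (mV vs NHE), vectorised.
#' @return Dimensionless oxidised-fraction signal (in `[0, 1]` for b <= 1).
#' @examples
#' p <- redox_two_step_params(E1 = -270, E2 = -270, b = 0.5)
#' fraction_oxidised_two_step(p, -270)   # 0.5 at the shared midpoint
#' @export
fraction_oxidised_two_step <- function(params, potential) {
  stopifnot(inherits(params, "redox_two_step_params"))
  s <- nernst_constants()$slope_1e
  t_ox <- pow10((potential - params$E1) / s)
  t_red <- pow10((params$E2 - potential) / s)
  (t_ox + params$b) / (1 + t_ox + t_red)
}

#' Oxidised fraction under the concerted two-electron Nernst model
#'
#' Evaluates \deqn{y = \frac{1}{1 + 10^{(E_m-x)/29.5}}}, a single wave with
#' the two-electron slope.  Symmetric about the midpoint:
#' `y(Em + d) + y(Em - d) = 1`.
#'
#' @param params A [redox_concerted_params()].
#' @param potential Applied potential (mV vs NHE), vectorised.
#' @return Oxidised fraction in (0, 1).
#' @examples
#' fraction_oxidised_concerted(redox_concerted_params(-264), -234.5)  # 0.909
#' @export
fraction_oxidised_concerted <- function(params, potential) {
  stopifnot(inherits(params, "redox_concerted_params"))
  s <- nernst_constants()$slope_2e
  1 / (1 + pow10((params$Em - potential) / s))
}

#' Species fractions along the two-step titration
#'
#' Reads the three denominator terms of the two-step model as relative
#' populations, oxidised : semiquinone : reduced =
#' `10^((x-E1)/59) : 1 : 10^((E2-x)/59)`, and normalises them to fractions
#' summing to one.  This interpretive reading is isolated here; under it the
#' semiquinone fraction peaks at the mean of the two potentials, with peak
#' height `1/(1 + 2*10^((E2-E1)/118))` — below 1/3 whenever `E2 >= E1`.
#'
#' @param params A [redox_two_step_params()] (`b` does not enter).
#' @param potential Applied potential (mV vs NHE), vectorised.
#' @return Data frame with columns `f_ox`, `f_sq`, `f_red` summing to 1.
#' @export
species_fractions_two_step <- function(params, potential) {
  stopifnot(inherits(params, "redox_two_step_params"))
  s <- nernst_constants()$slope_1e
  t_ox <- pow10((potential - params$E1) / s)
  t_red <- pow10((params$E2 - potential) / s)
  tot <- 1 + t_ox + t_red
  data.frame(f_ox = t_ox / tot, f_sq = 1 / tot, f_red = t_red / tot)
}

#' Scale raw titration absorbances to oxidised fractions
#'
#' Linear rescaling `y = (A - A_red) / (A_ox - A_red)` using the absorbance
#' of the fully oxidised and fully reduced solution.  Values falling outside
#' `[0, 1]` (noise beyond the endpoints) are retained, not clipped, and
#' flagged in the `out_of_range` column.
#'
#' @param points Data frame with columns `potential` (mV) and `absorbance`
#'   (AU); other columns are carried through.
#' @param endpoints Numeric length-2 `c(A_ox, A_red)`; must differ.
#' @return `points` with columns `y` and `out_of_range` added.
#' @export
normalise_titration <- function(points, endpoints) {
  stopifnot(is.data.frame(points),
            all(c("potential", "absorbance") %in% names(points)))
  A_ox <- endpoints[[1]]
  A_red <- endpoints[[2]]
  if (!is.finite(A_ox) || !is.finite(A_red) || A_ox == A_red) {
    nk_stop("degenerate endpoints: A_ox and A_red must be distinct finite values",
            "nitrokin_degenerate_endpoints")
  }
  points$y <- (points$absorbance - A_red) / (A_ox - A_red)
  points$out_of_range <- points$y < 0 | points$y > 1
  points
}

#' The stepped potential schedule of the titration protocol
#'
#' The reductive sweep steps the applied potential from −50 mV to −350 mV
#' in 20 mV steps; the oxidative return sweep goes to −335 mV and then from
#' −320 mV up to −90 mV in 20 mV steps, finishing at −60 mV.  Potentials
#' are vs NHE.
#'
#' @param cycles `"both"` (default), `"reductive"` or `"oxidative"`.
#' @return Data frame with columns `potential` (mV) and `cycle`.
#' @export
titration_schedule <- function(cycles = c("both", "reductive", "oxidative")) {
  cycles <- match.arg(cycles)
  red <- data.frame(potential = seq(-50, -350, by = -20),
                    cycle = "reductive", stringsAsFactors = FALSE)
  ox <- data.frame(potential = c(-335, seq(-320, -90, by = 20), -60),
                   cycle = "oxidative", stringsAsFactors = FALSE)
  switch(cycles, both = rbind(red, ox), reductive = red, oxidative = ox)
}
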