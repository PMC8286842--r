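---
title: "Models and methods in nitrokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in nitrokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrokin)
```

`nitrokin` analyses the steady-state kinetics and flavin redox chemistry of
two-substrate oxidoreductases of the nitroreductase family.  This vignette
records the models, their assumptions, the tunable parameters, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## Units and conventions

Concentrations are µM, per-enzyme rates s⁻¹, absolute rates µM s⁻¹, and
potentials mV vs NHE, throughout.  Conversions (absorbance to molarity,
electrode-reference offsets) happen only at I/O boundaries and are always
explicit options, never guesses.  Rates are stored absolute and divided by
the enzyme concentration at fit time, since the rate laws describe
`v/[E]`.  Whether `[E]` means active sites or dimers is the user's choice
of input — the package is agnostic and the quoted `kcat` scales
accordingly.

## The ping-pong rate law

In a substituted-enzyme mechanism the reductant (NADPH) and the oxidising
substrate visit the enzyme sequentially, exchanging two electrons via the
FMN cofactor.  The steady-state rate over both substrate concentrations is

$$\frac{v}{[E]} = \frac{k_{cat}[A][B]}{K_{mA}[B] + K_{mB}[A] + [A][B]},$$

with no `KmA·KmB` constant term in the denominator — the signature that
makes double-reciprocal lines at different fixed co-substrate
concentrations parallel (common slope `KmA/kcat`).  `pingpong_rate()`
implements this law; `fit_pingpong_global()` estimates the three
parameters from all points simultaneously with **unit weights** (equal
weighting of all points).  A relative-weighting option is deliberately
absent: with multiplicative noise a weighted fit would be slightly more
efficient, but unit weights are the analysis convention this package
reproduces, and the recovery tests show the difference is immaterial at
the few-percent noise level typical of these assays.

Mixed inhibition multiplies each Michaelis term by `(1 + [I]/Ki)` for its
half-reaction:

$$\frac{v}{[E]} = \frac{k_{cat}[A][B]}
 {K_{mA}[B]\left(1+\tfrac{[I]}{K_{iA}}\right) +
  K_{mB}[A]\left(1+\tfrac{[I]}{K_{iB}}\right) + [A][B]}.$$

"No competition in this half" is encoded by an explicit unbounded
sentinel, `Ki = Inf`, which makes the factor exactly 1 — never by a
silently large finite number.  The restricted single-half models are
therefore true parameter restrictions of the full model, and
`compare_nested()` applies the extra-sum-of-squares F test
`F = ((rss_r − rss_f)/(df_r − df_f)) / (rss_f / df_f)` to decide whether
both halves are genuinely inhibited.

## Spectrophotometric arithmetic

Initial rates are the OLS slope of absorbance against time over an early
window (`initial_rate_from_trace()`).  The default window is the first
20% of the trace or the first 15 s, whichever is longer: assay traces are
typically 1–2 min, and this keeps the window inside the initial-linear
regime while retaining enough points for a stable slope.  Slopes convert
to molar rates through `rate = 10^6 |slope| / (Δε · path)`; the built-in
`extinction_table()` carries the molar absorbance changes for the
nitrofurazone (4300 at 420 nm, 880 at 440 nm), nitrofurantoin (13 807 at
400 nm, 7970 at 420 nm), CB1954 (1200 at 420 nm) and NADPH (6200 at
340 nm) readouts, plus the cytochrome-c-coupled readout (13 500 at 550 nm
*per NADPH oxidised*, flagged `per_nadph`).  The coupled assay is handled
purely as a stoichiometric readout — no kinetic model of the coupling
reaction is attempted, since it is used only to amplify the absorbance
change.

`protein_concentration()` inverts the two-wavelength forward model
`A454 = ε_FMN,454·[FMN]·l` and
`A280 = (ε_NfsA,280·[NfsA] + ε_FMN,280·[FMN])·l` to correct protein
estimates for free FMN.  A negative protein concentration (FMN accounting
for more than the whole A280) is reported as an error rather than clipped,
because it signals an inconsistent measurement, not a small protein
amount.

## Redox titration models

The oxidised fraction of the flavin, read from its 458 nm absorbance as a
function of applied potential `x`, is described either by two sequential
one-electron Nernst waves,

$$y = \frac{10^{(x-E_1)/59} + b}{1 + 10^{(x-E_1)/59} + 10^{(E_2-x)/59}},$$

where `b` is the relative absorbance of the semiquinone intermediate, or
by a single concerted two-electron wave,

$$y = \frac{1}{1 + 10^{(E_m-x)/29.5}}.$$

The slope constants are fixed at the conventional 25 °C values 59 and
29.5 mV/decade (an optional temperature-parameterised mode exists, off by
default) so the fitted equations match the published form digit for
digit.

**A note on the E1/E2 labels.** In the two-step equation as fitted, `E1`
appears in the term that grows with *oxidising* potential and `E2` in the
term that grows with *reducing* potential.  Under the standard population
algebra for O/S/R couples those roles are usually carried by the other
label, so a strongly stabilised semiquinone corresponds to `E1 > E2`
under this package's (published-form) parametrisation.  The package
implements the equation verbatim and documents the interpretation in one
place, `species_fractions_two_step()`, which reads the three denominator
terms as the relative populations oxidised : semiquinone : reduced.  For
flavins like NfsA's, whose two potentials are nearly equal, the labelling
is immaterial; it matters only when simulating strongly separated
potentials, and the package's tests use the parametrisation consistently.

## The two-stage titration fit

`fit_redox()` follows the two-stage procedure used for OTTLE titrations:

1. **Endpoints.**  Each titration cycle is fitted with *free* absorbance
   endpoints `(A_ox, A_red)` to establish the absorbance of the fully
   oxidised and fully reduced solution.  Both candidate models are fitted
   at this stage and the endpoints of the better-fitting one are kept.
   This is a deliberate design choice: estimating endpoints with the
   concerted shape alone biases them whenever the underlying curve is
   two-step (the broader two-step transition leaks into the endpoint
   estimates), enough to displace the downstream `E1` by ~15 mV on clean
   synthetic data.  With the dual-model stage 1, noiseless data generated
   by either model round-trips exactly.
2. **Normalisation.**  Every point is scaled to an oxidised fraction
   `y = (A − A_red)/(A_ox − A_red)` with its cycle's endpoints
   (`normalise_titration()`).  Values outside [0, 1] are retained and
   flagged, never clipped.  If the scaled data span less than 0.5 of the
   range, a poorly-anchored-endpoints warning is raised and recorded in
   the fit.
3. **Pooled fit.**  The scaled points from all cycles are fitted jointly
   to both models, and the fits compared.

Endpoint uncertainty is carried forward only as the warning flag, not as
stage-2 weights — the simplest faithful reading of a two-stage analysis,
and consistent with the unit-weighting convention above.

Because the concerted model is *not* an exact parameter restriction of
the two-step equation (no setting of `E1`, `E2`, `b` reproduces the
29.5 mV shape identically at finite separation), the primary comparison
uses the small-sample-corrected information criterion (AICc, error
variance counted as a parameter); the F test treating the concerted model
as a two-parameter restriction is also reported, flagged approximate.
Both agree on all synthetic cases exercised in the tests.

## Fitting machinery

All fits use Levenberg–Marquardt least squares (`minpack.lm::nls.lm`)
with cost tolerance 1e−10 and parameter tolerance 1e−8.  Positive
parameters (`kcat`, `Km`, `Ki`, `b`) are optimised on the log scale,
which enforces positivity without constrained optimisation; potentials
and absorbance endpoints are fitted in natural space.  Eight starts are
used by default: the first from data-driven heuristics (`kcat₀` = max
observed `v/[E]`, `Km₀` = median concentration, `E₀` = potential nearest
`y = 0.5`, endpoints from the absorbance extremes), the rest jittered
(log-normal factor ~3 for log-scale parameters, ±30 mV s.d. for
potentials).  The reported optimum is the best of all starts; ties within
1e−9 relative cost are broken by the smaller parameter-vector norm, so a
fit with a given seed is fully deterministic.  Standard errors come from
`σ² (JᵀJ)⁻¹` with a central-difference Jacobian in natural space at the
optimum (SVD pseudo-inverse fallback for near-singular designs), and
per-parameter *P* values are two-sided *t* tests against zero with the
residual degrees of freedom.  `kcat/Km` standard errors use first-order
propagation *including* the `kcat`–`Km` covariance by default; ignoring
the covariance (the other common convention, whose use is flagged in the
result) changes the SE by the `−2(kcat/Km³)cov` term, a few tens of
percent for typical correlated estimates.

Nernst exponentials are evaluated with exponents clamped to ±300 decades;
the clamp only engages thousands of mV outside any physical titration
range and exists purely to keep limiting values finite.

## The synthetic-data generators

The generators define the study conditions under which the package's
statistical behaviour is demonstrated:

* **Kinetics grids.**  The experimental concentration grids behind the
  published fits are not printed, so the default design is declared, not
  inferred: each substrate at `Km × {0.25, 0.5, 1, 2, 4, 8}`, full
  factorial (36 points), one replicate, `[E]` = 0.01 µM (a typical ~10 nM
  catalytic amount).  This brackets both Km values symmetrically in log
  space, the information-rich region of the rate surface.
* **Inhibition designs** mirror the assay layout: each substrate varied
  over its six levels at fixed co-substrate (the top of the co-substrate
  range), crossed with inhibitor at `{0, Ki, 2.5·Ki}` — an
  inhibitor-free series plus two inhibited ones.
* **Noise** is multiplicative Gaussian with cv 3% for rates (motivated by
  the few-percent standard errors typical of fitted steady-state
  parameters) and additive Gaussian with σ = 1e−4 AU for titration
  absorbances (photometric noise does not scale with signal).
* **Titrations** follow the stepped protocol: a reductive sweep from −50
  to −350 mV in 20 mV steps, then an oxidative return at −335 and −320 to
  −90 mV in 20 mV steps, ending at −60 mV (30 points over both cycles).
  Endpoints default to 0.8/0.1 AU — arbitrary but recorded in provenance.
  The two cycles share one underlying curve (no hysteresis, matching
  well-equilibrated titrations); an `endpoint_drift` knob exists only for
  robustness testing of the per-cycle normalisation.

What the generators do *not* emulate — substrate depletion curvature,
enzyme inactivation, inner-filter effects, co-solvent and ionic-strength
effects, mediator kinetics — bounds what the passing tests show: they
demonstrate that the estimators are correct and well-calibrated for data
that follow the stated models with the stated noise, not that real assays
are free of these artefacts.

## Problem sizes and runtime

The recovery experiments run the full pipeline at its defaults: 10–20
seeds of 36-point surfaces for the kinetic and inhibition recoveries and
30-point titrations for the redox fits.  These sizes match the scale of
the corresponding experiments; every fit takes milliseconds, so the whole
test suite and the reproduction script run in seconds.

## Known limitations

* No Bayesian inference or bootstrap intervals; uncertainty is curvature
  based (Monte-Carlo propagation appears only as a test oracle).
* Pre-steady-state (burst) kinetics and explicit microscopic rate
  constants of the two half-reactions are out of scope.
* The concerted-vs-two-step verdict for nearly equal potentials is driven
  by small shape differences near the transition, so it degrades
  gracefully (towards the parsimonious model) as titration noise grows —
  as it should.
* Table-format support is deliberately narrow (the documented CSV
  dialects with unit-suffixed headers); anything else should be converted
  explicitly rather than guessed at.
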