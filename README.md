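# nitrokin

Steady-state and redox analysis for flavin-dependent nitroreductases.

Bacterial nitroreductases such as *Escherichia coli* NfsA reduce
nitroaromatic antibiotics (nitrofurantoin, nitrofurazone), anticancer
prodrugs (CB1954) and quinones using NADPH, via a substituted-enzyme
(ping-pong) mechanism: NADPH first reduces the FMN cofactor and leaves,
then the nitroaromatic substrate binds and is reduced by the flavin.
Characterising such an enzyme requires three linked pieces of quantitative
analysis, and `nitrokin` implements all of them for R users working on
enzyme kinetics and flavin biophysics:

1. **Global ping-pong kinetics.** Initial rates measured over a grid of
   both substrate concentrations are fitted simultaneously to

   ```
   v/[E] = kcat [A][B] / (KmA [B] + KmB [A] + [A][B])
   ```

   giving the turnover number `kcat` and a Michaelis constant for each
   substrate, with standard errors, *t*-based *P* values and catalytic
   efficiencies `kcat/Km` with delta-method error propagation
   (`fit_pingpong_global()`, `derived_efficiency()`).  Apparent
   single-substrate fits at a fixed co-substrate are also provided
   (`fit_single_substrate()`).

2. **Mixed inhibition of both half-reactions.** Rates measured with and
   without an inhibitor are fitted simultaneously to

   ```
   v/[E] = kcat [A][B] / (KmA [B](1+[I]/KiA) + KmB [A](1+[I]/KiB) + [A][B])
   ```

   yielding a dissociation constant for the inhibitor in each half of the
   ping-pong cycle.  Restricted fits (inhibition of only one half, the
   excluded Ki held at the unbounded sentinel `Inf`) are compared with the
   full model by the extra-sum-of-squares F test
   (`fit_inhibition_global()`, `compare_nested()`).

3. **Redox titrations.** Spectroelectrochemical (OTTLE) titrations of the
   protein's FMN are fitted both to two sequential one-electron Nernst
   waves (potentials E1 and E2, semiquinone absorbance fraction `b`) and to
   a concerted two-electron wave (midpoint Em),

   ```
   y = (10^((x-E1)/59) + b) / (1 + 10^((x-E1)/59) + 10^((E2-x)/59))
   y = 1 / (1 + 10^((Em-x)/29.5))
   ```

   using the published two-stage procedure: per-cycle endpoint estimation,
   normalisation to the oxidised fraction, then a pooled fit of both
   models with an information-criterion comparison (`fit_redox()`).

Around the models sit the assay arithmetic (initial-rate extraction from
absorbance traces, Beer–Lambert conversion through a built-in table of
molar absorbance changes, two-wavelength protein/FMN deconvolution), a
synthetic-data generator for every input, CSV readers/writers and a small
command line (`inst/cli/nitrokin.R`).

## Worked example

Simulate a 6×6 initial-rate surface at published NfsA/nitrofurantoin
parameters (kcat 81 s⁻¹, Km 20.6 and 10.9 µM) with 3% multiplicative
noise, and refit it:

```r
library(nitrokin)
p   <- kinetic_params(kcat = 81, Km_A = 20.6, Km_B = 10.9)
obs <- simulate_kinetics(p, noise = noise_model(cv = 0.03, seed = 42))
fit <- fit_pingpong_global(obs)
fit
#> Nonlinear least-squares fit: pingpong_global
#>   36 points, 3 free parameter(s), rss = 43.0337, converged: TRUE
#>      estimate std_error  p_value
#> kcat 78.35551 1.1928106 1.46e-36
#> Km_A 19.54600 0.7408811 9.32e-24
#> Km_B 10.25478 0.3891706 9.68e-24

eff <- derived_efficiency(fit, which = "A")
sprintf("kcat/Km = %.2f +/- %.2f s-1 uM-1", eff$efficiency, eff$se)
#> [1] "kcat/Km = 4.01 +/- 0.11 s-1 uM-1"
```

All three parameters are recovered within a few percent of the generating
truth, and the catalytic efficiency with its propagated standard error
brackets the true 81/20.6 = 3.9 s⁻¹ µM⁻¹.

A titration generated from two nearly equal one-electron potentials is
correctly preferred over a concerted two-electron description:

```r
pts  <- simulate_titration(redox_two_step_params(-272, -268, b = 0.3),
                           noise = noise_model(kind = "additive",
                                               sigma_abs = 0.003, seed = 1))
rfit <- fit_redox(pts)
rfit$comparison
#> Model comparison (AICc (primary); approximate extra-sum-of-squares F (secondary), approximate)
#>   full: nernst_two_step   reduced: nernst_concerted
#>   F(2, 27) = 1266, p = 2.066e-27
#>   AICc: full -317.70, reduced -186.32 (delta -131.39)
#>   preferred at alpha = 0.05: nernst_two_step
round(rfit$two_step$estimates, 1)
#>     E1     E2      b
#> -274.1 -268.6    0.2
```

## Command line

```sh
Rscript inst/cli/nitrokin.R simulate-kinetics --kcat 81 --km-a 20.6 --km-b 10.9 \
    --cv 0.03 --seed 5 --out rates.csv
Rscript inst/cli/nitrokin.R fit-kinetics rates.csv --out run/
```

writes `run/report.json` (schema `nitrokin/1`, with estimates, standard
errors, comparison verdicts and input-hash provenance) and a flat
`run/estimates.csv`.
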