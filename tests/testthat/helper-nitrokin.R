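# Shared fixtures: the published parameter sets used as generator truths.

# Global ping-pong fits (A = nitroaromatic substrate, B = NADPH)
params_nitrofurantoin <- function() kinetic_params(81, Km_A = 20.6, Km_B = 10.9)
params_nitrofurazone <- function() kinetic_params(29.6, Km_A = 13.0, Km_B = 34.0)
params_cb1954 <- function() kinetic_params(42, Km_A = 190, Km_B = 12)

# FMN inhibition of nitrofurazone reduction (A = NADPH, B = nitrofurazone)
params_fmn_inhibition <- function() {
  inhibition_params(21.4, Km_A = 62, Km_B = 11, Ki_A = 8, Ki_B = 7)
}

# Redox titration truths
truth_two_step <- function() redox_two_step_params(-272, -268, b = 0.3)
truth_concerted <- function() redox_concerted_params(-264)

noiseless <- function(seed = 1) {
  noise_model(kind = "additive", sigma_abs = 0, seed = seed)
}

noiseless_mult <- function(seed = 1) {
  noise_model(kind = "multiplicative", cv = 0, seed = seed)
}
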