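test_that("generators are seed-deterministic and seeds decorrelate", {
  p <- params_nitrofurantoin()
  a <- simulate_kinetics(p, noise = noise_model(seed = 7))
  b <- simulate_kinetics(p, noise = noise_model(seed = 7))
  expect_identical(a$rate, b$rate)
  c2 <- simulate_kinetics(p, noise = noise_model(seed = 8))
  expect_false(any(a$rate == c2$rate))

  t1 <- simulate_titration(truth_two_step(),
                           noise = noise_model(kind = "additive", seed = 3))
  t2 <- simulate_titration(truth_two_step(),
                           noise = noise_model(kind = "additive", seed = 3))
  expect_identical(t1$absorbance, t2$absorbance)
})

test_that("noiseless output of every generator round-trips through its fit", {
  p <- params_nitrofurazone()
  obs <- simulate_kinetics(p, noise = noiseless_mult())
  expect_equal(unname(fit_pingpong_global(obs)$estimates),
               c(29.6, 13.0, 34.0), tolerance = 1e-6)

  ip <- params_fmn_inhibition()
  iobs <- simulate_inhibition(ip, noise = noiseless_mult())
  expect_equal(unname(fit_inhibition_global(iobs)$estimates),
               c(21.4, 62, 11, 8, 7), tolerance = 1e-6)

  pts <- simulate_titration(truth_concerted(), noise = noiseless())
  expect_equal(suppressWarnings(
    fit_redox(pts))$concerted$estimates[["Em"]], -264, tolerance = 1e-6)

  entry <- lookup_extinction("nitrofurantoin", 400)
  tr <- simulate_assay_trace(1.0, entry, noise = noiseless())
  ir <- initial_rate_from_trace(tr)
  expect_equal(ir$slope, 0.013807, tolerance = 1e-12)
  expect_equal(absorbance_rate_to_molar_rate(ir$slope, entry), 1.0,
               tolerance = 1e-12)
})

test_that("generated values match the forward models point by point", {
  p <- params_nitrofurantoin()
  obs <- simulate_kinetics(p, noise = noiseless_mult())
  expect_equal(obs$rate,
               pingpong_rate(p, obs$conc_A, obs$conc_B) * obs$conc_E,
               tolerance = 1e-12)
  pts <- simulate_titration(truth_two_step(), noise = noiseless())
  y <- fraction_oxidised_two_step(truth_two_step(), pts$potential)
  expect_equal(pts$absorbance, 0.1 + y * 0.7, tolerance = 1e-12)
})

test_that("inhibition designs include both series and decrease with inhibitor", {
  ip <- params_fmn_inhibition()
  obs <- simulate_inhibition(ip, noise = noiseless_mult())
  expect_setequal(unique(obs$label), c("varyA", "varyB"))
  expect_equal(sort(unique(obs$conc_I)), c(0, 8, 20))
  # rates strictly decrease with I at each fixed (A, B)
  one <- obs[obs$label == "varyA" & obs$conc_A == max(obs$conc_A), ]
  one <- one[order(one$conc_I), ]
  expect_true(all(diff(one$rate) < 0))
})

test_that("degenerate designs and endpoints are rejected", {
  p <- params_nitrofurantoin()
  expect_error(design_grid(numeric(0), 1:3), class = "nitrokin_design_error")
  expect_error(
    simulate_inhibition(params_fmn_inhibition(),
                        design_grid(1:3, 1:3, conc_I_levels = c(5, 10))),
    class = "nitrokin_design_error")
  expect_error(
    simulate_titration(truth_concerted(), endpoints = c(0.5, 0.5)),
    class = "nitrokin_degenerate_endpoints")
  expect_error(
    simulate_inhibition(inhibition_params(1, 1, 1, Inf, Inf)),
    class = "nitrokin_design_error")
  expect_error(simulate_assay_trace(1, lookup_extinction("NADPH"),
                                    duration = 0.1, dt = 0.5),
               class = "nitrokin_input_error")
})

test_that("trace generator round-trips a noisy rate within tolerance", {
  entry <- lookup_extinction("CB1954", 420)
  tr <- simulate_assay_trace(0.5, entry, duration = 120, dt = 1,
                             noise = noise_model(kind = "additive",
                                                 sigma_abs = 1e-4, seed = 4))
  ir <- initial_rate_from_trace(tr, window = c(0, 120))
  back <- absorbance_rate_to_molar_rate(ir$slope, entry)
  expect_equal(back, 0.5, tolerance = 0.05)
})
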