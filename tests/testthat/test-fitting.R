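test_that("noiseless data generated by each kinetic model is recovered exactly", {
  p <- params_nitrofurantoin()
  obs <- simulate_kinetics(p, noise = noiseless_mult())
  fit <- fit_pingpong_global(obs)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates),
               c(p$kcat, p$Km_A, p$Km_B), tolerance = 1e-6)

  ip <- params_fmn_inhibition()
  iobs <- simulate_inhibition(ip, noise = noiseless_mult())
  ifit <- fit_inhibition_global(iobs)
  expect_equal(unname(ifit$estimates),
               c(ip$kcat, ip$Km_A, ip$Km_B, ip$Ki_A, ip$Ki_B),
               tolerance = 1e-6)

  S <- c(1, 2, 5, 11, 25, 60, 150)
  v <- 9.0 * S / (11 + S)
  sfit <- fit_single_substrate(S, v)
  expect_equal(unname(sfit$estimates), c(9.0, 11), tolerance = 1e-6)
  # v at S = Km_app equals kcat_app / 2
  expect_equal(9.0 * 11 / (11 + 11), 9.0 / 2)
})

test_that("identifiability failures raise design-deficient errors", {
  p <- params_nitrofurantoin()
  obs <- simulate_kinetics(p, noise = noiseless_mult())
  oneB <- obs[obs$conc_B == obs$conc_B[1], ]
  expect_error(fit_pingpong_global(oneB), class = "nitrokin_design_error")
  expect_error(fit_pingpong_global(obs[1:3, ]),
               class = "nitrokin_design_error")
  iobs <- simulate_inhibition(params_fmn_inhibition(),
                              noise = noiseless_mult())
  expect_error(fit_inhibition_global(iobs[iobs$conc_I == 0, ]),
               class = "nitrokin_design_error")
  expect_error(fit_inhibition_global(iobs[iobs$conc_I > 0, ]),
               class = "nitrokin_design_error")
  expect_error(fit_single_substrate(c(5, 5, 5), c(1, 1.1, 0.9)),
               class = "nitrokin_design_error")
})

test_that("noisy recovery is unbiased: single-substrate and global ping-pong", {
  # benzoquinone-like apparent parameters, 3% noise
  set.seed(11)
  S <- 3 * 2^(-2:4)
  v <- 24 * S / (3 + S) * (1 + 0.03 * rnorm(length(S)))
  fit <- fit_single_substrate(S, v)
  expect_lt(abs(fit$estimates[["kcat_app"]] - 24),
            3 * fit$std_errors[["kcat_app"]])

  # median relative bias over 20 seeds below 5% for every global parameter
  p <- params_nitrofurazone()
  ests <- sapply(1:20, function(s) {
    obs <- simulate_kinetics(p, noise = noise_model(cv = 0.03, seed = s))
    fit_pingpong_global(obs, n_starts = 4, seed = s)$estimates
  })
  bias <- abs(ests - c(p$kcat, p$Km_A, p$Km_B)) /
    c(p$kcat, p$Km_A, p$Km_B)
  expect_lt(max(apply(bias, 1, median)), 0.05)
})

test_that("restricted inhibition fits never beat the full model on its own data", {
  ip <- params_fmn_inhibition()
  obs <- simulate_inhibition(ip, noise = noise_model(cv = 0.03, seed = 3))
  full <- fit_inhibition_global(obs, mode = "both_halves")
  halfA <- fit_inhibition_global(obs, mode = "half_A_only")
  halfB <- fit_inhibition_global(obs, mode = "half_B_only")
  expect_gte(halfA$rss, full$rss * (1 - 1e-9))
  expect_gte(halfB$rss, full$rss * (1 - 1e-9))
  expect_true(is.infinite(halfA$estimates[["Ki_B"]]))
  expect_true(is.na(halfA$std_errors[["Ki_B"]]))
  # with both halves genuinely inhibited, the F test detects the restriction
  cmp <- compare_nested(full, halfA)
  expect_equal(cmp$preferred, full$model_id)
})

test_that("extra-sum-of-squares F statistic matches the closed form", {
  mk <- function(rss, dof, n, id, k) {
    structure(list(model_id = id, estimates = setNames(rep(1, k),
                                                       paste0("p", 1:k)),
                   std_errors = setNames(rep(0.1, k), paste0("p", 1:k)),
                   p_values = setNames(rep(0.01, k), paste0("p", 1:k)),
                   rss = rss, dof = dof, n_points = n, n_free = k,
                   fixed = character(), covariance = NULL, converged = TRUE,
                   provenance = list(), warnings = character()),
              class = "nk_fit")
  }
  full <- mk(1, 10, 12, "full", 2)
  reduced <- mk(2, 11, 12, "reduced", 1)
  reduced$estimates <- full$estimates[1]
  cmp <- compare_nested(full, reduced)
  expect_equal(cmp$f_statistic, 10)
  expect_equal(cmp$p_value, pf(10, 1, 10, lower.tail = FALSE))
  # identical models: F = 0, p = 1, parsimony wins
  same <- mk(1, 11, 12, "reduced2", 1)
  same$estimates <- full$estimates[1]
  cmp0 <- compare_nested(full, same)
  expect_equal(cmp0$f_statistic, 0)
  expect_equal(cmp0$p_value, 1)
  expect_equal(cmp0$preferred, "reduced2")
  # malformed comparisons are usage errors
  expect_error(compare_nested(reduced, full), class = "nitrokin_usage_error")
  other <- mk(2, 11, 12, "other", 1)
  other$estimates <- c(zz = 1)
  expect_error(compare_nested(full, other), class = "nitrokin_usage_error")
})

test_that("standard errors shrink roughly as 1/sqrt(n) under replication", {
  p <- params_nitrofurantoin()
  se_k <- sapply(c(1, 4, 16), function(k) {
    grid <- design_grid(p$Km_A * 2^(-2:3), p$Km_B * 2^(-2:3),
                        replicates = k)
    obs <- simulate_kinetics(p, grid, noise_model(cv = 0.03, seed = 42))
    fit_pingpong_global(obs, n_starts = 2)$std_errors[["kcat"]]
  })
  expect_equal(se_k[1] / se_k[2], 2, tolerance = 0.2)
  expect_equal(se_k[2] / se_k[3], 2, tolerance = 0.2)
})

test_that("delta-method SE of kcat/Km agrees with Monte-Carlo propagation", {
  skip_if_not_installed("MASS")
  kcat <- 42; Km <- 12
  V <- matrix(c(1, 0.15, 0.15, 0.09), 2)
  prop <- derived_efficiency(kcat, Km = Km, var_kcat = V[1, 1],
                             var_Km = V[2, 2], cov_kcat_Km = V[1, 2])
  set.seed(99)
  draws <- MASS::mvrnorm(10000, c(kcat, Km), V)
  mc_se <- sd(draws[, 1] / draws[, 2])
  expect_true(prop$covariance_used)
  expect_equal(prop$se, mc_se, tolerance = 0.1)
})

test_that("catalytic efficiencies and significance match closed-form values", {
  expect_equal(derived_efficiency(42, Km = 12)$efficiency, 3.5)
  expect_equal(derived_efficiency(24, Km = 3)$efficiency, 8)
  z <- derived_efficiency(1, Km = 1)
  expect_equal(z$efficiency, 1)
  expect_equal(z$se, 0)
  expect_false(z$covariance_used)  # no covariance supplied -> flagged

  mk_fit <- function(est, se, dof) {
    structure(list(model_id = "m", estimates = est, std_errors = se,
                   p_values = est, rss = 1, dof = dof,
                   n_points = dof + length(est), n_free = length(est),
                   fixed = character(), covariance = NULL, converged = TRUE,
                   provenance = list(), warnings = character()),
              class = "nk_fit")
  }
  f <- mk_fit(c(a = 10, b = 0, c = 2, d = 5), c(a = 1, b = 1, c = 1, d = 0),
              dof = 30)
  f$dof <- 30
  p <- parameter_significance(f)
  expect_lt(p[["a"]], 1e-4)
  expect_equal(p[["b"]], 1)
  f$dof <- 10
  p10 <- parameter_significance(f)
  expect_equal(p10[["c"]], 2 * pt(-2, 10), tolerance = 1e-12)
  expect_equal(p10[["c"]], 0.0734, tolerance = 1e-3)
  expect_equal(p10[["d"]], 0)
  expect_true(attr(p10, "degenerate")[["d"]])
})

test_that("fit p-values use the t distribution with residual dof", {
  p <- params_nitrofurantoin()
  obs <- simulate_kinetics(p, noise = noise_model(cv = 0.03, seed = 5))
  fit <- fit_pingpong_global(obs)
  expect_equal(unname(fit$p_values),
               as.numeric(parameter_significance(fit)), tolerance = 1e-12)
  expect_true(all(fit$p_values < 1e-4))  # all parameters well determined
})
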