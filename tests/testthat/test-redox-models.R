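test_that("two-step Nernst curve matches hand-substituted values and limits", {
  p <- redox_two_step_params(-270, -270, b = 0.5)
  expect_equal(fraction_oxidised_two_step(p, -270), 0.5, tolerance = 1e-12)
  q <- truth_two_step()
  expect_equal(fraction_oxidised_two_step(q, q$E1 + 1e6), 1,
               tolerance = 1e-12)
  expect_equal(fraction_oxidised_two_step(q, q$E1 - 1e6), 0,
               tolerance = 1e-12)
  # stable for excursions of +/- 1000 mV around the transition
  x <- seq(-1270, 730, by = 10)
  y <- fraction_oxidised_two_step(p, x)
  expect_true(all(is.finite(y)))
})

test_that("concerted Nernst curve matches hand values, midpoint and symmetry", {
  p <- truth_concerted()
  expect_equal(fraction_oxidised_concerted(p, -264), 0.5)
  expect_equal(fraction_oxidised_concerted(p, -234.5), 1 / (1 + 0.1),
               tolerance = 1e-12)
  expect_equal(fraction_oxidised_concerted(p, -200),
               1 / (1 + 10^(-64 / 29.5)), tolerance = 1e-12)
  d <- seq(0, 400, by = 7)
  expect_equal(fraction_oxidised_concerted(p, p$Em + d) +
                 fraction_oxidised_concerted(p, p$Em - d),
               rep(1, length(d)), tolerance = 1e-12)
})

test_that("both model curves are monotone non-decreasing in potential", {
  x <- seq(-800, 300, by = 5)
  for (p in list(redox_two_step_params(-272, -268, 0.3),
                 redox_two_step_params(-200, -330, 1),
                 redox_two_step_params(-330, -200, 0.1))) {
    expect_true(all(diff(fraction_oxidised_two_step(p, x)) >= 0))
  }
  expect_true(all(diff(fraction_oxidised_concerted(
    truth_concerted(), x)) >= 0))
})

test_that("species fractions sum to one with the expected symmetry and peak", {
  p <- redox_two_step_params(-270, -270, b = 0.3)
  f <- species_fractions_two_step(p, seq(-600, 100, by = 25))
  expect_equal(f$f_ox + f$f_sq + f$f_red, rep(1, nrow(f)), tolerance = 1e-12)
  # equal potentials: all three denominator terms equal at the midpoint
  mid <- species_fractions_two_step(p, -270)
  expect_equal(unlist(mid), c(f_ox = 1, f_sq = 1, f_red = 1) / 3,
               tolerance = 1e-12)
  # limits
  hi <- species_fractions_two_step(p, 1e5)
  expect_equal(unlist(hi), c(f_ox = 1, f_sq = 0, f_red = 0),
               tolerance = 1e-12)
  lo <- species_fractions_two_step(p, -1e5)
  expect_equal(unlist(lo), c(f_ox = 0, f_sq = 0, f_red = 1),
               tolerance = 1e-12)
  # the semiquinone fraction peaks at the mean of the two potentials
  q <- redox_two_step_params(-220, -320, b = 0.5)
  x <- seq(-500, -50, by = 1)
  fs <- species_fractions_two_step(q, x)$f_sq
  expect_equal(x[which.max(fs)], mean(c(q$E1, q$E2)), tolerance = 2)
  # crossed terms (E2 >= E1 in this parametrisation) cap the peak below 0.5
  r <- redox_two_step_params(-320, -220, b = 0.5)
  expect_lt(max(species_fractions_two_step(r, x)$f_sq), 0.5)
  expect_gt(max(fs), 0.5)  # separated potentials stabilise the semiquinone
})

test_that("a stabilised semiquinone produces a plateau with two inflection points", {
  # strongly separated potentials under the implemented parametrisation
  p <- redox_two_step_params(-150, -450, b = 0.4)
  x <- seq(-600, 0, by = 2)
  y <- fraction_oxidised_two_step(p, x)
  d2 <- diff(diff(y))
  sign_changes <- sum(abs(diff(sign(d2[abs(d2) > 1e-10]))) > 0)
  expect_gte(sign_changes, 3)  # two sigmoid waves: >= 3 curvature reversals
  # the plateau sits near the b-weighted level between the waves
  expect_equal(y[x == -300], p$b, tolerance = 0.01)
})

test_that("midpoint slope of the merged two-step curve lies between 1e- and 2e- behaviour", {
  E <- -270
  p <- redox_two_step_params(E, E, b = 0.5)
  h <- 0.01
  slope_two_step <- (fraction_oxidised_two_step(p, E + h) -
                       fraction_oxidised_two_step(p, E - h)) / (2 * h)
  one_e <- function(x) pmin(1, 10^((x - E) / 59) / (1 + 10^((x - E) / 59)))
  slope_1e <- (one_e(E + h) - one_e(E - h)) / (2 * h)
  pc <- redox_concerted_params(E)
  slope_2e <- (fraction_oxidised_concerted(pc, E + h) -
                 fraction_oxidised_concerted(pc, E - h)) / (2 * h)
  expect_gt(slope_two_step, slope_1e)
  expect_lte(slope_two_step, slope_2e + 1e-12)
})

test_that("titration normalisation maps endpoints linearly and round-trips", {
  pts <- data.frame(potential = c(-100, -200, -300),
                    absorbance = c(0.8, 0.45, 0.1))
  n <- normalise_titration(pts, c(0.8, 0.1))
  expect_equal(n$y, c(1, 0.5, 0))
  expect_false(any(n$out_of_range))
  # values outside [0,1] are kept and flagged
  n2 <- normalise_titration(data.frame(potential = 0, absorbance = 0.9),
                            c(0.8, 0.1))
  expect_gt(n2$y, 1)
  expect_true(n2$out_of_range)
  expect_error(normalise_titration(pts, c(0.5, 0.5)),
               class = "nitrokin_degenerate_endpoints")
  # inverse-transform oracle
  y <- runif(20)
  A <- 0.1 + y * (0.8 - 0.1)
  back <- normalise_titration(data.frame(potential = seq_along(y),
                                         absorbance = A), c(0.8, 0.1))
  expect_equal(back$y, y, tolerance = 1e-12)
})

test_that("the stepped potential schedule reproduces the titration protocol", {
  s <- titration_schedule()
  red <- s$potential[s$cycle == "reductive"]
  expect_equal(red, seq(-50, -350, by = -20))
  ox <- s$potential[s$cycle == "oxidative"]
  expect_equal(ox, c(-335, seq(-320, -90, by = 20), -60))
})

test_that("temperature-parameterised Nernst slopes match the fixed printed values at 25C", {
  fixed <- nernst_constants()
  expect_equal(fixed$slope_2e, fixed$slope_1e / 2)
  warm <- nernst_constants(temperature_K = 298.15)
  expect_equal(warm$slope_1e, fixed$slope_1e, tolerance = 0.01)
})
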