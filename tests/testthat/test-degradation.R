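test_that("degradation kinetics match a numeric ODE oracle", {
  params <- mechanistic_params(ternary_binding(100, 100, 10),
                               cell_system(50, 10), kcat = 5)
  expect_equal(degradation_time_course(100, 6, params),
               ode_degradation_oracle(100, 6, params), tolerance = 1e-6)
  set.seed(7)
  for (i in 1:20) {
    p <- random_mechanistic()
    cc <- 10^runif(1, -1, 4)
    tt <- runif(1, 0.5, 72)
    expect_equal(degradation_time_course(cc, tt, p),
                 ode_degradation_oracle(cc, tt, p), tolerance = 1e-6)
  }
})

test_that("degradation starts at zero and saturates to steady state", {
  params <- mechanistic_params(ternary_binding(30, 300, 5),
                               cell_system(20, 24), kcat = 2)
  expect_identical(degradation_time_course(100, 0, params), 0)
  dss <- protacpd:::mechanistic_dss(100, params)
  t_sat <- 10 * params$cell$half_life / (1 - dss)
  expect_equal(degradation_time_course(100, t_sat, params), dss,
               tolerance = 1e-3)
  tt <- seq(0, 100, by = 2)
  expect_true(all(diff(degradation_time_course(100, tt, params)) >= 0))
})

test_that("catalytic efficiency TE50 and its hyperbola behave as derived", {
  # kdeg = 0.043 1/h with kcat = 4.6 1/h: ~1% engagement halves the target
  p <- mechanistic_params(ternary_binding(100, 100, 10),
                          cell_system(50, half_life = log(2) / 0.043),
                          kcat = 4.6)
  expect_equal(te50(p), 0.043 / 4.6, tolerance = 1e-9)
  expect_equal(round(100 * te50(p), 3), 0.935)
  p_eq <- mechanistic_params(p$binding, p$cell, kcat = p$cell$kdeg_p)
  expect_equal(te50(p_eq), 1, tolerance = 1e-12)
  expect_equal(dss_from_te(te50(p), te50(p)), 0.5, tolerance = 1e-12)
  p0 <- mechanistic_params(p$binding, p$cell, kcat = 0)
  expect_error(te50(p0), "kcat = 0")
})

test_that("hook curve hits its exact half/peak identities and symmetry", {
  hp <- hook_params(0.949, 0.29, 68.9)
  expect_equal(hook_degradation(68.9, hp), 0.949, tolerance = 1e-12)
  expect_equal(hook_degradation(0.29, hp), 0.949 / 2, tolerance = 1e-12)
  # mirrored half-maximal concentration on the far side of the peak
  expect_equal(hook_degradation(68.9^2 / 0.29, hp), 0.949 / 2,
               tolerance = 1e-12)
  expect_identical(hook_degradation(0, hp), 0)
  set.seed(11)
  cc <- 10^runif(200, -4, 6)
  expect_equal(hook_degradation(cc, hp),
               hook_degradation(hp$dcmax^2 / cc, hp), tolerance = 1e-12)
})

test_that("Emax model is the low-concentration limit of the hook model", {
  ep <- emax_params(0.9, 10)
  expect_equal(emax_effect(10, ep), 0.45, tolerance = 1e-12)
  expect_identical(emax_effect(0, ep), 0)
  hp <- hook_params(0.9, 10, 10 * 1e6)
  cc <- 10^seq(-2, 2, length.out = 50)  # up to 10 * DC50
  expect_equal(hook_degradation(cc, hp), emax_effect(cc, ep),
               tolerance = 1e-3)
})

test_that("extended hook interpolates between zero and the steady state", {
  eh <- extended_hook_params(hook_params(0.949, 0.29, 68.9), 45)
  expect_identical(extended_hook(c(1, 68.9), 0, eh), c(0, 0))
  # at the peak after 6 h: 0.949 * (1 - exp(-log(2)*6 / (45*0.051)))
  expect_equal(extended_hook(68.9, 6, eh), 0.794, tolerance = 1e-3)
  expect_equal(extended_hook(c(0.1, 5, 68.9), 1e6, eh),
               hook_degradation(c(0.1, 5, 68.9), eh$hook),
               tolerance = 1e-9)
})

test_that("mechanistic parameters map exactly onto hook parameters", {
  p <- mechanistic_params(ternary_binding(40, 40, 3),
                          cell_system(30, 20), kcat = 1.5)
  expect_equal(hook_from_mechanistic(p)$dcmax, 40, tolerance = 1e-12)
  set.seed(13)
  for (i in 1:25) {
    pp <- random_mechanistic()
    hp <- hook_from_mechanistic(pp)
    # peak location: grid scan of the mechanistic steady state
    grid <- 10^seq(log10(hp$dcmax) - 3, log10(hp$dcmax) + 3,
                   length.out = 2001)
    dss <- protacpd:::mechanistic_dss(grid, pp)
    expect_lt(abs(log10(grid[which.max(dss)]) - log10(hp$dcmax)), 0.01)
    # full-curve equivalence on 50 log-spaced concentrations
    cc <- 10^seq(log10(hp$dc50) - 2, log10(hp$dcmax) + 3, length.out = 50)
    expect_equal(hook_degradation(cc, hp),
                 protacpd:::mechanistic_dss(cc, pp), tolerance = 1e-9)
    # and the identities transfer to the mechanistic curve
    expect_equal(protacpd:::mechanistic_dss(hp$dc50, pp), hp$dmax / 2,
                 tolerance = 1e-9)
  }
  expect_error(hook_from_mechanistic(
    mechanistic_params(p$binding, p$cell, 0)), "kcat = 0")
})
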