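test_that("Dmax predictions respond to E3 expression and half-life", {
  params <- mechanistic_params(ternary_binding(20, 200, 6),
                               cell_system(40, 12), kcat = 3)
  base <- predict_dmax_across_systems(params, list(ref = cell_system(40, 12)))
  half_e0 <- predict_dmax_across_systems(params,
                                         list(thp1 = cell_system(20, 12)))
  quad_hl <- predict_dmax_across_systems(params,
                                         list(spleno = cell_system(40, 48)))
  expect_lt(half_e0[["thp1"]], base[["ref"]])
  expect_gt(quad_hl[["spleno"]], base[["ref"]])
  p0 <- mechanistic_params(params$binding, params$cell, 0)
  expect_equal(unname(predict_dmax_across_systems(
    p0, list(cell_system(40, 12), cell_system(20, 48)))), c(0, 0))
})

test_that("Dmax predictions are monotone in every mechanistic parameter", {
  set.seed(23)
  for (i in 1:40) {
    p <- random_mechanistic()
    dmax0 <- hook_from_mechanistic(p)$dmax
    bump <- function(kd_poi = 1, kd_e3 = 1, alpha = 1, e0 = 1, hl = 1,
                     kcat = 1) {
      hook_from_mechanistic(mechanistic_params(
        ternary_binding(p$binding$kd_poi * kd_poi,
                        p$binding$kd_e3 * kd_e3,
                        p$binding$alpha * alpha),
        cell_system(p$cell$e3_total * e0, p$cell$half_life * hl),
        p$kcat * kcat))$dmax
    }
    expect_gt(bump(alpha = 1.5), dmax0)
    expect_gt(bump(e0 = 1.5), dmax0)
    expect_gt(bump(kcat = 1.5), dmax0)
    expect_gt(bump(hl = 1.5), dmax0)
    expect_lt(bump(kd_poi = 1.5), dmax0)
    expect_lt(bump(kd_e3 = 1.5), dmax0)
  }
})

test_that("the engagement-degradation hyperbola evaluates pointwise", {
  p <- mechanistic_params(ternary_binding(100, 100, 10),
                          cell_system(50, log(2) / 0.043), kcat = 4.6)
  t50 <- te50(p)
  expect_equal(te_dmax_curve(p, c(0, t50)), c(0, 0.5), tolerance = 1e-12)
  p01 <- mechanistic_params(p$binding, cell_system(50, log(2) / 0.01),
                            kcat = 1)  # TE50 = 0.01
  expect_equal(te_dmax_curve(p01, 0.05), 0.05 / 0.06, tolerance = 1e-12)
})

test_that("affinity planning finds the fold-change or flags the ceiling", {
  params <- mechanistic_params(ternary_binding(50, 500, 4),
                               cell_system(30, 24), kcat = 2)
  current <- hook_from_mechanistic(params)
  same <- required_affinity_change(params, current)
  expect_true(same$feasible)
  expect_equal(unname(same$fold_changes), c(1, 1, 1), tolerance = 1e-6)
  # round trip: a 10-fold tighter POI affinity defines the target
  better <- mechanistic_params(
    ternary_binding(5, 500, 4), params$cell, 2)
  target <- hook_from_mechanistic(better)
  plan <- required_affinity_change(params, target, adjustable = "kd_poi")
  expect_true(plan$feasible)
  expect_equal(plan$fold_changes[["kd_poi"]], 10, tolerance = 1e-6)
  expect_equal(plan$fold_changes[["kd_e3"]], 1)
  expect_equal(plan$achieved$dmax, target$dmax, tolerance = 1e-9)
  # above the asymptotic ceiling 1/(1 + TE50): infeasible, advise kcat
  ceiling <- 1 / (1 + te50(params))
  too_deep <- hook_params(min(ceiling + 0.001, 0.9999), current$dc50,
                          current$dcmax)
  plan2 <- required_affinity_change(params, too_deep)
  expect_false(plan2$feasible)
  expect_equal(plan2$ceiling, ceiling, tolerance = 1e-12)
  expect_match(plan2$recommendation, "kcat")
})

test_that("time courses start inhibition-dominated and end at steady state", {
  eh <- extended_hook_params(hook_params(0.9, 1, 100), half_life = 24)
  pd <- pd_params(p50 = 0.5, hill = 1, pd_min = 0, ic50 = 120)
  tc <- predict_time_courses(100, c(0, 2, 6, 24, 96, 1e5), eh, pd)
  expect_equal(tc$degradation[1], 0)
  expect_equal(tc$target_modulation[1], tc$inhibition[1], tolerance = 1e-12)
  expect_equal(unique(tc$inhibition), 100 / 220, tolerance = 1e-12)
  expect_true(all(diff(tc$degradation) >= 0))
  expect_true(all(diff(tc$pd_response) <= 1e-12))
  i_inf <- inhibition_from_ic50(100, 120, 0.5)
  pd_inf <- pd_response(target_modulation(hook_degradation(100, eh$hook),
                                          i_inf), pd)
  expect_equal(tc$pd_response[nrow(tc)], pd_inf, tolerance = 1e-6)
  # the degradation-vs-inhibition balance shifts toward degradation
  shares <- vapply(seq_len(nrow(tc))[-1], function(r) {
    deconvolve_contributions(tc$degradation[r], tc$inhibition[r])[["inhibition"]]
  }, numeric(1))
  expect_true(all(diff(shares) <= 1e-12))
})

test_that("the downstream response shows no hook along concentration", {
  set.seed(29)
  grid <- 10^seq(-3, 5, length.out = 80)
  for (i in 1:200) {
    p <- random_mechanistic()
    pdp <- local({
      h <- 10^runif(1, -0.3, 0.8)
      pd_params(runif(1, 0.1, 1) * 0.5^(1 / h), h, runif(1, 0, 0.3))
    })
    d <- protacpd:::mechanistic_dss(grid, p)
    i_frac <- inhibition_fraction(grid, p$binding$kd_poi)
    pd <- pd_response(pmin(target_modulation(d, i_frac), 1), pdp)
    expect_true(all(diff(pd) <= 1e-12))
  }
})
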