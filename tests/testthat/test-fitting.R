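test_that("hook fit recovers noise-free truth exactly", {
  truth <- hook_params(0.8, 5, 500)
  d <- simulate_dataset(hook_truth_default(seed = 1, noise_sd = 0))
  est <- coef(fit_hook(d))
  expect_equal(est[["dmax"]], 0.8, tolerance = 1e-6)
  expect_equal(est[["dc50"]], 5, tolerance = 1e-6)
  expect_equal(est[["dcmax"]], 500, tolerance = 1e-6)
})

test_that("hook fit recovers parameters from noisy replicated data", {
  ok <- matrix(NA, 100, 3)
  for (s in 1:100) {
    tr <- synthetic_truth("hook", hook_params(0.8, 5, 500),
                          concentrations = 10^seq(-1, 4, length.out = 10),
                          times = 24, replicates = 3, noise_sd = NULL,
                          noise_cv = 0.05, seed = 100 + s)
    est <- coef(fit_hook(simulate_dataset(tr), seed = s))
    ok[s, ] <- abs(est / c(0.8, 5, 500) - 1) <= 0.15
  }
  # 5% multiplicative noise, 3 replicates: every parameter within 15%
  # relative in at least 90% of datasets (Monte Carlo margin)
  expect_gte(mean(ok[, 1]), 0.9)  # dmax
  expect_gte(mean(ok[, 2]), 0.9)  # dc50
  expect_gte(mean(ok[, 3]), 0.9)  # dcmax
})

test_that("hook fit on monotone data collapses onto the Emax model", {
  tr <- synthetic_truth("hook", hook_params(0.9, 10, 10 * 1e6),
                        concentrations = 10^seq(-1, 3, length.out = 10),
                        times = 24, replicates = 1, noise_sd = 0, seed = 1)
  d <- simulate_dataset(tr)
  fh <- fit_hook(d)
  fe <- fit_emax(d)
  expect_gt(coef(fh)[["dcmax"]], max(d$conc_nM))
  expect_equal(predict(fh, d$conc_nM), predict(fe, d$conc_nM),
               tolerance = 5e-3)
  expect_match(fh$note, "Emax")
})

test_that("Emax fit recovers hyperbolic truth and honors exclusion", {
  # pure hyperbola: exact recovery
  cc <- 10^seq(-1, 3, length.out = 10)
  d <- dose_response_dataset("cpd", cc, 24, 1,
                             1 - emax_effect(cc, emax_params(0.9, 10)))
  est <- coef(fit_emax(d))
  expect_equal(est[["emax"]], 0.9, tolerance = 1e-6)
  expect_equal(est[["ec50"]], 10, tolerance = 1e-6)
  # moderate hook: excluding the hook region leaves a near-hyperbolic
  # rising arm, so EC50 lands close to the generating DC50
  hp_mild <- hook_params(0.7, 10, 1000)
  d_mild <- simulate_dataset(synthetic_truth(
    "hook", hp_mild, 10^seq(-1, 4.5, length.out = 12), times = 24,
    replicates = 1, noise_sd = 0, seed = 2))
  f_mild <- fit_emax(d_mild, exclude_above_hook = TRUE)
  expect_gt(length(f_mild$excluded), 0)
  expect_lt(abs(coef(f_mild)[["ec50"]] / hp_mild$dc50 - 1), 0.20)
  # strong hook (DCmax = 10 * DC50): the asymptotic Emax of the excluded
  # fit overshoots the degradation the compound can actually reach
  hp <- hook_params(0.7, 10, 100)
  dh <- simulate_dataset(synthetic_truth(
    "hook", hp, 10^seq(-1, 4, length.out = 12), times = 24,
    replicates = 1, noise_sd = 0, seed = 2))
  f_on <- fit_emax(dh, exclude_above_hook = TRUE)
  expect_gt(coef(f_on)[["emax"]], max(hook_degradation(dh$conc_nM, hp)))
  # fitting through the hook without exclusion leaves gross structure in
  # the residuals -- the bias is detectable, not silent
  f_off <- fit_emax(dh, exclude_above_hook = FALSE)
  expect_gt(max(abs(f_off$residuals)), 0.05)
})

test_that("extended hook fit recovers steady state and half-life", {
  eh <- extended_hook_params(table1_steady_state, 45)
  tr <- synthetic_truth("extended_hook", eh,
                        concentrations = 10^seq(-2.5, 3.5, length.out = 12),
                        times = c(6, 24), replicates = 1, noise_sd = 0,
                        seed = 3)
  d <- simulate_dataset(tr)
  est <- coef(fit_extended_hook(d, estimate_half_life = TRUE))
  expect_equal(est[["dmax"]], 0.949, tolerance = 1e-4)
  expect_equal(est[["dc50"]], 0.29, tolerance = 1e-4)
  expect_equal(est[["dcmax"]], 68.9, tolerance = 1e-4)
  expect_equal(est[["half_life"]], 45, tolerance = 1e-3)
})

test_that("apparent DC50 shrinks toward steady state while DCmax stays put", {
  eh <- extended_hook_params(table1_steady_state, 45)
  concs <- 10^seq(-3, 4, length.out = 40)
  ests <- sapply(c(6, 24), function(tt) {
    tr <- synthetic_truth("extended_hook", eh, concs, times = tt,
                          replicates = 1, noise_sd = 0, seed = 4)
    coef(fit_hook(simulate_dataset(tr)))
  })
  # apparent DC50 inflated before steady state and shrinking over time
  expect_gt(ests["dc50", 1], ests["dc50", 2])
  expect_true(all(ests["dc50", ] > eh$hook$dc50))
  # apparent Dmax grows toward the steady-state value
  expect_lt(ests["dmax", 1], ests["dmax", 2])
  expect_lt(ests["dmax", 1], eh$hook$dmax)
  # DCmax essentially unchanged by incubation time
  expect_equal(unname(ests["dcmax", ]), rep(eh$hook$dcmax, 2),
               tolerance = 0.03)
})

test_that("single-time data plus a known half-life extrapolate in time", {
  eh <- extended_hook_params(table1_steady_state, 45)
  tr <- synthetic_truth("extended_hook", eh,
                        concentrations = 10^seq(-2.5, 3.5, length.out = 12),
                        times = 6, replicates = 1, noise_sd = 0, seed = 5)
  d <- simulate_dataset(tr)
  fit <- fit_extended_hook(d, half_life = 45)
  cc <- c(0.1, 1, 68.9, 1000)
  est <- coef(fit)
  manual <- 1 - extended_hook(cc, 24, extended_hook_params(
    hook_params(est[["dmax"]], est[["dc50"]], est[["dcmax"]]), 45))
  expect_equal(predict(fit, cc, 24), manual, tolerance = 1e-12)
  # unidentifiable without the half-life
  expect_error(fit_extended_hook(d, estimate_half_life = TRUE),
               "not identifiable")
})

test_that("kcat calibration recovers the generating rate constant", {
  binding <- ternary_binding(15, 250, 8)
  cell <- cell_system(e3_total = 40, half_life = 16)
  truth <- mechanistic_params(binding, cell, kcat = 4.6)
  tr <- synthetic_truth("mechanistic", truth,
                        concentrations = 10^seq(-1, 4, length.out = 10),
                        times = 24, replicates = 1, noise_sd = 0, seed = 6)
  d <- simulate_dataset(tr)
  expect_equal(coef(fit_kcat(d, binding, cell))[["kcat"]], 4.6,
               tolerance = 0.02)
  # monotonicity over a generator grid
  fitted <- vapply(c(1, 2, 4, 8), function(k) {
    tk <- synthetic_truth("mechanistic",
                          mechanistic_params(binding, cell, k),
                          10^seq(-1, 4, length.out = 10), 24, 1, 0, seed = 6)
    coef(fit_kcat(simulate_dataset(tk), binding, cell))[["kcat"]]
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
  # flat baseline data: kcat = 0 with a warning
  flat <- dose_response_dataset("cpd", 10^seq(0, 3, length.out = 6), 24, 1,
                                rep(1, 6))
  expect_warning(f0 <- fit_kcat(flat, binding, cell), "no degradation")
  expect_equal(coef(f0)[["kcat"]], 0)
})

test_that("PD fit recovers saturation and Hill parameters", {
  deg <- table1_steady_state
  pd_true <- pd_params(p50 = 0.87, hill = 7, pd_min = 0)
  tr <- synthetic_truth("pd", list(pd = pd_true, degradation = deg),
                        concentrations = 10^seq(-3, 3, length.out = 15),
                        times = 24, replicates = 1, noise_sd = 0, seed = 7)
  d <- simulate_dataset(tr)
  est <- coef(fit_pd(d, deg, fix_pd_min = 0))
  expect_equal(est[["p50"]], 0.87, tolerance = 0.01)
  expect_equal(est[["hill"]], 7, tolerance = 0.01)
})

test_that("neglecting inhibition misfits the high-concentration tail", {
  deg <- hook_params(0.85, 2, 80)
  pd_true <- pd_params(p50 = 0.6, hill = 1.5, pd_min = 0, ic50 = 150)
  tr <- synthetic_truth("pd", list(pd = pd_true, degradation = deg),
                        concentrations = 10^seq(-2, 4, length.out = 15),
                        times = 24, replicates = 1, noise_sd = 0, seed = 8)
  d <- simulate_dataset(tr)
  with_i <- fit_pd(d, deg, ic50 = 150, fix_pd_min = 0)
  no_i <- fit_pd(d, deg, ic50 = NULL, fix_pd_min = 0)
  expect_lt(with_i$rss, no_i$rss)
  # the misfit concentrates beyond the hook, where only inhibition can
  # keep the response suppressed
  tail_idx <- d$conc_nM > deg$dcmax
  expect_gt(max(abs(no_i$residuals[tail_idx])), 0.05)
  expect_lt(max(abs(with_i$residuals[tail_idx])), 1e-6)
})

test_that("several compounds can share PD parameters in one fit", {
  degs <- list(a = hook_params(0.9, 1, 100),
               b = hook_params(0.7, 10, 300),
               c = hook_params(0.5, 0.5, 50))
  pd_true <- pd_params(p50 = 0.65, hill = 2, pd_min = 0.1)
  sets <- lapply(names(degs), function(nm) {
    tr <- synthetic_truth("pd", list(pd = pd_true, degradation = degs[[nm]]),
                          concentrations = 10^seq(-2, 3, length.out = 10),
                          times = 24, replicates = 1, noise_sd = 0,
                          seed = 9, compound = nm)
    simulate_dataset(tr)
  })
  d <- as_dose_response(do.call(rbind, sets))
  est <- coef(fit_pd(d, degs))
  expect_equal(est[["p50"]], 0.65, tolerance = 0.01)
  expect_equal(est[["hill"]], 2, tolerance = 0.02)
  expect_equal(est[["pd_min"]], 0.1, tolerance = 0.01)
})

test_that("fits are invariant to row order and rescale with units", {
  d <- simulate_dataset(hook_truth_default(seed = 10))
  est <- coef(fit_hook(d))
  shuffled <- d[sample(nrow(d)), ]
  expect_equal(coef(fit_hook(shuffled)), est, tolerance = 1e-6)
  # nM -> uM rescaling: concentration parameters shrink 1000-fold
  d_um <- d
  d_um$conc_nM <- d$conc_nM / 1000
  est_um <- coef(fit_hook(d_um))
  expect_equal(est_um[["dmax"]], est[["dmax"]], tolerance = 1e-4)
  expect_equal(est_um[["dc50"]] * 1000, est[["dc50"]], tolerance = 1e-3)
  expect_equal(est_um[["dcmax"]] * 1000, est[["dcmax"]], tolerance = 1e-3)
})

test_that("the hook model never fits worse than the nested Emax model", {
  set.seed(77)
  for (s in 1:15) {
    shape <- hook_params(runif(1, 0.3, 0.95), 10^runif(1, -0.5, 1),
                         10^runif(1, 1.5, 3))
    tr <- synthetic_truth("hook", shape,
                          concentrations = 10^seq(-1, 4, length.out = 10),
                          times = 24, replicates = 2,
                          noise_sd = 0.05, seed = 200 + s)
    d <- simulate_dataset(tr)
    expect_lte(fit_hook(d, seed = s)$rss,
               fit_emax(d, seed = s)$rss * (1 + 1e-9))
  }
})

test_that("underdetermined designs are rejected with clear messages", {
  d <- dose_response_dataset("cpd", c(1, 10), 24, 1, c(0.9, 0.5))
  expect_error(fit_hook(d), "4 distinct")
  d2 <- simulate_dataset(hook_truth_default(seed = 1))
  d2$time_h <- rep(c(6, 24), length.out = nrow(d2))
  expect_error(fit_hook(d2), "single incubation time")
  d3 <- simulate_dataset(hook_truth_default(seed = 1))
  d3$readout <- "pd_response"
  expect_error(fit_hook(d3), "protein_level")
})
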