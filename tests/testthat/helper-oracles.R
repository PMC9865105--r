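# Independent numeric oracles and shared fixtures. The oracles solve the
# underlying physics by brute force (root-finding on the mass-action
# system, numeric ODE integration) and never reuse the closed forms they
# are meant to check.

# Rapid-equilibrium ternary-complex system solved directly: free protein P
# and free ligase E satisfy the coupled mass balances
#   P0 = P * (1 + C/KD,P) + TC,  E0 = E * (1 + C/KD,E) + TC,
#   TC = alpha * C * P * E / (KD,P * KD,E).
# Solved by nested uniroot on E; returns TC / P0.
te_equilibrium_oracle <- function(C, binding, e3_total, poi_total) {
  kp <- binding$kd_poi
  ke <- binding$kd_e3
  al <- binding$alpha
  if (C == 0) return(0)
  f <- function(E) {
    P <- poi_total / (1 + C / kp + al * C * E / (kp * ke))
    E * (1 + C / ke + al * C * P / (kp * ke)) - e3_total
  }
  E <- uniroot(f, c(1e-14 * e3_total, e3_total), tol = 1e-16)$root
  P <- poi_total / (1 + C / kp + al * C * E / (kp * ke))
  al * C * P * E / (kp * ke) / poi_total
}

# Turnover ODE integrated numerically:
#   d(P/P0)/dt = kdeg - kdeg * x - kcat * TE * x
# with TE held at its (time-constant) in vitro value.
ode_degradation_oracle <- function(C, t_end, params) {
  te_val <- ternary_te(C, params$binding, params$cell$e3_total)
  kdeg <- params$cell$kdeg_p
  rhs <- function(t, y, p) {
    list(kdeg - kdeg * y[1] - params$kcat * te_val * y[1])
  }
  sol <- deSolve::ode(y = c(x = 1), times = c(0, t_end), func = rhs,
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  unname(1 - sol[nrow(sol), "x"])
}

# Random valid parameter draws used by property suites.
random_binding <- function() {
  ternary_binding(kd_poi = 10^runif(1, -1, 3), kd_e3 = 10^runif(1, -1, 3),
                  alpha = 10^runif(1, -1, 1.5))
}

random_mechanistic <- function() {
  mechanistic_params(random_binding(),
                     cell_system(e3_total = 10^runif(1, 0, 2),
                                 half_life = 10^runif(1, 0, 2)),
                     kcat = 10^runif(1, -1, 1))
}

# Study-condition generator defaults used across fitting tests: 10
# log-spaced concentrations spanning the full profile, 3 replicates,
# additive sd 0.05 on the fraction scale.
hook_truth_default <- function(seed, noise_sd = 0.05,
                               hook = hook_params(0.8, 5, 500),
                               replicates = 3L) {
  synthetic_truth("hook", hook,
                  concentrations = 10^seq(-1, 4, length.out = 10),
                  times = 24, replicates = replicates,
                  noise_sd = noise_sd, seed = seed)
}

table1_steady_state <- hook_params(dmax = 0.949, dc50 = 0.29, dcmax = 68.9)

# Reference grid of minimum incubation times (hours) for half-lives
# 2..192 h (rows) by assumed steady-state Dmax 30..99% (columns), under
# the default tolerances (DC50 within 1.5-fold, Dmax within 5 points).
reference_incubation_grid <- matrix(c(
    5,   4,   4,   3,   3,   3,   3,   3,   3,   3,
    9,   8,   7,   6,   6,   6,   6,   5,   5,   5,
   13,  11,  10,   9,   9,   9,   8,   8,   7,   7,
   26,  22,  20,  18,  18,  17,  16,  15,  14,  13,
   51,  44,  40,  36,  35,  33,  31,  29,  27,  26,
   77,  66,  60,  54,  52,  49,  46,  43,  41,  38,
  102,  87,  80,  72,  69,  65,  61,  58,  54,  51,
  153, 131, 120, 108, 103,  97,  92,  86,  81,  76,
  204, 174, 159, 144, 137, 130, 122, 115, 107, 101,
  407, 348, 318, 288, 273, 259, 244, 229, 214, 202),
  nrow = 10, byrow = TRUE)
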