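test_that("boost energy follows the two-branch harmonic form", {
  p <- boost_params("lower_bound", sigma_0 = 6, E = 3, k = 0.1, k0 = 0.5)
  expect_equal(boost_energy(5, p), 0)              # V >= E
  p2 <- boost_params("lower_bound", sigma_0 = 6, E = 10, k = 0.1, k0 = 0.5)
  expect_equal(boost_energy(8, p2), 0.5 * 0.1 * 2^2)
  expect_equal(boost_energy(10, p2), 0)            # boundary V = E
  # vectorised and non-negative
  v <- seq(-5, 15, by = 0.5)
  expect_true(all(boost_energy(v, p2) >= 0))
})

test_that("the boosted surface is C1 at the threshold", {
  p <- boost_params("lower_bound", sigma_0 = 6, E = 10, k = 0.05, k0 = 0.5)
  vstar <- function(V) V + boost_energy(V, p)
  eps <- 1e-7
  # energy continuity: both one-sided limits approach V*(E) = E
  expect_equal(vstar(10 - eps), 10 - eps, tolerance = 1e-12)
  expect_equal(vstar(10 + eps), 10 + eps, tolerance = 1e-12)
  # force continuity: one-sided difference quotients agree
  d_below <- (vstar(10 - eps) - vstar(10 - 2 * eps)) / eps
  d_above <- (vstar(10 + 2 * eps) - vstar(10 + eps)) / eps
  expect_equal(d_below, d_above, tolerance = 1e-5)
  expect_equal(boost_force_scale(10, p), 1)
})

test_that("force scaling matches the boost derivative and its limits", {
  p <- boost_params("lower_bound", sigma_0 = 6, E = 25, k = 0.01, k0 = 0.5)
  expect_equal(boost_force_scale(30, p), 1)
  expect_equal(boost_force_scale(5, p), 1 - 0.01 * 20)  # 0.8
  # flattened-landscape limit: E = Vmin + 1/k and V = Vmin -> scale 0
  pf <- boost_params("lower_bound", sigma_0 = 6, E = 0 + 1 / 0.02, k = 0.02,
                     k0 = 0.5)
  expect_equal(boost_force_scale(0, pf), 0)
  # threshold above Vmin + 1/k would invert forces: error
  pb <- boost_params("lower_bound", sigma_0 = 6, E = 60, k = 0.02, k0 = 0.5)
  expect_error(boost_force_scale(0, pb), "negative force scale")
})

test_that("lower-bound parameters follow the threshold and k0 formulas", {
  st <- potential_stats(v_max = 100, v_min = 0, v_avg = 60, sigma_v = 4,
                        n_samples = 1000)
  p <- compute_boost_params(st, sigma_0 = 1, mode = "lower_bound")
  expect_equal(p$k0, min(1, (1 / 4) * 100 / 40))  # 0.625
  expect_equal(p$E, 100)
  expect_equal(p$k, 0.625 / 100)
  # clamp branch
  p1 <- compute_boost_params(st, sigma_0 = 10, mode = "lower_bound")
  expect_equal(p1$k0, 1.0)
  # Eq. 4 consistency to 1e-12 relative
  expect_equal(p$k * (st$v_max - st$v_min) / p$k0, 1, tolerance = 1e-12)
})

test_that("upper-bound mode places the threshold at Vmin + 1/k or fails cleanly", {
  st <- potential_stats(v_max = 100, v_min = 0, v_avg = 60, sigma_v = 4,
                        n_samples = 1000)
  p <- compute_boost_params(st, sigma_0 = 1, mode = "upper_bound")
  expect_equal(p$E, st$v_min + 1 / p$k)
  expect_gte(p$E, st$v_max)
  expect_true(p$k0 > 0 && p$k0 <= 1)
  expect_error(compute_boost_params(st, sigma_0 = 5, mode = "upper_bound"),
               "infeasible")
  st0 <- potential_stats(v_max = 1, v_min = 0, v_avg = 0.5, sigma_v = 0,
                         n_samples = 10)
  expect_error(compute_boost_params(st0, 1), "degenerate")
})

test_that("random valid statistics always yield thresholds inside the bound", {
  set.seed(4)
  for (i in 1:1000) {
    vmin <- runif(1, -100, 100)
    span <- runif(1, 0.5, 200)
    vmax <- vmin + span
    vavg <- runif(1, vmin + 0.01 * span, vmax - 0.01 * span)
    sv <- runif(1, 0.01, 20)
    s0 <- runif(1, 0.01, 20)
    st <- potential_stats(v_max = vmax, v_min = vmin, v_avg = vavg,
                          sigma_v = sv, n_samples = 100)
    p <- compute_boost_params(st, s0, "lower_bound")
    expect_true(p$k0 > 0 && p$k0 <= 1)
    expect_gte(p$E + 1e-9, vmax)
    expect_lte(p$E, vmin + 1 / p$k + 1e-9)
    expect_equal(p$k * span, p$k0, tolerance = 1e-12)
  }
})

test_that("the boosted potential is monotone in V below the threshold", {
  st <- potential_stats(v_max = 50, v_min = 10, v_avg = 35, sigma_v = 3,
                        n_samples = 100)
  p <- compute_boost_params(st, 2, "lower_bound")
  v <- seq(10, p$E, length.out = 500)
  vstar <- v + boost_energy(v, p)
  expect_true(all(diff(vstar) > -1e-12))
})

test_that("unbiased sampling of a harmonic well satisfies equipartition", {
  k_spring <- 2
  sys <- toy_potential("harmonic", spring_k = k_spring, center = 0, mass = 12)
  cfg <- langevin_config(n_steps = 4e5, timestep = 0.002, seed = 21,
                         stride = 4)
  run <- run_langevin(sys, cfg)
  x <- run$positions[, 1]
  target <- KB_KCAL * 300 / k_spring  # kT / k
  # generous band: correlated samples inflate the naive standard error
  expect_lt(abs(stats::var(x) - target) / target, 0.1)
  expect_true(all(run$records$dV == 0))
})

test_that("boosted runs log non-negative boost energies consistent with the records", {
  sys <- toy_potential("double_well_1d")
  cfg <- langevin_config(n_steps = 5e4, seed = 3, stride = 10)
  run <- run_langevin(sys, cfg, boost = "lower_bound", sigma_0 = 6)
  rec <- run$records
  expect_true(all(rec$dV >= 0))
  expect_true(all(rec$dV[rec$V >= rec$E] == 0))
  expect_true(all(rec$dV[rec$V < rec$E] > 0))
  # logged dV equals the closed form at the logged V
  expect_equal(rec$dV, ifelse(rec$V >= rec$E, 0, 0.5 * rec$k * (rec$E - rec$V)^2),
               tolerance = 1e-12)
  # logged V matches the system energy at the stored coordinates
  v_check <- vapply(seq_len(nrow(run$positions)),
                    function(i) sys$energy(run$positions[i, ]), numeric(1))
  expect_equal(rec$V, v_check, tolerance = 1e-9)
})

test_that("runs are reproducible and blow-ups are reported", {
  sys <- toy_potential("double_well_1d")
  cfg <- langevin_config(n_steps = 2e4, seed = 5, stride = 10)
  r1 <- run_langevin(sys, cfg, boost = "lower_bound")
  r2 <- run_langevin(sys, cfg, boost = "lower_bound")
  expect_identical(r1$positions, r2$positions)
  expect_identical(r1$records, r2$records)
  # absurd timestep must blow up with a step report
  bad <- langevin_config(n_steps = 1e4, timestep = 5, seed = 1, stride = 10)
  expect_error(run_langevin(sys, bad), "step")
})

test_that("unbiased double-well sampling matches the Boltzmann density", {
  sys <- toy_potential("double_well_1d", h = 1, b = 1.5)  # low barrier mixes fast
  cfg <- langevin_config(n_steps = 8e5, timestep = 0.002, seed = 9, stride = 4)
  run <- run_langevin(sys, cfg)
  x <- run$positions[, 1]
  beta <- 1 / (KB_KCAL * 300)
  xs <- seq(-3, 3, length.out = 401)
  dens <- exp(-beta * sapply(xs, sys$analytic_pmf))
  cdf <- cumsum(dens) / sum(dens)
  ks <- max(abs(stats::ecdf(x)(xs) - cdf))
  expect_lt(ks, 0.05)
})

test_that("anharmonicity separates Gaussian from bimodal boost distributions", {
  set.seed(12)
  expect_lt(anharmonicity(rnorm(1e5, 3, 1)), 0.05)
  two_point <- sample(c(0, 5), 1e4, replace = TRUE)
  expect_gt(anharmonicity(two_point), 0.5)
  expect_warning(g <- anharmonicity(rep(1, 200)), "constant")
  expect_identical(g, Inf)
  expect_error(anharmonicity(rnorm(50)), "100")
})

test_that("well-transition counting uses hysteresis", {
  x <- c(-2, -1.5, 0, 1.5, 0.5, -1.2, -0.5, 1.4)
  expect_equal(count_well_transitions(x), 3)
  expect_equal(count_well_transitions(c(-2, 0, -2, 0, -2)), 0)
  expect_error(count_well_transitions(x, 2, 1), "lo < hi")
})
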