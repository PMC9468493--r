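test_that("parameter constructor validates and carries the free set", {
  p <- kinetic_params()
  expect_equal(unname(p[["vs"]]), 0.9)
  expect_equal(unname(p[["d5"]]), 0.08234)
  expect_setequal(attr(p, "free"), c("vs", "v1", "v2", "tau", "vp", "ks"))
  expect_error(kinetic_params(vs = -1), "positive")
  expect_error(kinetic_params(c1 = 1.2), "c1")
})

test_that("ER calcium follows the conservation relationship", {
  p <- kinetic_params()
  expect_equal(er_calcium(2.0, p), 2.0)                 # C_CS = C0
  expect_equal(er_calcium(2 * 1.185, p), 0)             # numerator vanishes
  expect_equal(er_calcium(0, p), 2 * 1.185 / 0.185, tolerance = 1e-12)
  expect_error(er_calcium(3, p), "negative")
  # conservation holds identically along a simulated trajectory
  traj <- simulate_kinetics(kinetic_state(0.1, 0.5, 0.5), p, duration = 120)
  lhs <- p[["c1"]] * er_calcium(traj$c_cs, p) + traj$c_cs
  expect_equal(lhs, rep(p[["C0"]] * (1 + p[["c1"]]), nrow(traj)),
               tolerance = 1e-14)
})

test_that("fluxes have the stated structure and monotone gating", {
  p <- kinetic_params()
  # C_ER = C_CS at c_cs = C0: channel and leak flux vanish
  fx <- compute_fluxes(kinetic_state(2, 0.5, 0.5), p)
  expect_equal(fx$j_c, 0)
  expect_equal(fx$j_l, 0)
  # q = 0 closes the channel
  expect_equal(compute_fluxes(kinetic_state(0.3, 0, 0.5), p)$j_c, 0)
  # SERCA at half-activation: vs / 2
  expect_equal(compute_fluxes(kinetic_state(0.1, 0.5, 0.5), p)$j_s, 0.45)
  # monotone gating: j_c non-decreasing in q and p; j_s non-decreasing in c
  grid <- seq(0.05, 0.95, length.out = 8)
  jc_q <- vapply(grid, function(q)
    compute_fluxes(kinetic_state(0.2, q, 0.4), p)$j_c, numeric(1))
  jc_p <- vapply(grid, function(ip3)
    compute_fluxes(kinetic_state(0.2, 0.5, ip3), p)$j_c, numeric(1))
  js_c <- vapply(grid, function(cc)
    compute_fluxes(kinetic_state(cc, 0.5, 0.4), p)$j_s, numeric(1))
  expect_true(all(diff(jc_q) >= 0))
  expect_true(all(diff(jc_p) >= 0))
  expect_true(all(diff(js_c) >= 0))
})

test_that("state derivative is consistent with the fluxes", {
  p <- kinetic_params()
  s <- kinetic_state(0.3, 0.6, 0.4)
  d <- state_derivative(s, p)
  fx <- compute_fluxes(s, p)
  expect_equal(unname(d[["c_cs"]]), fx$j_c - fx$j_s + fx$j_l,
               tolerance = 1e-12)
  # q = 1: the recovery variable can only decrease
  expect_lt(state_derivative(kinetic_state(0.5, 1, 0.3), p)[["q"]], 0)
  # IP3 at baseline with zero calcium: production term only, 0.2 * vp
  expect_equal(unname(state_derivative(c(0, 0.5, 0.16), p)[["p"]]),
               0.2 * 0.13, tolerance = 1e-12)
})

test_that("frame stepping composes micro-steps and validates the grid", {
  p <- kinetic_params()
  s <- kinetic_state(0.1, 0.5, 0.5)
  expect_equal(as.numeric(evolve_step(s, p, frame_dt = 0)), as.numeric(s))
  # one 1 s frame at micro_dt 0.1 equals ten composed 0.1 s frames
  s10 <- s
  for (i in 1:10) s10 <- evolve_step(s10, p, frame_dt = 0.1, micro_dt = 0.1)
  expect_equal(as.numeric(evolve_step(s, p, frame_dt = 1, micro_dt = 0.1)),
               as.numeric(s10), tolerance = 1e-14)
  expect_error(evolve_step(s, p, frame_dt = 0.35, micro_dt = 0.1),
               "integer multiple")
  expect_error(evolve_step(s, p, frame_dt = 1, micro_dt = -0.1), "positive")
})

test_that("microtime Euler stepping matches a fine-step RK4 reference", {
  p <- kinetic_params()
  s <- c(0.1, 0.5, 0.5)
  euler10 <- s
  for (i in 1:10) euler10 <- as.numeric(evolve_step(euler10, p, 1, 0.1))
  ref <- rk4_integrate(s, p, t_end = 10, dt = 1e-3)
  expect_true(all(abs(euler10 - ref) / abs(ref) < 0.01))
})

test_that("simulated trajectories are bounded, varying, and confine q", {
  p <- kinetic_params()
  short <- simulate_kinetics(kinetic_state(0.1, 0.5, 0.5), p, duration = 1)
  expect_equal(nrow(short), 2L)
  expect_equal(as.numeric(short[1, -1]), c(0.1, 0.5, 0.5))

  traj <- simulate_kinetics(kinetic_state(0.1, 0.5, 0.5), p, duration = 300)
  cmax <- p[["C0"]] * (1 + p[["c1"]])
  expect_true(all(traj$c_cs > 0 & traj$c_cs < cmax))
  expect_true(all(traj$q >= 0 & traj$q <= 1))
  expect_gt(max(traj$c_cs) - min(traj$c_cs), 0)
})

test_that("the dynamics admit a fixed point where trajectories are constant", {
  p <- kinetic_params()
  # relax onto the attractor, then verify stationarity
  relax <- simulate_kinetics(kinetic_state(0.1, 0.5, 0.5), p, duration = 2000)
  fp <- as.numeric(relax[nrow(relax), -1])
  expect_lt(max(abs(state_derivative(fp, p))), 1e-6)
  const <- simulate_kinetics(fp, p, duration = 50)
  expect_lt(max(const$c_cs) - min(const$c_cs), 1e-6)
})
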