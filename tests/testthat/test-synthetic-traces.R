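test_that("the noiseless limit reproduces the deterministic forward model", {
  obs <- observation_params(kappa_f = 10, d_f = 2)
  tr <- generate_trace(obs = obs, obs_noise_sd = 0, duration = 60, seed = 9)
  traj <- simulate_kinetics(kinetic_state(0.1, 0.5, 0.5), kinetic_params(),
                            duration = 59)
  expect_equal(tr$fluorescence, predict_trace(traj$c_cs, obs),
               tolerance = 1e-12)
  expect_equal(length(tr$times), 60L)
  expect_equal(tr$frame_dt, 1)
})

test_that("trace generation is seed-reproducible", {
  a <- generate_trace(obs_noise_sd = 0.05, duration = 60, seed = 4)
  b <- generate_trace(obs_noise_sd = 0.05, duration = 60, seed = 4)
  c <- generate_trace(obs_noise_sd = 0.05, duration = 60, seed = 5)
  expect_identical(a$fluorescence, b$fluorescence)
  expect_false(identical(a$fluorescence, c$fluorescence))
})

test_that("observation noise has the configured magnitude", {
  obs <- observation_params(kappa_f = 10, d_f = 2)
  clean <- generate_trace(obs = obs, obs_noise_sd = 0, duration = 1e4,
                          seed = 2)
  noisy <- generate_trace(obs = obs, obs_noise_sd = 0.05, duration = 1e4,
                          seed = 2)
  sd_hat <- stats::sd(noisy$fluorescence - clean$fluorescence)
  expect_lt(abs(sd_hat - 0.05) / 0.05, 0.03)
})

test_that("state-noise injection keeps traces finite and physical", {
  obs <- observation_params(kappa_f = 10, d_f = 2)
  tr <- generate_trace(obs = obs, obs_noise_sd = 0, state_noise_sd = 0.05,
                       duration = 120, seed = 8)
  expect_true(all(is.finite(tr$fluorescence)))
  # fluorescence stays inside the observable range of the indicator
  expect_true(all(tr$fluorescence >= obs$d_f &
                    tr$fluorescence <= obs$kappa_f + obs$d_f))
})

test_that("cohorts regenerate identically and encode group shifts", {
  eff <- list(A = c(), B = c(vs = 0.85))
  c1 <- generate_cohort(6, eff, seed = 33, duration = 30)
  c2 <- generate_cohort(6, eff, seed = 33, duration = 30)
  expect_identical(lapply(c1$traces, `[[`, "fluorescence"),
                   lapply(c2$traces, `[[`, "fluorescence"))
  expect_equal(nrow(c1$truth), 12L)
  expect_setequal(c1$truth$roi_id, vapply(c1$traces, `[[`, "", "roi_id"))
  # group B's true SERCA rates are lower on average by construction
  expect_lt(mean(c1$truth$vs[c1$truth$group == "B"]),
            mean(c1$truth$vs[c1$truth$group == "A"]))
  # a null shift leaves the groups exchangeable
  c0 <- generate_cohort(15, list(A = c(), B = c(vs = 1.0)), seed = 14,
                        duration = 30)
  ks <- ks_compare(c0$truth$vs[c0$truth$group == "A"],
                   c0$truth$vs[c0$truth$group == "B"])
  expect_gt(ks$p_value, 0.01)
  expect_error(generate_cohort(3, list(A = c(vs = -2))), "positive")
  expect_error(generate_cohort(3, list(A = c(bogus = 1))), "free kinetic")
})
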