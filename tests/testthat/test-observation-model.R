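test_that("the observation function is a saturating affine map", {
  obs <- observation_params(kappa_f = 2, d_f = 1)
  expect_equal(observe(0, obs), 1)                       # offset only
  expect_equal(observe(obs$k_d, obs), 2 / 2 + 1)         # half-saturation
  expect_equal(observation_params()$k_d, 0.167)          # GCaMP6m, 167 nM
  expect_error(observe(-0.1, obs), "non-negative")
  expect_error(observation_params(kappa_f = 0), "positive")
  expect_error(observation_params(k_d = -1), "positive")
})

test_that("fluorescence is strictly increasing and bounded by the plateau", {
  obs <- observation_params(kappa_f = 5, d_f = 0.3)
  cc <- sort(stats::runif(50, 0, 20))
  y <- observe(cc, obs)
  expect_true(all(diff(y) > 0))
  expect_true(all(y >= obs$d_f & y < obs$kappa_f + obs$d_f))
})

test_that("trace prediction is elementwise and invertible", {
  obs <- observation_params(kappa_f = 2, d_f = 1)
  expect_identical(predict_trace(numeric(0), obs), numeric(0))
  expect_equal(predict_trace(rep(obs$k_d, 4), obs), rep(2, 4))
  y3 <- predict_trace(c(0, obs$k_d, 1e3 * obs$k_d), obs)
  expect_equal(y3[1:2], c(1, 2))
  expect_equal(y3[3], 3, tolerance = 1e-3)
  # round trip to machine precision strictly inside the range
  cc <- stats::runif(30, 0.01, 5)
  expect_equal(invert_observation(observe(cc, obs), obs), cc,
               tolerance = 1e-12)
  expect_error(invert_observation(obs$kappa_f + obs$d_f, obs), "range")
})
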