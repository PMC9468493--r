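test_that("R-squared matches hand-computed values and guards its domain", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)  # SS_res 1, SS_tot 2
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(r_squared(1:3, 1:4), "equal")
})

test_that("acceptance depends only on a positive finite state-noise precision", {
  mk <- function(alpha, diverged = FALSE)
    structure(list(alpha = list(mean = alpha), diverged = diverged),
              class = "posterior_summary")
  expect_true(accept_run(mk(3.2)))
  expect_false(accept_run(mk(-0.1)))
  expect_false(accept_run(mk(NaN)))
  expect_false(accept_run(mk(3.2, diverged = TRUE)))
})

test_that("the generative prediction composes simulation and observation", {
  cfg <- inversion_config()
  obs <- observation_params(kappa_f = 10, d_f = 2)
  theta0 <- c(c_cs0 = 0.1, q0 = 0.5, p0 = 0.5,
              vs = 0, v1 = 0, v2 = 0, tau = 0, vp = 0, ks = 0)
  pred <- generative_predict(theta0, obs, n_frames = 60, config = cfg)
  traj <- simulate_kinetics(kinetic_state(0.1, 0.5, 0.5), kinetic_params(),
                            duration = 59)
  expect_equal(pred, predict_trace(traj$c_cs, obs), tolerance = 1e-12)
  # a single frame is the observed initial state
  expect_equal(generative_predict(theta0, obs, n_frames = 1, config = cfg),
               observe(0.1, obs))
  # the prediction is sensitive to the SERCA rate exponent
  theta1 <- theta0; theta1[["vs"]] <- 0.5
  pred1 <- generative_predict(theta1, obs, n_frames = 60, config = cfg)
  expect_false(isTRUE(all.equal(pred, pred1)))
})

test_that("configuration constraints are enforced", {
  expect_error(inversion_config(frame_dt = 1, micro_dt = 0.3),
               "integer multiple")
  expect_error(inversion_config(max_iterations = 0))
  expect_error(inversion_config(alpha_rate = -1))
  expect_error(invert_trace(1:5), "at least 10 frames")
  expect_error(invert_trace(list(a = 1)), "ca_trace")
})

test_that("single-trace inversion fits synthetic data and ascends free energy", {
  tr <- generate_trace(obs_noise_sd = 0.1, duration = 120, seed = 21)
  fit <- invert_trace(tr)
  expect_true(fit$accepted)
  expect_gt(fit$r_squared, 0.9)
  expect_true(all(diff(fit$free_energy) >= 0))
  expect_lte(length(fit$free_energy), inversion_config()$max_iterations)
  expect_true(all(fit$physical_mean > 0))
  expect_equal(length(fit$predicted), 120L)
  expect_true(all(fit$states$q >= 0 & fit$states$q <= 1))
})

test_that("an uninformative likelihood leaves the posterior at the prior", {
  # huge measurement-noise prior: expected precision ~ 1e-12
  cfg <- inversion_config(sigma_shape = 1e-6, sigma_rate = 1e6,
                          max_iterations = 20)
  tr <- generate_trace(obs_noise_sd = 0.05, duration = 60, seed = 5)
  fit <- invert_trace(tr, config = cfg)
  expect_false(isTRUE(fit$diverged))
  expect_true(all(abs(fit$theta_mean) < 1e-3))
  pm <- default_priors()
  expect_equal(unname(fit$physical_mean),
               pm$mean[match(names(fit$physical_mean), pm$name)],
               tolerance = 1e-3)
})

test_that("a flat trace terminates with posteriors near the prior", {
  tr <- make_trace(0:29, rep(7, 30))
  fit <- invert_trace(tr)
  expect_false(isTRUE(fit$diverged))
  expect_lte(fit$n_iterations, inversion_config()$max_iterations)
  pr <- default_priors()
  for (nm in names(fit$theta_mean)) {
    sd_nm <- sqrt(pr$variance[pr$name == nm])
    expect_lt(abs(fit$theta_mean[[nm]]), sd_nm)
  }
})

test_that("the precision-block posterior respects the evidence bound and
           peaks at its conjugate optimum", {
  # restricted model: y_t ~ N(mu_t, 1/sigma) with mu the fitted trace and
  # sigma ~ Gamma(1, 1); the variational gamma posterior must lower-bound
  # the log evidence (computed by quadrature) and beat perturbed posteriors
  tr <- generate_trace(obs_noise_sd = 0.1, duration = 60, seed = 13)
  fit <- invert_trace(tr)
  y <- fit$observed; mu <- fit$predicted
  n <- length(y); ss <- sum((y - mu)^2)
  c0 <- 1; d0 <- 1
  loglik <- function(s) -n / 2 * log(2 * pi) + n / 2 * log(s) - s * ss / 2
  # log evidence by quadrature on the precision scale
  lmax <- stats::optimize(function(s) loglik(s) + stats::dgamma(s, c0, d0,
                                                                log = TRUE),
                          c(1e-8, 1e4), maximum = TRUE)$objective
  ev <- stats::integrate(function(s) exp(loglik(s) +
                                           stats::dgamma(s, c0, d0, log = TRUE) -
                                           lmax),
                         0, Inf, rel.tol = 1e-10)$value
  log_ev <- log(ev) + lmax
  f_restricted <- function(cc, dd) {
    e_s <- cc / dd; el_s <- digamma(cc) - log(dd)
    elik <- -n / 2 * log(2 * pi) + n / 2 * el_s - e_s * ss / 2
    kl <- (cc - c0) * digamma(cc) - lgamma(cc) + lgamma(c0) +
      c0 * (log(dd) - log(d0)) + cc * (d0 - dd) / dd
    elik - kl
  }
  cc_opt <- c0 + n / 2; dd_opt <- d0 + ss / 2   # conjugate update
  expect_lte(f_restricted(cc_opt, dd_opt), log_ev)
  expect_gt(log_ev - f_restricted(cc_opt, dd_opt), -1e-8)
  # the bound degrades when the precision posterior is held off-optimum
  expect_lt(f_restricted(cc_opt, dd_opt * 3), f_restricted(cc_opt, dd_opt))
  expect_lt(f_restricted(cc_opt, dd_opt / 3), f_restricted(cc_opt, dd_opt))
  # the package's gamma shape follows the conjugate counting rule; its rate
  # additionally carries the state-covariance correction, so it upper-bounds
  # the naive residual rate
  expect_equal(fit$sigma$shape, cc_opt)
  expect_gte(fit$sigma$rate, d0 + ss / 2 - 1e-8)
})
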