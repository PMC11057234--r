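# The lambda weighting and linear combination need no meshes; trial
# estimates here are synthetic numbers.

fake_trials <- function(n, seed = 1) {
  monoshape:::with_seed(seed, {
    base <- runif(n, 20, 70)
    data.frame(
      theta_v2s3_deg = base + rnorm(n, 0, 6),
      theta_s3v_deg = base + rnorm(n, 0, 6),   # correlated regressors
      theta_sym2_deg = base + rnorm(n, 0, 3),
      theta_persp_deg = base + rnorm(n, 0, 2),
      gamma_deg = runif(n, 5, 25))
  })
}

test_that("lambda reproduces the closed form and its limits", {
  direct <- function(gamma, t) {
    phi <- 2 * atan(tan(gamma / 2 * pi / 180) * tan(t * pi / 180))
    (1 - cos(phi)) / 2
  }
  expect_equal(lambda_weight(0), 0)
  expect_equal(lambda_weight(20, 75), direct(20, 75), tolerance = 1e-15)
  expect_lt(abs(lambda_weight(20, 75) - 0.302), 5e-4)
  expect_lt(abs(lambda_weight(7, 75) - 0.050), 5e-4)
  # monotone increasing in gamma for several t
  for (t in c(30, 60, 75, 85)) {
    lam <- vapply(seq(0, 170, by = 1), lambda_weight, numeric(1),
                  t_deg = t)
    expect_true(all(diff(lam) > 0))
    expect_true(all(lam >= 0 & lam <= 1))
  }
  # phi -> pi limit drives lambda to 1
  expect_equal(lambda_weight(179.9, 89.9), 1, tolerance = 1e-3)
})

test_that("theta_lm and predict_slant combine estimates as specified", {
  est <- list(v2s3 = 40, s3v = 50, sym2 = 60, persp = 20, gamma_deg = 20)
  expect_equal(theta_lm(est, model_coefficients(0, 1, 0, 0)), 40)
  expect_equal(theta_lm(est, model_coefficients(33)), 33)
  est2 <- lapply(est, function(x) 2 * x); est2$gamma_deg <- est$gamma_deg
  b <- model_coefficients(0, 0.2, 0.3, 0.5)
  expect_equal(theta_lm(est2, b), 2 * theta_lm(est, b))

  lam <- lambda_weight(20, 75)
  pred <- predict_slant(est, model_coefficients(0, 1, 0, 0), clamp = FALSE)
  expect_equal(pred, lam * 20 + (1 - lam) * 40)
  # convexity: prediction between the two combined values
  expect_gte(pred, 20); expect_lte(pred, 40)
  # equal inputs are a fixed point for any lambda
  est_eq <- list(v2s3 = 37, s3v = 37, sym2 = 37, persp = 37,
                 gamma_deg = 150)
  expect_equal(predict_slant(est_eq, model_coefficients(0, 1, 0, 0),
                             clamp = FALSE), 37)
  # NA sym2 only allowed with beta3 = 0
  est_na <- est; est_na$sym2 <- NA_real_
  expect_equal(theta_lm(est_na, model_coefficients(0, 1, 0, 0)), 40)
  expect_error(theta_lm(est_na, model_coefficients(0, 0, 0, 1)), "beta3")
})

test_that("noiseless responses are fit exactly", {
  trials <- fake_trials(40, seed = 2)
  beta_true <- model_coefficients(5, 0.6, 0.1, 0.25)
  sim <- simulate_observer(trials, beta_true, response_noise_deg = 0)
  fit <- fit_coefficients(sim)
  expect_equal(fit$beta0, beta_true$beta0, tolerance = 1e-9)
  expect_equal(fit$beta1, beta_true$beta1, tolerance = 1e-9)
  expect_equal(fit$beta2, beta_true$beta2, tolerance = 1e-9)
  expect_equal(fit$beta3, beta_true$beta3, tolerance = 1e-9)
  expect_lt(fit$rmse_deg, 1e-9)
})

test_that("coefficients are recovered within 3 SE under response noise", {
  trials <- fake_trials(100, seed = 3)
  beta_true <- model_coefficients(2, 0.5, 0.2, 0.3)
  sim <- simulate_observer(trials, beta_true, response_noise_deg = 2,
                           seed = 7)
  fit <- fit_coefficients(sim)
  # analytic SEs of the transformed linear model
  lam <- vapply(sim$gamma_deg, lambda_weight, numeric(1), t_deg = 75)
  X <- cbind(1, sim$theta_v2s3_deg, sim$theta_s3v_deg,
             sim$theta_sym2_deg) * (1 - lam)
  se <- sqrt(diag(solve(crossprod(X))) * 2^2)
  est <- c(fit$beta0, fit$beta1, fit$beta2, fit$beta3)
  tru <- c(2, 0.5, 0.2, 0.3)
  expect_true(all(abs(est - tru) < 3 * se))
})

test_that("simulation is reproducible and noise inflates residuals", {
  trials <- fake_trials(60, seed = 4)
  beta <- model_coefficients(0, 0.4, 0.3, 0.3)
  s1 <- simulate_observer(trials, beta, 2, seed = 11)
  s2 <- simulate_observer(trials, beta, 2, seed = 11)
  expect_identical(s1$response_slant_deg, s2$response_slant_deg)

  rmse_at <- function(noise) {
    mean(vapply(1:10, function(rep) {
      sim <- simulate_observer(trials, beta, noise, seed = 100 + rep)
      fit_coefficients(sim)$rmse_deg
    }, numeric(1)))
  }
  r <- vapply(c(0.5, 2, 6), rmse_at, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("degenerate designs are reported as collinear", {
  trials <- fake_trials(30, seed = 5)
  trials$theta_s3v_deg <- trials$theta_v2s3_deg  # exact collinearity
  sim <- simulate_observer(trials, model_coefficients(0, 1, 0, 0))
  expect_error(fit_coefficients(sim), "collinear")
  expect_error(fit_coefficients(sim[1:3, ]), "at least 5")
})

test_that("grouped fits return one model per group", {
  trials <- rbind(cbind(fake_trials(30, seed = 6), object_type = "random"),
                  cbind(fake_trials(30, seed = 7),
                        object_type = "rectangular"))
  sim <- simulate_observer(trials, model_coefficients(0, 0.5, 0.25, 0.25),
                           2, seed = 8)
  sim$object_type <- trials$object_type
  fits <- fit_coefficients(sim, group_by = "object_type")
  expect_setequal(names(fits), c("random", "rectangular"))
  expect_true(all(vapply(fits, function(f) f$n_trials, numeric(1)) == 30))
})
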