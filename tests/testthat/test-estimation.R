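# canonical truths used for the round-trip checks, one per submodel
.roundtrip_cases <- list(
  reciprocity = list(truth = c(R_amp = 0.85, beta = 0.3),
                     x = seq(0, 5, length.out = 100)),
  sameness = list(truth = c(s_max = 0.9, r = 9.4, theta = 0.3),
                  x = seq(0, 1, length.out = 100)),
  interest = list(truth = c(I0 = 0.2, b = 0.8, lambda = 0.1),
                  x = seq(0, 40, length.out = 100)),
  relationship = list(truth = c(a = 0.8, k = 0.3, t_infl = 24),
                      x = seq(0, 60, length.out = 100)),
  sensory = list(truth = c(sigma = 0.8, delta = 0.05),
                 x = seq(0.5, 20, length.out = 100)),
  movement = list(truth = c(M0 = 0.4, Gamma = 0.6, omega = 4, phi = 0.5),
                  x = seq(0, 3, length.out = 200))
)

test_that("noiseless dense data recover every submodel to optimiser tolerance", {
  reg <- submodel_registry()
  for (nm in names(.roundtrip_cases)) {
    case <- .roundtrip_cases[[nm]]
    d <- data.frame(x = case$x, value = reg[[nm]]$predict(case$truth, case$x))
    fit <- fit_submodel(d, nm, seed = 1,
                        n_starts = if (nm == "movement") 24 else 8)
    expect_true(fit$converged, info = nm)
    expect_equal(coef(fit)[names(case$truth)], case$truth, tolerance = 1e-6,
                 info = nm)
    expect_lt(fit$ssr, 1e-12)
  }
})

test_that("noisy sigmoid estimates land within three asymptotic SEs", {
  reg <- submodel_registry()$sameness
  truth <- c(s_max = 0.9, r = 9.4, theta = 0.3)
  x <- seq(0, 1, length.out = 200)
  set.seed(101)
  y <- reg$predict(truth, x) + rnorm(200, 0, 0.02)
  fit <- fit_submodel(data.frame(x = x, value = y), "sameness", seed = 1)
  expect_true(fit$converged)
  expect_true(all(abs(coef(fit) - truth) <= 3 * fit$se))
  # summary exposes the same table
  s <- summary(fit)
  expect_equal(s$table$estimate, unname(coef(fit)))
})

test_that("fits extract the right variable from an EMA dataset", {
  reg <- submodel_registry()$sameness
  x <- seq(0, 1, length.out = 60)
  ema <- data.frame(subject = "s1", time = x, variable = "S",
                    value = reg$predict(c(s_max = 0.8, r = 6, theta = 0.2), x),
                    tier = 1L)
  class(ema) <- c("ema_dataset", "data.frame")
  fit <- fit_submodel(ema, "sameness", seed = 1)
  expect_equal(unname(coef(fit)), c(0.8, 6, 0.2), tolerance = 1e-6)
  expect_error(fit_submodel(ema, "interest"), "no observations")
})

test_that("underdetermined fits error; estimates ignore row order", {
  reg <- submodel_registry()$sameness
  x <- seq(0, 1, length.out = 40)
  d <- data.frame(x = x, value = reg$predict(c(s_max = 0.9, r = 9.4,
                                               theta = 0.3), x))
  expect_error(fit_submodel(d[1:2, ], "sameness"), "fewer observations")
  f1 <- fit_submodel(d, "sameness", seed = 3)
  set.seed(77)
  f2 <- fit_submodel(d[sample(nrow(d)), ], "sameness", seed = 3)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9)
})

test_that("predict and residuals methods are coherent", {
  reg <- submodel_registry()$interest
  x <- seq(0, 30, length.out = 50)
  d <- data.frame(x = x, value = reg$predict(c(I0 = 0.2, b = 0.8,
                                               lambda = 0.1), x))
  fit <- fit_submodel(d, "interest", seed = 1)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(d$value - predict(fit), residuals(fit))
  expect_equal(predict(fit, newdata = c(0, 10)),
               c(1.0, 0.2 + 0.8 * exp(-1)), tolerance = 1e-6)
})

test_that("recovery experiments are seeded and sharpen with less noise", {
  r1 <- recovery_experiment(n_replicates = 5, seed = 2)
  r2 <- recovery_experiment(n_replicates = 5, seed = 2)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
  expect_equal(nrow(r1$per_param), 3L)
  noisy <- recovery_experiment(design = list(n_obs = 200, noise_sd = 0.1,
                                             x_range = c(0, 1)),
                               n_replicates = 8, seed = 5)
  quiet <- recovery_experiment(design = list(n_obs = 200, noise_sd = 0.01,
                                             x_range = c(0, 1)),
                               n_replicates = 8, seed = 5)
  for (p in c("s_max", "r", "theta")) {
    expect_lt(quiet$per_param$rmse[quiet$per_param$parameter == p],
              noisy$per_param$rmse[noisy$per_param$parameter == p])
  }
  expect_error(recovery_experiment(n_replicates = 1), ">= 2")
})

test_that("identifiability audit flags exact multiplicative confounds", {
  a <- identifiability_audit("reciprocity")
  expect_length(a$directions, 1L)
  expect_match(a$confounded, "alpha \\* R0")
  d <- a$directions[[1]]
  expect_equal(abs(unname(d[c("alpha", "R0")])), c(1, 1) / sqrt(2),
               tolerance = 1e-6)
  expect_lt(abs(d[["beta"]]), 1e-6)

  s <- identifiability_audit("sameness")
  expect_match(s$confounded, "r_base \\* pi_precision")

  # fixing one factor of the product removes the null direction
  a_fixed <- identifiability_audit("reciprocity", fixed = "alpha")
  expect_length(a_fixed$directions, 0L)
})
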