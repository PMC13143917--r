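test_that("stereotypy amplitude saturates in entropy and divides by engagement", {
  p <- movement_params(Gamma_max = 1, k_H = 2, k_engage = 1, k_alt = 1)
  expect_equal(effective_amplitude(p, 0), 0)                  # zero numerator
  expect_equal(effective_amplitude(p, 2), 0.5)                # half-saturation
  # hand evaluation: (6/8) / (1 + 1*0.5) = 0.5
  expect_equal(effective_amplitude(p, 6, E_engage = 0.5), 0.5)
  # saturation limit Gamma_max / (1 + k_engage*E + k_alt*Phi)
  expect_equal(effective_amplitude(p, 1e6 * p$k_H, 0.5, 0.25),
               1 / (1 + 0.5 + 0.25), tolerance = 1e-6)
  expect_error(effective_amplitude(p, -1), "nonnegative")
})

test_that("movement intensity oscillates about the baseline", {
  p <- movement_params(M0 = 0.4, Gamma_max = 1, omega = 2 * pi, phi = 0,
                       k_H = 2)
  sig <- entropy_signal(c(0, 10), H_env = 2)    # Gamma_eff = 0.5 throughout
  # zero amplitude leaves the baseline
  sig0 <- entropy_signal(c(0, 10), H_env = 0)
  expect_equal(movement_intensity(p, sig0, c(0.3, 1.7)), c(0.4, 0.4))
  # sine maximum at omega*t + phi = pi/2
  expect_equal(movement_intensity(p, sig, 0.25), 0.4 + 0.5)
  # mean over one full period is the baseline (numerical quadrature)
  avg <- stats::integrate(function(t) movement_intensity(p, sig, t), 0, 1,
                          rel.tol = 1e-10)$value
  expect_equal(avg, 0.4, tolerance = 1e-8)
  # optional clamp floors the observable intensity at zero
  p_big <- movement_params(M0 = 0.1, Gamma_max = 1, omega = 2 * pi, k_H = 0.5)
  expect_lt(min(movement_intensity(p_big, sig, seq(0, 1, 0.01))), 0)
  expect_gte(min(movement_intensity(p_big, sig, seq(0, 1, 0.01), clamp = TRUE)), 0)
})

test_that("bout simulation is seeded, thinned by entropy and non-overlapping", {
  p <- movement_params(k_H = 2)
  sig <- entropy_signal(c(0, 50), H_env = 2)    # lambda = rate_scale / 2
  b1 <- simulate_bouts(p, sig, rate_scale = 4, seed = 7)
  b2 <- simulate_bouts(p, sig, rate_scale = 4, seed = 7)
  expect_identical(b1, b2)                       # determinism contract
  expect_true(all(diff(b1$onset) > 0))
  # bouts never overlap after truncation
  expect_true(all(b1$onset + b1$duration <= c(b1$onset[-1], Inf) + 1e-12))
  expect_true(all(b1$duration > 0))
  # zero intensity gives an empty sequence
  b0 <- simulate_bouts(p, sig, rate_scale = 0, seed = 7)
  expect_equal(nrow(b0), 0L)
  expect_error(simulate_bouts(p, sig, rate_scale = 4, seed = 1,
                              duration_dist = list(dist = "exponential",
                                                   rate = -1)),
               "unnormalisable")
})

test_that("empirical onset-rate ratio tracks the entropy nonlinearity", {
  p <- movement_params(k_H = 2)
  sig_lo <- entropy_signal(c(0, 30), H_env = 1)  # lambda = rs * 1/3
  sig_hi <- entropy_signal(c(0, 30), H_env = 3)  # lambda = rs * 3/5
  n_lo <- n_hi <- numeric(200)
  for (i in 1:200) {
    n_lo[i] <- nrow(simulate_bouts(p, sig_lo, rate_scale = 2, seed = 1000 + i))
    n_hi[i] <- nrow(simulate_bouts(p, sig_hi, rate_scale = 2, seed = 3000 + i))
  }
  ratio <- mean(n_lo) / mean(n_hi)
  expected <- (1 / 3) / (3 / 5)
  se <- expected * sqrt(1 / sum(n_lo) + 1 / sum(n_hi))
  expect_lt(abs(ratio - expected), 4 * se)
})

test_that("sameness distress has its midpoint at the tolerance threshold", {
  r <- routine_params(s_max = 0.9, r_base = 2, pi_precision = 4, theta = 0.3)
  expect_equal(deviation_distress(r, 0.3), 0.45)          # sigmoid midpoint
  expect_equal(deviation_distress(r, 50), 0.9, tolerance = 1e-9)  # asymptote
  # steepness at the midpoint equals s_max * r / 4 (analytic derivative)
  h <- 1e-6
  slope <- (deviation_distress(r, 0.3 + h) - deviation_distress(r, 0.3 - h)) / (2 * h)
  expect_equal(slope, 0.9 * 8 / 4, tolerance = 1e-6)
  # strictly increasing in deviation, precision (beyond theta) and ceiling
  set.seed(21)
  for (i in 1:30) {
    rr <- routine_params(s_max = runif(1, 0.3, 1), r_base = runif(1, 0.5, 5),
                         pi_precision = runif(1, 0.5, 5),
                         theta = runif(1, 0.05, 0.5))
    d <- runif(1, rr$theta + 0.01, rr$theta + 1)
    expect_gt(deviation_distress(rr, d + 0.1), deviation_distress(rr, d))
    rr_hi <- rr; rr_hi$pi_precision <- rr$pi_precision * 1.5
    expect_gt(deviation_distress(rr_hi, d), deviation_distress(rr, d))
    rr_s <- rr; rr_s$s_max <- rr$s_max * 1.1
    expect_gt(deviation_distress(rr_s, d), deviation_distress(rr, d))
  }
})

test_that("worked-scenario steepness calibration matches the bisection oracle", {
  # solve r_base so the seating-routine distress hits 0.85 at deviation 0.6
  r_cal <- solve_r_base(S_target = 0.85, s_max = 0.9, pi_precision = 4,
                        theta = 0.3, dev = 0.6)
  expect_equal(r_cal, 2.36099, tolerance = 1e-5)
  expect_equal(r_cal, log(17) / 1.2, tolerance = 1e-10)   # closed form
  r <- routine_params(s_max = 0.9, r_base = r_cal, pi_precision = 4,
                      theta = 0.3)
  expect_equal(deviation_distress(r, 0.6), 0.85, tolerance = 1e-9)
})

test_that("total sameness sums per-routine distress", {
  r1 <- routine_params(label = "a", s_max = 0.9, r_base = 9, theta = 0.3)
  r2 <- routine_params(label = "b", s_max = 0.5, r_base = 4, theta = 0.1)
  # singleton reduces to the per-routine call; order is irrelevant
  expect_equal(total_sameness(list(r1), 0.4), deviation_distress(r1, 0.4))
  expect_equal(total_sameness(list(r1, r2), c(0.4, 0.2)),
               total_sameness(list(r2, r1), c(0.2, 0.4)))
  # no deviation leaves only the sigmoid floors
  expect_equal(total_sameness(list(r1, r2), c(0, 0)),
               0.9 / (1 + exp(9 * 0.3)) + 0.5 / (1 + exp(4 * 0.1)))
  expect_error(total_sameness(list(r1, r2), 0.4), "aligned")
})

test_that("equifinal configurations agree at the anchor and differ off it", {
  for (target in c(0.5, 0.85)) {
    cfg <- equifinality_profiles(S_target = target, deviation_ref = 0.6)
    expect_named(cfg, c("high_precision", "low_threshold", "high_ceiling"))
    at_ref <- vapply(cfg, deviation_distress, numeric(1), x_current = 0.6)
    expect_equal(unname(at_ref), rep(target, 3), tolerance = 1e-6)
    # distinguishable response curves at half the reference deviation
    at_half <- vapply(cfg, deviation_distress, numeric(1), x_current = 0.3)
    expect_gt(min(dist(at_half)), 1e-3)
    # the high-precision regime carries the elevated precision weight
    expect_gte(cfg$high_precision$pi_precision, 4)
  }
  expect_error(equifinality_profiles(1.2, 0.6), "infeasible")
})

test_that("interest engagement decays from each acquisition toward the floor", {
  p <- interest_params(I0 = 0.2, interests = list(
    list(b_base = 0.8, R_int = 1, R_norm = 1, lambda_base = 0.1,
         P_acc = 0, t_acquired = 0)))
  expect_equal(interest_engagement(p, 0), 1.0)           # I0 + b at onset
  expect_equal(interest_engagement(p, 10), 0.2 + 0.8 * exp(-1),
               tolerance = 1e-12)                         # direct evaluation
  expect_equal(interest_engagement(p, 1e4), 0.2, tolerance = 1e-9)
  # perfect prediction accuracy freezes the term at b forever
  p_frozen <- interest_params(I0 = 0.1, interests = list(
    list(b_base = 0.5, R_int = 2, R_norm = 1, lambda_base = 0.3,
         P_acc = 1, t_acquired = 12)))
  expect_equal(interest_engagement(p_frozen, c(12, 120, 1200)),
               rep(0.1 + 1.0, 3))
  # before acquisition an interest contributes nothing
  expect_equal(interest_engagement(p_frozen, 6), 0.1)
})

test_that("net habituation rate turns negative under high arousal", {
  p <- sensory_stimulus_params(sigma = 1, delta_base = 0.1, gaba_ratio = 1,
                               k_sens = 0)
  expect_equal(habituation_rate(p, 0), 0.1)              # identity case
  p2 <- sensory_stimulus_params(sigma = 1, delta_base = 0.1, gaba_ratio = 0.5,
                                k_sens = 0.2)
  expect_equal(habituation_rate(p2, 0.5), -0.05)         # sensitisation regime
  # non-increasing in arousal
  xs <- seq(0, 2, 0.1)
  expect_true(all(diff(habituation_rate(p2, xs)) <= 0))
  expect_error(habituation_rate(p2, -1), "nonnegative")
})

test_that("cumulative impact matches adaptive quadrature on all branches", {
  for (sigma in c(0.1, 0.8, 2)) {
    for (delta in c(-0.5, -0.1, -1e-6, 0, 1e-6, 0.1, 0.5)) {
      for (T in c(0.5, 2, 10)) {
        closed <- cumulative_impact(sigma, delta, T)
        quad <- impact_by_quadrature(sigma, delta, T)
        expect_lt(abs(closed - quad), 1e-8 * (1 + abs(quad)))
      }
    }
  }
  expect_equal(cumulative_impact(0.8, 0, 90), 72)   # linear accumulation
  expect_equal(cumulative_impact(1, 0.5, 2), 2 * (1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(cumulative_impact(0.5, -0.2, 3), 2.5 * (exp(0.6) - 1),
               tolerance = 1e-12)
  expect_equal(cumulative_impact(1, 0.3, 0), 0)     # empty integral
  expect_error(cumulative_impact(1, 0, -1), "negative")
})

test_that("impact branches are continuous and ordered across delta signs", {
  for (sigma in c(0.3, 1, 2)) {
    for (T in c(0.5, 2, 10)) {
      p0 <- cumulative_impact(sigma, 0, T)
      for (d in c(-1e-8 * (1 - 1e-3), 1e-8 * (1 - 1e-3),
                  -1e-8 * (1 + 1e-3), 1e-8 * (1 + 1e-3))) {
        expect_lt(abs(cumulative_impact(sigma, d, T) - p0), 1e-6 * sigma * T)
      }
      # sensitisation > habituation failure > habituation at equal sigma, T
      expect_gt(cumulative_impact(sigma, -0.2, T), p0)
      expect_lt(cumulative_impact(sigma, 0.2, T), p0)
      # bounded by sigma/delta as T grows, linear at delta = 0
      expect_lt(cumulative_impact(sigma, 0.2, 1e6), sigma / 0.2 + 1e-9)
    }
  }
})

test_that("total sensory load is additive over stimuli with lagged arousal", {
  s1 <- list(params = sensory_stimulus_params(sigma = 0.8, delta_base = 0.05,
                                              gaba_ratio = 1, k_sens = 0.1),
             T = 2, Xi = 0.5)
  expect_equal(total_sensory_load(list()), 0)
  one <- total_sensory_load(list(s1))
  delta1 <- habituation_rate(s1$params, 0.5)
  expect_equal(one, cumulative_impact(0.8, delta1, 2))
  expect_equal(total_sensory_load(list(s1, s1)), 2 * one)
})
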