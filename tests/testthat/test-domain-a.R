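test_that("effective depletion rate matches hand evaluation of the ratio", {
  p0 <- reciprocity_params(beta_base = 0.3, M_social = 0, Pr_env = 0,
                           I_align = 0, R0 = 0.85)
  # identity case: no loads, no protection
  expect_equal(effective_depletion_rate(p0, 0, 0, 0), 0.3)
  # hand-evaluated: 0.3 * (1 + .4 + .2 + .5) / (1 + .6 + 0 + .3) = 0.3*2.1/1.9
  p <- reciprocity_params(beta_base = 0.3, M_social = 0.6, Pr_env = 0,
                          I_align = 0.3)
  expect_equal(effective_depletion_rate(p, 0.4, 0.2, 0.5), 0.3 * 2.1 / 1.9,
               tolerance = 1e-12)
  expect_error(effective_depletion_rate(p, -0.1, 0, 0), "nonnegative")
})

test_that("depletion rate is monotone in loads and protective terms", {
  set.seed(11)
  for (i in 1:50) {
    p <- reciprocity_params(beta_base = runif(1, 0.1, 0.5),
                            k_E = runif(1, 0, 2), k_Lambda = runif(1, 0, 2),
                            k_P = runif(1, 0, 2), k_M = runif(1, 0, 2),
                            k_Pr = runif(1, 0, 2), k_I = runif(1, 0, 2),
                            M_social = runif(1, 0, 1), Pr_env = runif(1, 0, 1),
                            I_align = runif(1, 0, 1), R0 = 0.8, alpha = 1)
    E <- runif(1, 0, 2); L <- runif(1, 0, 2); Pi <- runif(1, 0, 2)
    b <- effective_depletion_rate(p, E, L, Pi)
    expect_gte(effective_depletion_rate(p, E + 0.5, L, Pi), b)
    expect_gte(effective_depletion_rate(p, E, L + 0.5, Pi), b)
    expect_gte(effective_depletion_rate(p, E, L, Pi + 0.5), b)
    # doubling a protective term never increases the rate
    p2 <- p; p2$M_social <- 2 * p$M_social
    expect_lte(effective_depletion_rate(p2, E, L, Pi), b)
    p3 <- p; p3$I_align <- 2 * p$I_align
    expect_lte(effective_depletion_rate(p3, E, L, Pi), b)
  }
})

test_that("reciprocity trajectory reproduces the constant-load closed form", {
  p <- reciprocity_params(R0 = 0.85, alpha = 1, beta_base = 0.5,
                          M_social = 0, Pr_env = 0, I_align = 0)
  ctx <- social_context_signal(seq(0, 3, by = 0.01))
  tr <- reciprocity_trajectory(p, ctx)
  expect_equal(tr$R[1], 0.85)                      # R(0) = alpha * R0
  expect_equal(tr$R[tr$time == 1], 0.85 * exp(-0.5), tolerance = 1e-12)
  expect_equal(tr$R, 0.85 * exp(-0.5 * tr$time), tolerance = 1e-12)
  # non-increasing whenever beta_eff >= 0
  expect_true(all(diff(tr$R) <= 0))
  expect_error(reciprocity_trajectory(p, ctx[0, ]), "empty")
})

test_that("time-varying depletion is stable under grid refinement", {
  p <- reciprocity_params(R0 = 0.85, alpha = 1, beta_base = 0.4,
                          M_social = 0, Pr_env = 0, I_align = 0)
  mk <- function(dt) {
    t <- seq(0, 2, by = dt)
    social_context_signal(t, E_exec = 0.5 + 0.5 * sin(2 * t),
                          Lambda_s = 0.3, Pi_load = 0.2)
  }
  coarse <- reciprocity_trajectory(p, mk(0.02))
  fine <- reciprocity_trajectory(p, mk(0.005))
  at <- c(0.5, 1, 2)
  expect_equal(coarse$R[match(at, coarse$time)],
               fine$R[match(at, fine$time)], tolerance = 1e-4)
})

test_that("nonverbal effectiveness is the weighted channel sum", {
  ch <- list(nonverbal_channel("a", 0.3, 0.5, 1.0),
             nonverbal_channel("b", 0.2, 1.0, 0.5))
  expect_equal(nonverbal_effectiveness(ch), 0.25)   # hand summation
  # zero-efficiency channel contributes nothing
  ch0 <- c(ch, list(nonverbal_channel("c", 5, 0, 1)))
  expect_equal(nonverbal_effectiveness(ch0), 0.25)
  # permutation invariance and linearity in each cue score
  expect_equal(nonverbal_effectiveness(rev(ch0)), 0.25)
  ch_scaled <- ch
  ch_scaled[[1]]$x <- 2 * ch[[1]]$x
  expect_equal(nonverbal_effectiveness(ch_scaled) - nonverbal_effectiveness(ch),
               0.3 * 0.5 * 1.0)
  # with full efficiency N reduces to the normative weighted score
  ch_eta1 <- default_channels(eta = 1, x = c(0.2, 0.4, 0.6, 0.8, 1, 0.1))
  expect_equal(nonverbal_effectiveness(ch_eta1),
               sum(1 / 6 * c(0.2, 0.4, 0.6, 0.8, 1, 0.1)))
  expect_error(nonverbal_effectiveness(list()), "empty")
})

test_that("relationship growth anchors, limits and additivity hold", {
  r <- relationship_params(a_max = 1.2, M_soc = 0.8, M_norm = 1,
                           k_base = 0.5, R_sal = 0.9, R_norm = 1,
                           P_var = 0.2, t_infl = 24)
  a <- 1.2 * 0.8
  k <- 0.5 * 0.9 * 0.8
  # half-maximum at the inflection time
  expect_equal(relationship_quality(list(r), 24)$C, a / 2)
  # asymptote reached far past the inflection
  expect_equal(relationship_quality(list(r), 24 + 50 / k)$C, a,
               tolerance = 1e-9)
  # P_var = 1 freezes the component at a/2 for all t
  r_frozen <- relationship_params(a_max = 1, P_var = 1, t_infl = 24)
  for (t in c(-100, 0, 24, 500))
    expect_equal(relationship_quality(list(r_frozen), t)$C, 0.5)
  # additivity over relationships, and non-decreasing in t
  r2 <- relationship_params(a_max = 0.7, k_base = 0.2, t_infl = 60)
  ts <- seq(0, 120, by = 1)
  both <- relationship_quality(list(r, r2), ts)$C
  expect_equal(both, relationship_quality(list(r), ts)$C +
                 relationship_quality(list(r2), ts)$C, tolerance = 1e-12)
  expect_true(all(diff(both) >= 0))
  expect_error(relationship_quality(list(r), Inf), "finite")
})
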