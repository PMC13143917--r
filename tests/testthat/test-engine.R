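test_that("coupling map saturates between zero and one", {
  expect_equal(coupling_map(0, 50), 0)
  expect_equal(coupling_map(50, 50), 0.5)
  g <- coupling_map(seq(0, 500, 10), 50)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g >= 0 & g < 1))
  expect_error(coupling_map(10, 0), "positive")
})

test_that("engine dependency graph is acyclic given the arousal lag", {
  g <- engine_dependency_graph()
  ord <- asdyn:::.topological_order(g)
  expect_false(is.null(ord))
  # the lag is what breaks the loop: making the arousal edge instantaneous
  # closes the cycle Xi -> delta_s -> P_total -> Lambda_s -> Xi
  g2 <- g
  g2$lagged <- FALSE
  expect_null(asdyn:::.topological_order(g2))
  # the composite is terminal: nothing depends on A
  expect_false("A" %in% g$from)
})

test_that("decoupled scenario reduces to the pure exponential limit", {
  prof <- individual_profile(
    reciprocity = reciprocity_params(R0 = 0.8, alpha = 1, beta_base = 0.3,
                                     M_social = 0.6, Pr_env = 0.2,
                                     I_align = 0.1),
    stimuli = list(),
    routines = list(r1 = routine_params(s_max = 0, r_base = 1)))
  sc <- quiet_scenario(prof, horizon = 120)
  b <- run_scenario(sc, seed = 1)
  s <- b$series
  beta_expect <- 0.3 / (1 + 0.6 + 0.2 + 0.1)
  expect_equal(s$beta_eff, rep(beta_expect, nrow(s)), tolerance = 1e-12)
  expect_equal(s$R, 0.8 * exp(-beta_expect * s$time / 60), tolerance = 1e-10)
  expect_equal(s$P_total, rep(0, nrow(s)))
  expect_equal(s$M, rep(prof$movement$M0, nrow(s)))      # zero entropy
  expect_equal(nrow(b$events), 0L)
})

test_that("same-seed runs are byte-identical", {
  sc <- restaurant_vignette()
  b1 <- run_scenario(sc, seed = 42)
  b2 <- run_scenario(sc, seed = 42)
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))
})

test_that("the packaged restaurant scenario reproduces its printed numbers", {
  b <- run_scenario(restaurant_vignette(), seed = 1)
  s <- b$series
  # linear accumulation of the ambient-noise load: 0.8 * 90 = 72
  expect_equal(s$P_total[s$time == 90], 72, tolerance = 1e-9)
  # withdrawal at the first 15-minute report with P_total above 70
  expect_equal(b$metadata$withdrawal_time, 90)
  expect_true("withdrawal" %in% b$events$type)
  # table-relocation distress at the calibrated steepness
  expect_equal(s$S[s$time == 70], 0.85, tolerance = 1e-9)
  expect_lt(s$S[s$time == 69], 0.06)
  # depletion accelerates as sensory load accumulates; reciprocity declines
  expect_true(all(diff(s$R) < 0))
  expect_gt(s$beta_eff[s$time == 60], s$beta_eff[1])
  # amplitude rises with the filling room
  expect_gt(s$Gamma_eff[s$time == 60], s$Gamma_eff[s$time == 30])
  # composite stays in the unit interval
  expect_true(all(s$A >= 0 & s$A <= 1))
})

test_that("raising the regulatory threshold suppresses withdrawal", {
  sc <- restaurant_vignette()
  sc$profile$threshold <- 1000          # above sigma * horizon = 96
  b <- run_scenario(sc, seed = 1)
  expect_true(is.na(b$metadata$withdrawal_time))
  expect_false("withdrawal" %in% b$events$type)
})

test_that("halving the fast step moves the endpoints by less than 1e-3", {
  sc1 <- restaurant_vignette()
  sc2 <- restaurant_vignette()
  sc2$dt <- 0.5
  b1 <- run_scenario(sc1, seed = 1)
  b2 <- run_scenario(sc2, seed = 1)
  end1 <- b1$series[nrow(b1$series), ]
  end2 <- b2$series[nrow(b2$series), ]
  expect_lt(abs(end1$P_total - end2$P_total) / end1$P_total, 1e-3)
  expect_lt(abs(end1$R - end2$R) / end1$R, 1e-3)
})

test_that("load accumulation stops when the exposure ends", {
  sc <- restaurant_vignette()
  sc$exposures[[1]]$end <- 60
  b <- run_scenario(sc, seed = 1)
  s <- b$series
  expect_equal(s$P_total[s$time == 60], 48, tolerance = 1e-9)
  after <- s$P_total[s$time >= 60]
  expect_equal(after, rep(48, length(after)), tolerance = 1e-9)
  # optional first-order clearance drains it instead
  sc$clearance_rate <- 0.05
  b2 <- run_scenario(sc, seed = 1)
  s2 <- b2$series
  expect_lt(s2$P_total[s2$time == 120], s2$P_total[s2$time == 60])
})

test_that("scenario validation rejects dangling references and bad windows", {
  prof <- individual_profile()
  expect_error(scenario(prof, horizon = 60,
                        events = list(list(time = 70, routine = "routine",
                                           magnitude = 0.5))),
               "outside horizon")
  expect_error(scenario(prof, horizon = 60,
                        events = list(list(time = 10, routine = "nope",
                                           magnitude = 0.5))),
               "undeclared routine")
  expect_error(scenario(prof, horizon = 60,
                        exposures = list(list(label = "ghost", start = 0,
                                              end = 10))),
               "undeclared stimulus")
  expect_error(scenario(prof, horizon = 60, dt = 0), "positive")
  bad <- individual_profile()
  bad$movement$k_H <- 0
  expect_error(run_scenario(quiet_scenario(bad), seed = 1), "invalid profile")
})
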