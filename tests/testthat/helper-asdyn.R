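# shared fixture builders (all fixtures are generated in code)

# minimal decoupled scenario: no stimuli, flat zero entropy, no events,
# zero context loads
quiet_scenario <- function(profile = individual_profile(), horizon = 60) {
  scenario(profile, horizon = horizon, dt = 1, report_dt = 15,
           time_unit = "minutes",
           env = data.frame(time = c(0, horizon), H_env = 0),
           context = list(E_exec = 0, Pi_load = 0, E_engage = 0,
                          Phi_alt = 0))
}

# quadrature oracle for the cumulative sensory impact (independent of the
# closed-form implementation path)
impact_by_quadrature <- function(sigma, delta, T) {
  if (T == 0) return(0)
  stats::integrate(function(t) sigma * exp(-delta * t), 0, T,
                   rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# bisection oracle: solve r_base so that the sameness sigmoid hits S_target
solve_r_base <- function(S_target, s_max, pi_precision, theta, dev,
                         lo = 1e-4, hi = 100) {
  f <- function(r) {
    s_max / (1 + exp(-r * pi_precision * (dev - theta))) - S_target
  }
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}
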