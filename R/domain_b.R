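#' Entropy/engagement signal
#'
#' Time-indexed exogenous drivers of the stereotypy submodel: environmental
#' entropy (bits), engagement in absorbing activity and the availability of
#' alternative regulatory behaviours.
#'
#' @param time strictly increasing grid (hours).
#' @param H_env environmental entropy (bits, >= 0), recycled.
#' @param E_engage engagement level (>= 0), recycled.
#' @param Phi_alt availability of alternative regulatory behaviours (>= 0),
#'   recycled.
#' @return data.frame of class `entropy_signal`.
#' @export
entropy_signal <- function(time, H_env, E_engage = 0, Phi_alt = 0) {
  if (length(time) == 0L) stop("entropy_signal: empty time grid")
  if (any(diff(time) <= 0)) stop("entropy_signal: grid must be strictly increasing")
  x <- data.frame(time = time,
                  H_env = rep_len(H_env, length(time)),
                  E_engage = rep_len(E_engage, length(time)),
                  Phi_alt = rep_len(Phi_alt, length(time)))
  if (any(x$H_env < 0)) stop("entropy_signal: entropy must be nonnegative")
  class(x) <- c("entropy_signal", "data.frame")
  x
}

#' Effective stereotypy amplitude
#'
#' `Gamma_eff = Gamma_max * H / (H + k_H) * 1 / (1 + k_engage*E + k_alt*Phi)`:
#' amplitude saturates in environmental entropy (half-maximal at `H = k_H`)
#' and is divided down by engagement and alternative regulation. Always in
#' `[0, Gamma_max)`.
#'
#' @param p [movement_params()].
#' @param H_env environmental entropy, bits (>= 0); vectorised.
#' @param E_engage engagement level (>= 0).
#' @param Phi_alt alternative-behaviour availability (>= 0).
#' @return effective amplitude (frequency units).
#' @export
effective_amplitude <- function(p, H_env, E_engage = 0, Phi_alt = 0) {
  if (any(H_env < 0)) stop("effective_amplitude: entropy must be nonnegative")
  p$Gamma_max * (H_env / (H_env + p$k_H)) /
    (1 + p$k_engage * E_engage + p$k_alt * Phi_alt)
}

#' Stereotyped movement intensity
#'
#' `M(t) = M0 + Gamma_eff(t) * sin(omega * t + phi)`, with the amplitude
#' evaluated from the entropy signal (linear interpolation in time). The model
#' may dip below `M0`; an optional nonnegativity clamp is available for
#' observation realism and is off by default.
#'
#' @param p [movement_params()].
#' @param signals an [entropy_signal()].
#' @param t evaluation time(s), hours, within the signal grid.
#' @param clamp clip negative intensities to zero?
#' @return movement intensity at `t`.
#' @export
movement_intensity <- function(p, signals, t, clamp = FALSE) {
  H <- stats::approx(signals$time, signals$H_env, xout = t, rule = 2)$y
  E <- stats::approx(signals$time, signals$E_engage, xout = t, rule = 2)$y
  Phi <- stats::approx(signals$time, signals$Phi_alt, xout = t, rule = 2)$y
  m <- p$M0 + effective_amplitude(p, H, E, Phi) * sin(p$omega * t + p$phi)
  if (clamp) m <- pmax(m, 0)
  m
}

#' Simulate stereotypy bouts (non-homogeneous Poisson process)
#'
#' Hybrid bout model: bout onsets follow a non-homogeneous Poisson process
#' with the saturating entropy-driven rate
#' `lambda(t) = rate_scale * H(t) / (H(t) + k_H)`, simulated by thinning;
#' within each bout the behaviour follows the sinusoidal intensity model.
#' Onsets are strictly increasing and bout durations are truncated at the next
#' onset so bouts never overlap.
#'
#' @param p [movement_params()].
#' @param signals an [entropy_signal()]; its grid defines the horizon.
#' @param rate_scale onset-rate scale, per hour (>= 0).
#' @param duration_dist bout-duration specification: a list with `dist`
#'   (`"lognormal"`, `"exponential"` or `"fixed"`) and its parameters
#'   (`meanlog`/`sdlog`, `rate`, or `value`).
#' @param seed integer seed; identical seeds give identical sequences.
#' @param rate_fn optional replacement for the saturating onset-rate, a
#'   function of time returning a rate bounded by `rate_scale`.
#' @return object of class `bout_sequence`: data.frame `(onset, duration)`
#'   with the oscillation parameters attached as attributes.
#' @export
simulate_bouts <- function(p, signals, rate_scale,
                           duration_dist = list(dist = "lognormal",
                                                meanlog = log(0.05),
                                                sdlog = 0.5),
                           seed, rate_fn = NULL) {
  if (rate_scale < 0) stop("simulate_bouts: rate_scale must be >= 0")
  if (missing(seed)) stop("simulate_bouts: an explicit seed is required")
  horizon <- max(signals$time)
  if (!is.finite(horizon)) stop("simulate_bouts: horizon must be finite")
  if (is.null(rate_fn)) {
    rate_fn <- function(t) {
      H <- stats::approx(signals$time, signals$H_env, xout = t, rule = 2)$y
      rate_scale * H / (H + p$k_H)
    }
  }
  rdur <- switch(duration_dist$dist,
    lognormal = function(n) stats::rlnorm(n, duration_dist$meanlog, duration_dist$sdlog),
    exponential = {
      if (duration_dist$rate <= 0) stop("simulate_bouts: unnormalisable duration spec")
      function(n) stats::rexp(n, duration_dist$rate)
    },
    fixed = {
      if (duration_dist$value <= 0) stop("simulate_bouts: unnormalisable duration spec")
      function(n) rep(duration_dist$value, n)
    },
    stop("simulate_bouts: unknown duration distribution '", duration_dist$dist, "'")
  )
  set.seed(seed)
  onsets <- numeric(0)
  if (rate_scale > 0) {
    t <- 0
    repeat {
      t <- t + stats::rexp(1, rate_scale)   # candidate from dominating rate
      if (t > horizon) break
      if (stats::runif(1) <= rate_fn(t) / rate_scale) onsets <- c(onsets, t)
    }
  }
  durations <- if (length(onsets)) rdur(length(onsets)) else numeric(0)
  if (length(onsets) > 1L) {
    gap <- diff(c(onsets, Inf))
    durations <- pmin(durations, gap)       # truncate at next onset
  }
  durations <- pmin(durations, horizon - onsets)
  out <- data.frame(onset = onsets, duration = durations)
  attr(out, "oscillation") <- p[c("M0", "Gamma_max", "omega", "phi")]
  attr(out, "seed") <- seed
  class(out) <- c("bout_sequence", "data.frame")
  out
}

#' Distress from routine deviation
#'
#' Precision-weighted sigmoid:
#' `S_k = s_max / (1 + exp(-r_base * pi * (|x - x_expected| - theta)))`.
#' Half-maximal exactly at the tolerance threshold, saturating at `s_max`, and
#' strictly increasing in the deviation magnitude. The value at zero deviation
#' is the small sigmoid floor `s_max / (1 + exp(r * theta))`, not zero.
#'
#' @param r [routine_params()].
#' @param x_current current state of the routine (deviation units); vectorised.
#' @return distress `S_k` in `(0, s_max)`.
#' @export
deviation_distress <- function(r, x_current) {
  dev <- abs(x_current - r$x_expected)
  rate <- r$r_base * r$pi_precision
  r$s_max / (1 + exp(-rate * (dev - r$theta)))
}

#' Total insistence on sameness
#'
#' `S = sum_k S_k` over routines, each evaluated at its current state.
#'
#' @param routines list of [routine_params()] objects.
#' @param states numeric vector of current states, aligned with `routines`.
#' @return total distress `S`.
#' @export
total_sameness <- function(routines, states) {
  if (length(routines) != length(states))
    stop("total_sameness: routines and states must be aligned")
  sum(mapply(function(r, x) deviation_distress(r, x), routines, states))
}

#' Equifinal routine configurations for a target distress
#'
#' Clinically similar distress at a reference deviation can arise from three
#' mechanistically distinct parameter regimes: elevated precision (steep
#' response), a constitutionally low tolerance threshold, or a high distress
#' ceiling. For a target `S_target` at deviation `deviation_ref` this returns
#' one configuration of each kind, every one satisfying
#' `S_k(deviation_ref) = S_target` (to well below 1e-6 by closed-form
#' anchoring) while the full response curves differ away from the anchor.
#'
#' @param S_target target distress at the reference deviation (0 < S_target < 1).
#' @param deviation_ref reference deviation magnitude (> 0).
#' @return named list of three [routine_params()]: `high_precision`,
#'   `low_threshold`, `high_ceiling`.
#' @export
equifinality_profiles <- function(S_target, deviation_ref) {
  if (S_target <= 0 || S_target >= 1)
    stop("equifinality_profiles: infeasible target (need 0 < S_target < 1 with s_max <= 1)")
  if (deviation_ref <= 0)
    stop("equifinality_profiles: deviation_ref must be positive")
  logit <- function(q) log(q / (1 - q))
  # shared ceiling for the first two regimes, slightly above the target
  s_ab <- min(1, S_target + 0.05)
  solve_r <- function(s, theta) logit(S_target / s) / (deviation_ref - theta)

  # regime 1: high precision, threshold at half the reference deviation
  th1 <- deviation_ref / 2
  pi1 <- 4
  r1 <- routine_params(label = "high_precision", s_max = s_ab,
                       r_base = solve_r(s_ab, th1) / pi1, pi_precision = pi1,
                       theta = th1)
  # regime 2: low threshold, moderate precision
  th2 <- deviation_ref / 10
  r2 <- routine_params(label = "low_threshold", s_max = s_ab,
                       r_base = solve_r(s_ab, th2), pi_precision = 1,
                       theta = th2)
  # regime 3: ceiling at the maximum; anchor by solving the threshold
  lg <- logit(S_target)
  rate3 <- if (lg > 0) max(2 / deviation_ref, 1.5 * lg / deviation_ref) else 2 / deviation_ref
  th3 <- deviation_ref - lg / rate3
  r3 <- routine_params(label = "high_ceiling", s_max = 1,
                       r_base = rate3, pi_precision = 1, theta = th3)

  out <- list(high_precision = r1, low_threshold = r2, high_ceiling = r3)
  anchored <- vapply(out, deviation_distress, numeric(1), x_current = deviation_ref)
  if (any(abs(anchored - S_target) > 1e-9))
    stop("equifinality_profiles: infeasible target")
  out
}

#' Restricted-interest engagement
#'
#' `I(t) = I0 + sum_l b_l * exp(-lambda_l * (t - t_acquired_l))` with
#' `b_l = b_base * (R_int / R_norm)` and
#' `lambda_l = lambda_base * (1 - P_acc)`. Each term decays from its own
#' acquisition time; interests not yet acquired at `t` contribute nothing.
#' Perfect within-domain prediction (`P_acc = 1`) freezes a term at `b_l`.
#'
#' @param p [interest_params()].
#' @param t evaluation time(s), months.
#' @return engagement intensity `I(t)`; tends to `I0` as `t` grows when all
#'   decay rates are positive.
#' @export
interest_engagement <- function(p, t) {
  out <- rep(p$I0, length(t))
  for (it in p$interests) {
    b <- it$b_base * (it$R_int / it$R_norm)
    lambda <- it$lambda_base * (1 - it$P_acc)
    dt <- t - it$t_acquired
    active <- dt >= 0
    out[active] <- out[active] + b * exp(-lambda * dt[active])
  }
  out
}

#' Net habituation/sensitisation rate
#'
#' `delta = delta_base * gaba_ratio - k_sens * Xi`. Reduced GABAergic function
#' lowers the habituation rate; sufficient arousal pushes it negative, i.e.
#' into the sensitisation regime.
#'
#' @param p [sensory_stimulus_params()].
#' @param Xi arousal/anxiety level (>= 0); vectorised.
#' @return net rate `delta`, per hour (may be negative).
#' @export
habituation_rate <- function(p, Xi) {
  if (any(Xi < 0)) stop("habituation_rate: arousal must be nonnegative")
  p$delta_base * p$gaba_ratio - p$k_sens * Xi
}

#' Cumulative sensory impact of one stimulus
#'
#' Closed-form evaluation of `P(s) = integral_0^T sigma * exp(-delta * t) dt`:
#' bounded saturation for `delta > 0`, exactly linear accumulation
#' `sigma * T` for `delta = 0` (habituation failure), and unbounded
#' exponential growth for `delta < 0` (sensitisation). Near `delta = 0`
#' (|delta| <= `eps`) a second-order series is used to avoid catastrophic
#' cancellation; the three branches are continuous in `delta`.
#'
#' @param sigma sensitivity intensity (>= 0).
#' @param delta net habituation rate (any sign).
#' @param T exposure duration (>= 0); vectorised.
#' @param eps series-branch half-width (default 1e-8).
#' @return cumulative impact `P(s)`.
#' @export
cumulative_impact <- function(sigma, delta, T, eps = 1e-8) {
  if (any(T < 0)) stop("cumulative_impact: negative exposure duration")
  if (sigma < 0) stop("cumulative_impact: sigma must be >= 0")
  if (abs(delta) <= eps) {
    dT <- delta * T
    sigma * T * (1 - dT / 2 + dT^2 / 6)
  } else if (delta > 0) {
    (sigma / delta) * (1 - exp(-delta * T))
  } else {
    (sigma / abs(delta)) * (exp(abs(delta) * T) - 1)
  }
}

#' Total cumulative sensory load
#'
#' `P_total = sum_s P(s)`, with each stimulus's net rate computed from its own
#' (lagged) arousal via [habituation_rate()].
#'
#' @param stimuli list of exposures, each a list with `params`
#'   ([sensory_stimulus_params()]), exposure duration `T` (>= 0) and arousal
#'   `Xi` (>= 0; the engine supplies the previous-step value).
#' @return total load `P_total`.
#' @export
total_sensory_load <- function(stimuli) {
  if (length(stimuli) == 0L) return(0)
  sum(vapply(stimuli, function(s) {
    delta <- habituation_rate(s$params, s$Xi)
    cumulative_impact(s$params$sigma, delta, s$T)
  }, numeric(1)))
}
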