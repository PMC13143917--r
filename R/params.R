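#' Social-reciprocity submodel parameters
#'
#' Reciprocity is modelled as an exponentially depleting resource,
#' `R(t) = alpha * R0 * exp(-integral of beta_eff)`, where the effective
#' depletion rate `beta_eff` rises with executive, sensory and predictive load
#' and falls with motivation, predictability and interest alignment.
#'
#' @param R0 initial reciprocity at interaction onset (0-1).
#' @param alpha baseline social capacity coefficient (> 0); `alpha * R0` must
#'   lie in `[0, 1]`.
#' @param beta_base baseline depletion rate, per hour (>= 0).
#' @param k_E,k_Lambda,k_P sensitivities to executive, sensory and predictive
#'   load (>= 0, dimensionless).
#' @param k_M,k_Pr,k_I sensitivities to the protective terms: social
#'   motivation, environmental predictability, interest alignment (>= 0).
#' @param M_social,Pr_env,I_align static protective levels (>= 0).
#' @return object of class `reciprocity_params`.
#' @export
reciprocity_params <- function(R0 = 0.85, alpha = 1, beta_base = 0.3,
                               k_E = 1, k_Lambda = 1, k_P = 1,
                               k_M = 1, k_Pr = 1, k_I = 1,
                               M_social = 0.6, Pr_env = 0, I_align = 0.3) {
  p <- structure(as.list(environment()), class = "reciprocity_params")
  .stop_on_violations(.check_reciprocity(p))
  p
}

.check_reciprocity <- function(p) {
  v <- character(0)
  sens <- c(p$k_E, p$k_Lambda, p$k_P, p$k_M, p$k_Pr, p$k_I)
  if (any(sens < 0)) v <- c(v, "reciprocity: all sensitivity coefficients must be >= 0")
  if (p$beta_base < 0) v <- c(v, "reciprocity: beta_base must be >= 0")
  if (p$alpha * p$R0 < 0 || p$alpha * p$R0 > 1)
    v <- c(v, "reciprocity: alpha * R0 must lie in [0, 1]")
  if (any(c(p$M_social, p$Pr_env, p$I_align) < 0))
    v <- c(v, "reciprocity: protective levels must be >= 0")
  v
}

#' Nonverbal communication channel
#'
#' One channel of the weighted-summation effectiveness model
#' `N = sum(w_norm * eta * x)`. Six named channels (gaze, facial expression,
#' gesture, posture, paralinguistics, proxemics) form the default registry but
#' arbitrary channel lists are allowed.
#'
#' @param name channel label.
#' @param w_norm normative importance weight (>= 0).
#' @param eta individual processing efficiency in `[0, 1]`.
#' @param x cue frequency/appropriateness score in `[0, 1]`.
#' @return object of class `nonverbal_channel`.
#' @export
nonverbal_channel <- function(name, w_norm, eta, x) {
  p <- structure(list(name = name, w_norm = w_norm, eta = eta, x = x),
                 class = "nonverbal_channel")
  .stop_on_violations(.check_channel(p))
  p
}

.check_channel <- function(p) {
  v <- character(0)
  if (p$eta < 0 || p$eta > 1)
    v <- c(v, sprintf("channel '%s': eta must lie in [0, 1]", p$name))
  if (p$w_norm < 0)
    v <- c(v, sprintf("channel '%s': w_norm must be >= 0", p$name))
  v
}

#' Default six-channel nonverbal registry
#'
#' @param eta efficiencies, recycled over the six channels.
#' @param x cue scores, recycled over the six channels.
#' @param w_norm normative weights, recycled.
#' @return list of [nonverbal_channel()] objects.
#' @export
default_channels <- function(eta = 1, x = 1, w_norm = 1 / 6) {
  names6 <- c("gaze", "facial_expression", "gesture", "posture",
              "paralinguistics", "proxemics")
  eta <- rep_len(eta, 6L); x <- rep_len(x, 6L); w_norm <- rep_len(w_norm, 6L)
  Map(nonverbal_channel, names6, w_norm, eta, x)
}

#' Relationship-development submodel parameters
#'
#' Each relationship follows a sigmoid growth curve with asymptote
#' `a = a_max * (M_soc / M_norm)` and growth rate
#' `k = k_base * (R_sal / R_norm) * (1 - P_var)`.
#'
#' @param a_max potential maximum depth (> 0).
#' @param M_soc,M_norm individual and normative social motivation (> 0).
#' @param k_base baseline growth rate, per month (> 0).
#' @param R_sal,R_norm reward salience and its norm (> 0).
#' @param P_var prediction-error variance in `[0, 1]`.
#' @param t_infl inflection time, months.
#' @return object of class `relationship_params`.
#' @export
relationship_params <- function(a_max = 1, M_soc = 1, M_norm = 1,
                                k_base = 0.5, R_sal = 1, R_norm = 1,
                                P_var = 0, t_infl = 12) {
  p <- structure(as.list(environment()), class = "relationship_params")
  .stop_on_violations(.check_relationship(p))
  p
}

.check_relationship <- function(p) {
  v <- character(0)
  if (p$P_var < 0 || p$P_var > 1) v <- c(v, "relationship: P_var must lie in [0, 1]")
  if (p$M_norm <= 0 || p$R_norm <= 0)
    v <- c(v, "relationship: norms M_norm and R_norm must be strictly positive")
  if (p$a_max <= 0) v <- c(v, "relationship: a_max must be > 0")
  if (p$k_base <= 0) v <- c(v, "relationship: k_base must be > 0")
  if (p$M_soc <= 0 || p$R_sal <= 0)
    v <- c(v, "relationship: M_soc and R_sal must be > 0")
  v
}

#' Stereotyped-movement submodel parameters
#'
#' Movement intensity is `M(t) = M0 + Gamma_eff * sin(omega * t + phi)` with
#' amplitude driven by environmental entropy through a saturating
#' (Michaelis-Menten) term and divided down by engagement and the availability
#' of alternative regulatory behaviours.
#'
#' @param M0 baseline motor activity (>= 0).
#' @param Gamma_max maximum oscillation amplitude (>= 0).
#' @param omega angular frequency, radians per hour.
#' @param phi phase shift, radians.
#' @param k_H entropy half-saturation constant, bits (> 0).
#' @param k_engage sensitivity to engagement (>= 0).
#' @param k_alt sensitivity to alternative regulatory behaviours (>= 0).
#' @return object of class `movement_params`.
#' @export
movement_params <- function(M0 = 0.3, Gamma_max = 1, omega = 2 * pi,
                            phi = 0, k_H = 2, k_engage = 1, k_alt = 1) {
  p <- structure(as.list(environment()), class = "movement_params")
  .stop_on_violations(.check_movement(p))
  p
}

.check_movement <- function(p) {
  v <- character(0)
  if (p$k_H <= 0) v <- c(v, "movement: entropy half-saturation k_H must be positive")
  if (p$Gamma_max < 0) v <- c(v, "movement: Gamma_max must be >= 0")
  if (p$M0 < 0) v <- c(v, "movement: M0 must be >= 0")
  if (p$k_engage < 0 || p$k_alt < 0)
    v <- c(v, "movement: k_engage and k_alt must be >= 0")
  v
}

#' Routine (insistence-on-sameness) parameters
#'
#' Distress at a deviation `|x - x_expected|` from the routine's expected state
#' follows a precision-weighted sigmoid with steepness
#' `r = r_base * pi_precision` and midpoint at the tolerance threshold `theta`.
#'
#' @param label routine identifier.
#' @param s_max maximum distress (>= 0).
#' @param r_base baseline steepness, per deviation unit (> 0).
#' @param pi_precision Bayesian precision weight (>= 0).
#' @param theta tolerance threshold, deviation units (>= 0).
#' @param x_expected expected state, deviation units.
#' @return object of class `routine_params`.
#' @export
routine_params <- function(label = "routine", s_max = 0.9, r_base = 2,
                           pi_precision = 1, theta = 0.3, x_expected = 0) {
  p <- structure(as.list(environment()), class = "routine_params")
  .stop_on_violations(.check_routine(p))
  p
}

.check_routine <- function(p) {
  v <- character(0)
  if (p$s_max < 0) v <- c(v, sprintf("routine '%s': s_max must be >= 0", p$label))
  if (p$r_base <= 0) v <- c(v, sprintf("routine '%s': r_base must be > 0", p$label))
  if (p$theta < 0) v <- c(v, sprintf("routine '%s': theta must be >= 0", p$label))
  if (p$pi_precision < 0)
    v <- c(v, sprintf("routine '%s': pi_precision must be >= 0", p$label))
  v
}

#' Restricted-interest submodel parameters
#'
#' Engagement is `I(t) = I0 + sum_l b_l * exp(-lambda_l * dt_l)` where each
#' interest decays from its own acquisition time with
#' `b = b_base * (R_int / R_norm)` and `lambda = lambda_base * (1 - P_acc)`.
#'
#' @param I0 persistent engagement floor (>= 0).
#' @param interests list of interests, each a list with fields `b_base`
#'   (>= 0), `R_int` (> 0), `R_norm` (> 0), `lambda_base` (per month, >= 0),
#'   `P_acc` (0-1) and `t_acquired` (months).
#' @return object of class `interest_params`.
#' @export
interest_params <- function(I0 = 0.2,
                            interests = list(list(b_base = 0.8, R_int = 1,
                                                  R_norm = 1, lambda_base = 0.1,
                                                  P_acc = 0.8, t_acquired = 0))) {
  p <- structure(list(I0 = I0, interests = interests), class = "interest_params")
  .stop_on_violations(.check_interest(p))
  p
}

.check_interest <- function(p) {
  v <- character(0)
  if (p$I0 < 0) v <- c(v, "interest: I0 must be >= 0")
  for (i in seq_along(p$interests)) {
    it <- p$interests[[i]]
    need <- c("b_base", "R_int", "R_norm", "lambda_base", "P_acc", "t_acquired")
    if (!all(need %in% names(it))) {
      v <- c(v, sprintf("interest %d: missing fields", i)); next
    }
    if (it$P_acc < 0 || it$P_acc > 1)
      v <- c(v, sprintf("interest %d: P_acc must lie in [0, 1]", i))
    if (it$lambda_base < 0 || it$b_base < 0)
      v <- c(v, sprintf("interest %d: rates and intensities must be >= 0", i))
    if (it$R_norm <= 0 || it$R_int <= 0)
      v <- c(v, sprintf("interest %d: reward values must be > 0", i))
  }
  v
}

#' Sensory-stimulus parameters
#'
#' Cumulative impact of a stimulus over an exposure of length `T` is
#' `P(s) = integral_0^T sigma * exp(-delta * t) dt`, where the net
#' habituation rate `delta = delta_base * gaba_ratio - k_sens * Xi` can turn
#' negative (sensitisation) under high arousal `Xi`.
#'
#' @param label stimulus identifier.
#' @param sigma sensitivity intensity, index per hour (>= 0).
#' @param delta_base baseline habituation rate, per hour.
#' @param gaba_ratio GABAergic function relative to norm (>= 0).
#' @param k_sens sensitisation coefficient linking arousal to habituation
#'   impairment (>= 0).
#' @return object of class `sensory_stimulus_params`.
#' @export
sensory_stimulus_params <- function(label = "stimulus", sigma = 0.8,
                                    delta_base = 0, gaba_ratio = 1,
                                    k_sens = 0) {
  p <- structure(as.list(environment()), class = "sensory_stimulus_params")
  .stop_on_violations(.check_stimulus(p))
  p
}

.check_stimulus <- function(p) {
  v <- character(0)
  if (p$sigma < 0) v <- c(v, sprintf("stimulus '%s': sigma must be >= 0", p$label))
  if (p$gaba_ratio < 0)
    v <- c(v, sprintf("stimulus '%s': gaba_ratio must be >= 0", p$label))
  if (p$k_sens < 0) v <- c(v, sprintf("stimulus '%s': k_sens must be >= 0", p$label))
  v
}

#' Composite-index weights and normalisation bounds
#'
#' Seven nonnegative weights, one per normalised component
#' (`R`, `N`, `C`, `M`, `S`, `I`, `P_total`), summing to one. The first three
#' weights correspond to the social-communication domain coefficients
#' (alpha_1..alpha_3) and the last four to the restricted-repetitive domain
#' coefficients (beta_1..beta_4) of the two-domain formulation.
#'
#' @param w numeric vector of seven weights; renormalised to sum to one with a
#'   message if the supplied sum differs from 1 by more than 1e-12.
#' @param bounds named list of `c(min, max)` normalisation bounds per
#'   component; `NULL` entries are filled by the engine at run time.
#' @param orientation named logical vector; `TRUE` means the component is
#'   reflected (`z <- 1 - z`) before weighting, so that larger normalised
#'   values always mean greater symptom expression. Defaults to reflecting
#'   `R`, `N`, `C` (where higher raw values indicate better functioning).
#' @return object of class `composite_weights`.
#' @export
composite_weights <- function(w = rep(1 / 7, 7), bounds = NULL,
                              orientation = NULL) {
  comp <- .composite_components
  if (length(w) != 7L) stop("composite_weights: exactly seven weights required")
  if (any(w < 0)) stop("composite_weights: weights must be >= 0")
  if (all(w == 0)) stop("composite_weights: at least one weight must be positive")
  if (abs(sum(w) - 1) > 1e-12) {
    message(sprintf("composite_weights: renormalising weights (sum was %.6g)", sum(w)))
    w <- w / sum(w)
  }
  names(w) <- comp
  if (is.null(orientation)) {
    orientation <- stats::setNames(comp %in% c("R", "N", "C"), comp)
  } else {
    orientation <- orientation[comp]
    names(orientation) <- comp
  }
  if (!is.null(bounds)) {
    for (nm in names(bounds)) {
      b <- bounds[[nm]]
      if (!is.null(b) && b[2] <= b[1])
        stop(sprintf("composite_weights: bound max must exceed min for '%s'", nm))
    }
  }
  structure(list(w = w, bounds = bounds, orientation = orientation),
            class = "composite_weights")
}

.composite_components <- c("R", "N", "C", "M", "S", "I", "P_total")

#' Map two-domain coefficients to unified composite weights
#'
#' Convenience wrapper for the two-domain naming of the weights: `alpha[1:3]`
#' weight the social-communication components (`R`, `N`, `C`) and `beta[1:4]`
#' weight the restricted-repetitive components (`M`, `S`, `I`, `P_total`).
#'
#' @param alpha numeric(3) social-communication weights.
#' @param beta numeric(4) restricted-repetitive weights.
#' @param ... passed to [composite_weights()].
#' @return object of class `composite_weights`.
#' @export
domain_weights <- function(alpha, beta, ...) {
  stopifnot(length(alpha) == 3L, length(beta) == 4L)
  composite_weights(w = c(alpha, beta), ...)
}

#' Assemble a full individual profile
#'
#' Bundles the per-person parameter sets of all seven submodels together with
#' the composite weights and the engine-level person parameters (arousal
#' recursion coefficients, sensory coupling capacity, regulatory threshold).
#'
#' @param reciprocity [reciprocity_params()].
#' @param channels list of [nonverbal_channel()] objects.
#' @param relationships list of [relationship_params()] objects.
#' @param movement [movement_params()].
#' @param routines named list of [routine_params()] objects.
#' @param interests [interest_params()].
#' @param stimuli named list of [sensory_stimulus_params()] objects.
#' @param weights [composite_weights()].
#' @param arousal numeric(3) coefficients `(a, b, c)` of the arousal recursion
#'   `Xi[n+1] = max(0, a * Xi[n] + b * Lambda_s[n] + c * S[n])`.
#' @param capacity sensory-coupling capacity (> 0): the cumulative load at
#'   which the instantaneous load `Lambda_s = P_total / (P_total + capacity)`
#'   reaches one half.
#' @param threshold regulatory threshold on `P_total`; a withdrawal event fires
#'   at the first reporting-grid time where `P_total` exceeds it (`Inf`
#'   disables).
#' @return object of class `individual_profile`.
#' @export
individual_profile <- function(reciprocity = reciprocity_params(),
                               channels = default_channels(),
                               relationships = list(relationship_params()),
                               movement = movement_params(),
                               routines = list(routine = routine_params()),
                               interests = interest_params(),
                               stimuli = list(stimulus = sensory_stimulus_params()),
                               weights = composite_weights(),
                               arousal = c(a = 0.8, b = 0.5, c = 0.5),
                               capacity = 50,
                               threshold = Inf) {
  if (is.null(names(routines)) || any(!nzchar(names(routines))))
    names(routines) <- vapply(routines, `[[`, "", "label")
  if (is.null(names(stimuli)) || any(!nzchar(names(stimuli))))
    names(stimuli) <- vapply(stimuli, `[[`, "", "label")
  structure(list(reciprocity = reciprocity, channels = channels,
                 relationships = relationships, movement = movement,
                 routines = routines, interests = interests,
                 stimuli = stimuli, weights = weights,
                 arousal = arousal, capacity = capacity,
                 threshold = threshold),
            class = "individual_profile")
}

#' Validate an individual profile
#'
#' Checks every submodel's parameter invariants plus the engine-level
#' constraints and returns the violations as a character vector (empty when the
#' profile is valid). Validation never raises; it is idempotent and
#' side-effect free.
#'
#' @param profile an [individual_profile()].
#' @return character vector of violation messages (empty iff valid).
#' @export
validate_profile <- function(profile) {
  v <- character(0)
  v <- c(v, .check_reciprocity(profile$reciprocity))
  for (ch in profile$channels) v <- c(v, .check_channel(ch))
  for (rl in profile$relationships) v <- c(v, .check_relationship(rl))
  v <- c(v, .check_movement(profile$movement))
  for (r in profile$routines) v <- c(v, .check_routine(r))
  v <- c(v, .check_interest(profile$interests))
  for (s in profile$stimuli) v <- c(v, .check_stimulus(s))
  w <- profile$weights
  if (any(w$w < 0)) v <- c(v, "composite: weights must be >= 0")
  if (abs(sum(w$w) - 1) > 1e-12)
    v <- c(v, "composite: weight normalisation violated (weights must sum to 1)")
  if (!is.null(w$bounds)) {
    for (nm in names(w$bounds)) {
      b <- w$bounds[[nm]]
      if (!is.null(b) && b[2] <= b[1])
        v <- c(v, sprintf("composite: bound max must exceed min for '%s'", nm))
    }
  }
  if (profile$capacity <= 0) v <- c(v, "engine: coupling capacity must be > 0")
  if (length(profile$arousal) != 3L || any(!is.finite(profile$arousal)))
    v <- c(v, "engine: arousal recursion needs three finite coefficients")
  v
}

.stop_on_violations <- function(v) {
  if (length(v)) stop(paste(v, collapse = "; "), call. = FALSE)
  invisible(NULL)
}

#' @export
print.individual_profile <- function(x, ...) {
  cat("Individual profile\n")
  cat(sprintf("  reciprocity: R0=%.3g alpha=%.3g beta_base=%.3g /hour\n",
              x$reciprocity$R0, x$reciprocity$alpha, x$reciprocity$beta_base))
  cat(sprintf("  channels: %d; relationships: %d; routines: %d; interests: %d; stimuli: %d\n",
              length(x$channels), length(x$relationships), length(x$routines),
              length(x$interests$interests), length(x$stimuli)))
  cat(sprintf("  coupling capacity: %.3g; regulatory threshold: %.3g\n",
              x$capacity, x$threshold))
  viol <- validate_profile(x)
  if (length(viol)) cat("  INVALID:", paste(viol, collapse = "; "), "\n")
  else cat("  valid\n")
  invisible(x)
}
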