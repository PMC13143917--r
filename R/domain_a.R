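#' Social context signal
#'
#' Time-indexed exogenous loads entering the effective depletion rate:
#' executive load, instantaneous sensory load and predictive-processing load.
#'
#' @param time strictly increasing time grid (hours).
#' @param E_exec executive load (>= 0), recycled over the grid.
#' @param Lambda_s instantaneous sensory load (>= 0), recycled.
#' @param Pi_load predictive-processing load (>= 0), recycled.
#' @return data.frame of class `social_context_signal`.
#' @export
social_context_signal <- function(time, E_exec = 0, Lambda_s = 0, Pi_load = 0) {
  if (length(time) == 0L) stop("social_context_signal: empty time grid")
  if (any(diff(time) <= 0)) stop("social_context_signal: grid must be strictly increasing")
  x <- data.frame(time = time,
                  E_exec = rep_len(E_exec, length(time)),
                  Lambda_s = rep_len(Lambda_s, length(time)),
                  Pi_load = rep_len(Pi_load, length(time)))
  if (any(x$E_exec < 0) || any(x$Lambda_s < 0) || any(x$Pi_load < 0))
    stop("social_context_signal: loads must be nonnegative")
  class(x) <- c("social_context_signal", "data.frame")
  x
}

#' Effective social-reciprocity depletion rate
#'
#' `beta_eff = beta_base * (1 + k_E*E + k_Lambda*Lambda + k_P*Pi) /
#'             (1 + k_M*M_social + k_Pr*Pr_env + k_I*I_align)`.
#' Loads accelerate depletion (numerator); motivation, predictability and
#' interest alignment protect (denominator). Vectorised over the loads.
#'
#' @param p [reciprocity_params()].
#' @param E_exec executive load (>= 0).
#' @param Lambda_s instantaneous sensory load (>= 0).
#' @param Pi_load predictive-processing load (>= 0).
#' @param I_align optional override of the profile's static interest-alignment
#'   level (used by the engine when alignment switches mid-scenario).
#' @return depletion rate, per hour.
#' @examples
#' p <- reciprocity_params(beta_base = 0.3, M_social = 0.6, I_align = 0.3)
#' effective_depletion_rate(p, E_exec = 0.4, Lambda_s = 0.2, Pi_load = 0.5)
#' @export
effective_depletion_rate <- function(p, E_exec = 0, Lambda_s = 0, Pi_load = 0,
                                     I_align = NULL) {
  if (any(E_exec < 0) || any(Lambda_s < 0) || any(Pi_load < 0))
    stop("effective_depletion_rate: loads must be nonnegative")
  if (is.null(I_align)) I_align <- p$I_align
  num <- 1 + p$k_E * E_exec + p$k_Lambda * Lambda_s + p$k_P * Pi_load
  den <- 1 + p$k_M * p$M_social + p$k_Pr * p$Pr_env + p$k_I * I_align
  p$beta_base * num / den
}

#' Social reciprocity trajectory
#'
#' `R(t) = alpha * R0 * exp(-H(t))` with the integrated hazard
#' `H(t) = integral_0^t beta_eff(tau) dtau` accumulated by the trapezoid rule
#' over the context grid. With constant loads this reproduces the closed form
#' `alpha * R0 * exp(-beta_eff * t)` exactly.
#'
#' @param p [reciprocity_params()].
#' @param context a [social_context_signal()] whose grid starts at the
#'   interaction onset.
#' @return data.frame `(time, beta_eff, R)`.
#' @export
reciprocity_trajectory <- function(p, context) {
  if (nrow(context) == 0L) stop("reciprocity_trajectory: empty grid")
  t <- context$time - context$time[1]
  beta <- effective_depletion_rate(p, context$E_exec, context$Lambda_s,
                                   context$Pi_load)
  n <- length(t)
  hazard <- c(0, cumsum((beta[-n] + beta[-1]) / 2 * diff(t)))
  data.frame(time = context$time, beta_eff = beta,
             R = p$alpha * p$R0 * exp(-hazard))
}

#' Nonverbal communication effectiveness
#'
#' Weighted summation across channels: `N = sum_i w_norm_i * eta_i * x_i`.
#' Linear in each cue score; a channel with zero processing efficiency
#' contributes nothing.
#'
#' @param channels non-empty list of [nonverbal_channel()] objects.
#' @return effectiveness `N` (dimensionless).
#' @export
nonverbal_effectiveness <- function(channels) {
  if (length(channels) == 0L) stop("nonverbal_effectiveness: empty channel list")
  sum(vapply(channels, function(ch) ch$w_norm * ch$eta * ch$x, numeric(1)))
}

#' Cumulative relationship quality
#'
#' `C(t) = sum_j a_j / (1 + exp(-k_j * (t - t_infl_j)))` with
#' `a_j = a_max * (M_soc / M_norm)` and
#' `k_j = k_base * (R_sal / R_norm) * (1 - P_var)`. A degenerate growth rate
#' `k_j = 0` (e.g. `P_var = 1`) yields the analytic limit `a_j / 2` at all
#' times. Non-decreasing in `t`, additive over relationships.
#'
#' @param relationships list of [relationship_params()] objects.
#' @param t evaluation time(s), months.
#' @return list with `C` (numeric, per time) and `components` (matrix,
#'   times x relationships).
#' @export
relationship_quality <- function(relationships, t) {
  if (any(!is.finite(t))) stop("relationship_quality: t must be finite")
  comp <- vapply(relationships, function(p) {
    a <- p$a_max * (p$M_soc / p$M_norm)
    k <- p$k_base * (p$R_sal / p$R_norm) * (1 - p$P_var)
    a / (1 + exp(-k * (t - p$t_infl)))
  }, numeric(length(t)))
  comp <- matrix(comp, nrow = length(t))
  list(C = rowSums(comp), components = comp)
}
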