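#' Sensory-to-social coupling map
#'
#' Maps cumulative sensory load onto the instantaneous sensory load entering
#' the depletion rate: `Lambda_s = P_total / (P_total + capacity)`, a
#' saturating, dimensionless load in `[0, 1)` that is half-maximal when the
#' cumulative load equals the capacity.
#'
#' @param P_total cumulative sensory load (>= 0); vectorised.
#' @param capacity load scale (> 0).
#' @return instantaneous load in `[0, 1)`.
#' @export
coupling_map <- function(P_total, capacity) {
  if (capacity <= 0) stop("coupling_map: capacity must be positive")
  P_total / (P_total + capacity)
}

#' Engine dependency graph
#'
#' The within-step dependency structure of the coupled update. Arousal enters
#' the habituation rate only through its previous-step value (a lagged edge),
#' which is what keeps the within-step graph acyclic; the composite index is a
#' terminal summary node that feeds nothing back.
#'
#' @return data.frame `(from, to, lagged)`.
#' @export
engine_dependency_graph <- function() {
  e <- rbind(
    c("Xi",        "delta_s",  TRUE),   # one-step arousal lag
    c("delta_s",   "P_total",  FALSE),
    c("exposures", "P_total",  FALSE),
    c("P_total",   "Lambda_s", FALSE),
    c("Lambda_s",  "beta_eff", FALSE),
    c("beta_eff",  "R",        FALSE),
    c("H_env",     "Gamma_eff", FALSE),
    c("Gamma_eff", "M",        FALSE),
    c("events",    "S",        FALSE),
    c("Lambda_s",  "Xi",       FALSE),
    c("S",         "Xi",       FALSE),
    c("R",         "A",        FALSE),
    c("N",         "A",        FALSE),
    c("C",         "A",        FALSE),
    c("M",         "A",        FALSE),
    c("S",         "A",        FALSE),
    c("I",         "A",        FALSE),
    c("P_total",   "A",        FALSE)
  )
  data.frame(from = e[, 1], to = e[, 2], lagged = as.logical(e[, 3]),
             stringsAsFactors = FALSE)
}

# Kahn topological sort over the non-lagged edges; NULL if a cycle exists
.topological_order <- function(graph) {
  g <- graph[!graph$lagged, , drop = FALSE]
  nodes <- unique(c(g$from, g$to, graph$from, graph$to))
  order <- character(0)
  indeg <- vapply(nodes, function(n) sum(g$to == n), integer(1))
  queue <- nodes[indeg == 0]
  while (length(queue)) {
    n <- queue[1]; queue <- queue[-1]
    order <- c(order, n)
    out <- g$to[g$from == n]
    g <- g[g$from != n, , drop = FALSE]
    for (m in out) if (!sum(g$to == m)) queue <- c(queue, m)
  }
  if (nrow(g)) NULL else order
}

#' Define a simulation scenario
#'
#' A scenario couples an [individual_profile()] to an environment: an entropy
#' track, a stimulus exposure schedule, routine-deviation events, static
#' context loads, and optional mid-scenario switches of the interest-alignment
#' protective term. Profile rates (`beta_base`, `omega`, relationship and
#' interest rates) are canonical (per hour / per month) and converted to the
#' scenario time unit by the engine; stimulus `sigma` and `delta` are
#' interpreted in scenario time units.
#'
#' @param profile an [individual_profile()].
#' @param horizon scenario length, in `time_unit`.
#' @param dt fast-tier step (> 0), in `time_unit`.
#' @param report_dt reporting grid spacing (> 0), in `time_unit`; withdrawal is
#'   detected on this grid.
#' @param time_unit `"minutes"` or `"hours"`.
#' @param env data.frame `(time, H_env)` defining a piecewise-linear entropy
#'   track (times in `time_unit`).
#' @param exposures list of stimulus exposures, each `list(label, start, end)`
#'   referencing a stimulus declared in the profile.
#' @param events list of routine-deviation events, each
#'   `list(time, routine, magnitude, duration = Inf)` referencing a declared
#'   routine; the deviation persists for `duration` time units.
#' @param context list of static loads: `E_exec`, `Pi_load` (reciprocity) and
#'   `E_engage`, `Phi_alt` (movement).
#' @param switches optional list with an `I_align` data.frame `(time, value)`
#'   of interest-alignment changes.
#' @param age_months age at which the slow-tier submodels (relationships,
#'   interests) are evaluated; quasi-static over a fast-tier scenario.
#' @param clearance_rate optional first-order post-exposure decay rate of the
#'   accumulated load (per `time_unit`); 0 keeps accumulation monotone.
#' @param clamp_M clip negative movement intensity to zero?
#' @return object of class `asdyn_scenario`.
#' @export
scenario <- function(profile, horizon, dt = 1, report_dt = 15,
                     time_unit = c("minutes", "hours"),
                     env = data.frame(time = c(0, horizon), H_env = 0),
                     exposures = list(), events = list(),
                     context = list(E_exec = 0, Pi_load = 0,
                                    E_engage = 0, Phi_alt = 0),
                     switches = list(), age_months = 300,
                     clearance_rate = 0, clamp_M = FALSE) {
  time_unit <- match.arg(time_unit)
  if (dt <= 0 || report_dt <= 0) stop("scenario: steps must be positive")
  if (horizon <= 0) stop("scenario: horizon must be positive")
  for (ev in events) {
    if (ev$time < 0 || ev$time > horizon)
      stop("scenario: event at time ", ev$time, " outside horizon")
    if (!ev$routine %in% names(profile$routines))
      stop("scenario: event references undeclared routine '", ev$routine, "'")
  }
  for (ex in exposures) {
    if (!ex$label %in% names(profile$stimuli))
      stop("scenario: exposure references undeclared stimulus '", ex$label, "'")
    if (ex$start < 0 || ex$end > horizon || ex$end <= ex$start)
      stop("scenario: exposure window for '", ex$label, "' outside horizon")
  }
  ctx <- utils::modifyList(list(E_exec = 0, Pi_load = 0, E_engage = 0,
                                Phi_alt = 0), context)
  structure(list(profile = profile, horizon = horizon, dt = dt,
                 report_dt = report_dt, time_unit = time_unit, env = env,
                 exposures = exposures, events = events, context = ctx,
                 switches = switches, age_months = age_months,
                 clearance_rate = clearance_rate, clamp_M = clamp_M),
            class = "asdyn_scenario")
}

# default normalisation bounds from theoretical ranges of the profile; the
# P_total ceiling uses the habituation-failure (linear) reference load
.default_bounds <- function(profile, sc) {
  C_max <- sum(vapply(profile$relationships,
                      function(p) p$a_max * p$M_soc / p$M_norm, numeric(1)))
  N_max <- sum(vapply(profile$channels, `[[`, numeric(1), "w_norm"))
  I_max <- profile$interests$I0 +
    sum(vapply(profile$interests$interests,
               function(it) it$b_base * it$R_int / it$R_norm, numeric(1)))
  S_max <- sum(vapply(profile$routines, `[[`, numeric(1), "s_max"))
  M_max <- profile$movement$M0 + profile$movement$Gamma_max
  P_max <- sum(vapply(sc$exposures, function(ex) {
    profile$stimuli[[ex$label]]$sigma * (ex$end - ex$start)
  }, numeric(1)))
  pos <- function(x) if (is.finite(x) && x > 0) x else 1
  list(R = c(0, 1), N = c(0, pos(N_max)), C = c(0, pos(C_max)),
       M = c(0, pos(M_max)), S = c(0, pos(S_max)), I = c(0, pos(I_max)),
       P_total = c(0, pos(P_max)))
}

#' Run a scenario through the hierarchical coupling engine
#'
#' Per fast step, in dependency order: (1) the cumulative sensory load is
#' advanced over each active exposure with the net habituation rate computed
#' from the previous step's arousal (the one-step lag that keeps the update
#' acyclic); (2) the cumulative load is mapped to an instantaneous sensory
#' load by [coupling_map()]; (3) the depletion rate and the reciprocity level
#' are advanced by integrated hazard (trapezoid); (4) stereotypy amplitude and
#' intensity are evaluated from the current entropy; (5) sameness distress is
#' evaluated over the active routine deviations; (6) arousal is updated for
#' the next step. The slow-tier submodels (relationships, interests) are
#' quasi-static over a fast-tier scenario and evaluated at the scenario age.
#' The composite index is computed last and never fed back. A withdrawal event
#' fires at the first reporting-grid time where the cumulative load exceeds
#' the profile's regulatory threshold.
#'
#' @param sc an [scenario()].
#' @param seed integer seed (recorded; the default engine path is
#'   deterministic, but the seed governs any stochastic extension and makes
#'   run provenance explicit).
#' @return object of class `trajectory_bundle`: list with `series` (data.frame
#'   of all state variables on the fast grid), `events` (data.frame
#'   `time, type, cause`), and `metadata`.
#' @export
run_scenario <- function(sc, seed) {
  if (missing(seed)) stop("run_scenario: an explicit seed is required")
  stopifnot(inherits(sc, "asdyn_scenario"))
  viol <- validate_profile(sc$profile)
  if (length(viol)) stop("run_scenario: invalid profile: ",
                         paste(viol, collapse = "; "))
  if (is.null(.topological_order(engine_dependency_graph())))
    stop("run_scenario: engine dependency graph is cyclic")
  set.seed(seed)
  pr <- sc$profile
  u_hours <- if (sc$time_unit == "minutes") 1 / 60 else 1

  times <- seq(0, sc$horizon, by = sc$dt)
  n <- length(times)
  H <- stats::approx(sc$env$time, sc$env$H_env, xout = times, rule = 2)$y

  # interest-alignment schedule (step function over the switch list)
  I_align <- rep(pr$reciprocity$I_align, n)
  ev_log <- list()
  if (!is.null(sc$switches$I_align)) {
    sw <- sc$switches$I_align
    for (i in seq_len(nrow(sw))) {
      I_align[times >= sw$time[i]] <- sw$value[i]
      ev_log[[length(ev_log) + 1L]] <-
        data.frame(time = sw$time[i], type = "interest_alignment",
                   cause = sprintf("I_align set to %.3g", sw$value[i]))
    }
  }

  # active routine deviation magnitude per routine and step
  routines <- pr$routines
  dev_mag <- matrix(0, n, length(routines),
                    dimnames = list(NULL, names(routines)))
  for (ev in sc$events) {
    dur <- if (is.null(ev$duration)) Inf else ev$duration
    rows <- times >= ev$time & times < ev$time + dur
    dev_mag[rows, ev$routine] <- pmax(dev_mag[rows, ev$routine], ev$magnitude)
    ev_log[[length(ev_log) + 1L]] <-
      data.frame(time = ev$time, type = "routine_deviation",
                 cause = sprintf("routine '%s' deviation %.3g", ev$routine,
                                 ev$magnitude))
  }
  S_of <- function(i) {
    sum(vapply(seq_along(routines), function(k) {
      r <- routines[[k]]
      deviation_distress(r, r$x_expected + dev_mag[i, k])
    }, numeric(1)))
  }

  # state arrays
  P_total <- Lambda_s <- beta_eff <- R <- Gamma_eff <- M <- S <- Xi <-
    numeric(n)
  exposure_tau <- stats::setNames(numeric(length(sc$exposures)),
                                  vapply(sc$exposures, `[[`, "", "label"))
  ar <- pr$arousal

  S[1] <- S_of(1)
  Lambda_s[1] <- coupling_map(0, pr$capacity)
  beta_eff[1] <- effective_depletion_rate(pr$reciprocity, sc$context$E_exec,
                                          Lambda_s[1], sc$context$Pi_load,
                                          I_align = I_align[1])
  R[1] <- pr$reciprocity$alpha * pr$reciprocity$R0
  Gamma_eff[1] <- effective_amplitude(pr$movement, H[1], sc$context$E_engage,
                                      sc$context$Phi_alt)
  M[1] <- pr$movement$M0 +
    Gamma_eff[1] * sin(pr$movement$omega * times[1] * u_hours + pr$movement$phi)
  Xi[1] <- max(0, ar[2] * Lambda_s[1] + ar[3] * S[1])
  hazard <- 0

  for (i in 2:n) {
    # (1) cumulative sensory load, lagged arousal in the habituation rate
    P_step <- if (sc$clearance_rate > 0)
      P_total[i - 1] * exp(-sc$clearance_rate * sc$dt) else P_total[i - 1]
    for (j in seq_along(sc$exposures)) {
      ex <- sc$exposures[[j]]
      a <- max(ex$start, times[i - 1]); b <- min(ex$end, times[i])
      if (b > a) {
        stim <- pr$stimuli[[ex$label]]
        delta <- habituation_rate(stim, Xi[i - 1])
        dP <- cumulative_impact(stim$sigma, delta, exposure_tau[j] + (b - a)) -
          cumulative_impact(stim$sigma, delta, exposure_tau[j])
        exposure_tau[j] <- exposure_tau[j] + (b - a)
        P_step <- P_step + dP
      }
    }
    P_total[i] <- P_step
    if (!is.finite(P_total[i]))
      stop("run_scenario: non-finite cumulative load at step ", i,
           " (t = ", times[i], ")")
    # (2) coupling to instantaneous sensory load
    Lambda_s[i] <- coupling_map(P_total[i], pr$capacity)
    # (3) depletion rate and reciprocity via integrated hazard
    beta_eff[i] <- effective_depletion_rate(pr$reciprocity, sc$context$E_exec,
                                            Lambda_s[i], sc$context$Pi_load,
                                            I_align = I_align[i])
    hazard <- hazard + (beta_eff[i - 1] + beta_eff[i]) / 2 * sc$dt * u_hours
    R[i] <- pr$reciprocity$alpha * pr$reciprocity$R0 * exp(-hazard)
    # (4) stereotypy amplitude and intensity from current entropy
    Gamma_eff[i] <- effective_amplitude(pr$movement, H[i], sc$context$E_engage,
                                        sc$context$Phi_alt)
    M[i] <- pr$movement$M0 +
      Gamma_eff[i] * sin(pr$movement$omega * times[i] * u_hours +
                           pr$movement$phi)
    # (5) sameness distress over active deviations
    S[i] <- S_of(i)
    # (6) arousal for the next step
    Xi[i] <- max(0, ar[1] * Xi[i - 1] + ar[2] * Lambda_s[i] + ar[3] * S[i])
  }
  if (sc$clamp_M) M <- pmax(M, 0)

  # slow tier: quasi-static over the fast horizon
  N <- nonverbal_effectiveness(pr$channels)
  C <- relationship_quality(pr$relationships, sc$age_months)$C
  I <- interest_engagement(pr$interests, sc$age_months)

  # composite, computed last, never fed back; default bounds are theoretical
  # ranges widened to the realised trajectory (sensitisation can exceed the
  # linear-accumulation reference ceiling), so clipping marks genuinely
  # out-of-band values only
  w <- pr$weights
  if (is.null(w$bounds)) {
    w$bounds <- .default_bounds(pr, sc)
    w$bounds$P_total[2] <- max(w$bounds$P_total[2], max(P_total) + 1e-12)
    w$bounds$M <- c(min(0, min(M)), max(w$bounds$M[2], max(M)))
    w$bounds$S[2] <- max(w$bounds$S[2], max(S) + 1e-12)
  }
  A <- vapply(seq_len(n), function(i) {
    composite_index(c(R = R[i], N = N, C = C, M = M[i], S = S[i], I = I,
                      P_total = P_total[i]), w)$A
  }, numeric(1))

  # withdrawal on the reporting grid
  report_times <- seq(0, sc$horizon, by = sc$report_dt)
  withdrawal_time <- NA_real_
  if (is.finite(pr$threshold)) {
    idx <- vapply(report_times, function(tt) which.min(abs(times - tt)),
                  integer(1))
    hit <- which(P_total[idx] > pr$threshold)
    if (length(hit)) {
      withdrawal_time <- report_times[hit[1]]
      ev_log[[length(ev_log) + 1L]] <-
        data.frame(time = withdrawal_time, type = "withdrawal",
                   cause = sprintf(
                     "P_total %.4g above regulatory threshold %.4g",
                     P_total[idx[hit[1]]], pr$threshold))
    }
  }

  events <- if (length(ev_log)) do.call(rbind, ev_log) else
    data.frame(time = numeric(0), type = character(0), cause = character(0))
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL

  series <- data.frame(time = times, R = R, N = N, C = C, M = M, S = S, I = I,
                       P_total = P_total, Xi = Xi, beta_eff = beta_eff,
                       Gamma_eff = Gamma_eff, Lambda_s = Lambda_s, A = A)
  structure(list(series = series, events = events,
                 metadata = list(seed = seed, dt = sc$dt,
                                 report_dt = sc$report_dt,
                                 time_unit = sc$time_unit,
                                 age_months = sc$age_months,
                                 bounds = w$bounds,
                                 orientation = w$orientation,
                                 composite_note = "descriptive summary; not fed back",
                                 profile_hash = .object_hash(sc$profile),
                                 withdrawal_time = withdrawal_time)),
            class = "trajectory_bundle")
}

.object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' @export
print.trajectory_bundle <- function(x, ...) {
  s <- x$series
  cat(sprintf("Trajectory bundle: %d steps of %g %s (horizon %g)\n",
              nrow(s) - 1L, x$metadata$dt, x$metadata$time_unit,
              max(s$time)))
  cat(sprintf("  final: R=%.3f M=%.3f S=%.3f P_total=%.2f A=%.3f\n",
              s$R[nrow(s)], s$M[nrow(s)], s$S[nrow(s)],
              s$P_total[nrow(s)], s$A[nrow(s)]))
  if (nrow(x$events)) {
    cat("  events:\n")
    for (i in seq_len(nrow(x$events)))
      cat(sprintf("    t=%g %s (%s)\n", x$events$time[i], x$events$type[i],
                  x$events$cause[i]))
  } else cat("  events: none\n")
  invisible(x)
}

#' @export
plot.trajectory_bundle <- function(x, variables = c("R", "M", "S", "P_total", "A"),
                                   ...) {
  s <- x$series
  old <- graphics::par(mfrow = c(length(variables), 1),
                       mar = c(2.5, 4, 0.5, 0.5))
  on.exit(graphics::par(old))
  for (v in variables) {
    graphics::plot(s$time, s[[v]], type = "l", xlab = "", ylab = v, ...)
    wt <- x$metadata$withdrawal_time
    if (!is.na(wt)) graphics::abline(v = wt, lty = 2)
  }
  invisible(x)
}

#' The packaged restaurant scenario
#'
#' A two-hour social event in a busy restaurant for an adult with high
#' auditory sensitivity and near-absent habituation: ambient noise accumulates
#' linearly (`sigma = 0.8` per minute, `delta = 0`), entropy rises from 3.0 to
#' 5.5 bits as the room fills, an unexpected table relocation at t = 70
#' minutes deviates the seating routine by 0.6 (precision 4.0, threshold 0.3,
#' ceiling 0.9), interest alignment rises from 0.3 to 0.9 at t = 75 minutes
#' when conversation turns to a restricted interest, and the regulatory
#' threshold sits at a cumulative load of 70, reached between the 75- and
#' 90-minute reports.
#'
#' @return an [scenario()] ready for [run_scenario()].
#' @examples
#' b <- run_scenario(restaurant_vignette(), seed = 1)
#' b$series$P_total[b$series$time == 90]   # 72
#' @export
restaurant_vignette <- function() {
  profile <- individual_profile(
    reciprocity = reciprocity_params(R0 = 0.85, alpha = 1, beta_base = 0.3,
                                     k_E = 1, k_Lambda = 1, k_P = 1,
                                     k_M = 1, k_Pr = 1, k_I = 1,
                                     M_social = 0.6, Pr_env = 0,
                                     I_align = 0.3),
    channels = default_channels(eta = 0.7, x = 0.6),
    relationships = list(relationship_params(a_max = 1, k_base = 0.05,
                                             t_infl = 240)),
    movement = movement_params(M0 = 0.5, Gamma_max = 0.8, omega = 8 * pi,
                               phi = 0, k_H = 4, k_engage = 1, k_alt = 1),
    routines = list(seating = routine_params(
      label = "seating", s_max = 0.9, r_base = log(17) / 1.2,
      pi_precision = 4, theta = 0.3, x_expected = 0)),
    interests = interest_params(I0 = 0.2, interests = list(
      list(b_base = 0.8, R_int = 3.2, R_norm = 1, lambda_base = 0.05,
           P_acc = 0.9, t_acquired = 276))),
    stimuli = list(ambient_noise = sensory_stimulus_params(
      label = "ambient_noise", sigma = 0.8, delta_base = 0, gaba_ratio = 1,
      k_sens = 0)),
    weights = composite_weights(),
    capacity = 50, threshold = 70)
  scenario(profile, horizon = 120, dt = 1, report_dt = 15,
           time_unit = "minutes",
           env = data.frame(time = c(0, 120), H_env = c(3.0, 5.5)),
           exposures = list(list(label = "ambient_noise", start = 0,
                                 end = 120)),
           events = list(list(time = 70, routine = "seating",
                              magnitude = 0.6)),
           context = list(E_exec = 0.4, Pi_load = 0.5, E_engage = 0,
                          Phi_alt = 0),
           switches = list(I_align = data.frame(time = 75, value = 0.9)),
           age_months = 300)
}
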