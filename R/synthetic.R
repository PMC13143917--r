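#' Default population specification for profile sampling
#'
#' Ranges for each person-specific parameter, in canonical units. Entries are
#' either a single number (a point mass) or a `c(min, max)` pair drawn
#' uniformly. The baseline depletion rate spans the theoretically plausible
#' 0.1-0.5 per hour band; the remaining ranges are chosen to produce
#' realistic, well-behaved trajectories (moderate loads, saturating entropy
#' responses, routines with sub-unit ceilings).
#'
#' @return named list of ranges, one entry per sampled parameter.
#' @export
default_population_spec <- function() {
  list(
    R0 = c(0.6, 0.95), alpha = 1, beta_base = c(0.1, 0.5),
    k_E = c(0.5, 1.5), k_Lambda = c(0.5, 1.5), k_P = c(0.5, 1.5),
    k_M = c(0.5, 1.5), k_Pr = c(0.5, 1.5), k_I = c(0.5, 1.5),
    M_social = c(0.2, 0.8), Pr_env = c(0, 0.5), I_align = c(0, 0.6),
    eta = c(0.3, 1), x = c(0.3, 1),
    a_max = c(0.5, 1.5), M_soc = c(0.4, 1), M_norm = 1,
    rel_k_base = c(0.1, 0.8), R_sal = c(0.4, 1), rel_R_norm = 1,
    P_var = c(0, 0.6), t_infl = c(60, 300),
    M0 = c(0.2, 0.6), Gamma_max = c(0.4, 1.2), omega = c(2, 10), phi = 0,
    k_H = c(1, 4), k_engage = c(0.5, 1.5), k_alt = c(0.5, 1.5),
    s_max = c(0.5, 1), r_base = c(1, 4), pi_precision = c(1, 5),
    theta = c(0.1, 0.5),
    I0 = c(0.1, 0.4), b_base = c(0.4, 1), R_int = c(1, 3), int_R_norm = 1,
    lambda_base = c(0.05, 0.3), P_acc = c(0.5, 0.95), t_acquired = c(0, 240),
    sigma = c(0.2, 1), delta_base = c(0, 0.1), gaba_ratio = c(0.5, 1),
    k_sens = c(0, 0.3),
    capacity = c(20, 80), threshold = c(40, 120)
  )
}

.draw <- function(spec, name) {
  if (!name %in% names(spec))
    stop("sample_profile: population spec missing parameter '", name, "'")
  v <- spec[[name]]
  if (length(v) == 1L) v else stats::runif(1, v[1], v[2])
}

#' Sample an individual profile from a population specification
#'
#' Draws every person-specific parameter independently from its range (point
#' masses are returned exactly), assembles an [individual_profile()] and
#' guarantees it validates. Fully reproducible given the seed.
#'
#' @param rng_seed integer seed.
#' @param population_spec ranges per parameter; see
#'   [default_population_spec()].
#' @param n_relationships,n_interests,n_routines,n_stimuli structure counts.
#' @return a valid [individual_profile()].
#' @export
sample_profile <- function(rng_seed,
                           population_spec = default_population_spec(),
                           n_relationships = 2, n_interests = 1,
                           n_routines = 1, n_stimuli = 1) {
  set.seed(rng_seed)
  sp <- population_spec
  rec <- reciprocity_params(
    R0 = .draw(sp, "R0"), alpha = .draw(sp, "alpha"),
    beta_base = .draw(sp, "beta_base"),
    k_E = .draw(sp, "k_E"), k_Lambda = .draw(sp, "k_Lambda"),
    k_P = .draw(sp, "k_P"), k_M = .draw(sp, "k_M"),
    k_Pr = .draw(sp, "k_Pr"), k_I = .draw(sp, "k_I"),
    M_social = .draw(sp, "M_social"), Pr_env = .draw(sp, "Pr_env"),
    I_align = .draw(sp, "I_align"))
  channels <- default_channels(
    eta = vapply(1:6, function(i) .draw(sp, "eta"), numeric(1)),
    x = vapply(1:6, function(i) .draw(sp, "x"), numeric(1)))
  rels <- lapply(seq_len(n_relationships), function(j) {
    relationship_params(a_max = .draw(sp, "a_max"), M_soc = .draw(sp, "M_soc"),
                        M_norm = .draw(sp, "M_norm"),
                        k_base = .draw(sp, "rel_k_base"),
                        R_sal = .draw(sp, "R_sal"),
                        R_norm = .draw(sp, "rel_R_norm"),
                        P_var = .draw(sp, "P_var"),
                        t_infl = .draw(sp, "t_infl"))
  })
  mov <- movement_params(M0 = .draw(sp, "M0"), Gamma_max = .draw(sp, "Gamma_max"),
                         omega = .draw(sp, "omega"), phi = .draw(sp, "phi"),
                         k_H = .draw(sp, "k_H"), k_engage = .draw(sp, "k_engage"),
                         k_alt = .draw(sp, "k_alt"))
  routines <- lapply(seq_len(n_routines), function(k) {
    routine_params(label = paste0("routine_", k), s_max = .draw(sp, "s_max"),
                   r_base = .draw(sp, "r_base"),
                   pi_precision = .draw(sp, "pi_precision"),
                   theta = .draw(sp, "theta"))
  })
  names(routines) <- vapply(routines, `[[`, "", "label")
  ints <- interest_params(I0 = .draw(sp, "I0"), interests = lapply(
    seq_len(n_interests), function(l) {
      list(b_base = .draw(sp, "b_base"), R_int = .draw(sp, "R_int"),
           R_norm = .draw(sp, "int_R_norm"),
           lambda_base = .draw(sp, "lambda_base"),
           P_acc = .draw(sp, "P_acc"), t_acquired = .draw(sp, "t_acquired"))
    }))
  stimuli <- lapply(seq_len(n_stimuli), function(s) {
    sensory_stimulus_params(label = paste0("stimulus_", s),
                            sigma = .draw(sp, "sigma"),
                            delta_base = .draw(sp, "delta_base"),
                            gaba_ratio = .draw(sp, "gaba_ratio"),
                            k_sens = .draw(sp, "k_sens"))
  })
  names(stimuli) <- vapply(stimuli, `[[`, "", "label")
  prof <- individual_profile(reciprocity = rec, channels = channels,
                             relationships = rels, movement = mov,
                             routines = routines, interests = ints,
                             stimuli = stimuli,
                             capacity = .draw(sp, "capacity"),
                             threshold = .draw(sp, "threshold"))
  viol <- validate_profile(prof)
  if (length(viol)) stop("sample_profile: drew invalid profile: ",
                         paste(viol, collapse = "; "))
  prof
}

#' Generate a synthetic environment track
#'
#' Piecewise-linear nonnegative entropy over the horizon, a stimulus exposure
#' schedule, and routine-deviation events as a seeded homogeneous Poisson
#' stream with uniform per-event magnitudes.
#'
#' @param rng_seed integer seed.
#' @param spec list with `horizon` (time units), `n_nodes` (entropy
#'   breakpoints), `H_range` (`c(min, max)` bits), `exposures` (passed through
#'   to the scenario), `event_rate` (events per time unit, >= 0),
#'   `event_magnitude` (`c(min, max)`), `routine` (label the events target).
#' @return object of class `environment_track`: list with `env` (data.frame
#'   `time, H_env`), `exposures`, `events`.
#' @export
generate_environment <- function(rng_seed,
                                 spec = list(horizon = 120, n_nodes = 5,
                                             H_range = c(2, 6),
                                             exposures = list(),
                                             event_rate = 0,
                                             event_magnitude = c(0.2, 0.8),
                                             routine = "routine_1")) {
  if (spec$horizon <= 0) stop("generate_environment: horizon must be positive")
  if (spec$event_rate < 0) stop("generate_environment: negative event rate")
  set.seed(rng_seed)
  nn <- max(2L, spec$n_nodes)
  tt <- seq(0, spec$horizon, length.out = nn)
  H <- stats::runif(nn, spec$H_range[1], spec$H_range[2])
  H <- pmax(H, 0)
  events <- list()
  if (spec$event_rate > 0) {
    t <- 0
    repeat {
      t <- t + stats::rexp(1, spec$event_rate)
      if (t > spec$horizon) break
      events[[length(events) + 1L]] <- list(
        time = t, routine = spec$routine,
        magnitude = stats::runif(1, spec$event_magnitude[1],
                                 spec$event_magnitude[2]))
    }
  }
  structure(list(env = data.frame(time = tt, H_env = H),
                 exposures = spec$exposures, events = events,
                 seed = rng_seed),
            class = "environment_track")
}

# Table of observation channels: valid range and identifiability tier of each
# observable state variable (tier 1 = EMA-identifiable in naturalistic
# sampling; tier 2 = structured observation; tier 3 = neuroimaging-informed).
.observation_channels <- function() {
  data.frame(
    variable = c("R", "N", "C", "M", "S", "I", "P_total", "Xi", "beta_eff",
                 "Gamma_eff", "A"),
    lo = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    hi = c(1, Inf, Inf, Inf, Inf, Inf, Inf, Inf, Inf, Inf, 1),
    tier = c(1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE)
}

#' Observe a trajectory as a noisy EMA dataset
#'
#' Samples the latent trajectory at prompt times (nearest-neighbour lookup on
#' the truth grid), adds independent Gaussian noise per observation and clips
#' to each variable's valid range. Every observation carries its variable's
#' identifiability tier so fitting runs can be restricted to, e.g.,
#' EMA-identifiable (tier 1) channels. Reproducible given the seed, with the
#' generating truth linked in the attributes.
#'
#' @param truth a `trajectory_bundle` from [run_scenario()].
#' @param design sampling design: either `times` (explicit prompt times) or
#'   `prompts_per_day` plus `jitter` (uniform jitter half-width, same time
#'   unit as the trajectory); `variables` selects observed channels.
#' @param noise list with `sd`, a single value or named per-variable vector.
#' @param rng_seed integer seed.
#' @param subject subject identifier.
#' @return data.frame of class `ema_dataset` with columns
#'   `subject, time, variable, value, tier`; truth provenance in
#'   `attr(, "truth")`.
#' @export
observe <- function(truth, design = list(prompts_per_day = 6, jitter = 30,
                                         variables = c("R", "M", "S",
                                                       "P_total")),
                    noise = list(sd = 0.05), rng_seed, subject = "s1") {
  if (missing(rng_seed)) stop("observe: an explicit seed is required")
  chan <- .observation_channels()
  vars <- design$variables
  unknown <- setdiff(vars, chan$variable)
  if (length(unknown))
    stop("observe: unknown variable name(s): ", paste(unknown, collapse = ", "))
  s <- truth$series
  horizon <- max(s$time)
  set.seed(rng_seed)
  if (!is.null(design$times)) {
    pt <- design$times
    if (any(pt < 0 | pt > horizon))
      stop("observe: design times outside the truth grid")
  } else {
    per_day <- if (truth$metadata$time_unit == "minutes") 1440 else 24
    n_prompts <- max(1L, round(design$prompts_per_day * horizon / per_day))
    pt <- seq(0, horizon, length.out = n_prompts + 2L)[-c(1L, n_prompts + 2L)]
    jit <- if (is.null(design$jitter)) 0 else design$jitter
    if (jit > 0) {
      pt <- pt + stats::runif(length(pt), -jit, jit)
      pt <- pmin(pmax(pt, 0), horizon)
    }
  }
  idx <- vapply(pt, function(tt) which.min(abs(s$time - tt)), integer(1))
  obs <- do.call(rbind, lapply(vars, function(v) {
    ch <- chan[chan$variable == v, ]
    sd_v <- if (length(noise$sd) > 1L) noise$sd[[v]] else noise$sd
    raw <- s[[v]][idx] + stats::rnorm(length(idx), 0, sd_v)
    data.frame(subject = subject, time = pt, variable = v,
               value = pmin(pmax(raw, ch$lo), ch$hi), tier = ch$tier,
               stringsAsFactors = FALSE)
  }))
  obs <- obs[order(obs$time, obs$variable), ]
  rownames(obs) <- NULL
  attr(obs, "truth") <- list(profile_hash = truth$metadata$profile_hash,
                             trajectory_seed = truth$metadata$seed,
                             observation_seed = rng_seed)
  class(obs) <- c("ema_dataset", "data.frame")
  obs
}
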