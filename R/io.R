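#' Write a trajectory bundle to CSV (long format) with a JSON sidecar
#'
#' Values go to `<path>` as `time, variable, value` rows; events and metadata
#' go to `<path>.meta.json`.
#'
#' @param bundle a `trajectory_bundle`.
#' @param path output CSV path.
#' @param digits significant digits for the CSV (default keeps full double
#'   precision via 17 digits).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(bundle, path, digits = 17) {
  s <- bundle$series
  vars <- setdiff(names(s), "time")
  long <- data.frame(
    time = rep(s$time, length(vars)),
    variable = rep(vars, each = nrow(s)),
    value = unlist(s[vars], use.names = FALSE))
  long <- long[order(long$time, long$variable), ]
  fmt <- long
  fmt$value <- sprintf(paste0("%.", digits, "g"), fmt$value)
  fmt$time <- sprintf(paste0("%.", digits, "g"), fmt$time)
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  meta <- bundle$metadata
  meta$events <- bundle$events
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a trajectory bundle written by [write_trajectory()]
#'
#' Malformed or non-numeric rows raise an error naming the offending line
#' numbers. A missing metadata sidecar degrades to a warning and an empty
#' metadata list.
#'
#' @param path CSV path.
#' @return a `trajectory_bundle`.
#' @export
read_trajectory <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  if (!all(c("time", "variable", "value") %in% names(raw)))
    stop("read_trajectory: expected columns time, variable, value")
  tm <- suppressWarnings(as.numeric(raw$time))
  vl <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(tm) | is.na(vl))
  if (length(bad))
    stop("read_trajectory: non-numeric cell(s) at data line(s) ",
         paste(bad + 1L, collapse = ", "))   # +1 for the header line
  long <- data.frame(time = tm, variable = raw$variable, value = vl)
  wide <- stats::reshape(long, idvar = "time", timevar = "variable",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- wide[order(wide$time), ]
  rownames(wide) <- NULL
  meta_path <- paste0(path, ".meta.json")
  events <- data.frame(time = numeric(0), type = character(0),
                       cause = character(0))
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$events) && length(meta$events)) {
      events <- as.data.frame(meta$events)
    }
    meta$events <- NULL
  } else {
    warning("read_trajectory: metadata sidecar not found; loading with empty metadata")
    meta <- list()
  }
  structure(list(series = wide, events = events, metadata = meta),
            class = "trajectory_bundle")
}

#' Write an individual profile to JSON or YAML
#'
#' @param profile an [individual_profile()].
#' @param path output path; the `.yaml`/`.yml` extension selects YAML,
#'   anything else JSON.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  x <- list(
    reciprocity = unclass(profile$reciprocity),
    channels = lapply(profile$channels, unclass),
    relationships = lapply(profile$relationships, unclass),
    movement = unclass(profile$movement),
    routines = lapply(profile$routines, unclass),
    interests = unclass(profile$interests),
    stimuli = lapply(profile$stimuli, unclass),
    weights = list(w = as.numeric(profile$weights$w),
                   bounds = profile$weights$bounds,
                   orientation = as.logical(profile$weights$orientation)),
    arousal = as.numeric(profile$arousal),
    capacity = profile$capacity,
    threshold = if (is.finite(profile$threshold)) profile$threshold else NULL)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            null = "null")
  invisible(path)
}

#' Read an individual profile from JSON or YAML
#'
#' Field names follow the parameter constructors, one section per submodel.
#' Composite weights are renormalised on load (with a message when the stored
#' sum differs from one). Times given in minutes in scenario files are
#' handled by the scenario layer; profile rates are canonical (per hour,
#' per month).
#'
#' @param path profile file (`.json`, `.yaml` or `.yml`).
#' @return an [individual_profile()].
#' @export
read_profile <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = FALSE)
  as_num <- function(v) if (is.null(v)) NULL else as.numeric(unlist(v))
  rp <- do.call(reciprocity_params, x$reciprocity)
  channels <- lapply(x$channels, function(ch) do.call(nonverbal_channel, ch))
  rels <- lapply(x$relationships, function(r) do.call(relationship_params, r))
  mov <- do.call(movement_params, x$movement)
  routines <- lapply(x$routines, function(r) do.call(routine_params, r))
  ints <- interest_params(I0 = x$interests$I0,
                          interests = x$interests$interests)
  stim <- lapply(x$stimuli, function(s) do.call(sensory_stimulus_params, s))
  bounds <- if (length(x$weights$bounds))
    lapply(x$weights$bounds, as_num) else NULL
  orientation <- if (!is.null(x$weights$orientation))
    stats::setNames(as.logical(unlist(x$weights$orientation)),
                    .composite_components) else NULL
  w <- composite_weights(w = as_num(x$weights$w), bounds = bounds,
                         orientation = orientation)
  individual_profile(reciprocity = rp, channels = channels,
                     relationships = rels, movement = mov,
                     routines = routines, interests = ints, stimuli = stim,
                     weights = w,
                     arousal = as_num(x$arousal),
                     capacity = x$capacity,
                     threshold = if (is.null(x$threshold)) Inf else x$threshold)
}

#' Read a scenario (with inline profile) from JSON or YAML
#'
#' @param path scenario file with a `profile` section plus the [scenario()]
#'   fields (`horizon`, `dt`, `report_dt`, `time_unit`, `env`, `exposures`,
#'   `events`, `context`, `switches`, `age_months`).
#' @return an [scenario()].
#' @export
read_scenario <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = FALSE)
  pf <- tempfile(fileext = ".json")
  on.exit(unlink(pf))
  jsonlite::write_json(x$profile, pf, auto_unbox = TRUE, digits = NA)
  profile <- read_profile(pf)
  env <- data.frame(time = as.numeric(unlist(x$env$time)),
                    H_env = as.numeric(unlist(x$env$H_env)))
  switches <- list()
  if (!is.null(x$switches$I_align)) {
    sw <- x$switches$I_align
    switches$I_align <- data.frame(time = as.numeric(unlist(sw$time)),
                                   value = as.numeric(unlist(sw$value)))
  }
  scenario(profile,
           horizon = x$horizon,
           dt = if (is.null(x$dt)) 1 else x$dt,
           report_dt = if (is.null(x$report_dt)) 15 else x$report_dt,
           time_unit = if (is.null(x$time_unit)) "minutes" else x$time_unit,
           env = env,
           exposures = if (is.null(x$exposures)) list() else x$exposures,
           events = if (is.null(x$events)) list() else x$events,
           context = if (is.null(x$context)) list() else x$context,
           switches = switches,
           age_months = if (is.null(x$age_months)) 300 else x$age_months)
}

#' Write an EMA dataset to CSV with a truth sidecar
#'
#' @param ema an `ema_dataset` from [observe()].
#' @param path output CSV path; truth provenance goes to
#'   `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_ema <- function(ema, path) {
  utils::write.csv(as.data.frame(ema), path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(attr(ema, "truth"), paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
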