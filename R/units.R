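#' Unit tags and dimensional analysis
#'
#' The model mixes quantities measured in hours, months, bits, radians and
#' abstract deviation units. Every exponent and every sinusoid argument in the
#' model equations must reduce to a dimensionless quantity; [dimensional_check()]
#' verifies this mechanically for any product of tagged quantities.
#'
#' Two modes are supported. In `"permissive"` mode (the default) hours, minutes
#' and months are all treated as the same base dimension (time), so an
#' hour^-1 rate multiplied by a duration in months cancels. In `"strict"` mode
#' hour and month are distinct base dimensions and such mixed products are
#' flagged.
#'
#' @param units character vector of unit tokens, e.g. `c("hour^-1", "hour")`.
#'   Recognised tokens: `dimensionless`, `hour`, `hour^-1`, `minute`,
#'   `minute^-1`, `month`, `month^-1`, `bits`, `bits^-1`, `radians`,
#'   `radians^-1`, `deviation`, `deviation^-1`.
#' @param mode `"permissive"` or `"strict"` (see Details).
#' @return `TRUE` iff the product of all supplied units reduces to a
#'   dimensionless quantity.
#' @examples
#' dimensional_check(c("hour^-1", "hour"))          # TRUE
#' dimensional_check(c("bits", "bits^-1"))          # TRUE
#' dimensional_check(c("hour^-1", "month"))         # TRUE  (permissive)
#' dimensional_check(c("hour^-1", "month"), "strict") # FALSE
#' @export
dimensional_check <- function(units, mode = c("permissive", "strict")) {
  mode <- match.arg(mode)
  exps <- .unit_exponents(mode)
  total <- numeric(length(.unit_dims))
  names(total) <- .unit_dims
  for (u in units) {
    if (!u %in% names(exps)) {
      stop("unknown unit token: '", u, "'", call. = FALSE)
    }
    total <- total + exps[[u]]
  }
  all(abs(total) < 1e-12)
}

.unit_dims <- c("hour", "minute", "month", "bits", "radians", "deviation")

# exponent vector per token; in permissive mode all time units share the
# "hour" slot so they cancel against each other
.unit_exponents <- function(mode) {
  base <- function(dim, p) {
    v <- numeric(length(.unit_dims))
    names(v) <- .unit_dims
    if (!is.null(dim)) v[dim] <- p
    v
  }
  time_dim <- function(d) if (mode == "permissive") "hour" else d
  list(
    "dimensionless" = base(NULL, 0),
    "hour"          = base(time_dim("hour"), 1),
    "hour^-1"       = base(time_dim("hour"), -1),
    "minute"        = base(time_dim("minute"), 1),
    "minute^-1"     = base(time_dim("minute"), -1),
    "month"         = base(time_dim("month"), 1),
    "month^-1"      = base(time_dim("month"), -1),
    "bits"          = base("bits", 1),
    "bits^-1"       = base("bits", -1),
    # angles are dimensionless: an angular argument (omega*t + phi) is valid
    "radians"       = base(NULL, 0),
    "radians^-1"    = base(NULL, 0),
    "deviation"     = base("deviation", 1),
    "deviation^-1"  = base("deviation", -1)
  )
}

#' Tag a quantity with a unit
#'
#' Lightweight record pairing a quantity name with a unit token from the closed
#' vocabulary understood by [dimensional_check()].
#'
#' @param quantity name of the quantity (e.g. `"beta_base"`).
#' @param unit unit token (e.g. `"hour^-1"`).
#' @return an object of class `unit_tag`.
#' @export
unit_tag <- function(quantity, unit) {
  stopifnot(is.character(quantity), length(quantity) == 1L,
            is.character(unit), length(unit) == 1L)
  # fail early on unknown tokens
  dimensional_check(unit)
  structure(list(quantity = quantity, unit = unit), class = "unit_tag")
}

#' @export
print.unit_tag <- function(x, ...) {
  cat(sprintf("%s [%s]\n", x$quantity, x$unit))
  invisible(x)
}

#' Symbol-to-field concordance
#'
#' The model notation reuses some letters across submodels (for example `k_E`
#' multiplies executive load in the reciprocity equation but engagement in the
#' stereotypy amplitude; three different quantities describe "sensory load").
#' Field names in this package are namespaced to avoid those collisions; this
#' table records the mapping from mathematical symbol to package field, one row
#' per symbol.
#'
#' @return a data.frame with columns `symbol`, `field`, `structure`, `unit`.
#' @export
notation_table <- function() {
  rows <- list(
    c("R(t)",        "R",            "trajectory_bundle", "dimensionless"),
    c("R_0",         "R0",           "reciprocity_params", "dimensionless"),
    c("alpha",       "alpha",        "reciprocity_params", "dimensionless"),
    c("beta_base",   "beta_base",    "reciprocity_params", "hour^-1"),
    c("beta_eff",    "beta_eff",     "trajectory_bundle", "hour^-1"),
    c("k_E",         "k_E",          "reciprocity_params", "dimensionless"),
    c("k_Lambda",    "k_Lambda",     "reciprocity_params", "dimensionless"),
    c("k_P",         "k_P",          "reciprocity_params", "dimensionless"),
    c("k_M",         "k_M",          "reciprocity_params", "dimensionless"),
    c("k_Pr",        "k_Pr",         "reciprocity_params", "dimensionless"),
    c("k_I",         "k_I",          "reciprocity_params", "dimensionless"),
    c("E(t) (executive)", "E_exec",  "social_context_signal", "dimensionless"),
    c("Pi_load(t)",  "Pi_load",      "social_context_signal", "dimensionless"),
    c("Lambda_s(t)", "Lambda_s",     "social_context_signal", "dimensionless"),
    c("M (motivation)", "M_social",  "reciprocity_params", "dimensionless"),
    c("Pr",          "Pr_env",       "reciprocity_params", "dimensionless"),
    c("I (alignment)", "I_align",    "reciprocity_params", "dimensionless"),
    c("N",           "N",            "trajectory_bundle", "dimensionless"),
    c("w_norm,i",    "w_norm",       "nonverbal_channel", "dimensionless"),
    c("eta_i",       "eta",          "nonverbal_channel", "dimensionless"),
    c("x_i",         "x",            "nonverbal_channel", "dimensionless"),
    c("C(t)",        "C",            "trajectory_bundle", "dimensionless"),
    c("a_max,j",     "a_max",        "relationship_params", "dimensionless"),
    c("M_soc",       "M_soc",        "relationship_params", "dimensionless"),
    c("M_norm",      "M_norm",       "relationship_params", "dimensionless"),
    c("k_base,j",    "k_base",       "relationship_params", "month^-1"),
    c("R_sal",       "R_sal",        "relationship_params", "dimensionless"),
    c("R_norm (relationships)", "R_norm", "relationship_params", "dimensionless"),
    c("P_var",       "P_var",        "relationship_params", "dimensionless"),
    c("t_j",         "t_infl",       "relationship_params", "month"),
    c("M(t)",        "M",            "trajectory_bundle", "dimensionless"),
    c("M_0",         "M0",           "movement_params", "dimensionless"),
    c("Gamma_max",   "Gamma_max",    "movement_params", "dimensionless"),
    c("Gamma_eff",   "Gamma_eff",    "trajectory_bundle", "dimensionless"),
    c("omega",       "omega",        "movement_params", "radians"),
    c("phi",         "phi",          "movement_params", "radians"),
    c("H_env(t)",    "H_env",        "entropy_signal", "bits"),
    c("k_H",         "k_H",          "movement_params", "bits"),
    c("E(t) (engagement)", "E_engage", "entropy_signal", "dimensionless"),
    c("Phi_alt(t)",  "Phi_alt",      "entropy_signal", "dimensionless"),
    c("k_E (engagement)", "k_engage", "movement_params", "dimensionless"),
    c("k_Phi",       "k_alt",        "movement_params", "dimensionless"),
    c("S_k",         "S",            "trajectory_bundle", "dimensionless"),
    c("s_k",         "s_max",        "routine_params", "dimensionless"),
    c("r_base,k",    "r_base",       "routine_params", "deviation^-1"),
    c("pi_k",        "pi_precision", "routine_params", "dimensionless"),
    c("theta_k",     "theta",        "routine_params", "deviation"),
    c("x_bar_k",     "x_expected",   "routine_params", "deviation"),
    c("I(t)",        "I",            "trajectory_bundle", "dimensionless"),
    c("I_0",         "I0",           "interest_params", "dimensionless"),
    c("b_base,l",    "b_base",       "interest_params", "dimensionless"),
    c("R_int,l",     "R_int",        "interest_params", "dimensionless"),
    c("R_norm (interests)", "R_norm_interest", "interest_params", "dimensionless"),
    c("lambda_base,l", "lambda_base", "interest_params", "month^-1"),
    c("P_acc,l",     "P_acc",        "interest_params", "dimensionless"),
    c("P(s)",        "P_total",      "trajectory_bundle", "dimensionless"),
    c("sigma_s",     "sigma",        "sensory_stimulus_params", "hour^-1"),
    c("delta_base,s", "delta_base",  "sensory_stimulus_params", "hour^-1"),
    c("GABA_func/GABA_norm", "gaba_ratio", "sensory_stimulus_params", "dimensionless"),
    c("k_sens",      "k_sens",       "sensory_stimulus_params", "dimensionless"),
    c("Xi(t)",       "Xi",           "trajectory_bundle", "dimensionless"),
    c("A(t)",        "A",            "trajectory_bundle", "dimensionless"),
    c("alpha_1..3, beta_1..4", "w",  "composite_weights", "dimensionless")
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(symbol = r[1], field = r[2], structure = r[3], unit = r[4],
               stringsAsFactors = FALSE)
  }))
  out
}
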