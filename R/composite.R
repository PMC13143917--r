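#' Normalise a raw component to the unit interval
#'
#' `z = (x - x_min) / (x_max - x_min)`, clipped to `[0, 1]` with a warning
#' naming the component whenever clipping occurs.
#'
#' @param x raw value(s).
#' @param x_min,x_max normalisation bounds, `x_max > x_min`.
#' @param component component name used in the clip warning.
#' @return normalised value(s) in `[0, 1]`.
#' @export
normalise <- function(x, x_min, x_max, component = "component") {
  if (x_max <= x_min) stop("normalise: x_max must exceed x_min")
  z <- (x - x_min) / (x_max - x_min)
  if (any(z < 0 | z > 1)) {
    warning(sprintf("normalise: clipping %d value(s) of '%s' to [0, 1]",
                    sum(z < 0 | z > 1), component))
    z <- pmin(pmax(z, 0), 1)
  }
  z
}

#' Composite symptom index
#'
#' `A = sum_i w_i * z_i` over the seven normalised components
#' (`R`, `N`, `C`, `M`, `S`, `I`, `P_total`). Each raw component is normalised
#' with its recorded bounds and, where the orientation flag says so
#' (default: `R`, `N`, `C`, for which higher raw values mean better
#' functioning), reflected (`z <- 1 - z`) so that larger `z` always means
#' greater symptom expression. With weights summing to one, `A` lies in
#' `[0, 1]`. The index is a descriptive summary: it is never fed back into the
#' mechanistic equations, and the direct plus indirect appearance of
#' `P_total` (also driving depletion via the sensory-load coupling) is
#' retained as acknowledged redundancy.
#'
#' @param v named numeric vector with the seven raw components.
#' @param w [composite_weights()]; its `bounds` must cover all components.
#' @return list with `A`, the normalised oriented `z`, and the per-component
#'   `contributions` (`w * z`).
#' @export
composite_index <- function(v, w) {
  comp <- .composite_components
  if (!all(comp %in% names(v)))
    stop("composite_index: components must be named ",
         paste(comp, collapse = ", "))
  if (!inherits(w, "composite_weights")) stop("composite_index: invalid weights")
  if (abs(sum(w$w) - 1) > 1e-12) stop("composite_index: weights must sum to 1")
  if (is.null(w$bounds) || !all(comp %in% names(w$bounds)))
    stop("composite_index: normalisation bounds missing")
  z <- vapply(comp, function(nm) {
    b <- w$bounds[[nm]]
    normalise(v[[nm]], b[1], b[2], component = nm)
  }, numeric(1))
  z[w$orientation[comp]] <- 1 - z[w$orientation[comp]]
  contributions <- w$w * z
  list(A = sum(contributions), z = z, contributions = contributions)
}
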