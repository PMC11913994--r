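#' Define a tunable instrument factor
#'
#' A factor couples a natural instrument setting (kPa, degrees C, kV, ...) to
#' the coded scale used by all designs and models in this package.  Coded
#' -1/+1 correspond to `low`/`high`; the coded origin is the midpoint.
#' Settable values are multiples of `rounding_step` (the granularity at which
#' the instrument accepts the setting), and `hard_min`/`hard_max` are
#' feasibility limits of the hardware.  Axial (star) points of a central
#' composite design may fall outside `[low, high]`; they are clipped to the
#' hard bounds, never to the nominal range.
#'
#' @param name Short identifier, e.g. `"CID"`.
#' @param low,high Natural values mapped to coded -1 and +1. `low < high`.
#' @param unit Unit string (documentation only).
#' @param rounding_step Granularity of settable natural values (> 0).
#' @param hard_min,hard_max Optional instrument feasibility bounds.
#' @return An object of class `doe_factor`.
#' @examples
#' cid <- doe_factor("CID", 140, 250, unit = "kPa", rounding_step = 5)
#' decode_level(cid, -1.35)   # 120 kPa
#' @export
doe_factor <- function(name, low, high, unit = "", rounding_step = 1,
                       hard_min = -Inf, hard_max = Inf) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.finite(low) || !is.finite(high) || low >= high)
    stop("factor '", name, "': need finite low < high")
  if (!is.finite(rounding_step) || rounding_step <= 0)
    stop("factor '", name, "': rounding_step must be > 0")
  if (hard_min > hard_max)
    stop("factor '", name, "': hard_min > hard_max")
  structure(
    list(name = name, unit = unit, low = low, high = high,
         rounding_step = rounding_step,
         hard_min = hard_min, hard_max = hard_max),
    class = "doe_factor")
}

#' @export
print.doe_factor <- function(x, ...) {
  cat(sprintf("<factor> %s [%s]: %g (-1) .. %g (+1), step %g", x$name, x$unit,
              x$low, x$high, x$rounding_step))
  if (is.finite(x$hard_min) || is.finite(x$hard_max))
    cat(sprintf(", hard bounds [%g, %g]", x$hard_min, x$hard_max))
  cat("\n")
  invisible(x)
}

factor_center <- function(f) (f$low + f$high) / 2
factor_half_range <- function(f) (f$high - f$low) / 2

#' Round a natural value to the settable grid of a factor
#'
#' Uses round-half-to-even (the behaviour of base [round()]), so 282.5 with a
#' step of 1 degree rounds to 282, and 120.75 with a 5 kPa step rounds to 120.
#'
#' @param x Natural value(s).
#' @param step Rounding step.
#' @export
round_to_step <- function(x, step) {
  # snap to a sane number of decimals afterwards so 1.8 is stored as 1.8,
  # not 1.7999999999999998
  digits <- max(0L, ceiling(-log10(step)) + 2L)
  round(round(x / step) * step, digits)
}

#' Convert natural to coded units
#'
#' @param factor A [doe_factor()].
#' @param natural Natural value(s).
#' @return Coded value(s); the midpoint of `[low, high]` maps to 0.
#' @export
code_level <- function(factor, natural) {
  stopifnot(inherits(factor, "doe_factor"))
  if (any(!is.finite(natural)))
    stop("code_level: non-finite natural value for factor '", factor$name, "'")
  (natural - factor_center(factor)) / factor_half_range(factor)
}

#' Convert coded to natural units
#'
#' The raw natural value is clipped to the factor's hard bounds and then
#' rounded to the factor's `rounding_step`, so the result is always a value
#' the instrument can actually be set to.
#'
#' @param factor A [doe_factor()].
#' @param coded Coded value(s).
#' @param clip Clip to hard bounds before rounding (default `TRUE`).
#' @return Settable natural value(s).
#' @export
decode_level <- function(factor, coded, clip = TRUE) {
  stopifnot(inherits(factor, "doe_factor"))
  if (any(!is.finite(coded)))
    stop("decode_level: non-finite coded value for factor '", factor$name, "'")
  x <- factor_center(factor) + coded * factor_half_range(factor)
  if (clip) x <- pmin(pmax(x, factor$hard_min), factor$hard_max)
  round_to_step(x, factor$rounding_step)
}

stopifnot_factor_list <- function(factors) {
  if (!is.list(factors) || !length(factors) ||
      !all(vapply(factors, inherits, TRUE, "doe_factor")))
    stop("'factors' must be a non-empty list of doe_factor objects")
  nm <- vapply(factors, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate factor names")
  names(factors) <- nm
  factors
}

#' Factor panels used in the oxylipin ESI/collision-cell study
#'
#' `screening_factors()` returns the seven-factor panel screened in the
#' fractional factorial stage (interface voltage IntV, interface temperature
#' IntT, heating gas HG, drying gas DG, heating block HB, desolvation line
#' DL, and CID gas pressure; nebulizing gas is held at 3 L/min and is not a
#' factor).  `optimization_factors()` returns the three factors carried into
#' the central composite optimization, with the narrower ranges used there
#' and the 400 degree hard ceiling on IntT.  `ce_factors()` returns the
#' collision-energy x CID frame of the multilevel D-optimal stage.
#'
#' @return A named list of [doe_factor()] objects.
#' @export
screening_factors <- function() {
  stopifnot_factor_list(list(
    doe_factor("IntV", 2, 4, "kV", 0.1, hard_min = 0.5, hard_max = 5.5),
    doe_factor("IntT", 200, 400, "degC", 1, hard_min = 100, hard_max = 400),
    doe_factor("HG", 5, 10, "L/min", 0.5, hard_min = 0, hard_max = 20),
    doe_factor("DG", 5, 10, "L/min", 0.5, hard_min = 0, hard_max = 20),
    doe_factor("HB", 300, 500, "degC", 1, hard_min = 100, hard_max = 500),
    doe_factor("DL", 200, 300, "degC", 1, hard_min = 100, hard_max = 300),
    doe_factor("CID", 140, 270, "kPa", 5, hard_min = 100, hard_max = 400)))
}

#' @rdname screening_factors
#' @export
optimization_factors <- function() {
  stopifnot_factor_list(list(
    doe_factor("CID", 140, 250, "kPa", 5, hard_min = 100, hard_max = 400),
    doe_factor("IntT", 300, 400, "degC", 1, hard_min = 100, hard_max = 400),
    doe_factor("IntV", 2, 3, "kV", 0.1, hard_min = 0.5, hard_max = 5.5)))
}

#' @rdname screening_factors
#' @export
ce_factors <- function() {
  stopifnot_factor_list(list(
    doe_factor("CE", 12, 28, "eV", 2, hard_min = 0, hard_max = 60),
    doe_factor("CID", 190, 250, "kPa", 10, hard_min = 100, hard_max = 400)))
}
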