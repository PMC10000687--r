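# Polarization arithmetic: Fpol ratios, the G-factor consistency solution,
# and the exact forward model used by the simulator.
#
# Internally every Fpol is the raw dimensionless ratio in [-1, 1]; the
# conventional "x10^-2" reporting scale (100 x raw) is applied only at
# reporting boundaries via fpol_display().

#' Fluorescence polarization value
#'
#' Light S3 wrapper around the raw polarization ratio
#' \eqn{(I_{\parallel} - G I_{\perp}) / (I_{\parallel} + G I_{\perp})}.
#' The raw value lives in \eqn{[-1, 1]} for nonnegative intensities; the
#' field reports Fpol multiplied by 100 (the "\eqn{\times 10^{-2}}" scale),
#' available through [fpol_display()].
#'
#' @param raw numeric vector of raw polarization ratios in \eqn{[-1, 1]}.
#' @return An object of class `"fpol"` (a classed numeric vector).
#' @seealso [fpol_from_intensities()], [fpol_display()]
#' @export
#' @examples
#' p <- fpol(0.25)
#' fpol_display(p)  # 25
fpol <- function(raw) {
  raw <- as.numeric(raw)
  bad <- is.finite(raw) & (raw < -1 | raw > 1)
  if (any(bad)) {
    stop("raw Fpol values must lie in [-1, 1]; got ",
         paste(utils::head(raw[bad], 3), collapse = ", "), call. = FALSE)
  }
  structure(raw, class = "fpol")
}

#' @rdname fpol
#' @param x an `"fpol"` object or numeric vector of raw ratios.
#' @export
fpol_display <- function(x) 100 * fpol_raw(x)

#' @rdname fpol
#' @export
fpol_raw <- function(x) {
  if (inherits(x, "fpol")) unclass(x) else as.numeric(x)
}

#' @export
print.fpol <- function(x, ...) {
  cat("Fpol (x10^-2 display scale):\n")
  print(round(fpol_display(x), 3), ...)
  invisible(x)
}

#' Four-configuration polarization calibration measurements
#'
#' Mean fluorescence intensities of a uniform dye solution acquired under
#' vertically/horizontally polarized excitation crossed with
#' vertically/horizontally polarized detection. Subscript convention:
#' first letter excitation, second letter detection, so `i_vh` is
#' vertically polarized excitation detected through the horizontal
#' analyzer. All four intensities must be strictly positive for a valid
#' calibration.
#'
#' @param i_vv,i_vh,i_hh,i_hv mean intensities (arbitrary detector units).
#' @param solution_label text label for the calibration solution, e.g.
#'   `"MB-PBS"` or `"MB-glycerol"`.
#' @param images optional named list of full images (`vv`, `vh`, `hh`,
#'   `hv`) from which the means were taken.
#' @return An object of class `"calibration_set"`.
#' @seealso [solve_g_factor()], [simulate_calibration_set()]
#' @export
calibration_set <- function(i_vv, i_vh, i_hh, i_hv, solution_label = "",
                            images = NULL) {
  ints <- c(i_vv = i_vv, i_vh = i_vh, i_hh = i_hh, i_hv = i_hv)
  if (any(!is.finite(ints)) || any(ints <= 0)) {
    stop("all four calibration intensities must be finite and > 0",
         call. = FALSE)
  }
  structure(
    list(i_vv = as.numeric(i_vv), i_vh = as.numeric(i_vh),
         i_hh = as.numeric(i_hh), i_hv = as.numeric(i_hv),
         solution_label = solution_label, images = images),
    class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat("Polarization calibration set",
      if (nzchar(x$solution_label)) paste0(" [", x$solution_label, "]"),
      "\n", sep = "")
  cat(sprintf("  Ivv = %.4g  Ivh = %.4g  Ihh = %.4g  Ihv = %.4g\n",
              x$i_vv, x$i_vh, x$i_hh, x$i_hv))
  invisible(x)
}

.check_g <- function(g) {
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g <= 0)
    stop("G-factor must be a single positive number", call. = FALSE)
  as.numeric(g)
}

#' Fpol from co- and cross-polarized intensities
#'
#' The defining ratio of fluorescence polarization with instrument
#' correction: \deqn{Fpol = \frac{I_{\parallel} - G\,I_{\perp}}
#' {I_{\parallel} + G\,I_{\perp}}} where the G-factor corrects the
#' instrument's unequal transmission of the two polarization states.
#' Vectorized over intensities.
#'
#' @param i_par co-polarized (parallel) intensity, nonnegative.
#' @param i_perp cross-polarized (perpendicular) intensity, nonnegative.
#' @param g G-factor (single positive number); see [solve_g_factor()].
#' @return An `"fpol"` vector.
#' @export
#' @examples
#' fpol_from_intensities(100, 80, g = 0.75)  # raw 0.25, display 25
fpol_from_intensities <- function(i_par, i_perp, g) {
  g <- .check_g(g)
  if (any(!is.finite(i_par)) || any(!is.finite(i_perp)) ||
      any(i_par < 0) || any(i_perp < 0)) {
    stop("intensities must be finite and nonnegative", call. = FALSE)
  }
  denom <- i_par + g * i_perp
  if (any(denom <= 0)) {
    stop("undefined Fpol: total emission i_par + g * i_perp must be > 0",
         call. = FALSE)
  }
  fpol((i_par - g * i_perp) / denom)
}

#' Solution Fpol under vertically or horizontally polarized excitation
#'
#' With vertically polarized excitation the co-polarized channel is the
#' vertical detector, and the horizontally detected component is weighted
#' by G: \eqn{Fpol_v = (I_{vv} - G I_{vh})/(I_{vv} + G I_{vh})}. With
#' horizontally polarized excitation the roles swap and the weighting
#' inverts: \eqn{Fpol_h = (I_{hh} - G^{-1} I_{hv})/(I_{hh} + G^{-1} I_{hv})}.
#' Because Fpol is a property of the solution, not of the instrument, the
#' two must agree at the true G — which is how [solve_g_factor()] defines G.
#'
#' @param cal a [calibration_set()].
#' @param g G-factor, single positive number.
#' @return An `"fpol"` value.
#' @export
fpol_vertical <- function(cal, g) {
  stopifnot(inherits(cal, "calibration_set"))
  fpol_from_intensities(cal$i_vv, cal$i_vh, g)
}

#' @rdname fpol_vertical
#' @export
fpol_horizontal <- function(cal, g) {
  stopifnot(inherits(cal, "calibration_set"))
  g <- .check_g(g)
  fpol_from_intensities(cal$i_hh, cal$i_hv, 1 / g)
}

#' Solve for the instrument G-factor
#'
#' The G-factor is defined by the consistency condition that the solution
#' Fpol measured under vertical and horizontal excitation agree
#' (\eqn{Fpol_v = Fpol_h}). Equating the two ratios and solving gives
#' \deqn{G = \sqrt{\frac{I_{vv}\, I_{hv}}{I_{hh}\, I_{vh}}}.}
#' The achieved residual \eqn{|Fpol_v - Fpol_h|} at the returned value is
#' reported so the solution is auditable; it is zero to rounding on any
#' positive quadruple.
#'
#' @param cal a [calibration_set()] with all four intensities > 0.
#' @return An object of class `"g_factor"`: list with `value` (positive
#'   scalar), `residual` (achieved \eqn{|Fpol_v - Fpol_h|}), and
#'   `provenance` (text).
#' @export
#' @examples
#' cal <- calibration_set(i_vv = 100, i_vh = 80, i_hh = 100, i_hv = 45)
#' solve_g_factor(cal)$value  # 0.75
solve_g_factor <- function(cal) {
  stopifnot(inherits(cal, "calibration_set"))
  g <- sqrt((cal$i_vv * cal$i_hv) / (cal$i_hh * cal$i_vh))
  res <- abs(fpol_raw(fpol_vertical(cal, g)) -
             fpol_raw(fpol_horizontal(cal, g)))
  structure(
    list(value = g, residual = res,
         provenance = sprintf(
           "closed form sqrt(Ivv*Ihv/(Ihh*Ivh)) on '%s'",
           cal$solution_label)),
    class = "g_factor")
}

#' @export
print.g_factor <- function(x, ...) {
  cat(sprintf("G-factor: %.6f  (residual |Fpolv - Fpolh| = %.3g)\n",
              x$value, x$residual))
  cat("  ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Forward model: detected intensities from emission and Fpol
#'
#' Exact inverse of [fpol_from_intensities()], used by the simulator to
#' render detected channel intensities from a physical emission total and
#' a true polarization. The co-polarized channel receives
#' \eqn{E (1 + p) / 2}; the cross-polarized channel receives
#' \eqn{E (1 - p) / (2G)}, i.e. the physically perpendicular component
#' divided by the instrument bias, so that
#' \eqn{I_{\parallel} + G I_{\perp}} recovers \eqn{E} and the ratio
#' recovers \eqn{p} exactly.
#'
#' @param emission_total nonnegative emission intensity \eqn{E}
#'   (\eqn{I_{\parallel} + G I_{\perp}}), vectorized.
#' @param fpol_value true polarization: an `"fpol"` object or numeric raw
#'   ratio in \eqn{[-1, 1]}, vectorized.
#' @param g G-factor, single positive number.
#' @return List with numeric components `i_par` and `i_perp`.
#' @export
#' @examples
#' forward_intensities(160, fpol(0.25), g = 0.75)  # i_par 100, i_perp 80
forward_intensities <- function(emission_total, fpol_value, g) {
  g <- .check_g(g)
  p <- fpol_raw(fpol_value)
  if (any(!is.finite(emission_total)) || any(emission_total < 0))
    stop("emission_total must be finite and nonnegative", call. = FALSE)
  if (any(!is.finite(p)) || any(p < -1) || any(p > 1))
    stop("fpol_value raw ratio must lie in [-1, 1]", call. = FALSE)
  list(i_par = emission_total * (1 + p) / 2,
       i_perp = emission_total * (1 - p) / (2 * g))
}
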