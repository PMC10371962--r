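#' Population input function
#'
#' A parametric plasma tracer concentration curve Cp(t): a linear rise from
#' zero to a peak at `t_peak` minutes followed by a sum-of-exponentials decay,
#'
#'   Cp(t) = s * (t / t_peak) * sum(A)                      for t <  t_peak
#'   Cp(t) = s * sum(A_k * exp(-lambda_k * (t - t_peak)))   for t >= t_peak
#'
#' where `s` is a dimensionless patient-specific scale. The time integral
#' needed by the Patlak slope is available in closed form, which is what makes
#' exact noiseless Ki recovery testable. The published population curve this
#' stands in for does not print its coefficients, so the defaults here are the
#' package's own (configurable) choice of a plausible FDG-like shape.
#'
#' @param amplitudes Non-negative amplitudes A_k (same units as the tissue
#'   images, typically SUV).
#' @param rates Positive decay constants lambda_k in 1/min.
#' @param t_peak Time of peak in minutes (>= 0; 0 means no rise segment).
#' @param scale Positive multiplicative scale.
#' @return An object of class `input_function`.
#' @export
input_function <- function(amplitudes = c(5, 1.5, 1),
                           rates = c(0.5, 0.1, 0.01),
                           t_peak = 1, scale = 1) {
  amplitudes <- as.numeric(amplitudes); rates <- as.numeric(rates)
  if (length(amplitudes) != length(rates)) {
    stop("amplitudes and rates must have equal length", call. = FALSE)
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("decay rates must be positive", call. = FALSE)
  }
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0)) {
    stop("amplitudes must be non-negative", call. = FALSE)
  }
  if (!is.finite(t_peak) || t_peak < 0) stop("t_peak must be >= 0", call. = FALSE)
  if (!is.finite(scale) || scale <= 0) stop("scale must be positive", call. = FALSE)
  degenerate <- all(amplitudes == 0)
  if (degenerate) warning("all amplitudes are zero: Cp is identically 0", call. = FALSE)
  structure(list(amplitudes = amplitudes, rates = rates, t_peak = t_peak,
                 scale = scale, degenerate = degenerate),
            class = "input_function")
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("<input_function> %d exponential(s), peak %.3g min, scale %.4g\n",
              length(x$amplitudes), x$t_peak, x$scale))
  invisible(x)
}

#' Evaluate Cp(t)
#'
#' @param f An [input_function()].
#' @param t Time(s) in minutes (>= 0).
#' @return Plasma concentration(s), same length as `t`.
#' @export
if_value <- function(f, t) {
  stopifnot(inherits(f, "input_function"))
  t <- as.numeric(t)
  if (!is.null(f$constant)) return(rep(f$scale * f$constant, length(t)))
  peak <- sum(f$amplitudes)
  out <- numeric(length(t))
  pre <- t < f$t_peak & t >= 0
  if (f$t_peak > 0) out[pre] <- peak * t[pre] / f$t_peak
  post <- t >= f$t_peak
  if (any(post)) {
    dt <- t[post] - f$t_peak
    out[post] <- colSums(f$amplitudes * exp(-outer(f$rates, dt)))
  }
  f$scale * out
}

#' Evaluate the running integral of Cp from 0 to t (closed form)
#'
#' @inheritParams if_value
#' @return Integral value(s) in (concentration x min) units.
#' @export
if_integral <- function(f, t) {
  stopifnot(inherits(f, "input_function"))
  t <- as.numeric(t)
  if (!is.null(f$constant)) return(f$scale * f$constant * t)
  peak <- sum(f$amplitudes)
  out <- numeric(length(t))
  pre <- t < f$t_peak & t >= 0
  if (f$t_peak > 0) out[pre] <- peak * t[pre]^2 / (2 * f$t_peak)
  post <- t >= f$t_peak
  if (any(post)) {
    dt <- t[post] - f$t_peak
    rise <- if (f$t_peak > 0) peak * f$t_peak / 2 else 0
    decay <- colSums((f$amplitudes / f$rates) * (1 - exp(-outer(f$rates, dt))))
    out[post] <- rise + decay
  }
  f$scale * out
}

#' Scale a population input function to an image-derived blood-pool value
#'
#' Applies the single multiplicative factor that makes the curve pass through
#' the measured blood-pool concentration at the time of the routine static
#' scan: scale = blood / Cp_pop(t1). The shape (and therefore the Patlak
#' denominator, which is homogeneous of degree zero in Cp) is unchanged.
#'
#' @param f Population [input_function()].
#' @param blood_suv_t1 Image-derived blood-pool value at `t1` (> 0).
#' @param t1 Time of the static scan in minutes.
#' @return A rescaled [input_function()].
#' @export
scale_input_function <- function(f, blood_suv_t1, t1) {
  stopifnot(inherits(f, "input_function"))
  if (!is.finite(blood_suv_t1) || blood_suv_t1 <= 0) {
    stop("blood-pool value must be positive", call. = FALSE)
  }
  v <- if_value(f, t1)
  if (v <= 0) stop("population input function is zero at t1; cannot scale", call. = FALSE)
  f$scale <- f$scale * blood_suv_t1 / v
  f
}

#' Constant input function
#'
#' A degenerate member of the input-function family with Cp(t) = level for
#' all t >= 0 and integral level * t. Useful for algebraic hand checks of the
#' Patlak slope (with Cp constant the denominator reduces to t2 - t1) and for
#' calibration experiments.
#'
#' @param level Constant plasma level (> 0).
#' @return An `input_function`.
#' @export
constant_input_function <- function(level = 1) {
  if (!is.finite(level) || level <= 0) stop("level must be positive", call. = FALSE)
  structure(list(amplitudes = level, rates = numeric(0), t_peak = 0, scale = 1,
                 degenerate = FALSE, constant = level),
            class = "input_function")
}
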