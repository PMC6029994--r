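#' @title Parametric arterial input function models
#' @name aif_models
#' @description
#' Parametric building blocks for the arterial input function (AIF):
#' the Feng bolus model (gamma variate plus two exponentials), the Hill
#' parent-fraction model, the linear plasma-to-whole-blood ratio, and the
#' constrained parent AIF assembled as their product with a measured
#' whole-blood curve. All times are minutes post-injection; activities are
#' kBq/mL; rate constants are 1/min.
NULL

stop_invalid <- function(...) {
  stop(structure(class = c("simekit_invalid_parameter", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_invalid(what, " must be finite")
  invisible(x)
}

#' Feng bolus model parameters
#'
#' Six-parameter input-function model: a gamma-variate fast component plus
#' two slower exponentials,
#' \deqn{C_P(t) = (A_1 t - A_2 - A_3) e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}
#'       + A_3 e^{-\lambda_3 t}.}
#' The decay rates must be ordered \eqn{\lambda_1 > \lambda_2 > \lambda_3 > 0}
#' so the gamma-variate term is the fast (bolus) component, and the model is
#' exactly zero at \eqn{t = 0} by construction.
#'
#' @param A1 linear-rise coefficient (kBq/mL/min), > 0
#' @param A2,A3 exponential amplitudes (kBq/mL), >= 0
#' @param lambda1,lambda2,lambda3 decay rates (1/min), strictly ordered
#'   decreasing and positive
#' @return object of class `feng_params`
#' @export
#' @examples
#' p <- feng_params(120, 15, 8, 1.2, 0.3, 0.012)
#' feng_aif(p, c(0, 1, 10, 60))
feng_params <- function(A1, A2, A3, lambda1, lambda2, lambda3) {
  v <- c(A1 = A1, A2 = A2, A3 = A3,
         lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3)
  check_finite(v, "Feng parameters")
  if (A1 <= 0) stop_invalid("A1 must be > 0")
  if (A2 < 0 || A3 < 0) stop_invalid("A2 and A3 must be >= 0")
  if (!(lambda1 > lambda2 && lambda2 > lambda3 && lambda3 > 0))
    stop_invalid("decay rates must satisfy lambda1 > lambda2 > lambda3 > 0")
  structure(as.list(v), class = "feng_params")
}

#' Hill parent-fraction model parameters
#'
#' Monotone parent-fraction model
#' \deqn{f(t) = 1 - (1 - a)\, t^b / (c + t^b),}
#' decreasing from 1 at injection towards the asymptote `a` as metabolites
#' accumulate in plasma.
#'
#' @param a asymptotic parent fraction, in \[0, 1\]
#' @param b steepness exponent (dimensionless), > 0
#' @param c half-transition scale (min^b), > 0
#' @return object of class `hill_params`
#' @export
hill_params <- function(a, b, c) {
  check_finite(c(a, b, c), "Hill parameters")
  if (a < 0 || a > 1) stop_invalid("Hill 'a' must lie in [0, 1]")
  if (b <= 0) stop_invalid("Hill 'b' must be > 0")
  if (c <= 0) stop_invalid("Hill 'c' must be > 0")
  structure(list(a = a, b = b, c = c), class = "hill_params")
}

#' Plasma-to-whole-blood ratio line parameters
#'
#' The time-varying ratio of plasma to whole-blood tracer concentration,
#' modelled as a straight line \eqn{r(t) = d t + e}. Must be positive over
#' the analysis window.
#'
#' @param d slope (1/min)
#' @param e intercept (dimensionless), > 0
#' @param window analysis window (min) over which positivity is required
#' @return object of class `ratio_params`
#' @export
ratio_params <- function(d, e, window = c(0, 90)) {
  check_finite(c(d, e), "ratio parameters")
  if (e <= 0) stop_invalid("ratio intercept 'e' must be > 0")
  if (min(d * window + e) <= 0)
    stop_invalid("plasma/whole-blood ratio d*t + e must stay positive on [",
                 window[1], ", ", window[2], "] min")
  structure(list(d = d, e = e), class = "ratio_params")
}

#' Whole-blood activity curve
#'
#' A sampled whole-blood time-activity curve (image-derived or from arterial
#' samples), evaluable at arbitrary times: linear interpolation between
#' samples, zero before the first sample, and constant extrapolation of the
#' last value beyond the final sample.
#'
#' @param times sample times (min), strictly increasing
#' @param activities whole-blood concentration (kBq/mL), >= 0
#' @return object of class `whole_blood_curve`
#' @export
whole_blood_curve <- function(times, activities) {
  if (length(times) != length(activities) || length(times) < 2)
    stop_invalid("need >= 2 paired (time, activity) samples")
  check_finite(c(times, activities), "whole-blood samples")
  if (any(diff(times) <= 0)) stop_invalid("sample times must be strictly increasing")
  if (any(activities < 0)) stop_invalid("whole-blood activities must be >= 0")
  structure(list(times = as.numeric(times), activities = as.numeric(activities)),
            class = "whole_blood_curve")
}

#' @export
print.whole_blood_curve <- function(x, ...) {
  cat(sprintf("whole_blood_curve: %d samples on [%.3g, %.3g] min, peak %.4g kBq/mL\n",
              length(x$times), min(x$times), max(x$times), max(x$activities)))
  invisible(x)
}

#' Evaluate an input-function object on a time grid
#'
#' Generic dense evaluation used by the forward model. Methods exist for
#' plain functions, [feng_params], [whole_blood_curve], and the composite
#' AIF objects ([constrained_aif], the fitted AIF inside a SIME result).
#'
#' @param x an evaluable input object
#' @param t times (min)
#' @param ... passed to methods
#' @return numeric vector of concentrations at `t`
#' @export
eval_aif <- function(x, t, ...) UseMethod("eval_aif")

#' @export
eval_aif.function <- function(x, t, ...) x(t)

#' @export
eval_aif.feng_params <- function(x, t, ...) feng_aif(x, t)

#' @export
eval_aif.whole_blood_curve <- function(x, t, ...) {
  stats::approx(x$times, x$activities, xout = t, method = "linear",
                yleft = 0, yright = x$activities[length(x$activities)])$y
}

#' Evaluate the Feng input-function model
#'
#' @param p [feng_params]
#' @param t times (min), >= 0
#' @return concentrations (kBq/mL); exactly 0 at `t = 0`. Values are not
#'   clipped: parameter bounds during fitting keep the curve physical, and
#'   clipping would break Jacobian consistency.
#' @export
feng_aif <- function(p, t) {
  stopifnot(inherits(p, "feng_params"))
  if (any(t < 0)) stop_invalid("times must be >= 0")
  (p$A1 * t - p$A2 - p$A3) * exp(-p$lambda1 * t) +
    p$A2 * exp(-p$lambda2 * t) + p$A3 * exp(-p$lambda3 * t)
}

#' Evaluate the Hill parent-fraction model
#'
#' @param p [hill_params]
#' @param t times (min), >= 0
#' @return parent fractions in \[a, 1\]; exactly 1 at `t = 0`
#' @export
hill_fraction <- function(p, t) {
  stopifnot(inherits(p, "hill_params"))
  if (any(t < 0)) stop_invalid("times must be >= 0")
  tb <- t^p$b
  1 - (1 - p$a) * tb / (p$c + tb)
}

#' Evaluate the plasma-to-whole-blood ratio line
#'
#' @param p [ratio_params]
#' @param t times (min)
#' @return ratios `d*t + e`; errors if any requested value is <= 0 (a
#'   non-positive plasma/whole-blood ratio is unphysical)
#' @export
ratio_line <- function(p, t) {
  stopifnot(inherits(p, "ratio_params"))
  r <- p$d * t + p$e
  if (any(r <= 0)) stop_invalid("ratio d*t + e is non-positive on the requested grid")
  r
}

#' Constrained parent AIF
#'
#' Assembles the metabolite-free parent AIF as the product of a measured
#' whole-blood curve, the Hill parent fraction, and the linear
#' plasma-to-whole-blood ratio:
#' \deqn{C_P(t) = C_{WB}(t)\, f_{Hill}(t)\, (d t + e).}
#' This is the AIF model of the constrained SIME variant: with the
#' whole-blood curve measured, only five parameters (a, b, c, d, e) remain.
#'
#' @param wb [whole_blood_curve]
#' @param hill [hill_params]
#' @param ratio [ratio_params]
#' @return evaluable object of class `constrained_aif`
#' @export
constrained_aif <- function(wb, hill, ratio) {
  stopifnot(inherits(wb, "whole_blood_curve"), inherits(hill, "hill_params"),
            inherits(ratio, "ratio_params"))
  structure(list(wb = wb, hill = hill, ratio = ratio), class = "constrained_aif")
}

#' @export
eval_aif.constrained_aif <- function(x, t, ...) {
  constrained_parent_aif(x$wb, x$hill, x$ratio, t)
}

#' Evaluate the constrained parent AIF on a grid
#'
#' @param wb [whole_blood_curve]
#' @param h [hill_params]
#' @param r [ratio_params]
#' @param t times (min)
#' @return concentrations `C_WB(t) * f_Hill(t) * (d t + e)` (kBq/mL)
#' @export
constrained_parent_aif <- function(wb, h, r, t) {
  eval_aif(wb, t) * hill_fraction(h, t) * ratio_line(r, t)
}

#' Analytic Jacobian of an AIF model
#'
#' Closed-form partial derivatives of the AIF with respect to its free
#' parameters, evaluated on a time grid. Used to aid (and to verify) the
#' optimisation; agrees with central finite differences to high accuracy
#' at well-scaled points.
#'
#' For `model = "feng"` the columns are the derivatives with respect to
#' (A1, A2, A3, lambda1, lambda2, lambda3); for `model = "constrained"`
#' with respect to (a, b, c, d, e), the whole-blood curve being a fixed
#' measurement.
#'
#' @param model `"feng"` or `"constrained"`
#' @param params [feng_params], or for the constrained model a list with
#'   elements `hill` ([hill_params]) and `ratio` ([ratio_params])
#' @param t times (min)
#' @param wb [whole_blood_curve], required for the constrained model
#' @return numeric matrix, `length(t)` rows, one named column per parameter
#' @export
aif_jacobian <- function(model, params, t, wb = NULL) {
  model <- match.arg(model, c("feng", "constrained"))
  if (model == "feng") {
    p <- params
    stopifnot(inherits(p, "feng_params"))
    e1 <- exp(-p$lambda1 * t); e2 <- exp(-p$lambda2 * t); e3 <- exp(-p$lambda3 * t)
    cbind(A1 = t * e1,
          A2 = e2 - e1,
          A3 = e3 - e1,
          lambda1 = -t * (p$A1 * t - p$A2 - p$A3) * e1,
          lambda2 = -t * p$A2 * e2,
          lambda3 = -t * p$A3 * e3)
  } else {
    h <- params$hill; r <- params$ratio
    stopifnot(inherits(h, "hill_params"), inherits(r, "ratio_params"),
              inherits(wb, "whole_blood_curve"))
    cw <- eval_aif(wb, t)
    rt <- ratio_line(r, t)
    tb <- t^h$b
    den <- h$c + tb
    f <- 1 - (1 - h$a) * tb / den
    # d f / d b involves t^b * log(t); the t = 0 limit is 0 for b > 0
    lt <- ifelse(t > 0, log(t), 0)
    df_da <- tb / den
    df_db <- -(1 - h$a) * h$c * tb * lt / den^2
    df_dc <- (1 - h$a) * tb / den^2
    cbind(a = cw * rt * df_da,
          b = cw * rt * df_db,
          c = cw * rt * df_dc,
          d = cw * f * t,
          e = cw * f)
  }
}
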