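#' @title Blood-sample metabolite correction (gold-standard path)
#' @name blood
#' @description
#' The invasive reference workflow: fit the Hill function to measured
#' parent fractions, fit the plasma-to-whole-blood ratio line, and
#' assemble the metabolite-corrected AIF from arterial samples with an
#' optional rigid delay shift.
NULL

#' Arterial blood sample set
#'
#' @param times sample times (min), strictly increasing
#' @param wholeblood whole-blood activity (kBq/mL), >= 0
#' @param plasma plasma activity (kBq/mL), >= 0
#' @param pf_times metabolite-sample times (min)
#' @param pf parent-fraction measurements in \[0, 1\] at `pf_times`
#' @return object of class `blood_sample_set`
#' @export
blood_sample_set <- function(times, wholeblood, plasma, pf_times, pf) {
  if (length(times) != length(wholeblood) || length(times) != length(plasma))
    stop_invalid("times, wholeblood and plasma must have equal length")
  if (length(pf_times) != length(pf))
    stop_invalid("pf_times and pf must have equal length")
  check_finite(c(times, wholeblood, plasma, pf_times, pf), "blood samples")
  if (any(diff(times) <= 0)) stop_invalid("sample times must be strictly increasing")
  if (any(wholeblood < 0) || any(plasma < 0))
    stop_invalid("activities must be >= 0")
  if (any(pf < 0 | pf > 1)) stop_invalid("parent fractions must lie in [0, 1]")
  structure(list(times = as.numeric(times), wholeblood = as.numeric(wholeblood),
                 plasma = as.numeric(plasma), pf_times = as.numeric(pf_times),
                 pf = as.numeric(pf)), class = "blood_sample_set")
}

#' Fit the Hill function to measured parent fractions
#'
#' Unweighted bounded least squares of the three Hill parameters against
#' the measured fractions, initialised from a coarse (a, b, c) grid so the
#' fit is deterministic.
#'
#' @param times metabolite-sample times (min), >= 3 samples
#' @param fractions measured parent fractions in \[0, 1\]
#' @return [hill_params] with attributes `residuals` (per-sample) and
#'   `objective`
#' @export
fit_hill_to_samples <- function(times, fractions) {
  if (length(times) < 3)
    stop_invalid("need >= 3 samples to fit 3 Hill parameters")
  if (length(times) != length(fractions)) stop_invalid("length mismatch")
  check_finite(c(times, fractions), "parent-fraction samples")
  if (stats::sd(fractions) < 1e-12)
    stop_invalid("degenerate fit: all parent fractions identical ",
                 "(no metabolism signal; 'a' unidentifiable)")
  fn <- function(p) sum((1 - (1 - p[1]) * times^p[2] / (p[3] + times^p[2]) -
                           fractions)^2)
  grid <- expand.grid(a = c(0.05, 0.2, 0.4, 0.7), b = c(0.5, 1, 2, 4),
                      c = c(2, 10, 30, 100, 300))
  g <- grid[which.min(apply(grid, 1, fn)), ]
  ctrl <- list(iter.max = 500, eval.max = 2000, rel.tol = 1e-15,
               x.tol = 1e-14)
  fit <- stats::nlminb(c(g$a, g$b, g$c), fn, lower = c(0, 1e-3, 1e-3),
                       upper = c(1, 10, 1e4), control = ctrl)
  # one restart polishes the last digits (PORT quasi-Newton memory reset)
  fit <- stats::nlminb(fit$par, fn, lower = c(0, 1e-3, 1e-3),
                       upper = c(1, 10, 1e4), control = ctrl)
  out <- hill_params(fit$par[1], fit$par[2], fit$par[3])
  attr(out, "residuals") <- hill_fraction(out, times) - fractions
  attr(out, "objective") <- fit$objective
  out
}

#' Fit the plasma-to-whole-blood ratio line
#'
#' Ordinary least-squares straight line through the per-sample ratios
#' plasma/wholeblood versus time.
#'
#' @param times sample times (min), >= 2
#' @param plasma plasma activities (kBq/mL)
#' @param wholeblood whole-blood activities (kBq/mL), > 0 at every sample
#' @return [ratio_params]
#' @export
fit_ratio_to_samples <- function(times, plasma, wholeblood) {
  if (length(times) < 2) stop_invalid("need >= 2 samples to fit a line")
  if (length(times) != length(plasma) || length(times) != length(wholeblood))
    stop_invalid("length mismatch")
  if (any(wholeblood <= 0))
    stop_invalid("whole-blood activity must be > 0 at every used sample")
  r <- plasma / wholeblood
  if (length(times) == 2) {
    d <- (r[2] - r[1]) / (times[2] - times[1])
    e <- r[1] - d * times[1]
  } else {
    co <- stats::coef(stats::lm(r ~ times))
    d <- unname(co[2]); e <- unname(co[1])
  }
  ratio_params(d, e)
}

#' Metabolite-corrected AIF from arterial samples
#'
#' Builds the gold-standard parent AIF
#' \eqn{C_P(t) = C_{WB}(t) f_{Hill}(t) (d t + e)} from a full arterial
#' sample set: the whole-blood curve is interpolated from the samples, the
#' Hill function is fitted to the measured parent fractions, and the ratio
#' line to the plasma/whole-blood pairs. A rigid time shift (usually
#' negative, to correct the radial-artery-to-brain delay so the curve
#' matches the first PET frame) is applied to the blood time axis; no
#' dispersion correction is performed.
#'
#' @param samples [blood_sample_set]
#' @param delay_shift rigid shift added to the blood sample times (min)
#' @return evaluable object of class `sample_aif` with elements `wb`,
#'   `hill`, `ratio`, `delay_shift`
#' @export
sample_based_aif <- function(samples, delay_shift = 0) {
  stopifnot(inherits(samples, "blood_sample_set"))
  t_shift <- samples$times + delay_shift
  keep <- t_shift >= 0
  if (sum(keep) < 2)
    stop_invalid("delay shift moves the samples out of the analysis window")
  wb <- whole_blood_curve(t_shift[keep], samples$wholeblood[keep])
  hill <- fit_hill_to_samples(samples$pf_times + delay_shift, samples$pf)
  # the plasma/whole-blood ratio is undefined where whole blood is zero
  # (pre-arrival samples); those are excluded from the line fit
  pos <- keep & samples$wholeblood > 0
  if (sum(pos) < 2)
    stop_invalid("need >= 2 samples with positive whole-blood activity")
  ratio <- fit_ratio_to_samples(samples$times[pos] + delay_shift,
                                samples$plasma[pos],
                                samples$wholeblood[pos])
  structure(list(wb = wb, hill = hill, ratio = ratio,
                 delay_shift = delay_shift), class = "sample_aif")
}

#' @export
eval_aif.sample_aif <- function(x, t, ...) {
  constrained_parent_aif(x$wb, x$hill, x$ratio, t)
}

#' Trapezoid area under a sampled curve
#'
#' AUC of the piecewise-linear interpolant over a window, with the window
#' endpoints interpolated if they fall between samples. The conventional
#' split for bolus curves is a peak window \[0, 3\] min and a tail window
#' \[3, 90\] min.
#'
#' @param values curve values
#' @param times sample times (min), strictly increasing
#' @param window `c(t0, t1)` integration window, within the sampled domain
#' @return area (value units x min)
#' @export
curve_auc <- function(values, times, window = range(times)) {
  if (length(values) != length(times) || length(times) < 2)
    stop_invalid("need >= 2 paired (time, value) samples")
  if (any(diff(times) <= 0)) stop_invalid("times must be strictly increasing")
  if (window[2] <= window[1]) stop_invalid("empty integration window")
  if (window[1] < times[1] - 1e-9 || window[2] > times[length(times)] + 1e-9)
    stop_invalid("window outside the sampled domain")
  inner <- times > window[1] & times < window[2]
  pts <- c(window[1], times[inner], window[2])
  vals <- stats::approx(times, values, xout = pts)$y
  sum(diff(pts) * (vals[-length(vals)] + vals[-1]) / 2)
}
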