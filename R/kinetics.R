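#' @title Two-tissue compartment forward model
#' @name kinetics
#' @description
#' The irreversible-free/bound two-tissue compartment (2-TC) model used to
#' relate the parent AIF to regional PET time-activity curves: analytic
#' impulse response, exact convolution with a piecewise-linear input, the
#' fractional-blood-volume term, frame averaging over the acquisition
#' schedule, and the macroparameters V_T and BP_ND.
NULL

#' Kinetic parameters of the 2-TC model for one region
#'
#' @param K1 plasma-to-tissue transfer (mL/cm^3/min), > 0
#' @param k2,k3,k4 rate constants (1/min), >= 0
#' @param vb fractional cerebral blood volume, in \[0, 1); fixed at 0.05 by
#'   default and excluded from all fits
#' @return object of class `kinetic_params`
#' @export
#' @examples
#' kp <- kinetic_params(0.2, 0.1, 0.06, 0.03)
#' volume_of_distribution(kp)  # 2 * (1 + 2) = 6
kinetic_params <- function(K1, k2, k3, k4, vb = 0.05) {
  check_finite(c(K1, k2, k3, k4, vb), "kinetic parameters")
  if (K1 <= 0) stop_invalid("K1 must be > 0")
  if (k2 < 0 || k3 < 0 || k4 < 0) stop_invalid("k2, k3, k4 must be >= 0")
  if (vb < 0 || vb >= 1) stop_invalid("vb must lie in [0, 1)")
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vb = vb),
            class = "kinetic_params")
}

#' Dynamic-PET frame schedule
#'
#' Contiguous, non-overlapping acquisition frames. Frame mid-times are
#' `t_j = start_j + dur_j / 2`, so each frame spans
#' `[t_j - dur_j/2, t_j + dur_j/2]`.
#'
#' @param starts frame start times (min)
#' @param durations frame durations (min), > 0
#' @return object of class `frame_schedule` with elements `starts`,
#'   `durations`, `mids`, `ends`, `t_end`
#' @export
frame_schedule <- function(starts, durations) {
  check_finite(c(starts, durations), "frame schedule")
  if (length(starts) != length(durations) || length(starts) < 1)
    stop_invalid("starts and durations must be equal-length, non-empty")
  if (any(durations <= 0)) stop_invalid("frame durations must be > 0")
  ends <- starts + durations
  if (length(starts) > 1 &&
      any(abs(starts[-1] - ends[-length(ends)]) > 1e-9))
    stop_invalid("frames must be contiguous and non-overlapping")
  structure(list(starts = as.numeric(starts), durations = as.numeric(durations),
                 mids = as.numeric(starts + durations / 2),
                 ends = as.numeric(ends), t_end = ends[length(ends)]),
            class = "frame_schedule")
}

#' The default 35-frame, 90-minute schedule
#'
#' 6 x 5 s, 10 x 15 s, 4 x 30 s, 5 x 2 min, 5 x 5 min, 5 x 10 min.
#'
#' @return a [frame_schedule] of 35 frames totalling 90 min
#' @export
default_frame_schedule <- function() {
  durations <- c(rep(5 / 60, 6), rep(15 / 60, 10), rep(30 / 60, 4),
                 rep(2, 5), rep(5, 5), rep(10, 5))
  frame_schedule(cumsum(c(0, durations[-length(durations)])), durations)
}

#' Regional time-activity curve
#'
#' @param region region label (e.g. "cerebellum", "parietal", "hippocampus",
#'   "striatum", or free text)
#' @param schedule [frame_schedule]
#' @param values frame-averaged activity concentrations (kBq/mL), one per frame
#' @return object of class `region_tac`
#' @export
region_tac <- function(region, schedule, values) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(values) != length(schedule$starts))
    stop_invalid("need exactly one TAC value per frame")
  check_finite(values, "TAC values")
  structure(list(region = as.character(region), schedule = schedule,
                 values = as.numeric(values)), class = "region_tac")
}

#' @export
print.region_tac <- function(x, ...) {
  cat(sprintf("region_tac '%s': %d frames over %.3g min, peak %.4g kBq/mL\n",
              x$region, length(x$values), x$schedule$t_end, max(x$values)))
  invisible(x)
}

# Decompose h(t) into exponential terms: list(cc, alpha) for c*exp(-a t)
# terms and (tcc, talpha) for c*t*exp(-a t) terms. Repeated root
# (discriminant < 1e-12, requires k3 = 0 and k2 = k4) uses the analytic
# limit h = K1 e^{-at}[1 + (k3 + k4 - a) t].
h_terms <- function(kp) {
  s <- kp$k2 + kp$k3 + kp$k4
  disc <- s^2 - 4 * kp$k2 * kp$k4
  if (disc < 1e-12) {
    a <- s / 2
    list(cc = kp$K1, alpha = a,
         tcc = kp$K1 * (kp$k3 + kp$k4 - a), talpha = a)
  } else {
    sq <- sqrt(disc)
    a1 <- (s - sq) / 2
    a2 <- (s + sq) / 2
    list(cc = kp$K1 * c(kp$k3 + kp$k4 - a1, a2 - kp$k3 - kp$k4) / sq,
         alpha = c(a1, a2), tcc = NULL, talpha = NULL)
  }
}

#' Impulse response of the 2-TC model
#'
#' Analytic tissue impulse response
#' \deqn{h(t) = \frac{K_1}{\alpha_2 - \alpha_1}\left[(k_3 + k_4 - \alpha_1)
#'   e^{-\alpha_1 t} + (\alpha_2 - k_3 - k_4) e^{-\alpha_2 t}\right]}
#' with \eqn{\alpha_{1,2} = [(k_2+k_3+k_4) \mp \sqrt{(k_2+k_3+k_4)^2 -
#' 4 k_2 k_4}]/2}; the repeated-root degeneracy is handled by the analytic
#' limit form. `h(0) = K1` always, and for `k4 > 0` the total integral is
#' `K1/k2 * (1 + k3/k4)`, i.e. V_T.
#'
#' @param kp [kinetic_params]
#' @param t times (min), >= 0
#' @return response values (same time scale as the rate constants)
#' @export
impulse_response <- function(kp, t) {
  stopifnot(inherits(kp, "kinetic_params"))
  if (any(t < 0)) stop_invalid("times must be >= 0")
  tr <- h_terms(kp)
  h <- rep(0, length(t))
  for (i in seq_along(tr$cc))
    h <- h + tr$cc[i] * exp(-tr$alpha[i] * t)
  for (i in seq_along(tr$tcc))
    h <- h + tr$tcc[i] * t * exp(-tr$talpha[i] * t)
  h
}

# Tissue curve (C_P convolved with h) on a uniform grid of step dt.
# The convolution with each exponential (or t-times-exponential) term of h
# is exact for the piecewise-linear sampled input; the one-pass recursions
# live in src/conv.cpp.
conv_tissue <- function(cp, dt, kp) {
  tr <- h_terms(kp)
  conv_terms_cpp(cp, dt, tr$cc, tr$alpha,
                 tr$tcc %||% numeric(0), tr$talpha %||% numeric(0))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Weight matrix mapping a curve sampled on tgrid to frame averages:
# row f gives (1/dur_f) * integral over [start_f, end_f] of the
# piecewise-linear interpolant, as a linear form in the grid values.
frame_weight_matrix <- function(tgrid, schedule) {
  n <- length(tgrid)
  nf <- length(schedule$starts)
  W <- matrix(0, nf, n)
  for (f in seq_len(nf)) {
    a <- schedule$starts[f]; b <- schedule$ends[f]
    if (a < tgrid[1] - 1e-9 || b > tgrid[n] + 1e-9)
      stop_invalid("frame [", a, ", ", b, "] outside the evaluation grid")
    inner <- which(tgrid > a + 1e-12 & tgrid < b - 1e-12)
    pts <- c(a, tgrid[inner], b)
    # trapezoid weights on the point set
    dp <- diff(pts)
    tw <- c(dp / 2, 0) + c(0, dp / 2)
    w <- rep(0, n)
    if (length(inner)) w[inner] <- tw[seq_along(inner) + 1]
    # distribute endpoint weights onto bracketing grid nodes
    for (end in c(1, length(pts))) {
      k <- findInterval(pts[end], tgrid, rightmost.closed = TRUE)
      k <- min(max(k, 1), n - 1)
      th <- (pts[end] - tgrid[k]) / (tgrid[k + 1] - tgrid[k])
      w[k] <- w[k] + tw[end] * (1 - th)
      w[k + 1] <- w[k + 1] + tw[end] * th
    }
    W[f, ] <- w / schedule$durations[f]
  }
  W
}

# Sparse triplets of a frame-weight matrix sorted by grid-node index,
# as consumed by the fused convolution + frame-average C++ kernel.
frame_weights_sorted <- function(W) {
  nz <- which(W != 0)
  nf <- nrow(W)
  fid <- (nz - 1L) %% nf + 1L
  idx <- (nz - 1L) %/% nf + 1L
  o <- order(idx)
  list(wv = W[nz][o], idx = as.integer(idx[o]), fid = as.integer(fid[o]))
}

# Sparse applicator for a frame-weight matrix: each grid node carries
# weight in at most two frames, so the dense matrix-vector product is
# replaced by a grouped sum over the nonzeros.
frame_average_sparse <- function(W) {
  nz <- which(W != 0)
  nf <- nrow(W)
  fid <- (nz - 1L) %% nf + 1L
  idx <- (nz - 1L) %/% nf + 1L
  wv <- W[nz]
  idx <- as.integer(idx)
  fid <- as.integer(fid)
  function(E) frame_avg_cpp(E, wv, idx, fid, nf)
}

#' Model-predicted frame-averaged TAC
#'
#' Computes the instantaneous tissue output
#' \deqn{E(t) = (1 - V_b)\,(C_P \ast h)(t) + V_b\, C_{WB}(t)}
#' on a uniform fine grid and averages it over each acquisition frame,
#' \eqn{\bar E(t_j) = (1/\Delta t_j) \int_{t_j^-}^{t_j^+} E(s)\,ds}.
#' The convolution is exact for the piecewise-linear sampled input, so the
#' only discretisation error is the linear interpolation of `parent` and
#' `wb` at step `step`. In original-SIME mode (no measured whole-blood
#' curve) pass `wb = NULL`: the parent AIF then also fills the blood-volume
#' term.
#'
#' @param parent evaluable parent AIF (see [eval_aif])
#' @param wb evaluable whole-blood curve, or `NULL` to substitute the parent
#' @param kp [kinetic_params]
#' @param schedule [frame_schedule]
#' @param step fine-grid step (min); default 0.01
#' @return a [region_tac] (region label `"model"`)
#' @export
model_tac <- function(parent, wb, kp, schedule, step = 0.01) {
  stopifnot(inherits(kp, "kinetic_params"), inherits(schedule, "frame_schedule"))
  # uniform grid covering the schedule (the convolution recursion assumes
  # a constant step, so the end point is rounded up, never appended)
  tgrid <- seq_len(ceiling(schedule$t_end / step - 1e-9) + 1L) * step - step
  cp <- eval_aif(parent, tgrid)
  cwb <- if (is.null(wb)) cp else eval_aif(wb, tgrid)
  E <- (1 - kp$vb) * conv_tissue(cp, step, kp) + kp$vb * cwb
  W <- frame_weight_matrix(tgrid, schedule)
  region_tac("model", schedule, as.numeric(W %*% E))
}

#' Total volume of distribution
#'
#' \deqn{V_T = \frac{K_1}{k_2}\left(1 + \frac{k_3}{k_4}\right)}
#' (mL/cm^3), the equilibrium tissue-to-plasma concentration ratio; equals
#' the total integral of the 2-TC impulse response.
#'
#' @param kp [kinetic_params]
#' @return V_T (mL/cm^3)
#' @export
volume_of_distribution <- function(kp) {
  stopifnot(inherits(kp, "kinetic_params"))
  if (kp$k2 <= 0 || kp$k4 <= 0)
    stop_invalid("V_T undefined: k2 and k4 must be > 0")
  kp$K1 / kp$k2 * (1 + kp$k3 / kp$k4)
}

#' Non-displaceable binding potential
#'
#' \deqn{BP_{ND} = (V_T - V_{ND}) / V_{ND}} with V_ND the volume of
#' distribution of a reference region devoid of specific binding (the
#' cerebellum in this tracer's analysis).
#'
#' @param v_t V_T of the target region (mL/cm^3)
#' @param v_nd V_T of the reference region (mL/cm^3), > 0
#' @return BP_ND (dimensionless)
#' @export
binding_potential <- function(v_t, v_nd) {
  if (any(v_nd <= 0)) stop_invalid("reference V_ND must be > 0")
  (v_t - v_nd) / v_nd
}
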