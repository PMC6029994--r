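#' @title Synthetic dynamic-PET study generator
#' @name synthetic
#' @description
#' Generates fully synthetic serotonin-receptor-like studies for parameter
#' recovery experiments: a bolus-shaped true parent AIF (Feng model), a
#' whole-blood curve consistent with it through the Hill parent fraction
#' and the linear plasma/whole-blood ratio, four regional TACs
#' (low/moderate/moderate/high binding) on the 35-frame, 90-min schedule,
#' frame-duration-scaled Gaussian noise, and test-retest cohorts.
NULL

# TAC noise: Gaussian with sd = scale * sqrt(max(mean, floor) / frame
# duration); the 1/duration factor gives long late frames lower relative
# noise, as in count-limited PET. Scales are a stated design choice.
noise_scales <- c(none = 0, low = 0.15, mid = 0.35, high = 0.7)
pf_noise_sd <- c(none = 0, low = 0.01, mid = 0.02, high = 0.04)
NOISE_FLOOR <- 0.1  # kBq/mL, so zero-activity frames keep nonzero variance

#' Ground-truth parameter set for a synthetic study
#'
#' Deterministic named profiles. The `"default"` profile uses a bolus with
#' its peak near 0.9 min, a parent fraction falling towards 0.25, a gently
#' rising plasma/whole-blood ratio, and four regions whose true binding
#' potentials relative to the cerebellum are 0 / 0.42 / 0.90 / 3.50
#' (low, moderate, moderate, high binding — the magnitudes reported for
#' this tracer class). The `"flat"` profile gives all regions the
#' cerebellar kinetics, so every true BP_ND is 0.
#'
#' @param profile `"default"` or `"flat"`
#' @param seed stored for provenance (the profile itself is deterministic)
#' @return object of class `study_truth`: `feng`, `hill`, `ratio`,
#'   `kinetics` (named list of [kinetic_params]), `profile`, `seed`
#' @export
generate_truth <- function(profile = c("default", "flat"), seed = 1) {
  profile <- match.arg(profile)
  feng <- feng_params(A1 = 120, A2 = 15, A3 = 8,
                      lambda1 = 1.2, lambda2 = 0.3, lambda3 = 0.012)
  hill <- hill_params(a = 0.25, b = 1.7, c = 25)
  ratio <- ratio_params(d = 0.001, e = 1.05)
  cer <- kinetic_params(0.22, 0.11, 0.015, 0.05)      # V_T = 2.6
  v_nd <- volume_of_distribution(cer)
  mk <- function(K1, bp) {
    # K1/k2 = 2 in every region, so BP_ND is set purely by k3/k4
    k4 <- 0.05
    k3 <- k4 * (v_nd * (1 + bp) / (K1 / (K1 / 2)) - 1)
    kinetic_params(K1, K1 / 2, k3, k4)
  }
  kin <- if (profile == "default")
    list(cerebellum = cer, parietal = mk(0.25, 0.42),
         hippocampus = mk(0.20, 0.90), striatum = mk(0.30, 3.50))
  else list(cerebellum = cer, parietal = cer, hippocampus = cer,
            striatum = cer)
  structure(list(feng = feng, hill = hill, ratio = ratio, kinetics = kin,
                 profile = profile, seed = seed), class = "study_truth")
}

# blood sampling grid: 5-s intervals through the bolus, then progressively
# sparser out to 90 min (mimics dense early arterial sampling)
wb_sample_times <- function(t_end = 90) {
  t <- c(seq(0, 2, by = 5 / 60), seq(2.25, 5, by = 0.25),
         seq(5.5, 10, by = 0.5), seq(11, 20, by = 1),
         seq(22.5, t_end, by = 2.5))
  t[t <= t_end]
}

metabolite_sample_times <- function() c(3.5, 10, 17.5, 32.5, 55, 85)

#' Generate one synthetic study from a ground truth
#'
#' The true parent AIF is the Feng curve; the whole-blood curve is derived
#' by inverting the product model, `C_WB = C_P / (f_Hill * ratio)`, and
#' sampled on a dense early grid, so the constrained AIF model is exactly
#' well-specified for recovery tests. Regional TACs are the 2-TC forward
#' model driven by the product AIF built from the sampled whole-blood
#' curve, frame-averaged on the default 35-frame schedule, plus Gaussian
#' noise with variance proportional to mean / frame duration. The six
#' metabolite samples are emitted at 3.5, 10, 17.5, 32.5, 55 and 85 min
#' with optional fraction noise (clamped to \[0, 1\]).
#'
#' @param truth [study_truth]
#' @param noise `"none"`, `"low"`, `"mid"` or `"high"`
#' @param seed RNG seed for the noise draws
#' @param schedule [frame_schedule]; default the 35-frame, 90-min schedule
#' @param step fine-grid step for TAC generation (min)
#' @return object of class `synthetic_study`: `truth`, `wb`
#'   ([whole_blood_curve]), `samples` ([blood_sample_set]), `tacs` (named
#'   list of [region_tac]), `schedule`, `noise`, `seed`
#' @export
generate_study <- function(truth, noise = c("none", "low", "mid", "high"),
                           seed = 1, schedule = default_frame_schedule(),
                           step = 0.01) {
  stopifnot(inherits(truth, "study_truth"))
  noise <- match.arg(noise)
  ts <- wb_sample_times(schedule$t_end)
  denom <- hill_fraction(truth$hill, ts) * ratio_line(truth$ratio, ts)
  if (any(denom <= 0)) stop_invalid("f_Hill * ratio vanishes on the blood grid")
  cp_s <- feng_aif(truth$feng, ts)
  wb <- whole_blood_curve(ts, cp_s / denom)
  parent <- constrained_aif(wb, truth$hill, truth$ratio)

  clean <- lapply(truth$kinetics, function(kp)
    model_tac(parent, wb, kp, schedule, step = step))
  scale <- noise_scales[[noise]]
  tacs <- with_seed(seed, lapply(names(clean), function(rg) {
    mu <- clean[[rg]]$values
    sd <- scale * sqrt(pmax(mu, NOISE_FLOOR) / schedule$durations)
    region_tac(rg, schedule, mu + stats::rnorm(length(mu), 0, sd))
  }))
  names(tacs) <- names(clean)

  pf_t <- metabolite_sample_times()
  pf_t <- pf_t[pf_t <= schedule$t_end]
  pf_true <- hill_fraction(truth$hill, pf_t)
  pf <- with_seed(seed + 1L, pmin(pmax(
    pf_true + stats::rnorm(length(pf_t), 0, pf_noise_sd[[noise]]), 0), 1))
  samples <- blood_sample_set(ts, wb$activities,
                              wb$activities * ratio_line(truth$ratio, ts),
                              pf_t, pf)
  structure(list(truth = truth, wb = wb, samples = samples, tacs = tacs,
                 schedule = schedule, noise = noise, seed = seed,
                 subject = NA_integer_, scan = NA_integer_),
            class = "synthetic_study")
}

#' Generate a cohort of synthetic studies
#'
#' Per-subject ground truths are drawn by jittering every regional rate
#' constant of the profile truth log-normally with 15% coefficient of
#' variation (the AIF shape and metabolite parameters are shared across
#' subjects). With `test_retest = TRUE` each subject contributes two
#' studies with the identical truth but independent noise realisations,
#' emulating same-day test-retest scanning.
#'
#' @param n_subjects number of subjects, >= 1
#' @param test_retest if `TRUE`, two studies per subject sharing the truth
#' @param seed master seed; sub-seeds for jitter and noise derive from it
#' @param profile truth profile passed to [generate_truth]
#' @param noise noise level passed to [generate_study]
#' @return list of [generate_study] results with `subject` and `scan` set
#' @export
generate_cohort <- function(n_subjects, test_retest = FALSE, seed = 1,
                            profile = "default", noise = "mid") {
  if (n_subjects < 1) stop_invalid("n_subjects must be >= 1")
  base <- generate_truth(profile, seed)
  sdlog <- sqrt(log(1 + 0.15^2))
  n_scans <- if (test_retest) 2L else 1L
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      n_subjects * (n_scans + 1L)))
  out <- list()
  for (s in seq_len(n_subjects)) {
    truth_s <- with_seed(seeds[s], {
      kin <- lapply(base$kinetics, function(kp) {
        f <- stats::rlnorm(4, meanlog = -sdlog^2 / 2, sdlog = sdlog)
        kinetic_params(kp$K1 * f[1], kp$k2 * f[2], kp$k3 * f[3],
                       kp$k4 * f[4], vb = kp$vb)
      })
      structure(list(feng = base$feng, hill = base$hill, ratio = base$ratio,
                     kinetics = kin, profile = profile, seed = seeds[s]),
                class = "study_truth")
    })
    for (sc in seq_len(n_scans)) {
      st <- generate_study(truth_s, noise,
                           seed = seeds[n_subjects + (s - 1L) * n_scans + sc])
      st$subject <- s
      st$scan <- sc
      out[[length(out) + 1L]] <- st
    }
  }
  out
}

#' Apply a calibration bias to a whole-blood curve
#'
#' Emulates image-derived input-function failure modes (e.g. partial-volume
#' under-correction): a uniform multiplicative bias, or a bias confined to
#' the bolus peak.
#'
#' @param wb [whole_blood_curve]
#' @param bias either a positive scalar (uniform factor) or a list with
#'   `type` (`"uniform"` or `"peak"`), `factor` (> 0) and for `"peak"` an
#'   optional `t_split` (min, default 3) before which the factor applies
#' @return biased [whole_blood_curve]
#' @export
perturb_wb <- function(wb, bias) {
  stopifnot(inherits(wb, "whole_blood_curve"))
  if (is.numeric(bias)) bias <- list(type = "uniform", factor = bias)
  if (is.null(bias$factor) || bias$factor <= 0)
    stop_invalid("bias factor must be > 0")
  act <- wb$activities
  if (identical(bias$type, "uniform")) {
    act <- act * bias$factor
  } else if (identical(bias$type, "peak")) {
    t_split <- if (is.null(bias$t_split)) 3 else bias$t_split
    act <- ifelse(wb$times < t_split, act * bias$factor, act)
  } else stop_invalid("unknown bias type '", bias$type, "'")
  whole_blood_curve(wb$times, act)
}

#' True theta vector of a synthetic study
#'
#' Packs the generating parameters in [sime_cost] order for the requested
#' mode (constrained: a, b, c, d, e then the four rate constants per
#' region; original mode packs the true Feng parameters instead).
#'
#' @param study [generate_study] result
#' @param mode `"constrained"` or `"original"`
#' @return named numeric vector
#' @export
true_theta <- function(study, mode = c("constrained", "original")) {
  mode <- match.arg(mode)
  tr <- study$truth
  phi <- if (mode == "constrained")
    c(a = tr$hill$a, b = tr$hill$b, c = tr$hill$c,
      d = tr$ratio$d, e = tr$ratio$e)
  else unlist(tr$feng)
  kin <- unlist(lapply(tr$kinetics, function(k) c(k$K1, k$k2, k$k3, k$k4)))
  c(phi, kin)
}

#' Per-study V_T estimates for a cohort by individual refitting
#'
#' Refits every region of every study against a fixed AIF and tabulates
#' the resulting V_T. The `"true"` AIF isolates TAC-noise effects (used in
#' test-retest reliability simulations); `"sample"` uses the study's own
#' noiseless blood samples through [sample_based_aif].
#'
#' @param cohort list of synthetic studies
#' @param aif `"true"` or `"sample"`
#' @param config [sime_config]
#' @return data.frame with columns `subject`, `scan`, `region`, `vt`
#' @export
cohort_vt_refit <- function(cohort, aif = c("true", "sample"),
                            config = sime_config()) {
  aif <- match.arg(aif)
  rows <- list()
  for (st in cohort) {
    parent <- if (aif == "true")
      constrained_aif(st$wb, st$truth$hill, st$truth$ratio)
    else sample_based_aif(st$samples)
    for (rg in names(st$tacs)) {
      kp <- refit_individual(st$tacs[[rg]], parent, st$wb, config)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = st$subject, scan = st$scan, region = rg,
        vt = volume_of_distribution(kp))
    }
  }
  do.call(rbind, rows)
}
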