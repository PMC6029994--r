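test_that("impulse_response limits: h(0) = K1, one-tissue degeneracy, repeated root", {
  set.seed(3)
  for (i in 1:20) {
    kp <- random_kp()
    expect_equal(impulse_response(kp, 0), kp$K1)
  }
  # k3 = k4 = 0: pure one-tissue washout K1 exp(-k2 t)
  kp1 <- kinetic_params(0.3, 0.2, 0, 0)
  tt <- seq(0, 60, by = 0.5)
  expect_equal(impulse_response(kp1, tt), 0.3 * exp(-0.2 * tt), tolerance = 1e-12)
  # repeated root (k3 = 0, k2 = k4) continuous with a nearby distinct-root case
  kr <- kinetic_params(0.2, 0.1, 0, 0.1)
  kn <- kinetic_params(0.2, 0.1 + 1e-7, 0, 0.1)
  expect_equal(impulse_response(kr, tt), impulse_response(kn, tt),
               tolerance = 1e-5)
})

test_that("impulse_response matches the RK4 ODE oracle", {
  kp <- kinetic_params(0.2, 0.15, 0.05, 0.03)
  tt <- seq(0.25, 90, by = 0.25)
  h <- impulse_response(kp, tt)
  h_ode <- rk4_impulse_oracle(kp$K1, kp$k2, kp$k3, kp$k4, tt)
  expect_lt(sqrt(sum((h - h_ode)^2) / sum(h_ode^2)), 1e-4)
})

test_that("volume_of_distribution closed form, quadrature oracle and errors", {
  expect_equal(volume_of_distribution(kinetic_params(0.2, 0.1, 0.06, 0.03)), 6)
  kp0 <- kinetic_params(0.3, 0.2, 1e-12, 0.05)
  expect_equal(volume_of_distribution(kp0), 0.3 / 0.2, tolerance = 1e-9)
  expect_error(volume_of_distribution(kinetic_params(0.2, 0, 0.05, 0.03)),
               "undefined")
  expect_error(volume_of_distribution(kinetic_params(0.2, 0.1, 0.05, 0)),
               "undefined")
  # V_T equals the integral of the impulse response (adaptive quadrature)
  set.seed(21)
  for (i in 1:10) {
    kp <- random_kp()
    q <- stats::integrate(function(t) impulse_response(kp, t), 0, Inf,
                          rel.tol = 1e-10)$value
    expect_lt(abs(q / volume_of_distribution(kp) - 1), 1e-6)
  }
})

test_that("binding_potential arithmetic and guards", {
  expect_identical(binding_potential(2, 2), 0)
  expect_identical(binding_potential(4, 2), 1)
  expect_equal(binding_potential(9, 2), 3.5)
  expect_error(binding_potential(1, 0), "V_ND")
})

test_that("frame schedule invariants and the default 35-frame schedule", {
  sched <- default_frame_schedule()
  expect_length(sched$starts, 35)
  expect_equal(sched$t_end, 90)
  expect_equal(sched$mids, sched$starts + sched$durations / 2)
  expect_error(frame_schedule(c(0, 1), c(2, 1)), "contiguous")
  expect_error(frame_schedule(0, -1), "> 0")
  expect_error(region_tac("x", sched, 1:3), "per frame")
})

test_that("model_tac trivial cases: null input and constant blood signal", {
  sched <- default_frame_schedule()
  zero <- function(t) rep(0, length(t))
  kp <- kinetic_params(0.2, 0.1, 0.05, 0.05)
  expect_equal(model_tac(zero, zero, kp, sched)$values, rep(0, 35))
  # K1 -> 0 with constant C_P = C_WB = c: every frame average is V_b * c
  const7 <- function(t) rep(7, length(t))
  kp0 <- kinetic_params(1e-12, 0.1, 0.05, 0.05, vb = 0.05)
  expect_equal(model_tac(const7, const7, kp0, sched)$values,
               rep(0.05 * 7, 35), tolerance = 1e-8)
})

test_that("model_tac agrees with the fine-grid ODE oracle on the synthetic study", {
  st <- noiseless_study()
  parent <- constrained_aif(st$wb, st$truth$hill, st$truth$ratio)
  cp_fun <- function(t) eval_aif(parent, t)
  cwb_fun <- function(t) eval_aif(st$wb, t)
  for (rg in names(st$truth$kinetics)) {
    kp <- st$truth$kinetics[[rg]]
    got <- model_tac(parent, st$wb, kp, st$schedule, step = 0.005)$values
    want <- rk4_tac_oracle(kp, cp_fun, cwb_fun, st$schedule)
    expect_lt(max(abs(got - want) / pmax(abs(want), 0.01 * max(abs(want)))),
              1e-3)
  }
})

test_that("frame averaging conserves the integral and model_tac is bilinear", {
  sched <- default_frame_schedule()
  # duration-weighted sum of frame averages equals the total integral of
  # the piecewise-linear curve (trapezoid-consistent)
  set.seed(9)
  kp <- random_kp()
  parent <- function(t) feng_aif(feng_params(120, 15, 8, 1.2, 0.3, 0.012), t)
  tac <- model_tac(parent, parent, kp, sched, step = 0.01)
  tgrid <- seq(0, 90, by = 0.01)
  E <- (1 - kp$vb) * simekit:::conv_tissue(parent(tgrid), 0.01, kp) +
    kp$vb * parent(tgrid)
  total <- sum(diff(tgrid) * (E[-1] + E[-length(E)]) / 2)
  expect_equal(sum(tac$values * sched$durations), total, tolerance = 1e-10)
  # joint linearity in (C_P, C_WB) for fixed kinetics
  s <- 2.6
  parent_s <- function(t) s * parent(t)
  tac_s <- model_tac(parent_s, parent_s, kp, sched, step = 0.01)
  expect_equal(tac_s$values, s * tac$values, tolerance = 1e-12)
  half <- function(t) 0.5 * parent(t)
  tac_sum <- model_tac(function(t) parent(t) + half(t),
                       function(t) parent(t) + half(t), kp, sched, step = 0.01)
  tac_h <- model_tac(half, half, kp, sched, step = 0.01)
  expect_equal(tac_sum$values, tac$values + tac_h$values, tolerance = 1e-10)
})
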