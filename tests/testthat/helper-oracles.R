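# Independent numerical oracles used by the unit and acceptance tests.
# These deliberately avoid the package's analytic-convolution path: the
# compartment ODEs are integrated by a classical RK4 scheme on a fine grid
# (step chosen so frame boundaries of the default schedule are grid nodes).

# Homogeneous 2-TC system after a unit impulse: CF(0+) = K1, CB(0) = 0.
# States may be vectors (one entry per parameter draw); returns CF + CB.
rk4_impulse_oracle <- function(K1, k2, k3, k4, times, dt = 1 / 240) {
  n_steps <- ceiling(max(times) / dt)
  cf <- K1
  cb <- rep(0, length(K1))
  tgrid <- (0:n_steps) * dt
  ht <- matrix(0, n_steps + 1, length(K1))
  ht[1, ] <- cf + cb
  deriv <- function(cf, cb) list(df = -(k2 + k3) * cf + k4 * cb,
                                 db = k3 * cf - k4 * cb)
  for (s in seq_len(n_steps)) {
    k1d <- deriv(cf, cb)
    k2d <- deriv(cf + dt / 2 * k1d$df, cb + dt / 2 * k1d$db)
    k3d <- deriv(cf + dt / 2 * k2d$df, cb + dt / 2 * k2d$db)
    k4d <- deriv(cf + dt * k3d$df, cb + dt * k3d$db)
    cf <- cf + dt / 6 * (k1d$df + 2 * k2d$df + 2 * k3d$df + k4d$df)
    cb <- cb + dt / 6 * (k1d$db + 2 * k2d$db + 2 * k3d$db + k4d$db)
    ht[s + 1, ] <- cf + cb
  }
  # linear interpolation onto the requested times, per draw
  apply(ht, 2, function(h) stats::approx(tgrid, h, xout = times)$y)
}

# Driven 2-TC system: dCF/dt = K1 CP - (k2+k3) CF + k4 CB, dCB/dt = k3 CF
# - k4 CB, with CP given as a function. Output E = (1-vb)(CF+CB) + vb CWB,
# frame-averaged by the trapezoid rule (dt divides every frame boundary of
# the default schedule).
rk4_tac_oracle <- function(kp, cp_fun, cwb_fun, schedule, dt = 1 / 240) {
  n_steps <- round(schedule$t_end / dt)
  tgrid <- (0:n_steps) * dt
  cp_full <- cp_fun(c(tgrid, tgrid[n_steps + 1] + dt / 2))  # guard
  cp_half <- cp_fun(tgrid + dt / 2)
  cf <- 0; cb <- 0
  E <- numeric(n_steps + 1)
  deriv <- function(cf, cb, cp) c(kp$K1 * cp - (kp$k2 + kp$k3) * cf + kp$k4 * cb,
                                  kp$k3 * cf - kp$k4 * cb)
  E[1] <- 0
  for (s in seq_len(n_steps)) {
    d1 <- deriv(cf, cb, cp_full[s])
    d2 <- deriv(cf + dt / 2 * d1[1], cb + dt / 2 * d1[2], cp_half[s])
    d3 <- deriv(cf + dt / 2 * d2[1], cb + dt / 2 * d2[2], cp_half[s])
    d4 <- deriv(cf + dt * d3[1], cb + dt * d3[2], cp_full[s + 1])
    cf <- cf + dt / 6 * (d1[1] + 2 * d2[1] + 2 * d3[1] + d4[1])
    cb <- cb + dt / 6 * (d1[2] + 2 * d2[2] + 2 * d3[2] + d4[2])
    E[s + 1] <- cf + cb
  }
  E <- (1 - kp$vb) * E + kp$vb * cwb_fun(tgrid)
  vapply(seq_along(schedule$starts), function(f) {
    i0 <- round(schedule$starts[f] / dt) + 1
    i1 <- round(schedule$ends[f] / dt) + 1
    seg <- E[i0:i1]
    dt * (sum(seg) - (seg[1] + seg[length(seg)]) / 2) / schedule$durations[f]
  }, 0)
}

# random valid kinetic parameter draw (away from the repeated-root corner)
random_kp <- function() {
  kinetic_params(K1 = runif(1, 0.05, 0.6), k2 = runif(1, 0.03, 0.4),
                 k3 = runif(1, 0.005, 0.3), k4 = runif(1, 0.01, 0.15))
}

# small noiseless default study shared across test files (computed once)
noiseless_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_study(generate_truth(), "none",
                                                 seed = 1)
    cache
  }
})
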