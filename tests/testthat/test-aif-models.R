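test_that("feng_aif matches the frozen scalar-evaluation oracle and is 0 at t = 0", {
  p <- feng_params(800, 20, 5, 4, 0.5, 0.01)
  # frozen values computed by direct scalar evaluation in an independent
  # script before the build
  expect_equal(feng_aif(p, c(1, 10, 60)),
               c(31.275482501767, 4.658946030162, 2.744058180472),
               tolerance = 1e-12)
  # exact cancellation at t = 0 for arbitrary valid parameter draws
  set.seed(4)
  for (i in 1:20) {
    l <- sort(runif(3, 0.001, 8), decreasing = TRUE)
    l[1] <- l[1] + 0.1; l[2] <- max(l[2], l[3] + 0.01)
    q <- feng_params(runif(1, 1, 1000), runif(1, 0, 50), runif(1, 0, 50),
                     l[1], l[2], l[3])
    expect_identical(feng_aif(q, 0), 0)
  }
})

test_that("feng_params rejects invalid parameters", {
  expect_error(feng_params(800, 20, 5, 0.01, 0.5, 4), "lambda")
  expect_error(feng_params(-1, 20, 5, 4, 0.5, 0.01), "A1")
  expect_error(feng_params(NaN, 20, 5, 4, 0.5, 0.01), "finite")
})

test_that("hill_fraction matches its oracle, limits and monotonicity", {
  p <- hill_params(0.2, 1.5, 20)
  expect_identical(hill_fraction(p, 0), 1)
  expect_lt(abs(hill_fraction(p, 1e6) - 0.2), 1e-3)
  # frozen independent scalar evaluation at the six metabolite-sample times
  expect_equal(hill_fraction(p, c(3.5, 10, 17.5, 32.5, 55, 85)),
               c(0.802684195087, 0.509940709378, 0.371659541202,
                 0.277942889719, 0.237392707749, 0.219908885025),
               tolerance = 1e-12)
  expect_error(hill_params(0.2, -1, 20), "'b'")
  expect_error(hill_params(0.2, 1.5, 0), "'c'")
  expect_error(hill_params(1.2, 1.5, 20), "'a'")
  # monotone non-increasing on dense grids over random valid draws
  set.seed(7)
  tg <- seq(0, 120, by = 0.05)
  for (i in 1:25) {
    q <- hill_params(runif(1), runif(1, 0.05, 8), runif(1, 0.05, 500))
    f <- hill_fraction(q, tg)
    expect_true(all(diff(f) <= 1e-12))
    expect_true(all(f >= q$a - 1e-12 & f <= 1 + 1e-12))
  }
})

test_that("ratio_line evaluates the line and rejects non-positive ratios", {
  expect_equal(ratio_line(ratio_params(0, 1), c(0, 45, 90)), rep(1, 3))
  expect_equal(ratio_line(ratio_params(0.002, 1.1), 50), 1.2)
  expect_error(ratio_params(-0.02, 1.0), "positive")
  # valid on the default window but evaluated beyond it
  expect_error(ratio_line(ratio_params(-0.005, 0.6), 200), "non-positive")
})

test_that("whole_blood_curve honours its interpolation contract", {
  wb <- whole_blood_curve(c(1, 2, 5, 10), c(3, 8, 4, 2))
  expect_identical(eval_aif(wb, c(1, 2, 5, 10)), c(3, 8, 4, 2))  # exact at samples
  expect_equal(eval_aif(wb, 1.5), 5.5)                           # linear between
  expect_equal(eval_aif(wb, 0.5), 0)                             # zero before first
  expect_equal(eval_aif(wb, 50), 2)                              # constant after last
  expect_error(whole_blood_curve(c(1, 1), c(1, 2)), "increasing")
  expect_error(whole_blood_curve(c(1, 2), c(-1, 2)), ">= 0")
})

test_that("constrained_parent_aif is the product of its factors", {
  wb <- whole_blood_curve(c(0, 0.5, 1, 3, 10, 90), c(0, 40, 25, 12, 6, 2))
  h1 <- hill_params(1, 2, 10)          # unit parent fraction
  r1 <- ratio_params(0, 1)             # unit ratio
  tt <- c(0, 0.7, 2, 8, 45, 90)
  expect_equal(constrained_parent_aif(wb, h1, r1, tt), eval_aif(wb, tt))
  # composition at t = 0: f(0) = 1, so C_P(0) = e * C_WB(0)
  r2 <- ratio_params(0.001, 1.3)
  h2 <- hill_params(0.3, 1.8, 15)
  expect_equal(constrained_parent_aif(wb, h2, r2, 0), 1.3 * eval_aif(wb, 0))
  # factor-wise oracle on the default 35-frame mid-times
  mids <- default_frame_schedule()$mids
  r3 <- ratio_params(0.001, 1.05)
  expect_equal(constrained_parent_aif(wb, h2, r3, mids),
               eval_aif(wb, mids) * hill_fraction(h2, mids) *
                 ratio_line(r3, mids))
  # linearity in the whole-blood curve
  wb2 <- whole_blood_curve(wb$times, 3.7 * wb$activities)
  expect_equal(constrained_parent_aif(wb2, h2, r3, mids),
               3.7 * constrained_parent_aif(wb, h2, r3, mids))
})

test_that("analytic AIF Jacobians match central finite differences", {
  fd_check <- function(fun, x, jac, tol = 1e-5) {
    # central differences column by column, step scaled per parameter
    for (j in seq_along(x)) {
      hstep <- 1e-6 * max(abs(x[j]), 1e-3)
      xp <- x; xm <- x
      xp[j] <- x[j] + hstep; xm[j] <- x[j] - hstep
      num <- (fun(xp) - fun(xm)) / (2 * hstep)
      scale <- max(abs(num), abs(jac[, j]), 1e-8)
      expect_lt(max(abs(num - jac[, j])) / scale, tol)
    }
  }
  tt <- c(0.2, 0.9, 2.5, 11, 40, 88)
  set.seed(11)
  for (i in 1:10) {
    p <- c(runif(1, 50, 500), runif(1, 2, 40), runif(1, 1, 20),
           runif(1, 1.5, 5), runif(1, 0.1, 0.5), runif(1, 0.002, 0.05))
    jac <- aif_jacobian("feng", do.call(feng_params, as.list(p)), tt)
    fd_check(function(x) feng_aif(do.call(feng_params, as.list(x)), tt), p, jac)
  }
  wb <- whole_blood_curve(c(0, 0.5, 1, 3, 10, 90), c(0, 40, 25, 12, 6, 2))
  for (i in 1:10) {
    p <- c(runif(1, 0.05, 0.9), runif(1, 0.5, 4), runif(1, 3, 200),
           runif(1, -0.005, 0.01), runif(1, 0.8, 1.5))
    jac <- aif_jacobian("constrained",
                        list(hill = hill_params(p[1], p[2], p[3]),
                             ratio = ratio_params(p[4], p[5])), tt, wb = wb)
    fd_check(function(x)
      constrained_parent_aif(wb, hill_params(x[1], x[2], x[3]),
                             ratio_params(x[4], x[5]), tt), p, jac)
  }
  # d f / d a at t = 0 is 0: the 'a' column vanishes there
  jac0 <- aif_jacobian("constrained",
                       list(hill = hill_params(0.3, 2, 10),
                            ratio = ratio_params(0, 1)), 0, wb = wb)
  expect_identical(unname(jac0[1, "a"]), 0)
  expect_error(aif_jacobian("nope", NULL, 1), "arg")
})
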