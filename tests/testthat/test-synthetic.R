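test_that("generate_truth profiles: binding design, determinism, flat profile", {
  tr <- generate_truth("default", seed = 1)
  vt <- vapply(tr$kinetics, volume_of_distribution, 0)
  # low < moderate < moderate < high binding ordering
  expect_true(all(diff(vt[c("cerebellum", "parietal", "hippocampus",
                             "striatum")]) > 0))
  bp <- binding_potential(vt, vt[["cerebellum"]])
  # profile designed to echo the reported BP_ND magnitudes
  expect_equal(unname(bp[["striatum"]]), 3.5, tolerance = 0.05 / 3.5)
  expect_equal(unname(bp[["hippocampus"]]), 0.9, tolerance = 1e-9)
  expect_equal(unname(bp[["parietal"]]), 0.42, tolerance = 1e-9)
  expect_identical(generate_truth("default", 1), generate_truth("default", 1))
  flat <- generate_truth("flat")
  vt_f <- vapply(flat$kinetics, volume_of_distribution, 0)
  expect_equal(unname(binding_potential(vt_f, vt_f[1])), rep(0, 4))
  expect_error(generate_truth("nope"), "arg")
})

test_that("generate_study is deterministic and exactly consistent with the product model", {
  tr <- generate_truth()
  s1 <- generate_study(tr, "mid", seed = 42)
  s2 <- generate_study(tr, "mid", seed = 42)
  expect_identical(s1$tacs, s2$tacs)
  expect_identical(s1$samples, s2$samples)
  s3 <- generate_study(tr, "mid", seed = 43)
  expect_false(identical(s1$tacs, s3$tacs))
  # product-model round trip at the blood sampling grid: machine precision
  cp <- constrained_parent_aif(s1$wb, tr$hill, tr$ratio, s1$wb$times)
  expect_equal(cp, feng_aif(tr$feng, s1$wb$times), tolerance = 1e-12)
  # noiseless study: the SIME cost at the generating parameters is ~ 0
  s0 <- generate_study(tr, "none", seed = 1)
  pr <- sime_problem(unname(s0$tacs), "constrained", wb = s0$wb)
  expect_lt(sime_cost(pr, true_theta(s0, "constrained")),
            1e-10 * sum(vapply(s0$tacs, function(x) sum(x$values^2), 0)))
})

test_that("noise model: Monte-Carlo SD matches the variance law, durations weight it", {
  tr <- generate_truth()
  clean <- generate_study(tr, "none", seed = 1)
  mu <- clean$tacs$cerebellum$values
  durs <- clean$schedule$durations
  sd_target <- 0.35 * sqrt(pmax(mu, 0.1) / durs)   # the "mid" noise law
  # 1500 replicates: the 10 pct band sits ~3 SE from a 500-replicate SD
  # estimate (a ~5 pct chance of a spurious failure over 35 frames), so
  # the sample is extended -- same seed scheme, the first 500 draws kept
  draws <- vapply(1:1500, function(r)
    generate_study(tr, "mid", seed = 10000 + r)$tacs$cerebellum$values,
    numeric(35))
  sd_emp <- apply(draws, 1, sd)
  expect_lt(max(abs(sd_emp / sd_target - 1)), 0.10)
  # equal mean in a 5-s and a 10-min frame: relative noise lower in the
  # long frame by sqrt(duration ratio)
  expect_gt(sd_target[1] / mu[1], sd_target[35] / mu[35])
})

test_that("generate_cohort structure, shared truths, jitter", {
  co <- generate_cohort(5, test_retest = TRUE, seed = 7, noise = "mid")
  expect_length(co, 10)
  subj <- vapply(co, function(s) s$subject, 0L)
  expect_equal(sort(unique(subj)), 1:5)
  for (s in 1:5) {
    pair <- co[subj == s]
    expect_identical(pair[[1]]$truth, pair[[2]]$truth)   # shared truth
    expect_false(identical(pair[[1]]$tacs, pair[[2]]$tacs))  # new noise
  }
  # subjects differ from the profile truth (log-normal jitter applied)
  base <- generate_truth()
  expect_false(identical(co[[1]]$truth$kinetics, base$kinetics))
  expect_error(generate_cohort(0), ">= 1")
})

test_that("noiseless test-retest pairs give ICC exactly +1", {
  co <- generate_cohort(4, test_retest = TRUE, seed = 19, noise = "none")
  vt <- cohort_vt_refit(co, aif = "true")
  wide <- merge(vt[vt$scan == 1, ], vt[vt$scan == 2, ],
                by = c("subject", "region"))
  for (rg in unique(wide$region)) {
    d <- wide[wide$region == rg, ]
    tab <- test_retest_table(d$subject, rg, d$vt.x, d$vt.y)
    expect_equal(icc(tab, rg), 1, tolerance = 1e-6)
  }
})

test_that("perturb_wb bias profiles", {
  st <- noiseless_study()
  wb <- st$wb
  expect_identical(perturb_wb(wb, 1.0)$activities, wb$activities)
  b9 <- perturb_wb(wb, 0.9)
  expect_equal(curve_auc(b9$activities, b9$times, c(0, 90)),
               0.9 * curve_auc(wb$activities, wb$times, c(0, 90)),
               tolerance = 1e-12)
  pk <- perturb_wb(wb, list(type = "peak", factor = 0.8, t_split = 3))
  expect_equal(pk$activities[wb$times >= 3], wb$activities[wb$times >= 3])
  expect_equal(pk$activities[wb$times < 3], 0.8 * wb$activities[wb$times < 3])
  expect_error(perturb_wb(wb, 0), "> 0")
  expect_error(perturb_wb(wb, list(type = "wavy", factor = 1)), "unknown")
})
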