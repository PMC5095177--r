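test_that("flux equation is linear in the concentration difference and flow", {
  area <- pi * 0.038^2
  expect_equal(compute_flux(10, 10, 0.06, area), 0)
  expect_equal(compute_flux(10, 8, 0.06, area), 0.12 / 4.5365e-3,
               tolerance = 1e-4)
  expect_equal(compute_flux(8, 10, 0.06, area), -compute_flux(10, 8, 0.06,
                                                              area))
  # exact rational check on small integers: (6-2)*3/2 = 6
  expect_identical(compute_flux(6, 2, 3, 2), 6)
  expect_identical(compute_flux(6, 2, 6, 2), 12)   # linear in F
  expect_identical(compute_flux(6, 2, 3, 4), 3)    # inverse in A
  expect_error(compute_flux(1, 0, 0, 1), "flow_lh")
  expect_error(compute_flux(1, 0, 1, -1), "area_m2")
})

test_that("steady-state screen retains constant series and excludes steps", {
  # identical fluxes across 4 days, 2 cores -> retained with p = 1
  rep1 <- steady_state_filter(rep(5, 8), rep(c(24, 48, 72, 96), 2),
                              rep(c("a", "b"), each = 4))
  expect_equal(rep1$p_value, 1)
  expect_true(all(rep1$retained))

  # 10x step at day 4 over noise sd = 0.1 (3 replicate cores): excluded,
  # and the F test agrees with a brute-force permutation of time labels
  set.seed(42)
  tp <- rep(c(24, 48, 72, 96), each = 3)
  core <- rep(c("a", "b", "c"), 4)
  fl <- ifelse(tp == 96, 50, 5) + rnorm(12, 0, 0.1)
  expect_lt(perm_f_oracle(fl, tp), 0.05)
  rep2 <- suppressMessages(steady_state_filter(fl, tp, core))
  expect_lt(rep2$p_value, 0.05)
  expect_true("96" %in% rep2$excluded)
  expect_false(any(rep2$retained[tp == 96]))
  expect_true(all(rep2$retained[tp != 96]))

  # 2 time points only: retained untested with a logged warning
  expect_message(rep3 <- steady_state_filter(c(1, 2, 1.1, 2.2),
                                             c(24, 48, 24, 48),
                                             c("a", "a", "b", "b")),
                 "fewer than 3")
  expect_true(all(rep3$retained))

  # whole-core exclusion policy drops the most deviant core once the
  # among-time-point test fails (three cores; core c runs hot overall)
  set.seed(43)
  tp4 <- rep(c(24, 48, 72, 96), 3)
  fl4 <- c(c(5, 5, 5, 50), c(5, 5, 5, 50), c(25, 25, 25, 70)) +
    rnorm(12, 0, 0.05)
  rep4 <- suppressMessages(
    steady_state_filter(fl4, tp4, rep(c("a", "b", "c"), each = 4),
                        exclusion = "core"))
  expect_true("c" %in% rep4$excluded)
  expect_false(any(rep4$retained[9:12]))
  expect_true(all(rep4$retained[1:8]))
})

test_that("exclusion count grows with alpha (filter monotone in alpha)", {
  set.seed(7)
  tp <- rep(c(24, 48, 72, 96), each = 2)
  core <- rep(c("a", "b"), 4)
  fl <- rnorm(8, 5, 1)
  n_exc <- vapply(c(1e-12, 0.05, 0.999), function(a)
    length(suppressMessages(
      steady_state_filter(fl, tp, core, alpha = a))$excluded), numeric(1))
  expect_equal(n_exc[1], 0)                 # alpha -> 0 retains everything
  expect_true(n_exc[3] >= n_exc[2])
  expect_gt(n_exc[3], 0)                    # alpha -> 1 excludes aggressively
})

test_that("above-control gate is directional and shift-invariant", {
  expect_false(detect_above_control(rep(3, 4), rep(3, 4))$detected)
  expect_equal(detect_above_control(rep(3, 4), rep(3, 4))$p_value, 1)

  # 10 sigma shift, n = 4 per group: detected, agreeing with the exact
  # permutation oracle over all 70 relabelings
  set.seed(11)
  ctl <- rnorm(4, 0, 1)
  trt <- rnorm(4, 10, 1)
  res <- detect_above_control(trt, ctl)
  expect_true(res$detected)
  cmb <- utils::combn(8, 4)
  xs <- c(trt, ctl)
  perm_p <- mean(apply(cmb, 2, function(i)
    mean(xs[i]) - mean(xs[-i]) >= mean(trt) - mean(ctl)))
  expect_lt(perm_p, 0.05)

  # adding a common constant changes neither decision nor p-value
  res2 <- detect_above_control(trt + 100, ctl + 100)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-8)

  # lower treatment is never "detected"
  expect_false(detect_above_control(ctl, trt)$detected)
  expect_error(detect_above_control(1, c(1, 2)), "insufficient replication")
})
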