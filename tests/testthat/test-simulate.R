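test_that("simulator is deterministic under a fixed seed", {
  t1 <- truth_parameters(n_stations = 2, seed = 77)
  a <- simulate_incubation(t1)
  b <- simulate_incubation(t1)
  expect_identical(as.data.frame(a$incubations), as.data.frame(b$incubations))
  t2 <- truth_parameters(n_stations = 2, seed = 78)
  expect_false(identical(as.data.frame(simulate_incubation(t2)$incubations),
                         as.data.frame(a$incubations)))
})

test_that("noise-free control treatment carries no 29/30N2 or 15NH4 signal", {
  sim <- simulate_incubation(truth_parameters(n_stations = 1,
                                              noise = zero_noise))
  fx <- flux_table(sim$incubations)
  ctl <- fx[fx$treatment == "control", ]
  expect_equal(ctl$flux[ctl$analyte == "N2_29"], rep(0, 8))
  expect_equal(ctl$flux[ctl$analyte == "N2_30"], rep(0, 8))
  expect_equal(ctl$flux[ctl$analyte == "NH4_15"], rep(0, 8))
  expect_true(all(ctl$flux[ctl$analyte == "O2"] < 0))
})

test_that("simulated N2 production conserves nitrogen mass", {
  truth <- truth_parameters(nfix = 0.3, noise = zero_noise)
  tr <- truth_rates(truth)
  for (i in seq_along(truth$station_ids)) {
    p <- tr$production[[i]]$no3_15
    emitted <- 2 * (p[["N2_28"]] + p[["N2_29"]] + p[["N2_30"]])
    r <- tr$rates[i, ]
    expect_equal(emitted, r$d14 + r$d15 + r$a_tot - r$nfix,
                 tolerance = 1e-10)
  }
})

test_that("forward-then-inverse identity holds for every pathway at zero noise", {
  truth <- truth_parameters(n_stations = 2, a_tot = 0.4, f_a = 0.5,
                            dnra_tot = 0.6, nfix = c(0, 0.25),
                            noise = zero_noise)
  sim <- simulate_incubation(truth)
  fit <- suppressMessages(ipt(sim$incubations, sim$stations))
  expd <- truth_rates(truth)$rates
  # anammox algebra: A_tot = 0.4 at F_A = 0.5 gives A14 = 0.2
  expect_equal(fit$station$a_tot, rep(0.4, 2), tolerance = 1e-10)
  expect_equal(fit$station$a14, rep(0.2, 2), tolerance = 1e-10)
  # the 29N2 anammox correction exactly cancels the injected signal
  expect_equal(fit$station$d14, expd$d14, tolerance = 1e-10)
  expect_equal(fit$station$d15, expd$d15, tolerance = 1e-10)
  expect_equal(fit$station$dn_rate, expd$dn_rate, tolerance = 1e-10)
  expect_equal(fit$station$dnra14, expd$dnra14, tolerance = 1e-10)
  expect_equal(fit$station$nfix, expd$nfix, tolerance = 1e-10)
  expect_equal(fit$station$sod, expd$sod, tolerance = 1e-10)
})

test_that("recovery report flags exact recovery as zero error", {
  truth <- truth_parameters(n_stations = 1, noise = zero_noise)
  sim <- simulate_incubation(truth)
  fit <- suppressMessages(ipt(sim$incubations, sim$stations))
  rr <- recovery_report(truth, fit)
  expect_lt(max(rr$rel_error, na.rm = TRUE), 1e-10)
  expect_equal(max(rr$abs_error, na.rm = TRUE), 0, tolerance = 1e-8)
})

test_that("a step change is caught by the steady-state screen", {
  truth <- truth_parameters(n_stations = 1, noise = zero_noise,
                            step_change = list(time_h = 96, factor = 10))
  sim <- simulate_incubation(truth)
  fit <- suppressMessages(ipt(sim$incubations, sim$stations))
  expect_false(any(fit$fluxes$retained[fit$fluxes$time_h == 96 &
                                         fit$fluxes$analyte == "N2_30" &
                                         fit$fluxes$treatment == "no3_15"]))
  # rates recovered exactly from the remaining steady time points
  rr <- recovery_report(truth, fit)
  expect_lt(max(rr$rel_error, na.rm = TRUE), 1e-10)
})

test_that("simulated communities honour size and seed contracts", {
  expect_equal(nrow(simulate_community(0)), 0L)
  expect_equal(bpc_community(simulate_community(0))$bpc, 0)
  a <- simulate_community(8, seed = 5)
  expect_identical(a, simulate_community(8, seed = 5))
  expect_equal(nrow(a), 8L)
  expect_true(all(a$biomass >= 0 & a$abundance >= 0))
  rng <- bpc_score_range()
  expect_true(all(a$mobility >= rng$mobility[1] &
                    a$mobility <= rng$mobility[2]))
})
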