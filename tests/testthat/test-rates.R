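test_that("isotope pairing recovers denitrification from 29/30N2", {
  r <- denitrification_rates(2, 1)
  expect_equal(r$d15, 4)
  expect_equal(r$d14, 4)          # f = 0.5 forces p29/p30 = 2 and D14 = D15
  r0 <- denitrification_rates(0, 1)
  expect_equal(r0$d15, 2)
  expect_equal(r0$d14, 0)         # no mixed pairs -> no 14N denitrification
  # forward binomial model at f = 0.8, P = 10
  f <- 0.8; P <- 10
  fb <- denitrification_rates(2 * f * (1 - f) * P, f^2 * P)
  expect_equal(fb$d15, 2 * f * P)         # 16
  expect_equal(fb$d14, 2 * (1 - f) * P)   # 4
  # p30 = 0 with p29 > 0: pairing violated, D14 not computable
  viol <- suppressMessages(denitrification_rates(1, 0))
  expect_false(viol$pairing_ok)
  expect_true(is.na(viol$d14))
})

test_that("binomial pairing oracle holds across the tracer fraction range", {
  for (f in c(0.05, 0.2, 0.5, 0.8, 0.95)) {
    for (P in c(0.1, 2, 40)) {
      r <- denitrification_rates(2 * f * (1 - f) * P, f^2 * P)
      expect_equal(r$d15, 2 * f * P, tolerance = 1e-12)
      expect_equal(r$d14, 2 * (1 - f) * P, tolerance = 1e-12)
      nf <- nitrogen_fixation((1 - f)^2 * P, 2 * f * (1 - f) * P, f^2 * P)
      expect_equal(nf$nfix, 0)    # binomial-consistent fluxes -> no fixation
    }
  }
})

test_that("anammox correction subtracts the labelled-pool 29N2 share", {
  expect_equal(correct_p29_for_anammox(1.0, 0, 0.8), 1.0)   # no anammox
  expect_equal(correct_p29_for_anammox(1.0, 0.2, 0.8), 0.92)
  expect_message(out <- correct_p29_for_anammox(0.05, 0.2, 1), "saturated")
  expect_equal(out, 0)
})

test_that("Dw/Dn partition conserves D14 and floors coupled share at zero", {
  eq <- partition_dw_dn(3.7, 2.9, 10, 10)
  expect_equal(eq$dw, 3.7)                       # equal pools: Dw = D15
  p <- partition_dw_dn(7.8, 7.3, 5.2, 26.0)
  expect_equal(p$dw, 1.56)
  expect_equal(p$dn, 5.74)
  expect_equal(p$dw + p$dn, 7.3)
  z <- partition_dw_dn(7.8, 7.3, 0, 26.0)
  expect_equal(z$dw, 0); expect_equal(z$dn, 7.3) # no ambient nitrate
  fl <- suppressMessages(partition_dw_dn(100, 1, 5, 5))
  expect_equal(fl$dn, 0)                          # floored with warning
  expect_error(partition_dw_dn(1, 1, 5, 0), "no3_15")
})

test_that("anammox and DNRA scale by their tracer fractions", {
  a <- anammox_rates(0.2, 0.5)
  expect_equal(a$a_tot, 0.4)
  expect_equal(a$a14, 0.2)
  expect_equal(anammox_rates(0.7, 1)$a14, 0)     # all anammox uses tracer
  expect_error(anammox_rates(1, 0), "f_a")

  d <- dnra_rates(0.45, 0.9)
  expect_equal(d$dnra_tot, 0.5)
  expect_equal(d$dnra14, 0.05)
  expect_equal(dnra_rates(0.45, 1)$dnra14, 0)
  expect_equal(dnra_rates(0.45, 0.9, mode = "total_over_fn")$dnra14, 0.5)
  expect_equal(dnra_rates(0, 0.9)$dnra_tot, 0)
  expect_error(dnra_rates(1, 0), "f_n")
})

test_that("nitrogen fixation is the doubled 28N2 deficit", {
  nf <- nitrogen_fixation(0.5, 2, 1)
  expect_equal(nf$p28_expected, 1)
  expect_equal(nf$nfix, 1.0)
  expect_equal(nitrogen_fixation(2, 2, 1)$nfix, 0)  # surplus, not deficit
  expect_false(suppressMessages(nitrogen_fixation(1, 2, 0))$computable)
})

test_that("SOD, ra and Dn% follow their definitions", {
  expect_equal(sediment_oxygen_demand(rep(-207, 4)), -207)
  expect_equal(sediment_oxygen_demand(c(-10, 4)), -3)  # no sign forcing
  expect_error(sediment_oxygen_demand(numeric(0)), "at least one")

  expect_equal(round(ra_fraction(0.29, 20.4), 1), 1.4)
  expect_equal(round(ra_fraction(0.24, 7.3), 1), 3.2)
  expect_equal(ra_fraction(0.5, 0), 100)
  expect_true(is.na(ra_fraction(0, 0)))

  expect_equal(round(dn_percent(5.5, 7.3)), 75)
  expect_equal(dn_percent(3, 3), 100)
  expect_equal(dn_percent(0, 3), 0)
  expect_true(is.na(dn_percent(1, 0)))
})

test_that("conservation identities hold exactly on rational inputs", {
  set.seed(3)
  for (i in 1:25) {
    p29 <- sample(1:40, 1) / 4; p30 <- sample(1:40, 1) / 8
    f <- sample(1:7, 1) / 8
    r <- denitrification_rates(p29, p30)
    pt <- partition_dw_dn(r$d15, r$d14, sample(0:20, 1) / 2, sample(1:40, 1))
    if (pt$dn > 0) expect_equal(pt$dw + pt$dn, r$d14, tolerance = 1e-12)
    a <- anammox_rates(sample(1:10, 1) / 10, f)
    expect_equal(a$a_tot, a$a14 + a$a15, tolerance = 1e-12)
    p15 <- sample(1:10, 1) / 10
    d <- dnra_rates(p15, f)
    expect_equal(d$dnra_tot, d$dnra14 + p15, tolerance = 1e-12)
    expect_true(ra_fraction(a$a14, r$d14) >= 0 &&
                  ra_fraction(a$a14, r$d14) <= 100)
    if (r$d14 > 0)
      expect_true(dn_percent(pt$dn, r$d14) >= 0 &&
                    dn_percent(pt$dn, r$d14) <= 100)
  }
})

test_that("rate equations are homogeneous of degree 1 in production", {
  set.seed(4)
  for (i in 1:10) {
    p29 <- runif(1, 0.1, 5); p30 <- runif(1, 0.1, 5); k <- runif(1, 0.5, 4)
    r1 <- denitrification_rates(p29, p30)
    r2 <- denitrification_rates(k * p29, k * p30)
    expect_equal(r2$d15, k * r1$d15)
    expect_equal(r2$d14, k * r1$d14)   # ratio invariant, D15 scales
    expect_equal(anammox_rates(k * p29, 0.7)$a_tot,
                 k * anammox_rates(p29, 0.7)$a_tot)
    expect_equal(dnra_rates(k * p29, 0.7)$dnra14,
                 k * dnra_rates(p29, 0.7)$dnra14)
    expect_equal(nitrogen_fixation(k * 0.2, k * p29, k * p30)$nfix,
                 k * nitrogen_fixation(0.2, p29, p30)$nfix)
  }
})

test_that("station aggregation yields mean, s.e.m. and optional weighting", {
  df <- data.frame(d14 = c(4, 6, 8))
  ag <- aggregate_station(df)
  expect_equal(ag$mean, 6)
  expect_equal(ag$se, sd(c(4, 6, 8)) / sqrt(3))
  expect_equal(ag$n, 3L)
  one <- aggregate_station(data.frame(d14 = 5))
  expect_equal(one$mean, 5); expect_equal(one$se, 0)

  # core-n weighting shifts the cross-station mean toward replicated rows
  r <- hanna_shoal_rates()
  wt <- aggregate_station(r["d14"], weights = r$n)
  expect_equal(wt$mean, sum(r$n * r$d14) / sum(r$n))
  expect_equal(wt$mean, 9.225)
  un <- aggregate_station(r["d14"])
  expect_equal(un$mean, 9.82)
})
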