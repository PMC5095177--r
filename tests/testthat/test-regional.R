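test_that("correlation matrix is symmetric with exact unit diagonal", {
  x <- c(1, 2, 3, 4, 5)
  cm <- correlation_matrix(data.frame(x = x, y = 2 * x + 1,
                                      z = c(2, 1, 5, 3, 2)))
  expect_equal(cm$r["x", "y"], 1)
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  expect_lt(cm$p["x", "y"], 1e-8)

  cz <- correlation_matrix(data.frame(x = x, const = rep(2, 5)))
  expect_true(is.na(cz$r["x", "const"]))   # zero variance -> undefined
  expect_error(correlation_matrix(data.frame(x = 1:2, y = 2:3)), ">= 3")
})

test_that("OLS fit matches the normal-equation oracle", {
  f <- suppressWarnings(fit_linear(1:5, 2 * (1:5)))  # perfect-fit warning
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r2, 1)

  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(5)
    fit <- fit_linear(x, y)
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)   # brute-force normal equations
    expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
    expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  }
  expect_error(fit_linear(rep(1, 5), rnorm(5)), "constant predictor")
})

test_that("slope standard error matches the textbook formula", {
  set.seed(6)
  x <- 1:5
  y <- 3 + 0.5 * x + rnorm(5, 0, 0.3)
  fit <- fit_linear(x, y)
  res <- y - (fit$intercept + fit$slope * x)
  s2 <- sum(res^2) / (5 - 2)
  se_slope <- sqrt(s2 / sum((x - mean(x))^2))
  expect_equal(unname(summary(fit$fit)$coefficients["x", "Std. Error"]),
               se_slope, tolerance = 1e-10)
})

test_that("rate prediction is affine with a zero floor", {
  model <- chukchi_constants()$bpc_model
  expect_equal(predict_d14(0, model), 4.76)
  expect_equal(predict_d14(1000, model), 7.36)
  expect_equal(predict_d14(c(10, 20), list(slope = 0, intercept = 3)),
               c(3, 3))
  expect_equal(suppressMessages(
    predict_d14(10, list(slope = -1, intercept = 3))), 0)
})

test_that("kriging honours data exactly and beats IDW on a smooth field", {
  # constant field reproduced everywhere
  pts <- data.frame(lon = c(-165, -164, -163, -162, -161),
                    lat = c(71.2, 71.8, 71.4, 71.9, 71.5), value = 5)
  s <- interpolate_surface(pts, n_lon = 8, n_lat = 8)
  expect_equal(unique(s$grid$value), 5)

  # exactness at data points on a smooth Gaussian random field
  # (exponential covariance, 200 km correlation range)
  set.seed(13)
  pts2 <- data.frame(lon = runif(10, -166, -158), lat = runif(10, 71, 72.5))
  kmdeg <- 111.195
  xy <- cbind(pts2$lon * cos(mean(pts2$lat) * pi / 180) * kmdeg,
              pts2$lat * kmdeg)
  S <- 4 * exp(-as.matrix(dist(xy)) / 200)
  pts2$value <- 8 + drop(chol(S + diag(1e-8, 10)) %*% rnorm(10))
  s2 <- interpolate_surface(pts2, n_lon = 12, n_lat = 12)
  expect_equal(s2$method, "ordinary_kriging")
  expect_equal(surface_at(s2, pts2$lon, pts2$lat), pts2$value,
               tolerance = 1e-6)

  # leave-one-out RMSE: kriging below inverse-distance on the smooth field
  loo <- function(interp) {
    errs <- vapply(seq_len(nrow(pts2)), function(i) {
      fit <- interp(pts2[-i, ])
      surface_at(fit, pts2$lon[i], pts2$lat[i]) - pts2$value[i]
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  rmse_ok <- loo(function(p) interpolate_surface(p, 4, 4))
  rmse_idw <- loo(function(p) {
    s <- interpolate_surface(p, 4, 4)
    s$method <- "idw"; s$variogram <- NULL
    s
  })
  expect_lt(rmse_ok, rmse_idw)

  # duplicate locations degrade the variogram -> IDW fallback
  dup <- rbind(pts2, pts2[1, ])
  s3 <- suppressMessages(interpolate_surface(dup, 6, 6))
  expect_equal(s3$method, "idw")
})

test_that("surface binning partitions the range and conserves area", {
  grid <- expand.grid(lon = seq(-165, -160, length.out = 10),
                      lat = seq(71, 72, length.out = 10))
  grid$cell_area_m2 <- 1e6
  grid$value <- seq(0, 7, length.out = 100)
  surf <- list(grid = grid)
  b <- bin_surface(surf, 7)
  expect_equal(b$range_low, 0:6)
  expect_equal(b$range_high, 1:7)
  expect_equal(sum(b$area_m2), sum(grid$cell_area_m2))
  expect_true(all(diff(c(b$range_low, b$range_high[7])) > 0))

  grid$value <- 4
  b1 <- bin_surface(list(grid = grid), 5)
  expect_equal(nrow(b1), 1L)                  # constant surface: one bin
  expect_equal(b1$area_m2, sum(grid$cell_area_m2))
})

test_that("technique 1 annualizes a single mean rate with propagated error", {
  u <- upscale_technique1(9.25, 6.27, 65500 * 1e6)
  expect_equal(u$annual_rate, 5.3075, tolerance = 1e-4)
  expect_equal(u$uncertainty, 3.5976, tolerance = 1e-4)
  expect_equal(upscale_technique1(0, 0, 1e6)$annual_rate, 0)
  # unit identity: 1 umol m-2 h-1 over 1 m2 for 1 h = 1e-15 Gmol
  expect_equal(upscale_technique1(1, 0, 1, hours_per_year = 1)$annual_rate,
               1e-15)
})

test_that("technique 2 sums per-bin representative rates", {
  bins <- data.frame(range_low = 4, range_high = 6, area_m2 = 1e6,
                     mean_rate = 5, sd_rate = 0, n_cells = 1)
  expect_equal(upscale_technique2(bins)$annual_rate, 5 * 1e6 * 8760 * 1e-15)
  # splitting a bin with identical means leaves the total unchanged
  halves <- data.frame(range_low = c(4, 5), range_high = c(5, 6),
                       area_m2 = c(4e5, 6e5), mean_rate = 5,
                       sd_rate = 0, n_cells = 1)
  expect_equal(upscale_technique2(halves)$annual_rate,
               upscale_technique2(bins)$annual_rate)
  bins$mean_rate <- 0
  expect_equal(upscale_technique2(bins)$annual_rate, 0)
})

test_that("technique 3 is seeded, degenerate-exact and unbiased", {
  bins <- data.frame(range_low = c(2, 5), range_high = c(2, 5),
                     area_m2 = c(3e6, 7e6), mean_rate = c(2, 5),
                     sd_rate = 0, n_cells = c(3, 7))
  # zero-width ranges equal technique 2 at the midpoints with sd = 0
  u <- upscale_technique3(bins, iterations = 10, cell_area_m2 = 1e6,
                          seed = 1)
  expect_equal(u$annual_rate, upscale_technique2(bins)$annual_rate)
  expect_equal(u$uncertainty, 0)

  # fixed seed -> bit-identical
  wide <- data.frame(range_low = 4, range_high = 6, area_m2 = 5e7,
                     mean_rate = 5, sd_rate = 0, n_cells = 50)
  a <- upscale_technique3(wide, 50, 1e6, seed = 99)
  b <- upscale_technique3(wide, 50, 1e6, seed = 99)
  expect_identical(a$annual_rate, b$annual_rate)

  # Monte Carlo mean within 3 standard errors of the midpoint expectation
  mc <- upscale_technique3(wide, 400, 1e6, seed = 7)
  expected <- 5 * 5e7 * 8760 * 1e-15
  expect_lt(abs(mc$annual_rate - expected),
            3 * mc$uncertainty / sqrt(mc$iterations))
})

test_that("teragram extrapolation reproduces the global percentage bounds", {
  area <- 5.052e6 * 1e6
  # invert the unit chain to the rates that give 2.8 and 15.7 Tg N yr-1
  rate_for <- function(tg) tg * 1e18 / (14 * area * 8760)
  ex <- extrapolate_annual(rate_for(2.8), rate_for(15.7), area)
  expect_equal(ex$tg_n_yr, c(2.8, 15.7), tolerance = 1e-10)
  expect_equal(round(ex$pct_of_global, 1), c(0.5, 2.7))
  z <- extrapolate_annual(0, 0, area)
  expect_equal(z$tg_n_yr, c(0, 0))
  expect_error(extrapolate_annual(2, 1, area), "rate_low")
})
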