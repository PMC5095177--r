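# Regional statistics: correlation and regression between rates and
# station variables, spatial interpolation of predicted rates, surface
# binning, and three annualization (upscaling) techniques.

UMOL_TO_GMOL <- 1e-15   # umol -> Gmol
G_PER_MOL_N <- 14       # g N per mol N
KM2_TO_M2 <- 1e6

#' Pearson correlation matrix with p-values
#'
#' Pairwise-complete Pearson correlations between station-level variables,
#' with two-sided p-values from [stats::cor.test()]. Zero-variance
#' variables yield NA for their pairs.
#'
#' @param df data.frame of numeric variables (rows = stations).
#' @return list of class `"cor_matrix"`: `r` and `p` matrices (unit
#'   diagonal; symmetric), `n` (pairwise sample sizes).
#' @export
correlation_matrix <- function(df) {
  df <- as.data.frame(df)
  df <- df[vapply(df, is.numeric, logical(1))]
  if (nrow(df) < 3L) stopf("need >= 3 stations for correlations")
  k <- ncol(df)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(names(df),
                                                        names(df)))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    ok <- stats::complete.cases(df[[i]], df[[j]])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) >= 3L && stats::sd(df[[i]][ok]) > 0 &&
        stats::sd(df[[j]][ok]) > 0) {
      ct <- stats::cor.test(df[[i]][ok], df[[j]][ok])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = n), class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, digits = 2, ...) {
  cat("Pearson correlation matrix (r; * where p < 0.05):\n")
  fr <- format(round(x$r, digits))
  fr[] <- paste0(fr, ifelse(!is.na(x$p) & x$p < 0.05 &
                              row(x$p) != col(x$p), "*", " "))
  print(fr, quote = FALSE)
  invisible(x)
}

#' Ordinary least squares fit of a rate against a predictor
#'
#' Thin wrapper around [stats::lm()] returning the quantities used for
#' rate prediction: slope, intercept, r, r-squared, two-sided slope
#' p-value and n.
#'
#' @param x predictor (e.g. station BPc).
#' @param y response (e.g. station D14, umol N m-2 h-1).
#' @return list of class `"rate_lm"`: `slope`, `intercept`, `r`, `r2`,
#'   `p_value`, `n`, and the underlying `lm` fit.
#' @export
fit_linear <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("need >= 3 points for a regression")
  if (stats::sd(x) == 0) stopf("constant predictor: regression undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              r = sign(stats::coef(fit)[2]) * sqrt(sm$r.squared),
              r2 = sm$r.squared,
              p_value = unname(sm$coefficients[2, 4]),
              n = length(x), fit = fit)
  class(out) <- "rate_lm"
  out
}

#' @export
print.rate_lm <- function(x, ...) {
  cat(sprintf("y = %.4g x + %.4g  (r2 = %.3f, p = %.3g, n = %d)\n",
              x$slope, x$intercept, x$r2, x$p_value, x$n))
  invisible(x)
}

#' Predict a rate from a fitted (or published) linear model
#'
#' Affine prediction `intercept + slope * x`; negative predictions are
#' floored at zero with a logged warning (a negative denitrification rate
#' is not physical).
#'
#' @param bpc predictor values (e.g. BPc).
#' @param model a `"rate_lm"` or any list with `slope` and `intercept`.
#' @return predicted rates (umol N m-2 h-1), >= 0.
#' @examples
#' predict_d14(1000, chukchi_constants()$bpc_model)  # 7.36
#' @export
predict_d14 <- function(bpc, model) {
  y <- model$intercept + model$slope * bpc
  if (any(y < 0)) {
    bn_log("regional", sprintf("%d negative prediction(s) floored at 0",
                               sum(y < 0)))
    y <- pmax(0, y)
  }
  y
}

# ---- ordinary kriging stand-in -----------------------------------------

# Empirical semivariogram (equal-width distance bins) and an exponential
# model gamma(h) = sill * (1 - exp(-h / range)) fitted by least squares.
# No nugget: the interpolator must honour the data exactly.
.fit_variogram <- function(d, v, n_bins = 12L) {
  brk <- seq(0, max(d), length.out = n_bins + 1L)
  bin <- cut(d, brk, include.lowest = TRUE)
  h <- tapply(d, bin, mean)
  g <- tapply(v, bin, mean)
  ok <- is.finite(h) & is.finite(g)
  h <- h[ok]; g <- g[ok]
  if (length(h) < 3L || all(g <= 0)) return(NULL)
  obj <- function(par) {
    sill <- exp(par[1]); rng <- exp(par[2])
    sum((g - sill * (1 - exp(-h / rng)))^2)
  }
  st <- c(log(max(g)), log(max(d) / 3))
  opt <- try(stats::optim(st, obj), silent = TRUE)
  if (inherits(opt, "try-error")) return(NULL)
  list(sill = exp(opt$par[1]), range = exp(opt$par[2]))
}

.idw <- function(px, py, x, y, z, power = 2) {
  vapply(seq_along(px), function(i) {
    d2 <- (x - px[i])^2 + (y - py[i])^2
    if (any(d2 == 0)) return(z[which(d2 == 0)[1]])
    w <- 1 / d2^(power / 2)
    sum(w * z) / sum(w)
  }, numeric(1))
}

#' Interpolate station rates onto a regular grid
#'
#' Ordinary kriging with a fitted exponential semivariogram and no nugget,
#' so the surface honours each datum exactly; used as a declared stand-in
#' for the proprietary empirical Bayesian kriging of GIS software. Falls
#' back to inverse-distance weighting when the variogram cannot be fitted
#' (duplicate or collinear points, constant field, singular kriging
#' system), with the method recorded in the result. Coordinates are
#' treated on a plate-carree plane with longitudes shortened by
#' cos(latitude); per-cell areas carry the same correction.
#'
#' @param points data.frame with `lon`, `lat`, `value` (>= 5 rows).
#' @param n_lon,n_lat grid dimensions.
#' @param expand fractional margin added around the data extent.
#' @param idw_power inverse-distance power for the fallback.
#' @return list of class `"rate_surface"`: `grid` (data.frame `lon, lat,
#'   value, cell_area_m2`), `method` ("ordinary_kriging" or "idw"),
#'   `variogram` (fitted parameters or NULL), `points`.
#' @export
interpolate_surface <- function(points, n_lon = 50L, n_lat = 50L,
                                expand = 0.05, idw_power = 2) {
  stopifnot(all(c("lon", "lat", "value") %in% names(points)))
  if (nrow(points) < 5L) stopf("need >= 5 points to interpolate")
  lat0 <- mean(points$lat)
  kmdeg <- 111.195
  px <- points$lon * cos(lat0 * pi / 180) * kmdeg
  py <- points$lat * kmdeg
  z <- points$value

  rlon <- range(points$lon); rlat <- range(points$lat)
  mlon <- diff(rlon) * expand; mlat <- diff(rlat) * expand
  lon_seq <- seq(rlon[1] - mlon, rlon[2] + mlon, length.out = n_lon)
  lat_seq <- seq(rlat[1] - mlat, rlat[2] + mlat, length.out = n_lat)
  grid <- expand.grid(lon = lon_seq, lat = lat_seq)
  gx <- grid$lon * cos(lat0 * pi / 180) * kmdeg
  gy <- grid$lat * kmdeg
  dlon <- if (n_lon > 1) diff(lon_seq[1:2]) else mlon * 2 + diff(rlon)
  dlat <- if (n_lat > 1) diff(lat_seq[1:2]) else mlat * 2 + diff(rlat)
  grid$cell_area_m2 <- dlon * cos(grid$lat * pi / 180) * kmdeg *
    dlat * kmdeg * KM2_TO_M2

  method <- "ordinary_kriging"
  vg <- NULL
  pred <- NULL
  if (stats::sd(z) == 0) {
    pred <- rep(z[1], nrow(grid))     # kriging reproduces a constant field
  } else {
    dd <- as.matrix(stats::dist(cbind(px, py)))
    if (any(dd[upper.tri(dd)] == 0)) {
      bn_log("regional", "duplicate point locations; falling back to IDW")
    } else {
      iu <- which(upper.tri(dd), arr.ind = TRUE)
      semiv <- 0.5 * (z[iu[, 1]] - z[iu[, 2]])^2
      vg <- .fit_variogram(dd[upper.tri(dd)], semiv)
      if (!is.null(vg)) {
        gamma_f <- function(h) vg$sill * (1 - exp(-h / vg$range))
        n <- length(z)
        A <- rbind(cbind(gamma_f(dd), 1), c(rep(1, n), 0))
        sol <- try(solve(A), silent = TRUE)
        if (!inherits(sol, "try-error")) {
          G0 <- rbind(gamma_f(sqrt(outer(px, gx, "-")^2 +
                                     outer(py, gy, "-")^2)),
                      1)
          W <- sol %*% G0
          pred <- as.numeric(crossprod(W[seq_len(n), , drop = FALSE], z))
        }
      }
    }
  }
  if (is.null(pred)) {
    method <- "idw"
    if (is.null(vg))
      bn_log("regional", "variogram fit failed; falling back to IDW")
    pred <- .idw(gx, gy, px, py, z, idw_power)
  }
  grid$value <- pred
  out <- list(grid = grid[, c("lon", "lat", "value", "cell_area_m2")],
              method = method, variogram = vg, points = points)
  class(out) <- "rate_surface"
  out
}

#' Evaluate a fitted surface at point locations
#'
#' Re-solves the fitted interpolator at arbitrary locations (used e.g. for
#' leave-one-out checks and the exactness property at data points).
#'
#' @param surface a `"rate_surface"`.
#' @param lon,lat target coordinates.
#' @return interpolated values.
#' @export
surface_at <- function(surface, lon, lat) {
  pts <- surface$points
  lat0 <- mean(pts$lat)
  kmdeg <- 111.195
  px <- pts$lon * cos(lat0 * pi / 180) * kmdeg
  py <- pts$lat * kmdeg
  qx <- lon * cos(lat0 * pi / 180) * kmdeg
  qy <- lat * kmdeg
  z <- pts$value
  if (surface$method == "idw" || is.null(surface$variogram)) {
    if (stats::sd(z) == 0) return(rep(z[1], length(lon)))
    return(.idw(qx, qy, px, py, z))
  }
  vg <- surface$variogram
  gamma_f <- function(h) vg$sill * (1 - exp(-h / vg$range))
  dd <- as.matrix(stats::dist(cbind(px, py)))
  n <- length(z)
  A <- rbind(cbind(gamma_f(dd), 1), c(rep(1, n), 0))
  G0 <- rbind(gamma_f(sqrt(outer(px, qx, "-")^2 + outer(py, qy, "-")^2)), 1)
  W <- solve(A) %*% G0
  as.numeric(crossprod(W[seq_len(n), , drop = FALSE], z))
}

#' Bin an interpolated rate surface
#'
#' Partitions the surface's value range into bins (equal-interval by
#' default, quantile optionally) and accumulates per-bin areas and mean
#' rates. A constant surface collapses to a single bin carrying the full
#' area.
#'
#' @param surface a `"rate_surface"` (or any list with a `grid` data.frame
#'   holding `value` and `cell_area_m2`).
#' @param n_bins number of bins (>= 2).
#' @param scheme `"equal"` interval (default) or `"quantile"`.
#' @return data.frame of class `"surface_bins"`: `range_low, range_high,
#'   area_m2, mean_rate, sd_rate, n_cells`; attribute `total_area_m2`.
#' @export
bin_surface <- function(surface, n_bins = 7L, scheme = c("equal",
                                                         "quantile")) {
  scheme <- match.arg(scheme)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stopf("n_bins must be >= 2")
  g <- surface$grid
  v <- g$value
  if (diff(range(v)) == 0) {
    out <- data.frame(range_low = min(v), range_high = max(v),
                      area_m2 = sum(g$cell_area_m2), mean_rate = v[1],
                      sd_rate = 0, n_cells = length(v))
  } else {
    brk <- if (scheme == "equal")
      seq(min(v), max(v), length.out = n_bins + 1L)
    else unique(stats::quantile(v, seq(0, 1, length.out = n_bins + 1L)))
    idx <- cut(v, brk, include.lowest = TRUE, labels = FALSE)
    out <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(b) {
      sel <- idx == b
      data.frame(range_low = brk[b], range_high = brk[b + 1L],
                 area_m2 = sum(g$cell_area_m2[sel]),
                 mean_rate = if (any(sel)) mean(v[sel]) else NA_real_,
                 sd_rate = if (sum(sel) > 1L) stats::sd(v[sel]) else 0,
                 n_cells = sum(sel))
    }))
  }
  rownames(out) <- NULL
  structure(out, class = c("surface_bins", "data.frame"),
            total_area_m2 = sum(out$area_m2))
}

.upscale_result <- function(technique, annual, unc, units = "Gmol",
                            iterations = NA_integer_, seed = NA_integer_) {
  out <- list(technique = technique, annual_rate = annual,
              uncertainty = unc, units = units, iterations = iterations,
              seed = seed)
  class(out) <- "upscale_result"
  out
}

#' @export
print.upscale_result <- function(x, ...) {
  cat(sprintf("Technique %s: %.3g +- %.3g %s N yr-1%s\n", x$technique,
              x$annual_rate, x$uncertainty, x$units,
              if (is.na(x$iterations)) "" else
                sprintf(" (%d iterations, seed %d)", x$iterations, x$seed)))
  invisible(x)
}

#' Upscaling technique 1: single mean rate over the whole area
#'
#' Annualizes one mean rate (with its standard deviation as propagated
#' uncertainty) over the full study area:
#' `annual = mean * area * hours * 1e-15` Gmol N yr-1.
#'
#' @param mean_rate,sd_rate rate mean and s.d. (umol N m-2 h-1).
#' @param area_m2 area (m2), > 0.
#' @param hours_per_year annualization factor (default 8760).
#' @return an `"upscale_result"` (Gmol N yr-1).
#' @examples
#' k <- chukchi_constants()
#' upscale_technique1(k$d14_mean, k$d14_sd, k$study_area_km2 * 1e6)
#' @export
upscale_technique1 <- function(mean_rate, sd_rate, area_m2,
                               hours_per_year = 8760) {
  if (area_m2 <= 0) stopf("area_m2 must be > 0")
  f <- area_m2 * hours_per_year * UMOL_TO_GMOL
  .upscale_result(1L, mean_rate * f, sd_rate * f)
}

#' Upscaling technique 2: binned surface with per-bin representative rates
#'
#' Each bin's mean rate represents its area; the annual total is the sum
#' over bins, `sum(mean_b * area_b) * hours * 1e-15` Gmol N yr-1, with
#' uncertainty propagated from the per-bin rate standard deviations
#' (in quadrature over bins).
#'
#' @param bins a `"surface_bins"` data.frame.
#' @param hours_per_year annualization factor.
#' @return an `"upscale_result"` (Gmol N yr-1).
#' @export
upscale_technique2 <- function(bins, hours_per_year = 8760) {
  ok <- is.finite(bins$mean_rate) & bins$area_m2 > 0
  f <- hours_per_year * UMOL_TO_GMOL
  annual <- sum(bins$mean_rate[ok] * bins$area_m2[ok]) * f
  unc <- sqrt(sum((bins$sd_rate[ok] * bins$area_m2[ok])^2)) * f
  .upscale_result(2L, annual, unc)
}

#' Upscaling technique 3: Monte Carlo draws within bin ranges
#'
#' Per iteration, every grid cell of each bin receives an independent
#' uniform draw from the bin's rate range; cell totals are summed over the
#' area and annualized. The mean and standard deviation over iterations
#' give the regional estimate and its uncertainty. Drawing per m2 at basin
#' scale is computationally absurd, so draws are made per grid cell of
#' configurable area; the per-m2 variance is recovered in the limit of
#' small cells.
#'
#' @param bins a `"surface_bins"` data.frame.
#' @param iterations number of Monte Carlo iterations (>= 1).
#' @param cell_area_m2 area represented by one draw (default 1 km2).
#' @param seed integer seed (recorded in the result).
#' @param hours_per_year annualization factor.
#' @return an `"upscale_result"` (Gmol N yr-1) with `iterations` and
#'   `seed` recorded.
#' @export
upscale_technique3 <- function(bins, iterations = 1e5, cell_area_m2 = 1e6,
                               seed = 20130802L, hours_per_year = 8760) {
  stopifnot(iterations >= 1, cell_area_m2 > 0)
  set.seed(seed)
  ok <- bins$area_m2 > 0 & is.finite(bins$range_low)
  lo <- bins$range_low[ok]; hi <- bins$range_high[ok]
  ncell <- pmax(1L, round(bins$area_m2[ok] / cell_area_m2))
  f <- cell_area_m2 * hours_per_year * UMOL_TO_GMOL
  totals <- numeric(iterations)
  for (it in seq_len(iterations)) {
    s <- 0
    for (b in seq_along(lo)) {
      s <- s + if (hi[b] > lo[b])
        sum(stats::runif(ncell[b], lo[b], hi[b])) else ncell[b] * lo[b]
    }
    totals[it] <- s * f
  }
  .upscale_result(3L, mean(totals),
                  if (iterations > 1) stats::sd(totals) else 0,
                  iterations = as.integer(iterations),
                  seed = as.integer(seed))
}

#' Extrapolate an hourly rate range to annual teragrams of nitrogen
#'
#' `Tg = rate * 14 g mol-1 * area * hours * 1e-18`, reported for the low
#' and high bounds together with their percentage of a global reference
#' denitrification total.
#'
#' @param rate_low,rate_high bounding rates (umol N m-2 h-1),
#'   `rate_low <= rate_high`.
#' @param area_m2 shelf area (m2).
#' @param reference_tg global reference (Tg N yr-1, default 573).
#' @param hours_per_year annualization factor.
#' @return data.frame with rows `low`/`high`: `tg_n_yr`, `pct_of_global`.
#' @export
extrapolate_annual <- function(rate_low, rate_high, area_m2,
                               reference_tg = 573, hours_per_year = 8760) {
  if (rate_low > rate_high) stopf("rate_low must be <= rate_high")
  tg <- c(low = rate_low, high = rate_high) * G_PER_MOL_N * area_m2 *
    hours_per_year * 1e-18     # umol -> mol (1e-6), g -> Tg (1e-12)
  data.frame(bound = names(tg), tg_n_yr = unname(tg),
             pct_of_global = unname(100 * tg / reference_tg),
             stringsAsFactors = FALSE)
}
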