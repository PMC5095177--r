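# The central estimator: from a validated incubation table and station
# metadata to per-replicate and station-level nitrogen cycling rates.
#
# Chain per station: per-observation fluxes -> steady-state screen per
# treatment x analyte -> above-control detection gates (anammox, DNRA,
# fixation) -> isotope pairing rate equations per retained (core, time)
# replicate unit -> station means +- s.e.m.

.gate_or_warn <- function(trt, ctl, alpha, what, station) {
  if (length(ctl) < 2L) {
    bn_log("detect", sprintf("no control series for %s; gate passed untested",
                             what), station)
    return(list(detected = TRUE, p_value = NA_real_))
  }
  detect_above_control(trt, ctl, alpha)
}

# One-sided one-sample test that a deficit series exceeds zero; exact
# degenerate conventions: constant zero -> p = 1; constant positive -> p = 0.
.one_sample_gate <- function(x, alpha) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(list(detected = FALSE, p_value = NA_real_))
  s <- stats::sd(x)
  if (s <= .Machine$double.eps * max(abs(x), 1)) {
    p <- if (mean(x) > 0) 0 else 1
  } else {
    p <- stats::pt(mean(x) / (s / sqrt(length(x))), df = length(x) - 1L,
                   lower.tail = FALSE)
  }
  list(detected = p < alpha, p_value = p)
}

#' Fit co-occurring nitrogen cycling rates from flow-through incubations
#'
#' The package's central estimator. Computes per-observation benthic fluxes,
#' screens them for steady state, applies the above-control detection gates,
#' and evaluates the isotope pairing rate equations per retained
#' (core, time) replicate unit, then aggregates to station means with
#' standard errors. Returns a classed object with `print`, `summary`,
#' `coef`, `plot` and `simulate` methods.
#'
#' @param incubations an `"incubation_table"` (from [read_incubations()],
#'   [as_incubation_table()] or [simulate_incubation()]).
#' @param stations a station table (from [read_stations()] or
#'   [hanna_shoal_stations()]) supplying ambient nitrate and the tracer
#'   fractions `f_n`, `f_a` per station.
#' @param config an [ipt_config()] list.
#' @return object of class `"ipt"` with elements `station` (one row per
#'   station, summary means and standard errors), `units` (replicate
#'   unit rates), `fluxes` (screened flux table with `retained` flags),
#'   `detection` (per-station gate results), `steady_state` (screen
#'   reports), `config`, `call`.
#' @examples
#' truth <- truth_parameters(n_stations = 1,
#'                           noise = c(gas_cv = 0, nh4_cv = 0,
#'                                     nh4_floor = 0))
#' sim <- simulate_incubation(truth)
#' fit <- suppressMessages(ipt(sim$incubations, sim$stations))
#' coef(fit)
#' @export
ipt <- function(incubations, stations, config = ipt_config()) {
  stopifnot(inherits(config, "ipt_config"))
  fx <- flux_table(incubations)
  stations <- as.data.frame(stations)
  if (!all(c("f_n", "f_a") %in% names(stations)))
    stations <- tracer_fractions(stations)

  # --- steady-state screen per station x treatment x analyte -------------
  fx$retained <- TRUE
  reports <- list()
  grp <- interaction(fx$station_id, fx$treatment, fx$analyte, drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    rep_g <- steady_state_filter(fx$flux[idx], fx$time_h[idx],
                                 fx$core_id[idx], alpha = config$alpha,
                                 exclusion = config$exclusion)
    fx$retained[idx] <- rep_g$retained
    reports[[g]] <- rep_g
  }

  pick <- function(st, trt, an, retained_only = TRUE) {
    sel <- fx$station_id == st & fx$treatment == trt & fx$analyte == an
    if (retained_only) sel <- sel & fx$retained
    fx[sel, c("core_id", "time_h", "flux")]
  }

  units <- list()
  station_rows <- list()
  detection <- list()
  for (st in unique(fx$station_id)) {
    srow <- stations[stations$station_id == st, ]
    if (nrow(srow) != 1L) stopf("station %s missing from station table", st)
    f_n <- srow$f_n; f_a <- srow$f_a
    no3_14 <- srow$bottom_no3_14; no3_15 <- srow$no3_15

    # --- anammox from the 15NH4+ treatment -----------------------------
    p29_nh4 <- pick(st, "nh4_15", "N2_29")
    ctl_29 <- pick(st, "control", "N2_29")
    gate_a <- .gate_or_warn(p29_nh4$flux, ctl_29$flux, config$alpha,
                            "anammox 29N2", st)
    if (nrow(p29_nh4) && gate_a$detected) {
      am <- anammox_rates(2 * p29_nh4$flux, f_a)   # N-atom basis
    } else {
      am <- list(a_tot = rep(0, nrow(p29_nh4)), a15 = rep(0, nrow(p29_nh4)),
                 a14 = rep(0, nrow(p29_nh4)))
    }
    a_tot_station <- if (length(am$a_tot)) mean(am$a_tot) else 0

    # --- DNRA from 15NH4+ production in the 15NO3- treatment -----------
    p15 <- pick(st, "no3_15", "NH4_15")
    ctl_15 <- pick(st, "control", "NH4_15")
    gate_d <- .gate_or_warn(p15$flux, ctl_15$flux, config$alpha,
                            "15NH4+ production", st)
    if (nrow(p15) && gate_d$detected) {
      dn_r <- dnra_rates(p15$flux, f_n, mode = config$dnra14_mode)
    } else {
      dn_r <- list(dnra_tot = rep(0, nrow(p15)), dnra14 = rep(0, nrow(p15)))
    }

    # --- denitrification / fixation units from the 15NO3- treatment ----
    p28 <- pick(st, "no3_15", "N2_28")
    p29 <- pick(st, "no3_15", "N2_29")
    p30 <- pick(st, "no3_15", "N2_30")
    key <- function(d) paste(d$core_id, d$time_h)
    common <- Reduce(intersect, list(key(p28), key(p29), key(p30)))
    udf <- NULL
    if (length(common)) {
      i28 <- match(common, key(p28)); i29 <- match(common, key(p29))
      i30 <- match(common, key(p30))
      rows <- lapply(seq_along(common), function(i) {
        p29c <- config$anammox_correction(max(0, p29$flux[i29[i]]),
                                          a_tot_station, f_n)
        dr <- denitrification_rates(p29c, max(0, p30$flux[i30[i]]))
        part <- if (is.na(dr$d14)) list(dw = NA_real_, dn = NA_real_) else
          partition_dw_dn(dr$d15, dr$d14, no3_14, no3_15)
        # symmetric anammox correction on 28N2 before the fixation deficit
        p28c <- max(0, p28$flux[i28[i]] - 0.5 * a_tot_station * (1 - f_n))
        nf <- nitrogen_fixation(p28c, p29c, max(0, p30$flux[i30[i]]))
        data.frame(station_id = st, core_id = p28$core_id[i28[i]],
                   time_h = p28$time_h[i28[i]],
                   d15 = dr$d15, d14 = dr$d14, dw = part$dw, dn = part$dn,
                   dn_pct = dn_percent(part$dn, dr$d14),
                   nfix_deficit = if (nf$computable)
                     nf$p28_expected - p28c else NA_real_,
                   pairing_ok = dr$pairing_ok, stringsAsFactors = FALSE)
      })
      udf <- do.call(rbind, rows)
    }

    # fixation gate: mean 28N2 deficit significantly above zero
    gate_f <- .one_sample_gate(if (is.null(udf)) numeric(0) else
      udf$nfix_deficit, config$alpha)
    nfix_units <- if (!is.null(udf) && gate_f$detected)
      pmax(0, 2 * udf$nfix_deficit) else rep(0, NROW(udf))

    # --- SOD -----------------------------------------------------------
    o2 <- do.call(rbind, lapply(config$sod_treatments, function(trt)
      pick(st, trt, "O2")))
    sod <- if (NROW(o2)) sediment_oxygen_demand(o2$flux) else NA_real_
    sod_se <- if (NROW(o2)) sem(o2$flux) else NA_real_

    units[[st]] <- list(
      denit = if (is.null(udf)) udf else cbind(udf, nfix = nfix_units),
      anammox = if (nrow(p29_nh4)) data.frame(
        station_id = st, core_id = p29_nh4$core_id, time_h = p29_nh4$time_h,
        a_tot = am$a_tot, a15 = am$a15, a14 = am$a14,
        stringsAsFactors = FALSE) else NULL,
      dnra = if (nrow(p15)) data.frame(
        station_id = st, core_id = p15$core_id, time_h = p15$time_h,
        dnra_tot = dn_r$dnra_tot, dnra14 = dn_r$dnra14,
        stringsAsFactors = FALSE) else NULL,
      o2 = o2)
    detection[[st]] <- list(anammox = gate_a, dnra = gate_d,
                            nitrogen_fixation = gate_f)

    mse <- function(x) {
      x <- x[is.finite(x)]
      if (!length(x)) c(NA_real_, NA_real_) else c(mean(x), sem(x))
    }
    dvals <- if (is.null(udf)) rep(NA_real_, 0) else udf$d14
    d14m <- mse(dvals); d15m <- mse(udf$d15); dwm <- mse(udf$dw)
    dnm <- mse(udf$dn); dnp <- mse(udf$dn_pct)
    a14m <- mse(am$a14); atm <- mse(am$a_tot)
    dnram <- mse(dn_r$dnra14); dnrtm <- mse(dn_r$dnra_tot)
    nfm <- mse(nfix_units)
    # ra from station means (A14 and D14 come from different cores);
    # s.e. by first-order propagation of the two means
    ra <- ra_fraction(a14m[1], d14m[1])
    ra_se <- if (is.finite(ra) && (a14m[1] + d14m[1]) > 0) {
      tot <- a14m[1] + d14m[1]
      100 / tot^2 * sqrt((d14m[1] * a14m[2])^2 + (a14m[1] * d14m[2])^2)
    } else NA_real_
    station_rows[[st]] <- data.frame(
      station = st, n = sum(is.finite(dvals)),
      d15 = d15m[1], d15_se = d15m[2], d14 = d14m[1], d14_se = d14m[2],
      dw = dwm[1], dw_se = dwm[2], dn_rate = dnm[1], dn_rate_se = dnm[2],
      dn_pct = dnp[1], dn_pct_se = dnp[2],
      a_tot = atm[1], a_tot_se = atm[2], a14 = a14m[1], a14_se = a14m[2],
      ra = ra, ra_se = ra_se,
      dnra_tot = dnrtm[1], dnra_tot_se = dnrtm[2],
      dnra14 = dnram[1], dnra14_se = dnram[2],
      nfix = nfm[1], nfix_se = nfm[2],
      sod = sod, sod_se = sod_se,
      anammox_detected = gate_a$detected, dnra_detected = gate_d$detected,
      nfix_detected = gate_f$detected, stringsAsFactors = FALSE)
  }

  out <- list(station = do.call(rbind, c(station_rows,
                                         make.row.names = FALSE)),
              units = units, fluxes = fx, detection = detection,
              steady_state = reports, stations = stations, config = config,
              call = match.call())
  class(out) <- "ipt"
  out
}

#' Cross-station summary of a fitted rate set
#'
#' Means and standard errors of the station-level rates, optionally
#' weighting stations by their replicate counts.
#'
#' @param fit an `"ipt"` object.
#' @param scheme aggregation scheme; defaults to the fitted config's.
#' @return data.frame with one row per rate (`rate`, `mean`, `se`, `n`).
#' @export
cross_station <- function(fit, scheme = fit$config$aggregation_scheme) {
  st <- fit$station
  cols <- c("d15", "d14", "dw", "dn_rate", "dn_pct", "a_tot", "a14", "ra",
            "dnra_tot", "dnra14", "nfix", "sod")
  w <- if (scheme == "core_n_weighted") st$n else NULL
  aggregate_station(st[, cols], cols, weights = w)
}

#' @export
print.ipt <- function(x, ...) {
  cat("Isotope pairing rate fit:",
      nrow(x$station), "station(s),",
      sum(x$fluxes$retained), "of", nrow(x$fluxes),
      "flux observations retained\n")
  cols <- c("station", "n", "d15", "d14", "dn_rate", "dn_pct", "a14", "ra",
            "dnra14", "sod")
  print(format(x$station[, cols], digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
summary.ipt <- function(object, ...) {
  out <- list(station = object$station,
              cross_station = cross_station(object),
              detection = object$detection,
              n_excluded = sum(!object$fluxes$retained),
              config = object$config)
  class(out) <- "summary.ipt"
  out
}

#' @export
print.summary.ipt <- function(x, ...) {
  cat("Station rates (mean +- s.e.m., umol N m-2 h-1; SOD umol O2):\n")
  cols <- c("station", "n", "d15", "d14", "dn_rate", "dn_pct", "a14", "ra",
            "dnra14", "sod")
  print(format(x$station[, cols], digits = 3), row.names = FALSE)
  cat("\nCross-station summary (", x$config$aggregation_scheme, "):\n",
      sep = "")
  print(format(x$cross_station, digits = 3), row.names = FALSE)
  det <- vapply(x$detection, function(d)
    paste(names(d)[!vapply(d, `[[`, TRUE, "detected")], collapse = ", "),
    character(1))
  nd <- det[nzchar(det)]
  if (length(nd))
    cat("\nNot detected:",
        paste(sprintf("%s (%s)", names(nd), nd), collapse = "; "), "\n")
  cat("Flux observations excluded by the steady-state screen:",
      x$n_excluded, "\n")
  invisible(x)
}

#' @export
coef.ipt <- function(object, ...) {
  cols <- c("d15", "d14", "dw", "dn_rate", "dn_pct", "a_tot", "a14", "ra",
            "dnra_tot", "dnra14", "nfix", "sod")
  m <- as.matrix(object$station[, cols])
  rownames(m) <- object$station$station
  m
}

#' @export
plot.ipt <- function(x, rates = c("d14", "a14", "dnra14"), ...) {
  st <- x$station
  op <- graphics::par(mfrow = c(length(rates), 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  for (r in rates) {
    m <- st[[r]]; se <- st[[paste0(r, "_se")]]
    bp <- graphics::barplot(m, names.arg = st$station, ylab = r,
                            ylim = range(0, m + 2 * se, na.rm = TRUE), ...)
    ok <- is.finite(se) & se > 0
    if (any(ok))
      graphics::arrows(bp[ok], m[ok] - se[ok], bp[ok], m[ok] + se[ok],
                       angle = 90, code = 3, length = 0.04)
  }
  invisible(x)
}

#' Simulate new incubation series from a fitted rate set
#'
#' Uses the fitted station means as the generative truth and re-runs the
#' forward incubation simulator, giving parametric-bootstrap style
#' replicate data sets.
#'
#' @param object an `"ipt"` object.
#' @param nsim number of simulated data sets.
#' @param seed integer seed.
#' @param ... passed to [truth_parameters()] (e.g. `noise_sd`).
#' @return list of length `nsim`; each element is a [simulate_incubation()]
#'   result.
#' @export
simulate.ipt <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  st <- object$station
  meta <- object$stations[match(st$station, object$stations$station_id), ]
  lapply(seq_len(nsim), function(i) {
    truth <- truth_parameters(
      station_ids = st$station,
      d14 = pmax(0, st$d14),
      dn_frac = pmin(0.99, pmax(0, st$dn_rate / pmax(st$d14, 1e-12))),
      f_n = meta$f_n, f_a = meta$f_a,
      a_tot = pmax(0, st$a_tot), dnra_tot = pmax(0, st$dnra_tot),
      nfix = pmax(0, st$nfix), sod = st$sod,
      no3_14 = meta$bottom_no3_14,
      seed = sample.int(.Machine$integer.max, 1L), ...)
    simulate_incubation(truth)
  })
}
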