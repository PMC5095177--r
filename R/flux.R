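# Benthic flux computation and the two statistical screens applied before
# any rate equation: the steady-state (among-time-point) screen and the
# above-control detection gate.

#' Benthic solute flux from a flow-through core
#'
#' Flux across the sediment-water interface of a flow-through incubation:
#' `(C_o - C_i) * F / A`. Positive flux is out of the sediment into the
#' water column ("production").
#'
#' @param c_out outflow concentration (uM).
#' @param c_in inflow concentration (uM).
#' @param flow_lh flow rate (L h-1), > 0.
#' @param area_m2 core surface area (m2), > 0.
#' @return flux in umol m-2 h-1 (same solute basis as the concentrations).
#' @examples
#' compute_flux(10, 8, 0.06, pi * 0.038^2)  # ~26.45 umol m-2 h-1
#' @export
compute_flux <- function(c_out, c_in, flow_lh, area_m2) {
  if (any(flow_lh <= 0)) stopf("flow_lh must be > 0")
  if (any(area_m2 <= 0)) stopf("area_m2 must be > 0")
  (c_out - c_in) * flow_lh / area_m2
}

#' Per-observation flux table from an incubation table
#'
#' Applies [compute_flux()] to every (core, treatment, time, analyte)
#' observation. When the 15NH4+ analyte is supplied as a pool fraction, it
#' is first converted to a concentration against the matching `NH4_total`
#' observation.
#'
#' @param inc an `"incubation_table"` (see [read_incubations()]).
#' @return data.frame with columns `station_id, core_id, treatment, time_h,
#'   analyte, flux` (umol m-2 h-1; N2 analytes on the N2-molecule basis).
#' @export
flux_table <- function(inc) {
  df <- as.data.frame(inc)
  if (identical(attr(inc, "nh4_15_as"), "fraction")) {
    key <- function(d) paste(d$station_id, d$core_id, d$treatment, d$time_h)
    tot <- df[df$analyte == "NH4_total", ]
    i15 <- df$analyte == "NH4_15"
    m <- match(key(df[i15, ]), key(tot))
    if (anyNA(m)) stopf("NH4_15 fraction rows lack matching NH4_total rows")
    df$inflow[i15] <- df$inflow[i15] * tot$inflow[m]
    df$outflow[i15] <- df$outflow[i15] * tot$outflow[m]
  }
  data.frame(station_id = df$station_id, core_id = df$core_id,
             treatment = df$treatment, time_h = df$time_h,
             analyte = df$analyte,
             flux = compute_flux(df$outflow, df$inflow, df$flow_lh,
                                 df$area_m2),
             stringsAsFactors = FALSE)
}

# Among-group F statistic (between-MS / within-MS); returns Inf when the
# within-group variance is zero but group means differ.
.f_stat <- function(x, g) {
  g <- factor(g)
  gm <- tapply(x, g, mean)
  ns <- tapply(x, g, length)
  ssb <- sum(ns * (gm - mean(x))^2)
  ssw <- sum((x - gm[g])^2)
  dfb <- nlevels(g) - 1L
  dfw <- length(x) - nlevels(g)
  if (ssw <= .Machine$double.eps * sum(x^2) || dfw < 1L) {
    if (ssb <= .Machine$double.eps * max(1, sum(x^2))) return(c(stat = 0,
                                                                p = 1))
    return(c(stat = Inf, p = 0))
  }
  f <- (ssb / dfb) / (ssw / dfw)
  c(stat = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE))
}

.perm_f_p <- function(x, g, n_perm = 199L) {
  obs <- .f_stat(x, g)[["stat"]]
  if (!is.finite(obs)) return(0)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (.f_stat(x, sample(g))[["stat"]] >= obs) hits <- hits + 1L
  }
  (hits + 1L) / (n_perm + 1L)
}

#' Steady-state screen on a flux series
#'
#' Tests whether fluxes differ among sampling time points (cores as the
#' replicate unit) with a one-way F test; observations violating the
#' steady-state assumption are excluded iteratively: the time point (or
#' core, by policy) whose mean deviates most from the grand mean in
#' standardized units is dropped and the test repeated, until the test is
#' non-significant or fewer than 3 groups remain. Series with fewer than 3
#' time points are retained with a logged warning; if the residual degrees
#' of freedom are too small for the F distribution, a permutation test on
#' the same statistic is used.
#'
#' @param flux numeric flux values (umol m-2 h-1), one per observation.
#' @param time_h sampling time of each observation.
#' @param core_id replicate (core) label of each observation.
#' @param alpha significance level of the screen.
#' @param exclusion `"timepoint"` (drop offending time points, default) or
#'   `"core"` (drop offending cores).
#' @param n_perm permutation count for the low-replication fallback.
#' @return list of class `"steady_state_report"`: `p_value` (of the initial
#'   test), `retained` logical per observation, `excluded` (character vector
#'   of dropped time points or cores), `method`.
#' @export
steady_state_filter <- function(flux, time_h, core_id, alpha = 0.05,
                                exclusion = c("timepoint", "core"),
                                n_perm = 199L) {
  exclusion <- match.arg(exclusion)
  stopifnot(length(flux) == length(time_h), length(flux) == length(core_id))
  keep <- rep(TRUE, length(flux))
  excluded <- character(0)
  if (length(unique(time_h)) < 3L) {
    bn_log("steady-state", "fewer than 3 time points; retained untested")
    out <- list(p_value = NA_real_, retained = keep, excluded = excluded,
                method = "untested")
    class(out) <- "steady_state_report"
    return(out)
  }
  test_once <- function(idx) {
    x <- flux[idx]; g <- factor(time_h[idx])
    n_per <- tapply(x, g, length)
    dfw <- length(x) - nlevels(g)
    if (dfw >= 2L && all(n_per >= 2L)) {
      list(p = .f_stat(x, g)[["p"]], method = "F")
    } else {
      list(p = .perm_f_p(x, g, n_perm), method = "permutation")
    }
  }
  first <- test_once(which(keep))
  p0 <- first$p
  p <- p0
  while (!is.na(p) && p < alpha) {
    idx <- which(keep)
    grp <- if (exclusion == "timepoint") time_h[idx] else core_id[idx]
    if (length(unique(grp)) <= 2L) break
    gm <- tapply(flux[idx], grp, mean)
    z <- abs(gm - mean(flux[idx])) / max(stats::sd(flux[idx]),
                                         .Machine$double.xmin)
    worst <- names(which.max(z))
    excluded <- c(excluded, worst)
    keep[keep][as.character(grp) == worst] <- FALSE
    if (length(unique(time_h[keep])) < 3L) break
    p <- test_once(which(keep))$p
  }
  if (length(excluded))
    bn_log("steady-state", sprintf("excluded %s %s (p = %.3g)", exclusion,
                                   paste(excluded, collapse = ", "), p0))
  out <- list(p_value = p0, retained = keep, excluded = excluded,
              method = first$method)
  class(out) <- "steady_state_report"
  out
}

#' Above-control detection gate
#'
#' One-sided test that a tracer-treatment signal exceeds the control
#' treatment (one-way analysis of variance between the two groups, halved to
#' the directional p-value). A pathway whose signal does not exceed control
#' is reported "not detected" and its derived rate set to zero downstream.
#' Adding a common constant to both groups leaves the decision unchanged.
#'
#' @param treatment numeric fluxes in the tracer treatment (n >= 2).
#' @param control numeric fluxes in the control treatment (n >= 2).
#' @param alpha significance level.
#' @return list: `detected` (logical), `p_value` (one-sided).
#' @export
detect_above_control <- function(treatment, control, alpha = 0.05) {
  if (length(treatment) < 2L || length(control) < 2L)
    stopf("insufficient replication: need >= 2 values per group")
  x <- c(treatment, control)
  if (max(x) - min(x) <= .Machine$double.eps * max(abs(x), 1))
    return(list(detected = FALSE, p_value = 1))
  g <- rep(c("t", "c"), c(length(treatment), length(control)))
  res <- .f_stat(x, g)
  p_two <- res[["p"]]
  higher <- mean(treatment) > mean(control)
  p_one <- if (higher) p_two / 2 else 1 - p_two / 2
  list(detected = higher && p_one < alpha, p_value = unname(p_one))
}
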