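# Isotope pairing rate equations. Unit conventions:
#  * N2 production fluxes p28, p29, p30 are on the N2-molecule basis
#    (umol N2 m-2 h-1), as measured by membrane-inlet mass spectrometry.
#  * All derived nitrogen rates are umol N m-2 h-1: one 15N atom per 29N2,
#    two per 30N2; N2-molecule quantities are converted with an explicit
#    factor 2 at the operation boundary.
#  * The 15NH4+-treatment 29N2 signal is passed to anammox_rates() on the
#    N-atom basis (2 x molecule flux).

#' Denitrification of tracer and ambient nitrate (isotope pairing)
#'
#' Classical isotope pairing from 29N2 and 30N2 production in the 15NO3-
#' treatment: `D15 = p29 + 2 p30` (15N atoms) and
#' `D14 = D15 * p29 / (2 p30)`. Under binomial pairing of N atoms drawn
#' from a nitrate pool with labelled fraction f and gross pair production P,
#' these recover `D15 = 2 f P` and `D14 = 2 (1 - f) P` exactly.
#'
#' @param p29 anammox-corrected 29N2 production (umol N2 m-2 h-1), >= 0.
#' @param p30 30N2 production (umol N2 m-2 h-1); must be > 0 for D14.
#' @return list: `d15`, `d14` (umol N m-2 h-1), `pairing_ok` (FALSE when
#'   p30 = 0 with p29 > 0, i.e. tracer pairing violated and D14 is not
#'   computable).
#' @examples
#' denitrification_rates(2, 1)  # d15 = 4, d14 = 4 (f = 0.5)
#' @export
denitrification_rates <- function(p29, p30) {
  if (p29 < 0) stopf("p29 must be >= 0")
  d15 <- p29 + 2 * p30
  if (p30 <= 0) {
    if (p29 > 0) {
      bn_log("ipt", "tracer pairing violated: p30 = 0 with p29 > 0")
      return(list(d15 = d15, d14 = NA_real_, pairing_ok = FALSE))
    }
    return(list(d15 = 0, d14 = 0, pairing_ok = TRUE))
  }
  list(d15 = d15, d14 = d15 * p29 / (2 * p30), pairing_ok = TRUE)
}

#' Remove the anammox contribution to 29N2 in the nitrate-tracer treatment
#'
#' Anammox pairs an ambient 14NH4+ atom with an N atom from the
#' nitrite/nitrate-derived pool, of which a fraction `f_n` is labelled in
#' the 15NO3- treatment; that pathway contributes `A_tot * f_n / 2` to the
#' 29N2 molecule flux and is subtracted before isotope pairing (the factor
#' 1/2 converts the N-atom anammox rate to N2 molecules). Clamped at zero
#' with a logged warning when the correction would exceed the measured
#' production.
#'
#' @param p29_total measured 29N2 production in the 15NO3- treatment
#'   (umol N2 m-2 h-1).
#' @param a_tot total anammox rate (umol N m-2 h-1), from the 15NH4+
#'   treatment.
#' @param f_n labelled fraction of the nitrate pool, in (0, 1].
#' @return denitrification-only 29N2 production (umol N2 m-2 h-1).
#' @export
correct_p29_for_anammox <- function(p29_total, a_tot, f_n) {
  stopifnot(p29_total >= 0, a_tot >= 0, f_n > 0, f_n <= 1)
  corr <- p29_total - 0.5 * a_tot * f_n
  if (corr < 0) {
    bn_log("ipt", "anammox correction saturated; p29 clamped to 0")
    corr <- 0
  }
  corr
}

#' Partition ambient denitrification into water-column and coupled shares
#'
#' Direct denitrification of water-column nitrate is
#' `Dw = D15 * [14NO3-] / [15NO3-]`; the remainder is coupled
#' nitrification-denitrification `Dn = D14 - Dw` (floored at 0 with a
#' warning when the water-column share exceeds D14).
#'
#' @param d15,d14 tracer and ambient denitrification (umol N m-2 h-1).
#' @param no3_14 ambient bottom-water nitrate (uM).
#' @param no3_15 labelled nitrate pool (uM), > 0.
#' @return list `dw`, `dn` with `dw + dn = d14` (unless floored).
#' @export
partition_dw_dn <- function(d15, d14, no3_14, no3_15) {
  if (no3_15 <= 0) stopf("no3_15 must be > 0")
  dw <- d15 * no3_14 / no3_15
  dn <- d14 - dw
  if (is.finite(dn) && dn < 0) {
    bn_log("ipt", sprintf("Dw (%.3g) exceeds D14 (%.3g); Dn floored at 0",
                          dw, d14))
    dn <- 0
  }
  list(dw = dw, dn = dn)
}

#' Anammox rates from the ammonium-tracer treatment
#'
#' Total anammox is the 15NH4+-treatment 29N2 production scaled by the
#' labelled share of the ammonium pool: `A_tot = p29_nh4 / F_A`; the
#' tracer-fuelled part is `A15 = p29_nh4` and the ambient-pool rate
#' `A14 = A_tot - A15`.
#'
#' @param p29_nh4 29N2 production in the 15NH4+ treatment on the N-atom
#'   basis (umol N m-2 h-1, i.e. 2 x the molecule flux).
#' @param f_a labelled fraction of the ammonium pool, in (0, 1].
#' @return list `a_tot`, `a15`, `a14` (umol N m-2 h-1).
#' @export
anammox_rates <- function(p29_nh4, f_a) {
  if (f_a <= 0 || f_a > 1) stopf("f_a must be in (0, 1]")
  a_tot <- p29_nh4 / f_a
  list(a_tot = a_tot, a15 = p29_nh4, a14 = a_tot - p29_nh4)
}

#' DNRA rates from 15NH4+ production in the nitrate-tracer treatment
#'
#' Dissimilatory nitrate reduction to ammonium:
#' `DNRA_tot = p15NH4 / F_N`. The ambient-nitrate-fuelled share is, by
#' default, `DNRA14 = DNRA_tot * (1 - F_N)` (mirroring the anammox A14
#' construction); the alternative reading `DNRA14 = DNRA_tot` per labelled
#' pool is selectable.
#'
#' @param p15nh4 15NH4+ production (umol N m-2 h-1).
#' @param f_n labelled fraction of the nitrate pool, in (0, 1].
#' @param mode `"ambient_share"` (default) or `"total_over_fn"`.
#' @return list `dnra_tot`, `dnra14` (umol N m-2 h-1).
#' @export
dnra_rates <- function(p15nh4, f_n,
                       mode = c("ambient_share", "total_over_fn")) {
  mode <- match.arg(mode)
  if (f_n <= 0 || f_n > 1) stopf("f_n must be in (0, 1]")
  dnra_tot <- p15nh4 / f_n
  dnra14 <- if (mode == "ambient_share") dnra_tot * (1 - f_n) else dnra_tot
  list(dnra_tot = dnra_tot, dnra14 = dnra14)
}

#' Nitrogen fixation as a 28N2 deficit against binomial pairing
#'
#' Under pure denitrification with binomial pairing the expected 28N2
#' production is `p28_exp = p29^2 / (4 p30)`. Simultaneous nitrogen fixation
#' consumes N2, so a measured 28N2 efflux below that expectation indicates
#' fixation: `Nfix = 2 (p28_exp - p28_measured)` (N-atom basis) when
#' positive; otherwise 0.
#'
#' @param p28_measured measured 28N2 production (umol N2 m-2 h-1).
#' @param p29 denitrification-only 29N2 production (umol N2 m-2 h-1).
#' @param p30 30N2 production (umol N2 m-2 h-1), > 0.
#' @return list `nfix` (umol N m-2 h-1, >= 0), `p28_expected`,
#'   `computable` (FALSE when p30 = 0).
#' @export
nitrogen_fixation <- function(p28_measured, p29, p30) {
  if (p30 <= 0) {
    bn_log("ipt", "nitrogen fixation not computable: p30 = 0")
    return(list(nfix = NA_real_, p28_expected = NA_real_, computable = FALSE))
  }
  p28_exp <- p29^2 / (4 * p30)
  list(nfix = max(0, 2 * (p28_exp - p28_measured)), p28_expected = p28_exp,
       computable = TRUE)
}

#' Sediment oxygen demand
#'
#' Mean O2 flux over the retained (steady-state) time points of the dark
#' incubation; oxygen uptake is negative under the efflux-positive sign
#' convention. Mixed-sign fluxes average arithmetically, no sign forcing.
#'
#' @param o2_flux retained O2 fluxes (umol O2 m-2 h-1), length >= 1.
#' @return mean O2 flux (umol O2 m-2 h-1).
#' @export
sediment_oxygen_demand <- function(o2_flux) {
  if (length(o2_flux) < 1L) stopf("need at least one retained O2 flux")
  mean(o2_flux)
}

#' Anammox share of total N2 production
#'
#' `ra = 100 * A14 / (A14 + D14)`, the percentage of ambient N2 production
#' attributable to anammox.
#'
#' @param a14 ambient anammox rate (umol N m-2 h-1).
#' @param d14 ambient denitrification rate (umol N m-2 h-1).
#' @return percentage in [0, 100]; NA when both rates are zero.
#' @examples
#' ra_fraction(0.29, 20.4)  # 1.4 % at the station with peak denitrification
#' @export
ra_fraction <- function(a14, d14) {
  tot <- a14 + d14
  ifelse(tot > 0, 100 * a14 / tot, NA_real_)
}

#' Coupled nitrification-denitrification share of D14
#'
#' `100 * Dn / D14`, the percentage of ambient denitrification fuelled by
#' nitrate produced within the sediment by nitrification.
#'
#' @param dn coupled nitrification-denitrification rate (umol N m-2 h-1).
#' @param d14 ambient denitrification rate (umol N m-2 h-1).
#' @return percentage; NA when D14 = 0.
#' @export
dn_percent <- function(dn, d14) {
  ifelse(d14 > 0, 100 * dn / d14, NA_real_)
}

#' Aggregate replicate rate sets to station (or cross-station) summaries
#'
#' Means with standard errors over replicate units. Cross-station summaries
#' optionally weight stations by their replicate counts.
#'
#' @param rates data.frame of replicate-level rates (one column per rate).
#' @param cols columns to aggregate (default: all numeric).
#' @param weights optional replicate counts for `"core_n_weighted"`
#'   cross-station aggregation.
#' @return data.frame with one row per rate: `mean`, `se`, `n`.
#' @export
aggregate_station <- function(rates, cols = NULL, weights = NULL) {
  if (is.null(cols)) cols <- names(rates)[vapply(rates, is.numeric,
                                                 logical(1))]
  out <- do.call(rbind, lapply(cols, function(cc) {
    x <- rates[[cc]]
    ok <- is.finite(x)
    x <- x[ok]
    if (!length(x)) return(data.frame(rate = cc, mean = NA_real_,
                                      se = NA_real_, n = 0L))
    if (is.null(weights)) {
      data.frame(rate = cc, mean = mean(x), se = sem(x), n = length(x))
    } else {
      w <- weights[ok]
      m <- sum(w * x) / sum(w)
      data.frame(rate = cc, mean = m,
                 se = sqrt(sum(w * (x - m)^2) / sum(w) / (length(x) - 1L)),
                 n = length(x))
    }
  }))
  rownames(out) <- NULL
  out
}
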