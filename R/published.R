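# Published station tables from the Hanna Shoal (northeast Chukchi Sea)
# study the package models. These are inputs for desk-scale recomputation of
# the study's summary statistics: station characteristics, station-mean
# biogeochemical rates, and the regional constants used in upscaling.

#' Hanna Shoal station characteristics
#'
#' Bottom-water and sediment chemistry for the five occupied stations
#' (August 2013): depth, position, ambient bottom-water NO3-/NH4+/dissolved
#' oxygen, tracer-amended pool concentrations, sediment organic carbon,
#' total nitrogen, molar C:N, and porewater NH4+. Amended concentrations are
#' mid-range values of the reported amendment windows (29.1-34.4 uM NO3-,
#' 15.1-17.7 uM NH4+) except CBL11, whose amended nitrate pool is set so the
#' labelled pool is 26.0 uM above the 5.2 uM ambient value.
#'
#' @return a `"station_table"` data.frame (5 rows) with derived tracer
#'   fractions, as returned by [tracer_fractions()].
#' @examples
#' hanna_shoal_stations()[, c("station_id", "bottom_no3_14", "no3_15")]
#' @export
hanna_shoal_stations <- function() {
  df <- data.frame(
    station_id = c("CBL11", "CBL13", "H17", "H29", "H33"),
    latitude  = c(72.1033, 71.2982, 71.9913, 71.9286, 71.8228),
    longitude = c(-165.4556, -161.6887, -163.3834, -158.3279, -159.6097),
    depth_m   = c(47, 50, 41, 66, 50),
    bottom_no3_14 = c(5.2, 4.7, 5.1, 5.5, 6.8),
    no3_total_amended = c(31.2, 30.5, 31.0, 31.5, 32.8),
    nh4_total_amended = c(17.0, 16.0, 16.1, 15.8, 16.8),
    bottom_nh4 = c(2.6, 1.6, 1.7, 1.4, 2.4),
    bottom_do  = c(83.9, 74.3, 82.8, 79.2, 75.5),
    sediment_oc = c(0.90, 1.79, 0.65, 1.51, 1.24),
    sediment_tn = c(0.14, 0.23, 0.09, 0.21, 0.15),
    cn_ratio   = c(8.2, 9.0, 8.2, 8.6, 9.6),
    porewater_nh4 = c(85.5, 38.7, 70.5, 61.6, 76.5),
    stringsAsFactors = FALSE
  )
  structure(tracer_fractions(df), class = c("station_table", "data.frame"))
}

#' Hanna Shoal station-mean biogeochemical rates
#'
#' Station means (with standard errors and replicate counts) of the derived
#' nitrogen cycling rates: tracer-fuelled and ambient denitrification (D15,
#' D14), coupled nitrification-denitrification (Dn, as a rate and as a
#' percentage of D14), ambient anammox (A14), the anammox share of total N2
#' production (ra), ambient DNRA (DNRA14), and sediment oxygen demand (SOD).
#' Rates are umol N m-2 h-1 (SOD: umol O2 m-2 h-1); percentages in percent.
#'
#' @return data.frame with one row per station; `<rate>` columns are means,
#'   `<rate>_se` standard errors, `n` the replicate count.
#' @examples
#' r <- hanna_shoal_rates()
#' with(r[r$station == "CBL13", ], d14 + d15)  # peak total potential: 40.8
#' @export
hanna_shoal_rates <- function() {
  data.frame(
    station = c("CBL11", "CBL13", "H17", "H29", "H33"),
    n   = c(6L, 4L, 6L, 4L, 4L),
    d15 = c(7.8, 20.4, 6.9, 1.5, 18.6),
    d15_se = c(0.5, 3.5, 1.1, 0.5, 4.0),
    d14 = c(7.3, 20.4, 5.2, 4.5, 11.7),
    d14_se = c(0.4, 3.0, 0.7, 0.5, 1.8),
    dn_rate = c(5.5, 16.1, 3.6, 4.1, 6.7),
    dn_rate_se = c(0.3, 2.2, 0.5, 0.4, 0.9),
    dn_pct = c(75, 79, 69, 92, 58),
    dn_pct_se = c(0.4, 0.7, 3.1, 2.3, 3.6),
    a14 = c(0.24, 0.29, 0.15, 0.10, 0.33),
    a14_se = c(0.03, 0.05, 0.02, 0.04, 0.08),
    ra  = c(3.2, 1.4, 2.9, 2.4, 3.2),
    ra_se = c(0.4, 0.1, 0.4, 1.6, 1.1),
    dnra14 = c(0.09, 0.53, 0.25, 0.11, 0.18),
    dnra14_se = c(0.06, 0.18, 0.13, 0.12, 0.09),
    sod = c(-207, -436, -230, -102, -548),
    sod_se = c(7.2, 49.5, 17.1, 26.8, 28.4),
    stringsAsFactors = FALSE
  )
}

#' Regional constants for Chukchi and pan-Arctic upscaling
#'
#' Fixed geographic and literature quantities used by the upscaling
#' functions: the northeast Chukchi study-site area, the pan-Arctic shelf
#' area, the global marine denitrification reference, the core-count
#' weighted cross-station mean ambient denitrification rate and its standard
#' deviation, and the fitted BPc regression coefficients used to predict
#' denitrification from bioturbation potential.
#'
#' @return named list: `study_area_km2` (65,500), `arctic_shelf_km2`
#'   (5.052e6), `global_denitrification_tg` (573), `d14_mean` (9.25) and
#'   `d14_sd` (6.27) in umol N m-2 h-1, and `bpc_model` with `slope`
#'   (0.0026) and `intercept` (4.76).
#' @export
chukchi_constants <- function() {
  list(study_area_km2 = 65500,
       arctic_shelf_km2 = 5.052e6,
       global_denitrification_tg = 573,
       d14_mean = 9.25,
       d14_sd = 6.27,
       bpc_model = list(slope = 0.0026, intercept = 4.76))
}
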