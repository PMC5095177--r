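# Readers and validators for the three input tables: station metadata,
# long-format incubation series, and infauna taxon records. All tables are
# plain CSV (RFC 4180); readers validate and never rescale values.

.station_cols <- c("station_id", "latitude", "longitude", "depth_m",
                   "bottom_no3_14", "no3_total_amended", "nh4_total_amended",
                   "bottom_nh4", "bottom_do", "sediment_oc", "sediment_tn",
                   "cn_ratio", "porewater_nh4")

.analytes <- c("N2_28", "N2_29", "N2_30", "O2", "NH4_15", "NH4_total")
.treatments <- c("control", "no3_15", "nh4_15")

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("%s table is missing column(s): %s", what,
          paste(miss, collapse = ", "))
}

#' Read and validate a station metadata table
#'
#' One row per station, with ambient and tracer-amended bottom-water
#' chemistry. The 15N tracer pool sizes are derivable from it: the labelled
#' nitrate pool equals `no3_total_amended - bottom_no3_14` (the tracer was
#' quantified as the concentration difference after amendment).
#'
#' @param path CSV file path.
#' @return data.frame of class `"station_table"`, one validated row per
#'   station, with derived columns `no3_15` (uM), `f_n` and `f_a` (labelled
#'   fractions of the nitrate and ammonium pools).
#' @examples
#' st <- read_stations(write_stations(hanna_shoal_stations(), tempfile()))
#' st[st$station_id == "CBL11", "no3_15"]   # 26.0 uM labelled nitrate
#' @export
read_stations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, .station_cols, "station")
  if (nrow(df) == 0L) return(structure(df, class = c("station_table",
                                                     "data.frame")))
  if (anyDuplicated(df$station_id))
    stopf("duplicate station_id in station table")
  bad <- which(abs(df$latitude) > 90)
  if (length(bad)) stopf("station %s: |latitude| > 90", df$station_id[bad[1]])
  conc_cols <- setdiff(.station_cols, c("station_id", "latitude", "longitude"))
  for (cc in conc_cols) {
    bad <- which(!is.na(df[[cc]]) & df[[cc]] < 0)
    if (length(bad))
      stopf("station %s: negative value in %s", df$station_id[bad[1]], cc)
  }
  bad <- which(!is.na(df$no3_total_amended) &
                 df$no3_total_amended <= df$bottom_no3_14)
  if (length(bad))
    stopf("station %s: amended NO3- (%g) not above ambient (%g)",
          df$station_id[bad[1]], df$no3_total_amended[bad[1]],
          df$bottom_no3_14[bad[1]])
  df <- tracer_fractions(df)
  structure(df, class = c("station_table", "data.frame"))
}

#' Derive tracer pool sizes and labelled fractions per station
#'
#' Adds `no3_15` (uM), `f_n` (= no3_15 / no3_total_amended) and `f_a`
#' (= labelled share of the amended ammonium pool, computed against ambient
#' `bottom_nh4`) to a station table.
#'
#' @param stations station data.frame with the amended and ambient columns.
#' @return the input with `no3_15`, `f_n`, `f_a` columns added.
#' @export
tracer_fractions <- function(stations) {
  stations$no3_15 <- stations$no3_total_amended - stations$bottom_no3_14
  stations$f_n <- stations$no3_15 / stations$no3_total_amended
  stations$f_a <- (stations$nh4_total_amended - stations$bottom_nh4) /
    stations$nh4_total_amended
  stations
}

#' Read and validate a long-format incubation table
#'
#' Long (tidy) layout keyed by station, core, treatment, time and analyte,
#' with inflow and outflow concentrations, flow rate and core geometry on
#' every row. Core area may be given directly (`area_m2`) or via
#' `diameter_cm` (A = pi (d/2)^2); an explicit area wins when both exist.
#'
#' @param path CSV file path with columns `station_id, core_id, treatment,
#'   time_h, analyte, inflow, outflow, flow_lh` and `area_m2` and/or
#'   `diameter_cm`. Treatments are `control`, `no3_15`, `nh4_15`; analytes
#'   `N2_28, N2_29, N2_30, O2, NH4_15` (plus `NH4_total` in fraction mode).
#' @param nh4_15_as `"conc"` if `NH4_15` rows are absolute concentrations
#'   (uM) or `"fraction"` if they are the labelled share of the total
#'   ammonium pool (then `NH4_total` rows must be present).
#' @return data.frame of class `"incubation_table"`, sorted by core and
#'   time, with a resolved `area_m2` column and attribute `nh4_15_as`.
#' @export
read_incubations <- function(path, nh4_15_as = c("conc", "fraction")) {
  nh4_15_as <- match.arg(nh4_15_as)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_incubation_table(df, nh4_15_as = nh4_15_as)
}

#' Validate an in-memory incubation data.frame
#'
#' The validation backend of [read_incubations()]; also applied to simulator
#' output so generated and file-read series pass identical checks.
#'
#' @inheritParams read_incubations
#' @param df long-format incubation data.frame.
#' @return validated `"incubation_table"` data.frame.
#' @export
as_incubation_table <- function(df, nh4_15_as = c("conc", "fraction")) {
  nh4_15_as <- match.arg(nh4_15_as)
  base_cols <- c("station_id", "core_id", "treatment", "time_h", "analyte",
                 "inflow", "outflow", "flow_lh")
  .require_cols(df, base_cols, "incubation")
  if (!("area_m2" %in% names(df)) && !("diameter_cm" %in% names(df)))
    stopf("incubation table needs an area_m2 or diameter_cm column")
  if (!("area_m2" %in% names(df))) df$area_m2 <- NA_real_
  if ("diameter_cm" %in% names(df)) {
    use_d <- is.na(df$area_m2)
    df$area_m2[use_d] <- pi * (df$diameter_cm[use_d] / 100 / 2)^2
  }
  bad <- !(df$treatment %in% .treatments)
  if (any(bad)) stopf("unknown treatment '%s'", df$treatment[which(bad)[1]])
  bad <- !(df$analyte %in% .analytes)
  if (any(bad)) stopf("unknown analyte '%s'", df$analyte[which(bad)[1]])
  if (any(df$flow_lh <= 0)) stopf("flow_lh must be > 0")
  if (any(df$area_m2 <= 0 | is.na(df$area_m2)))
    stopf("core area must be > 0 (supply area_m2 or diameter_cm)")
  key <- paste(df$station_id, df$core_id, df$treatment, df$time_h, df$analyte)
  if (anyDuplicated(key))
    stopf("duplicate (core, treatment, time, analyte) row: %s",
          key[anyDuplicated(key)])
  # per-series checks
  sid <- paste(df$station_id, df$core_id, df$treatment, df$analyte)
  ntp <- tapply(df$time_h, sid, function(t) length(unique(t)))
  if (any(ntp < 2L))
    stopf("series %s has fewer than 2 time points", names(ntp)[ntp < 2L][1])
  for (trt in c("no3_15", "nh4_15")) {
    need <- if (trt == "no3_15") c("N2_29", "N2_30", "NH4_15") else "N2_29"
    sub <- df[df$treatment == trt, ]
    if (nrow(sub)) {
      for (st in unique(sub$station_id)) {
        have <- unique(sub$analyte[sub$station_id == st])
        miss <- setdiff(need, have)
        if (length(miss))
          stopf("station %s treatment %s lacks required analyte(s): %s",
                st, trt, paste(miss, collapse = ", "))
      }
    }
  }
  if (nh4_15_as == "fraction" && !("NH4_total" %in% df$analyte))
    stopf("nh4_15_as='fraction' requires NH4_total analyte rows")
  df <- df[order(df$station_id, df$core_id, df$treatment, df$analyte,
                 df$time_h), ]
  rownames(df) <- NULL
  structure(df, class = c("incubation_table", "data.frame"),
            nh4_15_as = nh4_15_as)
}

#' Read and validate an infauna taxon table
#'
#' One row per station x taxon with abundance (ind m-2), biomass (g m-2) and
#' ordinal mobility/reworking scores. Zero-abundance rows are retained (they
#' contribute nothing downstream); a positive biomass with zero abundance is
#' rejected as inconsistent.
#'
#' @param path CSV with columns `station_id, taxon, group, abundance,
#'   biomass, mobility, reworking` (scores may be NA; group-level defaults
#'   are substituted later with a logged warning).
#' @param score_range list with `mobility` and `reworking` c(min, max)
#'   vectors bounding the ordinal vocabularies.
#' @return data.frame of class `"taxon_table"`.
#' @export
read_taxa <- function(path, score_range = bpc_score_range()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("station_id", "taxon", "group", "abundance", "biomass",
                      "mobility", "reworking"), "taxon")
  if (nrow(df) == 0L)
    return(structure(df, class = c("taxon_table", "data.frame")))
  if (any(df$abundance < 0) || any(df$biomass < 0))
    stopf("negative abundance or biomass in taxon table")
  bad <- which(df$abundance == 0 & df$biomass > 0)
  if (length(bad))
    stopf("station %s taxon %s: biomass > 0 with abundance = 0",
          df$station_id[bad[1]], df$taxon[bad[1]])
  for (sc in c("mobility", "reworking")) {
    rng <- score_range[[sc]]
    bad <- which(!is.na(df[[sc]]) & (df[[sc]] < rng[1] | df[[sc]] > rng[2]))
    if (length(bad))
      stopf("taxon %s: %s score %g outside [%g, %g]",
            df$taxon[bad[1]], sc, df[[sc]][bad[1]], rng[1], rng[2])
  }
  structure(df, class = c("taxon_table", "data.frame"))
}

#' Write a table back to CSV
#'
#' Plain `write.csv` wrappers so that write-then-read round-trips reproduce
#' identical records (the reader never rescales values).
#'
#' @param x a station, incubation or taxon data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly for `write_incubations`/`write_taxa`; `path`
#'   for `write_stations` (convenient for piping into the reader).
#' @export
write_stations <- function(x, path) {
  utils::write.csv(x[, intersect(.station_cols, names(x))], path,
                   row.names = FALSE)
  path
}

#' @rdname write_stations
#' @export
write_incubations <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stations
#' @export
write_taxa <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
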