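# Small programmatic fixtures shared across test files.

station_csv <- function(path = tempfile(fileext = ".csv"),
                        df = hanna_shoal_stations()) {
  write_stations(df, path)
}

# a minimal hand-built long incubation table: one station, one core per
# treatment, `n_tp` daily time points, constant production fluxes
tiny_incubation_df <- function(n_tp = 4, flow = 0.072, diam_cm = 7.6,
                               fluxes = list(
                                 control = c(N2_28 = 5, N2_29 = 0,
                                             N2_30 = 0, O2 = -207,
                                             NH4_15 = 0),
                                 no3_15 = c(N2_28 = 2, N2_29 = 3,
                                            N2_30 = 2, O2 = -207,
                                            NH4_15 = 0.4),
                                 nh4_15 = c(N2_28 = 5, N2_29 = 0.5,
                                            N2_30 = 0, O2 = -207))) {
  area <- pi * (diam_cm / 200)^2
  inflow <- c(N2_28 = 450, N2_29 = 3.3, N2_30 = 0.006, O2 = 300,
              NH4_15 = 0)
  rows <- list()
  for (trt in names(fluxes)) {
    for (an in names(fluxes[[trt]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        station_id = "S1", core_id = paste0("S1_", trt, "_c1"),
        treatment = trt, time_h = seq_len(n_tp) * 24, analyte = an,
        inflow = inflow[[an]],
        outflow = inflow[[an]] + fluxes[[trt]][[an]] * area / flow,
        flow_lh = flow, diameter_cm = diam_cm, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

tiny_taxa_df <- function() {
  data.frame(
    station_id = c("CBL13", "CBL13", "H17"),
    taxon = c("Maldane sarsi", "Astarte borealis", "Maldane sarsi"),
    group = c("polychaete", "bivalve", "polychaete"),
    abundance = c(5057, 120, 3.3),
    biomass = c(45, 18, 0.05),
    mobility = c(1, 2, 1),
    reworking = c(4, 2, 4), stringsAsFactors = FALSE)
}

zero_noise <- c(gas_cv = 0, nh4_cv = 0, nh4_floor = 0)

# brute-force permutation p-value for an among-group F test
perm_f_oracle <- function(x, g, n_perm = 2000, seed = 1) {
  set.seed(seed)
  fstat <- function(x, g) {
    gm <- tapply(x, g, mean); ns <- tapply(x, g, length)
    ssb <- sum(ns * (gm - mean(x))^2)
    ssw <- sum((x - gm[g])^2)
    if (ssw == 0) return(Inf)
    (ssb / (length(gm) - 1)) / (ssw / (length(x) - length(gm)))
  }
  obs <- fstat(x, factor(g))
  hits <- sum(replicate(n_perm, fstat(x, factor(sample(g))) >= obs))
  (hits + 1) / (n_perm + 1)
}
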