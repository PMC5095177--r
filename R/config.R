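#' Analysis configuration for the rate pipeline
#'
#' Collects the tunable settings used by [ipt()] and its helpers. Defaults
#' follow the study design the package models: two-sided screens at
#' `alpha = 0.05` (one-sided where the question is directional), unweighted
#' station aggregation, and 8760 h per year for annualization.
#'
#' @param alpha significance level for the steady-state and above-control
#'   screens (0 < alpha < 1).
#' @param aggregation_scheme how cross-station summaries weight stations:
#'   `"station_unweighted"` (each station mean counts once) or
#'   `"core_n_weighted"` (stations weighted by their replicate count).
#' @param hours_per_year hours used to annualize hourly rates.
#' @param random_seed integer seed recorded with stochastic results.
#' @param n_bins number of bins for surface binning (>= 2).
#' @param exclusion steady-state exclusion policy: drop offending
#'   `"timepoint"`s (default) or whole `"core"`s.
#' @param dnra14_mode how the ambient-nitrate DNRA share is defined:
#'   `"ambient_share"` (DNRA14 = DNRA_tot * (1 - F_N), mirroring the anammox
#'   A14 construction; default) or `"total_over_fn"` (DNRA14 = p15NH4 / F_N).
#' @param nh4_15_as whether the 15NH4+ analyte carries an absolute
#'   concentration (`"conc"`, uM) or the labelled fraction of the total
#'   ammonium pool (`"fraction"`, requires an `NH4_total` analyte).
#' @param sod_treatments treatments whose O2 fluxes enter sediment oxygen
#'   demand (all incubations are dark; the unamended control is the default).
#' @param anammox_correction function used to remove the anammox 29N2
#'   contribution in the 15NO3- treatment before isotope pairing; must accept
#'   `(p29_total, a_tot, f_n)` and return the corrected p29. Defaults to
#'   [correct_p29_for_anammox()]. Pluggable because the exact published
#'   variant of this accounting differs between laboratories.
#' @return a list of class `"ipt_config"`.
#' @seealso [ipt()]
#' @export
ipt_config <- function(alpha = 0.05,
                       aggregation_scheme = c("station_unweighted",
                                              "core_n_weighted"),
                       hours_per_year = 8760,
                       random_seed = 20130802L,
                       n_bins = 7L,
                       exclusion = c("timepoint", "core"),
                       dnra14_mode = c("ambient_share", "total_over_fn"),
                       nh4_15_as = c("conc", "fraction"),
                       sod_treatments = "control",
                       anammox_correction = correct_p29_for_anammox) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stopf("n_bins must be >= 2, got %d", n_bins)
  stopifnot(hours_per_year > 0, is.function(anammox_correction))
  cfg <- list(alpha = alpha,
              aggregation_scheme = match.arg(aggregation_scheme),
              hours_per_year = hours_per_year,
              random_seed = as.integer(random_seed),
              n_bins = n_bins,
              exclusion = match.arg(exclusion),
              dnra14_mode = match.arg(dnra14_mode),
              nh4_15_as = match.arg(nh4_15_as),
              sod_treatments = sod_treatments,
              anammox_correction = anammox_correction)
  class(cfg) <- "ipt_config"
  cfg
}
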