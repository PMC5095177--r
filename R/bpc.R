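# Community bioturbation potential (BPc): per-taxon contributions
# sqrt(B_i / A_i) * A_i * M_i * R_i summed over a station's community.

#' Default ordinal score vocabularies for the BPc index
#'
#' Mobility is scored 1-4 (fixed tube through free three-dimensional
#' movement) and sediment reworking 1-5 (epifauna through regenerators),
#' following the trait scoring commonly used with this index.
#'
#' @return list with `mobility` and `reworking` c(min, max) ranges.
#' @export
bpc_score_range <- function() {
  list(mobility = c(1, 4), reworking = c(1, 5))
}

#' Default group-level trait scores
#'
#' Editable lookup used when a taxon record lacks mobility or reworking
#' scores: taxa inherit their group's default with a logged warning rather
#' than being dropped (dropping would bias BPc low). The defaults are
#' deliberately mid-range trait assignments for the broad groups: tube
#' building and burrowing polychaetes rework sediment substantially;
#' bivalves and amphipods less so.
#'
#' @return data.frame with `group`, `mobility`, `reworking`.
#' @export
bpc_score_defaults <- function() {
  data.frame(group = c("polychaete", "bivalve", "amphipod", "other"),
             mobility = c(3, 2, 3, 2),
             reworking = c(4, 2, 2, 2),
             stringsAsFactors = FALSE)
}

#' Per-taxon bioturbation potential contribution
#'
#' `sqrt(B_i / A_i) * A_i * M_i * R_i`, i.e. mean individual body mass to
#' the one-half power times abundance times the mobility and reworking
#' scores; zero when the taxon is absent (A_i = 0). Equivalently
#' `sqrt(A_i * B_i) * M_i * R_i`, so doubling both abundance and biomass
#' doubles the contribution.
#'
#' @param abundance A_i, individuals m-2 (>= 0).
#' @param biomass B_i, g m-2 (>= 0).
#' @param mobility,reworking positive ordinal scores.
#' @return contribution in BPc index units.
#' @examples
#' bpc_taxon(100, 25, 3, 2)  # 300
#' @export
bpc_taxon <- function(abundance, biomass, mobility, reworking) {
  if (any(abundance < 0) || any(biomass < 0))
    stopf("abundance and biomass must be >= 0")
  if (any(mobility <= 0) || any(reworking <= 0))
    stopf("mobility and reworking scores must be positive")
  ifelse(abundance == 0, 0,
         sqrt(biomass / abundance) * abundance * mobility * reworking)
}

#' Community bioturbation potential for one station
#'
#' Sums [bpc_taxon()] contributions over a station's taxon records and
#' reports community totals. Records with missing scores inherit the
#' group-level defaults with a logged warning.
#'
#' @param taxa taxon records for one station (see [read_taxa()]).
#' @param defaults group-level score defaults, see [bpc_score_defaults()].
#' @return list of class `"bpc_result"`: `bpc`, `contributions` (per
#'   taxon), `abundance`, `biomass`, `richness` (taxa with A_i > 0), and
#'   `group_abundance` (named vector).
#' @export
bpc_community <- function(taxa, defaults = bpc_score_defaults()) {
  taxa <- as.data.frame(taxa)
  if (nrow(taxa) == 0L) {
    out <- list(bpc = 0, contributions = numeric(0), abundance = 0,
                biomass = 0, richness = 0L,
                group_abundance = stats::setNames(numeric(0), character(0)))
    class(out) <- "bpc_result"
    return(out)
  }
  if (length(unique(taxa$station_id)) > 1L)
    stopf("bpc_community expects records from a single station")
  for (sc in c("mobility", "reworking")) {
    miss <- is.na(taxa[[sc]])
    if (any(miss)) {
      bn_log("bpc", sprintf("%d taxa missing %s score; group defaults used",
                            sum(miss), sc), taxa$station_id[1])
      taxa[[sc]][miss] <-
        defaults[[sc]][match(taxa$group[miss], defaults$group)]
      if (anyNA(taxa[[sc]]))
        stopf("no default %s score for group '%s'", sc,
              taxa$group[is.na(taxa[[sc]])][1])
    }
  }
  contr <- bpc_taxon(taxa$abundance, taxa$biomass, taxa$mobility,
                     taxa$reworking)
  names(contr) <- taxa$taxon
  out <- list(bpc = sum(contr), contributions = contr,
              abundance = sum(taxa$abundance), biomass = sum(taxa$biomass),
              richness = sum(taxa$abundance > 0),
              group_abundance = tapply(taxa$abundance, taxa$group, sum))
  class(out) <- "bpc_result"
  out
}

#' @export
print.bpc_result <- function(x, ...) {
  cat(sprintf(
    "BPc = %.1f (%d taxa, %.0f ind m-2, %.1f g m-2)\n",
    x$bpc, x$richness, x$abundance, x$biomass))
  invisible(x)
}

#' BPc per station from a multi-station taxon table
#'
#' @param taxa a `"taxon_table"` covering one or more stations.
#' @param defaults group-level score defaults.
#' @return data.frame with one row per station: `station_id, bpc,
#'   abundance, biomass, richness`.
#' @export
bpc_table <- function(taxa, defaults = bpc_score_defaults()) {
  taxa <- as.data.frame(taxa)
  out <- do.call(rbind, lapply(split(taxa, taxa$station_id), function(d) {
    b <- bpc_community(d, defaults)
    data.frame(station_id = d$station_id[1], bpc = b$bpc,
               abundance = b$abundance, biomass = b$biomass,
               richness = b$richness, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
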