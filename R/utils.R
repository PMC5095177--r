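#' @keywords internal
"_PACKAGE"

# Standard error of the mean; single value -> 0 (one core is its own mean).
sem <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n <= 1L) return(0)
  stats::sd(x) / sqrt(n)
}

#' Structured pipeline log
#'
#' Writes one structured line (timestamp, stage, station, message) to stderr
#' via [message()], and appends to the file named by
#' `options(benthicN.logfile=)` when set. Suppress with
#' `suppressMessages()` as usual.
#'
#' @param stage character; pipeline stage tag (e.g. "flux", "rates").
#' @param msg character; the message.
#' @param station optional station id for context.
#' @return invisibly, the formatted line.
#' @export
bn_log <- function(stage, msg, station = NA_character_) {
  line <- sprintf("%s [%s] %s%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage,
                  if (is.na(station)) "" else paste0(station, ": "),
                  msg)
  logfile <- getOption("benthicN.logfile", NULL)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
  message(line)
  invisible(line)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Great-circle-free local metric: plate carree with cos(latitude) shortening
# of longitude; adequate at shelf scale. Returns km.
latlon_dist <- function(lon1, lat1, lon2, lat2, lat_ref = NULL) {
  if (is.null(lat_ref)) lat_ref <- mean(c(lat1, lat2))
  kmdeg <- 111.195
  dx <- (lon1 - lon2) * cos(lat_ref * pi / 180) * kmdeg
  dy <- (lat1 - lat2) * kmdeg
  sqrt(dx^2 + dy^2)
}
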