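#' proxinet: contact-network processing for a preschool RFID deployment
#'
#' Tools to go from raw wearable-badge beacon logs (observed DID, timestamp,
#' RSSI triplets) to cleaned signal sequences, reconstructed temporal contact
#' networks, and free-/class-time annotations, together with a deployment
#' simulator exporting matching ground truth.
#'
#' @import tibble
#' @importFrom dplyr %>% arrange bind_rows distinct filter group_by left_join
#'   mutate n rename select slice summarise ungroup anti_join semi_join
#' @importFrom rlang .data
#' @importFrom stats dnorm glm plogis predict rnorm runif sd setNames
#'   binomial aggregate
#' @importFrom utils head read.csv tail write.csv
#' @keywords internal
"_PACKAGE"

# Beacon period of the badges, in seconds. Every badge broadcasts a hello
# packet on this period; all slot arithmetic in the package is on this grid.
SLOT_S <- 5

# Recordable RSSI range after initial cleaning (dBm); the radio sensitivity
# floor is -94 dBm, below which packets are never stored.
RSSI_MIN <- -94L
RSSI_CLEAN_MIN <- -93L
RSSI_MAX <- -16L

#' Classify a badge identifier
#'
#' DIDs are 4-digit decimal codes: leading digit 0 for children, 1 for adults,
#' 2 for stationary RX badges (last digit gives the class for 2001-2007, or a
#' gym room for 2010/2011).
#'
#' @param did character vector of 4-digit DIDs.
#' @return character vector in \code{c("child", "adult", "rx")}.
#' @export
#' @examples
#' badge_kind(c("0412", "1003", "2001"))
badge_kind <- function(did) {
  did <- as.character(did)
  bad <- !grepl("^[0-9]{4}$", did)
  if (any(bad)) {
    stop("malformed DID (expected 4 decimal digits): ", did[bad][1])
  }
  first <- substr(did, 1, 1)
  out <- rep(NA_character_, length(did))
  out[first == "0"] <- "child"
  out[first == "1"] <- "adult"
  out[first == "2"] <- "rx"
  if (anyNA(out)) {
    stop("DID with unknown leading digit: ", did[is.na(out)][1])
  }
  out
}

#' Session windows of the school day
#'
#' The school runs a morning session from 08:30 to 11:20 and an afternoon
#' session from 13:45 to 15:50 (no afternoon session on Wednesdays, giving
#' nine half-days per week). Timestamps are seconds since the project T0
#' midnight; day \code{d} occupies \code{[(d-1)*86400, d*86400)}.
#'
#' @param day integer 1-5 (Monday-Friday).
#' @param session "M" or "A".
#' @return named numeric vector \code{c(start, end)} in seconds since T0.
#' @export
#' @examples
#' session_window(1, "M")  # Monday morning: 30600 .. 40800
session_window <- function(day, session) {
  stopifnot(length(day) == 1, day %in% 1:5, session %in% c("M", "A"))
  if (day == 3 && session == "A") {
    stop("no afternoon session on Wednesdays")
  }
  tod <- if (session == "M") c(8.5, 11 + 20 / 60) else c(13.75, 15 + 50 / 60)
  off <- (day - 1) * 86400
  c(start = off + round(tod[1] * 3600), end = off + round(tod[2] * 3600))
}

#' Half-day sessions of one deployment week
#'
#' @return tibble with columns \code{day}, \code{session} (nine rows; there is
#'   no Wednesday afternoon session).
#' @export
week_sessions <- function() {
  tibble::tibble(
    day = rep(1:5, each = 2),
    session = rep(c("M", "A"), 5)
  ) %>%
    dplyr::filter(!(.data$day == 3 & .data$session == "A"))
}

# empty canonical record table
empty_records <- function() {
  tibble::tibble(
    observed_did = character(),
    timestamp = numeric(),
    rssi = integer()
  )
}

# Canonical record ordering: timestamp ascending, ties by observed_did.
sort_records <- function(records) {
  records[order(records$timestamp, records$observed_did), , drop = FALSE]
}

# Validate a record table against the type invariants. `raw` relaxes the
# RSSI floor to the -94 dBm sensitivity limit (simulator output before
# initial cleaning).
validate_records <- function(records, raw = FALSE) {
  floor_dbm <- if (raw) RSSI_MIN else RSSI_CLEAN_MIN
  bad <- which(records$rssi < floor_dbm | records$rssi > RSSI_MAX |
                 !is.finite(records$rssi))
  if (length(bad)) {
    stop(sprintf("record %d: RSSI %s outside [%d, %d] dBm",
                 bad[1], records$rssi[bad[1]], floor_dbm, RSSI_MAX))
  }
  bad_t <- which(!is.finite(records$timestamp) | records$timestamp < 0)
  if (length(bad_t)) {
    stop(sprintf("record %d: invalid timestamp", bad_t[1]))
  }
  invisible(records)
}
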