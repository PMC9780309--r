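#' File dialects and initial cleaning
#'
#' Half-day beacon logs are comma-separated triplet files
#' \code{(observed DID, timestamp, RSSI)} named \code{CID-D-DID-MA.csv}
#' (class, day-of-week 1-5, badge DID, M/A session), organized under
#' \code{Y_WEEKXX/HD_individual_{cleaned,preprocessed}/{PROX,RX}/}.
#' Reconstructed temporal networks are stored one file per half-day as
#' \code{D-MA-RM.csv}, one interaction event per row.
#'
#' @name signal_io
NULL

TNET_METHODS <- c("unrec", "naive", "hmm", "blstm_RSSI")

#' Construct a half-day signal sequence
#'
#' @param owner badge DID owning the log.
#' @param class_id class number 1-7.
#' @param day day of week 1-5.
#' @param session "M" or "A".
#' @param records tibble with columns \code{observed_did}, \code{timestamp},
#'   \code{rssi}; sorted on construction (timestamp, then observed DID).
#' @param raw if TRUE, allow RSSI down to the -94 dBm sensitivity floor
#'   (simulator output before initial cleaning).
#' @return object of class \code{half_day}.
#' @export
half_day <- function(owner, class_id, day, session, records = empty_records(),
                     raw = FALSE) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("observed_did", "timestamp", "rssi") %in% names(records)))
  records$observed_did <- as.character(records$observed_did)
  records$rssi <- as.integer(records$rssi)
  validate_records(records, raw = raw)
  structure(
    list(owner = as.character(owner), kind = badge_kind(owner),
         class_id = as.integer(class_id), day = as.integer(day),
         session = session, records = sort_records(records)),
    class = "half_day"
  )
}

#' @export
print.half_day <- function(x, ...) {
  cat(sprintf("<half_day> %s (%s) class %d day %d %s: %d records\n",
              x$owner, x$kind, x$class_id, x$day, x$session,
              nrow(x$records)))
  invisible(x)
}

#' Compose / parse the CID-D-DID-MA.csv filename grammar
#'
#' @param class_id,day,did,session filename fields.
#' @return \code{signal_filename}: the file name; \code{parse_signal_filename}:
#'   a list with fields \code{class_id}, \code{day}, \code{did},
#'   \code{session}, \code{kind}.
#' @export
signal_filename <- function(class_id, day, did, session) {
  stopifnot(class_id %in% 1:7, day %in% 1:5, session %in% c("M", "A"))
  sprintf("%d-%d-%s-%s.csv", class_id, day, as.character(did), session)
}

#' @rdname signal_filename
#' @param name a file name (directories are stripped).
#' @export
parse_signal_filename <- function(name) {
  name <- basename(name)
  m <- regmatches(name, regexec("^([1-7])-([1-5])-([0-9]{4})-([MA])\\.csv$",
                                name))[[1]]
  if (length(m) != 5) {
    stop("file name does not follow the CID-D-DID-MA.csv grammar: ", name)
  }
  list(class_id = as.integer(m[2]), day = as.integer(m[3]), did = m[4],
       session = m[5], kind = badge_kind(m[4]))
}

#' Read one half-day triplet file
#'
#' @param path path to a \code{CID-D-DID-MA.csv} file. Rows are
#'   \code{observed_did,timestamp,rssi} with no header; an empty body yields a
#'   zero-record sequence. Records are returned time-sorted regardless of file
#'   order.
#' @param raw allow raw-simulator RSSI floor of -94 dBm.
#' @return a \code{\link{half_day}} object.
#' @export
read_half_day <- function(path, raw = FALSE) {
  meta <- parse_signal_filename(path)
  if (file.size(path) == 0) {
    return(half_day(meta$did, meta$class_id, meta$day, meta$session))
  }
  df <- utils::read.csv(path, header = FALSE,
                        colClasses = c("character", "numeric", "numeric"),
                        col.names = c("observed_did", "timestamp", "rssi"))
  if (any(is.na(df$timestamp)) || any(is.na(df$rssi))) {
    stop("non-numeric field in ", basename(path), " at row ",
         which(is.na(df$timestamp) | is.na(df$rssi))[1])
  }
  half_day(meta$did, meta$class_id, meta$day, meta$session,
           tibble::as_tibble(df), raw = raw)
}

#' Write a half-day sequence under a PROX/RX tree
#'
#' @param hd a \code{\link{half_day}} object.
#' @param root directory that holds the \code{PROX} and \code{RX} subfolders
#'   (created if absent). The subfolder is chosen from the badge kind.
#' @return the written path, invisibly.
#' @export
write_half_day <- function(hd, root) {
  stopifnot(inherits(hd, "half_day"))
  sub <- if (hd$kind == "rx") "RX" else "PROX"
  dir.create(file.path(root, sub), recursive = TRUE, showWarnings = FALSE)
  path <- file.path(root, sub,
                    signal_filename(hd$class_id, hd$day, hd$owner, hd$session))
  df <- hd$records
  # canonical dialect: no header, no quoting, integer-or-half-second times
  lines <- sprintf("%s,%s,%d", df$observed_did,
                   format_time(df$timestamp), df$rssi)
  writeLines(lines, path)
  invisible(path)
}

format_time <- function(t) {
  ifelse(t == round(t), format(round(t), scientific = FALSE, trim = TRUE),
         sprintf("%.1f", t))
}

#' Read / write temporal-network event files
#'
#' Event files \code{D-MA-RM.csv} carry a header row
#' \code{t,i,j,delta,labels,flag}: an interaction event starting at \code{t}
#' between badges \code{i} and \code{j} lasting \code{delta} seconds (a
#' positive multiple of the 5-s beacon period), a 4-symbol free/class label
#' string over \code{{F,C}} and a same-class flag in \code{{0,1}}.
#'
#' @param records tibble with columns \code{t}, \code{i}, \code{j},
#'   \code{delta}, \code{labels}, \code{flag}.
#' @param root output directory (created if needed).
#' @param day,session filename fields.
#' @param method reconstruction-method tag, one of \code{unrec}, \code{naive},
#'   \code{hmm}, \code{blstm_RSSI}.
#' @return \code{write_tnet}: the path, invisibly; \code{read_tnet}: the
#'   record tibble with a \code{method} attribute.
#' @export
write_tnet <- function(records, root, day, session, method) {
  records <- validate_tnet(records, method)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(root, sprintf("%d-%s-%s.csv", day, session, method))
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tnet
#' @param path path of a \code{D-MA-RM.csv} file.
#' @export
read_tnet <- function(path) {
  m <- regmatches(basename(path),
                  regexec("^([1-5])-([MA])-(.+)\\.csv$", basename(path)))[[1]]
  if (length(m) != 4) stop("not a D-MA-RM.csv tnet file name: ", basename(path))
  method <- m[4]
  df <- utils::read.csv(path, header = TRUE,
                        colClasses = c("numeric", "character", "character",
                                       "numeric", "character", "integer"))
  out <- validate_tnet(tibble::as_tibble(df), method)
  attr(out, "method") <- method
  attr(out, "day") <- as.integer(m[2])
  attr(out, "session") <- m[3]
  out
}

validate_tnet <- function(records, method) {
  if (!method %in% TNET_METHODS) {
    stop("unknown reconstruction method tag: ", method)
  }
  records <- tibble::as_tibble(records)
  need <- c("t", "i", "j", "delta", "labels", "flag")
  stopifnot(all(need %in% names(records)))
  records <- records[, need]
  if (nrow(records)) {
    if (any(records$delta <= 0 | records$delta %% SLOT_S != 0)) {
      stop("event duration must be a positive multiple of the 5-s slot")
    }
    if (any(!grepl("^[FC]{4}$", records$labels))) {
      stop("labels must be 4-symbol strings over {F,C}")
    }
    if (any(!records$flag %in% c(0L, 1L))) stop("flag must be 0 or 1")
  }
  records
}

#' Remove incident-affected signals
#'
#' Signals emitted or received by unused, broken or missing badges are removed
#' bidirectionally: for each incident (badge, interval) the badge's own
#' received records in the interval are dropped, and every appearance of the
#' badge as \code{observed_did} in other badges' sequences in the interval is
#' dropped too.
#'
#' @param sequences named list of \code{\link{half_day}} objects for one
#'   half-day (names are the owner DIDs).
#' @param incidents tibble with columns \code{did}, \code{t_start},
#'   \code{t_end} (half-open interval) and optionally \code{reason}.
#' @return the cleaned list of sequences.
#' @export
apply_incident_log <- function(sequences, incidents) {
  if (is.null(incidents) || nrow(incidents) == 0) return(sequences)
  known <- names(sequences)
  unknown <- setdiff(unique(as.character(incidents$did)), known)
  if (length(unknown)) {
    stop("incident references unknown DID: ", unknown[1])
  }
  for (k in seq_len(nrow(incidents))) {
    b <- as.character(incidents$did[k])
    t0 <- incidents$t_start[k]; t1 <- incidents$t_end[k]
    for (nm in names(sequences)) {
      rec <- sequences[[nm]]$records
      keep <- if (nm == b) {
        !(rec$timestamp >= t0 & rec$timestamp < t1)
      } else {
        !(rec$observed_did == b & rec$timestamp >= t0 & rec$timestamp < t1)
      }
      sequences[[nm]]$records <- rec[keep, , drop = FALSE]
    }
  }
  sequences
}

#' Merge half-day file fragments
#'
#' A participant can appear with several file fragments for one half-day
#' (badge replacement, system errors). Fragments are merged into a single
#' sequence: the union of records, clipped to the session window, duplicate
#' \code{(observed_did, timestamp)} rows collapsed keeping the strongest RSSI,
#' and sorted.
#'
#' @param fragments list of \code{\link{half_day}} objects sharing owner, day
#'   and session.
#' @param window session window \code{c(start, end)}; defaults to the
#'   fragments' own \code{\link{session_window}}.
#' @return one merged \code{\link{half_day}}.
#' @export
merge_fragments <- function(fragments, window = NULL) {
  stopifnot(length(fragments) >= 1)
  owners <- vapply(fragments, function(f) f$owner, "")
  days <- vapply(fragments, function(f) f$day, 1L)
  sessions <- vapply(fragments, function(f) f$session, "")
  if (length(unique(owners)) != 1 || length(unique(days)) != 1 ||
      length(unique(sessions)) != 1) {
    stop("fragments mix owners or half-days")
  }
  if (is.null(window)) window <- session_window(days[1], sessions[1])
  rec <- dplyr::bind_rows(lapply(fragments, function(f) f$records))
  rec <- rec[rec$timestamp >= window[1] & rec$timestamp < window[2], ,
             drop = FALSE]
  if (nrow(rec)) {
    rec <- rec %>%
      dplyr::group_by(.data$observed_did, .data$timestamp) %>%
      dplyr::slice(which.max(.data$rssi)) %>%
      dplyr::ungroup()
  }
  half_day(owners[1], fragments[[1]]$class_id, days[1], sessions[1], rec)
}

#' Flatten sequences to a single signal table (and back)
#'
#' Internally most pipeline stages work on a flat table with one row per
#' received packet: \code{badge} (the receiver/owner), \code{observed_did},
#' \code{timestamp}, \code{rssi}.
#'
#' @param sequences named list of \code{\link{half_day}} objects.
#' @return a tibble.
#' @export
signal_table <- function(sequences) {
  if (!length(sequences)) {
    return(tibble::tibble(badge = character(), observed_did = character(),
                          timestamp = numeric(), rssi = integer()))
  }
  dplyr::bind_rows(lapply(sequences, function(hd) {
    if (nrow(hd$records) == 0) return(NULL)
    tibble::tibble(badge = hd$owner, hd$records)
  }))
}

#' @rdname signal_table
#' @param tbl a signal table.
#' @param roster tibble with columns \code{did}, \code{kind}, \code{class_id}
#'   covering every badge (receivers and observed).
#' @param day,session half-day identity of the table.
#' @return \code{sequences_from_table}: named list of \code{half_day}, one per
#'   roster badge (badges without records get empty sequences).
#' @export
sequences_from_table <- function(tbl, roster, day, session) {
  out <- list()
  for (k in seq_len(nrow(roster))) {
    did <- roster$did[k]
    rec <- tbl[tbl$badge == did, c("observed_did", "timestamp", "rssi"),
               drop = FALSE]
    out[[did]] <- half_day(did, roster$class_id[k], day, session, rec)
  }
  out
}

#' Presence and coverage tables
#'
#' One row per participant per week. The IN-OUT table states enrollment
#' (\code{IN}/\code{OUT}); the DURATION table gives the covered observation
#' time in seconds (5 s per distinct beacon slot with any received signal in
#' the participant's own log), or \code{NA} when an enrolled participant had
#' no data that week.
#'
#' @param roster participant roster (\code{did}, \code{kind}, \code{class_id});
#'   RX badges are excluded from the tables.
#' @param signals_by_week named list (week label -> signal table of that
#'   week's pre-processed records).
#' @param enrollment tibble \code{did}, \code{week}, \code{enrolled} (logical);
#'   missing combinations default to enrolled.
#' @return list with tibbles \code{in_out} and \code{duration} (columns:
#'   \code{did}, one column per week).
#' @export
presence_tables <- function(roster, signals_by_week, enrollment = NULL) {
  part <- roster$did[roster$kind != "rx"]
  weeks <- names(signals_by_week)
  stopifnot(length(weeks) > 0)
  is_in <- function(did, wk) {
    if (is.null(enrollment)) return(TRUE)
    hit <- enrollment$did == did & enrollment$week == wk
    if (!any(hit)) TRUE else all(enrollment$enrolled[hit])
  }
  in_out <- duration <- tibble::tibble(did = part)
  for (wk in weeks) {
    tbl <- signals_by_week[[wk]]
    cov <- unname(covered_seconds(tbl, part))
    ins <- unname(vapply(part, is_in, TRUE, wk = wk))
    in_out[[wk]] <- ifelse(ins, "IN", "OUT")
    dur <- ifelse(cov > 0, cov, NA_real_)
    dur[!ins] <- NA_real_
    duration[[wk]] <- dur
  }
  list(in_out = in_out, duration = duration)
}

covered_seconds <- function(tbl, dids) {
  if (nrow(tbl) == 0) return(stats::setNames(numeric(length(dids)), dids))
  slots <- unique(tbl[, c("badge", "timestamp")])
  slots$slot <- SLOT_S * floor(slots$timestamp / SLOT_S)
  per <- stats::aggregate(slot ~ badge, data = slots,
                          FUN = function(s) length(unique(s)))
  out <- stats::setNames(numeric(length(dids)), dids)
  hit <- per$badge %in% dids
  out[per$badge[hit]] <- SLOT_S * per$slot[hit]
  out
}

#' @rdname presence_tables
#' @param tables result of \code{presence_tables}.
#' @param dir output directory; files \code{IN-OUT.csv}, \code{DURATION.csv}.
#' @export
write_presence_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tables$in_out, file.path(dir, "IN-OUT.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(tables$duration, file.path(dir, "DURATION.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Initial cleaning of a raw signal table
#'
#' Drops packets below the -93 dBm recordable floor, clips to the session
#' window, and collapses duplicate (receiver, sender, timestamp) rows keeping
#' the strongest RSSI.
#'
#' @param signals raw signal table (\code{badge}, \code{observed_did},
#'   \code{timestamp}, \code{rssi}).
#' @param window session window \code{c(start, end)}.
#' @return cleaned signal table.
#' @export
initial_clean_signals <- function(signals, window) {
  sig <- signals[signals$rssi >= RSSI_CLEAN_MIN &
                   signals$timestamp >= window[1] &
                   signals$timestamp < window[2], , drop = FALSE]
  if (nrow(sig)) {
    ord <- order(sig$badge, sig$observed_did, sig$timestamp, -sig$rssi)
    sig <- sig[ord, , drop = FALSE]
    key <- paste(sig$badge, sig$observed_did, sig$timestamp)
    sig <- sig[!duplicated(key), , drop = FALSE]
  }
  dplyr::arrange(sig, .data$badge, .data$timestamp, .data$observed_did)
}
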