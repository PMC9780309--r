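#' Pre-processing parameters
#'
#' Defaults are the deployed calibration: 3-minute sliding windows with a
#' 1-minute step and an 80\%-of-expected completeness floor; worn/unworn
#' thresholds of -62 dBm mean and 2.5 SD at the class RX; more restrictive
#' -55 dBm / 1.5 on a badge's own log (protecting close face-to-face
#' contacts); inactive periods bridged when closer than 2 minutes and padded
#' by a 30-s safety margin; edge bursts trimmed with a -45 dBm strong-signal
#' threshold, a 1-minute window and a 20-s continuation offset.
#'
#' @param window_s,step_s sliding-window length and step (s).
#' @param completeness fraction of expected signals required for a window to
#'   count (floor is the ceiling of \code{completeness * window_s / 5}).
#' @param rx_mean_dbm,rx_sd RX-based (unworn-near-hub) thresholds: flag when
#'   mean >= \code{rx_mean_dbm} and SD <= \code{rx_sd}.
#' @param prox_mean_dbm,prox_sd own-log (piled badges) thresholds.
#' @param bridge_s concatenate flagged intervals closer than this gap.
#' @param margin_s safety margin added on both ends of each interval.
#' @param strong_dbm edge-burst strong-signal threshold (RSSI strictly above).
#' @param edge_window_s,edge_offset_s edge-burst scan window and continuation
#'   offset.
#' @return a named list of parameters.
#' @export
preprocess_params <- function(window_s = 180, step_s = 60,
                              completeness = 0.8,
                              rx_mean_dbm = -62, rx_sd = 2.5,
                              prox_mean_dbm = -55, prox_sd = 1.5,
                              bridge_s = 120, margin_s = 30,
                              strong_dbm = -45, edge_window_s = 60,
                              edge_offset_s = 20) {
  list(window_s = window_s, step_s = step_s, completeness = completeness,
       rx_mean_dbm = rx_mean_dbm, rx_sd = rx_sd,
       prox_mean_dbm = prox_mean_dbm, prox_sd = prox_sd,
       bridge_s = bridge_s, margin_s = margin_s, strong_dbm = strong_dbm,
       edge_window_s = edge_window_s, edge_offset_s = edge_offset_s)
}

#' Number of signals required for a complete sliding window
#'
#' @param window_s window length in seconds.
#' @param completeness required fraction of the expected count.
#' @param period_s beacon period.
#' @return integer floor (29 for the default 3-minute window at 5-s beacons).
#' @export
completeness_floor <- function(window_s = 180, completeness = 0.8,
                               period_s = SLOT_S) {
  as.integer(ceiling(completeness * window_s / period_s))
}

#' Sliding-window RSSI statistics for one source badge
#'
#' Windows of \code{window_s} seconds advance in steps of \code{step_s} over
#' the session window; for each position the count, mean and population
#' standard deviation of the RSSI values received from \code{source_did} are
#' computed. Windows holding fewer than the completeness floor are marked
#' incomplete and excluded from flagging.
#'
#' @param observer_seq a \code{\link{half_day}} or a record tibble
#'   (\code{observed_did}, \code{timestamp}, \code{rssi}).
#' @param source_did the emitting badge whose signals are scanned.
#' @param window_s,step_s window geometry (s).
#' @param span time span to scan, \code{c(start, end)}; defaults to the
#'   observer's session window.
#' @param completeness completeness fraction.
#' @return tibble \code{t_start}, \code{t_end}, \code{n_signals},
#'   \code{mean_rssi}, \code{std_rssi}, \code{complete}.
#' @export
sliding_window_stats <- function(observer_seq, source_did, window_s = 180,
                                 step_s = 60, span = NULL,
                                 completeness = 0.8) {
  if (inherits(observer_seq, "half_day")) {
    if (is.null(span)) span <- session_window(observer_seq$day,
                                              observer_seq$session)
    rec <- observer_seq$records
  } else {
    rec <- observer_seq
    if (is.null(span)) span <- range(rec$timestamp)
  }
  rec <- rec[rec$observed_did == source_did, , drop = FALSE]
  starts <- seq(span[1], span[2] - window_s, by = step_s)
  t <- sort(rec$timestamp)
  r <- rec$rssi[order(rec$timestamp)]
  cs1 <- c(0, cumsum(as.numeric(r)))
  cs2 <- c(0, cumsum(as.numeric(r)^2))
  lo <- findInterval(starts - 1e-9, t)          # records strictly before start
  hi <- findInterval(starts + window_s - 1e-9, t)  # records before end
  n <- hi - lo
  s1 <- cs1[hi + 1] - cs1[lo + 1]
  s2 <- cs2[hi + 1] - cs2[lo + 1]
  mean_rssi <- ifelse(n > 0, s1 / n, NA_real_)
  var_pop <- ifelse(n > 0, pmax(0, s2 / n - (s1 / n)^2), NA_real_)
  floor_n <- completeness_floor(window_s, completeness)
  tibble::tibble(t_start = starts, t_end = starts + window_s,
                 n_signals = as.integer(n), mean_rssi = mean_rssi,
                 std_rssi = sqrt(var_pop), complete = n >= floor_n)
}

# union of flagged window spans -> disjoint intervals
flags_to_intervals <- function(stats_tbl, flagged) {
  w <- stats_tbl[flagged, , drop = FALSE]
  if (!nrow(w)) {
    return(tibble::tibble(t_start = numeric(), t_end = numeric()))
  }
  union_intervals(w[, c("t_start", "t_end")])
}

# merge overlapping or touching intervals
union_intervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv$t_start, iv$t_end), , drop = FALSE]
  s <- iv$t_start; e <- iv$t_end
  keep_s <- s[1]; keep_e <- e[1]
  for (k in seq_along(s)[-1]) {
    if (s[k] <= keep_e[length(keep_e)]) {
      keep_e[length(keep_e)] <- max(keep_e[length(keep_e)], e[k])
    } else {
      keep_s <- c(keep_s, s[k]); keep_e <- c(keep_e, e[k])
    }
  }
  tibble::tibble(t_start = keep_s, t_end = keep_e)
}

#' Detect an unworn badge from the class RX log
#'
#' An unused badge sitting near the charging hub is heard by the class RX
#' with strong and stable RSSI. Complete windows with mean >= -62 dBm and
#' SD <= 2.5 are flagged and their spans unioned into inactive intervals.
#'
#' @param rx_seq the class RX \code{\link{half_day}} (or record tibble).
#' @param prox_did badge to scan for.
#' @param params \code{\link{preprocess_params}}.
#' @param span scan span override.
#' @return tibble \code{did}, \code{t_start}, \code{t_end}, \code{cause}
#'   (\code{"issue2"}).
#' @export
detect_unworn_rx <- function(rx_seq, prox_did, params = preprocess_params(),
                             span = NULL) {
  st <- sliding_window_stats(rx_seq, prox_did, params$window_s,
                             params$step_s, span, params$completeness)
  flagged <- st$complete & st$mean_rssi >= params$rx_mean_dbm &
    st$std_rssi <= params$rx_sd
  iv <- flags_to_intervals(st, flagged)
  tibble::tibble(did = rep(prox_did, nrow(iv)), iv,
                 cause = rep("issue2", nrow(iv)))
}

#' Detect piled badges from a badge's own log
#'
#' When badges are laid together far from the hub they exchange very strong,
#' very stable signals. The same windowing is applied to the badge's own
#' received sequence, per observed peer, with the more restrictive thresholds
#' mean >= -55 dBm and SD <= 1.5 (so that genuine close face-to-face contacts,
#' which fluctuate, are never flagged).
#'
#' @param prox_seq the badge's \code{\link{half_day}} (or record tibble).
#' @param params \code{\link{preprocess_params}}.
#' @param span scan span override.
#' @return tibble \code{did} (the owner), \code{t_start}, \code{t_end},
#'   \code{cause} (\code{"issue3"}); owner taken from the sequence, or
#'   \code{NA} for a bare tibble.
#' @export
detect_unworn_prox <- function(prox_seq, params = preprocess_params(),
                               span = NULL) {
  owner <- if (inherits(prox_seq, "half_day")) prox_seq$owner else
    NA_character_
  rec <- if (inherits(prox_seq, "half_day")) prox_seq$records else prox_seq
  peers <- unique(rec$observed_did)
  ivs <- list()
  for (p in peers) {
    st <- sliding_window_stats(prox_seq, p, params$window_s, params$step_s,
                               span, params$completeness)
    flagged <- st$complete & st$mean_rssi >= params$prox_mean_dbm &
      st$std_rssi <= params$prox_sd
    iv <- flags_to_intervals(st, flagged)
    if (nrow(iv)) ivs[[length(ivs) + 1]] <- iv
  }
  if (!length(ivs)) {
    return(tibble::tibble(did = character(), t_start = numeric(),
                          t_end = numeric(), cause = character()))
  }
  iv <- union_intervals(dplyr::bind_rows(ivs))
  tibble::tibble(did = rep(owner, nrow(iv)), iv,
                 cause = rep("issue3", nrow(iv)))
}

#' Consolidate inactive intervals
#'
#' Per badge and cause: intervals separated by less than \code{bridge_s}
#' seconds are concatenated (transitively), then every interval is extended
#' by the \code{margin_s} safety margin on both ends and clipped to the
#' session window; the result is non-overlapping. Idempotent.
#'
#' @param intervals tibble \code{did}, \code{t_start}, \code{t_end},
#'   \code{cause}.
#' @param session session window \code{c(start, end)}.
#' @param bridge_s,margin_s bridging gap and safety margin (s).
#' @return consolidated interval tibble.
#' @export
consolidate_intervals <- function(intervals, session, bridge_s = 120,
                                  margin_s = 30) {
  if (!nrow(intervals)) return(intervals)
  out <- list()
  for (key in split(seq_len(nrow(intervals)),
                    paste(intervals$did, intervals$cause))) {
    grp_did <- intervals$did[key[1]]
    grp_cause <- intervals$cause[key[1]]
    iv <- union_intervals(intervals[key, c("t_start", "t_end"), drop = FALSE])
    # concatenate consecutive intervals separated by less than bridge_s
    s <- iv$t_start; e <- iv$t_end
    ms <- s[1]; me <- e[1]
    for (q in seq_along(s)[-1]) {
      if (s[q] - me[length(me)] < bridge_s) {
        me[length(me)] <- max(me[length(me)], e[q])
      } else {
        ms <- c(ms, s[q]); me <- c(me, e[q])
      }
    }
    # safety margins on both ends, clipped to the session window
    merged <- union_intervals(tibble::tibble(
      t_start = pmax(session[1], ms - margin_s),
      t_end = pmin(session[2], me + margin_s)))
    out[[length(out) + 1]] <- tibble::tibble(
      did = grp_did, merged, cause = grp_cause)
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$did, .data$t_start)
}

#' Trim gathered-badge bursts at the sequence edges
#'
#' Badges gathered during equipment or retrieval exchange short, strong
#' (above -45 dBm), unstable signals at the beginning and end of a data clip.
#' The sequence is scanned forwards: within a 1-minute window from the first
#' timestamp, strong signals update the strong-signal time; past the window
#' the strong-signal time is extended only when a new strong record occurs
#' within 20 s of the previous one. The head interval is
#' \code{[t0, t_s]} (inclusive of the boundary strong signal); if no strong
#' signal occurs in the initial window the head is empty and the sequence is
#' kept whole. The backward pass mirrors this from the last timestamp.
#'
#' @param prox_seq the badge's \code{\link{half_day}} (or record tibble).
#' @param params \code{\link{preprocess_params}}.
#' @return tibble \code{did}, \code{t_start}, \code{t_end}, \code{cause}
#'   (\code{"issue4"}), with zero, one or two rows (head/tail). Intervals are
#'   closed on the strong-signal boundary: records at \code{t_end} are
#'   removed too.
#' @export
trim_edge_bursts <- function(prox_seq, params = preprocess_params()) {
  owner <- if (inherits(prox_seq, "half_day")) prox_seq$owner else
    NA_character_
  rec <- if (inherits(prox_seq, "half_day")) prox_seq$records else prox_seq
  out <- tibble::tibble(did = character(), t_start = numeric(),
                        t_end = numeric(), cause = character())
  if (!nrow(rec)) return(out)
  t <- sort(rec$timestamp)
  strong <- sort(rec$timestamp[rec$rssi > params$strong_dbm])
  head_ts <- edge_scan(t[1], strong, params$edge_window_s,
                       params$edge_offset_s, forward = TRUE)
  tail_ts <- edge_scan(t[length(t)], strong, params$edge_window_s,
                       params$edge_offset_s, forward = FALSE)
  ivs <- list()
  if (!is.na(head_ts)) {
    ivs[[length(ivs) + 1]] <- tibble::tibble(
      did = owner, t_start = t[1], t_end = head_ts, cause = "issue4")
  }
  if (!is.na(tail_ts)) {
    ivs[[length(ivs) + 1]] <- tibble::tibble(
      did = owner, t_start = tail_ts, t_end = t[length(t)], cause = "issue4")
  }
  if (length(ivs)) dplyr::bind_rows(ivs) else out
}

# forward/backward strong-signal chain scan; returns final t_s or NA
edge_scan <- function(t_edge, strong, window_s, offset_s, forward = TRUE) {
  if (!forward) {
    return(-edge_scan(-t_edge, rev(-strong), window_s, offset_s, TRUE))
  }
  if (!length(strong)) return(NA_real_)
  in_win <- strong[strong >= t_edge & strong < t_edge + window_s]
  if (!length(in_win)) return(NA_real_)
  ts <- max(in_win)
  later <- strong[strong > ts]
  for (s in later) {
    if (s - ts <= offset_s) ts <- s else break
  }
  ts
}

#' Apply inactive-interval removals bidirectionally
#'
#' For each interval of badge B, B's received records inside the interval are
#' removed, as are records naming B as \code{observed_did} in every other
#' badge's sequence. Interval ends are treated per cause: window-based causes
#' (issue2/issue3) are half-open \code{[t_start, t_end)}; edge trims
#' (issue4) include the boundary strong signal, \code{[t_start, t_end]}.
#'
#' @param signals signal table of the half-day.
#' @param intervals tibble \code{did}, \code{t_start}, \code{t_end},
#'   \code{cause}.
#' @return the reduced signal table.
#' @export
apply_removals <- function(signals, intervals) {
  for (k in seq_len(nrow(intervals))) {
    b <- intervals$did[k]
    t0 <- intervals$t_start[k]; t1 <- intervals$t_end[k]
    closed <- identical(intervals$cause[k], "issue4")
    inside <- signals$timestamp >= t0 &
      (if (closed) signals$timestamp <= t1 else signals$timestamp < t1)
    drop <- inside & (signals$badge == b | signals$observed_did == b)
    signals <- signals[!drop, , drop = FALSE]
  }
  signals
}

#' Repair silent and deaf badges
#'
#' A silent badge receives but never appears in any peer's log: its received
#' sequence is copied with the direction reversed and added to the senders'
#' logs. A deaf badge appears in peers' logs but recorded nothing itself: its
#' incoming log is rebuilt by gathering and reversing all records of it. A
#' badge with no data on either side is unrecoverable and only flagged.
#'
#' @param signals signal table of the half-day.
#' @param roster badge roster.
#' @return list \code{signals}, \code{silent}, \code{deaf},
#'   \code{unrecoverable} (DIDs).
#' @export
repair_silent_deaf <- function(signals, roster) {
  part <- roster$did[roster$kind != "rx"]
  emitted_by <- unique(signals$observed_did)
  has_log <- unique(signals$badge[signals$badge %in% part])
  silent <- setdiff(has_log, emitted_by)
  deaf <- intersect(setdiff(part, has_log), emitted_by)
  unrecoverable <- setdiff(setdiff(part, has_log), emitted_by)
  add <- list()
  for (s in silent) {
    own <- signals[signals$badge == s, , drop = FALSE]
    own <- own[badge_kind_safe(own$observed_did) != "rx", , drop = FALSE]
    if (nrow(own)) {
      add[[length(add) + 1]] <- tibble::tibble(
        badge = own$observed_did, observed_did = s,
        timestamp = own$timestamp, rssi = own$rssi)
    }
  }
  for (d in deaf) {
    heard <- signals[signals$observed_did == d &
                       badge_kind_safe(signals$badge) != "rx", , drop = FALSE]
    if (nrow(heard)) {
      add[[length(add) + 1]] <- tibble::tibble(
        badge = d, observed_did = heard$badge,
        timestamp = heard$timestamp, rssi = heard$rssi)
    }
  }
  if (length(add)) {
    signals <- dplyr::bind_rows(c(list(signals), add))
    # a badge both heard by a silent one and rebuilt as deaf would receive
    # the same mirrored record twice: collapse duplicates, keep strongest
    ord <- order(signals$badge, signals$observed_did, signals$timestamp,
                 -signals$rssi)
    signals <- signals[ord, , drop = FALSE]
    key <- paste(signals$badge, signals$observed_did, signals$timestamp)
    signals <- signals[!duplicated(key), , drop = FALSE]
    signals <- dplyr::arrange(signals, .data$badge, .data$timestamp,
                              .data$observed_did)
  }
  list(signals = signals, silent = silent, deaf = deaf,
       unrecoverable = unrecoverable)
}

#' Run the full four-issue pre-processing of one half-day
#'
#' Issues are treated in order: (1) silent/deaf repair, (2) unworn badges
#' detected at the class RX, (3) piled badges detected on each badge's own
#' log, (4) edge-burst trimming; each stage consumes the previous stage's
#' output, and each detected interval is removed bidirectionally after
#' bridging and safety margins. A class without a working RX skips Issue 2
#' (with a warning) but still runs Issue 3.
#'
#' @param signals cleaned signal table of one half-day (PROX and RX records).
#' @param roster badge roster (\code{did}, \code{kind}, \code{class_id}).
#' @param day,session half-day identity.
#' @param params \code{\link{preprocess_params}}.
#' @return list: \code{signals} (pre-processed, RX records removed from the
#'   output as in the shared dialect is \emph{not} done -- RX rows are kept),
#'   \code{report} (removed intervals by badge and cause), \code{repairs}
#'   (silent/deaf/unrecoverable DIDs).
#' @export
preprocess_half_day <- function(signals, roster, day = 1, session = "M",
                                params = preprocess_params()) {
  win <- unname(session_window(day, session))
  rep1 <- repair_silent_deaf(signals, roster)
  sig <- rep1$signals
  part <- roster[roster$kind != "rx", , drop = FALSE]
  report <- list()

  # Issue 2: RX-based unworn detection
  iv2 <- list()
  for (cl in sort(unique(part$class_id))) {
    rx_did <- roster$did[roster$kind == "rx" & !is.na(roster$class_id) &
                           roster$class_id == cl]
    rx_rec <- if (length(rx_did)) {
      sig[sig$badge == rx_did[1], c("observed_did", "timestamp", "rssi"),
          drop = FALSE]
    } else NULL
    if (is.null(rx_rec) || nrow(rx_rec) == 0) {
      warning("class ", cl, ": no RX data; Issue 2 skipped for this class")
      next
    }
    for (b in part$did[part$class_id == cl]) {
      iv <- detect_unworn_rx(rx_rec, b, params, span = win)
      if (nrow(iv)) iv2[[length(iv2) + 1]] <- iv
    }
  }
  iv2 <- if (length(iv2)) dplyr::bind_rows(iv2) else NULL
  if (!is.null(iv2)) {
    iv2 <- consolidate_intervals(iv2, win, params$bridge_s, params$margin_s)
    sig <- apply_removals(sig, iv2)
    report[[length(report) + 1]] <- iv2
  }

  # Issue 3: own-log pile detection
  iv3 <- list()
  for (b in part$did) {
    rec <- sig[sig$badge == b, c("observed_did", "timestamp", "rssi"),
               drop = FALSE]
    if (!nrow(rec)) next
    iv <- detect_unworn_prox(rec, params, span = win)
    if (nrow(iv)) {
      iv$did <- b
      iv3[[length(iv3) + 1]] <- iv
    }
  }
  iv3 <- if (length(iv3)) dplyr::bind_rows(iv3) else NULL
  if (!is.null(iv3)) {
    iv3 <- consolidate_intervals(iv3, win, params$bridge_s, params$margin_s)
    sig <- apply_removals(sig, iv3)
    report[[length(report) + 1]] <- iv3
  }

  # Issue 4: edge-burst trimming
  iv4 <- list()
  for (b in part$did) {
    rec <- sig[sig$badge == b, c("observed_did", "timestamp", "rssi"),
               drop = FALSE]
    if (!nrow(rec)) next
    iv <- trim_edge_bursts(rec, params)
    if (nrow(iv)) {
      iv$did <- b
      iv4[[length(iv4) + 1]] <- iv
    }
  }
  iv4 <- if (length(iv4)) dplyr::bind_rows(iv4) else NULL
  if (!is.null(iv4)) {
    sig <- apply_removals(sig, iv4)
    report[[length(report) + 1]] <- iv4
  }

  report <- if (length(report)) dplyr::bind_rows(report) else
    tibble::tibble(did = character(), t_start = numeric(),
                   t_end = numeric(), cause = character())
  list(signals = sig, report = report,
       repairs = rep1[c("silent", "deaf", "unrecoverable")])
}
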