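#' Inject recording artifacts into simulated signals
#'
#' Five artifact classes are injected, each recorded in the returned truth
#' bundle so downstream removal can be scored:
#' \itemize{
#'   \item \strong{unworn_hub}: an unworn badge left near the charging hub;
#'     the class RX hears it strongly and stably (window mean above -62 dBm,
#'     SD below 2.5) for the interval, while the badge has no genuine
#'     interactions.
#'   \item \strong{pile}: 2-4 badges gathered away from the hub (e.g. during
#'     a sports session); they exchange very strong, very stable signals
#'     (about -50 dBm, SD 1) and the RX loses contact with them.
#'   \item \strong{burst}: at session start and end, gathered badges exchange
#'     strong unstable signals including values above -45 dBm.
#'   \item \strong{silent}: the badge receives but never emits; it vanishes
#'     from all peers' logs while its own log stays intact.
#'   \item \strong{deaf}: the badge emits but records nothing; its own log is
#'     empty while peers still hear it.
#' }
#' For unworn/pile/burst intervals the latent dyad states of the affected
#' badges are zeroed (the child is not wearing the badge) and events are
#' rebuilt, keeping truth and signals mutually consistent.
#'
#' @param signals raw signal table from \code{\link{emit_signals}}.
#' @param truth truth list from \code{\link{simulate_events}}.
#' @param config a \code{\link{sim_config}}.
#' @param roster,schedule deployment context.
#' @param day,session half-day identity.
#' @return list \code{signals}, \code{truth} (with rebuilt events), and
#'   \code{artifact_intervals} (tibble \code{did}, \code{t_start},
#'   \code{t_end}, \code{cause}).
#' @export
inject_artifacts <- function(signals, truth, config, roster, schedule,
                             day = 1, session = "M") {
  win <- unname(session_window(day, session))
  art <- config$artifacts
  part <- roster[roster$kind != "rx", , drop = FALSE]
  children <- part$did[part$kind == "child"]
  intervals <- list()
  add_iv <- function(did, t0, t1, cause) {
    if (any(t0 < win[1] - 1e-9) || any(t1 > win[2] + 1e-9)) {
      stop("artifact interval outside the session window")
    }
    intervals[[length(intervals) + 1]] <<-
      tibble::tibble(did = did, t_start = t0, t_end = t1, cause = cause)
  }
  grid <- function(t) SLOT_S * round(t / SLOT_S)
  rand_interval <- function(dur_range, margin = 300) {
    dur <- grid(stats::runif(1, dur_range[1], dur_range[2]))
    lo <- win[1] + margin
    hi <- win[2] - margin - dur
    t0 <- grid(stats::runif(1, lo, max(lo, hi)))
    c(t0, t0 + dur)
  }
  class_of <- stats::setNames(part$class_id, part$did)
  rx_of <- stats::setNames(
    roster$did[roster$kind == "rx" & !is.na(roster$class_id)],
    roster$class_id[roster$kind == "rx" & !is.na(roster$class_id)])

  # whole-session radio faults are drawn first and kept disjoint from the
  # unworn/pile/burst incidents: a silent badge leaves no RX trace, so
  # stacking both on one badge would make its ground truth unscorable
  pool <- part$did
  silent <- pool[stats::runif(length(pool)) < art$silent_rate]
  deaf <- setdiff(pool[stats::runif(length(pool)) < art$deaf_rate], silent)
  children <- setdiff(children, c(silent, deaf))

  # (a) unworn badges left near the hub
  unworn <- children[stats::runif(length(children)) < art$unworn_rate]
  for (b in unworn) {
    iv <- rand_interval(art$unworn_dur)
    signals <- drop_badge_records(signals, b, iv)
    rx <- rx_of[as.character(class_of[b])]
    if (!is.na(rx)) {
      signals <- dplyr::bind_rows(
        signals, per_slot_records(rx, b, iv, config$rssi$hub, config))
    }
    truth$states <- zero_states(truth$states, b, iv)
    add_iv(b, iv[1], iv[2], "unworn_hub")
  }

  # (b') piles of badges gathered away from the hub (Issue-3 signature)
  for (cl in seq_len(config$n_classes)) {
    if (stats::runif(1) >= art$pile_prob) next
    pool <- setdiff(children[class_of[children] == cl], unworn)
    if (length(pool) < 2) next
    size <- min(length(pool), sample(art$pile_size[1]:art$pile_size[2], 1))
    pile <- sample(pool, size)
    iv <- rand_interval(art$pile_dur)
    for (b in pile) {
      signals <- drop_badge_records(signals, b, iv)
      truth$states <- zero_states(truth$states, b, iv)
      add_iv(b, iv[1], iv[2], "pile")
    }
    signals <- dplyr::bind_rows(
      signals, pairwise_records(pile, iv, config$rssi$pile, config))
  }

  # (b) gathered-badge bursts at session start and end
  if (art$burst_frac > 0 && art$burst_s > 0) {
    for (edge in c("head", "tail")) {
      iv <- if (edge == "head") c(win[1], win[1] + art$burst_s)
            else c(win[2] - art$burst_s, win[2])
      for (cl in seq_len(config$n_classes)) {
        pool <- children[class_of[children] == cl]
        n_b <- round(art$burst_frac * length(pool))
        if (n_b < 2) next
        gathered <- sample(pool, n_b)
        for (b in gathered) {
          signals <- drop_badge_records(signals, b, iv, keep_rx = TRUE)
          truth$states <- zero_states(truth$states, b, iv)
          add_iv(b, iv[1], iv[2], "burst")
        }
        signals <- dplyr::bind_rows(
          signals, pairwise_records(gathered, iv, config$rssi$gathered,
                                    config))
      }
    }
  }

  # (c) silent and (d) deaf badges (whole half-day)
  for (b in silent) {
    signals <- signals[signals$observed_did != b, , drop = FALSE]
    add_iv(b, win[1], win[2], "silent")
  }
  for (b in deaf) {
    signals <- signals[signals$badge != b, , drop = FALSE]
    add_iv(b, win[1], win[2], "deaf")
  }

  truth$events <- states_to_events(truth$states)
  truth$artifact_intervals <- if (length(intervals)) {
    dplyr::bind_rows(intervals)
  } else {
    tibble::tibble(did = character(), t_start = numeric(),
                   t_end = numeric(), cause = character())
  }
  list(signals = dplyr::arrange(signals, .data$badge, .data$timestamp,
                                .data$observed_did),
       truth = truth)
}

# remove all records involving badge b (as receiver or sender) in [t0, t1)
drop_badge_records <- function(signals, b, iv, keep_rx = FALSE) {
  inside <- signals$timestamp >= iv[1] & signals$timestamp < iv[2]
  involves <- signals$badge == b | signals$observed_did == b
  if (keep_rx) involves <- involves & badge_kind_safe(signals$badge) != "rx"
  signals[!(inside & involves), , drop = FALSE]
}

badge_kind_safe <- function(did) {
  c("0" = "child", "1" = "adult", "2" = "rx")[substr(did, 1, 1)]
}

zero_states <- function(states, b, iv) {
  if (!nrow(states)) return(states)
  hit <- (states$i == b | states$j == b) &
    states$slot >= iv[1] & states$slot < iv[2]
  states[!hit, , drop = FALSE]
}

# one record per slot from sender to receiver over [t0, t1)
per_slot_records <- function(receiver, sender, iv, regime, config) {
  slots <- slot_seq(iv[1], iv[2])
  keep <- stats::runif(length(slots)) >= config$packet_loss_prob
  r <- draw_rssi(length(slots), regime)
  keep <- keep & !is.na(r)
  tibble::tibble(badge = receiver, observed_did = sender,
                 timestamp = slots[keep] + slot_jitter(sum(keep), config),
                 rssi = r[keep])
}

# full pairwise exchange among a badge group over [t0, t1)
pairwise_records <- function(badges, iv, regime, config) {
  if (length(badges) < 2) {
    return(tibble::tibble(badge = character(), observed_did = character(),
                          timestamp = numeric(), rssi = integer()))
  }
  pr <- utils::combn(badges, 2)
  out <- list()
  for (q in seq_len(ncol(pr))) {
    out[[length(out) + 1]] <- per_slot_records(pr[1, q], pr[2, q], iv,
                                               regime, config)
    out[[length(out) + 1]] <- per_slot_records(pr[2, q], pr[1, q], iv,
                                               regime, config)
  }
  dplyr::bind_rows(out)
}

#' Simulate one half-day deployment end to end
#'
#' Roster, schedule, latent events, beacon emission and artifact injection
#' under one seed; fully deterministic for a fixed seed and configuration.
#'
#' @param config a \code{\link{sim_config}}.
#' @param day,session half-day to simulate.
#' @param seed RNG seed (defaults to \code{config$seed}).
#' @param artifacts inject artifacts (set FALSE for clean truth-faithful
#'   signals).
#' @param roster optionally reuse a roster across half-days.
#' @return list with \code{roster}, \code{schedule}, \code{truth} (states,
#'   events, schedule, artifact_intervals), \code{signals}, \code{day},
#'   \code{session}, \code{config}.
#' @export
simulate_half_day <- function(config, day = 1, session = "M",
                              seed = config$seed, artifacts = TRUE,
                              roster = NULL) {
  set.seed(seed)
  if (is.null(roster)) roster <- simulate_population(config)
  schedule <- simulate_schedule(config, day, session)
  truth <- simulate_events(config, roster, schedule)
  signals <- emit_signals(truth, config, roster, schedule)
  if (artifacts) {
    res <- inject_artifacts(signals, truth, config, roster, schedule,
                            day, session)
    signals <- res$signals
    truth <- res$truth
  } else {
    truth$artifact_intervals <- tibble::tibble(
      did = character(), t_start = numeric(), t_end = numeric(),
      cause = character())
  }
  truth$schedule <- schedule
  list(roster = roster, schedule = schedule, truth = truth,
       signals = signals, day = day, session = session, config = config)
}

#' Write a simulated half-day to the deployment folder layout
#'
#' Exports per-badge triplet files under
#' \code{<root>/Y_WEEKXX/HD_individual_cleaned/{PROX,RX}/} plus a
#' \code{truth/} folder holding the true events (tnet dialect, all-F labels
#' as placeholders), per-slot states, schedule and artifact intervals as
#' plain CSV.
#'
#' @param sim result of \code{\link{simulate_half_day}}.
#' @param root output root directory.
#' @param week week label, e.g. \code{"1_WEEK40"}.
#' @return the week directory, invisibly.
#' @export
write_deployment <- function(sim, root, week = "1_WEEK01") {
  wk <- file.path(root, week)
  clean_dir <- file.path(wk, "HD_individual_cleaned")
  sig <- initial_clean_signals(sim$signals,
                               session_window(sim$day, sim$session))
  seqs <- sequences_from_table(sig, sim$roster, sim$day, sim$session)
  for (hd in seqs) write_half_day(hd, clean_dir)
  tdir <- file.path(wk, "truth")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$truth$events, file.path(tdir, "events.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$truth$states, file.path(tdir, "states.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$schedule, file.path(tdir, "schedule.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$truth$artifact_intervals,
                   file.path(tdir, "artifacts.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$roster, file.path(tdir, "roster.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(wk)
}
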