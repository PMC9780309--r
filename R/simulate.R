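#' Simulator configuration
#'
#' Builds the configuration of a synthetic preschool deployment. Defaults
#' mirror the observed school: 7 classes totalling 174 children and 32 adults,
#' 5-second beacon emissions, morning sessions 08:30-11:20 and afternoon
#' sessions 13:45-15:50, and staggered yard (free-time) blocks shared by
#' groups of 2-4 classes. RSSI regimes are truncated normals on the integer
#' dBm grid whose ordering follows the field calibration: close face-to-face
#' interaction is strong (-68 dBm), same-room background is weak (-82 dBm),
#' gathered/piled badges (<= 10 cm) are very strong (-50 dBm) with occasional
#' values above -45 dBm, and an unworn badge sitting on the charging hub is
#' heard by the class RX strongly and stably (-58 dBm, SD 1.2).
#'
#' @param n_classes number of classes (at most 7 under the 200x RX scheme).
#' @param class_sizes children per class (recycled to \code{n_classes}).
#' @param n_adults adults, assigned round-robin to classes.
#' @param include_gym_rx add the two gym RX badges 2010/2011 to the roster.
#' @param packet_loss_prob probability a directed packet is lost.
#' @param background_prob per-slot probability that a co-located,
#'   non-interacting dyad exchanges a background-regime packet pair.
#' @param jitter_max maximum reception-time offset within a slot (integer s).
#' @param rssi named list of \code{c(mean, sd)} pairs for regimes
#'   \code{interaction}, \code{background}, \code{gathered}, \code{pile},
#'   \code{hub}, \code{rx_room}.
#' @param events latent contact-process parameters: per-dyad tie probabilities
#'   \code{p_same}/\code{p_cross}, and discrete power-law-with-cutoff
#'   parameters for event durations (\code{dur_alpha}, \code{dur_cut}) and
#'   inter-event gaps (\code{iet_alpha}, \code{iet_cut}), in 5-s slots.
#' @param artifacts artifact injection rates: \code{unworn_rate} and
#'   \code{unworn_dur} (unworn badge left near the hub), \code{pile_prob},
#'   \code{pile_size}, \code{pile_dur} (badges gathered away from the hub),
#'   \code{burst_frac} and \code{burst_s} (gathered-badge bursts at session
#'   edges), \code{silent_rate}, \code{deaf_rate}.
#' @param free_blocks free-time schedule template; see
#'   \code{\link{free_block_template}}.
#' @param schedule_jitter_s per-class uniform jitter applied to block edges
#'   (10-s grid), emulating classes leaving for the yard at slightly
#'   different moments.
#' @param seed default RNG seed for \code{\link{simulate_half_day}}.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_classes = 7,
                       class_sizes = c(25, 25, 25, 25, 25, 25, 24),
                       n_adults = 32,
                       include_gym_rx = FALSE,
                       packet_loss_prob = 0.05,
                       background_prob = 0.15,
                       jitter_max = 2,
                       rssi = list(interaction = c(-68, 6),
                                   background = c(-82, 6),
                                   gathered = c(-50, 5),
                                   pile = c(-50, 1.0),
                                   hub = c(-58, 1.2),
                                   rx_room = c(-80, 6)),
                       events = list(p_same = 0.5, p_cross = 0.1,
                                     dur_alpha = 2.0, dur_cut = 120,
                                     iet_alpha = 1.7, iet_cut = 600),
                       artifacts = list(unworn_rate = 0.08,
                                        unworn_dur = c(600, 1800),
                                        pile_prob = 0.4,
                                        pile_size = c(2, 4),
                                        pile_dur = c(300, 900),
                                        burst_frac = 0.3, burst_s = 120,
                                        silent_rate = 0.02,
                                        deaf_rate = 0.02),
                       free_blocks = NULL,
                       schedule_jitter_s = 60,
                       seed = 1L) {
  if (n_classes > 7) stop("the 200x RX id scheme supports at most 7 classes")
  stopifnot(n_classes >= 1,
            packet_loss_prob >= 0, packet_loss_prob <= 1,
            background_prob >= 0, background_prob <= 1)
  class_sizes <- rep_len(class_sizes, n_classes)
  stopifnot(all(class_sizes >= 1), n_adults >= 0)
  if (is.null(free_blocks)) free_blocks <- free_block_template(n_classes)
  if (nrow(free_blocks)) {
    n_shared <- vapply(free_blocks$classes, length, 1L)
    if (any(n_shared < 2)) stop("each free block must be shared by >= 2 classes")
  }
  structure(list(n_classes = n_classes, class_sizes = class_sizes,
                 n_adults = n_adults, include_gym_rx = include_gym_rx,
                 beacon_period_s = SLOT_S,
                 packet_loss_prob = packet_loss_prob,
                 background_prob = background_prob, jitter_max = jitter_max,
                 rssi = rssi, events = events, artifacts = artifacts,
                 free_blocks = free_blocks,
                 schedule_jitter_s = schedule_jitter_s, seed = seed),
            class = "sim_config")
}

#' Default free-time (yard) block template
#'
#' Classes go to the yard successively in groups of 2-4: the template lists,
#' per session, which class group shares each block and its nominal clock
#' time (seconds of day). Morning groups rotate through three half-hour
#' blocks from 09:30; afternoons hold two 25-minute blocks from 14:20.
#'
#' @param n_classes number of classes to partition into groups.
#' @return tibble with columns \code{session}, \code{classes} (list column),
#'   \code{start_tod}, \code{end_tod}.
#' @export
free_block_template <- function(n_classes) {
  if (n_classes < 2) {
    # a single class cannot share yard time: no free blocks
    return(tibble::tibble(session = character(), classes = list(),
                          start_tod = numeric(), end_tod = numeric()))
  }
  n_groups <- max(1, ceiling(n_classes / 3))
  sizes <- rep(floor(n_classes / n_groups), n_groups)
  extra <- n_classes - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  groups <- split(seq_len(n_classes), rep(seq_len(n_groups), times = sizes))
  groups <- unname(groups)
  m_start <- 9.5 * 3600 + (seq_along(groups) - 1) * 1800
  a_groups <- groups[seq_len(min(2, length(groups)))]
  a_start <- (14 + 20 / 60) * 3600 + (seq_along(a_groups) - 1) * 1500
  dplyr::bind_rows(
    tibble::tibble(session = "M", classes = groups,
                   start_tod = m_start, end_tod = m_start + 1800),
    tibble::tibble(session = "A", classes = a_groups,
                   start_tod = a_start, end_tod = a_start + 1500)
  )
}

#' Simulate the badge roster
#'
#' Children get DIDs 0xxx, adults 1xxx (three random digits, unique), and one
#' stationary RX badge per class (2001...200k), plus the gym RXs 2010/2011
#' when enabled.
#'
#' @param config a \code{\link{sim_config}}.
#' @return roster tibble: \code{did}, \code{kind}, \code{class_id}.
#' @export
simulate_population <- function(config) {
  n_child <- sum(config$class_sizes)
  n_adult <- config$n_adults
  tails <- sample(0:999, n_child + n_adult, replace = FALSE)
  child_did <- sprintf("0%03d", tails[seq_len(n_child)])
  adult_did <- if (n_adult) sprintf("1%03d", tails[n_child + seq_len(n_adult)])
               else character()
  child_class <- rep(seq_len(config$n_classes), times = config$class_sizes)
  adult_class <- if (n_adult) {
    rep_len(seq_len(config$n_classes), n_adult)
  } else integer()
  rx_did <- sprintf("200%d", seq_len(config$n_classes))
  rx_class <- seq_len(config$n_classes)
  if (config$include_gym_rx) {
    rx_did <- c(rx_did, "2010", "2011")
    rx_class <- c(rx_class, NA_integer_, NA_integer_)
  }
  tibble::tibble(
    did = c(child_did, adult_did, rx_did),
    kind = c(rep("child", n_child), rep("adult", n_adult),
             rep("rx", length(rx_did))),
    class_id = as.integer(c(child_class, adult_class, rx_class))
  )
}

#' Simulate the free-/class-time schedule of one half-day
#'
#' Instantiates the free-block template for the given session, applying
#' per-class edge jitter on the 10-s grid, and fills the remainder of the
#' session window with class-time. Every free-time segment overlaps a
#' free-time segment of at least one other class by construction.
#'
#' @param config a \code{\link{sim_config}}.
#' @param day,session half-day.
#' @return schedule tibble: \code{class_id}, \code{t_start}, \code{t_end},
#'   \code{label} (\code{"F"}/\code{"C"}), segments tiling the session window
#'   for every class.
#' @export
simulate_schedule <- function(config, day = 1, session = "M") {
  win <- unname(session_window(day, session))
  off <- (day - 1) * 86400
  blocks <- config$free_blocks[config$free_blocks$session == session, ,
                               drop = FALSE]
  jit <- function() {
    if (config$schedule_jitter_s <= 0) return(0)
    10 * sample.int(floor(config$schedule_jitter_s / 10) + 1, 1) - 10
  }
  free <- list()
  for (b in seq_len(nrow(blocks))) {
    for (cl in blocks$classes[[b]]) {
      t0 <- off + blocks$start_tod[b] + jit()
      t1 <- off + blocks$end_tod[b] - jit()
      t0 <- max(t0, win[1]); t1 <- min(t1, win[2])
      if (t1 <= t0) stop("free block degenerate after jitter/clipping")
      free[[length(free) + 1]] <-
        tibble::tibble(class_id = cl, t_start = t0, t_end = t1, label = "F")
    }
  }
  free <- if (length(free)) dplyr::bind_rows(free) else
    tibble::tibble(class_id = integer(), t_start = numeric(),
                   t_end = numeric(), label = character())
  out <- list()
  for (cl in seq_len(config$n_classes)) {
    f <- free[free$class_id == cl, , drop = FALSE]
    f <- f[order(f$t_start), , drop = FALSE]
    if (nrow(f) > 1 && any(f$t_start[-1] < f$t_end[-nrow(f)])) {
      stop("overlapping free blocks for class ", cl)
    }
    out[[cl]] <- fill_class_time(f, win, cl)
  }
  dplyr::bind_rows(out)
}

# Complement the free segments of one class with class-time so segments tile
# the session window.
fill_class_time <- function(free, win, class_id) {
  segs <- list()
  cur <- win[1]
  for (k in seq_len(nrow(free))) {
    if (free$t_start[k] > cur) {
      segs[[length(segs) + 1]] <- tibble::tibble(
        class_id = class_id, t_start = cur, t_end = free$t_start[k],
        label = "C")
    }
    segs[[length(segs) + 1]] <- free[k, ]
    cur <- free$t_end[k]
  }
  if (cur < win[2]) {
    segs[[length(segs) + 1]] <- tibble::tibble(
      class_id = class_id, t_start = cur, t_end = win[2], label = "C")
  }
  dplyr::bind_rows(segs)
}

# Sample from a discrete power law with exponential cutoff,
# P(k) ~ k^-alpha * exp(-k / cutoff), k = 1..kmax (slots).
rpowcut <- function(n, alpha, cutoff, kmax = NULL) {
  if (is.null(kmax)) kmax <- max(10L, as.integer(cutoff * 8))
  k <- seq_len(kmax)
  p <- k^(-alpha) * exp(-k / cutoff)
  sample.int(kmax, n, replace = TRUE, prob = p)
}

# batched sampler over a fixed pmf (avoids rebuilding the table per draw)
powcut_sampler <- function(alpha, cutoff, batch = 512L) {
  kmax <- max(10L, as.integer(cutoff * 8))
  p <- seq_len(kmax)^(-alpha) * exp(-seq_len(kmax) / cutoff)
  p <- p / sum(p)
  buf <- integer(0)
  idx <- 0L
  function() {
    if (idx == length(buf)) {
      buf <<- sample.int(kmax, batch, replace = TRUE, prob = p)
      idx <<- 0L
    }
    idx <<- idx + 1L
    buf[idx]
  }
}

#' Simulate latent contact events and per-slot dyad states
#'
#' A dyad can be active during class-time only if its members share a class,
#' and during free-time only when both classes are simultaneously in the
#' yard. Selected dyads (ties) follow an alternating renewal process whose
#' on-durations and off-gaps are drawn from discrete power laws with
#' exponential cutoff, producing the bursty dynamics characteristic of
#' face-to-face contact data; all boundaries lie on the 5-s beacon grid.
#'
#' @param config a \code{\link{sim_config}}.
#' @param roster from \code{\link{simulate_population}}.
#' @param schedule from \code{\link{simulate_schedule}}.
#' @return truth list: \code{states} (tibble \code{i}, \code{j}, \code{slot};
#'   \code{i < j}), \code{events} (tibble \code{t}, \code{i}, \code{j},
#'   \code{delta}), both mutually consistent.
#' @export
simulate_events <- function(config, roster, schedule) {
  part <- roster[roster$kind != "rx", , drop = FALSE]
  if (nrow(part) < 2) {
    return(list(states = empty_states(), events = empty_events()))
  }
  pairs <- utils::combn(seq_len(nrow(part)), 2)
  i_did <- part$did[pairs[1, ]]; j_did <- part$did[pairs[2, ]]
  same <- part$class_id[pairs[1, ]] == part$class_id[pairs[2, ]]
  p_tie <- ifelse(same, config$events$p_same, config$events$p_cross)
  tie <- stats::runif(length(p_tie)) < p_tie
  draw_iet <- powcut_sampler(config$events$iet_alpha, config$events$iet_cut)
  draw_dur <- powcut_sampler(config$events$dur_alpha, config$events$dur_cut)
  states <- list()
  for (k in which(tie)) {
    runs <- allowed_runs(part$class_id[pairs[1, k]],
                         part$class_id[pairs[2, k]], schedule)
    if (!nrow(runs)) next
    sl <- dyad_renewal_slots(runs, draw_iet, draw_dur)
    if (length(sl)) {
      a <- i_did[k]; b <- j_did[k]
      states[[length(states) + 1]] <- tibble::tibble(
        i = min(a, b), j = max(a, b), slot = sl)
    }
  }
  states <- if (length(states)) dplyr::bind_rows(states) else empty_states()
  list(states = states, events = states_to_events(states))
}

empty_states <- function() {
  tibble::tibble(i = character(), j = character(), slot = numeric())
}
empty_events <- function() {
  tibble::tibble(t = numeric(), i = character(), j = character(),
                 delta = numeric())
}

# Maximal time intervals during which a dyad is allowed to be active.
allowed_runs <- function(class_i, class_j, schedule) {
  if (class_i == class_j) {
    # together in their classroom and (jointly) in the yard: full session
    seg <- schedule[schedule$class_id == class_i, , drop = FALSE]
    return(tibble::tibble(t_start = min(seg$t_start), t_end = max(seg$t_end)))
  }
  fi <- schedule[schedule$class_id == class_i & schedule$label == "F", ,
                 drop = FALSE]
  fj <- schedule[schedule$class_id == class_j & schedule$label == "F", ,
                 drop = FALSE]
  interval_intersection(fi[, c("t_start", "t_end")],
                        fj[, c("t_start", "t_end")])
}

# Intersection of two sorted disjoint interval sets.
interval_intersection <- function(a, b) {
  out <- list()
  for (k in seq_len(nrow(a))) {
    lo <- pmax(a$t_start[k], b$t_start); hi <- pmin(a$t_end[k], b$t_end)
    ok <- hi > lo
    if (any(ok)) {
      out[[length(out) + 1]] <- tibble::tibble(t_start = lo[ok],
                                               t_end = hi[ok])
    }
  }
  if (!length(out)) tibble::tibble(t_start = numeric(), t_end = numeric())
  else dplyr::arrange(dplyr::bind_rows(out), .data$t_start)
}

# Alternating renewal (off-gap then on-duration) within each allowed run;
# returns active slot times (s).
dyad_renewal_slots <- function(runs, draw_iet, draw_dur) {
  slots <- numeric(0)
  for (k in seq_len(nrow(runs))) {
    n_slot <- floor((runs$t_end[k] - runs$t_start[k]) / SLOT_S)
    pos <- 0
    repeat {
      gap <- draw_iet()
      dur <- draw_dur()
      if (pos + gap >= n_slot) break
      on <- seq(pos + gap, min(pos + gap + dur - 1, n_slot - 1))
      slots <- c(slots, runs$t_start[k] + SLOT_S * on)
      pos <- pos + gap + dur
      if (pos >= n_slot) break
    }
  }
  slots
}

#' Convert per-slot dyad states to contact events (and validate consistency)
#'
#' Maximal runs of consecutive active slots (adjacent on the 5-s grid) become
#' events \code{(t, i, j, delta)} with \code{delta = 5 * run length}.
#'
#' @param states tibble \code{i}, \code{j}, \code{slot} of active slots.
#' @return events tibble \code{t}, \code{i}, \code{j}, \code{delta}.
#' @export
states_to_events <- function(states) {
  if (!nrow(states)) return(empty_events())
  states <- dplyr::arrange(states, .data$i, .data$j, .data$slot)
  new_run <- c(TRUE, states$i[-1] != states$i[-nrow(states)] |
                 states$j[-1] != states$j[-nrow(states)] |
                 states$slot[-1] != states$slot[-nrow(states)] + SLOT_S)
  run_id <- cumsum(new_run)
  states %>%
    dplyr::mutate(run = run_id) %>%
    dplyr::group_by(.data$run) %>%
    dplyr::summarise(t = min(.data$slot), i = .data$i[1], j = .data$j[1],
                     delta = SLOT_S * dplyr::n(), .groups = "drop") %>%
    dplyr::select("t", "i", "j", "delta") %>%
    dplyr::arrange(.data$t, .data$i, .data$j)
}

# Piecewise-constant room occupancy: per class segment, who is where.
# Returns schedule with room label: class c in room "room<c>" during C,
# "yard" during F. RX badges always sit in their class room.
room_blocks <- function(schedule) {
  schedule %>%
    dplyr::mutate(room = ifelse(.data$label == "C",
                                paste0("room", .data$class_id), "yard"))
}

# Draw integer-dBm RSSI from a regime, dropping sub-sensitivity packets and
# clamping at the strongest recordable value.
draw_rssi <- function(n, regime) {
  r <- as.integer(round(stats::rnorm(n, regime[1], regime[2])))
  r[r > RSSI_MAX] <- RSSI_MAX
  r[r < RSSI_MIN] <- NA_integer_   # below sensitivity floor: never recorded
  r
}

#' Emit beacon signals from the latent truth
#'
#' For each 5-s slot each active dyad exchanges two directed records drawn
#' from the interaction RSSI regime; co-located non-interacting dyads (same
#' classroom, or simultaneously in the yard) exchange background-regime
#' packet pairs with probability \code{background_prob}; every directed
#' packet is lost independently with \code{packet_loss_prob} and packets
#' below the -94 dBm sensitivity floor are never recorded. The class RX badge
#' logs every badge present in its classroom each slot (and loses contact
#' when the class is in the yard). Reception timestamps carry an integer
#' within-slot offset of at most \code{jitter_max} seconds.
#'
#' @param truth from \code{\link{simulate_events}}.
#' @param config a \code{\link{sim_config}}.
#' @param roster,schedule deployment context.
#' @return raw signal table: \code{badge} (receiver), \code{observed_did},
#'   \code{timestamp}, \code{rssi}.
#' @export
emit_signals <- function(truth, config, roster, schedule) {
  part <- roster[roster$kind != "rx", , drop = FALSE]
  class_of <- stats::setNames(part$class_id, part$did)
  loss <- config$packet_loss_prob
  out <- list()

  # interaction records: two directions per active dyad-slot
  st <- truth$states
  if (nrow(st)) {
    for (dir in 1:2) {
      rx <- if (dir == 1) st$i else st$j
      tx <- if (dir == 1) st$j else st$i
      keep <- stats::runif(nrow(st)) >= loss
      r <- draw_rssi(nrow(st), config$rssi$interaction)
      keep <- keep & !is.na(r)
      if (any(keep)) {
        out[[length(out) + 1]] <- tibble::tibble(
          badge = rx[keep], observed_did = tx[keep],
          timestamp = st$slot[keep] + slot_jitter(sum(keep), config),
          rssi = r[keep])
      }
    }
  }

  # background records among co-located non-interacting dyads
  bg <- background_dyad_slots(config, part, schedule, truth$states)
  if (nrow(bg)) {
    for (dir in 1:2) {
      rx <- if (dir == 1) bg$i else bg$j
      tx <- if (dir == 1) bg$j else bg$i
      keep <- stats::runif(nrow(bg)) >= loss
      r <- draw_rssi(nrow(bg), config$rssi$background)
      keep <- keep & !is.na(r)
      if (any(keep)) {
        out[[length(out) + 1]] <- tibble::tibble(
          badge = rx[keep], observed_did = tx[keep],
          timestamp = bg$slot[keep] + slot_jitter(sum(keep), config),
          rssi = r[keep])
      }
    }
  }

  # RX logs: each class RX hears its class members while they are in the room
  rxb <- roster[roster$kind == "rx" & !is.na(roster$class_id), , drop = FALSE]
  blocks <- schedule[schedule$label == "C", , drop = FALSE]
  for (k in seq_len(nrow(rxb))) {
    cl <- rxb$class_id[k]
    members <- part$did[part$class_id == cl]
    segs <- blocks[blocks$class_id == cl, , drop = FALSE]
    for (s in seq_len(nrow(segs))) {
      slots <- slot_seq(segs$t_start[s], segs$t_end[s])
      if (!length(slots) || !length(members)) next
      grid <- expand.grid(observed_did = members, slot = slots,
                          stringsAsFactors = FALSE)
      keep <- stats::runif(nrow(grid)) >= loss
      r <- draw_rssi(nrow(grid), config$rssi$rx_room)
      keep <- keep & !is.na(r)
      if (any(keep)) {
        out[[length(out) + 1]] <- tibble::tibble(
          badge = rxb$did[k], observed_did = grid$observed_did[keep],
          timestamp = grid$slot[keep] + slot_jitter(sum(keep), config),
          rssi = r[keep])
      }
    }
  }
  sig <- dplyr::bind_rows(out)
  if (!nrow(sig)) {
    sig <- tibble::tibble(badge = character(), observed_did = character(),
                          timestamp = numeric(), rssi = integer())
  }
  dplyr::arrange(sig, .data$badge, .data$timestamp, .data$observed_did)
}

slot_jitter <- function(n, config) {
  if (config$jitter_max <= 0) return(rep(0, n))
  sample(0:config$jitter_max, n, replace = TRUE)
}

slot_seq <- function(t0, t1) {
  lo <- SLOT_S * ceiling(t0 / SLOT_S)
  if (lo >= t1) return(numeric(0))
  seq(lo, t1 - 1e-9, by = SLOT_S)
}

# Sample co-located non-interacting dyad-slots at background_prob.
background_dyad_slots <- function(config, part, schedule, active_states) {
  p <- config$background_prob
  if (p <= 0) return(empty_states())
  rooms <- room_blocks(schedule)
  out <- list()
  # classroom blocks: all dyads within the class
  cls_blocks <- rooms[rooms$label == "C", , drop = FALSE]
  for (k in seq_len(nrow(cls_blocks))) {
    members <- part$did[part$class_id == cls_blocks$class_id[k]]
    out[[length(out) + 1]] <- sample_block_pairs(
      members, cls_blocks$t_start[k], cls_blocks$t_end[k], p)
  }
  # yard blocks: all badges simultaneously out; split the yard timeline at
  # every free-segment boundary so occupancy is constant within a piece
  fsegs <- rooms[rooms$label == "F", , drop = FALSE]
  if (nrow(fsegs)) {
    cuts <- sort(unique(c(fsegs$t_start, fsegs$t_end)))
    for (k in seq_len(length(cuts) - 1)) {
      lo <- cuts[k]; hi <- cuts[k + 1]
      cls_out <- fsegs$class_id[fsegs$t_start <= lo & fsegs$t_end >= hi]
      if (length(cls_out) < 1) next
      members <- part$did[part$class_id %in% cls_out]
      out[[length(out) + 1]] <- sample_block_pairs(members, lo, hi, p)
    }
  }
  bg <- dplyr::bind_rows(out)
  if (!nrow(bg)) return(empty_states())
  bg <- dplyr::distinct(bg)
  if (nrow(active_states)) bg <- dplyr::anti_join(bg, active_states,
                                                  by = c("i", "j", "slot"))
  bg
}

sample_block_pairs <- function(members, t0, t1, p) {
  slots <- slot_seq(t0, t1)
  if (length(members) < 2 || !length(slots)) return(empty_states())
  pr <- utils::combn(sort(members), 2)
  n_pair <- ncol(pr)
  # expected draws per pair ~ Binomial(n_slot, p); sample slot subsets
  out <- vector("list", n_pair)
  n_hit <- stats::rbinom(n_pair, length(slots), p)
  for (q in which(n_hit > 0)) {
    out[[q]] <- tibble::tibble(
      i = pr[1, q], j = pr[2, q],
      slot = sort(sample(slots, n_hit[q], replace = FALSE)))
  }
  keep <- !vapply(out, is.null, TRUE)
  if (!any(keep)) return(empty_states())
  dplyr::bind_rows(out[keep])
}
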