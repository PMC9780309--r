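#' Build handshake pairs for one dyad
#'
#' A handshake pair is a mutual observation on the 5-s beacon grid: badge A
#' logs B and B logs A, with both RSSI values at or above -93 dBm and the two
#' reception times no further than 2.5 s apart. Mutual records are matched
#' greedily by nearest timestamp, each record used at most once; unmatched
#' one-directional records are dropped by default.
#'
#' @param seq_i records of badge i observing j: tibble \code{timestamp},
#'   \code{rssi} (an \code{observed_did} column, if present, is filtered to
#'   \code{j}).
#' @param seq_j records of badge j observing i (filtered symmetrically).
#' @param i,j the dyad DIDs (canonical order is applied).
#' @param max_dt maximum raw-time separation of the two directions (s).
#' @param keep_unmatched also emit one-directional pairs with the missing
#'   direction's RSSI absent (\code{NA}).
#' @return tibble \code{slot} (5-s grid time), \code{i}, \code{j},
#'   \code{rssi_ij} (i's reading of j), \code{rssi_ji}, with \code{i < j}.
#' @export
build_handshakes <- function(seq_i, seq_j, i, j, max_dt = 2.5,
                             keep_unmatched = FALSE) {
  if (i > j) {  # canonicalize: swap roles
    return(build_handshakes(seq_j, seq_i, j, i, max_dt, keep_unmatched))
  }
  pick <- function(s, target) {
    if ("observed_did" %in% names(s)) {
      s <- s[s$observed_did == target, , drop = FALSE]
    }
    s <- s[s$rssi >= RSSI_CLEAN_MIN, , drop = FALSE]
    s[order(s$timestamp), , drop = FALSE]
  }
  a <- pick(seq_i, j)   # i hears j
  b <- pick(seq_j, i)   # j hears i
  na_pair <- tibble::tibble(slot = numeric(), i = character(),
                            j = character(), rssi_ij = integer(),
                            rssi_ji = integer())
  if (!nrow(a) && !nrow(b)) return(na_pair)
  # greedy nearest-time matching, each record used once
  m <- greedy_match(a$timestamp, b$timestamp, max_dt)
  out <- list()
  if (nrow(m)) {
    tmin <- pmin(a$timestamp[m$ia], b$timestamp[m$ib])
    out[[1]] <- tibble::tibble(
      slot = SLOT_S * floor(tmin / SLOT_S), i = i, j = j,
      rssi_ij = a$rssi[m$ia], rssi_ji = b$rssi[m$ib])
  }
  if (keep_unmatched) {
    ua <- setdiff(seq_len(nrow(a)), m$ia)
    ub <- setdiff(seq_len(nrow(b)), m$ib)
    if (length(ua)) {
      out[[length(out) + 1]] <- tibble::tibble(
        slot = SLOT_S * floor(a$timestamp[ua] / SLOT_S), i = i, j = j,
        rssi_ij = a$rssi[ua], rssi_ji = NA_integer_)
    }
    if (length(ub)) {
      out[[length(out) + 1]] <- tibble::tibble(
        slot = SLOT_S * floor(b$timestamp[ub] / SLOT_S), i = i, j = j,
        rssi_ij = NA_integer_, rssi_ji = b$rssi[ub])
    }
  }
  if (!length(out)) return(na_pair)
  res <- dplyr::arrange(dplyr::bind_rows(out), .data$slot)
  # one pair per slot: keep the closest-matched (first) occurrence
  res[!duplicated(res$slot), , drop = FALSE]
}

# pair elements of two sorted time vectors greedily by smallest |dt| <= max_dt
greedy_match <- function(ta, tb, max_dt) {
  if (!length(ta) || !length(tb)) {
    return(data.frame(ia = integer(), ib = integer()))
  }
  # candidates: for each a-record, the b-records inside [t - max_dt, t + max_dt]
  lo <- findInterval(ta - max_dt - 1e-9, tb)
  hi <- findInterval(ta + max_dt + 1e-9, tb)
  n_c <- pmax(0L, hi - lo)
  ia_all <- rep.int(seq_along(ta), n_c)
  ib_all <- sequence(n_c, from = lo + 1L)
  cand <- data.frame(ia = ia_all, ib = ib_all)
  cand$dt <- abs(ta[cand$ia] - tb[cand$ib])
  cand <- cand[order(cand$dt, cand$ia, cand$ib), , drop = FALSE]
  used_a <- logical(length(ta)); used_b <- logical(length(tb))
  ia <- ib <- integer()
  for (k in seq_len(nrow(cand))) {
    qa <- cand$ia[k]; qb <- cand$ib[k]
    if (!used_a[qa] && !used_b[qb]) {
      used_a[qa] <- TRUE; used_b[qb] <- TRUE
      ia <- c(ia, qa); ib <- c(ib, qb)
    }
  }
  data.frame(ia = ia, ib = ib)
}

#' Build handshake pairs for every dyad of a half-day
#'
#' @param signals pre-processed signal table.
#' @param roster badge roster; RX badges are excluded.
#' @param max_dt maximum raw-time separation (s).
#' @return handshake tibble over all dyads with at least one pair.
#' @export
handshakes_all <- function(signals, roster, max_dt = 2.5) {
  part <- roster$did[roster$kind != "rx"]
  sig <- signals[signals$badge %in% part & signals$observed_did %in% part, ,
                 drop = FALSE]
  if (!nrow(sig)) {
    return(tibble::tibble(slot = numeric(), i = character(), j = character(),
                          rssi_ij = integer(), rssi_ji = integer()))
  }
  sig$a <- pmin(sig$badge, sig$observed_did)
  sig$b <- pmax(sig$badge, sig$observed_did)
  out <- list()
  for (grp in split(seq_len(nrow(sig)), paste(sig$a, sig$b))) {
    d <- sig[grp, , drop = FALSE]
    i <- d$a[1]; j <- d$b[1]
    out[[length(out) + 1]] <- build_handshakes(
      d[d$badge == i, c("observed_did", "timestamp", "rssi")],
      d[d$badge == j, c("observed_did", "timestamp", "rssi")],
      i, j, max_dt)
  }
  dplyr::bind_rows(out)
}

# order-invariant features: stronger and weaker direction RSSI, with an
# absent direction imputed at the -93 dBm floor
handshake_features <- function(pairs) {
  r1 <- ifelse(is.na(pairs$rssi_ij), RSSI_CLEAN_MIN, pairs$rssi_ij)
  r2 <- ifelse(is.na(pairs$rssi_ji), RSSI_CLEAN_MIN, pairs$rssi_ji)
  tibble::tibble(r_max = pmax(r1, r2), r_min = pmin(r1, r2))
}

#' Train the logistic interaction classifier
#'
#' Logistic regression of the binary interaction state on the handshake RSSI
#' values (stronger and weaker direction). The fit is rejected unless the
#' predicted interaction probability is non-decreasing in each RSSI feature
#' (non-negative slope coefficients), the physically meaningful direction.
#'
#' @param gt_pairs handshake tibble (ground-truth observation sessions).
#' @param gt_labels binary vector (1 = interaction) aligned to
#'   \code{gt_pairs} rows.
#' @return object of class \code{state_classifier}.
#' @export
train_state_classifier <- function(gt_pairs, gt_labels) {
  stopifnot(nrow(gt_pairs) == length(gt_labels))
  y <- as.integer(gt_labels)
  if (length(unique(y)) < 2) {
    stop("degenerate fit: training labels contain a single class")
  }
  X <- handshake_features(gt_pairs)
  fit <- suppressWarnings(
    stats::glm(y ~ r_max + r_min, data = cbind(y = y, X),
               family = stats::binomial()))
  co <- stats::coef(fit)
  co[is.na(co)] <- 0   # collinear feature dropped by the fit
  if (any(co[c("r_max", "r_min")] < 0)) {
    stop("monotonicity violated: interaction probability must not decrease ",
         "with RSSI")
  }
  structure(list(coef = co), class = "state_classifier")
}

#' @export
print.state_classifier <- function(x, ...) {
  cat("<state_classifier> logit(p) =",
      sprintf("%.3f %+.3f*r_max %+.3f*r_min\n",
              x$coef[1], x$coef[2], x$coef[3]))
  invisible(x)
}

#' Classify handshake pairs into binary interaction states
#'
#' One state per handshake slot, thresholding the predicted probability at
#' 0.5; a probability of exactly 0.5 resolves conservatively to 0
#' (non-interaction).
#'
#' @param pairs handshake tibble.
#' @param classifier a \code{\link{train_state_classifier}} fit.
#' @return tibble \code{slot}, \code{i}, \code{j}, \code{state},
#'   \code{prob}.
#' @export
classify_states <- function(pairs, classifier) {
  stopifnot(inherits(classifier, "state_classifier"))
  if (!nrow(pairs)) {
    return(tibble::tibble(slot = numeric(), i = character(),
                          j = character(), state = integer(),
                          prob = numeric()))
  }
  X <- handshake_features(pairs)
  eta <- classifier$coef[1] + classifier$coef[2] * X$r_max +
    classifier$coef[3] * X$r_min
  p <- stats::plogis(eta)
  tibble::tibble(slot = pairs$slot, i = pairs$i, j = pairs$j,
                 state = as.integer(p > 0.5), prob = p)
}

#' Naive gap-merging reconstruction
#'
#' Any maximal run of non-interaction slots (0-states or slots missing from
#' the sequence -- packet loss is exactly what gap-merging bridges) of length
#' at most \code{gap_slots} lying between two interaction states is rewritten
#' to 1. Gap 0 is the identity (the unreconstructed sequence); the deployed
#' calibration is gap 6, i.e. 30 seconds at the 5-s beacon period.
#'
#' @param states tibble \code{slot}, \code{i}, \code{j}, \code{state} for one
#'   or more dyads.
#' @param gap_slots maximum bridged gap, in slots.
#' @return states tibble with bridged slots set to 1 (bridged missing slots
#'   are materialized).
#' @export
naive_reconstruct <- function(states, gap_slots = 6) {
  stopifnot(gap_slots >= 0)
  if (!nrow(states) || gap_slots == 0) return(states)
  out <- list()
  for (grp in split(seq_len(nrow(states)), paste(states$i, states$j))) {
    d <- states[grp, , drop = FALSE]
    d <- d[order(d$slot), , drop = FALSE]
    ones <- d$slot[d$state == 1]
    fill <- numeric(0)
    if (length(ones) > 1) {
      gap_len <- diff(ones) / SLOT_S - 1
      bridge <- which(gap_len >= 1 & gap_len <= gap_slots)
      for (q in bridge) {
        fill <- c(fill, seq(ones[q] + SLOT_S, ones[q + 1] - SLOT_S,
                            by = SLOT_S))
      }
    }
    if (length(fill)) {
      d$state[d$slot %in% fill] <- 1L
      new <- setdiff(fill, d$slot)
      if (length(new)) {
        d <- dplyr::bind_rows(d, tibble::tibble(
          slot = new, i = d$i[1], j = d$j[1], state = 1L))
      }
      d <- d[order(d$slot), , drop = FALSE]
    }
    out[[length(out) + 1]] <- d
  }
  dplyr::bind_rows(out)
}

#' Merge binary states into contact events
#'
#' Each maximal run of consecutive interaction slots (adjacent on the 5-s
#' grid) becomes one event with \code{t} the first slot time and
#' \code{delta = 5 * run length}.
#'
#' @param states tibble \code{slot}, \code{i}, \code{j}, \code{state}.
#' @return events tibble \code{t}, \code{i}, \code{j}, \code{delta}.
#' @export
merge_events <- function(states) {
  act <- states[states$state == 1, c("i", "j", "slot"), drop = FALSE]
  states_to_events(act)
}

#' Per-slot reconstruction accuracy against ground truth
#'
#' The fraction of matching binary states over the slots present in the
#' truth grid, pooled over all dyads and also averaged per dyad. Predicted
#' sequences missing a truth slot count that slot as state 0 (no detected
#' interaction).
#'
#' @param pred_states tibble \code{slot}, \code{i}, \code{j}, \code{state}.
#' @param true_states truth tibble: either the same shape, or active-slot
#'   form (\code{i}, \code{j}, \code{slot}) interpreted as all-1 with an
#'   explicit slot grid required via \code{grid}.
#' @param grid optional tibble \code{i}, \code{j}, \code{slot} giving the
#'   evaluation grid when \code{true_states} lists only active slots.
#' @return list: \code{pooled} accuracy, \code{per_dyad} tibble
#'   (\code{i}, \code{j}, \code{n_slots}, \code{accuracy}), \code{mean_dyad}.
#' @export
evaluate_accuracy <- function(pred_states, true_states, grid = NULL) {
  if (!("state" %in% names(true_states))) {
    stopifnot(!is.null(grid))
    truth <- grid
    truth$true_state <- 0L
    key <- paste(true_states$i, true_states$j, true_states$slot)
    truth$true_state[paste(truth$i, truth$j, truth$slot) %in% key] <- 1L
  } else {
    truth <- dplyr::rename(true_states, true_state = "state")
  }
  if (!nrow(truth)) stop("alignment error: empty truth grid")
  pred <- pred_states[, c("i", "j", "slot", "state")]
  m <- dplyr::left_join(truth, pred, by = c("i", "j", "slot"))
  if (all(is.na(m$state)) && nrow(pred) > 0) {
    stop("alignment error: prediction and truth grids are disjoint")
  }
  m$state[is.na(m$state)] <- 0L
  m$hit <- m$state == m$true_state
  per <- m %>%
    dplyr::group_by(.data$i, .data$j) %>%
    dplyr::summarise(n_slots = dplyr::n(), accuracy = mean(.data$hit),
                     .groups = "drop")
  list(pooled = mean(m$hit), per_dyad = per,
       mean_dyad = mean(per$accuracy))
}
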