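test_that("the completeness floor reproduces the 80%-of-expected rule", {
  # 3-minute window at the 5-s beacon period: 36 expected, floor 29
  expect_equal(180 / 5, 36)
  expect_equal(completeness_floor(180, 0.8), 29L)
  # the rule is the ceiling, not a round
  expect_equal(completeness_floor(60, 0.8), 10L)
  expect_equal(completeness_floor(175, 0.8), 28L)
})

test_that("sliding-window statistics match a brute-force recomputation", {
  span <- c(1000, 2000)
  # constant RSSI over a full window: mean exact, population SD zero
  rec <- make_records("0002", seq(1000, 1175, by = 5), -60)
  st <- sliding_window_stats(rec, "0002", span = span)
  expect_equal(st$mean_rssi[1], -60)
  expect_equal(st$std_rssi[1], 0)
  expect_equal(st$n_signals[1], 36L)
  expect_true(st$complete[1])

  set.seed(77)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    rec <- make_records("0002", sort(sample(seq(1000, 1999, 0.5), n)),
                        -sample(40:90, n, TRUE))
    st <- sliding_window_stats(rec, "0002", span = span)
    or <- oracle_window_stats(rec$timestamp, rec$rssi, span)
    expect_equal(st$n_signals, or$n_signals)
    expect_equal(st$mean_rssi, or$mean_rssi)
    expect_equal(st$std_rssi, or$std_rssi, tolerance = 1e-10)
  }
})

test_that("worn/unworn flagging follows the -62/2.5 and -55/1.5 rules", {
  span <- c(0, 600)
  t <- seq(0, 595, by = 5)
  # stable strong signal: mean -60, SD 2.0 -> flagged at the RX
  r1 <- rep(c(-58L, -62L), length.out = length(t))
  iv <- detect_unworn_rx(make_records("0011", t, r1), "0011", span = span)
  expect_gt(nrow(iv), 0)
  # strong but unstable (SD 4.0): a worn, moving child -> not flagged
  r2 <- rep(c(-56L, -64L), length.out = length(t))
  expect_equal(nrow(detect_unworn_rx(make_records("0011", t, r2), "0011",
                                     span = span)), 0)
  # weak but stable: far from hub -> not flagged
  r3 <- rep(-70L, length(t))
  expect_equal(nrow(detect_unworn_rx(make_records("0011", t, r3), "0011",
                                     span = span)), 0)

  # own-log thresholds: -50 with SD 1.0 (piled badges) flagged ...
  r4 <- rep(c(-49L, -51L), length.out = length(t))
  iv4 <- detect_unworn_prox(make_records("0012", t, r4), span = span)
  expect_gt(nrow(iv4), 0)
  expect_equal(iv4$cause[1], "issue3")
  # ... but -58 (close face-to-face contact) is protected: -58 < -55
  r5 <- rep(c(-57L, -59L), length.out = length(t))
  expect_equal(nrow(detect_unworn_prox(make_records("0012", t, r5),
                                       span = span)), 0)
  # incomplete windows never flag: same strong signal, 50% density
  sparse <- seq(0, 595, by = 10)
  expect_equal(nrow(detect_unworn_prox(
    make_records("0012", sparse, rep(-50L, length(sparse))), span = span)), 0)
})

test_that("interval consolidation bridges, pads and stays non-overlapping", {
  session <- c(0, 10000)
  iv <- tibble::tibble(did = "0001",
                       t_start = c(0, 190), t_end = c(100, 300),
                       cause = "issue2")
  out <- consolidate_intervals(iv, session, bridge_s = 120, margin_s = 30)
  # gap 90 < 120: merged to [0, 300), then margins, clipped at the session
  expect_equal(nrow(out), 1)
  expect_equal(out$t_start, 0)
  expect_equal(out$t_end, 330)

  # gap exactly 120 is NOT bridged (strictly-less rule)
  iv2 <- tibble::tibble(did = "0001", t_start = c(0, 220),
                        t_end = c(100, 300), cause = "issue2")
  out2 <- consolidate_intervals(iv2, session, 120, 0)
  expect_equal(nrow(out2), 2)

  # single interval: only margins applied
  iv3 <- tibble::tibble(did = "0001", t_start = 500, t_end = 700,
                        cause = "issue3")
  out3 <- consolidate_intervals(iv3, session, 120, 30)
  expect_equal(out3$t_start, 470)
  expect_equal(out3$t_end, 730)

  # fixpoint: margin-free consolidation is idempotent on random interval sets
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    s <- sort(sample(0:5000, n))
    rnd <- tibble::tibble(did = "0001", t_start = s,
                          t_end = s + sample(50:400, n, TRUE),
                          cause = "issue2")
    once <- consolidate_intervals(rnd, session, 120, 0)
    twice <- consolidate_intervals(once, session, 120, 0)
    expect_identical(once, twice)
    expect_true(all(once$t_start[-1] >= once$t_end[-nrow(once)]))
    # with margins the output is still non-overlapping
    m1 <- consolidate_intervals(rnd, session, 120, 30)
    expect_true(all(m1$t_start[-1] >= m1$t_end[-nrow(m1)]))
  }
})

test_that("edge-burst trimming follows the 1-minute/20-s chain rule", {
  # no record above -45 dBm anywhere: sequence kept whole
  rec <- make_records("0002", seq(100, 400, 5), rep(-60L, 61))
  expect_equal(nrow(trim_edge_bursts(rec)), 0)

  # strong at t0+5 and t0+70: 70 is outside the initial window and 65 s
  # after the previous strong time, so the head stops at t0+5
  rec2 <- make_records("0002", seq(100, 400, 5),
                       c(-60L, -40L, rep(-60L, 12), -40L, rep(-60L, 46)))
  iv <- trim_edge_bursts(rec2)
  head_iv <- iv[iv$t_start == 100, ]
  expect_equal(nrow(head_iv), 1)
  expect_equal(head_iv$t_end, 105)

  # chain continuation: strongs at 55 and 70 (15 s apart) extend past the
  # window
  rssi3 <- rep(-60L, 61)
  rssi3[c(2, 12, 15)] <- -40L   # t = 105, 155, 170
  rec3 <- make_records("0002", seq(100, 400, 5), rssi3)
  iv3 <- trim_edge_bursts(rec3)
  expect_equal(iv3$t_end[iv3$t_start == 100], 170)

  # forward scan equals the literal re-implementation on random sequences
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    t <- sort(sample(seq(0, 500, 5), n)) + sample(0:2, n, TRUE)
    r <- -sample(c(35:44, 60:80), n, TRUE)
    rec <- make_records("0002", t, r)
    iv <- trim_edge_bursts(rec)
    ts <- oracle_edge_forward(t, r)
    head_iv <- iv[iv$t_start == min(t), , drop = FALSE]
    if (is.na(ts)) {
      expect_equal(nrow(head_iv), 0)
    } else {
      expect_equal(head_iv$t_end, ts)
    }
  }
})

test_that("silent and deaf badges are repaired by direction reversal", {
  roster <- tibble::tibble(did = c("0001", "0002", "0003", "2001"),
                           kind = c("child", "child", "child", "rx"),
                           class_id = 1L)
  # 0001 silent: receives (0002, 100, -70) but never appears anywhere
  sig <- tibble::tibble(
    badge = c("0001", "0002", "0003"),
    observed_did = c("0002", "0003", "0002"),
    timestamp = c(100, 100, 102), rssi = c(-70L, -75L, -74L))
  rep1 <- repair_silent_deaf(sig, roster)
  expect_equal(rep1$silent, "0001")
  added <- rep1$signals[rep1$signals$observed_did == "0001", ]
  expect_equal(added$badge, "0002")
  expect_equal(added$timestamp, 100)
  expect_equal(added$rssi, -70L)

  # no silent or deaf badges -> identity
  sig2 <- tibble::tibble(badge = c("0001", "0002"),
                         observed_did = c("0002", "0001"),
                         timestamp = c(100, 101), rssi = c(-70L, -71L))
  rep2 <- repair_silent_deaf(sig2, roster[1:2, ])
  expect_identical(rep2$signals, sig2)
  expect_equal(length(rep2$silent), 0)

  # after repair, mutual-observation asymmetry vanishes for repaired pairs
  cfg <- tiny_sim_config(seed = 17, artifacts_on = FALSE)
  cfg$artifacts$silent_rate <- 0.3
  cfg$artifacts$deaf_rate <- 0.3
  sim <- simulate_half_day(cfg)
  rep3 <- repair_silent_deaf(sim$signals, sim$roster)
  affected <- unique(sim$truth$artifact_intervals$did)
  expect_gt(length(affected), 0)
  s <- rep3$signals[substr(rep3$signals$badge, 1, 1) != "2" &
                      substr(rep3$signals$observed_did, 1, 1) != "2", ]
  for (b in affected) {
    peers <- unique(c(s$observed_did[s$badge == b], s$badge[s$observed_did == b]))
    for (p in setdiff(peers, affected)) {
      t_fwd <- sort(s$timestamp[s$badge == b & s$observed_did == p])
      t_bwd <- sort(s$timestamp[s$badge == p & s$observed_did == b])
      expect_equal(t_fwd, t_bwd)
    }
  }
})

test_that("bidirectional removals are exactly scoped", {
  sig <- tibble::tibble(
    badge = c("0001", "0001", "0002", "0003"),
    observed_did = c("0002", "0003", "0001", "0001"),
    timestamp = c(100, 200, 100, 900), rssi = -70L)
  iv <- tibble::tibble(did = "0001", t_start = 0, t_end = 500,
                       cause = "issue2")
  out <- apply_removals(sig, iv)
  expect_equal(nrow(out), 1)          # only 0003's record at 900 survives
  expect_equal(out$timestamp, 900)
  expect_identical(apply_removals(sig, iv[0, ]), sig)

  # removal counts match a linear-scan oracle on random tables
  set.seed(41)
  for (rep in 1:5) {
    n <- 300
    sig2 <- tibble::tibble(
      badge = sample(c("0001", "0002", "0003"), n, TRUE),
      observed_did = sample(c("0001", "0002", "0003"), n, TRUE),
      timestamp = sample(0:2000, n, TRUE), rssi = -70L)
    t0 <- 300; t1 <- 1200
    out2 <- apply_removals(sig2, tibble::tibble(
      did = "0002", t_start = t0, t_end = t1, cause = "issue2"))
    exp_rm <- sum((sig2$badge == "0002" | sig2$observed_did == "0002") &
                    sig2$timestamp >= t0 & sig2$timestamp < t1)
    expect_equal(nrow(sig2) - nrow(out2), exp_rm)
  }
})

test_that("the four-issue pipeline is a no-op on artifact-free data and
           removes injected artifact time", {
  cfg <- tiny_sim_config(seed = 19, artifacts_on = FALSE)
  sim <- simulate_half_day(cfg)
  win <- session_window(1, "M")
  cleaned <- initial_clean_signals(sim$signals, win)
  pp <- preprocess_half_day(cleaned, sim$roster)
  expect_equal(nrow(pp$report), 0)
  expect_identical(pp$signals, cleaned)

  # with all artifact classes injected, every unworn/pile/burst interval is
  # overlapped by a removal of the matching cause
  cfg2 <- tiny_sim_config(n_classes = 2, class_size = 8, seed = 23,
                          artifacts_on = TRUE)
  sim2 <- simulate_half_day(cfg2)
  cleaned2 <- initial_clean_signals(sim2$signals, win)
  pp2 <- preprocess_half_day(cleaned2, sim2$roster)
  truth_iv <- sim2$truth$artifact_intervals
  overlapped <- function(k) {
    rm <- pp2$report[pp2$report$did == truth_iv$did[k], ]
    any(rm$t_start < truth_iv$t_end[k] & truth_iv$t_start[k] < rm$t_end)
  }
  # unworn and pile intervals are long and stable: every one is caught
  for (k in which(truth_iv$cause %in% c("unworn_hub", "pile"))) {
    expect_true(overlapped(k),
                label = paste("artifact", truth_iv$cause[k], "of",
                              truth_iv$did[k], "overlapped by a removal"))
  }
  # burst detectability scales with the number of gathered badges; at this
  # sparse class size most, but not necessarily all, bursts leave a strong
  # signal inside the scan window
  bursts <- which(truth_iv$cause == "burst")
  expect_gt(length(bursts), 3)
  expect_gte(mean(vapply(bursts, overlapped, TRUE)), 0.7)

  # record counts only ever shrink through removal stages
  expect_lte(nrow(pp2$signals), nrow(cleaned2) + 0 +
               sum(cleaned2$badge %in% sim2$roster$did))
})

test_that("a class without RX data skips Issue 2 with a warning but still
           runs Issue 3", {
  cfg <- tiny_sim_config(seed = 29, artifacts_on = FALSE)
  cfg$artifacts$pile_prob <- 1
  sim <- simulate_half_day(cfg)
  win <- session_window(1, "M")
  cleaned <- initial_clean_signals(sim$signals, win)
  no_rx <- cleaned[substr(cleaned$badge, 1, 1) != "2", ]
  w <- testthat::capture_warnings(pp <- preprocess_half_day(no_rx, sim$roster))
  expect_true(any(grepl("Issue 2", w)))
  expect_false(any(pp$report$cause == "issue2"))
  expect_true(any(pp$report$cause == "issue3"))
})
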