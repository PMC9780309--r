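test_that("inter/intra counts tally active child states per 10-s bin", {
  cm <- tibble::tibble(did = c("0001", "0002", "0101", "1001"),
                       kind = c("child", "child", "child", "adult"),
                       class_id = c(1L, 1L, 2L, 1L))
  span <- c(0, 40)
  # one intra-class dyad active for a whole 10-s bin: two 5-s states
  st <- tibble::tibble(slot = c(0, 5), i = "0001", j = "0002",
                       state = 1L)
  cv <- count_inter_intra(st, cm, 10, span)
  expect_equal(cv$intra[cv$class_id == 1 & cv$bin == 0], 2)
  expect_equal(sum(cv$inter), 0)

  # no interactions: all-zero curves
  cv0 <- count_inter_intra(st[0, ], cm, 10, span)
  expect_true(all(cv0$inter == 0) && all(cv0$intra == 0))

  # adult interactions are excluded from the ratio counts
  st_a <- tibble::tibble(slot = 0, i = "0001", j = "1001", state = 1L)
  cv_a <- count_inter_intra(st_a, cm, 10, span)
  expect_true(all(cv_a$intra == 0))

  expect_error(count_inter_intra(
    tibble::tibble(slot = 0, i = "0001", j = "0999", state = 1L),
    cm, 10, span), "missing from class map")

  # brute-force tally oracle on random states
  set.seed(101)
  dids <- cm$did
  st_r <- tibble::tibble(slot = 5 * sample(0:7, 30, TRUE),
                         i = sample(dids, 30, TRUE),
                         j = sample(dids, 30, TRUE), state = 1L)
  st_r <- st_r[st_r$i < st_r$j, ]
  st_r <- st_r[!duplicated(st_r), ]
  cv_r <- count_inter_intra(st_r, cm, 10, span)
  cls <- setNames(cm$class_id, cm$did)
  knd <- setNames(cm$kind, cm$did)
  for (cl in 1:2) {
    for (b in seq(0, 30, 10)) {
      sel <- st_r$slot >= b & st_r$slot < b + 10 &
        knd[st_r$i] == "child" & knd[st_r$j] == "child"
      both <- sel & cls[st_r$i] == cl & cls[st_r$j] == cl
      one <- sel & xor(cls[st_r$i] == cl, cls[st_r$j] == cl)
      expect_equal(cv_r$intra[cv_r$class_id == cl & cv_r$bin == b],
                   sum(both))
      expect_equal(cv_r$inter[cv_r$class_id == cl & cv_r$bin == b],
                   sum(one))
    }
  }
})

test_that("Gaussian smoothing is normalized, impulse-faithful and
           mass-conserving", {
  expect_equal(smooth_counts(rep(4, 50), 3), rep(4, 50), tolerance = 1e-9)
  # unit impulse reproduces the normalized kernel
  n <- 101
  x <- numeric(n); x[51] <- 1
  sm <- smooth_counts(x, 3)
  r <- ceiling(4 * 3)
  k <- dnorm(-r:r, sd = 3); k <- k / sum(k)
  expect_equal(sm[(51 - r):(51 + r)], k, tolerance = 1e-12)
  # interior mass conserved
  expect_equal(sum(sm), 1, tolerance = 1e-9)
})

test_that("the inter/intra ratio applies the zero-division default", {
  params <- segmentation_params(ratio_threshold = 0.15)
  # a fully silent half-day: 0/0 everywhere -> the 2 * threshold default
  cv <- tibble::tibble(class_id = 1L, bin = 10 * (0:9), inter = 0, intra = 0)
  out <- compute_ratio(cv, params)
  expect_equal(out$ratio, rep(0.30, 10))
  # constant counts pass through smoothing: 3/30 elementwise
  cv1 <- tibble::tibble(class_id = 1L, bin = 10 * (0:9), inter = 3,
                        intra = 30)
  expect_equal(compute_ratio(cv1, params)$ratio, rep(0.1, 10),
               tolerance = 1e-9)
  # elementwise oracle without smoothing effects
  cv2 <- cv; cv2$inter <- 5; cv2$intra <- 20
  out2 <- compute_ratio(cv2, params)
  expect_equal(out2$ratio, rep(0.25, 10), tolerance = 1e-9)
})

test_that("period segmentation bridges sub-gap fluctuations", {
  params <- segmentation_params(0.15, 600, 3, 10)
  span <- c(0, 2700)
  # ratio constantly 0: one class-time segment
  cv0 <- tibble::tibble(class_id = 1L, bin = seq(0, 2690, 10),
                        ratio = 0, inter = 0, intra = 1)
  seg0 <- segment_periods(cv0, params, span)
  expect_equal(nrow(seg0), 1)
  expect_equal(seg0$label, "C")

  # F(1200) C(300) F(1200): the 300-s dip is bridged into one F segment
  lab <- c(rep(1, 120), rep(0, 30), rep(1, 120))
  cv1 <- tibble::tibble(class_id = 1L, bin = 10 * (seq_along(lab) - 1),
                        ratio = ifelse(lab == 1, 0.5, 0))
  seg1 <- segment_periods(cv1, params, span)
  expect_equal(nrow(seg1), 1)
  expect_equal(seg1$label, "F")
  expect_equal(seg1$t_end - seg1$t_start, 2700)

  # bridging equals brute-force absorption on random label strings
  set.seed(202)
  for (rep in 1:40) {
    n <- sample(10:50, 1)
    labs <- sample(c("F", "C"), n, TRUE)
    gb <- sample(2:6, 1)
    expect_identical(proxinet:::bridge_labels(labs, gb),
                     oracle_bridge(labs, gb))
  }
})

test_that("edge alignment enforces at-least-two-classes-out free time", {
  # classes A, B out 540-600 s and 550-610 s: A's start clipped to 550,
  # B's end clipped to 600
  segs <- dplyr::bind_rows(
    tibble::tibble(class_id = 1L,
                   t_start = c(0, 540, 600), t_end = c(540, 600, 1000),
                   label = c("C", "F", "C")),
    tibble::tibble(class_id = 2L,
                   t_start = c(0, 550, 610), t_end = c(550, 610, 1000),
                   label = c("C", "F", "C")))
  out <- align_edges(segs)
  f1 <- out[out$class_id == 1 & out$label == "F", ]
  f2 <- out[out$class_id == 2 & out$label == "F", ]
  expect_equal(f1$t_start, 550)
  expect_equal(f1$t_end, 600)
  expect_equal(f2$t_start, 550)
  expect_equal(f2$t_end, 600)

  # a lone-class free-time period is relabeled class-time
  lone <- dplyr::bind_rows(
    tibble::tibble(class_id = 1L, t_start = c(0, 300, 400),
                   t_end = c(300, 400, 1000), label = c("C", "F", "C")),
    tibble::tibble(class_id = 2L, t_start = 0, t_end = 1000, label = "C"))
  out2 <- align_edges(lone)
  expect_true(all(out2$label[out2$class_id == 1] == "C"))

  # segments still tile each class's half-day
  for (cl in 1:2) {
    s <- out[out$class_id == cl, ]
    s <- s[order(s$t_start), ]
    expect_equal(s$t_start[-1], s$t_end[-nrow(s)])
  }

  # post-condition on simulated schedules: every retained F instant is
  # shared by >= 2 classes (interval-overlap oracle at 10-s resolution)
  for (seed in 1:5) {
    cfg <- sim_config(n_classes = 4, class_sizes = 3, n_adults = 0,
                      seed = seed)
    set.seed(seed)
    sch <- simulate_schedule(cfg, 1, "M")
    out3 <- align_edges(sch)
    f <- out3[out3$label == "F", ]
    for (k in seq_len(nrow(f))) {
      grid <- seq(f$t_start[k], f$t_end[k] - 1, by = 10)
      for (x in grid) {
        others <- f[f$class_id != f$class_id[k], ]
        expect_true(any(others$t_start <= x & x < others$t_end))
      }
    }
  }
})

test_that("the segmentation error is the free-time symmetric difference", {
  span <- c(0, 1000)
  mk <- function(f_start, f_end) {
    tibble::tibble(class_id = 1L,
                   t_start = c(span[1], f_start, f_end),
                   t_end = c(f_start, f_end, span[2]),
                   label = c("C", "F", "C"))
  }
  # truth [0,100) vs prediction [10,110): 100 + 100 - 2*90 = 20 s
  expect_equal(segmentation_error(mk(10, 110), mk(0.001, 100)), 20,
               tolerance = 0.01)
  p <- mk(200, 400)
  expect_equal(segmentation_error(p, p), 0)
  # symmetry
  q <- mk(250, 500)
  expect_equal(segmentation_error(p, q), segmentation_error(q, p))

  # slotwise oracle on random segmentations (possibly several F periods)
  set.seed(303)
  rand_segs <- function() {
    cuts <- sort(sample(seq(0, 1000, 10), sample(2:6, 1)))
    bounds <- unique(c(0, cuts, 1000))
    labs <- sample(c("F", "C"), length(bounds) - 1, TRUE)
    tibble::tibble(class_id = 1L, t_start = head(bounds, -1),
                   t_end = tail(bounds, -1), label = labs)
  }
  for (rep in 1:20) {
    a <- rand_segs(); b <- rand_segs()
    expect_equal(segmentation_error(a, b),
                 oracle_symmdiff_slotwise(a, b, c(0, 1000), step = 10))
  }
})

test_that("grid search is exhaustive with deterministic tie-breaks", {
  # single-cell grid returns that cell
  cv <- tibble::tibble(class_id = 1L, bin = 10 * (0:99),
                       inter = rep(c(0, 5), each = 50),
                       intra = rep(c(10, 5), each = 50))
  truth <- tibble::tibble(class_id = 1L, t_start = c(0, 500),
                          t_end = c(500, 1000), label = c("C", "F"))
  gs <- grid_search_segmentation(cv, truth, 0.15, 600, span = c(0, 1000),
                                 align = FALSE)
  expect_equal(gs$best$ratio_threshold, 0.15)
  expect_equal(gs$best$gap_threshold_s, 600)
  expect_equal(nrow(gs$surface), 1)
  # surface minimum equals an independently recomputed error at that cell
  params <- segmentation_params(0.15, 600)
  segs <- segment_all_classes(cv, params, c(0, 1000))
  expect_equal(gs$best$error_s, segmentation_error(segs, truth))
  expect_error(grid_search_segmentation(cv, truth, numeric(), 600), "empty")
})

test_that("event annotation produces the SSSSX label convention", {
  cm <- tibble::tibble(did = c("0001", "0002", "0101"),
                       kind = "child", class_id = c(1L, 1L, 2L))
  segs <- dplyr::bind_rows(
    tibble::tibble(class_id = 1L, t_start = c(0, 30), t_end = c(30, 100),
                   label = c("F", "C")),
    tibble::tibble(class_id = 2L, t_start = c(0, 30), t_end = c(30, 100),
                   label = c("F", "C")))
  # the canonical worked example: theta = (10, i, j, 40), classmates in
  # free time at t = 10 and in class at t = 50 -> FCFC1
  ev <- tibble::tibble(t = 10, i = "0001", j = "0002", delta = 40)
  out <- annotate_events(ev, segs, cm)
  expect_equal(out$labels, "FCFC")
  expect_equal(out$flag, 1L)

  # cross-class event fully inside free time -> FFFF0
  ev2 <- tibble::tibble(t = 10, i = "0001", j = "0101", delta = 15)
  out2 <- annotate_events(ev2, segs, cm)
  expect_equal(out2$labels, "FFFF")
  expect_equal(out2$flag, 0L)

  # an event end exactly on a boundary belongs to the later segment
  ev3 <- tibble::tibble(t = 20, i = "0001", j = "0002", delta = 10)
  expect_equal(annotate_events(ev3, segs, cm)$labels, "FCFC")
  # ... except the final session boundary, which closes the last segment
  ev4 <- tibble::tibble(t = 90, i = "0001", j = "0002", delta = 10)
  expect_equal(annotate_events(ev4, segs, cm)$labels, "CCCC")

  expect_error(annotate_events(
    tibble::tibble(t = 95, i = "0001", j = "0002", delta = 10), segs, cm),
    "outside")

  # summary percentages over an annotated set sum to 100 up to rounding
  set.seed(6)
  ev5 <- tibble::tibble(t = 5 * sample(0:17, 30, TRUE), i = "0001",
                        j = sample(c("0002", "0101"), 30, TRUE),
                        delta = 5 * sample(1:2, 30, TRUE))
  tn <- annotate_events(ev5, segs, cm)
  sm <- annotation_summary(tn)
  expect_lt(abs(sum(sm$count_pct) - 100), 0.05)
  expect_lt(abs(sum(sm$duration_pct) - 100), 0.05)
})
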