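test_that("handshake pairing obeys the +/-2.5 s mutual-observation rule", {
  a <- make_records("0002", 100.0, -70)   # A hears B
  b2 <- make_records("0001", 102.0, -72)  # B hears A, 2.0 s later
  p <- build_handshakes(a, b2, "0001", "0002")
  expect_equal(nrow(p), 1)
  expect_equal(p$slot, 100)
  expect_equal(p$rssi_ij, -70L)
  expect_equal(p$rssi_ji, -72L)

  b3 <- make_records("0001", 103.0, -72)  # 3.0 s apart: no pair
  expect_equal(nrow(build_handshakes(a, b3, "0001", "0002")), 0)

  # sub--93 dBm records never pair
  weak <- make_records("0001", 100.0, -94)
  expect_equal(nrow(build_handshakes(a, weak, "0001", "0002")), 0)

  # symmetry: swapping the dyad roles yields the identical canonical pairs
  p2 <- build_handshakes(b2, a, "0002", "0001")
  expect_identical(p, p2)
})

test_that("handshake count equals brute-force optimal matching on jittered
           sequences", {
  set.seed(55)
  for (rep in 1:30) {
    slots_a <- sort(sample(seq(0, 50, 5), sample(2:6, 1)))
    slots_b <- sort(sample(seq(0, 50, 5), sample(2:6, 1)))
    ta <- slots_a + sample(0:2, length(slots_a), TRUE)
    tb <- slots_b + sample(0:2, length(slots_b), TRUE)
    a <- make_records("0002", ta, -70)
    b <- make_records("0001", tb, -72)
    p <- build_handshakes(a, b, "0001", "0002")
    expect_equal(nrow(p), oracle_max_matching(ta, tb))
  }
})

test_that("the logistic state classifier separates regimes and matches an
           independent likelihood fit", {
  # separable toy set: interactions at -50, non-interactions at -90
  pairs <- tibble::tibble(slot = 5 * (0:19), i = "0001", j = "0002",
                          rssi_ij = rep(c(-50L, -90L), each = 10),
                          rssi_ji = rep(c(-52L, -88L), each = 10))
  y <- rep(c(1, 0), each = 10)
  clf <- train_state_classifier(pairs, y)
  st <- classify_states(pairs, clf)
  expect_equal(st$state, y)    # perfect training accuracy

  # monotonicity: stronger RSSI -> higher interaction probability
  strong <- classify_states(tibble::tibble(
    slot = 0, i = "a", j = "b", rssi_ij = -40L, rssi_ji = -40L), clf)$prob
  weak <- classify_states(tibble::tibble(
    slot = 0, i = "a", j = "b", rssi_ij = -90L, rssi_ji = -90L), clf)$prob
  expect_gt(strong, weak)

  # degenerate single-class labels are rejected
  expect_error(train_state_classifier(pairs, rep(1, 20)), "single class")

  # coefficients agree with an independent optimizer on an overlapping set
  set.seed(3)
  n <- 200
  r1 <- as.integer(round(c(rnorm(n / 2, -60, 8), rnorm(n / 2, -80, 8))))
  r2 <- as.integer(round(r1 + rnorm(n, 0, 3)))
  pr <- tibble::tibble(slot = 5 * seq_len(n), i = "0001", j = "0002",
                       rssi_ij = pmax(r1, r2), rssi_ji = pmin(r1, r2))
  yy <- rep(c(1, 0), each = n / 2)
  clf2 <- train_state_classifier(pr, yy)
  nll <- function(beta) {
    eta <- beta[1] + beta[2] * pmax(r1, r2) + beta[3] * pmin(r1, r2)
    -sum(yy * eta - log1p(exp(eta)))
  }
  ind <- stats::optim(c(0, 0, 0), nll, method = "BFGS")
  expect_equal(unname(clf2$coef), ind$par, tolerance = 1e-3)

  # per-slot probabilities equal the direct sigmoid formula
  st2 <- classify_states(pr, clf2)
  eta <- clf2$coef[1] + clf2$coef[2] * pmax(r1, r2) + clf2$coef[3] *
    pmin(r1, r2)
  expect_equal(st2$prob, unname(1 / (1 + exp(-eta))))
})

test_that("naive gap-merging equals exhaustive enumeration on short strings", {
  # 1,0,0,1 with gap 1 unchanged; with gap 2 filled
  s <- states_from_vector(c(1, 0, 0, 1))
  expect_identical(naive_reconstruct(s, 1)$state, c(1L, 0L, 0L, 1L))
  expect_identical(naive_reconstruct(s, 2)$state, rep(1L, 4))
  # gap 0 is the identity
  expect_identical(naive_reconstruct(s, 0), s)

  # exhaustive oracle over all binary strings up to length 8, plus a random
  # sample of length-12 strings
  check_strings <- function(strings, g) {
    bad <- 0L
    for (v in strings) {
      got <- naive_reconstruct(states_from_vector(v), g)
      want <- oracle_fill_dense(v, g)
      if (!identical(got$state[order(got$slot)], as.integer(want))) {
        bad <- bad + 1L
      }
    }
    bad
  }
  for (len in c(4, 8)) {
    combos <- expand.grid(rep(list(0:1), len))
    strings <- lapply(seq_len(nrow(combos)),
                      function(r) as.integer(combos[r, ]))
    for (g in c(1, 2, 6)) {
      expect_equal(check_strings(strings, g), 0L,
                   label = sprintf("mismatches at len %d gap %d", len, g))
    }
  }
  set.seed(8)
  long <- replicate(150, sample(0:1, 12, TRUE), simplify = FALSE)
  for (g in c(1, 3, 6)) expect_equal(check_strings(long, g), 0L)
})

test_that("gap semantics treat missing slots like zeros", {
  # 1-states at slots 0 and 35: six missing slots between them
  s <- tibble::tibble(slot = c(0, 35), i = "0001", j = "0002",
                      state = c(1L, 1L))
  filled <- naive_reconstruct(s, 6)
  expect_equal(nrow(filled), 8)
  expect_true(all(filled$state == 1))
  ev <- merge_events(filled)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$delta, 40)
  # a seventh missing slot exceeds the gap
  s2 <- tibble::tibble(slot = c(0, 40), i = "0001", j = "0002",
                       state = c(1L, 1L))
  expect_equal(nrow(merge_events(naive_reconstruct(s2, 6))), 2)
})

test_that("naive reconstruction is monotone in the gap threshold", {
  set.seed(66)
  for (rep in 1:10) {
    v <- sample(0:1, 40, TRUE, prob = c(0.6, 0.4))
    s <- states_from_vector(v)
    prev_events <- Inf
    prev_time <- -Inf
    for (g in 0:8) {
      ev <- merge_events(naive_reconstruct(s, g))
      expect_lte(nrow(ev), prev_events)
      expect_gte(sum(ev$delta), prev_time)
      prev_events <- nrow(ev)
      prev_time <- if (nrow(ev)) sum(ev$delta) else 0
    }
  }
})

test_that("event merging conserves interaction time", {
  expect_equal(merge_events(states_from_vector(1))$delta, 5)
  expect_equal(nrow(merge_events(states_from_vector(rep(0, 6)))), 0)
  set.seed(7)
  for (rep in 1:20) {
    v <- sample(0:1, 30, TRUE)
    ev <- merge_events(states_from_vector(v))
    expect_equal(sum(ev$delta), 5 * sum(v))
    if (nrow(ev)) expect_true(all(ev$delta %% 5 == 0 & ev$delta > 0))
  }
})

test_that("Viterbi decoding equals exhaustive path enumeration", {
  # near-deterministic model reproduces a noiseless input
  m <- hmm_model(init = c(0.5, 0.5),
                 trans = matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
                 means = rbind(c(-85, 0.05), c(-60, 0.95)),
                 sds = rbind(c(0.5, 0.02), c(0.5, 0.02)))
  truth_path <- c(0, 0, 1, 1, 1, 0)
  X <- cbind(ifelse(truth_path == 1, -60, -85),
             ifelse(truth_path == 1, 0.95, 0.05))
  expect_equal(viterbi_decode(m, X), truth_path)

  # random small models vs brute force over 2^6 paths
  set.seed(99)
  for (rep in 1:25) {
    tr <- matrix(runif(4, 0.1, 1), 2)
    m2 <- hmm_model(runif(2, 0.1, 1), tr,
                    means = rbind(runif(2, -90, -70), runif(2, -65, -45)),
                    sds = matrix(runif(4, 2, 8), 2))
    X2 <- cbind(runif(6, -90, -45), runif(6, -90, -45))
    expect_equal(viterbi_decode(m2, X2), unname(oracle_viterbi_enum(m2, X2)))
  }
})

test_that("supervised HMM fitting and reconstruction denoise a flipped
           sequence", {
  set.seed(12)
  # long alternating-blocks truth with well-separated emissions
  truth_path <- rep(rep(c(0, 1), 10), times = rep(c(12, 8), 10))
  n <- length(truth_path)
  slots <- 5 * (seq_len(n) - 1)
  r <- ifelse(truth_path == 1, -62, -84) + rnorm(n, 0, 3)
  pairs <- tibble::tibble(slot = slots, i = "0001", j = "0002",
                          rssi_ij = as.integer(round(r)),
                          rssi_ji = as.integer(round(r + rnorm(n, 0, 1))))
  clf <- train_state_classifier(pairs, truth_path)
  states <- classify_states(pairs, clf)
  feats <- build_hmm_features(pairs, states)
  model <- fit_hmm(cbind(feats$rssi_env, feats$prob), truth_path,
                   seq_id = rep(1, n))
  rec <- hmm_reconstruct(pairs, states, model)
  acc_hmm <- mean(rec$state[order(rec$slot)] == truth_path)
  expect_gt(acc_hmm, 0.85)
  expect_error(hmm_reconstruct(pairs, states, list()), "state error")
})

test_that("the BiLSTM slot reports a capability error without a model", {
  expect_error(bilstm_reconstruct(tibble::tibble()), "unavailable")
  # a supplied artifact with a predict closure is honoured
  fake <- list(predict_states = function(p) states_from_vector(c(1, 0)))
  expect_equal(bilstm_reconstruct(tibble::tibble(), fake)$state, c(1L, 0L))
})

test_that("accuracy evaluation matches independent counting", {
  a <- states_from_vector(c(1, 0, 1, 1))
  expect_equal(evaluate_accuracy(a, a)$pooled, 1)
  b <- a; b$state <- 1L - b$state
  expect_equal(evaluate_accuracy(b, a)$pooled, 0)
  # counting oracle on random grids with missing predictions
  set.seed(14)
  truth <- states_from_vector(sample(0:1, 30, TRUE))
  pred <- states_from_vector(sample(0:1, 30, TRUE))[sample(30, 20), ]
  res <- evaluate_accuracy(pred, truth)
  full <- merge(as.data.frame(truth), as.data.frame(pred),
                by = c("slot", "i", "j"), all.x = TRUE)
  full$state.y[is.na(full$state.y)] <- 0
  expect_equal(res$pooled, mean(full$state.x == full$state.y))
  expect_error(evaluate_accuracy(pred, truth[0, ]), "empty")
})
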