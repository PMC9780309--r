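#' Hidden Markov smoothing of binary interaction sequences
#'
#' A two-hidden-state (non-interaction / interaction) HMM with diagonal
#' Gaussian emissions over a short-term trailing envelope of the handshake
#' sequence: for each handshake slot the features are the mean handshake
#' RSSI over the last (up to) \code{envelope_slots} observed slots and the
#' logistic classifier's interaction probability at the current slot. The
#' model is fitted supervised on labeled ground-truth sequences and applied
#' by most-likely-path (Viterbi) decoding; decoding ties resolve to
#' non-interaction.
#'
#' @param init length-2 initial state probabilities (state 0, state 1).
#' @param trans 2x2 transition matrix (rows sum to 1).
#' @param means,sds 2 x n_feature Gaussian emission parameters (row = state).
#' @return an object of class \code{hmm_model}.
#' @export
hmm_model <- function(init, trans, means, sds) {
  means <- rbind(means)
  sds <- rbind(sds)
  stopifnot(length(init) == 2, all(dim(trans) == c(2, 2)),
            nrow(means) == 2, all(dim(sds) == dim(means)),
            all(init >= 0), all(trans >= 0), all(sds > 0))
  structure(list(init = init / sum(init),
                 trans = trans / rowSums(trans),
                 means = means, sds = sds),
            class = "hmm_model")
}

#' @rdname hmm_model
#' @param features numeric matrix of per-slot emission features.
#' @param labels binary state labels aligned to feature rows.
#' @param seq_id sequence (dyad) identifier per row; transitions are counted
#'   only within a sequence.
#' @param sd_floor lower bound on emission standard deviations (guards
#'   against degenerate single-valued features).
#' @export
fit_hmm <- function(features, labels, seq_id = rep(1, length(labels)),
                    sd_floor = 0.05) {
  features <- as.matrix(features)
  y <- as.integer(labels)
  stopifnot(nrow(features) == length(y), all(y %in% 0:1))
  if (length(unique(y)) < 2) stop("degenerate fit: single-class labels")
  trans <- matrix(1, 2, 2)  # add-one smoothing
  for (s in split(seq_along(y), seq_id)) {
    ys <- y[s]
    if (length(ys) > 1) {
      for (k in seq_len(length(ys) - 1)) {
        trans[ys[k] + 1, ys[k + 1] + 1] <- trans[ys[k] + 1, ys[k + 1] + 1] + 1
      }
    }
  }
  init <- c(mean(y == 0), mean(y == 1))
  means <- rbind(colMeans(features[y == 0, , drop = FALSE]),
                 colMeans(features[y == 1, , drop = FALSE]))
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  sds <- rbind(apply(features[y == 0, , drop = FALSE], 2, pop_sd),
               apply(features[y == 1, , drop = FALSE], 2, pop_sd))
  sds <- pmax(sds, sd_floor)
  hmm_model(init, trans, means, sds)
}

#' Most-likely hidden path (Viterbi) of a fitted HMM
#'
#' @param model an \code{\link{hmm_model}}.
#' @param features per-slot feature matrix of one sequence.
#' @return integer vector of decoded states in \{0, 1\}; ties resolve to 0.
#' @export
viterbi_decode <- function(model, features) {
  stopifnot(inherits(model, "hmm_model"))
  X <- as.matrix(features)
  n <- nrow(X)
  if (n == 0) return(integer(0))
  emis <- function(t) {
    vapply(1:2, function(s) {
      sum(stats::dnorm(X[t, ], model$means[s, ], model$sds[s, ], log = TRUE))
    }, 0)
  }
  lt <- log(model$trans)
  v <- log(model$init) + emis(1)
  back <- matrix(NA_integer_, n, 2)
  if (n > 1) {
    for (t in 2:n) {
      e <- emis(t)
      vn <- numeric(2)
      for (s in 1:2) {
        cand <- v + lt[, s]
        # tie-break toward state 0 (index 1): which.max takes the first
        back[t, s] <- which.max(cand)
        vn[s] <- cand[back[t, s]] + e[s]
      }
      v <- vn
    }
  }
  path <- integer(n)
  path[n] <- which.max(v)
  if (n > 1) {
    for (t in n:2) path[t - 1] <- back[t, path[t]]
  }
  path - 1L
}

#' Trailing-envelope features for HMM reconstruction
#'
#' @param pairs handshake tibble for one or more dyads.
#' @param states classified states (must carry \code{prob}) aligned by
#'   \code{(i, j, slot)}.
#' @param envelope_slots number of trailing observed slots (including the
#'   current one) summarized into the mean-RSSI feature.
#' @return tibble \code{i}, \code{j}, \code{slot}, \code{rssi_env},
#'   \code{prob}, ordered by dyad then slot.
#' @export
build_hmm_features <- function(pairs, states, envelope_slots = 3) {
  m <- dplyr::inner_join(
    pairs, states[, c("i", "j", "slot", "prob")],
    by = c("i", "j", "slot"))
  m$rssi_pair <- rowMeans(cbind(
    ifelse(is.na(m$rssi_ij), RSSI_CLEAN_MIN, m$rssi_ij),
    ifelse(is.na(m$rssi_ji), RSSI_CLEAN_MIN, m$rssi_ji)))
  out <- list()
  for (grp in split(seq_len(nrow(m)), paste(m$i, m$j))) {
    d <- m[grp, , drop = FALSE]
    d <- d[order(d$slot), , drop = FALSE]
    env <- vapply(seq_len(nrow(d)), function(k) {
      mean(d$rssi_pair[max(1, k - envelope_slots + 1):k])
    }, 0)
    out[[length(out) + 1]] <- tibble::tibble(
      i = d$i, j = d$j, slot = d$slot, rssi_env = env, prob = d$prob)
  }
  dplyr::bind_rows(out)
}

#' HMM reconstruction of binary state sequences
#'
#' @param pairs handshake tibble.
#' @param states classifier output for the same pairs (see
#'   \code{\link{classify_states}}).
#' @param model a fitted \code{\link{hmm_model}}.
#' @param envelope_slots trailing envelope width.
#' @return states tibble \code{slot}, \code{i}, \code{j}, \code{state}.
#' @export
hmm_reconstruct <- function(pairs, states, model, envelope_slots = 3) {
  if (!inherits(model, "hmm_model")) {
    stop("state error: model is not a fitted hmm_model")
  }
  feats <- build_hmm_features(pairs, states, envelope_slots)
  out <- list()
  for (grp in split(seq_len(nrow(feats)), paste(feats$i, feats$j))) {
    d <- feats[grp, , drop = FALSE]
    dec <- viterbi_decode(model, cbind(d$rssi_env, d$prob))
    out[[length(out) + 1]] <- tibble::tibble(
      slot = d$slot, i = d$i, j = d$j, state = dec)
  }
  if (!length(out)) {
    return(tibble::tibble(slot = numeric(), i = character(),
                          j = character(), state = integer()))
  }
  dplyr::bind_rows(out)
}

#' BiLSTM reconstruction (optional plug-in, not bundled)
#'
#' A bidirectional recurrent sequence labeler that uses both preceding and
#' succeeding handshake pairs is supported behind this stable interface, but
#' no trained network ships with the package and no deep-learning backend is
#' declared as a dependency. Calling it without a model artifact raises a
#' capability error; use the \code{"naive"} or \code{"hmm"} reconstruction
#' paths instead.
#'
#' @param pairs handshake tibble.
#' @param model a model artifact providing a \code{predict_states(pairs)}
#'   closure, or \code{NULL}.
#' @return states tibble when a model is supplied.
#' @export
bilstm_reconstruct <- function(pairs, model = NULL) {
  if (is.null(model) || !is.function(model$predict_states)) {
    stop("bilstm reconstruction unavailable: no trained model artifact ",
         "supplied and no recurrent-network backend is bundled; use ",
         "method = \"naive\" or \"hmm\".", call. = FALSE)
  }
  model$predict_states(pairs)
}

#' Reconstruct the temporal network of one half-day
#'
#' Convenience wrapper: handshakes, logistic classification, the selected
#' reconstruction, and event merging.
#'
#' @param signals pre-processed signal table.
#' @param roster badge roster.
#' @param classifier a \code{\link{train_state_classifier}} fit.
#' @param method \code{"unrec"}, \code{"naive"}, \code{"hmm"} or
#'   \code{"blstm_RSSI"}.
#' @param gap_slots naive gap threshold (slots).
#' @param hmm a fitted \code{\link{hmm_model}} (required for
#'   \code{method = "hmm"}).
#' @param bilstm optional model artifact for \code{"blstm_RSSI"}.
#' @return list \code{pairs}, \code{states} (classified), \code{recon}
#'   (reconstructed states), \code{events}.
#' @export
reconstruct_half_day <- function(signals, roster, classifier,
                                 method = c("naive", "unrec", "hmm",
                                            "blstm_RSSI"),
                                 gap_slots = 6, hmm = NULL, bilstm = NULL) {
  method <- match.arg(method)
  pairs <- handshakes_all(signals, roster)
  states <- classify_states(pairs, classifier)
  recon <- switch(method,
    unrec = states,
    naive = naive_reconstruct(states, gap_slots),
    hmm = hmm_reconstruct(pairs, states, hmm),
    blstm_RSSI = bilstm_reconstruct(pairs, bilstm))
  list(pairs = pairs, states = states, recon = recon,
       events = merge_events(recon))
}
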