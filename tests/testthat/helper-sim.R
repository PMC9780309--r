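# Small deployment configurations used across the suite. The full-size
# defaults mirror the real school; tests run scaled-down classes to keep the
# suite fast while exercising identical code paths.

tiny_sim_config <- function(n_classes = 2, class_size = 6, n_adults = 2,
                            seed = 1L, artifacts_on = TRUE, ...) {
  art <- if (artifacts_on) {
    list(unworn_rate = 0.15, unworn_dur = c(600, 1200),
         pile_prob = 0.6, pile_size = c(2, 3), pile_dur = c(300, 600),
         burst_frac = 0.4, burst_s = 120, silent_rate = 0.05,
         deaf_rate = 0.05)
  } else {
    list(unworn_rate = 0, unworn_dur = c(600, 1200), pile_prob = 0,
         pile_size = c(2, 3), pile_dur = c(300, 600), burst_frac = 0,
         burst_s = 0, silent_rate = 0, deaf_rate = 0)
  }
  sim_config(n_classes = n_classes, class_sizes = class_size,
             n_adults = n_adults, artifacts = art, seed = seed, ...)
}

# regimes far apart so the logistic boundary separates them perfectly
separated_sim_config <- function(n_classes = 2, class_size = 5,
                                 n_adults = 0, seed = 1L) {
  tiny_sim_config(
    n_classes = n_classes, class_size = class_size, n_adults = n_adults,
    seed = seed, artifacts_on = FALSE,
    packet_loss_prob = 0, background_prob = 0.1,
    rssi = list(interaction = c(-60, 2), background = c(-88, 2),
                gathered = c(-50, 5), pile = c(-50, 1.0),
                hub = c(-58, 1.2), rx_room = c(-80, 6)))
}

# dense state tibble for one dyad from a 0/1 vector anchored at slot0
states_from_vector <- function(v, slot0 = 0, i = "0001", j = "0002") {
  tibble::tibble(slot = slot0 + 5 * (seq_along(v) - 1), i = i, j = j,
                 state = as.integer(v))
}

make_records <- function(observed, t, rssi) {
  tibble::tibble(observed_did = observed, timestamp = t,
                 rssi = as.integer(rssi))
}
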