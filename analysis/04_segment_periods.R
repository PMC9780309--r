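#!/usr/bin/env Rscript
# Segment the half-day into free- and class-time per class from the smoothed
# inter/intra interaction ratio, grid-search the two hyperparameters against
# the true schedule, apply the edge-alignment correction, and annotate every
# reconstructed event with its SSSSX label.

suppressMessages(library(proxinet))
suppressMessages(library(dplyr))

wk <- "results/deployment/1_WEEK01"
roster <- tibble::as_tibble(read.csv(file.path(wk, "truth", "roster.csv"),
                                     colClasses = c(did = "character")))
schedule <- tibble::as_tibble(read.csv(file.path(wk, "truth",
                                                 "schedule.csv")))
events <- tibble::as_tibble(read.csv(
  "results/events_naive.csv", colClasses = c(i = "character",
                                             j = "character")))
true_states <- tibble::as_tibble(read.csv(
  file.path(wk, "truth", "states.csv"),
  colClasses = c(i = "character", j = "character")))
files <- list.files(file.path(wk, "HD_individual_preprocessed"),
                    recursive = TRUE, full.names = TRUE)
seqs <- lapply(files, read_half_day)
signals <- signal_table(setNames(seqs, vapply(seqs, `[[`, "", "owner")))

win <- session_window(1, "M")
pairs <- handshakes_all(signals, roster)
labels <- as.integer(paste(pairs$i, pairs$j, pairs$slot) %in%
                       paste(true_states$i, true_states$j, true_states$slot))
states <- classify_states(pairs, train_state_classifier(pairs, labels))
curves <- count_inter_intra(states, roster, bin_s = 10, span = win)

gs <- grid_search_segmentation(curves, schedule,
                               ratio_grid = c(0.05, 0.1, 0.15, 0.25, 0.5),
                               gap_grid = c(200, 400, 600, 1000),
                               span = win)
write.csv(gs$surface, "results/segmentation_grid.csv", row.names = FALSE)
cat(sprintf("grid optimum: ratio %.2f, gap %d s (error %.0f s)\n",
            gs$best$ratio_threshold, gs$best$gap_threshold_s,
            gs$best$error_s))

params <- segmentation_params()   # the deployed 0.15 / 600 s regime
segs <- align_edges(segment_all_classes(curves, params, span = win))
write.csv(segs, "results/segments.csv", row.names = FALSE)
err <- segmentation_error(segs, schedule)
cat(sprintf("error at the deployed parameters: %.0f s (%.2f%% of %d class-seconds)\n",
            err, 100 * err / (3 * diff(win)), 3 * diff(win)))

tnet <- annotate_events(events, segs, roster)
write_tnet(tnet, "results/tnet", day = 1, session = "M", method = "naive")
cat(sprintf("annotated %d events -> results/tnet/1-M-naive.csv\n",
            nrow(tnet)))
print(count(tnet, labels, flag, sort = TRUE), n = 6)
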