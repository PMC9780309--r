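#!/usr/bin/env Rscript
# Read the cleaned half-day files back through the file dialect and run the
# four-issue pre-processing chain (silent/deaf repair, RX-based unworn
# detection, pile detection, edge-burst trimming), then score the removals
# against the injected artifact truth.

suppressMessages(library(proxinet))
suppressMessages(library(dplyr))

wk <- "results/deployment/1_WEEK01"
roster <- tibble::as_tibble(read.csv(file.path(wk, "truth", "roster.csv"),
                                     colClasses = c(did = "character")))
files <- list.files(file.path(wk, "HD_individual_cleaned"),
                    recursive = TRUE, full.names = TRUE)
seqs <- lapply(files, read_half_day)
names(seqs) <- vapply(seqs, function(h) h$owner, "")
signals <- signal_table(seqs)

pp <- preprocess_half_day(signals, roster, day = 1, session = "M")

for (hd in sequences_from_table(pp$signals, roster, 1, "M")) {
  write_half_day(hd, file.path(wk, "HD_individual_preprocessed"))
}
write.csv(pp$report, "results/preprocess_report.csv", row.names = FALSE)

cat(sprintf("records: %d cleaned -> %d pre-processed\n",
            nrow(signals), nrow(pp$signals)))
cat("removed intervals by cause:\n")
print(count(pp$report, cause))
cat(sprintf("repaired badges: %d silent, %d deaf\n",
            length(pp$repairs$silent), length(pp$repairs$deaf)))

# recall of injected artifact time
truth_iv <- read.csv(file.path(wk, "truth", "artifacts.csv"),
                     colClasses = c(did = "character"))
inj <- truth_iv[truth_iv$cause %in% c("unworn_hub", "pile", "burst"), ]
ov <- function(a0, a1, b0, b1) pmax(0, pmin(a1, b1) - pmax(a0, b0))
cov <- sum(vapply(seq_len(nrow(inj)), function(k) {
  r <- pp$report[pp$report$did == inj$did[k], ]
  if (!nrow(r)) return(0)
  sum(ov(r$t_start, r$t_end, inj$t_start[k], inj$t_end[k]))
}, 0))
cat(sprintf("injected unworn/pile/burst time removed: %.1f%%\n",
            100 * cov / sum(inj$t_end - inj$t_start)))
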