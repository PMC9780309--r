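#' Pipeline configuration
#'
#' One declarative object wiring all stage parameters with their deployed
#' defaults, a seed, and the reconstruction method; fully serialized into
#' the run manifest so a run can be reproduced bit-exactly.
#'
#' @param sim a \code{\link{sim_config}}.
#' @param day,session half-day to process.
#' @param method reconstruction method (\code{"naive"}, \code{"unrec"},
#'   \code{"hmm"}).
#' @param gap_slots naive gap threshold.
#' @param preprocess a \code{\link{preprocess_params}} list.
#' @param segmentation a \code{\link{segmentation_params}} list.
#' @param seed run seed (overrides \code{sim$seed}).
#' @param out_dir output directory (\code{NULL}: keep results in memory
#'   only).
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(sim = sim_config(), day = 1, session = "M",
                            method = "naive", gap_slots = 6,
                            preprocess = preprocess_params(),
                            segmentation = segmentation_params(),
                            seed = sim$seed, out_dir = NULL) {
  structure(list(sim = sim, day = day, session = session, method = method,
                 gap_slots = gap_slots, preprocess = preprocess,
                 segmentation = segmentation, seed = seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

PIPELINE_STAGES <- c("simulate", "preprocess", "reconstruct", "segment",
                     "annotate", "summarize")

#' Run the processing pipeline
#'
#' Executes the selected stages in the fixed order simulate, preprocess,
#' reconstruct, segment, annotate, summarize. The interaction classifier is
#' trained on the simulated ground truth (handshake pairs labeled by the
#' true per-slot states), mirroring how the field classifier is trained on
#' in-situ observation sessions. A stage subset can be run by passing the
#' \code{state} returned by a previous call; a missing upstream product
#' raises a dependency error naming the stage.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param stages subset of stages to run (in pipeline order).
#' @param state previous \code{run_pipeline} result to resume from.
#' @return list with stage products (\code{sim}, \code{cleaned},
#'   \code{preprocessed}, \code{report}, \code{recon}, \code{segments},
#'   \code{tnet}, \code{summary}) and a \code{manifest}.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES, state = NULL) {
  stopifnot(inherits(config, "pipeline_config"),
            all(stages %in% PIPELINE_STAGES))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  st <- if (is.null(state)) list() else state
  need <- function(what, stage) {
    if (is.null(st[[what]])) {
      stop("dependency error: stage '", stage, "' needs '", what,
           "' from an earlier stage")
    }
    st[[what]]
  }
  win <- unname(session_window(config$day, config$session))
  counts <- list()

  if ("simulate" %in% stages) {
    st$sim <- simulate_half_day(config$sim, config$day, config$session,
                                seed = config$seed)
    st$cleaned <- initial_clean_signals(st$sim$signals, win)
    counts$simulate <- nrow(st$cleaned)
  }
  if ("preprocess" %in% stages) {
    cleaned <- need("cleaned", "preprocess")
    sim <- need("sim", "preprocess")
    pp <- preprocess_half_day(cleaned, sim$roster, config$day,
                              config$session, config$preprocess)
    st$preprocessed <- pp$signals
    st$report <- pp$report
    st$repairs <- pp$repairs
    counts$preprocess <- nrow(pp$signals)
  }
  if ("reconstruct" %in% stages) {
    sig <- need("preprocessed", "reconstruct")
    sim <- need("sim", "reconstruct")
    pairs <- handshakes_all(sig, sim$roster)
    labels <- truth_labels_for(pairs, sim$truth$states)
    clf <- train_state_classifier(pairs, labels)
    st$recon <- reconstruct_half_day(sig, sim$roster, clf,
                                     method = config$method,
                                     gap_slots = config$gap_slots,
                                     hmm = st$hmm)
    st$classifier <- clf
    counts$reconstruct <- nrow(st$recon$events)
  }
  if ("segment" %in% stages) {
    recon <- need("recon", "segment")
    sim <- need("sim", "segment")
    curves <- count_inter_intra(recon$states, sim$roster,
                                config$segmentation$bin_s, win)
    segs <- segment_all_classes(curves, config$segmentation, win)
    st$segments <- align_edges(segs)
    st$curves <- curves
    counts$segment <- nrow(st$segments)
  }
  if ("annotate" %in% stages) {
    recon <- need("recon", "annotate")
    segs <- need("segments", "annotate")
    sim <- need("sim", "annotate")
    st$tnet <- annotate_events(recon$events, segs, sim$roster)
    counts$annotate <- nrow(st$tnet)
  }
  if ("summarize" %in% stages) {
    tnet <- need("tnet", "summarize")
    st$summary <- if (nrow(tnet)) annotation_summary(tnet) else NULL
    st$network <- aggregate_network(tnet)
    counts$summarize <- nrow(st$network$edges)
  }

  st$manifest <- build_manifest(config, stages, counts, st)
  if (!is.null(config$out_dir)) write_pipeline_outputs(st, config)
  st
}

# classifier training labels from the simulator's true per-slot states
truth_labels_for <- function(pairs, true_states) {
  key <- paste(pairs$i, pairs$j, pairs$slot)
  as.integer(key %in% paste(true_states$i, true_states$j, true_states$slot))
}

build_manifest <- function(config, stages, counts, st) {
  cfg_json <- jsonlite::toJSON(serialize_config(config), auto_unbox = TRUE,
                               digits = NA)
  tf <- tempfile(fileext = ".json")
  writeLines(cfg_json, tf)
  digest <- unname(tools::md5sum(tf))
  unlink(tf)
  list(config_digest = digest, seed = config$seed,
       package_version = as.character(utils::packageVersion("proxinet")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       stages = stages, record_counts = counts,
       event_count = if (!is.null(st$recon)) nrow(st$recon$events) else NULL)
}

serialize_config <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip)
    else if (is.function(x)) deparse(x)
    else x
  }
  strip(config)
}

write_pipeline_outputs <- function(st, config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(st$sim)) {
    seqs <- sequences_from_table(st$cleaned, st$sim$roster, config$day,
                                 config$session)
    for (hd in seqs) write_half_day(hd, file.path(out,
                                                  "HD_individual_cleaned"))
  }
  if (!is.null(st$preprocessed) && !is.null(st$sim)) {
    seqs <- sequences_from_table(st$preprocessed, st$sim$roster, config$day,
                                 config$session)
    for (hd in seqs) {
      write_half_day(hd, file.path(out, "HD_individual_preprocessed"))
    }
  }
  if (!is.null(st$tnet)) {
    write_tnet(st$tnet, file.path(out, "tnet"), config$day, config$session,
               if (config$method == "unrec") "unrec" else config$method)
  }
  if (!is.null(st$segments)) {
    utils::write.csv(st$segments, file.path(out, "segments.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(st$summary)) {
    utils::write.csv(st$summary, file.path(out, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  writeLines(jsonlite::toJSON(st$manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out, "manifest.json"))
  invisible(out)
}
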