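#' Segmentation parameters
#'
#' Defaults are the deployed optimum: interaction counts on a 10-s grid
#' smoothed with a Gaussian kernel of sigma = 3 bins, a free-time ratio
#' threshold of 0.15 and a bridging gap threshold of 600 s.
#'
#' @param ratio_threshold inter/intra ratio at or above which a bin is a
#'   free-time candidate.
#' @param gap_threshold_s bridge opposite-label runs strictly shorter than
#'   this (s).
#' @param sigma_bins Gaussian smoothing sigma, in bins.
#' @param bin_s bin width (s).
#' @return named list.
#' @export
segmentation_params <- function(ratio_threshold = 0.15,
                                gap_threshold_s = 600,
                                sigma_bins = 3, bin_s = 10) {
  stopifnot(ratio_threshold > 0, gap_threshold_s > 0, sigma_bins > 0,
            bin_s > 0)
  list(ratio_threshold = ratio_threshold, gap_threshold_s = gap_threshold_s,
       sigma_bins = sigma_bins, bin_s = bin_s)
}

#' Inter-/intra-class interaction counts per class
#'
#' For every 10-s bin and class, counts the active interaction states that
#' children of the class had with peers of other classes (inter) and with
#' classmates (intra). Adults are excluded: the ratio tracks children's
#' mixing. Each active dyad-slot contributes one count to its bin.
#'
#' @param states classified binary states (\code{slot}, \code{i}, \code{j},
#'   \code{state}).
#' @param class_map roster tibble (\code{did}, \code{kind},
#'   \code{class_id}) covering every participant appearing in \code{states}.
#' @param bin_s bin width (s).
#' @param span half-day span \code{c(start, end)} defining the bin grid.
#' @return tibble \code{class_id}, \code{bin} (bin start time), \code{inter},
#'   \code{intra}, dense over the grid.
#' @export
count_inter_intra <- function(states, class_map, bin_s = 10, span) {
  act <- states[states$state == 1, , drop = FALSE]
  missing <- setdiff(unique(c(act$i, act$j)), class_map$did)
  if (length(missing)) {
    stop("participant missing from class map: ", missing[1])
  }
  cls <- stats::setNames(class_map$class_id, class_map$did)
  kind <- stats::setNames(class_map$kind, class_map$did)
  child <- kind[act$i] == "child" & kind[act$j] == "child"
  act <- act[child, , drop = FALSE]
  bins <- seq(bin_s * floor(span[1] / bin_s), span[2] - 1e-9, by = bin_s)
  classes <- sort(unique(class_map$class_id[class_map$kind == "child"]))
  grid <- tidyr::expand_grid(class_id = classes, bin = bins)
  grid$inter <- 0
  grid$intra <- 0
  if (nrow(act)) {
    act$bin <- bin_s * floor(act$slot / bin_s)
    act$ci <- cls[act$i]
    act$cj <- cls[act$j]
    for (cl in classes) {
      in_i <- act$ci == cl
      in_j <- act$cj == cl
      intra <- act$bin[in_i & in_j]
      inter <- act$bin[xor(in_i, in_j)]
      key <- grid$class_id == cl
      grid$intra[key] <- tabulate_on(intra, bins)
      grid$inter[key] <- tabulate_on(inter, bins)
    }
  }
  grid
}

tabulate_on <- function(x, bins) {
  if (!length(x)) return(numeric(length(bins)))
  as.numeric(table(factor(x, levels = bins)))
}

#' Gaussian smoothing of a count series
#'
#' Discrete Gaussian convolution with a kernel normalized to sum 1 and
#' reflected boundaries; a constant series is unchanged and interior mass is
#' conserved.
#'
#' @param x numeric series on a regular grid.
#' @param sigma_bins kernel sigma in grid units.
#' @return smoothed series of the same length.
#' @export
smooth_counts <- function(x, sigma_bins = 3) {
  n <- length(x)
  if (n == 0) return(x)
  r <- ceiling(4 * sigma_bins)
  k <- stats::dnorm(-r:r, sd = sigma_bins)
  k <- k / sum(k)
  # reflection padding at both boundaries
  idx <- c(rev(seq_len(min(r, n))), seq_len(n),
           rev(n + 1 - seq_len(min(r, n))))
  xp <- x[idx]
  while (length(xp) < n + 2 * r) xp <- c(xp[1], xp, xp[length(xp)])
  pad <- (length(xp) - n) / 2
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[pad + seq_len(n)])
}

#' Inter/intra ratio series for one class
#'
#' Smoothed inter counts divided by smoothed intra counts per bin; bins with
#' zero (smoothed) intra count get the default value
#' \code{2 * ratio_threshold} so that isolated-activity bins read as
#' free-time candidates.
#'
#' @param curve one class's rows from \code{\link{count_inter_intra}}.
#' @param params \code{\link{segmentation_params}}.
#' @return the curve with columns \code{inter_s}, \code{intra_s},
#'   \code{ratio} added.
#' @export
compute_ratio <- function(curve, params = segmentation_params()) {
  curve$inter_s <- smooth_counts(curve$inter, params$sigma_bins)
  curve$intra_s <- smooth_counts(curve$intra, params$sigma_bins)
  curve$ratio <- ifelse(curve$intra_s == 0, 2 * params$ratio_threshold,
                        curve$inter_s / curve$intra_s)
  curve
}

# Bridge sub-gap runs: first absorb class-time runs strictly shorter than
# gap_bins sandwiched between free-time runs, then the converse. Outer
# (boundary-touching) runs are never absorbed.
bridge_labels <- function(labels, gap_bins) {
  for (target in c("C", "F")) {
    r <- rle(labels)
    n <- length(r$lengths)
    if (n >= 3) {
      opp <- if (target == "C") "F" else "C"
      flip <- which(r$values == target & r$lengths < gap_bins)
      flip <- flip[flip > 1 & flip < n]
      if (length(flip)) {
        r$values[flip] <- opp
        labels <- inverse.rle(r)
      }
    }
  }
  labels
}

#' Segment one class's half-day into free- and class-time periods
#'
#' Bins with ratio at or above the threshold are free-time candidates; runs
#' of the opposite label strictly shorter than the gap threshold sandwiched
#' between two same-label runs are absorbed (free-time interruptions are
#' bridged first, then class-time interruptions), and the resulting runs
#' tile the half-day.
#'
#' @param curve ratio curve from \code{\link{compute_ratio}} (one class).
#' @param params \code{\link{segmentation_params}}.
#' @param span half-day span \code{c(start, end)}.
#' @return segments tibble \code{class_id}, \code{t_start}, \code{t_end},
#'   \code{label}.
#' @export
segment_periods <- function(curve, params = segmentation_params(),
                            span = NULL) {
  stopifnot(nrow(curve) > 0)
  curve <- curve[order(curve$bin), , drop = FALSE]
  if (is.null(span)) {
    span <- c(curve$bin[1], curve$bin[nrow(curve)] + params$bin_s)
  }
  labels <- ifelse(curve$ratio >= params$ratio_threshold, "F", "C")
  gap_bins <- params$gap_threshold_s / params$bin_s
  labels <- bridge_labels(labels, gap_bins)
  r <- rle(labels)
  ends <- c(curve$bin[cumsum(r$lengths)][-length(r$lengths)] + params$bin_s,
            span[2])
  starts <- c(span[1], utils::head(ends, -1))
  tibble::tibble(class_id = curve$class_id[1], t_start = starts,
                 t_end = ends, label = r$values)
}

#' Align free-time edges across classes
#'
#' Classes join and leave the yard one after another, so the first class out
#' briefly shows cross-class mixing while alone. For each yard session
#' (connected component of overlapping free-time segments across classes)
#' the earliest start is clipped to the second-earliest and the latest end
#' to the second-latest, and free-time detected for a single class with no
#' companion is relabeled class-time, so that every retained free-time
#' instant has at least two classes out.
#'
#' @param segments per-class segments of one half-day (all classes bound
#'   together).
#' @return segments with the correction applied, re-tiled per class.
#' @export
align_edges <- function(segments) {
  f <- segments[segments$label == "F", , drop = FALSE]
  if (!nrow(f)) return(segments)
  f <- f[order(f$t_start), , drop = FALSE]
  comp <- overlap_components(f)
  keep <- list()
  for (grp in split(seq_len(nrow(f)), comp)) {
    g <- f[grp, , drop = FALSE]
    if (length(unique(g$class_id)) < 2) next  # lone class: relabel C (drop F)
    ss <- sort(g$t_start)
    ee <- sort(g$t_end, decreasing = TRUE)
    g$t_start[which.min(g$t_start)] <- ss[2]
    g$t_end[which.max(g$t_end)] <- ee[2]
    g <- g[g$t_end > g$t_start, , drop = FALSE]
    keep[[length(keep) + 1]] <- g
  }
  f_new <- if (length(keep)) dplyr::bind_rows(keep) else f[0, ]
  out <- list()
  for (cl in unique(segments$class_id)) {
    span <- c(min(segments$t_start[segments$class_id == cl]),
              max(segments$t_end[segments$class_id == cl]))
    fc <- f_new[f_new$class_id == cl, c("class_id", "t_start", "t_end",
                                        "label"), drop = FALSE]
    fc <- fc[order(fc$t_start), , drop = FALSE]
    out[[length(out) + 1]] <- fill_class_time(fc, span, cl)
  }
  dplyr::bind_rows(out)
}

# connected components of intervals under temporal overlap
overlap_components <- function(iv) {
  n <- nrow(iv)
  comp <- seq_len(n)
  find <- function(k) { while (comp[k] != k) k <- comp[k]; k }
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b > a && iv$t_start[b] < iv$t_end[a] &&
          iv$t_start[a] < iv$t_end[b]) {
        comp[find(b)] <- find(a)
      }
    }
  }
  vapply(seq_len(n), find, 1L)
}

#' Segmentation error in seconds
#'
#' The free-time identification error between a predicted and a true
#' segmentation: the total time labeled free in exactly one of the two
#' (symmetric difference). For an overlapping predicted/true period pair
#' this equals \eqn{\tau_{pred} + \tau_{true} - 2 \tau_{overlap}}, and a
#' period with no counterpart contributes its full duration. Zero iff the
#' free-time sets are identical; symmetric in its arguments.
#'
#' @param pred_segments,true_segments segment tibbles covering the same
#'   half-day (any number of classes; error is summed over classes when a
#'   \code{class_id} column is present).
#' @return error in seconds.
#' @export
segmentation_error <- function(pred_segments, true_segments) {
  classes <- union(unique(pred_segments$class_id),
                   unique(true_segments$class_id))
  total <- 0
  for (cl in classes) {
    p <- pred_segments[pred_segments$class_id == cl &
                         pred_segments$label == "F", , drop = FALSE]
    t <- true_segments[true_segments$class_id == cl &
                         true_segments$label == "F", , drop = FALSE]
    total <- total + interval_symmdiff(p, t)
  }
  total
}

interval_symmdiff <- function(a, b) {
  len <- function(iv) sum(iv$t_end - iv$t_start)
  if (!nrow(a)) return(len(b))
  if (!nrow(b)) return(len(a))
  a <- union_intervals(a[, c("t_start", "t_end")])
  b <- union_intervals(b[, c("t_start", "t_end")])
  inter <- interval_intersection(a, b)
  len(a) + len(b) - 2 * len(inter)
}

#' Grid search of the segmentation hyperparameters
#'
#' Exhaustively evaluates every (ratio threshold, gap threshold) cell:
#' smooths the curves, computes ratios, segments every class, applies the
#' edge alignment and scores the total error against the reference schedule.
#' Ties resolve deterministically to the smaller gap, then smaller ratio.
#'
#' @param curves \code{\link{count_inter_intra}} output (all classes).
#' @param truth reference schedule segments (e.g. the simulator's).
#' @param ratio_grid,gap_grid candidate values (both non-empty).
#' @param sigma_bins,bin_s smoothing and binning settings.
#' @param span half-day span.
#' @param align apply \code{\link{align_edges}} before scoring.
#' @return list \code{best} (\code{ratio_threshold}, \code{gap_threshold_s},
#'   \code{error_s}) and \code{surface} (tibble \code{ratio_threshold},
#'   \code{gap_threshold_s}, \code{error_s}).
#' @export
grid_search_segmentation <- function(curves, truth, ratio_grid, gap_grid,
                                     sigma_bins = 3, bin_s = 10,
                                     span = NULL, align = TRUE) {
  if (!length(ratio_grid) || !length(gap_grid)) {
    stop("empty hyperparameter grid")
  }
  rows <- list()
  for (gap in sort(gap_grid)) {
    for (ratio in sort(ratio_grid)) {
      params <- segmentation_params(ratio, gap, sigma_bins, bin_s)
      segs <- segment_all_classes(curves, params, span)
      if (align) segs <- align_edges(segs)
      err <- segmentation_error(segs, truth)
      rows[[length(rows) + 1]] <- tibble::tibble(
        ratio_threshold = ratio, gap_threshold_s = gap, error_s = err)
    }
  }
  surface <- dplyr::bind_rows(rows)
  ord <- order(surface$error_s, surface$gap_threshold_s,
               surface$ratio_threshold)
  list(best = as.list(surface[ord[1], ]), surface = surface)
}

#' @rdname grid_search_segmentation
#' @param params a \code{\link{segmentation_params}} set.
#' @export
segment_all_classes <- function(curves, params = segmentation_params(),
                                span = NULL) {
  out <- list()
  for (cl in sort(unique(curves$class_id))) {
    cv <- compute_ratio(curves[curves$class_id == cl, , drop = FALSE],
                        params)
    out[[length(out) + 1]] <- segment_periods(cv, params, span)
  }
  dplyr::bind_rows(out)
}

#' Annotate contact events with free-/class-time state labels
#'
#' Each event gets four state symbols and a flag, \code{S S' S S' X}: the
#' free/class state of participant i at the event start and end, the same
#' for j, and \code{X = 1} iff i and j share a class. An event end falling
#' exactly on a segment boundary belongs to the later segment (half-open
#' convention); the final session boundary belongs to the last segment.
#'
#' @param events events tibble (\code{t}, \code{i}, \code{j}, \code{delta}).
#' @param segments per-class segments tiling the half-day.
#' @param class_map roster (\code{did}, \code{class_id}).
#' @return tnet record tibble \code{t}, \code{i}, \code{j}, \code{delta},
#'   \code{labels}, \code{flag}.
#' @export
annotate_events <- function(events, segments, class_map) {
  cls <- stats::setNames(class_map$class_id, class_map$did)
  lab_at <- function(class_id, x) {
    s <- segments[segments$class_id == class_id, , drop = FALSE]
    hit <- which(s$t_start <= x & x < s$t_end)
    if (!length(hit)) {
      if (length(s$t_end) && isTRUE(all.equal(max(s$t_end), x))) {
        hit <- which.max(s$t_end)
      } else {
        stop("event instant ", x, " outside the segmented span of class ",
             class_id)
      }
    }
    s$label[hit[1]]
  }
  n <- nrow(events)
  labels <- character(n)
  flag <- integer(n)
  for (k in seq_len(n)) {
    ci <- cls[[events$i[k]]]
    cj <- cls[[events$j[k]]]
    t0 <- events$t[k]
    t1 <- events$t[k] + events$delta[k]
    labels[k] <- paste0(lab_at(ci, t0), lab_at(ci, t1),
                        lab_at(cj, t0), lab_at(cj, t1))
    flag[k] <- as.integer(ci == cj)
  }
  tibble::tibble(t = events$t, i = events$i, j = events$j,
                 delta = events$delta, labels = labels, flag = flag)
}
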