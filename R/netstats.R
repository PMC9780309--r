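#' Round half away from zero
#'
#' Percentage and hour columns of the annotation summary use commercial
#' (half-up) rounding, not banker's rounding.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Free-/class-time annotation summary
#'
#' Per interaction type (the 4-symbol label plus the same-class flag, e.g.
#' \code{CCCC1}): event count, count share in percent (2 decimals, half-up),
#' total duration in seconds, duration share in percent, and duration in
#' hours (nearest integer).
#'
#' @param tnet_records annotated event tibble (\code{delta}, \code{labels},
#'   \code{flag}), or a pre-aggregated table with columns \code{type},
#'   \code{count}, \code{duration_s}.
#' @return tibble \code{type}, \code{count}, \code{count_pct},
#'   \code{duration_s}, \code{duration_pct}, \code{duration_h}, sorted by
#'   decreasing count.
#' @export
annotation_summary <- function(tnet_records) {
  if (all(c("type", "count", "duration_s") %in% names(tnet_records))) {
    agg <- tibble::as_tibble(tnet_records[, c("type", "count", "duration_s")])
  } else {
    stopifnot(all(c("delta", "labels", "flag") %in% names(tnet_records)))
    agg <- tnet_records %>%
      dplyr::mutate(type = paste0(.data$labels, .data$flag)) %>%
      dplyr::group_by(.data$type) %>%
      dplyr::summarise(count = dplyr::n(), duration_s = sum(.data$delta),
                       .groups = "drop")
  }
  agg %>%
    dplyr::mutate(
      count_pct = round_half_up(100 * .data$count / sum(.data$count), 2),
      duration_pct = round_half_up(
        100 * .data$duration_s / sum(.data$duration_s), 2),
      duration_h = round_half_up(.data$duration_s / 3600, 0)) %>%
    dplyr::select("type", "count", "count_pct", "duration_s",
                  "duration_pct", "duration_h") %>%
    dplyr::arrange(dplyr::desc(.data$count))
}

#' Published full-year annotation table of the DyLNet deployment
#'
#' The event counts and total durations per interaction type over the ten
#' shared deployment weeks, as released with the dataset; used to exercise
#' the summary arithmetic without the access-restricted event files.
#'
#' @return tibble \code{type}, \code{count}, \code{duration_s} (19 rows).
#' @export
dylnet_annotation_table <- function() {
  path <- system.file("extdata", "annotation_table_full_year.csv",
                      package = "proxinet", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, colClasses = c(
    "character", "integer", "numeric")))
}

#' Empirical event-duration distribution
#'
#' @param events events tibble with \code{delta}.
#' @param log_base optional log-binning base (> 1); when given, a
#'   \code{binned} element is added with geometric bins.
#' @return list \code{raw} (tibble \code{value}, \code{count}, \code{p}) and
#'   optionally \code{binned} (\code{lo}, \code{hi}, \code{p_density}).
#' @export
duration_distribution <- function(events, log_base = NULL) {
  stopifnot(nrow(events) > 0)
  empirical_distribution(events$delta, log_base)
}

#' Inter-event time distribution on links
#'
#' The gap between the end of one contact event and the start of the next on
#' the same dyad, pooled across dyads. A dyad with a single event
#' contributes no inter-event time.
#'
#' @param events events tibble (\code{t}, \code{i}, \code{j}, \code{delta}).
#' @param log_base optional log-binning base.
#' @return as \code{\link{duration_distribution}}; \code{raw} is empty when
#'   no dyad has two events.
#' @export
iet_distribution <- function(events, log_base = NULL) {
  stopifnot(nrow(events) > 0)
  iets <- events %>%
    dplyr::arrange(.data$i, .data$j, .data$t) %>%
    dplyr::group_by(.data$i, .data$j) %>%
    dplyr::mutate(iet = .data$t - dplyr::lag(.data$t + .data$delta)) %>%
    dplyr::ungroup()
  v <- iets$iet[!is.na(iets$iet)]
  if (any(v < 0)) stop("overlapping events on a dyad")
  if (!length(v)) {
    return(list(raw = tibble::tibble(value = numeric(), count = integer(),
                                     p = numeric())))
  }
  empirical_distribution(v, log_base)
}

empirical_distribution <- function(values, log_base = NULL) {
  tab <- table(values)
  raw <- tibble::tibble(value = as.numeric(names(tab)),
                        count = as.integer(tab))
  raw$p <- raw$count / sum(raw$count)
  out <- list(raw = raw)
  if (!is.null(log_base)) {
    stopifnot(log_base > 1)
    v <- values[values > 0]
    lo0 <- min(v)
    edges <- lo0 * log_base^(0:ceiling(log(max(v) / lo0, log_base) + 1))
    idx <- findInterval(v, edges, rightmost.closed = FALSE)
    cnt <- tabulate(idx, nbins = length(edges) - 1)
    width <- diff(edges)
    out$binned <- tibble::tibble(
      lo = edges[-length(edges)], hi = edges[-1], count = cnt,
      p_density = cnt / sum(cnt) / width)[cnt > 0, ]
  }
  out
}

#' Aggregate the temporal network over a span
#'
#' Edge weight is the total interaction duration per dyad over the events
#' passing the context filter; node strength is the sum of incident weights
#' and degree the number of distinct partners.
#'
#' @param events events tibble; must carry \code{labels} when a context
#'   filter other than \code{"all"} is used.
#' @param context_filter \code{"all"}, \code{"F"} (events fully in free
#'   time, labels \code{FFFF}) or \code{"C"} (fully in class time).
#' @return list \code{edges} (\code{i}, \code{j}, \code{weight}) and
#'   \code{nodes} (\code{did}, \code{degree}, \code{strength}).
#' @export
aggregate_network <- function(events, context_filter = c("all", "F", "C")) {
  context_filter <- match.arg(context_filter)
  ev <- events
  if (context_filter != "all") {
    stopifnot("labels" %in% names(ev))
    want <- strrep(context_filter, 4)
    ev <- ev[ev$labels == want, , drop = FALSE]
  }
  if (!nrow(ev)) {
    return(list(edges = tibble::tibble(i = character(), j = character(),
                                       weight = numeric()),
                nodes = tibble::tibble(did = character(), degree = integer(),
                                      strength = numeric())))
  }
  edges <- ev %>%
    dplyr::group_by(.data$i, .data$j) %>%
    dplyr::summarise(weight = sum(.data$delta), .groups = "drop")
  nodes <- dplyr::bind_rows(
    tibble::tibble(did = edges$i, weight = edges$weight),
    tibble::tibble(did = edges$j, weight = edges$weight)) %>%
    dplyr::group_by(.data$did) %>%
    dplyr::summarise(degree = dplyr::n(), strength = sum(.data$weight),
                     .groups = "drop")
  list(edges = edges, nodes = nodes)
}

#' Node-degree distribution of an aggregated network
#'
#' @param network result of \code{\link{aggregate_network}}.
#' @return tibble \code{degree}, \code{count}, \code{p} (empty for an empty
#'   network), plus \code{mean_degree} as an attribute.
#' @export
degree_distribution <- function(network) {
  deg <- network$nodes$degree
  if (!length(deg)) {
    out <- tibble::tibble(degree = integer(), count = integer(),
                          p = numeric())
    attr(out, "mean_degree") <- NaN
    return(out)
  }
  tab <- table(deg)
  out <- tibble::tibble(degree = as.integer(names(tab)),
                        count = as.integer(tab))
  out$p <- out$count / sum(out$count)
  attr(out, "mean_degree") <- mean(deg)
  out
}
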