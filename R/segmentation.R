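#' Segmentation parameters
#'
#' Tuning knobs for turning an event stream into collective movements.
#'
#' @param participation_fraction fraction of the group that must move for a
#'   departure cluster to count as a collective movement (default 0.5, the
#'   classical 50% rule).
#' @param simultaneity_window_s departures within this many seconds of the
#'   earliest departure are scored as simultaneous first movers (default 10 s;
#'   field protocols record "at the same time" without a stated resolution).
#' @param predeparture_window_s length of the pre-departure window before the
#'   first departure in which intent behaviours are attributed to the
#'   movement (default 1200 s = 20 min).
#' @param bout_gap_s minimum gap between a group pause and renewed movement
#'   for the resumption to open a new bout (default 60 s).
#' @param movement_gap_s minimum quiet gap separating two distinct collective
#'   movements (default 600 s).
#' @return A list of class `"segmentation_params"`.
#' @export
segmentation_params <- function(participation_fraction = 0.5,
                                simultaneity_window_s = 10,
                                predeparture_window_s = 1200,
                                bout_gap_s = 60,
                                movement_gap_s = 600) {
  stopifnot(participation_fraction > 0, participation_fraction <= 1,
            simultaneity_window_s >= 0, predeparture_window_s > 0,
            bout_gap_s > 0, movement_gap_s > 0)
  if (!(simultaneity_window_s < bout_gap_s && bout_gap_s < movement_gap_s))
    stop("need simultaneity_window_s < bout_gap_s < movement_gap_s")
  structure(list(participation_fraction = participation_fraction,
                 simultaneity_window_s = simultaneity_window_s,
                 predeparture_window_s = predeparture_window_s,
                 bout_gap_s = bout_gap_s,
                 movement_gap_s = movement_gap_s),
            class = "segmentation_params")
}

# Rows of a time-sorted frame with from <= time_s <= to (half-open on the
# right when right_open). O(log n) via findInterval.
slice_time <- function(df, from, to, right_open = FALSE) {
  t <- df$time_s
  i1 <- findInterval(from, t, left.open = TRUE) + 1L
  i2 <- findInterval(to, t, left.open = right_open)
  if (i1 > i2) return(df[0, , drop = FALSE])
  df[i1:i2, , drop = FALSE]
}

#' Segment an event log into collective movements
#'
#' Departure and joining events are clustered into maximal groups separated by
#' at least `movement_gap_s` of movement silence. A cluster qualifies as a
#' collective movement when the number of distinct movers reaches
#' `ceiling(participation_fraction * N)` (at least half the group under the
#' default). Each qualifying cluster yields one collective movement record
#' with time-ordered departures (first movement event per individual), the
#' simultaneous first-mover set, the pre-departure participant set, the front
#' individual at mid-travel (if uniquely recorded), a bout count, and the
#' joining-process duration.
#'
#' @param log an [event_log()].
#' @param roster the group [roster()].
#' @param params [segmentation_params()].
#' @return A list of `collective_movement` objects (possibly empty).
#' @export
segment_movements <- function(log, roster, params = segmentation_params()) {
  moves <- log[log$kind %in% MOVE_KINDS, , drop = FALSE]
  if (nrow(moves) == 0) return(list())
  predep_df <- log[log$kind %in% PREDEPARTURE_KINDS, , drop = FALSE]
  front_df <- log[log$kind == "front", , drop = FALSE]
  arrival_df <- log[log$kind == "arrival", , drop = FALSE]
  pause_df <- log[log$kind == "pause", , drop = FALSE]

  gaps <- c(Inf, diff(moves$time_s))
  cluster <- cumsum(gaps >= params$movement_gap_s)
  need <- ceiling(params$participation_fraction * nrow(roster))
  cluster_list <- split(seq_len(nrow(moves)), cluster)
  cluster_start <- vapply(cluster_list, function(i) moves$time_s[i[1]], 0)

  out <- list()
  for (ci in seq_along(cluster_list)) {
    cl <- moves[cluster_list[[ci]], , drop = FALSE]
    dep <- cl[!duplicated(cl$actor_id), , drop = FALSE]  # first move per actor
    if (nrow(dep) < need) next
    departures <- data.frame(id = dep$actor_id, time_s = dep$time_s,
                             stringsAsFactors = FALSE)
    departures <- departures[order(departures$time_s, departures$id), ]
    rownames(departures) <- NULL
    t0 <- departures$time_s[1]
    t1 <- departures$time_s[nrow(departures)]
    t_next <- if (ci < length(cluster_list)) cluster_start[ci + 1] else Inf

    mv <- new_collective_movement(
      movement_id = sprintf("M%03d", length(out) + 1L),
      departures = departures,
      first_movers = first_movers_from_departures(departures, params),
      predeparture_ids = character(0),
      joining_duration_s = if (nrow(departures) >= 2) t1 - t0 else NA_real_)
    mv$arrivals <- arrivals_from(
      slice_time(arrival_df, t0, t_next, right_open = TRUE), departures$id)
    mv$predeparture_ids <- sort(unique(slice_time(
      predep_df, t0 - params$predeparture_window_s, t0,
      right_open = TRUE)$actor_id))
    mv$front_id <- front_from(mv, slice_time(front_df, t0, movement_end(mv)))
    mv$n_bouts <- bouts_from(mv,
                             slice_time(pause_df, t0, t1),
                             slice_time(cl, t0, t1)$time_s, params)
    out[[length(out) + 1L]] <- mv
  }
  out
}

first_movers_from_departures <- function(departures, params) {
  t0 <- min(departures$time_s)
  sort(departures$id[departures$time_s - t0 <= params$simultaneity_window_s])
}

arrivals_from <- function(arr, mover_ids) {
  arr <- arr[arr$actor_id %in% mover_ids, , drop = FALSE]
  if (nrow(arr) == 0) return(NULL)
  arr <- arr[!duplicated(arr$actor_id), , drop = FALSE]
  data.frame(id = arr$actor_id, time_s = arr$time_s, stringsAsFactors = FALSE)
}

movement_end <- function(movement) {
  if (!is.null(movement$arrivals) && nrow(movement$arrivals))
    max(movement$arrivals$time_s)
  else max(movement$departures$time_s)
}

front_from <- function(movement, fr) {
  if (nrow(fr) == 0) return(NA_character_)
  mid <- (min(movement$departures$time_s) + movement_end(movement)) / 2
  d <- abs(fr$time_s - mid)
  ids <- unique(fr$actor_id[d == min(d)])
  if (length(ids) == 1L) ids else NA_character_
}

bouts_from <- function(movement, pauses, move_times, params) {
  movers <- movement$departures$id
  pauses <- pauses[pauses$actor_id %in% movers, , drop = FALSE]
  if (nrow(pauses) == 0) return(1L)
  need <- ceiling(params$participation_fraction * length(movers))
  cl <- cumsum(c(TRUE, diff(pauses$time_s) >= params$bout_gap_s))
  extra <- 0L
  for (grp in split(pauses, cl)) {
    if (length(unique(grp$actor_id)) < need) next
    if (any(move_times >= max(grp$time_s) + params$bout_gap_s))
      extra <- extra + 1L
  }
  1L + extra
}

#' Simultaneous first movers of a movement
#'
#' All individuals whose first movement event falls within
#' `simultaneity_window_s` (inclusive) of the earliest departure. The result
#' never depends on the ordering of equal-timestamp records.
#'
#' @param movement a `collective_movement`.
#' @param params [segmentation_params()].
#' @return Sorted character vector of member ids, length at least 1.
#' @export
detect_first_movers <- function(movement, params = segmentation_params()) {
  first_movers_from_departures(movement$departures, params)
}

#' Pre-departure participants of a movement
#'
#' Individuals with at least one intent behaviour (moving away, staying
#' peripheral, following a mover, joining a peripheral individual, pausing) in
#' the half-open window `[t0 - predeparture_window_s, t0)` before the first
#' departure at `t0`. Events at exactly `t0` belong to the departure itself
#' and are excluded.
#'
#' @param log the [event_log()].
#' @param movement a `collective_movement`.
#' @param params [segmentation_params()].
#' @return Sorted character vector of member ids (possibly empty).
#' @export
extract_predeparture_participants <- function(log, movement,
                                              params = segmentation_params()) {
  t0 <- min(movement$departures$time_s)
  pre <- log[log$kind %in% PREDEPARTURE_KINDS, , drop = FALSE]
  sort(unique(slice_time(pre, t0 - params$predeparture_window_s, t0,
                         right_open = TRUE)$actor_id))
}

#' Joining-process duration of a movement
#'
#' Time elapsed between the first mover's departure and the last mover's
#' departure, the recruitment-efficiency measure. Undefined (NA), not zero,
#' for a movement with a single departure record.
#'
#' @param movement a `collective_movement`.
#' @return Duration in seconds, or `NA_real_`.
#' @export
joining_duration <- function(movement) {
  if (nrow(movement$departures) < 2) return(NA_real_)
  max(movement$departures$time_s) - min(movement$departures$time_s)
}

#' Front individual at mid-travel
#'
#' Finds the walking-order (`"front"`) annotation closest to the movement's
#' temporal midpoint (first departure to last arrival, or last departure when
#' no arrivals were recorded). Returns that individual's id when the record is
#' unique; `NA` when no front record exists or two or more individuals share
#' the closest record (horses abreast), in which case the movement is excluded
#' from front-position tallies but retained for departure analyses.
#'
#' @param movement a `collective_movement`.
#' @param log the [event_log()].
#' @return A member id or `NA_character_`.
#' @export
front_at_midtravel <- function(movement, log) {
  fr <- log[log$kind == "front", , drop = FALSE]
  front_from(movement, slice_time(fr, min(movement$departures$time_s),
                                  movement_end(movement)))
}

#' Count moving bouts within a movement
#'
#' A movement has one bout unless a group-level pause interrupts it: a cluster
#' of `pause` events (gaps below `bout_gap_s`) involving at least
#' `participation_fraction` of the movement's movers, followed by renewed
#' departure/joining events at least `bout_gap_s` after the pause. Each such
#' interruption adds a bout. Downstream leadership analyses keep only
#' single-bout movements.
#'
#' @param movement a `collective_movement`.
#' @param log the [event_log()].
#' @param params [segmentation_params()].
#' @return Integer bout count, at least 1.
#' @export
count_bouts <- function(movement, log, params = segmentation_params()) {
  t0 <- min(movement$departures$time_s)
  t1 <- max(movement$departures$time_s)
  pauses <- slice_time(log[log$kind == "pause", , drop = FALSE], t0, t1)
  move_times <- slice_time(log[log$kind %in% MOVE_KINDS, , drop = FALSE],
                           t0, t1)$time_s
  bouts_from(movement, pauses, move_times, params)
}
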