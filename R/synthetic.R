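#' Configuration for the synthetic event-stream generator
#'
#' Describes the stochastic process the generator realizes: a family group
#' performing collective movements whose first movers are drawn from
#' per-individual propensities, preceded by pre-departure displays, joined by
#' the rest of the group with random latencies, and annotated with front
#' position and arrivals. The propensity vector is the single axis from
#' equally shared leadership (symmetric Dirichlet with large concentration)
#' to despotic leadership (one fixed spike).
#'
#' @param roster a [roster()].
#' @param n_movements number of collective movements to generate.
#' @param propensities fixed per-individual first-mover probabilities
#'   (summing to 1), or `NULL` to draw them from a symmetric Dirichlet.
#' @param leadership_concentration Dirichlet concentration `kappa > 0` used
#'   when `propensities` is `NULL`; large values give near-uniform
#'   propensities, small values concentrated ones.
#' @param predeparture_rates per-individual probability of displaying
#'   pre-departure behaviour before a movement (recycled if length 1).
#' @param coupling probability that the first mover is drawn from the
#'   pre-departure participant set (when non-empty) rather than from the
#'   whole group; `1` makes every sole first mover a prior displayer.
#' @param simultaneity_prob probability that a movement starts with 2-3
#'   simultaneous first movers.
#' @param simultaneity_window_s spread of simultaneous departures (seconds);
#'   must be positive when `simultaneity_prob > 0`.
#' @param joining_mean_s mean of the exponential joining-process duration
#'   (first to last departure), seconds.
#' @param front_scored_prob probability a movement carries a unique front
#'   record at mid-travel (otherwise no front annotation is emitted).
#' @param front_follows_first probability the front individual is the (sole)
#'   first mover; otherwise uniform over movers.
#' @param two_bout_prob probability a movement contains a group pause and
#'   resumption (two bouts).
#' @param intermovement_gap_mean_s mean exponential gap between movements on
#'   top of the pre-departure window, seconds.
#' @param travel_time_s time from an individual's departure to its arrival,
#'   seconds.
#' @param predeparture_events_max each participant emits 1 to this many
#'   intent events in the pre-departure window.
#' @param seed integer seed; all randomness derives from it.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(roster,
                             n_movements = 42L,
                             propensities = NULL,
                             leadership_concentration = 1,
                             predeparture_rates = 0.2,
                             coupling = 0.5,
                             simultaneity_prob = 0.25,
                             simultaneity_window_s = 10,
                             joining_mean_s = 400,
                             front_scored_prob = 0.5,
                             front_follows_first = 0.5,
                             two_bout_prob = 0,
                             intermovement_gap_mean_s = 3600,
                             travel_time_s = 300,
                             predeparture_events_max = 2L,
                             seed = 1L) {
  n <- nrow(roster)
  stopifnot(n_movements >= 1, leadership_concentration > 0,
            coupling >= 0, coupling <= 1,
            simultaneity_prob >= 0, simultaneity_prob <= 1,
            front_scored_prob >= 0, front_scored_prob <= 1,
            front_follows_first >= 0, front_follows_first <= 1,
            two_bout_prob >= 0, two_bout_prob <= 1,
            joining_mean_s > 0, travel_time_s > 0)
  if (simultaneity_prob > 0 && simultaneity_window_s <= 0)
    stop("simultaneity_prob > 0 requires a positive simultaneity window")
  if (!is.null(propensities)) {
    stopifnot(length(propensities) == n, all(propensities >= 0))
    if (abs(sum(propensities) - 1) > 1e-8)
      stop("propensities must sum to 1")
  }
  predeparture_rates <- rep_len(predeparture_rates, n)
  stopifnot(all(predeparture_rates >= 0), all(predeparture_rates <= 1))
  structure(list(roster = roster, n_movements = as.integer(n_movements),
                 propensities = propensities,
                 leadership_concentration = leadership_concentration,
                 predeparture_rates = predeparture_rates,
                 coupling = coupling,
                 simultaneity_prob = simultaneity_prob,
                 simultaneity_window_s = simultaneity_window_s,
                 joining_mean_s = joining_mean_s,
                 front_scored_prob = front_scored_prob,
                 front_follows_first = front_follows_first,
                 two_bout_prob = two_bout_prob,
                 intermovement_gap_mean_s = intermovement_gap_mean_s,
                 travel_time_s = travel_time_s,
                 predeparture_events_max = as.integer(predeparture_events_max),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Named generator presets
#'
#' * `"bo_like"`: a 12-member family calibrated to the published BO-group
#'   summaries — 42 movements, simultaneous departures in 14/42, first-mover
#'   propensities proportional to the reconstructed counts
#'   (6,2,11,0,8,0,1,0,0,0,0,0), pre-departure rates from the printed
#'   percentages, joining mean 471 s, front scored in 11/42 movements.
#' * `"ad_like"`: the 6-member family analogue — 43 movements, simultaneity
#'   8/43, propensities proportional to (6,6,11,8,1,3), joining mean 249 s,
#'   front scored in 21/43.
#' * `"null_uniform"`: near-uniform propensities (Dirichlet concentration
#'   1e4), no coupling, no simultaneity — the chance-level null.
#' * `"concentrated"`: one despotic individual with propensity 0.8.
#'
#' @param name preset name.
#' @param n_movements optional override of the movement count.
#' @param seed integer seed.
#' @return A [synthetic_config()].
#' @export
synthetic_preset <- function(name = c("bo_like", "ad_like", "null_uniform",
                                      "concentrated"),
                             n_movements = NULL, seed = 1L) {
  name <- match.arg(name)
  cfg <- switch(
    name,
    bo_like = synthetic_config(
      roster = bo_roster(),
      n_movements = 42L,
      propensities = c(6, 2, 11, 0, 8, 0, 1, 0, 0, 0, 0, 0) / 28,
      predeparture_rates = c(17.86, 10.71, 28.57, 17.86, 46.43, 21.43, 3.57,
                             14.29, 21.43, 14.29, 28.57, 10.71) / 100,
      coupling = 0.58, simultaneity_prob = 14 / 42,
      joining_mean_s = 471, front_scored_prob = 11 / 42,
      front_follows_first = 0.4, seed = seed),
    ad_like = synthetic_config(
      roster = ad_roster(),
      n_movements = 43L,
      propensities = c(6, 6, 11, 8, 1, 3) / 35,
      predeparture_rates = c(51.43, 37.14, 37.14, 40.00, 31.43, 28.57) / 100,
      coupling = 0.59, simultaneity_prob = 8 / 43,
      joining_mean_s = 249, front_scored_prob = 21 / 43,
      front_follows_first = 0.4, seed = seed),
    null_uniform = synthetic_config(
      roster = bo_roster(),
      n_movements = 42L,
      leadership_concentration = 1e4,
      predeparture_rates = 0.25, coupling = 0,
      simultaneity_prob = 0, joining_mean_s = 400, seed = seed),
    concentrated = {
      n <- 12L
      synthetic_config(
        roster = bo_roster(),
        n_movements = 500L,
        propensities = c(0.8, rep(0.2 / (n - 1), n - 1)),
        predeparture_rates = 0.25, coupling = 0.5,
        simultaneity_prob = 0, joining_mean_s = 400, seed = seed)
    })
  if (!is.null(n_movements)) cfg$n_movements <- as.integer(n_movements)
  cfg
}

# Substream seed for movement m, kept inside 32-bit integer range.
substream_seed <- function(seed, m) {
  as.integer((as.double(seed) * 48271 + m * 16807) %% 2147483647)
}

#' Generate a synthetic event log with known ground truth
#'
#' Realizes the process described by a [synthetic_config()]: for each
#' movement, pre-departure displays by a random participant set, one or more
#' (simultaneous) first movers drawn from the propensity vector (coupled to
#' the participant set with probability `coupling`), exponential joining of
#' the rest of the group, optional group pause and resumption (second bout),
#' a front annotation at the temporal midpoint, and arrivals. Identical
#' seeds give identical output; each movement uses a deterministic
#' sub-stream of the master seed.
#'
#' @param config a [synthetic_config()].
#' @return A list: `log` (an [event_log()]), `truth` (per-movement ground
#'   truth: first movers, pre-departure set, front id, bout count, departure
#'   times, joining duration) and `propensities` (the realized per-individual
#'   first-mover propensities).
#' @export
generate_events <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ros <- config$roster
  ids <- ros$id
  n <- length(ids)
  set.seed(config$seed)
  prop <- config$propensities
  if (is.null(prop)) {
    g <- stats::rgamma(n, shape = config$leadership_concentration)
    prop <- g / sum(g)
  }
  pre_window <- 1200
  t_cursor <- 0
  ev_time <- ev_actor <- ev_kind <- list()
  truth <- vector("list", config$n_movements)

  emit <- function(time, actor, kind) {
    i <- length(ev_time) + 1L
    ev_time[[i]] <<- time
    ev_actor[[i]] <<- actor
    ev_kind[[i]] <<- kind
  }

  for (m in seq_len(config$n_movements)) {
    set.seed(substream_seed(config$seed, m))
    t0 <- t_cursor + pre_window +
      max(stats::rexp(1, 1 / config$intermovement_gap_mean_s), 700)

    # pre-departure phase, then first mover(s); with probability `coupling`
    # the first mover comes from (and, if need be, is added to) the
    # participant set, so coupling = 1 guarantees every first mover displayed
    participants <- ids[stats::runif(n) < config$predeparture_rates]
    pick <- function(pool) {
      w <- prop[match(pool, ids)]
      if (sum(w) <= 0) w <- rep(1, length(pool))
      pool[sample.int(length(pool), 1, prob = w)]
    }
    if (stats::runif(1) < config$coupling) {
      first <- if (length(participants)) pick(participants) else pick(ids)
      participants <- union(participants, first)
    } else {
      first <- pick(ids)
    }
    for (id in participants) {
      k <- sample.int(config$predeparture_events_max, 1)
      times <- sort(stats::runif(k, t0 - pre_window, t0 - 1))
      emit(times, rep(id, k), sample(PREDEPARTURE_KINDS, k, replace = TRUE))
    }
    movers <- first
    dep_times <- t0
    if (stats::runif(1) < config$simultaneity_prob && n > 2) {
      n_extra <- sample(1:2, 1)
      pool <- setdiff(ids, first)
      extra <- character(0)
      for (j in seq_len(min(n_extra, length(pool)))) {
        e <- pick(pool)
        pool <- setdiff(pool, e)
        extra <- c(extra, e)
      }
      movers <- c(first, extra)
      dep_times <- c(t0, t0 + stats::runif(length(extra), 0,
                                           config$simultaneity_window_s * 0.9))
    }
    emit(dep_times, movers, c("departure", rep("departure",
                                               length(movers) - 1)))

    # joining by the rest of the group
    joiners <- setdiff(ids, movers)
    two_bout <- stats::runif(1) < config$two_bout_prob && length(joiners) >= 2
    duration <- config$simultaneity_window_s + 1 +
      stats::rexp(1, 1 / config$joining_mean_s)
    if (length(joiners)) {
      if (two_bout) {
        # first bout kept short so the pause-resume gap cannot be mistaken
        # for a movement boundary
        d1 <- min(duration, 400)
        half <- ceiling(length(joiners) / 2)
        jt <- sort(stats::runif(length(joiners),
                                config$simultaneity_window_s + 1, d1))
        join_times <- t0 + jt
        pause_t <- t0 + d1 + 100
        paused <- c(movers, joiners[seq_len(half)])
        emit(pause_t + seq_along(paused) * 0.1, paused,
             rep("pause", length(paused)))
        late <- (half + 1):length(joiners)
        join_times[late] <- pause_t + 60 + 30 * seq_along(late)
        duration <- max(join_times) - t0
      } else {
        # keep every within-movement departure gap well below the 600-s
        # movement separation so a long joining process cannot be split in
        # two by the segmentation; the total duration is preserved
        gap_cap <- 500
        lo <- config$simultaneity_window_s + 1
        duration <- min(duration, lo + gap_cap * length(joiners))
        jt <- sort(stats::runif(length(joiners), lo, duration))
        jt[length(jt)] <- duration
        if (any(diff(c(0, jt)) > gap_cap))
          jt <- lo + (duration - lo) * seq_along(joiners) / length(joiners)
        join_times <- t0 + jt
      }
      emit(join_times, joiners, rep("joining", length(joiners)))
    }
    all_dep_t <- c(dep_times, if (length(joiners)) join_times else numeric(0))
    all_dep_id <- c(movers, joiners)
    last_dep <- max(all_dep_t)

    # arrivals and front annotation
    arr_times <- all_dep_t + config$travel_time_s
    emit(arr_times, all_dep_id, rep("arrival", n))
    t_end <- max(arr_times)
    front <- NA_character_
    if (stats::runif(1) < config$front_scored_prob) {
      front <- if (length(movers) == 1 &&
                   stats::runif(1) < config$front_follows_first)
        first else sample(ids, 1)
      emit((t0 + t_end) / 2, front, "front")
    }

    truth[[m]] <- list(movement_id = sprintf("M%03d", m),
                       first_movers = sort(movers),
                       predeparture_ids = sort(participants),
                       front_id = front,
                       n_bouts = if (two_bout) 2L else 1L,
                       t0 = t0,
                       joining_duration_s = if (n > 1) last_dep - t0 else NA,
                       simultaneous = length(movers) > 1)
    t_cursor <- t_end
  }

  events <- data.frame(time_s = unlist(ev_time),
                       actor_id = unlist(ev_actor),
                       kind = unlist(ev_kind),
                       target_id = NA_character_,
                       stringsAsFactors = FALSE)
  events <- events[order(events$time_s), , drop = FALSE]
  log <- event_log(events, ros, session_id = sprintf("synthetic-seed%d",
                                                     config$seed))
  list(log = log, truth = truth,
       propensities = stats::setNames(prop, ids))
}

#' Roster of the 12-member study family (BO)
#'
#' Ids encode dominance rank, sex/age-class letter, and age in years
#' (e.g. `7f2` is a 2-yr-old immature female of rank 7).
#'
#' @return A [roster()].
#' @export
bo_roster <- function() {
  roster(id = c("1F16", "2M8", "3F15", "4F4", "5F5", "6F4",
                "7f2", "8f2", "9f1", "10m1", "11f1", "12m1"),
         sex = c("female", "male", "female", "female", "female", "female",
                 "female", "female", "female", "male", "female", "male"),
         age_years = c(16, 8, 15, 4, 5, 4, 2, 2, 1, 1, 1, 1),
         rank = 1:12, group_id = "BO")
}

#' Roster of the 6-member study family (AD)
#'
#' @return A [roster()].
#' @export
ad_roster <- function() {
  roster(id = c("1M12", "2F9", "3F9", "4F8", "5m1", "6m1"),
         sex = c("male", "female", "female", "female", "male", "male"),
         age_years = c(12, 9, 9, 8, 1, 1),
         rank = 1:6, group_id = "AD")
}
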