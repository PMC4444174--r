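#' movelead: leadership proxies in collective animal movements
#'
#' Analyse time-stamped behavioural event logs of animal groups on the move:
#' segment collective movements, tally leadership proxies (first departure,
#' front travel position, recruitment efficiency), test them against chance,
#' and relate them to dominance and age.
#'
#' @keywords internal
"_PACKAGE"

# Event vocabulary. Pre-departure acts signal moving intent in the window
# before a group departure; "front" is a walking-order annotation recorded
# during travel; "agonistic" carries a target (the loser of the interaction).
PREDEPARTURE_KINDS <- c("move_away", "stay_peripheral", "follow_mover",
                        "join_peripheral", "pause")
MOVE_KINDS  <- c("departure", "joining")
EVENT_KINDS <- c(PREDEPARTURE_KINDS, MOVE_KINDS, "arrival", "agonistic", "front")

AGE_CLASSES <- c("adult", "subadult", "foal")
SEXES       <- c("female", "male")

#' Build a validated group roster
#'
#' A roster lists the members of one social group: a unique id, sex, age in
#' years, an age class, and (optionally) a dominance rank where 1 is the
#' top-ranking individual.
#'
#' @param id character vector of unique member labels.
#' @param sex `"female"` or `"male"`, recycled if length 1.
#' @param age_years non-negative numeric ages.
#' @param age_class `"adult"`, `"subadult"` or `"foal"`; derived from
#'   `age_years` via `age_class_map` when omitted.
#' @param rank optional dominance ranks; must be a permutation of `1..N`.
#' @param group_id label for the group.
#' @param age_class_map named list with elements `foal_max` and `subadult_max`
#'   (years); ages at or below `foal_max` are foals, above `subadult_max`
#'   adults, in between subadults.
#' @return A data frame of class `"roster"` with attribute `group_id`.
#' @examples
#' roster(id = c("A", "B", "C"), sex = "female", age_years = c(10, 3, 1))
#' @export
roster <- function(id, sex, age_years, age_class = NULL, rank = NULL,
                   group_id = "group",
                   age_class_map = list(foal_max = 1, subadult_max = 2)) {
  id <- as.character(id)
  n <- length(id)
  if (n < 2L)
    stop("a roster needs at least 2 members, got ", n)
  if (anyDuplicated(id))
    stop("duplicate member ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  sex <- rep_len(match.arg(as.character(sex), SEXES, several.ok = TRUE), n)
  age_years <- as.numeric(age_years)
  if (length(age_years) != n || any(is.na(age_years)) || any(age_years < 0))
    stop("age_years must be non-negative and one per member")
  derived <- ifelse(age_years <= age_class_map$foal_max, "foal",
                    ifelse(age_years <= age_class_map$subadult_max,
                           "subadult", "adult"))
  if (is.null(age_class)) {
    age_class <- derived
  } else {
    age_class <- match.arg(as.character(age_class), AGE_CLASSES,
                           several.ok = TRUE)
    age_class <- rep_len(age_class, n)
    bad <- which(age_class != derived)
    if (length(bad))
      stop("age_class inconsistent with age_years for: ",
           paste(id[bad], collapse = ", "))
  }
  if (!is.null(rank)) {
    rank <- as.integer(rank)
    if (length(rank) != n || !setequal(rank, seq_len(n)))
      stop("ranks must be a permutation of 1..", n)
  }
  out <- data.frame(id = id, sex = sex, age_years = age_years,
                    age_class = age_class, stringsAsFactors = FALSE)
  out$rank <- if (is.null(rank)) NA_integer_ else rank
  attr(out, "group_id") <- as.character(group_id)
  class(out) <- c("roster", "data.frame")
  out
}

#' @export
print.roster <- function(x, ...) {
  cat("Roster '", attr(x, "group_id"), "': ", nrow(x), " individuals (",
      sum(x$age_class == "adult"), " adults)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Build a validated event log
#'
#' An event log is a time-ordered record of behavioural acts, one row per
#' event: time in seconds from session start, the acting individual, the kind
#' of act, and for directed acts (agonistic interactions, optionally
#' following/joining) a target individual.
#'
#' @param events data frame with columns `time_s`, `actor_id`, `kind` and
#'   optionally `target_id`.
#' @param roster a [roster()]; all actors (and targets) must be members.
#' @param group_id,session_id labels carried as attributes.
#' @return A data frame of class `"event_log"`, sorted by `time_s`.
#' @export
event_log <- function(events, roster, group_id = attr(roster, "group_id"),
                      session_id = "session") {
  stopifnot(is.data.frame(events))
  req <- c("time_s", "actor_id", "kind")
  miss <- setdiff(req, names(events))
  if (length(miss))
    stop("event log lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(events$target_id))
    events$target_id <- rep(NA_character_, nrow(events))
  events <- events[, c("time_s", "actor_id", "kind", "target_id")]
  events$time_s <- as.numeric(events$time_s)
  events$actor_id <- as.character(events$actor_id)
  events$kind <- as.character(events$kind)
  events$target_id <- as.character(events$target_id)

  bad_row <- function(test, what) {
    i <- which(test)
    if (length(i))
      stop(what, " at row(s): ", paste(utils::head(i, 10), collapse = ", "))
  }
  bad_row(is.na(events$time_s) | events$time_s < 0,
          "missing or negative time_s")
  bad_row(!events$kind %in% EVENT_KINDS, "unknown event kind")
  bad_row(!events$actor_id %in% roster$id, "actor not in roster")
  bad_row(!is.na(events$target_id) & !events$target_id %in% roster$id,
          "target not in roster")
  bad_row(events$kind == "agonistic" & is.na(events$target_id),
          "agonistic event without target_id")
  bad_row(!is.na(events$target_id) & events$target_id == events$actor_id,
          "self-directed event")

  if (is.unsorted(events$time_s)) {
    warning("events not in time order; sorting by time_s")
    events <- events[order(events$time_s), , drop = FALSE]
  }
  rownames(events) <- NULL
  attr(events, "group_id") <- as.character(group_id)
  attr(events, "session_id") <- as.character(session_id)
  class(events) <- c("event_log", "data.frame")
  events
}

#' @export
print.event_log <- function(x, ...) {
  cat("Event log '", attr(x, "session_id"), "' (group ", attr(x, "group_id"),
      "): ", nrow(x), " events over ",
      round(diff(range(x$time_s))), " s\n", sep = "")
  print(table(x$kind))
  invisible(x)
}

# One segmented collective movement. departures is a data.frame(id, time_s)
# ordered by time, first event per mover; front_id is NA unless exactly one
# individual held the front record at mid-travel.
new_collective_movement <- function(movement_id, departures, arrivals = NULL,
                                    first_movers, predeparture_ids,
                                    front_id = NA_character_, n_bouts = 1L,
                                    joining_duration_s = NA_real_) {
  stopifnot(nrow(departures) >= 1, length(first_movers) >= 1,
            all(first_movers %in% departures$id))
  structure(
    list(movement_id = movement_id,
         departures = departures,
         arrivals = arrivals,
         first_movers = first_movers,
         predeparture_ids = predeparture_ids,
         front_id = front_id,
         n_bouts = as.integer(n_bouts),
         joining_duration_s = joining_duration_s),
    class = "collective_movement")
}

#' @export
print.collective_movement <- function(x, ...) {
  cat("Collective movement ", x$movement_id, ": ", nrow(x$departures),
      " movers, first mover(s) {", paste(x$first_movers, collapse = ", "),
      "}, ", x$n_bouts, " bout(s)\n", sep = "")
  invisible(x)
}
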