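#' Tally the three leadership proxies per individual
#'
#' Counts, for each roster member, how often it (1) took part in the
#' pre-departure period, (2) was the sole first mover, and (3) walked in front
#' position at mid-travel. Movements started by simultaneous first movers
#' contribute to nobody's first-mover count (they are excluded from the
#' departure analysis), and movements without a unique front record contribute
#' to nobody's front count; both remain in the totals.
#'
#' @param movements list of `collective_movement` objects (single-bout,
#'   already filtered).
#' @param roster the group [roster()].
#' @return A list of class `"proxy_counts"`: `counts` (data frame with one row
#'   per member: `predeparture_count`, `first_mover_count`, `front_count`) and
#'   `denominators` (`n_single_first_mover_movements`,
#'   `n_front_scored_movements`, `n_total_movements`).
#' @export
tally_proxies <- function(movements, roster) {
  ids <- roster$id
  zero <- stats::setNames(integer(length(ids)), ids)
  pre <- fm <- fr <- zero
  n_single <- n_front <- 0L
  for (mv in movements) {
    pre[mv$predeparture_ids] <- pre[mv$predeparture_ids] + 1L
    if (length(mv$first_movers) == 1L) {
      n_single <- n_single + 1L
      fm[mv$first_movers] <- fm[mv$first_movers] + 1L
    }
    if (!is.na(mv$front_id)) {
      n_front <- n_front + 1L
      fr[mv$front_id] <- fr[mv$front_id] + 1L
    }
  }
  structure(list(
    counts = data.frame(id = ids,
                        predeparture_count = unname(pre),
                        first_mover_count = unname(fm),
                        front_count = unname(fr),
                        stringsAsFactors = FALSE),
    denominators = list(n_single_first_mover_movements = n_single,
                        n_front_scored_movements = n_front,
                        n_total_movements = length(movements))),
    class = "proxy_counts")
}

#' @export
print.proxy_counts <- function(x, ...) {
  d <- x$denominators
  cat("Leadership proxy tallies over", d$n_total_movements, "movements (",
      d$n_single_first_mover_movements, "single-first-mover,",
      d$n_front_scored_movements, "front-scored)\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

# Shared builder for the concordance table. Inputs are per-individual
# numerators and denominators for the five conditional columns.
build_concordance <- function(ids, num, den) {
  pct <- function(n, d) ifelse(d > 0, 100 * n / d, NA_real_)
  tab <- data.frame(id = ids, stringsAsFactors = FALSE)
  cols <- names(num)
  for (col in cols) {
    tab[[paste0("num_", col)]] <- num[[col]]
    tab[[paste0("den_", col)]] <- den[[col]]
    tab[[paste0("pct_", col)]] <- pct(num[[col]], den[[col]])
  }
  defined_mean <- function(v) mean(v[!is.na(v)])
  defined_sem <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    stats::sd(v) / sqrt(length(v))
  }
  summary <- data.frame(
    column = cols,
    mean = vapply(cols, function(c) defined_mean(tab[[paste0("pct_", c)]]), 0),
    sem = vapply(cols, function(c) defined_sem(tab[[paste0("pct_", c)]]), 0),
    n_defined = vapply(cols, function(c) sum(!is.na(tab[[paste0("pct_", c)]])),
                       0L),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(table = tab, summary = summary), class = "concordance_table")
}

#' Concordance between pre-departure behaviour and subsequent leadership
#'
#' For each individual, forward conditionals ask how often a pre-departure
#' display was followed by leading: P(departed first | displayed), P(front |
#' displayed), P(departed first and front | displayed). Retrospective
#' conditionals ask how often leading had been announced: P(displayed |
#' departed first) and P(displayed | front). "Departed first" always means
#' sole first mover. Cells with a zero denominator are undefined (`NA`), never
#' zero; column means and SEMs are taken over defined cells only.
#'
#' @param movements list of single-bout `collective_movement` objects.
#' @param roster the group [roster()].
#' @return A list of class `"concordance_table"` with elements `table`
#'   (per-individual numerators, denominators and percentages) and `summary`
#'   (per-column mean, SEM and number of defined cells).
#' @export
concordance <- function(movements, roster) {
  ids <- roster$id
  zero <- stats::setNames(integer(length(ids)), ids)
  n_pre <- n_fm <- n_fr <- zero                 # marginals
  fm_pre <- fr_pre <- both_pre <- zero          # joint with own display
  pre_fm <- pre_fr <- zero
  for (mv in movements) {
    pre_ids <- mv$predeparture_ids
    sole <- if (length(mv$first_movers) == 1L) mv$first_movers else NULL
    front <- if (!is.na(mv$front_id)) mv$front_id else NULL
    n_pre[pre_ids] <- n_pre[pre_ids] + 1L
    if (!is.null(sole)) n_fm[sole] <- n_fm[sole] + 1L
    if (!is.null(front)) n_fr[front] <- n_fr[front] + 1L
    if (!is.null(sole) && sole %in% pre_ids) {
      fm_pre[sole] <- fm_pre[sole] + 1L
      pre_fm[sole] <- pre_fm[sole] + 1L
    }
    if (!is.null(front) && front %in% pre_ids) {
      fr_pre[front] <- fr_pre[front] + 1L
      pre_fr[front] <- pre_fr[front] + 1L
    }
    if (!is.null(sole) && !is.null(front) && sole == front &&
        sole %in% pre_ids)
      both_pre[sole] <- both_pre[sole] + 1L
  }
  build_concordance(
    ids,
    num = list(first_after_predep = unname(fm_pre),
               front_after_predep = unname(fr_pre),
               first_and_front_after_predep = unname(both_pre),
               predep_before_first = unname(pre_fm),
               predep_before_front = unname(pre_fr)),
    den = list(first_after_predep = unname(n_pre),
               front_after_predep = unname(n_pre),
               first_and_front_after_predep = unname(n_pre),
               predep_before_first = unname(n_fm),
               predep_before_front = unname(n_fr)))
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Concordance between pre-departure display and leadership proxies\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Joining durations grouped by first mover
#'
#' Collects the joining-process durations of single-first-mover movements and
#' groups them by the identity of the first mover, keeping only movers that
#' departed first at least `min_departures` times. The grouping feeds the
#' Kruskal-Wallis comparison of recruitment efficiency.
#'
#' @param movements list of single-bout `collective_movement` objects.
#' @param roster the group [roster()].
#' @param min_departures minimum sole-first-mover count to qualify
#'   (default 3).
#' @return A list: `groups` (named list of duration vectors),
#'   `test_applicable` (`TRUE` when at least two movers qualify).
#' @export
joining_efficiency <- function(movements, roster, min_departures = 3L) {
  durs <- list()
  for (mv in movements) {
    if (length(mv$first_movers) != 1L) next
    d <- mv$joining_duration_s
    if (is.na(d)) next
    id <- mv$first_movers
    durs[[id]] <- c(durs[[id]], d)
  }
  groups <- durs[vapply(durs, length, 0L) >= min_departures]
  groups <- groups[order(names(groups))]
  list(groups = groups, test_applicable = length(groups) >= 2L)
}

#' Reconstruct integer counts from published percentages
#'
#' Published summary tables report per-individual percentages; the underlying
#' integer counts are recoverable when the denominator is known or can be
#' identified. For each candidate denominator `d` the counts are
#' `round(p * d / 100)`; a candidate is consistent when every product lies
#' within percentage-printing precision (0.005 percentage points) of an
#' integer, and, when `expected_total` is given, the counts sum to it. Exactly
#' one candidate must survive.
#'
#' @param percentages numeric vector in `[0, 100]`.
#' @param candidate_denominators positive integers to try.
#' @param expected_total required sum of the counts, or `NULL`.
#' @return A list: `counts` (integer vector) and `chosen_denominator`.
#' @export
reconstruct_counts <- function(percentages, candidate_denominators,
                               expected_total = NULL) {
  stopifnot(all(percentages >= 0), all(percentages <= 100),
            all(candidate_denominators >= 1))
  cands <- as.integer(candidate_denominators)
  fits <- lapply(cands, function(d) {
    raw <- percentages * d / 100
    counts <- as.integer(round(raw))
    resid <- abs(raw - counts)
    ok <- all(resid <= 0.005 * d / 100 + 1e-9)
    if (ok && !is.null(expected_total)) ok <- sum(counts) == expected_total
    list(d = d, counts = counts, ok = ok, max_resid = max(resid))
  })
  keep <- Filter(function(f) f$ok, fits)
  if (length(keep) == 0L)
    stop("no candidate denominator is integer-consistent; residuals: ",
         paste(sprintf("%d:%.4f", cands,
                       vapply(fits, function(f) f$max_resid, 0)),
               collapse = ", "))
  counts_list <- lapply(keep, `[[`, "counts")
  if (length(keep) > 1L) {
    identical_counts <- all(vapply(counts_list[-1], identical, TRUE,
                                   counts_list[[1]]))
    if (!identical_counts || is.null(expected_total))
      stop("ambiguous reconstruction: denominators ",
           paste(vapply(keep, `[[`, 0L, "d"), collapse = ", "),
           " are all consistent; supply expected_total")
  }
  list(counts = counts_list[[1]], chosen_denominator = keep[[1]]$d)
}
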