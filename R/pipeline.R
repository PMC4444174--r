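#' Run the full leadership analysis on an event log
#'
#' Orchestrates the pipeline: segment collective movements, keep single-bout
#' movements, tally the three leadership proxies, test each tally against a
#' discrete uniform distribution (Monte-Carlo Williams-corrected G),
#' run per-individual chance-level post-hoc tests with Holm correction,
#' correlate tallies with age, compare joining durations across first movers
#' (Kruskal-Wallis), build the pre-departure/leadership concordance table,
#' and, when agonistic events are present, assess the dominance hierarchy
#' (linearity, ranks, rank-age correlation).
#'
#' @param log an [event_log()].
#' @param roster the group [roster()].
#' @param params [segmentation_params()].
#' @param B Monte-Carlo simulations for the uniformity tests (default 2000).
#' @param alpha significance level for post-hoc flags.
#' @param seed integer seed for all stochastic steps.
#' @param min_departures qualifying threshold for the joining-efficiency
#'   comparison.
#' @param analyses character vector of sections to run, any of
#'   `"departure"`, `"front"`, `"predeparture"`, `"joining"`,
#'   `"concordance"`, `"hierarchy"`.
#' @return A structured results list; stochastic entries carry their seeds.
#'   With zero single-bout movements, analysis sections are `NA` markers.
#' @export
run_pipeline <- function(log, roster, params = segmentation_params(),
                         B = 2000L, alpha = 0.05, seed = 1L,
                         min_departures = 3L,
                         analyses = c("departure", "front", "predeparture",
                                      "joining", "concordance", "hierarchy")) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  movements <- segment_movements(log, roster, params)
  single <- Filter(function(m) m$n_bouts == 1L, movements)
  res <- list(manifest = list(
    group_id = attr(log, "group_id"), n_individuals = nrow(roster),
    n_movements = length(movements),
    n_single_bout = length(single),
    params = unclass(params), B = as.integer(B), alpha = alpha,
    seed = as.integer(seed), analyses = analyses))
  if (length(single) == 0L) {
    res$note <- "0 movements"
    return(res)
  }
  tallies <- tally_proxies(single, roster)
  res$proxy_counts <- tallies
  counts <- tallies$counts
  den <- tallies$denominators

  proxy_section <- function(x, n, sub_seed) {
    if (sum(x) == 0) return(list(note = "no observations"))
    list(g_test = mc_uniform_test(x, B = B, seed = sub_seed),
         posthoc = posthoc_chance_tests(x, n = n, alpha = alpha,
                                        ids = counts$id),
         age_correlation = spearman_test(roster$age_years, x))
  }
  if ("departure" %in% analyses)
    res$departure <- proxy_section(counts$first_mover_count,
                                   den$n_single_first_mover_movements,
                                   seed)
  if ("front" %in% analyses)
    res$front <- proxy_section(counts$front_count,
                               den$n_front_scored_movements, seed + 1L)
  if ("predeparture" %in% analyses)
    res$predeparture <- proxy_section(counts$predeparture_count,
                                      sum(counts$predeparture_count),
                                      seed + 2L)
  if ("joining" %in% analyses) {
    je <- joining_efficiency(single, roster, min_departures = min_departures)
    res$joining <- list(
      groups = je$groups, test_applicable = je$test_applicable,
      mean_duration_s = mean(unlist(lapply(single, function(m)
        m$joining_duration_s)), na.rm = TRUE),
      kruskal_wallis = if (je$test_applicable) kruskal_wallis(je$groups)
      else list(note = "fewer than 2 qualifying first movers"))
  }
  if ("concordance" %in% analyses)
    res$concordance <- concordance(single, roster)
  if ("hierarchy" %in% analyses && any(log$kind == "agonistic")) {
    dm <- build_dominance_matrix(log, roster)
    res$hierarchy <- list(
      matrix = dm,
      linearity = hierarchy_linearity(dm, seed = seed + 3L),
      ranks = rank_individuals(dm)$ranks,
      rank_age = if (!all(is.na(roster$rank))) rank_age_correlation(roster))
  }
  res
}

#' Recompute the analysis from published percentage tables
#'
#' Reproduction mode: instead of raw event logs, start from a published
#' per-individual percentage table and its movement totals (see
#' [group_summary()]), reconstruct the integer tallies with
#' [reconstruct_counts()], and run the same inference layer. The
#' concordance table is rebuilt with the denominators the source table used:
#' pre-departure counts for the forward conditionals and sole-first-mover
#' counts for both retrospective conditionals.
#'
#' @param summary a list shaped like [group_summary()] output: `roster`,
#'   `percentages`, `totals`.
#' @param B,alpha,seed as in [run_pipeline()].
#' @return A structured results list with a provenance note that inputs were
#'   summary-derived.
#' @export
run_from_summary <- function(summary, B = 2000L, alpha = 0.05, seed = 1L) {
  ros <- summary$roster
  pct <- summary$percentages
  tot <- summary$totals
  n_single <- tot$single_first_mover

  dep <- reconstruct_counts(pct$departed_first, n_single, n_single)
  # front percentages may be over the front-scored count or over the
  # single-first-mover count depending on the group; the reconstruction
  # disambiguates, the counts must sum to the front-scored total
  front <- reconstruct_counts(pct$front,
                              unique(c(tot$front_scored, n_single)),
                              tot$front_scored)
  pre <- reconstruct_counts(pct$predeparture, n_single)

  section <- function(counts, n, sub_seed) {
    list(counts = counts,
         g_test = mc_uniform_test(counts, B = B, seed = sub_seed),
         posthoc = posthoc_chance_tests(counts, n = n, alpha = alpha,
                                        ids = ros$id),
         age_correlation = spearman_test(ros$age_years, counts))
  }
  res <- list(
    manifest = list(group_id = attr(ros, "group_id"),
                    provenance = "summary-derived (published percentages)",
                    B = as.integer(B), alpha = alpha,
                    seed = as.integer(seed)),
    proxy_counts = structure(list(
      counts = data.frame(id = ros$id,
                          predeparture_count = pre$counts,
                          first_mover_count = dep$counts,
                          front_count = front$counts,
                          stringsAsFactors = FALSE),
      denominators = list(
        n_single_first_mover_movements = n_single,
        n_front_scored_movements = tot$front_scored,
        n_total_movements = tot$total)), class = "proxy_counts"),
    departure = section(dep$counts, n_single, seed),
    front = section(front$counts, tot$front_scored, seed + 1L),
    predeparture = section(pre$counts, sum(pre$counts), seed + 2L),
    proportions = list(
      simultaneous_share = tot$simultaneous_first_movers / tot$total,
      top_first_mover_share = max(dep$counts) / n_single),
    rank_age = if (!all(is.na(ros$rank))) rank_age_correlation(ros))

  to_num <- function(p, d) as.integer(round(p * d / 100))
  res$concordance <- build_concordance(
    ros$id,
    num = list(
      first_after_predep = to_num(pct$first_after_predep, pre$counts),
      front_after_predep = to_num(pct$front_after_predep, pre$counts),
      first_and_front_after_predep =
        to_num(pct$first_and_front_after_predep, pre$counts),
      predep_before_first = to_num(pct$predep_before_first, dep$counts),
      predep_before_front = to_num(pct$predep_before_front, dep$counts)),
    den = list(first_after_predep = pre$counts,
               front_after_predep = pre$counts,
               first_and_front_after_predep = pre$counts,
               predep_before_first = dep$counts,
               predep_before_front = dep$counts))
  res
}
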