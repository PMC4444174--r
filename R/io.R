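#' Read a group roster from CSV
#'
#' The file must be comma-separated with a header and columns `id`, `sex`,
#' `age_years`, `age_class`; a `rank` column is optional. Rows failing
#' validation raise errors naming the offending lines.
#'
#' @param path file path.
#' @param group_id label for the group; defaults to the file name.
#' @return A [roster()].
#' @export
read_roster <- function(path, group_id = tools::file_path_sans_ext(basename(path))) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "sex", "age_years", "age_class")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("roster file lacks columns: ", paste(miss, collapse = ", "))
  roster(id = df$id, sex = df$sex, age_years = df$age_years,
         age_class = df$age_class,
         rank = if ("rank" %in% names(df) && !all(is.na(df$rank))) df$rank,
         group_id = group_id)
}

#' Write a roster to CSV
#'
#' @param x a [roster()].
#' @param path file path.
#' @export
write_roster <- function(x, path) {
  out <- as.data.frame(x)
  if (all(is.na(out$rank))) out$rank <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a behavioural event log from CSV
#'
#' The file must be comma-separated with a header and columns `time_s`,
#' `actor_id`, `kind`, `target_id` (empty target for undirected acts). Events
#' out of time order are sorted with a warning; ill-typed rows are rejected
#' with line-numbered diagnostics.
#'
#' @param path file path.
#' @param roster the [roster()] the log refers to.
#' @param session_id label; defaults to the file name.
#' @return An [event_log()].
#' @export
read_events <- function(path, roster,
                        session_id = tools::file_path_sans_ext(basename(path))) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(target_id = "character"))
  df$target_id[!is.na(df$target_id) & df$target_id == ""] <- NA_character_
  event_log(df, roster, session_id = session_id)
}

#' Write an event log to CSV
#'
#' @param x an [event_log()].
#' @param path file path.
#' @export
write_events <- function(x, path) {
  out <- as.data.frame(x)
  out$target_id[is.na(out$target_id)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write pipeline results to disk
#'
#' Writes a machine-readable JSON report plus, when movements were analysed,
#' CSV tables: per-individual proxy tallies and the concordance table (the
#' conditional percentages linking pre-departure behaviour to subsequent
#' leadership, in the same column layout as the published summary table).
#'
#' @param results a list from [run_pipeline()] or [run_from_summary()].
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(results_to_json(results), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  paths <- c(paths, json_path)
  if (!is.null(results$proxy_counts)) {
    p <- file.path(dir, "proxy_counts.csv")
    utils::write.csv(results$proxy_counts$counts, p, row.names = FALSE,
                     quote = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(results$concordance)) {
    p <- file.path(dir, "concordance.csv")
    utils::write.csv(format_concordance(results$concordance,
                                        results$proxy_counts), p,
                     row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

# Strip classes/attributes so jsonlite serialises plainly and deterministically.
results_to_json <- function(x) {
  if (is.data.frame(x)) {
    x <- as.data.frame(x)
    attr(x, "group_id") <- NULL
    attr(x, "session_id") <- NULL
    return(x)
  }
  if (is.list(x)) return(lapply(unclass(x), results_to_json))
  x
}

# Full summary-table layout: the three marginal percentage columns followed
# by the five conditionals, rounded to 2 decimals; NA cells left blank.
format_concordance <- function(conc, proxy_counts = NULL) {
  tab <- conc$table
  if (!is.null(proxy_counts)) {
    cnt <- proxy_counts$counts
    den <- proxy_counts$denominators
    lead <- data.frame(
      id = cnt$id,
      pct_predeparture =
        100 * cnt$predeparture_count / den$n_single_first_mover_movements,
      pct_departed_first =
        100 * cnt$first_mover_count / den$n_single_first_mover_movements,
      pct_front = 100 * cnt$front_count / den$n_front_scored_movements,
      stringsAsFactors = FALSE)
    tab <- merge(lead, tab, by = "id", sort = FALSE)
  }
  pct <- grep("^pct_", names(tab), value = TRUE)
  for (col in pct) tab[[col]] <- ifelse(is.na(tab[[col]]), "",
                                        sprintf("%.2f", tab[[col]]))
  tab
}
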