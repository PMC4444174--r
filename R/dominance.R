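#' Build a dominance matrix from agonistic interactions
#'
#' Accumulates a square win matrix from agonistic events (actor = winner,
#' target = loser). Dyads with wins in both directions are reported: a
#' hierarchy assessed from unidirectional interactions should have few or
#' none.
#'
#' @param log an [event_log()].
#' @param roster the group [roster()].
#' @return A list of class `"dominance_matrix"`: `wins` (N x N integer
#'   matrix, rows beat columns) and `bidirectional_dyads` (data frame of
#'   dyads with wins both ways).
#' @export
build_dominance_matrix <- function(log, roster) {
  ids <- roster$id
  n <- length(ids)
  wins <- matrix(0L, n, n, dimnames = list(ids, ids))
  ag <- log[log$kind == "agonistic", , drop = FALSE]
  if (nrow(ag)) {
    if (anyNA(ag$target_id)) stop("agonistic event without target_id")
    tab <- table(factor(ag$actor_id, ids), factor(ag$target_id, ids))
    wins <- wins + unclass(tab)
    storage.mode(wins) <- "integer"
  }
  bidir <- which(wins > 0 & t(wins) > 0 & upper.tri(wins), arr.ind = TRUE)
  bd <- data.frame(id_a = ids[bidir[, 1]], id_b = ids[bidir[, 2]],
                   wins_ab = wins[bidir], wins_ba = t(wins)[bidir],
                   stringsAsFactors = FALSE)
  structure(list(wins = wins, bidirectional_dyads = bd),
            class = "dominance_matrix")
}

# Per-individual counts of dominated members (strict majority of wins) and
# unknown/tied dyads, from a raw win matrix.
dominance_digraph <- function(wins) {
  n <- nrow(wins)
  dominated <- numeric(n)
  unknown <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (wins[i, j] > wins[j, i]) dominated[i] <- dominated[i] + 1
    else if (wins[i, j] == wins[j, i]) unknown[i] <- unknown[i] + 0.5
  }
  # unknown[i] counted 0.5 per side above; rescale to dyads per individual
  list(dominated = dominated, unknown_dyads_per_ind = unknown * 2,
       n_unknown = sum(unknown))
}

# Landau linearity index from dominated/unknown counts; each unknown or tied
# dyad contributes its expectation of half a win to both members.
landau_h <- function(dominated, unknown_per_ind) {
  n <- length(dominated)
  v <- dominated + 0.5 * unknown_per_ind
  (12 / (n^3 - n)) * sum((v - (n - 1) / 2)^2)
}

#' Linearity of a dominance hierarchy (Landau h, de Vries h')
#'
#' Reduces the win matrix to a dominance digraph by strict majority of wins
#' per dyad (exact ties and never-interacting dyads are unknown). `h` is
#' Landau's linearity index with each unknown dyad contributing its
#' expectation of half a win to both members; `h'` adds de Vries' correction
#' for the binomial variance of randomly directed unknown dyads,
#' `h' = h + 6u / (N^3 - N)` with `u` unknown dyads, so `h' > h` whenever
#' unknowns exist and `h' = h = 1` for a complete transitive hierarchy. The
#' p-value is the right-tail proportion of linearity indices of random
#' tournaments (every dyad directed by a fair coin) at or above the observed
#' `h'`, with the add-one estimator.
#'
#' @param matrix a `"dominance_matrix"` from [build_dominance_matrix()], or a
#'   square win matrix.
#' @param randomizations number of random tournaments (default 10000).
#' @param seed integer seed.
#' @return A list of class `"linearity"`: `h`, `h_prime`, `n_unknown_dyads`,
#'   `p`, `n_randomizations`, `seed`, `N`.
#' @export
hierarchy_linearity <- function(matrix, randomizations = 10000L, seed = 1L) {
  wins <- if (inherits(matrix, "dominance_matrix")) matrix$wins else matrix
  n <- nrow(wins)
  if (n < 3) stop("linearity needs at least 3 individuals")
  dg <- dominance_digraph(wins)
  h <- landau_h(dg$dominated, dg$unknown_dyads_per_ind)
  h_prime <- h + 6 * dg$n_unknown / (n^3 - n)
  set.seed(seed)
  npairs <- n * (n - 1) / 2
  h_rand <- numeric(randomizations)
  iu <- which(upper.tri(wins), arr.ind = TRUE)
  for (b in seq_len(randomizations)) {
    up <- stats::runif(npairs) < 0.5
    v <- tabulate(c(iu[up, 1], iu[!up, 2]), nbins = n)
    h_rand[b] <- (12 / (n^3 - n)) * sum((v - (n - 1) / 2)^2)
  }
  p <- (1 + sum(h_rand >= h_prime - 1e-12)) / (randomizations + 1)
  structure(list(h = h, h_prime = h_prime, n_unknown_dyads = dg$n_unknown,
                 p = p, n_randomizations = as.integer(randomizations),
                 seed = as.integer(seed), N = n),
            class = "linearity")
}

#' @export
print.linearity <- function(x, ...) {
  cat(sprintf("Hierarchy linearity: h = %.3f, h' = %.3f (%g unknown dyads), p = %.4g\n",
              x$h, x$h_prime, x$n_unknown_dyads, x$p))
  invisible(x)
}

# Number of dyads whose majority direction contradicts an order (earlier
# position should dominate later).
order_inconsistencies <- function(wins, ord) {
  n <- length(ord)
  m <- wins[ord, ord, drop = FALSE]
  sum(m[lower.tri(m)] > t(m)[lower.tri(m)])
}

#' Order individuals into a dominance rank
#'
#' Deterministic local-search heuristic: individuals start ordered by number
#' of dominated members (descending, ties by total wins then id); the order
#' is then refined by first-improvement passes over all pairwise swaps and
#' single-individual relocations until no move reduces the number of dyads
#' inconsistent with the order. Rank 1 is the top individual. An all-zero
#' matrix yields ranks in id order with a degeneracy warning.
#'
#' @param matrix a `"dominance_matrix"` or square win matrix.
#' @return A list: `ranks` (named integer vector, 1 = top), `order` (ids top
#'   to bottom), `inconsistencies`.
#' @export
rank_individuals <- function(matrix) {
  wins <- if (inherits(matrix, "dominance_matrix")) matrix$wins else matrix
  n <- nrow(wins)
  stopifnot(n >= 2)
  ids <- rownames(wins)
  if (is.null(ids)) ids <- sprintf("ind%02d", seq_len(n))
  if (all(wins == 0))
    warning("no agonistic wins: ranks are degenerate (id order)")
  dg <- dominance_digraph(wins)
  ord <- order(-dg$dominated, -rowSums(wins), ids)
  cost <- order_inconsistencies(wins, ord)
  repeat {
    improved <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      cand <- ord
      cand[c(i, j)] <- cand[c(j, i)]
      cc <- order_inconsistencies(wins, cand)
      if (cc < cost) {
        ord <- cand; cost <- cc; improved <- TRUE
      }
    }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      cand <- append(ord[-i], ord[i], after = j - 1)
      cc <- order_inconsistencies(wins, cand)
      if (cc < cost) {
        ord <- cand; cost <- cc; improved <- TRUE
      }
    }
    if (!improved) break
  }
  ranks <- stats::setNames(match(seq_len(n), ord), ids)
  list(ranks = ranks, order = ids[ord], inconsistencies = cost)
}

#' Correlation between dominance rank and age
#'
#' Tie-aware Spearman correlation (see [spearman_test()]) between the
#' roster's dominance ranks and ages. With rank 1 the top individual and
#' older individuals higher-ranked, the expected sign is negative.
#'
#' @param roster a [roster()] with ranks present.
#' @return As [spearman_test()].
#' @export
rank_age_correlation <- function(roster) {
  if (all(is.na(roster$rank)))
    stop("roster has no dominance ranks")
  spearman_test(roster$rank, roster$age_years)
}
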