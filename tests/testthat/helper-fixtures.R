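# Small in-code fixtures shared across test files.

tiny_roster <- function(n = 12) {
  roster(id = sprintf("h%02d", seq_len(n)),
         sex = rep(c("female", "male"), length.out = n),
         age_years = rev(seq_len(n)),
         rank = seq_len(n), group_id = "tiny")
}

# Event log in which `movers` depart at the given offsets from t0.
departure_log <- function(roster, movers, offsets, t0 = 2000,
                          extra = NULL) {
  ev <- data.frame(time_s = t0 + offsets, actor_id = movers,
                   kind = c("departure", rep("joining", length(movers) - 1)),
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) ev <- rbind(ev, extra)
  event_log(ev[order(ev$time_s), ], roster)
}

# Hand-built movement record, bypassing segmentation.
make_movement <- function(ids, times, first_movers = NULL,
                          predeparture_ids = character(0),
                          front_id = NA_character_, id = "M001") {
  dep <- data.frame(id = ids, time_s = times, stringsAsFactors = FALSE)
  dep <- dep[order(dep$time_s, dep$id), ]
  movelead:::new_collective_movement(
    movement_id = id, departures = dep,
    first_movers = if (is.null(first_movers)) dep$id[1] else first_movers,
    predeparture_ids = predeparture_ids, front_id = front_id,
    joining_duration_s = if (nrow(dep) >= 2) diff(range(dep$time_s)) else NA)
}

# Transitive win matrix: earlier id beats later id `w` times.
transitive_matrix <- function(n, w = 3, ids = sprintf("t%02d", seq_len(n))) {
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- w
  m
}

# Independent brute-force Spearman permutation p-value (used as an oracle):
# recursive enumeration, no shared code with the package internals.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rs <- stats::cor(rx, ry)
  perm_rec <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perm_rec(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  vals <- vapply(perm_rec(seq_along(ry)),
                 function(p) stats::cor(rx, ry[p]), 0)
  list(rs = rs, p = mean(abs(vals) >= abs(rs) - 1e-12))
}

# Direct Kruskal-Wallis H from the textbook rank formula with tie correction.
oracle_kruskal_H <- function(groups) {
  v <- unlist(groups); N <- length(v); r <- rank(v)
  idx <- rep(seq_along(groups), vapply(groups, length, 0L))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, sum)^2 / tapply(r, idx, length)) - 3 * (N + 1)
  ties <- table(v)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}
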