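test_that("the win matrix accumulates agonistic events and flags bidirectional dyads", {
  ros <- tiny_roster(4)
  empty <- build_dominance_matrix(
    event_log(data.frame(time_s = 1, actor_id = "h01", kind = "departure"),
              ros), ros)
  expect_true(all(empty$wins == 0))
  expect_equal(nrow(empty$bidirectional_dyads), 0)

  ev <- data.frame(
    time_s = 1:5,
    actor_id = c("h01", "h01", "h01", "h02", "h01"),
    kind = "agonistic",
    target_id = c("h02", "h02", "h02", "h01", "h03"),
    stringsAsFactors = FALSE)
  dm <- build_dominance_matrix(event_log(ev, ros), ros)
  expect_equal(dm$wins["h01", "h02"], 3L)
  expect_equal(dm$wins["h02", "h01"], 1L)
  expect_equal(dm$bidirectional_dyads$id_a, "h01")
  expect_equal(dm$bidirectional_dyads$id_b, "h02")

  # a transitive generated hierarchy has no bidirectional dyads
  set.seed(3)
  n <- 6
  ids <- sprintf("h%02d", 1:n)
  wins <- data.frame()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    wins <- rbind(wins, data.frame(time_s = nrow(wins) + 1,
                                   actor_id = ids[i], kind = "agonistic",
                                   target_id = ids[j]))
  dmt <- build_dominance_matrix(event_log(wins, tiny_roster(n)), tiny_roster(n))
  expect_equal(nrow(dmt$bidirectional_dyads), 0)
})

test_that("linearity is 1 for transitive hierarchies and minimal for all-tied ones", {
  lin <- hierarchy_linearity(transitive_matrix(6), randomizations = 2000,
                             seed = 1)
  expect_equal(lin$h, 1)
  expect_equal(lin$h_prime, 1)
  expect_lt(lin$p, 0.05)

  n <- 6
  tied <- matrix(2L, n, n); diag(tied) <- 0L
  lin_t <- hierarchy_linearity(tied, randomizations = 2000, seed = 1)
  expect_equal(lin_t$h, 0)
  expect_equal(lin_t$h_prime, 3 / (n + 1))   # expectation under coin flips
  expect_gt(lin_t$p, 0.5)
  expect_gt(lin_t$h_prime, lin_t$h)          # unknowns always raise h'
})

test_that("h agrees with the direct formula on a circular triad and ignores labels", {
  # 4 individuals: a > b > c > a circular, d beaten by everyone
  m <- matrix(0L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m["a", "b"] <- 2; m["b", "c"] <- 2; m["c", "a"] <- 2
  m["a", "d"] <- 1; m["b", "d"] <- 1; m["c", "d"] <- 1
  v <- c(a = 2, b = 2, c = 2, d = 0)   # dominated counts, by inspection
  h_direct <- (12 / (4^3 - 4)) * sum((v - 3 / 2)^2)
  lin <- hierarchy_linearity(m, randomizations = 500, seed = 2)
  expect_equal(lin$h, h_direct)
  expect_equal(lin$h_prime, h_direct)  # no unknown dyads
  perm <- c(3, 1, 4, 2)
  lin_p <- hierarchy_linearity(m[perm, perm], randomizations = 500, seed = 2)
  expect_equal(lin_p$h, lin$h)
})

test_that("wins consistent with the existing order never decrease h", {
  set.seed(9)
  for (rep in 1:10) {
    n <- 5
    m <- matrix(rpois(n * n, 1), n, n); diag(m) <- 0
    h0 <- hierarchy_linearity(m, randomizations = 10, seed = 1)$h
    # reinforce an already-dominant direction
    won <- which(m > t(m), arr.ind = TRUE)
    if (nrow(won) == 0) next
    pick <- won[sample(nrow(won), 1), ]
    m2 <- m; m2[pick[1], pick[2]] <- m2[pick[1], pick[2]] + 1
    h1 <- hierarchy_linearity(m2, randomizations = 10, seed = 1)$h
    expect_gte(h1, h0 - 1e-12)
  }
})

test_that("rank ordering recovers transitive orders and stays near the optimum", {
  m <- transitive_matrix(6)
  rk <- rank_individuals(m)
  expect_equal(rk$order, rownames(m))
  expect_equal(rk$inconsistencies, 0)
  expect_warning(rank_individuals(matrix(0L, 3, 3,
                                         dimnames = list(letters[1:3],
                                                         letters[1:3]))),
                 "degenerate")

  # exhaustive oracle at N = 6: the heuristic is optimal or within one
  # inconsistency, and optimal in the large majority of random matrices
  perms <- movelead:::all_permutations(6)
  exhaustive_opt <- function(m) {
    min(apply(perms, 2, function(ord)
      movelead:::order_inconsistencies(m, ord)))
  }
  gap <- integer(50)
  for (s in 1:50) {
    set.seed(100 + s)
    m <- matrix(rpois(36, 1.2), 6, 6); diag(m) <- 0
    dimnames(m) <- list(letters[1:6], letters[1:6])
    gap[s] <- rank_individuals(m)$inconsistencies - exhaustive_opt(m)
  }
  expect_true(all(gap <= 1))
  expect_gte(mean(gap == 0), 0.9)
})

test_that("dominance rank correlates negatively with age in both study rosters", {
  bo <- rank_age_correlation(bo_roster())
  expect_equal(bo$rs, -0.96, tolerance = 0.005)
  expect_lt(bo$p, 0.001)
  ad <- rank_age_correlation(ad_roster())
  expect_equal(ad$rs, -0.97, tolerance = 0.005)
  expect_lt(ad$p, 0.05)
  noranks <- roster(id = c("x", "y", "z"), sex = "female",
                    age_years = c(5, 4, 3))
  expect_error(rank_age_correlation(noranks), "rank")
})

test_that("linearity p-values are approximately uniform under random tournaments", {
  set.seed(17)
  n <- 6
  pvals <- replicate(100, {
    dir <- runif(n * (n - 1) / 2) < 0.5
    m <- matrix(0L, n, n)
    ut <- which(upper.tri(m), arr.ind = TRUE)
    for (i in seq_len(nrow(ut))) {
      if (dir[i]) m[ut[i, 1], ut[i, 2]] <- 1L else m[ut[i, 2], ut[i, 1]] <- 1L
    }
    hierarchy_linearity(m, randomizations = 400,
                        seed = sample.int(1e6, 1))$p
  })
  expect_lt(abs(mean(pvals <= 0.5) - 0.5), 0.15)
  expect_lte(mean(pvals <= 0.05), 0.12)
})
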