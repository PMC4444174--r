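test_that("proxy tallies apply the exclusion rules and ignore movement order", {
  ros <- tiny_roster(4)
  mvs <- list(
    make_movement(c("h01", "h02", "h03"), c(0, 50, 100),
                  predeparture_ids = c("h01", "h04"), front_id = "h02"),
    make_movement(c("h01", "h02", "h03"), c(1e4, 1e4, 1e4 + 90),
                  first_movers = c("h01", "h02"),       # simultaneous
                  predeparture_ids = "h02"),
    make_movement(c("h02", "h03", "h04"), c(2e4, 2e4 + 60, 2e4 + 80),
                  predeparture_ids = character(0)))     # no front record
  tal <- tally_proxies(mvs, ros)
  expect_equal(tal$counts$first_mover_count, c(1, 1, 0, 0))  # sim. excluded
  expect_equal(tal$counts$front_count, c(0, 1, 0, 0))
  expect_equal(tal$counts$predeparture_count, c(1, 1, 0, 1))
  expect_equal(tal$denominators$n_single_first_mover_movements, 2)
  expect_equal(tal$denominators$n_front_scored_movements, 1)
  expect_equal(tal$denominators$n_total_movements, 3)
  tal_rev <- tally_proxies(rev(mvs), ros)
  expect_equal(tal_rev$counts, tal$counts)
})

test_that("tallies equal the generator's own bookkeeping", {
  g <- generate_events(synthetic_preset("bo_like", seed = 11))
  mv <- segment_movements(g$log, bo_roster())
  tal <- tally_proxies(mv, bo_roster())
  truth_fm <- table(factor(unlist(lapply(
    g$truth, function(tr) if (length(tr$first_movers) == 1) tr$first_movers)),
    levels = bo_roster()$id))
  truth_pre <- table(factor(unlist(lapply(g$truth, `[[`, "predeparture_ids")),
                            levels = bo_roster()$id))
  truth_front <- table(factor(unlist(lapply(
    g$truth, function(tr) if (!is.na(tr$front_id)) tr$front_id)),
    levels = bo_roster()$id))
  expect_equal(tal$counts$first_mover_count, as.vector(truth_fm))
  expect_equal(tal$counts$predeparture_count, as.vector(truth_pre))
  expect_equal(tal$counts$front_count, as.vector(truth_front))
})

test_that("concordance conditionals are counted per movement with NA for empty denominators", {
  ros <- tiny_roster(4)
  # h01 displays 5 times, departs first (sole) after 4 of them
  mvs <- lapply(1:5, function(i)
    make_movement(c(if (i < 5) "h01" else "h02", "h03", "h04"),
                  c(0, 60, 120) + i * 1e4,
                  predeparture_ids = "h01"))
  conc <- concordance(mvs, ros)
  tab <- conc$table
  expect_equal(tab$pct_first_after_predep[tab$id == "h01"], 80)
  expect_equal(tab$num_first_after_predep[tab$id == "h01"], 4)
  expect_equal(tab$pct_predep_before_first[tab$id == "h01"], 100)
  # h02 was a first mover without displaying: retrospective 0, forward NA
  expect_equal(tab$pct_predep_before_first[tab$id == "h02"], 0)
  expect_true(is.na(tab$pct_first_after_predep[tab$id == "h02"]))
  # h03 was never a sole first mover: retrospective undefined
  expect_true(is.na(tab$pct_predep_before_first[tab$id == "h03"]))
  # forward numerators can never exceed their denominators
  g <- generate_events(synthetic_preset("bo_like", n_movements = 60, seed = 13))
  cg <- concordance(segment_movements(g$log, bo_roster()), bo_roster())
  for (col in c("first_after_predep", "front_after_predep",
                "predep_before_first", "predep_before_front"))
    expect_true(all(cg$table[[paste0("num_", col)]] <=
                      cg$table[[paste0("den_", col)]]))
  # column means reproduce their stored numerators/denominators
  s <- cg$summary
  for (i in seq_len(nrow(s))) {
    v <- cg$table[[paste0("pct_", s$column[i])]]
    expect_equal(s$mean[i], mean(v[!is.na(v)]))
  }
})

test_that("generator coupling controls how often first movers displayed beforehand", {
  cfg1 <- synthetic_config(bo_roster(), n_movements = 150, coupling = 1,
                           predeparture_rates = 0.3, simultaneity_prob = 0,
                           seed = 31)
  mv1 <- segment_movements(generate_events(cfg1)$log, bo_roster())
  c1 <- concordance(mv1, bo_roster())$table
  retro <- c1$pct_predep_before_first
  expect_true(all(retro[!is.na(retro)] == 100))
  cfg0 <- synthetic_config(bo_roster(), n_movements = 400, coupling = 0,
                           predeparture_rates = 0.3, simultaneity_prob = 0,
                           seed = 32)
  mv0 <- segment_movements(generate_events(cfg0)$log, bo_roster())
  c0 <- concordance(mv0, bo_roster())
  pooled <- sum(c0$table$num_predep_before_first) /
    sum(c0$table$den_predep_before_first)
  expect_lt(abs(pooled - 0.3), 3 * sqrt(0.3 * 0.7 / 400))
})

test_that("joining-efficiency grouping applies the qualifying threshold", {
  ros <- tiny_roster(4)
  mk <- function(first, i) make_movement(c(first, setdiff(ros$id, first)[1:2]),
                                         c(0, 100, 200) + i * 1e4)
  mvs <- c(lapply(1:4, function(i) mk("h01", i)),
           lapply(5:7, function(i) mk("h02", i)),
           lapply(8:9, function(i) mk("h03", i)))
  je <- joining_efficiency(mvs, ros)
  expect_named(je$groups, c("h01", "h02"))
  expect_true(je$test_applicable)
  expect_equal(lengths(je$groups), c(h01 = 4L, h02 = 3L))
  je1 <- joining_efficiency(mvs, ros, min_departures = 1)
  expect_named(je1$groups, c("h01", "h02", "h03"))
  je9 <- joining_efficiency(mvs, ros, min_departures = 9)
  expect_false(je9$test_applicable)
})

test_that("integer counts are recoverable from printed percentages", {
  bo <- group_summary("BO")
  dep <- reconstruct_counts(bo$percentages$departed_first, 28L, 28L)
  expect_equal(dep$counts, c(6, 2, 11, 0, 8, 0, 1, 0, 0, 0, 0, 0))
  expect_equal(dep$chosen_denominator, 28L)
  ad <- group_summary("AD")
  front <- reconstruct_counts(ad$percentages$front, c(21L, 35L), 21L)
  expect_equal(front$counts, c(1, 5, 4, 11, 0, 0))
  expect_equal(front$chosen_denominator, 35L)
  # the wrong denominator is rejected on residuals
  expect_error(reconstruct_counts(ad$percentages$front, 21L), "residuals")
  # a zero column is ambiguous without an expected total
  expect_error(reconstruct_counts(rep(0, 5), c(10L, 20L)), "ambiguous")
  z <- reconstruct_counts(rep(0, 5), c(10L, 20L), expected_total = 0L)
  expect_equal(z$counts, rep(0L, 5))
  # reconstruction then recomputation reproduces the input to 2 decimals
  for (col in c("predeparture", "departed_first")) {
    rec <- reconstruct_counts(bo$percentages[[col]], 28L)
    expect_equal(round(100 * rec$counts / 28, 2), bo$percentages[[col]],
                 tolerance = 5e-3)
  }
})
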