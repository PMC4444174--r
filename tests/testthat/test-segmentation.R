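test_that("the participation threshold separates movements from partial departures", {
  ros <- tiny_roster(12)
  log6 <- departure_log(ros, sprintf("h%02d", 1:6), seq(0, 250, by = 50))
  expect_length(segment_movements(log6, ros), 1)          # 6 = ceiling(0.5*12)
  log5 <- departure_log(ros, sprintf("h%02d", 1:5), seq(0, 200, by = 50))
  expect_length(segment_movements(log5, ros), 0)
  # tightening the participation fraction never increases the movement count
  g <- generate_events(synthetic_preset("bo_like", n_movements = 20, seed = 21))
  fracs <- c(0.3, 0.5, 0.7, 0.9, 1)
  counts <- vapply(fracs, function(f)
    length(segment_movements(g$log, bo_roster(),
                             segmentation_params(participation_fraction = f))),
    0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("simultaneous first movers are bounded by the window, inclusively", {
  ros <- tiny_roster(12)
  p <- segmentation_params(simultaneity_window_s = 10)
  mv <- make_movement(sprintf("h%02d", 1:6), c(0, 4, 120, 130, 140, 150))
  expect_equal(detect_first_movers(mv, p), c("h01", "h02"))
  mv2 <- make_movement(sprintf("h%02d", 1:6), c(0, 11, 120, 130, 140, 150))
  expect_equal(detect_first_movers(mv2, p), "h01")
  mv3 <- make_movement(sprintf("h%02d", 1:6), c(0, 10, 120, 130, 140, 150))
  expect_equal(detect_first_movers(mv3, p), c("h01", "h02"))
  # invariant to permuting equal-timestamp departure records
  mv4 <- make_movement(c("h03", "h01", "h02"), c(0, 0, 300))
  mv5 <- make_movement(c("h01", "h03", "h02"), c(0, 0, 300))
  expect_identical(detect_first_movers(mv4, p), detect_first_movers(mv5, p))
})

test_that("the pre-departure window is half-open at the departure instant", {
  ros <- tiny_roster(4)
  mk <- function(offset) {
    extra <- data.frame(time_s = 2000 + offset, actor_id = "h04",
                        kind = "stay_peripheral", stringsAsFactors = FALSE)
    log <- departure_log(ros, c("h01", "h02"), c(0, 100), extra = extra)
    mv <- segment_movements(log, ros)[[1]]
    mv$predeparture_ids
  }
  expect_equal(mk(-1), "h04")              # inside the window
  expect_equal(mk(-1200), "h04")           # window start included
  expect_equal(mk(0), character(0))        # the departure instant is excluded
  expect_equal(mk(-1201), character(0))    # before the window
})

test_that("joining duration is the first-to-last departure interval, NA for lone departures", {
  expect_equal(joining_duration(make_movement(c("a", "b"), c(0, 300))), 300)
  expect_equal(joining_duration(make_movement(c("a", "b", "c"), c(5, 5, 5))), 0)
  expect_true(is.na(joining_duration(make_movement("a", 0))))
})

test_that("front position requires a unique record near mid-travel", {
  ros <- tiny_roster(4)
  front_rows <- function(ids, times)
    data.frame(time_s = times, actor_id = ids, kind = "front",
               stringsAsFactors = FALSE)
  log1 <- departure_log(ros, c("h01", "h02"), c(0, 400),
                        extra = front_rows("h02", 2200))
  mv1 <- segment_movements(log1, ros)[[1]]
  expect_equal(mv1$front_id, "h02")
  # two abreast at the closest record: excluded
  log2 <- departure_log(ros, c("h01", "h02"), c(0, 400),
                        extra = front_rows(c("h01", "h02"), c(2200, 2200)))
  expect_true(is.na(segment_movements(log2, ros)[[1]]$front_id))
  # no record at all
  log3 <- departure_log(ros, c("h01", "h02"), c(0, 400))
  expect_true(is.na(segment_movements(log3, ros)[[1]]$front_id))
})

test_that("group pauses followed by resumption split a movement into bouts", {
  ros <- tiny_roster(4)
  base <- data.frame(time_s = 2000 + c(0, 20, 40), actor_id = c("h01", "h02", "h03"),
                     kind = c("departure", "joining", "joining"),
                     stringsAsFactors = FALSE)
  log1 <- event_log(base, ros)
  mv1 <- segment_movements(log1, ros)[[1]]
  expect_equal(mv1$n_bouts, 1L)
  pause <- data.frame(time_s = 2000 + c(100, 101), actor_id = c("h01", "h02"),
                      kind = "pause", stringsAsFactors = FALSE)
  resume <- data.frame(time_s = 2000 + 300, actor_id = "h04",
                       kind = "joining", stringsAsFactors = FALSE)
  log2 <- event_log(rbind(base, pause, resume), ros)
  mv2 <- segment_movements(log2, ros)[[1]]
  expect_equal(mv2$n_bouts, 2L)
  # a pause by too few movers does not open a bout
  solo_pause <- data.frame(time_s = 2000 + 100, actor_id = "h01",
                           kind = "pause", stringsAsFactors = FALSE)
  log3 <- event_log(rbind(base, solo_pause, resume), ros)
  expect_equal(segment_movements(log3, ros)[[1]]$n_bouts, 1L)
})

test_that("segmentation recovers the generator's ground truth record for record", {
  g <- generate_events(synthetic_preset("bo_like", seed = 7))
  mv <- segment_movements(g$log, bo_roster())
  expect_length(mv, 42)
  expect_true(all(mapply(function(m, tr)
    identical(m$first_movers, tr$first_movers), mv, g$truth)))
  expect_true(all(mapply(function(m, tr)
    identical(m$predeparture_ids, tr$predeparture_ids), mv, g$truth)))
  expect_true(all(mapply(function(m, tr)
    identical(m$front_id, tr$front_id), mv, g$truth)))
  expect_equal(vapply(mv, joining_duration, 0),
               vapply(g$truth, function(tr) tr$joining_duration_s, 0),
               tolerance = 1e-9)
  # every departure event belongs to exactly one movement
  dep_total <- sum(g$log$kind %in% c("departure", "joining"))
  expect_equal(sum(vapply(mv, function(m) nrow(m$departures), 0L)), dep_total)

  cfg <- synthetic_preset("bo_like", seed = 3)
  cfg$two_bout_prob <- 0.3
  gb <- generate_events(cfg)
  mvb <- segment_movements(gb$log, bo_roster())
  expect_equal(vapply(mvb, function(m) m$n_bouts, 0L),
               vapply(gb$truth, function(tr) tr$n_bouts, 0L))
  expect_true(any(vapply(mvb, function(m) m$n_bouts, 0L) == 2L))
})

test_that("pre-departure participation frequencies track the generating probabilities", {
  rates <- c(0.8, 0.6, 0.4, 0.2, 0.1, 0.05, rep(0.3, 6))
  cfg <- synthetic_config(bo_roster(), n_movements = 500,
                          predeparture_rates = rates, coupling = 0,
                          simultaneity_prob = 0, seed = 5)
  g <- generate_events(cfg)
  mv <- segment_movements(g$log, bo_roster())
  tal <- tally_proxies(mv, bo_roster())
  freq <- tal$counts$predeparture_count / length(mv)
  se <- sqrt(rates * (1 - rates) / length(mv))
  expect_true(all(abs(freq - rates) <= 3 * se + 1e-9))
})
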