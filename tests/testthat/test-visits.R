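test_that("runs of labels become visits; zero threshold keeps all runs", {
  zt <- labelled_track(data.frame(zone = c("A", "B", "A"), dur = c(2, 3, 2)))
  v <- extract_visits(zt, min_dwell = 0)
  expect_equal(v$zone_id, c("A", "B", "A"))
  expect_equal(v$t_enter, c(0, 2, 5))
  expect_equal(v$t_exit, c(2, 5, 7))
  expect_equal(attr(v, "session_length"), 7)
})

test_that("sub-threshold runs merge into the flanking visit", {
  zt <- labelled_track(data.frame(zone = c("A", "B", "A"), dur = c(2, 0.1, 2)))
  v <- extract_visits(zt, min_dwell = 0.2)
  expect_equal(v$zone_id, "A")
  expect_equal(v$t_exit - v$t_enter, 4.1)
  # different flanks: short run joins the preceding visit
  zt2 <- labelled_track(data.frame(zone = c("A", "B", "C"), dur = c(2, 0.1, 2)))
  v2 <- extract_visits(zt2, min_dwell = 0.2)
  expect_equal(v2$zone_id, c("A", "C"))
  expect_equal(v2$t_exit[1L], 2.1)
})

test_that("'none' runs are absorbed into the preceding visit", {
  zt <- labelled_track(data.frame(zone = c("A", "none", "B"), dur = c(1, 0.5, 1)))
  v <- extract_visits(zt, min_dwell = 0)
  expect_equal(v$zone_id, c("A", "B"))
  expect_equal(v$t_exit - v$t_enter, c(1.5, 1))
  # all-none track: empty sequence with a warning
  zt2 <- labelled_track(data.frame(zone = "none", dur = 3))
  expect_warning(v2 <- extract_visits(zt2, 0), "no in-zone")
  expect_equal(nrow(v2), 0L)
})

test_that("consecutive visits always differ in zone", {
  set.seed(42)
  for (rep in 1:20) {
    runs <- data.frame(zone = sample(c("A", "B", "C", "none"), 12, replace = TRUE),
                       dur = round(stats::runif(12, 0.1, 1.5), 1))
    zt <- labelled_track(runs)
    v <- suppressWarnings(extract_visits(zt, min_dwell = 0.3))
    if (nrow(v) > 1L) {
      expect_true(all(v$zone_id[-1L] != v$zone_id[-nrow(v)]))
      expect_true(all(v$t_exit > v$t_enter))
      expect_equal(v$t_enter[-1L], v$t_exit[-nrow(v)])
    }
  }
})

test_that("increasing the de-bounce threshold never increases the visit count", {
  set.seed(7)
  for (rep in 1:15) {
    runs <- data.frame(zone = sample(c("A", "B", "C"), 15, replace = TRUE),
                       dur = round(stats::runif(15, 0.1, 2), 1))
    zt <- labelled_track(runs)
    counts <- vapply(c(0, 0.2, 0.5, 1, 2),
                     function(md) nrow(extract_visits(zt, md)), numeric(1L))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("session metrics do direct bookkeeping on a two-zone session", {
  spm <- arena_preset("spm")
  v <- data.frame(subject_id = "s1", session_id = "1",
                  zone_id = c("center", "shallow_1"),
                  t_enter = c(0, 300), t_exit = c(300, 600),
                  stringsAsFactors = FALSE)
  attr(v, "session_length") <- 600
  class(v) <- c("visit_sequence", "data.frame")
  m <- session_metrics(v, NULL, spm)
  z <- m$zones
  expect_equal(z$time_pct[z$zone_id == "center"], 50)
  expect_equal(z$time_pct[z$zone_id == "shallow_1"], 50)
  expect_equal(z$entries[z$zone_id == "center"], 1L)
  expect_equal(z$latency_s[z$zone_id == "shallow_1"], 300)
  # never-entered zones are censored at session length with zero entries
  expect_equal(z$latency_s[z$zone_id == "deep_1"], 600)
  expect_true(z$censored[z$zone_id == "deep_1"])
  expect_equal(z$entries[z$zone_id == "deep_1"], 0L)
})

test_that("entry count zero if and only if latency is censored", {
  spm <- arena_preset("spm")
  sim <- simulate_visits(spm, 6, 120, seed = 11, start_zone = "center")
  for (v in sim$visits) {
    z <- session_metrics(v, NULL, spm)$zones
    expect_equal(z$entries == 0L, z$censored)
    expect_equal(z$latency_s[z$censored],
                 rep(attr(v, "session_length"), sum(z$censored)))
  }
})

test_that("per-zone times sum to the session length", {
  spm <- arena_preset("spm")
  sim <- simulate_visits(spm, 8, 300, seed = 3, start_zone = "center")
  for (v in sim$visits) {
    m <- session_metrics(v, NULL, spm)
    expect_equal(sum(m$zones$time_s), m$overall$session_length,
                 tolerance = 1e-9)
    expect_equal(sum(m$zones$time_pct), 100, tolerance = 1e-9)
  }
})

test_that("mean velocity and immobility come from the raw track", {
  # constant 10 mm/s straight swim for 60 s
  tr <- swim_track("s1", "1", t = seq(0, 60, by = 0.1),
                   x = seq(0, 600, by = 1), y = rep(0, 601))
  v <- data.frame(subject_id = "s1", session_id = "1", zone_id = "chamber_1",
                  t_enter = 0, t_exit = 60.1, stringsAsFactors = FALSE)
  class(v) <- c("visit_sequence", "data.frame")
  m <- session_metrics(v, tr, arena_preset("slalom"), speed_thr = 1)
  expect_equal(m$overall$mean_velocity, 10, tolerance = 1e-9)
  expect_equal(m$overall$immobile_episodes, 0L)

  # 5 s stationary gap in the middle -> exactly one immobile episode
  x2 <- c(seq(0, 100, by = 1), rep(100, 50), seq(101, 200, by = 1))
  tr2 <- swim_track("s1", "1", t = seq_len(length(x2)) / 10, x = x2,
                    y = rep(0, length(x2)))
  m2 <- session_metrics(v, tr2, arena_preset("slalom"),
                        speed_thr = 1, min_immobile = 1)
  expect_equal(m2$overall$immobile_episodes, 1L)
})

test_that("mismatched subject/session ids are rejected", {
  tr <- swim_track("s1", "1", t = c(0, 1), x = c(0, 1), y = c(0, 0))
  v <- data.frame(subject_id = "s2", session_id = "1", zone_id = "chamber_1",
                  t_enter = 0, t_exit = 1, stringsAsFactors = FALSE)
  class(v) <- c("visit_sequence", "data.frame")
  expect_error(session_metrics(v, tr, arena_preset("slalom")), "different")
})

test_that("rendered tracks recover the generating visit sequence at zero de-bounce", {
  spm <- arena_preset("spm")
  sim <- simulate_visits(spm, 3, 60, seed = 21, start_zone = "center",
                         render_tracks = TRUE)
  for (i in seq_along(sim$visits)) {
    zt <- assign_zones(sim$tracks[[i]], spm)
    rec <- extract_visits(zt, min_dwell = 0)
    expect_equal(rec$zone_id, sim$visits[[i]]$zone_id)
  }
})
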