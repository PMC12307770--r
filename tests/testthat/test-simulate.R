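test_that("simulation output is byte-identical under the same seed", {
  spm <- arena_preset("spm")
  s1 <- simulate_visits(spm, 5, 120, seed = 99, subject_sd = 0.3)
  s2 <- simulate_visits(spm, 5, 120, seed = 99, subject_sd = 0.3)
  expect_identical(s1$visits, s2$visits)
  s3 <- simulate_visits(spm, 5, 120, seed = 100, subject_sd = 0.3)
  expect_false(identical(s1$visits, s3$visits))

  y1 <- simulate_ymaze(6, 30, seed = 5)
  y2 <- simulate_ymaze(6, 30, seed = 5)
  expect_identical(y1, y2)

  m1 <- simulate_repeated(0, 1, 1, 10, 3, seed = 2)
  expect_identical(m1, simulate_repeated(0, 1, 1, 10, 3, seed = 2))

  p1 <- simulate_population_values(c(.5, .5), c(0, 5), c(1, 1), 50, seed = 7)
  expect_identical(p1, simulate_population_values(c(.5, .5), c(0, 5), c(1, 1),
                                                  50, seed = 7))
})

test_that("visits tile the session and respect the adjacency graph", {
  spm <- arena_preset("spm")
  sim <- simulate_visits(spm, 6, 200, seed = 31, start_zone = "center")
  adj_ok <- function(a, b) {
    any((spm$adjacency[, 1L] == a & spm$adjacency[, 2L] == b) |
        (spm$adjacency[, 1L] == b & spm$adjacency[, 2L] == a))
  }
  for (v in sim$visits) {
    expect_equal(v$t_enter[1L], 0)
    expect_equal(v$t_exit[nrow(v)], 200)
    expect_equal(v$t_enter[-1L], v$t_exit[-nrow(v)])
    if (nrow(v) > 1L) {
      pairs <- cbind(v$zone_id[-nrow(v)], v$zone_id[-1L])
      expect_true(all(apply(pairs, 1L, function(p) adj_ok(p[1L], p[2L]))))
    }
  }
})

test_that("a neutral walk on the symmetric plus-maze shows no arm-type bias", {
  spm <- arena_preset("spm")
  sim <- simulate_visits(spm, 50, 3600, seed = 17, start_zone = "center",
                         avoidance = 0)
  delta <- vapply(sim$visits, function(v) {
    m <- session_metrics(v, NULL, spm)$zones
    sh <- sum(m$time_pct[m$zone_id %in% c("shallow_1", "shallow_2")])
    dp <- sum(m$time_pct[m$zone_id %in% c("deep_1", "deep_2")])
    sh - dp
  }, numeric(1L))
  expect_lt(abs(mean(delta)), 5)
})

test_that("strong avoidance suppresses aversive-zone occupancy in nearly all subjects", {
  spm <- arena_preset("spm")
  sim <- simulate_visits(spm, 40, 600, seed = 23, start_zone = "center",
                         avoidance = 5, aversive_roles = "shallow_arm")
  less <- vapply(sim$visits, function(v) {
    m <- session_metrics(v, NULL, spm)$zones
    sum(m$time_s[m$zone_id %in% c("shallow_1", "shallow_2")]) <
      sum(m$time_s[m$zone_id %in% c("deep_1", "deep_2")])
  }, logical(1L))
  expect_gte(mean(less), 0.95)
})

test_that("subject random effects create between-subject rate heterogeneity", {
  spm <- arena_preset("spm")
  n_visits <- function(sim) vapply(sim$visits, nrow, numeric(1L))
  flat <- simulate_visits(spm, 20, 300, seed = 5, subject_sd = 0)
  mixed <- simulate_visits(spm, 20, 300, seed = 5, subject_sd = 0.8)
  expect_gt(stats::var(n_visits(mixed)), stats::var(n_visits(flat)))
})

test_that("explorer mixtures shift dwell rates by component", {
  spm <- arena_preset("spm")
  fast <- simulate_visits(spm, 15, 300, seed = 9,
                          mixture = list(weights = 1, rate_multipliers = 4))
  slow <- simulate_visits(spm, 15, 300, seed = 9,
                          mixture = list(weights = 1, rate_multipliers = 0.25))
  expect_gt(mean(vapply(fast$visits, nrow, numeric(1L))),
            mean(vapply(slow$visits, nrow, numeric(1L))))
})

test_that("a disconnected zone graph is rejected", {
  zones <- list(zone_rectangle("a", 0, 1, 0, 1),
                zone_rectangle("b", 2, 3, 0, 1))
  arena <- arena_spec("spm", zones, matrix(character(0), 0, 2),
                      c(a = "center", b = "deep_arm"))
  expect_error(simulate_visits(arena, 2, 10, seed = 1), "disconnected")
})

test_that("Y-maze policies hit their deterministic extremes", {
  alt_pct <- function(seqs) {
    vapply(seqs, function(s) alternation_percent(classify_actions(s)),
           numeric(1L))
  }
  perfect <- simulate_ymaze(5, 40, p_alt = 1, p_direct = 0, seed = 1)
  expect_equal(alt_pct(perfect), rep(100, 5), ignore_attr = TRUE)
  never <- simulate_ymaze(5, 40, p_alt = 0, p_direct = 0, seed = 2)
  expect_equal(alt_pct(never), rep(0, 5), ignore_attr = TRUE)
  stayer <- simulate_ymaze(3, 40, p_alt = 0, p_direct = 1, seed = 3)
  for (s in stayer) expect_true(all(s[-(1:2)] == s[2L]))
  expect_error(simulate_ymaze(2, 10, p_alt = 0.8, p_direct = 0.5, seed = 1),
               "p_alt")
  expect_error(simulate_ymaze(2, 10, p_alt = -0.1, seed = 1), "p_alt")
})

test_that("repeated-measures generator carries its true repeatability", {
  m0 <- simulate_repeated(3, 0, 1, 100, 3, seed = 6)
  expect_equal(attr(m0, "true_R"), 0)
  expect_lt(repeatability(m0, n_boot = 100, seed = 1)$R, 0.15)

  m1 <- simulate_repeated(3, 1, 0, 20, 3, seed = 7)
  expect_equal(attr(m1, "true_R"), 1)
  expect_equal(repeatability(m1, n_boot = 100, seed = 1)$R, 1)

  m <- simulate_repeated(3, 1, 1, 100, 3, seed = 8)
  expect_equal(attr(m, "true_R"), 0.5)
  r <- repeatability(m, n_boot = 100, seed = 1)$R
  expect_gt(r, 0.45); expect_lt(r, 0.55)
})

test_that("a zero-weight component is distributionally inert", {
  x1 <- simulate_population_values(c(1, 0), c(0, 50), c(1, 1), 500, seed = 19)
  x2 <- simulate_population_values(1, 0, 1, 500, seed = 20)
  ks <- suppressWarnings(stats::ks.test(x1, x2))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(abs(x1) < 10))   # nothing drawn from the far component
})
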