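test_that("variance components match the hand-computed one-way ANOVA", {
  m <- rbind(s1 = c(0, 2), s2 = c(4, 6))
  vc <- variance_components(m)
  expect_equal(vc$var_between, 7, tolerance = 1e-12)
  expect_equal(vc$var_within, 2, tolerance = 1e-12)

  # zero residual: subjects constant across sessions
  m2 <- rbind(s1 = c(1, 1), s2 = c(3, 3))
  vc2 <- variance_components(m2)
  expect_equal(vc2$var_within, 0)
  expect_equal(vc2$var_between, 2)

  # identical subject profiles: between-subject variance truncated at 0
  m3 <- rbind(s1 = c(1, 3), s2 = c(1, 3))
  expect_equal(variance_components(m3)$var_between, 0)

  expect_error(variance_components(rbind(c(1, 2))), "2 subjects")
  expect_error(variance_components(rbind(c(1, NA), c(2, NA))), "2 subjects")
})

test_that("unbalanced designs use the k0 coefficient and drop single-session subjects", {
  m <- rbind(s1 = c(0, 2, NA), s2 = c(4, 6, 5), s3 = c(9, NA, NA))
  vc <- variance_components(m)   # s3 contributes no within-subject information
  expect_equal(vc$n_subjects, 2L)
  expect_equal(vc$n_obs, 5L)
  expect_equal(vc$k0, (5 - (4 + 9) / 5) / 1)
})

test_that("repeatability reproduces the hand example and its limits", {
  m <- rbind(s1 = c(0, 2), s2 = c(4, 6))
  r <- repeatability(m, n_boot = 200, seed = 1)
  expect_equal(r$R, 7 / 9, tolerance = 1e-12)
  expect_true(r$ci_low >= 0 && r$ci_high <= 1 && r$ci_low <= r$ci_high)

  # zero within-subject variance with distinct subjects -> R = 1
  m2 <- rbind(s1 = c(1, 1), s2 = c(3, 3))
  expect_equal(repeatability(m2, n_boot = 200, seed = 1)$R, 1)

  # fully degenerate data -> R defined as 0 with a collapsed interval
  m3 <- matrix(5, 3, 2)
  expect_warning(r3 <- repeatability(m3, n_boot = 200, seed = 1), "degenerate")
  expect_equal(r3$R, 0)
  expect_equal(c(r3$ci_low, r3$ci_high), c(0, 0))

  expect_warning(repeatability(m, n_boot = 50, seed = 1), "unstable")
})

test_that("the parametric bootstrap is deterministic under a seed", {
  m <- simulate_repeated(0, 1, 1, 30, 3, seed = 8)
  r1 <- repeatability(m, n_boot = 300, seed = 42)
  r2 <- repeatability(m, n_boot = 300, seed = 42)
  expect_identical(r1$boot_R, r2$boot_R)
  expect_identical(c(r1$ci_low, r1$ci_high), c(r2$ci_low, r2$ci_high))
  r3 <- repeatability(m, n_boot = 300, seed = 43)
  expect_false(identical(r1$boot_R, r3$boot_R))
})

test_that("repeatability is invariant to affine transforms of the endpoint", {
  m <- simulate_repeated(5, 2, 1, 40, 3, seed = 4)
  r <- repeatability(m, n_boot = 100, seed = 1)$R
  r_aff <- repeatability(-3.2 * m + 17, n_boot = 100, seed = 1)$R
  expect_equal(r_aff, r, tolerance = 1e-12)
})

test_that("estimated R grows with the true between-subject share", {
  grid <- c(0.3, 1, 3)
  means <- vapply(seq_along(grid), function(i) {
    mean(vapply(1:30, function(rep) {
      m <- simulate_repeated(0, sqrt(grid[i]), 1, 60, 3,
                             seed = 1000 * i + rep)
      vc <- variance_components(m)
      vc$var_between / (vc$var_between + vc$var_within)
    }, numeric(1L)))
  }, numeric(1L))
  expect_true(all(diff(means) > 0))
})

test_that("ANOVA components agree with the lme4 mixed-model fit on balanced data", {
  m <- simulate_repeated(10, 1.5, 1, 50, 4, seed = 77)
  vc <- variance_components(m)
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(rownames(m), ncol(m))))
  fit <- lme4::lmer(y ~ 1 + (1 | subject), data = df, REML = TRUE)
  vcs <- as.data.frame(lme4::VarCorr(fit))
  expect_equal(vc$var_between, vcs$vcov[vcs$grp == "subject"], tolerance = 1e-4)
  expect_equal(vc$var_within, vcs$vcov[vcs$grp == "Residual"], tolerance = 1e-4)
})

test_that("single and summary measures collapse sessions as documented", {
  m <- rbind(s1 = c(2, 4, 6), s2 = c(5, NA, NA), s3 = c(1, NA, 3))
  expect_equal(summarise_measures(m, "SuM"), c(s1 = 4, s2 = 5, s3 = 2))
  sim <- summarise_measures(m, "SiM")
  expect_equal(sim[["s1"]], 2)
  # subject with no session-1 value is excluded from SiM with a warning
  m2 <- rbind(s1 = c(2, 4), s2 = c(NA, 7))
  expect_warning(s <- summarise_measures(m2, "SiM"), "excluded")
  expect_equal(names(s), "s1")
})

test_that("inter-test correlations recover linear and rank relations", {
  x <- c(-2, -1, 0, 1, 2)
  names(x) <- paste0("s", 1:5)
  y_lin <- 2 * x + 1
  expect_equal(intertest_correlation(x, y_lin, "pearson")$r, 1, tolerance = 1e-12)
  y_cub <- x^3
  expect_equal(intertest_correlation(x, y_cub, "spearman")$r, 1, tolerance = 1e-12)
  expect_lt(intertest_correlation(x, y_cub, "pearson")$r, 1)

  # independent vectors: near-zero correlation at n = 1000
  set.seed(3)
  a <- stats::rnorm(1000); b <- stats::rnorm(1000)
  expect_lt(abs(intertest_correlation(a, b)$r), 0.1)

  expect_error(intertest_correlation(1:2, 2:3), "3 complete pairs")
  expect_warning(r0 <- intertest_correlation(rep(1, 5), stats::rnorm(5)),
                 "zero variance")
  expect_true(is.na(r0$r))
})

test_that("named vectors pair by subject id, not position", {
  x <- c(s1 = 1, s2 = 2, s3 = 3, s4 = 4)
  y <- c(s4 = 8, s3 = 6, s2 = 4, s1 = 2)   # same subjects, reversed order
  expect_equal(intertest_correlation(x, y)$r, 1, tolerance = 1e-12)
})

test_that("long repeated-measures tables reshape to subject x session matrices", {
  df <- data.frame(subject_id = c("a", "a", "b"), session = c(1, 2, 2),
                   value = c(1.5, 2.5, 9))
  m <- repeated_measures_matrix(df)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["a", "2"], 2.5)
  expect_true(is.na(m["b", "1"]))
})
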