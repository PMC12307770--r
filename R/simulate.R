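#' Simulate zone-visit sequences on an arena graph
#'
#' Generates behavior as a continuous-time Markov walk on the arena's zone
#' adjacency graph: the dwell time in zone `z` is exponential with mean
#' `mean_dwell[z]` scaled by a subject-level log-normal multiplier, and the
#' next zone is drawn proportionally to adjacency edge weights. An
#' *avoidance* parameter `a >= 0` makes the zones carrying `aversive_roles`
#' aversive: their mean dwell and their entry weight are both multiplied by
#' `exp(-a)`, so larger `a` means shorter stays in, and rarer entries to,
#' the aversive zones (mimicking shallow-arm / center avoidance).
#'
#' Subject heterogeneity enters through i.i.d. log-normal rate multipliers
#' with standard deviation `subject_sd` on the log scale, optionally mixed
#' over explorer sub-populations (`mixture`), which induces repeatable
#' between-subject differences downstream.
#'
#' @param arena An [arena_spec()] (its adjacency graph must be connected).
#' @param n_subjects Number of subjects.
#' @param session_length Session length in seconds (the last visit is
#'   truncated at it).
#' @param mean_dwell Mean zone dwell in seconds: scalar, or named vector per
#'   zone (default 5 s everywhere).
#' @param avoidance Avoidance strength `a >= 0` (default 0 = neutral walk).
#' @param aversive_roles Roles treated as aversive (default
#'   `c("shallow_arm", "center")` — note `"center"` is aversive only in the
#'   open tank; pass the roles that apply to your arena).
#' @param subject_sd SD of the subject log-normal dwell-rate multiplier
#'   (log scale; 0 = identical subjects).
#' @param mixture Optional explorer mixture: list with `weights` (sums to 1)
#'   and `rate_multipliers` (per-component multiplier on the dwell *rate*,
#'   so a multiplier > 1 is a faster explorer).
#' @param start_zone Zone id where every subject starts (default: first
#'   declared zone).
#' @param seed Master seed (required); subjects get stable sub-seeds.
#' @param session_id Session label stamped on the output (default "1").
#' @param render_tracks Also render each visit sequence to a 30 Hz track
#'   with within-zone positional jitter (slower; default `FALSE`).
#' @param frame_rate Rendering frame rate in Hz.
#' @return List with `visits` (one `visit_sequence` per subject) and, when
#'   rendered, `tracks` (one [swim_track()] per subject).
#' @export
simulate_visits <- function(arena, n_subjects, session_length,
                            mean_dwell = 5, avoidance = 0,
                            aversive_roles = c("shallow_arm", "center"),
                            subject_sd = 0, mixture = NULL,
                            start_zone = NULL, seed,
                            session_id = "1",
                            render_tracks = FALSE, frame_rate = 30) {
  stopifnot(inherits(arena, "arena_spec"), avoidance >= 0, subject_sd >= 0)
  if (missing(seed) || is.null(seed)) stop("`seed` is required", call. = FALSE)
  ids <- zone_ids(arena)
  if (!graph_connected(ids, arena$adjacency)) {
    stop("arena zone graph is disconnected", call. = FALSE)
  }
  dwell <- if (length(mean_dwell) == 1L && is.null(names(mean_dwell))) {
    stats::setNames(rep(mean_dwell, length(ids)), ids)
  } else {
    if (!all(ids %in% names(mean_dwell))) {
      stop("mean_dwell must name every zone", call. = FALSE)
    }
    mean_dwell[ids]
  }
  stopifnot(all(dwell > 0))
  if (!is.null(mixture)) {
    stopifnot(abs(sum(mixture$weights) - 1) < 1e-9,
              length(mixture$weights) == length(mixture$rate_multipliers),
              all(mixture$rate_multipliers > 0))
  }
  aversive <- ids %in% unlist(lapply(
    intersect(aversive_roles, unname(arena$labels)),
    function(r) zones_with_role(arena, r)))
  names(aversive) <- ids
  dwell_eff <- dwell * ifelse(aversive, exp(-avoidance), 1)
  # neighbour lists with entry weights
  nb <- lapply(ids, function(z) {
    e <- arena$adjacency
    nbs <- c(e[e[, 1L] == z, 2L], e[e[, 2L] == z, 1L])
    w <- ifelse(aversive[nbs], exp(-avoidance), 1)
    list(zones = nbs, w = w)
  })
  names(nb) <- ids
  if (is.null(start_zone)) start_zone <- ids[1L]
  stopifnot(start_zone %in% ids)

  seeds <- subject_seeds(seed, n_subjects)
  subj_ids <- sprintf("S%03d", seq_len(n_subjects))
  visits <- vector("list", n_subjects)
  tracks <- if (render_tracks) vector("list", n_subjects) else NULL
  for (i in seq_len(n_subjects)) {
    visits[[i]] <- with_seed(seeds[i], {
      mult <- 1
      if (!is.null(mixture)) {
        comp <- sample.int(length(mixture$weights), 1L, prob = mixture$weights)
        mult <- mult * mixture$rate_multipliers[comp]
      }
      if (subject_sd > 0) mult <- mult * exp(stats::rnorm(1L, 0, subject_sd))
      walk_zones(start_zone, dwell_eff / mult, nb, session_length,
                 subj_ids[i], session_id)
    })
    if (render_tracks) {
      tracks[[i]] <- with_seed(seeds[i] + 1L,
        render_track(visits[[i]], arena, frame_rate = frame_rate))
    }
  }
  names(visits) <- subj_ids
  if (render_tracks) names(tracks) <- subj_ids
  list(visits = visits, tracks = tracks)
}

graph_connected <- function(ids, edges) {
  if (length(ids) <= 1L) return(TRUE)
  seen <- ids[1L]
  repeat {
    nxt <- unique(c(edges[edges[, 1L] %in% seen, 2L],
                    edges[edges[, 2L] %in% seen, 1L]))
    new <- setdiff(nxt, seen)
    if (length(new) == 0L) break
    seen <- c(seen, new)
  }
  length(seen) == length(ids)
}

walk_zones <- function(zone, mean_dwell, nb, session_length,
                       subject_id, session_id) {
  t <- 0
  zs <- character(0L); t0 <- numeric(0L); t1 <- numeric(0L)
  while (t < session_length) {
    d <- stats::rexp(1L, rate = 1 / mean_dwell[[zone]])
    end <- min(t + d, session_length)
    zs <- c(zs, zone); t0 <- c(t0, t); t1 <- c(t1, end)
    t <- end
    if (t >= session_length) break
    nxt <- nb[[zone]]
    zone <- if (length(nxt$zones) == 1L) nxt$zones else
      sample(nxt$zones, 1L, prob = nxt$w)
  }
  out <- data.frame(subject_id = subject_id, session_id = session_id,
                    zone_id = zs, t_enter = t0, t_exit = t1,
                    stringsAsFactors = FALSE)
  attr(out, "session_length") <- session_length
  class(out) <- c("visit_sequence", "data.frame")
  out
}

# Render a visit sequence to a per-frame track: positions are drawn inside
# each visit's zone (smoothed toward random within-zone waypoints, then
# clamped back into the zone), so every sample stays in its generating zone.
render_track <- function(visits, arena, frame_rate = 30, smooth = 0.3) {
  stopifnot(nrow(visits) > 0L)
  dt <- 1 / frame_rate
  tt <- xx <- yy <- numeric(0L)
  pos <- zone_sample_point(arena$zones[[visits$zone_id[1L]]], shrink = 0.05)
  for (v in seq_len(nrow(visits))) {
    zone <- arena$zones[[visits$zone_id[v]]]
    times <- seq(visits$t_enter[v], visits$t_exit[v] - dt / 2, by = dt)
    if (length(times) == 0L) times <- visits$t_enter[v]
    target <- zone_sample_point(zone, shrink = 0.05)
    if (!zone_contains(zone, pos[1L], pos[2L])) {
      pos <- zone_sample_point(zone, shrink = 0.05)
    }
    for (s in seq_along(times)) {
      pos <- pos + smooth * (target - pos)
      if (!zone_contains(zone, pos[1L], pos[2L])) {
        pos <- zone_sample_point(zone, shrink = 0.05)
      }
      tt <- c(tt, times[s]); xx <- c(xx, pos[1L]); yy <- c(yy, pos[2L])
      if (stats::runif(1L) < 0.2) target <- zone_sample_point(zone, shrink = 0.05)
    }
  }
  swim_track(visits$subject_id[1L], visits$session_id[1L],
             t = tt, x = xx, y = yy, frame_rate = frame_rate)
}

#' Simulate Y-maze arm-visit sequences under a parameterized choice policy
#'
#' First two visits are uniform over distinct arms; every later choice is,
#' with probability `p_direct`, a repeat of the current arm (a direct
#' revisit); otherwise, with probability `p_alt`, the arm that completes an
#' alternation (the one differing from both the current and the previous
#' arm), and with the remaining probability a return to the previous arm
#' (an indirect revisit). `p_alt` is conditional on not making a direct
#' revisit. `p_alt = 0.5, p_direct = 0` is the uniform no-stay random-choice
#' policy, whose expected alternation percentage is 50%.
#'
#' @param n_subjects Number of subjects.
#' @param n_visits Visits per subject (`>= 2`).
#' @param p_alt Alternation probability given no direct revisit, in `[0, 1]`.
#' @param p_direct Direct-revisit probability, in `[0, 1]`;
#'   `p_alt + p_direct <= 1` is required.
#' @param seed Master seed (required).
#' @return Named list of character arm sequences over `{A, B, C}`, one per
#'   subject.
#' @examples
#' seqs <- simulate_ymaze(4, 20, p_alt = 1, p_direct = 0, seed = 1)
#' alternation_percent(classify_actions(seqs[[1]]))  # 100
#' @export
simulate_ymaze <- function(n_subjects, n_visits, p_alt = 0.5, p_direct = 0,
                           seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is required", call. = FALSE)
  if (p_alt < 0 || p_alt > 1 || p_direct < 0 || p_direct > 1 ||
      p_alt + p_direct > 1) {
    stop("need p_alt, p_direct in [0, 1] with p_alt + p_direct <= 1",
         call. = FALSE)
  }
  stopifnot(n_visits >= 2L)
  arms <- c("A", "B", "C")
  seeds <- subject_seeds(seed, n_subjects)
  out <- lapply(seq_len(n_subjects), function(i) {
    with_seed(seeds[i], {
      s <- character(n_visits)
      s[1L] <- sample(arms, 1L)
      s[2L] <- sample(setdiff(arms, s[1L]), 1L)
      for (v in seq_len(n_visits - 2L) + 2L) {
        cur <- s[v - 1L]; prev <- s[v - 2L]
        u <- stats::runif(1L)
        s[v] <- if (u < p_direct) {
          cur
        } else if (stats::runif(1L) < p_alt) {
          # arm completing an alternation; when cur == prev (after a direct
          # revisit) both other arms qualify
          other <- setdiff(arms, c(cur, prev))
          if (length(other) == 1L) other else sample(other, 1L)
        } else {
          if (prev != cur) prev else sample(setdiff(arms, cur), 1L)
        }
      }
      s
    })
  })
  names(out) <- sprintf("S%03d", seq_len(n_subjects))
  out
}

#' Simulate repeated measures with known true repeatability
#'
#' Draws from the normal random-intercept model
#' `y_ij = mu + b_i + e_ij`, `b_i ~ N(0, sd_between^2)`,
#' `e_ij ~ N(0, sd_within^2)`, under which the true repeatability is
#' `R = sd_between^2 / (sd_between^2 + sd_within^2)` (attached as attribute
#' `true_R`).
#'
#' @param mu Grand mean.
#' @param sd_between,sd_within Between-/within-subject SDs (`>= 0`).
#' @param n_subjects,k_sessions Design size (`n >= 2`, `k >= 2`).
#' @param seed Master seed (required).
#' @return Numeric `n_subjects x k_sessions` matrix with subject rownames
#'   and attribute `true_R`.
#' @export
simulate_repeated <- function(mu, sd_between, sd_within, n_subjects,
                              k_sessions, seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(sd_between >= 0, sd_within >= 0, n_subjects >= 2L, k_sessions >= 2L)
  m <- with_seed(seed, {
    b <- stats::rnorm(n_subjects, 0, sd_between)
    e <- matrix(stats::rnorm(n_subjects * k_sessions, 0, sd_within),
                n_subjects, k_sessions)
    mu + b + e
  })
  rownames(m) <- sprintf("S%03d", seq_len(n_subjects))
  colnames(m) <- as.character(seq_len(k_sessions))
  tot <- sd_between^2 + sd_within^2
  attr(m, "true_R") <- if (tot > 0) sd_between^2 / tot else 0
  m
}

#' Draw endpoint values from a univariate Gaussian mixture
#'
#' I.i.d. draws from `sum_k weights[k] * N(means[k], sds[k]^2)`, the
#' generating model for unimodal vs bimodal explorer populations used to
#' exercise the modality analysis.
#'
#' @param weights Component weights (sum to 1).
#' @param means,sds Component means and SDs (same length as `weights`).
#' @param n Number of draws.
#' @param seed Master seed (required).
#' @return Numeric vector of length `n`.
#' @export
simulate_population_values <- function(weights, means, sds, n, seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(abs(sum(weights) - 1) < 1e-9, all(weights >= 0),
            length(means) == length(weights), length(sds) == length(weights),
            all(sds >= 0))
  with_seed(seed, {
    comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
    stats::rnorm(n, means[comp], sds[comp])
  })
}
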