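#' Construct and validate a swim track
#'
#' A track is a per-frame record of one subject in one session:
#' `subject_id`, `session_id`, time `t` (s, strictly increasing), and
#' position `x`, `y` (mm).
#'
#' @param subject_id,session_id Identifiers (scalars).
#' @param t Numeric vector of sample times in seconds, strictly increasing.
#' @param x,y Numeric vectors of positions in mm, finite.
#' @param frame_rate Nominal acquisition rate in Hz (default 30, the usual
#'   video convention); used only to close the final sample interval.
#' @return A data.frame of class `swim_track` with attribute `frame_rate`.
#' @export
swim_track <- function(subject_id, session_id, t, x, y, frame_rate = 30) {
  stopifnot(length(t) == length(x), length(t) == length(y))
  if (length(t) < 2L) stop("a track needs at least 2 samples", call. = FALSE)
  if (any(diff(t) <= 0)) stop("track times must be strictly increasing", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("track coordinates must be finite", call. = FALSE)
  }
  out <- data.frame(subject_id = as.character(subject_id),
                    session_id = as.character(session_id),
                    t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                    stringsAsFactors = FALSE)
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("swim_track", "data.frame")
  out
}

track_frame_rate <- function(track) {
  fr <- attr(track, "frame_rate")
  if (is.null(fr)) 30 else fr
}

#' Label every track sample with the zone containing it
#'
#' Containment is decided by the animal's center point. A sample on a shared
#' boundary goes to the first zone in arena declaration order; a sample in no
#' zone is labelled `"none"` (with a warning if it falls outside the arena's
#' bounding box).
#'
#' @param track A [swim_track()] (or data.frame with `t`, `x`, `y`).
#' @param arena An [arena_spec()].
#' @return The track with an added character column `zone`.
#' @export
assign_zones <- function(track, arena) {
  stopifnot(inherits(arena, "arena_spec"))
  if (is.null(track) || nrow(track) == 0L) {
    stop("empty track", call. = FALSE)
  }
  zone <- rep(NA_character_, nrow(track))
  for (zid in names(arena$zones)) {
    hit <- is.na(zone) & zone_contains(arena$zones[[zid]], track$x, track$y)
    zone[hit] <- zid
  }
  if (anyNA(zone)) {
    bb <- arena_bbox(arena)
    outside <- is.na(zone) &
      (track$x < bb[1L] | track$x > bb[2L] | track$y < bb[3L] | track$y > bb[4L])
    if (any(outside)) {
      warning(sum(outside), " sample(s) outside the arena bounding box; labelled 'none'",
              call. = FALSE)
    }
    zone[is.na(zone)] <- "none"
  }
  track$zone <- zone
  track
}

# run-length segments of a zone-labelled track: label, t_start, t_end
track_runs <- function(track) {
  t <- track$t
  dt_last <- if (length(t) >= 2L) t[length(t)] - t[length(t) - 1L] else 1 / track_frame_rate(track)
  ends <- c(t[-1L], t[length(t)] + dt_last)
  r <- rle(track$zone)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  data.frame(zone_id = r$values, t_enter = t[idx_start], t_exit = ends[idx_end],
             stringsAsFactors = FALSE)
}

#' Extract zone visits from a labelled track
#'
#' Runs of identical zone labels become visits. `"none"` runs (tracking gaps,
#' dead space between zones) are absorbed into the preceding visit; leading
#' `"none"` runs, which have no preceding visit, are dropped. Runs shorter
#' than `min_dwell` are treated as tracking flicker and merged into a
#' flanking visit (the preceding one when the two flanks are different
#' zones), shortest first, until every remaining visit lasts at least
#' `min_dwell`. Consecutive visits therefore always differ in zone.
#'
#' @param zone_track Output of [assign_zones()] (needs a `zone` column).
#' @param min_dwell De-bounce threshold in seconds (default 0.2 s, about six
#'   frames at 30 Hz); 0 disables merging.
#' @return A `visit_sequence` data.frame with columns `subject_id`,
#'   `session_id`, `zone_id`, `t_enter`, `t_exit`, and attribute
#'   `session_length` (the time spanned by the visits).
#' @export
extract_visits <- function(zone_track, min_dwell = 0.2) {
  stopifnot(min_dwell >= 0)
  if (is.null(zone_track$zone)) stop("track has no 'zone' column; run assign_zones()", call. = FALSE)
  runs <- track_runs(zone_track)

  # drop leading "none", absorb later "none" into the preceding visit
  while (nrow(runs) > 0L && runs$zone_id[1L] == "none") runs <- runs[-1L, , drop = FALSE]
  if (nrow(runs) == 0L) {
    warning("track has no in-zone samples; empty visit sequence", call. = FALSE)
    return(empty_visits(zone_track))
  }
  keep <- runs$zone_id != "none"
  grp <- cumsum(keep)           # each none run joins the visit before it
  runs <- data.frame(
    zone_id = runs$zone_id[keep],
    t_enter = tapply(runs$t_enter, grp, min)[as.character(seq_len(sum(keep)))],
    t_exit = tapply(runs$t_exit, grp, max)[as.character(seq_len(sum(keep)))],
    stringsAsFactors = FALSE)
  runs <- coalesce_runs(runs)

  # de-bounce: merge sub-threshold runs, shortest first
  repeat {
    if (nrow(runs) <= 1L) break
    dur <- runs$t_exit - runs$t_enter
    short <- which(dur < min_dwell)
    if (length(short) == 0L) break
    i <- short[which.min(dur[short])]
    if (i == 1L) {
      runs$zone_id[1L] <- runs$zone_id[2L]          # merge into following
    } else {
      runs$zone_id[i] <- runs$zone_id[i - 1L]       # merge into preceding
    }
    runs <- coalesce_runs(runs)
  }

  out <- data.frame(subject_id = zone_track$subject_id[1L],
                    session_id = zone_track$session_id[1L],
                    zone_id = runs$zone_id,
                    t_enter = unname(runs$t_enter),
                    t_exit = unname(runs$t_exit),
                    stringsAsFactors = FALSE)
  attr(out, "session_length") <- out$t_exit[nrow(out)] - out$t_enter[1L]
  class(out) <- c("visit_sequence", "data.frame")
  out
}

empty_visits <- function(zone_track) {
  out <- data.frame(subject_id = character(0L), session_id = character(0L),
                    zone_id = character(0L), t_enter = numeric(0L),
                    t_exit = numeric(0L), stringsAsFactors = FALSE)
  attr(out, "session_length") <- 0
  class(out) <- c("visit_sequence", "data.frame")
  out
}

# merge adjacent runs with identical labels
coalesce_runs <- function(runs) {
  if (nrow(runs) <= 1L) return(runs)
  new_grp <- cumsum(c(TRUE, runs$zone_id[-1L] != runs$zone_id[-nrow(runs)]))
  data.frame(
    zone_id = runs$zone_id[!duplicated(new_grp)],
    t_enter = as.numeric(tapply(runs$t_enter, new_grp, min)),
    t_exit = as.numeric(tapply(runs$t_exit, new_grp, max)),
    stringsAsFactors = FALSE)
}

#' Per-session occupancy and kinematic metrics
#'
#' Computes, for every zone of the arena, the total time (s and % of
#' session), the number of entries, and the first-entry latency (censored at
#' the session length when the zone was never entered), plus overall mean
#' velocity (whole-session path length over elapsed time, immobile periods
#' included) and the number of immobile episodes (maximal runs of speed below
#' `speed_thr` lasting at least `min_immobile`).
#'
#' @param visits A [extract_visits()] result.
#' @param track The matching [swim_track()] (same subject and session); may
#'   be `NULL`, in which case velocity/immobility are `NA`.
#' @param arena The [arena_spec()] defining the zone universe.
#' @param speed_thr Immobility speed threshold, mm/s (default 1).
#' @param min_immobile Minimum immobile-episode duration, s (default 1).
#' @return A list with `zones` (data.frame: `zone_id`, `time_s`, `time_pct`,
#'   `entries`, `latency_s`, `censored`) and `overall` (list:
#'   `session_length`, `mean_velocity`, `immobile_episodes`).
#' @export
session_metrics <- function(visits, track = NULL, arena, speed_thr = 1,
                            min_immobile = 1) {
  stopifnot(inherits(arena, "arena_spec"))
  if (!is.null(track) && nrow(visits) > 0L) {
    if (track$subject_id[1L] != visits$subject_id[1L] ||
        track$session_id[1L] != visits$session_id[1L]) {
      stop("track and visits are from different subject/session", call. = FALSE)
    }
  }
  sl <- attr(visits, "session_length")
  if (is.null(sl)) sl <- if (nrow(visits)) visits$t_exit[nrow(visits)] - visits$t_enter[1L] else 0
  ids <- zone_ids(arena)
  dur <- visits$t_exit - visits$t_enter
  t0 <- if (nrow(visits)) visits$t_enter[1L] else 0
  zones <- data.frame(zone_id = ids, stringsAsFactors = FALSE)
  zones$time_s <- vapply(ids, function(z) sum(dur[visits$zone_id == z]), numeric(1L))
  zones$time_pct <- if (sl > 0) 100 * zones$time_s / sl else rep(0, length(ids))
  zones$entries <- vapply(ids, function(z) sum(visits$zone_id == z), integer(1L))
  zones$latency_s <- vapply(ids, function(z) {
    i <- which(visits$zone_id == z)
    if (length(i)) visits$t_enter[i[1L]] - t0 else sl
  }, numeric(1L))
  zones$censored <- zones$entries == 0L
  rownames(zones) <- NULL

  overall <- list(session_length = sl, mean_velocity = NA_real_,
                  immobile_episodes = NA_integer_)
  if (!is.null(track) && nrow(track) >= 2L) {
    dt <- diff(track$t)
    step <- sqrt(diff(track$x)^2 + diff(track$y)^2)
    elapsed <- track$t[nrow(track)] - track$t[1L]
    overall$mean_velocity <- sum(step) / elapsed
    speed <- step / dt
    slow <- speed < speed_thr
    r <- rle(slow)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ep_dur <- track$t[pmin(ends + 1L, nrow(track))] - track$t[starts]
    overall$immobile_episodes <- sum(r$values & ep_dur >= min_immobile)
  }
  list(zones = zones, overall = overall)
}
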