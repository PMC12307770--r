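#' Mean transition latency (MTL)
#'
#' Slalom-style exploration endpoint: per-chamber first-entry latencies are
#' min-max scaled across the analysis population (chamber by chamber), then
#' averaged over chambers within subject, giving a value in `[0, 1]` (0 =
#' fastest explorer of the population in every chamber). Missing entries must
#' be censored at the session length before calling (use
#' [session_metrics()], which does this).
#'
#' A chamber whose latency is identical for every subject carries no
#' population information and is scaled to 0 for everyone, so the average
#' stays defined.
#'
#' @param latencies Numeric matrix, subjects x chambers, of first-entry
#'   latencies in seconds (rownames = subject ids). `NA` cells are replaced
#'   by `session_length` (censoring).
#' @param session_length Session length in seconds used for censoring.
#' @return Named numeric vector of per-subject MTL values in `[0, 1]`.
#' @export
mean_transition_latency <- function(latencies, session_length = NULL) {
  latencies <- as.matrix(latencies)
  if (nrow(latencies) < 2L) {
    stop("mean transition latency needs at least 2 subjects (population scaling)",
         call. = FALSE)
  }
  if (anyNA(latencies)) {
    if (is.null(session_length)) {
      stop("latencies contain NA; supply `session_length` for censoring",
           call. = FALSE)
    }
    latencies[is.na(latencies)] <- session_length
  }
  scaled <- apply(latencies, 2L, scale_minmax)
  stats::setNames(rowMeans(scaled), rownames(latencies))
}

#' Slalom success rate
#'
#' Percent of subjects that reached the final chamber at least once during
#' the session.
#'
#' @param visits A `visit_sequence` data.frame covering one or more subjects
#'   (column `subject_id`), or a list of them.
#' @param final_zone Zone id of the last chamber (e.g. `"chamber_12"`).
#' @param subjects Optional character vector of all subjects in the batch
#'   (defaults to those present in `visits`); subjects with no visits count
#'   as failures.
#' @param arena Optional [arena_spec()]; when given, `final_zone` must be one
#'   of its zones.
#' @return Percent in `[0, 100]`.
#' @export
success_rate <- function(visits, final_zone, subjects = NULL, arena = NULL) {
  if (is.list(visits) && !is.data.frame(visits)) {
    visits <- do.call(rbind, lapply(visits, as.data.frame))
  }
  if (!is.null(arena) && !final_zone %in% zone_ids(arena)) {
    stop("unknown final zone id: ", final_zone, call. = FALSE)
  }
  if (is.null(subjects)) subjects <- unique(visits$subject_id)
  if (length(subjects) < 1L) stop("no subjects", call. = FALSE)
  reached <- unique(visits$subject_id[visits$zone_id == final_zone])
  100 * sum(subjects %in% reached) / length(subjects)
}

#' Anxiety score from aversive-zone activity
#'
#' Avoidance endpoint for the swimming plus-maze (and kindred assays): the
#' min-max scaled first-entry latency to the aversive (shallow) zone minus
#' the min-max scaled time spent there, i.e. `scaled(latency) -
#' scaled(time)`, equivalently `(scaled time - scaled latency) * (-1)`.
#' Scaling is across the analysis population, so the score lies in
#' `[-1, 1]`; higher values mean more avoidance (long latency, little time) —
#' a positively oriented anxiety-like measure. Latencies of subjects that
#' never entered must be censored at the session length beforehand.
#'
#' @param shallow_time Numeric vector, per-subject time in the aversive zone (s).
#' @param shallow_latency Numeric vector, per-subject first-entry latency (s).
#' @return Numeric vector of scores in `[-1, 1]`.
#' @export
anxiety_score <- function(shallow_time, shallow_latency) {
  stopifnot(length(shallow_time) == length(shallow_latency))
  if (length(shallow_time) < 2L) {
    stop("anxiety score needs at least 2 subjects (population scaling)",
         call. = FALSE)
  }
  scale_minmax(shallow_latency) - scale_minmax(shallow_time)
}

#' Zone preference by role
#'
#' Aggregates per-zone occupancy metrics to arena roles (e.g. the two
#' shallow arms of the plus-maze to one `"shallow_arm"` row, or
#' stimulus / intersection / no-stimulus in the sociability lane): summed
#' time percent and entry counts per role.
#'
#' @param metrics Result of [session_metrics()].
#' @param arena The [arena_spec()] whose labels define the roles.
#' @param roles Roles to report (default: all roles in the arena).
#' @return data.frame with `role`, `time_s`, `time_pct`, `entries`.
#' @export
zone_preference <- function(metrics, arena, roles = NULL) {
  stopifnot(inherits(arena, "arena_spec"))
  if (is.null(roles)) roles <- unique(unname(arena$labels))
  z <- metrics$zones
  out <- lapply(roles, function(r) {
    ids <- zones_with_role(arena, r)
    sel <- z$zone_id %in% ids
    data.frame(role = r,
               time_s = sum(z$time_s[sel]),
               time_pct = sum(z$time_pct[sel]),
               entries = sum(z$entries[sel]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Tidy endpoint table
#'
#' Binds per-subject endpoint values into the long one-row-per-value layout
#' (`subject_id, session_id, group, endpoint, value, censored`) used for
#' export and for downstream group statistics.
#'
#' @param subject_id,session_id,group Identifier vectors (recycled).
#' @param endpoint Endpoint name (recycled).
#' @param value Numeric values.
#' @param censored Logical censoring flags (default all `FALSE`).
#' @return data.frame of class `endpoint_table`.
#' @export
endpoint_table <- function(subject_id, session_id, group, endpoint, value,
                           censored = FALSE) {
  out <- data.frame(subject_id = as.character(subject_id),
                    session_id = as.character(session_id),
                    group = as.character(group),
                    endpoint = as.character(endpoint),
                    value = as.numeric(value),
                    censored = as.logical(censored),
                    stringsAsFactors = FALSE)
  class(out) <- c("endpoint_table", "data.frame")
  out
}
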