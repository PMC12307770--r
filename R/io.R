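#' Read tracking-export CSV into swim tracks
#'
#' Parses the tidy tracking dialect
#' `subject_id,session_id,t,x,y[,zone]` (UTF-8, comma separator, `"."`
#' decimal). Rows with an empty `x` or `y` field (lost tracking) are dropped
#' and their count reported; non-monotone time within a subject-session is a
#' validation error naming the session.
#'
#' @param path CSV file path.
#' @param frame_rate Nominal frame rate attached to each track (Hz).
#' @return Named list of [swim_track()] objects, one per subject-session,
#'   keyed `subject_id:session_id`.
#' @export
read_track_csv <- function(path, frame_rate = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, na.strings = c("", "NA"))
  req <- c("subject_id", "session_id", "t", "x", "y")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("track CSV missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dropped <- is.na(df$x) | is.na(df$y) | is.na(df$t)
  if (any(dropped)) {
    message(sum(dropped), " row(s) with empty t/x/y dropped (lines ",
            paste(utils::head(which(dropped) + 1L, 10L), collapse = ", "),
            if (sum(dropped) > 10L) ", ..." else "", ")")
    df <- df[!dropped, , drop = FALSE]
  }
  key <- paste(df$subject_id, df$session_id, sep = ":")
  out <- lapply(split(df, key), function(d) {
    if (any(diff(d$t) <= 0)) {
      stop("non-monotone time in session '", d$session_id[1L],
           "' of subject '", d$subject_id[1L], "'", call. = FALSE)
    }
    tr <- swim_track(d$subject_id[1L], d$session_id[1L], d$t, d$x, d$y,
                     frame_rate = frame_rate)
    if (!is.null(d$zone)) tr$zone <- as.character(d$zone)
    tr
  })
  out[unique(key)]
}

#' @rdname read_track_csv
#' @param tracks List of [swim_track()] objects (or one track).
#' @export
write_track_csv <- function(tracks, path) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(subject_id = tr$subject_id, session_id = tr$session_id,
               t = fmt_num(tr$t), x = fmt_num(tr$x), y = fmt_num(tr$y),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write visit-sequence CSV
#'
#' Dialect `subject_id,session_id,zone_id,t_enter,t_exit`; floats are
#' written with 17 significant digits so a write-read round trip reproduces
#' the in-memory values.
#'
#' @param path CSV file path.
#' @return A list of `visit_sequence` data.frames keyed
#'   `subject_id:session_id`.
#' @export
read_visits_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "session_id", "zone_id", "t_enter", "t_exit")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("visits CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$subject_id, df$session_id, sep = ":")
  out <- lapply(split(df, key), function(d) {
    d$subject_id <- as.character(d$subject_id)
    d$session_id <- as.character(d$session_id)
    rownames(d) <- NULL
    d <- d[order(d$t_enter), , drop = FALSE]
    attr(d, "session_length") <- d$t_exit[nrow(d)] - d$t_enter[1L]
    class(d) <- c("visit_sequence", "data.frame")
    d
  })
  out[unique(key)]
}

#' @rdname read_visits_csv
#' @param visits List of `visit_sequence` data.frames (or one).
#' @export
write_visits_csv <- function(visits, path) {
  if (is.data.frame(visits)) visits <- list(visits)
  df <- do.call(rbind, lapply(visits, function(v) {
    data.frame(subject_id = v$subject_id, session_id = v$session_id,
               zone_id = v$zone_id,
               t_enter = fmt_num(v$t_enter), t_exit = fmt_num(v$t_exit),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write endpoint tables
#'
#' Tidy dialect `subject_id,session_id,group,endpoint,value,censored`.
#'
#' @param path CSV file path.
#' @export
read_endpoints_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "session_id", "group", "endpoint", "value", "censored")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("endpoint CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  endpoint_table(df$subject_id, df$session_id, df$group, df$endpoint,
                 df$value, as.logical(df$censored))
}

#' @rdname read_endpoints_csv
#' @param table An [endpoint_table()].
#' @export
write_endpoints_csv <- function(table, path) {
  df <- as.data.frame(table)
  df$value <- fmt_num(df$value)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Arena specification JSON
#'
#' Serialises an [arena_spec()] (zones with shape and geometry, adjacency
#' pairs, role labels) to JSON and back.
#'
#' @param arena An [arena_spec()].
#' @param path JSON file path.
#' @export
write_arena_json <- function(arena, path) {
  stopifnot(inherits(arena, "arena_spec"))
  obj <- list(assay_id = arena$assay_id,
              zones = unname(arena$zones),
              adjacency = apply(arena$adjacency, 1L, as.list),
              labels = as.list(arena$labels))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_arena_json
#' @export
read_arena_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  zones <- lapply(obj$zones, function(z) {
    z <- lapply(z, function(f) if (is.list(f)) unlist(f) else f)
    switch(z$shape,
           rectangle = zone_rectangle(z$zone_id, z$xmin, z$xmax, z$ymin, z$ymax),
           circle = zone_circle(z$zone_id, z$cx, z$cy, z$r),
           annulus = zone_annulus(z$zone_id, z$cx, z$cy, z$r_inner, z$r_outer),
           polygon = zone_polygon(z$zone_id, z$x, z$y))
  })
  adj <- do.call(rbind, lapply(obj$adjacency, unlist))
  labels <- unlist(obj$labels)
  arena_spec(obj$assay_id, zones, adj, labels)
}
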