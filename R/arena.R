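#' Arena specifications
#'
#' An `arena_spec` describes one assay arena as a set of named 2-D zones
#' (rectangles, circles, annuli or polygons, coordinates in mm, origin at the
#' lower-left), an adjacency graph over the zones, and a map from zone id to
#' a functional role (e.g. `"shallow_arm"`, `"center"`, `"stimulus"`).
#' Zone declaration order matters: a point lying on a shared boundary is
#' assigned to the first declared zone that contains it.
#'
#' @param assay_id One of `"sociability"`, `"slalom"`, `"spm"`, `"sj"`,
#'   `"ot"`, `"ymaze"`.
#' @param zones Ordered list of zone definitions as returned by
#'   [zone_rectangle()], [zone_circle()], [zone_annulus()] or
#'   [zone_polygon()].
#' @param adjacency Two-column character matrix (or data.frame) of unordered
#'   zone-id pairs that share a traversable boundary.
#' @param labels Named character vector mapping zone id to role.
#' @return An object of class `arena_spec`.
#' @seealso [arena_preset()] for the six built-in assay geometries.
#' @export
arena_spec <- function(assay_id, zones, adjacency, labels) {
  assay_id <- match.arg(assay_id,
                        c("sociability", "slalom", "spm", "sj", "ot", "ymaze"))
  ids <- vapply(zones, function(z) z$zone_id, character(1L))
  if (anyDuplicated(ids)) stop("duplicate zone ids in arena", call. = FALSE)
  names(zones) <- ids
  adjacency <- as.matrix(adjacency)
  if (ncol(adjacency) != 2L) stop("adjacency must have two columns", call. = FALSE)
  mode(adjacency) <- "character"
  if (!all(adjacency %in% ids)) {
    stop("adjacency references unknown zone id(s): ",
         paste(setdiff(as.vector(adjacency), ids), collapse = ", "),
         call. = FALSE)
  }
  if (!all(names(labels) %in% ids)) {
    stop("labels reference unknown zone id(s)", call. = FALSE)
  }
  obj <- structure(
    list(assay_id = assay_id, zones = zones, adjacency = adjacency,
         labels = labels),
    class = "arena_spec")
  validate_arena(obj)
  obj
}

validate_arena <- function(arena) {
  stopifnot(inherits(arena, "arena_spec"))
  if (arena$assay_id == "ot") {
    zc <- arena$zones[[which(arena$labels[names(arena$zones)] == "center")[1L]]]
    zp <- arena$zones[[which(arena$labels[names(arena$zones)] == "periphery")[1L]]]
    ratio <- (zc$r / zp$r_outer)^2
    if (abs(ratio - 0.8) > 1e-9) {
      stop("open-tank central circle must cover 80% of the arena area ",
           "(radius ratio sqrt(0.8)); got area ratio ", ratio, call. = FALSE)
    }
  }
  invisible(arena)
}

#' @rdname arena_spec
#' @param zone_id Zone identifier (character scalar).
#' @param xmin,xmax,ymin,ymax Rectangle bounds in mm.
#' @export
zone_rectangle <- function(zone_id, xmin, xmax, ymin, ymax) {
  stopifnot(xmin < xmax, ymin < ymax)
  list(zone_id = zone_id, shape = "rectangle",
       xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax)
}

#' @rdname arena_spec
#' @param cx,cy Circle/annulus center in mm.
#' @param r Circle radius in mm.
#' @export
zone_circle <- function(zone_id, cx, cy, r) {
  stopifnot(r > 0)
  list(zone_id = zone_id, shape = "circle", cx = cx, cy = cy, r = r)
}

#' @rdname arena_spec
#' @param r_inner,r_outer Annulus radii in mm, `0 <= r_inner < r_outer`.
#' @export
zone_annulus <- function(zone_id, cx, cy, r_inner, r_outer) {
  stopifnot(r_inner >= 0, r_inner < r_outer)
  list(zone_id = zone_id, shape = "annulus", cx = cx, cy = cy,
       r_inner = r_inner, r_outer = r_outer)
}

#' @rdname arena_spec
#' @param x,y Polygon vertex coordinates in mm (closed implicitly).
#' @export
zone_polygon <- function(zone_id, x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  list(zone_id = zone_id, shape = "polygon", x = as.numeric(x), y = as.numeric(y))
}

# Vectorised point-in-zone test; boundary points count as inside (the
# declaration-order tie-break resolves shared boundaries).
zone_contains <- function(zone, px, py) {
  switch(zone$shape,
    rectangle = px >= zone$xmin & px <= zone$xmax &
                py >= zone$ymin & py <= zone$ymax,
    circle = (px - zone$cx)^2 + (py - zone$cy)^2 <= zone$r^2,
    annulus = {
      d2 <- (px - zone$cx)^2 + (py - zone$cy)^2
      d2 >= zone$r_inner^2 & d2 <= zone$r_outer^2
    },
    polygon = point_in_polygon(zone$x, zone$y, px, py),
    stop("unknown zone shape: ", zone$shape, call. = FALSE))
}

# Ray casting with an on-edge tolerance; returns logical vector over points.
point_in_polygon <- function(vx, vy, px, py, tol = 1e-9) {
  n <- length(vx)
  jx <- c(vx[n], vx[-n]); jy <- c(vy[n], vy[-n])
  out <- logical(length(px))
  on_edge <- logical(length(px))
  for (e in seq_len(n)) {
    x1 <- jx[e]; y1 <- jy[e]; x2 <- vx[e]; y2 <- vy[e]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    out <- xor(out, crosses)
    # distance from point to segment, for boundary inclusion
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    tt <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
    d2 <- (px - (x1 + tt * dx))^2 + (py - (y1 + tt * dy))^2
    on_edge <- on_edge | d2 <= tol^2
  }
  out | on_edge
}

zone_bbox <- function(zone) {
  switch(zone$shape,
    rectangle = c(zone$xmin, zone$xmax, zone$ymin, zone$ymax),
    circle = c(zone$cx - zone$r, zone$cx + zone$r,
               zone$cy - zone$r, zone$cy + zone$r),
    annulus = c(zone$cx - zone$r_outer, zone$cx + zone$r_outer,
                zone$cy - zone$r_outer, zone$cy + zone$r_outer),
    polygon = c(min(zone$x), max(zone$x), min(zone$y), max(zone$y)))
}

arena_bbox <- function(arena) {
  bb <- vapply(arena$zones, zone_bbox, numeric(4L))
  c(min(bb[1L, ]), max(bb[2L, ]), min(bb[3L, ]), max(bb[4L, ]))
}

# Uniform point inside a zone (rejection sampling for polygons/annuli).
zone_sample_point <- function(zone, shrink = 0) {
  if (zone$shape == "rectangle") {
    dx <- shrink * (zone$xmax - zone$xmin)
    dy <- shrink * (zone$ymax - zone$ymin)
    return(c(stats::runif(1L, zone$xmin + dx, zone$xmax - dx),
             stats::runif(1L, zone$ymin + dy, zone$ymax - dy)))
  }
  if (zone$shape == "circle") {
    r <- zone$r * (1 - shrink) * sqrt(stats::runif(1L))
    th <- stats::runif(1L, 0, 2 * pi)
    return(c(zone$cx + r * cos(th), zone$cy + r * sin(th)))
  }
  if (zone$shape == "annulus") {
    ri <- zone$r_inner * (1 + shrink)
    ro <- zone$r_outer * (1 - shrink)
    r <- sqrt(stats::runif(1L, ri^2, ro^2))
    th <- stats::runif(1L, 0, 2 * pi)
    return(c(zone$cx + r * cos(th), zone$cy + r * sin(th)))
  }
  bb <- zone_bbox(zone)
  cx <- mean(bb[1:2]); cy <- mean(bb[3:4])
  for (i in 1:200) {
    px <- cx + (stats::runif(1L, bb[1L], bb[2L]) - cx) * (1 - shrink)
    py <- cy + (stats::runif(1L, bb[3L], bb[4L]) - cy) * (1 - shrink)
    if (zone_contains(zone, px, py)) return(c(px, py))
  }
  c(cx, cy)
}

zone_ids <- function(arena) names(arena$zones)

#' Zones carrying a given role
#'
#' @param arena An [arena_spec()].
#' @param role Role string to look up (e.g. `"shallow_arm"`).
#' @return Character vector of zone ids with that role.
#' @export
zones_with_role <- function(arena, role) {
  ids <- names(arena$labels)[arena$labels == role]
  if (length(ids) == 0L) {
    stop("role '", role, "' not present in arena '", arena$assay_id, "'",
         call. = FALSE)
  }
  ids
}

#' @export
print.arena_spec <- function(x, ...) {
  cat("<arena_spec>", x$assay_id, "\n")
  cat("  zones:", length(x$zones), "(",
      paste(utils::head(names(x$zones), 6L), collapse = ", "),
      if (length(x$zones) > 6L) ", ..." else "", ")\n", sep = " ")
  cat("  adjacency edges:", nrow(x$adjacency), "\n")
  invisible(x)
}

#' Built-in arena presets
#'
#' Returns the geometry of one of the six assays with the published tank
#' dimensions (mm): the 12-chamber slalom maze (20 mm wide, 85 mm long),
#' the swimming plus-maze (two shallow and two deep 8 x 10 mm arms around an
#' 8 x 8 mm center), the 4-chamber show-jump tank (42 mm long), the circular
#' open tank (well diameter 35 mm, with an aversive central circle covering
#' 80% of the area, radius ratio `sqrt(0.8)`), the 3-arm Y-maze (7.5 mm wide,
#' 30 mm long arms at 120 degrees), and a schematic three-zone sociability
#' lane (stimulus / intersection / no-stimulus).
#'
#' @param assay_id Assay name; see [arena_spec()].
#' @return An [arena_spec()].
#' @examples
#' ot <- arena_preset("ot")
#' zones_with_role(ot, "center")
#' @export
arena_preset <- function(assay_id = c("sociability", "slalom", "spm", "sj",
                                      "ot", "ymaze")) {
  assay_id <- match.arg(assay_id)
  switch(assay_id,
    slalom = chain_arena("slalom", n_chambers = 12L, width = 20, length = 85),
    sj = chain_arena("sj", n_chambers = 4L, width = 20, length = 42),
    spm = spm_arena(),
    ot = ot_arena(),
    ymaze = ymaze_arena(),
    sociability = sociability_arena())
}

chain_arena <- function(assay_id, n_chambers, width, length) {
  step <- length / n_chambers
  zones <- lapply(seq_len(n_chambers), function(i) {
    zone_rectangle(sprintf("chamber_%d", i),
                   xmin = (i - 1L) * step, xmax = i * step,
                   ymin = 0, ymax = width)
  })
  adj <- cbind(sprintf("chamber_%d", seq_len(n_chambers - 1L)),
               sprintf("chamber_%d", seq_len(n_chambers - 1L) + 1L))
  labels <- stats::setNames(sprintf("chamber_%d", seq_len(n_chambers)),
                            sprintf("chamber_%d", seq_len(n_chambers)))
  labels[1L] <- "start"
  labels[n_chambers] <- "final_chamber"
  arena_spec(assay_id, zones, adj, labels)
}

spm_arena <- function() {
  # center square 8 x 8 at the middle; arms 8 wide x 10 long
  # declaration order: center first, so shared edges resolve to center
  h <- 4; arm <- 10
  zones <- list(
    zone_rectangle("center", -h, h, -h, h),
    zone_rectangle("shallow_1", -h, h, h, h + arm),
    zone_rectangle("shallow_2", -h, h, -h - arm, -h),
    zone_rectangle("deep_1", h, h + arm, -h, h),
    zone_rectangle("deep_2", -h - arm, -h, -h, h))
  adj <- cbind(rep("center", 4L),
               c("shallow_1", "shallow_2", "deep_1", "deep_2"))
  labels <- c(center = "center",
              shallow_1 = "shallow_arm", shallow_2 = "shallow_arm",
              deep_1 = "deep_arm", deep_2 = "deep_arm")
  arena_spec("spm", zones, adj, labels)
}

ot_arena <- function(diameter = 35) {
  r_out <- diameter / 2
  r_in <- r_out * sqrt(0.8)
  zones <- list(
    zone_circle("center", r_out, r_out, r_in),
    zone_annulus("periphery", r_out, r_out, r_in, r_out))
  arena_spec("ot", zones, cbind("center", "periphery"),
             c(center = "center", periphery = "periphery"))
}

ymaze_arena <- function(arm_width = 7.5, arm_length = 30) {
  # central equilateral triangle with side = arm width; one arm off each edge
  w <- arm_width
  rv <- w / sqrt(3)                       # circumradius of the triangle
  vang <- c(30, 150, 270) * pi / 180      # triangle vertices
  vx <- rv * cos(vang); vy <- rv * sin(vang)
  dirs <- c(90, 210, 330) * pi / 180      # outward arm directions
  arm_ids <- c("arm_A", "arm_B", "arm_C")
  arms <- lapply(1:3, function(k) {
    i <- k; j <- if (k == 3L) 1L else k + 1L
    ux <- cos(dirs[k]); uy <- sin(dirs[k])
    zone_polygon(arm_ids[k],
                 x = c(vx[i], vx[j], vx[j] + arm_length * ux,
                       vx[i] + arm_length * ux),
                 y = c(vy[i], vy[j], vy[j] + arm_length * uy,
                       vy[i] + arm_length * uy))
  })
  zones <- c(list(zone_polygon("center", vx, vy)), arms)
  adj <- cbind(rep("center", 3L), arm_ids)
  labels <- c(center = "center",
              stats::setNames(arm_ids, arm_ids))
  arena_spec("ymaze", zones, adj, labels)
}

sociability_arena <- function(width = 20, choice_len = 30, mid_len = 20) {
  # schematic lane: no-stimulus end | starting point / intersection | stimulus end
  zones <- list(
    zone_rectangle("no_stimulus", 0, choice_len, 0, width),
    zone_rectangle("intersection", choice_len, choice_len + mid_len, 0, width),
    zone_rectangle("stimulus", choice_len + mid_len,
                   choice_len + mid_len + choice_len, 0, width))
  adj <- rbind(c("no_stimulus", "intersection"),
               c("intersection", "stimulus"))
  labels <- c(no_stimulus = "no_stimulus", intersection = "intersection",
              stimulus = "stimulus")
  arena_spec("sociability", zones, adj, labels)
}
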