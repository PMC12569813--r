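# Spatial structure units are read from the Voronoi tessellation of all
# living stems (core + buffer): two trees are neighbours when their Voronoi
# cells share an edge, and cells are clipped to the plot disk before
# adjacency is read, so adjacency through the plot exterior cannot occur.

living_points <- function(x) {
  live <- tibble::as_tibble(x)[x$alive, , drop = FALSE]
  if (anyDuplicated(cbind(live$x, live$y))) {
    abort("coincident stems: two living trees share exact coordinates",
          class = "standopt_geometry_error")
  }
  live
}

check_noncollinear <- function(x, y, min_n) {
  if (length(x) < min_n) {
    abort(sprintf("degenerate geometry: need at least %d living trees", min_n),
          class = "standopt_geometry_error")
  }
  d2 <- (x - x[1])^2 + (y - y[1])^2
  b <- which.max(d2)
  cross <- abs((x - x[1]) * (y[b] - y[1]) - (y - y[1]) * (x[b] - x[1]))
  if (d2[b] == 0 || all(cross < 1e-9 * max(1, sqrt(d2[b])))) {
    abort("degenerate geometry: all living trees are collinear",
          class = "standopt_geometry_error")
  }
}

# squared distance from the origin-centred disk test: minimum distance from
# (0,0) to the segment (x1,y1)-(x2,y2)
segment_min_dist_origin <- function(x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- ifelse(len2 > 0, pmin(1, pmax(0, -(x1 * dx + y1 * dy) / len2)), 0)
  sqrt((x1 + t * dx)^2 + (y1 + t * dy)^2)
}

stand_deldir <- function(live, radius) {
  pad <- radius * 0.05 + 1
  suppressMessages(deldir::deldir(live$x, live$y,
                                  rw = c(-radius - pad, radius + pad,
                                         -radius - pad, radius + pad)))
}

# Adjacency over all living trees: list (by row of `live`) of integer
# vectors of neighbouring rows. Voronoi edges are kept only where they
# intersect the open plot disk.
voronoi_adjacency <- function(live, radius, dd = NULL) {
  check_noncollinear(live$x, live$y, 4)
  if (is.null(dd)) dd <- stand_deldir(live, radius)
  seg <- dd$dirsgs
  keep <- segment_min_dist_origin(seg$x1, seg$y1, seg$x2, seg$y2) < radius - 1e-9
  seg <- seg[keep, , drop = FALSE]
  n <- nrow(live)
  adj <- vector("list", n)
  if (nrow(seg)) {
    pairs <- rbind(cbind(seg$ind1, seg$ind2), cbind(seg$ind2, seg$ind1))
    sp <- split(pairs[, 2], pairs[, 1])
    for (nm in names(sp)) adj[[as.integer(nm)]] <- sort(unique(sp[[nm]]))
  }
  adj
}

#' Partition a stand into core and buffer trees
#'
#' The plot boundary is contracted inward by the stand's buffer width;
#' trees at distance exactly `radius - buffer_width` from the centre count
#' as core (ties resolve inward).
#'
#' @param x A [stand()].
#' @return A list with character vectors `core` and `buffer` of tree ids.
#' @export
partition_core_buffer <- function(x) {
  stopifnot(is_stand(x))
  r <- sqrt(x$x^2 + x$y^2)
  core <- r <= stand_radius(x) - stand_buffer(x) + 1e-12
  list(core = x$id[core], buffer = x$id[!core])
}

#' Voronoi spatial structure units
#'
#' One unit per living core tree: the reference tree together with the
#' living trees (core or buffer) whose clipped Voronoi cells share an edge
#' with its cell. Buffer trees appear as neighbours but never as
#' references. Neighbours are ordered by azimuth (clockwise from north)
#' around the reference tree.
#'
#' @param x A [stand()] with at least 4 non-collinear living trees.
#' @return A tibble with columns `reference_id`, `neighbour_ids`
#'   (list-column of character vectors) and `n`.
#' @export
voronoi_units <- function(x) {
  stopifnot(is_stand(x))
  live <- living_points(x)
  adj <- voronoi_adjacency(live, stand_radius(x))
  core_ids <- partition_core_buffer(x)$core
  refs <- which(live$id %in% core_ids)
  units <- lapply(refs, function(i) {
    nb <- adj[[i]]
    az <- azimuth_deg(live$x[nb] - live$x[i], live$y[nb] - live$y[i])
    live$id[nb[order(az)]]
  })
  tibble::tibble(reference_id = live$id[refs],
                 neighbour_ids = units,
                 n = lengths(units))
}

#' Delaunay triangulation with incenters
#'
#' Triangulates the living stems and returns every triangle with its area
#' and incenter (the side-length-weighted mean of the vertices), sorted by
#' area in descending order. The largest-triangle incenters are the
#' candidate canopy-gap planting locations.
#'
#' @param x A [stand()] with at least 3 non-collinear living trees.
#' @return A tibble with columns `id1`, `id2`, `id3`, `area` (m^2),
#'   `inc_x`, `inc_y` (m).
#' @export
delaunay_triangles <- function(x) {
  stopifnot(is_stand(x))
  live <- living_points(x)
  check_noncollinear(live$x, live$y, 3)
  dd <- stand_deldir(live, stand_radius(x))
  tl <- deldir::triang.list(dd)
  if (!length(tl)) abort("degenerate geometry: no Delaunay triangles",
                         class = "standopt_geometry_error")
  # geometry from the original coordinates: the tessellation library may
  # perturb vertex coordinates at the 1e-6 level
  pts <- vapply(tl, function(tr) as.integer(tr$ptNum), integer(3))
  x1 <- live$x[pts[1, ]]; x2 <- live$x[pts[2, ]]; x3 <- live$x[pts[3, ]]
  y1 <- live$y[pts[1, ]]; y2 <- live$y[pts[2, ]]; y3 <- live$y[pts[3, ]]
  area <- abs(x1 * (y2 - y3) + x2 * (y3 - y1) + x3 * (y1 - y2)) / 2
  # side a is opposite vertex 1, etc.
  a <- sqrt((x2 - x3)^2 + (y2 - y3)^2)
  b <- sqrt((x1 - x3)^2 + (y1 - y3)^2)
  cc <- sqrt((x1 - x2)^2 + (y1 - y2)^2)
  s <- a + b + cc
  rows <- tibble::tibble(id1 = live$id[pts[1, ]], id2 = live$id[pts[2, ]],
                         id3 = live$id[pts[3, ]], area = area,
                         inc_x = (a * x1 + b * x2 + cc * x3) / s,
                         inc_y = (a * y1 + b * y2 + cc * y3) / s)
  rows[order(rows$area, decreasing = TRUE), ]
}

#' Crown overlap area between two trees
#'
#' Crowns are disks of radius `crown_width / 2` centred on the stems. For
#' intersecting disks this is the standard two-circle lens area (the sum of
#' the two circular segments on either side of the radical line); when one
#' disk contains the other it is the smaller disk's area. For disjoint
#' crowns the published convention returns the literal sentinel 1.0 m^2,
#' which injects a unit of competition from non-touching neighbours; set
#' `no_overlap_value = 0` to disable it.
#'
#' @param xi,yi,cwi Stem coordinates (m) and crown width (m) of tree i.
#' @param xj,yj,cwj Same for tree j. All vectorised.
#' @param no_overlap_value Value returned for disjoint crowns (default 1).
#' @return Overlap area(s) in m^2.
#' @export
circle_overlap_area <- function(xi, yi, cwi, xj, yj, cwj, no_overlap_value = 1) {
  if (any(cwi <= 0) || any(cwj <= 0)) {
    abort("crown widths must be positive", class = "standopt_validation_error")
  }
  d <- sqrt((xi - xj)^2 + (yi - yj)^2)
  r1 <- rep_len(cwi / 2, length(d)); r2 <- rep_len(cwj / 2, length(d))
  out <- numeric(length(d))
  disjoint <- d >= r1 + r2
  contained <- !disjoint & d <= abs(r1 - r2)
  lens <- !disjoint & !contained
  out[disjoint] <- no_overlap_value
  out[contained] <- pi * pmin(r1, r2)[contained]^2
  if (any(lens)) {
    dd <- d[lens]; a1 <- r1[lens]; a2 <- r2[lens]
    t1 <- a1^2 * acos(pmin(1, pmax(-1, (dd^2 + a1^2 - a2^2) / (2 * dd * a1))))
    t2 <- a2^2 * acos(pmin(1, pmax(-1, (dd^2 + a2^2 - a1^2) / (2 * dd * a2))))
    k <- pmax(0, (-dd + a1 + a2) * (dd + a1 - a2) * (dd - a1 + a2) * (dd + a1 + a2))
    out[lens] <- t1 + t2 - sqrt(k) / 2
  }
  out
}

#' Voronoi cell polygons (diagnostic export)
#'
#' Cell polygons of the living stems clipped to the rectangular
#' tessellation window, for plotting and GeoJSON-style export.
#'
#' @param x A [stand()].
#' @return A tibble with columns `id`, `vx`, `vy` (one row per polygon
#'   vertex, in order).
#' @export
voronoi_cells <- function(x) {
  stopifnot(is_stand(x))
  live <- living_points(x)
  dd <- stand_deldir(live, stand_radius(x))
  tiles <- deldir::tile.list(dd)
  purrr::map_dfr(seq_along(tiles), function(i) {
    tibble::tibble(id = live$id[tiles[[i]]$ptNum],
                   vx = tiles[[i]]$x, vy = tiles[[i]]$y)
  })
}
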