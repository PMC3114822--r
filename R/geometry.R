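#' Line-source road geometry
#'
#' A `road_source` is an ordered polyline in planar (UTM, metres) coordinates
#' with a per-vertex elevation profile and the identifiers of the traffic
#' counters that measure it. Elevated roadways (bridges, viaducts) carry
#' non-zero elevations; distance computations against them use the effective
#' distance `sqrt(height^2 + horizontal^2)`.
#'
#' @param id Short identifier, e.g. `"WB"`.
#' @param vertices Two-column numeric matrix (easting, northing) in metres;
#'   at least two rows, consecutive rows distinct.
#' @param elevation Numeric vector of per-vertex heights above local ground
#'   (metres, >= 0). Recycled from a scalar. Default 0 (at-grade road).
#' @param counter_ids Character vector of traffic-counter ids on this road.
#' @return An object of class `road_source`.
#' @export
road_source <- function(id, vertices, elevation = 0, counter_ids = character()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (!is.matrix(vertices) || ncol(vertices) != 2 || nrow(vertices) < 2)
    stop("'vertices' must be a matrix with 2 columns and >= 2 rows")
  dup <- rowSums((vertices[-1, , drop = FALSE] -
                  vertices[-nrow(vertices), , drop = FALSE])^2) == 0
  if (any(dup)) stop("consecutive vertices must be distinct")
  if (length(elevation) == 1) elevation <- rep(elevation, nrow(vertices))
  if (length(elevation) != nrow(vertices))
    stop("'elevation' must have one value per vertex")
  if (any(elevation < 0)) stop("elevations must be >= 0")
  structure(list(id = as.character(id), vertices = vertices,
                 elevation = as.numeric(elevation),
                 counter_ids = as.character(counter_ids)),
            class = "road_source")
}

#' @export
print.road_source <- function(x, ...) {
  cat(sprintf("road_source '%s': %d vertices, length %.1f m, elevation %.1f-%.1f m\n",
              x$id, nrow(x$vertices), road_length(x),
              min(x$elevation), max(x$elevation)))
  invisible(x)
}

segment_lengths <- function(road) {
  v <- road$vertices
  sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
}

#' Total polyline length of a road
#' @param road A [road_source()].
#' @return Length in metres.
#' @export
road_length <- function(road) sum(segment_lengths(road))

## Project points onto a road polyline.
## Returns, per point: the global minimum distance over all segments (ties to
## the lowest segment index), the nearest point, the interpolated elevation
## there, and the local segment orientation (unit vector).
project_to_road <- function(points, road) {
  points <- rbind(points, deparse.level = 0)  # allow a single c(x, y)
  if (ncol(points) != 2) stop("'points' must have 2 columns")
  v <- road$vertices
  ns <- nrow(v) - 1
  n <- nrow(points)
  best <- rep(Inf, n)
  out <- list(distance = rep(Inf, n), seg = integer(n), tfrac = numeric(n),
              px = numeric(n), py = numeric(n), height = numeric(n),
              ux = numeric(n), uy = numeric(n))
  for (s in seq_len(ns)) {
    a <- v[s, ]; b <- v[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((points[, 1] - a[1]) * ab[1] + (points[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(1, pmax(0, t))
    qx <- a[1] + t * ab[1]; qy <- a[2] + t * ab[2]
    d <- sqrt((points[, 1] - qx)^2 + (points[, 2] - qy)^2)
    upd <- d < best  # strict: ties keep the lowest segment index
    if (any(upd)) {
      best[upd] <- d[upd]
      out$distance[upd] <- d[upd]
      out$seg[upd] <- s
      out$tfrac[upd] <- t[upd]
      out$px[upd] <- qx[upd]; out$py[upd] <- qy[upd]
      out$height[upd] <- road$elevation[s] +
        t[upd] * (road$elevation[s + 1] - road$elevation[s])
      u <- ab / sqrt(len2)
      out$ux[upd] <- u[1]; out$uy[upd] <- u[2]
    }
  }
  out
}

#' Shortest horizontal distance from points to a road
#'
#' Minimum Euclidean point-to-polyline distance: each point is projected onto
#' every segment (clamped to the segment ends) and the global minimum taken.
#'
#' @param points Two-column matrix (easting, northing) or a length-2 vector.
#' @param road A [road_source()].
#' @return Numeric vector of distances in metres (>= 0).
#' @export
nearest_distance <- function(points, road) {
  if (!inherits(road, "road_source")) stop("'road' must be a road_source")
  project_to_road(points, road)$distance
}

#' Effective (slant) distance to a possibly elevated road
#'
#' `sqrt(h^2 + g^2)` where `g` is the horizontal nearest distance and `h` the
#' road height above ground at the nearest point, linearly interpolated
#' between the bounding vertices' elevations. For an at-grade road this
#' equals [nearest_distance()]; directly underneath an elevated deck it
#' equals the deck height.
#'
#' @inheritParams nearest_distance
#' @return Numeric vector of effective distances in metres.
#' @export
effective_distance <- function(points, road) {
  if (!inherits(road, "road_source")) stop("'road' must be a road_source")
  pr <- project_to_road(points, road)
  sqrt(pr$distance^2 + pr$height^2)
}

#' Discretize a road into fixed-length segments
#'
#' Partitions the polyline arclength into consecutive pieces of
#' `segment_size` metres (the final piece may be shorter, and is kept).
#' Each piece carries its arclength midpoint (a point on the polyline), the
#' interpolated height there, and a traffic weight `e` (filled in later by
#' the caller; the final short piece's weight should be scaled by its length
#' fraction, which is recorded).
#'
#' @param road A [road_source()].
#' @param segment_size Nominal segment length in metres (> 0), default 10.
#' @return An object of class `segmented_source`: a list with `road_id` and a
#'   data frame `segments` with columns `mid_x`, `mid_y`, `length`, `height`,
#'   `frac` (length / segment_size) and `e` (initialised to `frac`).
#' @export
discretize_road <- function(road, segment_size = 10) {
  if (!inherits(road, "road_source")) stop("'road' must be a road_source")
  if (!is.numeric(segment_size) || segment_size <= 0)
    stop("'segment_size' must be > 0")
  total <- road_length(road)
  nseg <- ceiling(total / segment_size - 1e-9)
  starts <- (seq_len(nseg) - 1) * segment_size
  ends <- pmin(starts + segment_size, total)
  mids <- (starts + ends) / 2
  pm <- point_at_arclength(road, mids)
  segs <- data.frame(mid_x = pm$x, mid_y = pm$y, length = ends - starts,
                     height = pm$height, frac = (ends - starts) / segment_size)
  segs$e <- segs$frac
  structure(list(road_id = road$id, segment_size = segment_size,
                 segments = segs),
            class = "segmented_source")
}

## Locate points (and interpolated heights) at given arclengths along a road.
point_at_arclength <- function(road, s) {
  lens <- segment_lengths(road)
  cum <- c(0, cumsum(lens))
  idx <- findInterval(pmin(s, cum[length(cum)] - 1e-12), cum,
                      rightmost.closed = TRUE)
  idx <- pmin(idx, length(lens))
  t <- (s - cum[idx]) / lens[idx]
  v <- road$vertices
  list(x = v[idx, 1] + t * (v[idx + 1, 1] - v[idx, 1]),
       y = v[idx, 2] + t * (v[idx + 1, 2] - v[idx, 2]),
       height = road$elevation[idx] +
         t * (road$elevation[idx + 1] - road$elevation[idx]))
}

#' Upwind/downwind classification relative to a road
#'
#' Implements the sector rule used for wind-direction sensitivity analyses:
#' an observation is *downwind* of the road iff the direction the wind is
#' blowing **towards** is within 90 degrees of the bearing from the nearest
#' road point to the observation AND the wind is not blowing within 45
#' degrees of the local road axis (either sense). Everything else —
#' road-to-point winds outside the 90-degree cone, axis-parallel winds, and
#' boundary angles (exactly 45 or 90 degrees) — is *upwind*. Calm minutes
#' (speed below `calm_threshold`) get the sentinel `"calm"` and must be
#' excluded from stratified fits.
#'
#' @inheritParams nearest_distance
#' @param wind_dir Meteorological wind direction(s) in degrees (direction the
#'   wind blows FROM), recycled to the number of points.
#' @param wind_speed Wind speed(s) in m/s, recycled.
#' @param calm_threshold Speeds `<=` this are classified `"calm"`; default 0
#'   (only exactly-zero winds are calm).
#' @return Character vector: `"upwind"`, `"downwind"` or `"calm"`.
#' @export
wind_sector <- function(points, road, wind_dir, wind_speed = 1,
                        calm_threshold = 0) {
  if (!inherits(road, "road_source")) stop("'road' must be a road_source")
  points <- rbind(points, deparse.level = 0)
  n <- nrow(points)
  wind_dir <- rep_len(as.numeric(wind_dir), n) %% 360
  wind_speed <- rep_len(as.numeric(wind_speed), n)
  pr <- project_to_road(points, road)
  ## compass bearings (degrees clockwise from north)
  bear_rp <- (atan2(points[, 1] - pr$px, points[, 2] - pr$py) * 180 / pi) %% 360
  road_axis <- (atan2(pr$ux, pr$uy) * 180 / pi) %% 360
  blow_to <- (wind_dir + 180) %% 360
  d1 <- angdiff(blow_to, bear_rp)            # wind-to vs road->point
  da <- pmin(angdiff(blow_to, road_axis),    # wind-to vs road axis (either sense)
             angdiff(blow_to, (road_axis + 180) %% 360))
  sector <- ifelse(d1 < 90 & da > 45, "downwind", "upwind")
  sector[wind_speed <= calm_threshold] <- "calm"
  ## points exactly on the road have no defined road->point bearing
  sector[pr$distance == 0] <- "upwind"
  unname(sector)
}

## absolute angular difference in [0, 180]
angdiff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

#' Read road sources from GeoJSON
#'
#' Expects LineString features with properties `id`, `elevations` (one per
#' vertex, metres) and `counter_ids`; coordinates must already be planar UTM
#' metres (no geodesic handling).
#'
#' @param path Path to a GeoJSON file.
#' @return List of [road_source()] objects.
#' @export
read_roads_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "LineString"))
      stop("only LineString features are supported")
    coords <- do.call(rbind, lapply(f$geometry$coordinates, unlist))
    road_source(id = f$properties$id, vertices = coords,
                elevation = unlist(f$properties$elevations),
                counter_ids = unlist(f$properties$counter_ids))
  })
}

#' Write road sources to GeoJSON
#'
#' @param roads List of [road_source()] objects.
#' @param path Output path.
#' @param utm_zone Optional zone label recorded as a file-level property.
#' @export
write_roads_geojson <- function(roads, path, utm_zone = NA) {
  feats <- lapply(roads, function(r) {
    list(type = "Feature",
         properties = list(id = r$id,
                           elevations = r$elevation,
                           counter_ids = as.list(r$counter_ids)),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(r$vertices)),
                                              function(i) r$vertices[i, ])))
  })
  gj <- list(type = "FeatureCollection", utm_zone = utm_zone, features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
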