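# Great-circle geometry and the proportional range-marginality index.
#
# Distances are haversine on a sphere (default radius 6378137 m, the WGS84
# equatorial radius used by common geosphere defaults). The convex hull is
# computed PLANAR on raw (longitude, latitude) pairs while distances to its
# edges are geodesic — a deliberate hybrid mirroring the standard
# chull + dist2line toolchain for occurrence data. Continental ranges only:
# longitude spans > 180 degrees (antimeridian wrap) are rejected.

#' Default sphere radius (meters)
#' @export
earth_radius <- 6378137

deg2rad <- function(x) x * pi / 180

#' Great-circle (haversine) distance
#'
#' Distance in meters between points given in decimal degrees, on a
#' sphere of the supplied radius. Vectorized and symmetric.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84).
#' @param radius Sphere radius in meters.
#' @return Numeric vector of distances in meters.
#' @export
great_circle_distance <- function(lon1, lat1, lon2, lat2, radius = earth_radius) {
  stopifnot(all(abs(lat1) <= 90), all(abs(lat2) <= 90),
            all(abs(lon1) <= 180), all(abs(lon2) <= 180))
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dp <- p2 - p1
  dl <- deg2rad(lon2 - lon1)
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  a <- pmin(pmax(a, 0), 1)
  unname(2 * radius * asin(sqrt(a)))
}

# Unit vectors on the sphere for degree coordinates; rows are points.
to_xyz <- function(lon, lat) {
  lam <- deg2rad(lon); phi <- deg2rad(lat)
  cbind(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
}

#' Minimum great-circle distance from a point to a geodesic segment
#'
#' Cross-track distance to the great-circle arc between `s1` and `s2`
#' when the perpendicular foot lies within the arc, otherwise the
#' distance to the nearer endpoint. Degenerate segments (`s1 == s2`)
#' reduce to the point-to-point distance. A point coinciding exactly with
#' an endpoint returns exactly zero.
#'
#' @param plon,plat Point coordinates, decimal degrees (vectorized).
#' @param s1lon,s1lat,s2lon,s2lat Segment endpoints, decimal degrees.
#' @param radius Sphere radius in meters.
#' @return Numeric vector of distances in meters.
#' @export
point_to_geodesic_segment <- function(plon, plat, s1lon, s1lat, s2lon, s2lat,
                                      radius = earth_radius) {
  n <- max(length(plon), length(plat))
  plon <- rep_len(plon, n); plat <- rep_len(plat, n)
  if (s1lon == s2lon && s1lat == s2lat) {
    return(great_circle_distance(plon, plat, s1lon, s1lat, radius))
  }
  at_vertex <- (plon == s1lon & plat == s1lat) | (plon == s2lon & plat == s2lat)

  p <- to_xyz(plon, plat)
  a <- drop(to_xyz(s1lon, s1lat))
  b <- drop(to_xyz(s2lon, s2lat))
  nv <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  nv <- nv / sqrt(sum(nv^2))

  # foot of the great-circle perpendicular from p
  dpn <- drop(p %*% nv)
  f <- p - outer(dpn, nv)
  fn <- sqrt(rowSums(f^2))
  # p at a pole of the segment's great circle: foot undefined, endpoints decide
  degenerate_foot <- fn < 1e-12
  fn[degenerate_foot] <- 1
  f <- f / fn

  ang <- function(u, v) acos(pmin(pmax(u %*% v, -1), 1))
  ab <- drop(ang(rbind(a), b))
  within <- drop(ang(f, a)) + drop(ang(f, b)) <= ab + 1e-12
  within[degenerate_foot] <- FALSE

  d_cross <- radius * asin(pmin(pmax(abs(dpn), 0), 1))
  d_a <- great_circle_distance(plon, plat, s1lon, s1lat, radius)
  d_b <- great_circle_distance(plon, plat, s2lon, s2lat, radius)
  d <- ifelse(within, d_cross, pmin(d_a, d_b))
  d[at_vertex] <- 0
  unname(d)
}

#' Planar convex hull of coordinate pairs
#'
#' Hull of the raw (longitude, latitude) pairs, counter-clockwise, with
#' collinear boundary points removed. At least three distinct
#' non-collinear points are required.
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @return A two-column matrix (`lon`, `lat`) of hull vertices in
#'   counter-clockwise order, without a repeated closing vertex.
#' @export
convex_hull <- function(lon, lat) {
  pts <- unique(cbind(lon = lon, lat = lat))
  if (nrow(pts) < 3) {
    stop("degenerate range: fewer than 3 distinct coordinate pairs", call. = FALSE)
  }
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[idx, , drop = FALSE]
  if (nrow(hull) < 3) {
    stop("degenerate range: all points are collinear", call. = FALSE)
  }
  # chull returns clockwise order; reverse for counter-clockwise
  if (polygon_signed_area(hull) < 0) hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
  drop_collinear(hull)
}

polygon_signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

drop_collinear <- function(v) {
  repeat {
    n <- nrow(v)
    if (n <= 3) return(v)
    keep <- rep(TRUE, n)
    for (i in seq_len(n)) {
      a <- v[if (i == 1) n else i - 1, ]
      b <- v[i, ]
      c <- v[if (i == n) 1 else i + 1, ]
      cross <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
      if (abs(cross) < 1e-12) keep[i] <- FALSE
    }
    if (all(keep)) return(v)
    v <- v[keep, , drop = FALSE]
  }
}

#' Build a species range model from occurrence coordinates
#'
#' The range center is the arithmetic mean of the member longitudes and of
#' the member latitudes; the range boundary is the planar convex hull of
#' all coordinate pairs. The model is built from ALL coordinate-bearing
#' records of the species (before any trait filtering), since the range
#' is inferred from the full spread of datapoint coordinates.
#'
#' @param records Tibble of occurrence records for one species (columns
#'   `longitude`, `latitude`; optionally `species`), or a data frame of
#'   coordinates.
#' @param species Optional species label stored in the model.
#' @return An object of class `range_model`: list with `species`,
#'   `center` (named numeric, `lon`/`lat`), `hull` (CCW vertex matrix),
#'   `n_points`.
#' @export
build_range_model <- function(records, species = NULL) {
  if (is.null(species) && "species" %in% names(records)) {
    species <- unique(records$species)
    if (length(species) > 1) {
      stop("build_range_model expects records of a single species", call. = FALSE)
    }
  }
  keep <- !is.na(records$longitude) & !is.na(records$latitude)
  lon <- records$longitude[keep]; lat <- records$latitude[keep]
  if (length(lon) < 3) {
    stop("degenerate range for species ", species %||% "<unknown>",
         ": fewer than 3 coordinate-bearing records", call. = FALSE)
  }
  if (diff(range(lon)) > 180) {
    stop("species ", species %||% "<unknown>",
         " longitudes span > 180 degrees (antimeridian wrap not supported)",
         call. = FALSE)
  }
  hull <- convex_hull(lon, lat)
  structure(list(species = species %||% NA_character_,
                 center = c(lon = mean(lon), lat = mean(lat)),
                 hull = hull,
                 n_points = length(lon)),
            class = "range_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.range_model <- function(x, ...) {
  cat("Range model", if (!is.na(x$species)) paste0("for '", x$species, "'") else "",
      "\n  n_points:", x$n_points,
      "\n  center: (", signif(x$center["lon"], 6), ",", signif(x$center["lat"], 6), ")",
      "\n  hull vertices:", nrow(x$hull), "\n")
  invisible(x)
}

#' Minimum great-circle distance to the hull boundary
#'
#' Unsigned boundary distance (interior and exterior points alike):
#' the minimum over hull edges of the point-to-geodesic-segment distance.
#'
#' @param lon,lat Point coordinates, decimal degrees (vectorized).
#' @param model A `range_model`.
#' @param radius Sphere radius in meters.
#' @return Numeric vector of distances in meters.
#' @export
distance_to_hull <- function(lon, lat, model, radius = earth_radius) {
  v <- model$hull
  nv <- nrow(v)
  d <- rep(Inf, max(length(lon), length(lat)))
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    d <- pmin(d, point_to_geodesic_segment(lon, lat, v[i, 1], v[i, 2],
                                           v[j, 1], v[j, 2], radius))
  }
  d
}

#' Proportional range marginality
#'
#' For each point, the great-circle distance to the species range center
#' divided by the sum of that distance and the minimum great-circle
#' distance to the convex hull of all occurrence coordinates:
#' \deqn{r = d_{center} / (d_{center} + d_{margin}).}
#' Values increase from 0 for datapoints at the range center to 1 at the
#' range margin. A point exactly at the center yields exactly 0; a point
#' exactly on the hull boundary yields exactly 1.
#'
#' @param lon,lat Point coordinates, decimal degrees (vectorized).
#' @param model A `range_model`.
#' @param radius Sphere radius in meters.
#' @return Tibble with `d_center`, `d_margin` (meters) and `r` in `[0, 1]`.
#' @export
marginality <- function(lon, lat, model, radius = earth_radius) {
  d_center <- great_circle_distance(lon, lat, unname(model$center["lon"]),
                                    unname(model$center["lat"]), radius)
  d_margin <- distance_to_hull(lon, lat, model, radius)
  if (any(d_center == 0 & d_margin == 0)) {
    stop("undefined marginality: point at a degenerate hull's center/boundary",
         call. = FALSE)
  }
  r <- ifelse(d_center == 0, 0, d_center / (d_center + d_margin))
  tibble::tibble(d_center = d_center, d_margin = d_margin, r = r)
}

#' Export a range model as GeoJSON
#'
#' Writes the hull as a Polygon feature and the center as a Point
#' feature (WGS84, longitude-first coordinate order).
#'
#' @param model A `range_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
range_model_geojson <- function(model, path) {
  ring <- rbind(model$hull, model$hull[1, , drop = FALSE])
  fc <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature",
           properties = list(species = model$species, role = "range_hull",
                             n_points = model$n_points),
           geometry = list(type = "Polygon",
                           coordinates = list(lapply(seq_len(nrow(ring)),
                                                     function(i) unname(ring[i, ]))))),
      list(type = "Feature",
           properties = list(species = model$species, role = "range_center"),
           geometry = list(type = "Point",
                           coordinates = unname(model$center)))
    )
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
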