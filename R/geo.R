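# Geodesic distances and square spatial-block tiling shared by thinning,
# pseudo-absence generation and spatial cross-validation.

# Mean Earth radius, km. Fixed for determinism across machines.
EARTH_RADIUS_KM <- 6371.0

# km per degree of latitude on the 6371-km sphere (= R * pi/180).
KM_PER_DEG <- EARTH_RADIUS_KM * pi / 180

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371.0 km. Inputs are recycled;
#' all arguments are in WGS84 decimal degrees.
#'
#' @param lon1,lat1,lon2,lat2 Coordinate vectors.
#' @return Distances in kilometres.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  if (any(!is.finite(c(lon1, lat1, lon2, lat2))))
    stop("non-finite coordinates")
  if (any(abs(lat1) > 90) || any(abs(lat2) > 90))
    stop("latitude out of [-90, 90]")
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dp <- p2 - p1
  dl <- (lon2 - lon1) * pi / 180
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  a <- pmin(a, 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' All pairwise great-circle distances
#'
#' @param p,q Data frames with columns \code{lon}, \code{lat}. \code{q}
#'   defaults to \code{p}.
#' @return \code{nrow(p) x nrow(q)} matrix of kilometres.
#' @export
haversine_matrix <- function(p, q = p) {
  phi1 <- p$lat * pi / 180; phi2 <- q$lat * pi / 180
  lam1 <- p$lon * pi / 180; lam2 <- q$lon * pi / 180
  sdp <- sin(outer(phi1, phi2, function(a, b) (b - a) / 2))^2
  sdl <- sin(outer(lam1, lam2, function(a, b) (b - a) / 2))^2
  a <- sdp + outer(cos(phi1), cos(phi2)) * sdl
  2 * EARTH_RADIUS_KM * asin(sqrt(pmin(a, 1)))
}

# Distance from each point of `p` to its nearest point of `ref`;
# loops over the smaller side so either argument may be large.
dist_to_nearest_km <- function(p, ref) {
  np <- nrow(p); nr <- nrow(ref)
  if (np == 0L) return(numeric(0))
  if (nr == 0L) return(rep(Inf, np))
  if (nr <= np) {
    best <- rep(Inf, np)
    for (i in seq_len(nr))
      best <- pmin(best, haversine_km(p$lon, p$lat, ref$lon[i], ref$lat[i]))
    best
  } else {
    vapply(seq_len(np), function(i)
      min(haversine_km(ref$lon, ref$lat, p$lon[i], p$lat[i])), numeric(1))
  }
}

#' Define a square spatial-block tiling
#'
#' Blocks are squares of edge \code{block_km} in a local equirectangular
#' projection: \code{x = (lon - lon0) * 111.195 * cos(lat_ref)},
#' \code{y = (lat - lat0) * 111.195}, with block indices
#' \code{floor(x / block_km), floor(y / block_km)}. Points exactly on a block
#' edge fall in the higher-index block (half-open cells).
#'
#' @param origin_lon,origin_lat Tiling origin, degrees.
#' @param block_km Block edge length, kilometres (> 0).
#' @param lat_ref Reference latitude for the longitudinal scale, degrees;
#'   typically the domain mid-latitude.
#' @return An object of class \code{block_tiling}.
#' @export
block_tiling <- function(origin_lon, origin_lat, block_km, lat_ref) {
  stopifnot(is.finite(origin_lon), is.finite(origin_lat),
            is.finite(block_km), block_km > 0, is.finite(lat_ref))
  structure(list(origin_lon = origin_lon, origin_lat = origin_lat,
                 block_km = block_km, lat_ref = lat_ref),
            class = "block_tiling")
}

#' Block index of points
#'
#' @param tiling A \code{block_tiling}.
#' @param lon,lat Coordinate vectors, degrees.
#' @return Data frame with integer block coordinates \code{i}, \code{j} and a
#'   combined \code{key} string.
#' @export
block_index <- function(tiling, lon, lat) {
  stopifnot(inherits(tiling, "block_tiling"))
  x <- (lon - tiling$origin_lon) * KM_PER_DEG * cos(tiling$lat_ref * pi / 180)
  y <- (lat - tiling$origin_lat) * KM_PER_DEG
  i <- as.integer(floor(x / tiling$block_km))
  j <- as.integer(floor(y / tiling$block_km))
  data.frame(i = i, j = j, key = paste(i, j, sep = ":"),
             stringsAsFactors = FALSE)
}

# Default tiling for a point set: origin at the south-west corner of the
# points' bounding box, lat_ref at its mid-latitude.
tiling_for_points <- function(points, block_km) {
  block_tiling(min(points$lon), min(points$lat), block_km,
               lat_ref = (min(points$lat) + max(points$lat)) / 2)
}
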