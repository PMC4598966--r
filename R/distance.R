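# Earth mean radius (m) used for great-circle distances
EARTH_RADIUS_M <- 6371008.8

#' Distance between two points, in meters
#'
#' Planar frame: Euclidean distance on projected meters. Geographic frame:
#' great-circle (haversine) distance on a sphere of mean radius 6371008.8 m.
#' Both inputs must share the declared frame.
#'
#' @param a,b points: numeric `c(x, y)` pairs, or single-row [located_points]
#'   objects (whose frames, when present, must agree with `frame`).
#' @param frame coordinate frame the coordinates are expressed in.
#' @return nonnegative distance in meters.
#' @examples
#' pairwise_distance(c(0, 0), c(3, 4), "planar-meters")
#' @export
pairwise_distance <- function(a, b, frame = c("planar-meters", "geographic-wgs84")) {
  frame <- match.arg(frame)
  xy <- function(p) {
    if (inherits(p, "located_points")) {
      if (!identical(point_frame(p), frame))
        stop_spaccess("point frame %s does not match declared frame %s",
                      point_frame(p), frame, class = "spaccess_frame_error")
      as.numeric(c(p$x[1], p$y[1]))
    } else as.numeric(p[1:2])
  }
  a <- xy(a); b <- xy(b)
  assert_finite_num(a, "coordinates"); assert_finite_num(b, "coordinates")
  if (frame == "planar-meters") {
    sqrt(sum((a - b)^2))
  } else {
    if (all(a == b)) return(0)  # distHaversine is exact here anyway; explicit
    geosphere::distHaversine(a, b, r = EARTH_RADIUS_M)
  }
}

# full participant x provider distance matrix (meters); rows = participants
distance_matrix <- function(participants, providers) {
  frame <- check_same_frame(participants, providers)
  if (frame == "planar-meters") {
    dx <- outer(participants$x, providers$x, "-")
    dy <- outer(participants$y, providers$y, "-")
    sqrt(dx^2 + dy^2)
  } else {
    m <- geosphere::distm(cbind(participants$x, participants$y),
                          cbind(providers$x, providers$y),
                          fun = function(p1, p2)
                            geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M))
    m
  }
}

#' Nearest-provider distance for every participant
#'
#' For each participant, the minimum distance over all providers and the id of
#' the nearest provider. Exact distance ties are broken by the
#' lexicographically smallest provider id, for determinism.
#'
#' @param participants,providers [located_points] collections in the same
#'   frame.
#' @return data frame with columns `id`, `distance` (meters), `provider_id`.
#' @export
nearest_provider_distance <- function(participants, providers) {
  if (nrow(providers) == 0)
    stop_spaccess("provider set is empty: no supply to measure distance to",
                  class = "spaccess_empty_supply_error")
  m <- distance_matrix(participants, providers)
  ord <- order(providers$id)  # tie-break by id
  res <- vapply(seq_len(nrow(participants)), function(i) {
    d <- m[i, ]
    j <- ord[which.min(d[ord])]  # first (smallest id) among exact minima
    c(d[j], j)
  }, numeric(2))
  data.frame(id = participants$id,
             distance = res[1, ],
             provider_id = providers$id[res[2, ]],
             stringsAsFactors = FALSE)
}

#' Snap points to their zone centroids
#'
#' Replaces each point's coordinates with the centroid of its administrative
#' zone, the privacy-preserving geocoding convention for address data: the
#' exact address is never analyzed, only the zone center. Idempotent.
#'
#' @param points [located_points] with a `zone_id` column.
#' @param zones zone centroid table: data frame `zone_id`, `x`, `y` (same
#'   frame as `points`), or a [located_points] whose `id` is the zone id.
#' @return `points` with coordinates replaced; ids, order and other columns
#'   unchanged.
#' @export
snap_to_zone_centroid <- function(points, zones) {
  if (inherits(zones, "located_points")) {
    check_same_frame(points, zones)
    zones <- data.frame(zone_id = zones$id, x = zones$x, y = zones$y,
                        stringsAsFactors = FALSE)
  }
  if (!all(c("zone_id", "x", "y") %in% names(zones)))
    stop_spaccess("zone table needs columns zone_id, x, y",
                  class = "spaccess_validation_error")
  if (is.null(points$zone_id) || anyNA(points$zone_id)) {
    off <- if (is.null(points$zone_id)) points$id else points$id[is.na(points$zone_id)]
    stop_spaccess("points missing zone_id: %s",
                  paste(utils::head(off, 5), collapse = ", "),
                  class = "spaccess_validation_error")
  }
  idx <- match(as.character(points$zone_id), as.character(zones$zone_id))
  if (anyNA(idx))
    stop_spaccess("unresolvable zone for point(s): %s",
                  paste(utils::head(points$id[is.na(idx)], 5), collapse = ", "),
                  class = "spaccess_validation_error")
  points$x <- zones$x[idx]
  points$y <- zones$y[idx]
  points
}
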