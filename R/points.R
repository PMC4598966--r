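#' Located point collections
#'
#' A `located_points` object is a data frame with columns `id` (unique,
#' character), `x`, `y` (finite numerics) and optionally `zone_id`, carrying a
#' declared coordinate frame as an attribute. The frame is never guessed:
#' `"planar-meters"` means projected coordinates in meters (distances are
#' Euclidean); `"geographic-wgs84"` means longitude/latitude degrees
#' (distances are great-circle).
#'
#' @param df data frame with at least `id`, `x`, `y`; extra columns are kept.
#' @param frame coordinate frame, one of `"planar-meters"`,
#'   `"geographic-wgs84"`.
#' @return a `located_points` data frame with a `frame` attribute.
#' @examples
#' pts <- located_points(data.frame(id = c("a", "b"), x = c(0, 3), y = c(0, 4)))
#' point_frame(pts)
#' @export
located_points <- function(df, frame = c("planar-meters", "geographic-wgs84")) {
  frame <- match.arg(frame)
  if (!is.data.frame(df) || !all(c("id", "x", "y") %in% names(df)))
    stop_spaccess("point table needs columns id, x, y",
                  class = "spaccess_validation_error")
  df <- as.data.frame(df)
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop_spaccess("duplicate point ids: %s",
                  paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
                  class = "spaccess_validation_error")
  assert_finite_num(df$x, "x coordinates")
  assert_finite_num(df$y, "y coordinates")
  if (frame == "geographic-wgs84" &&
      (any(abs(df$x) > 180) || any(abs(df$y) > 90)))
    stop_spaccess("geographic coordinates out of lon/lat range",
                  class = "spaccess_validation_error")
  structure(df, frame = frame, class = c("located_points", "data.frame"))
}

#' @rdname located_points
#' @param points a `located_points` object.
#' @export
point_frame <- function(points) {
  f <- attr(points, "frame", exact = TRUE)
  if (is.null(f))
    stop_spaccess("object carries no coordinate frame; use located_points()",
                  class = "spaccess_frame_error")
  f
}

check_same_frame <- function(a, b) {
  fa <- point_frame(a); fb <- point_frame(b)
  if (!identical(fa, fb))
    stop_spaccess("coordinate frame mismatch: %s vs %s", fa, fb,
                  class = "spaccess_frame_error")
  fa
}

#' @export
print.located_points <- function(x, ...) {
  cat(sprintf("<located_points> %d points, frame %s\n",
              nrow(x), point_frame(x)))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("... %d more\n", nrow(x) - 6L))
  invisible(x)
}

#' Read and write point tables as CSV
#'
#' CSV dialect: UTF-8, header `id,x,y[,zone_id,...]`. The coordinate frame is
#' supplied by the caller (from configuration), never inferred from the file.
#'
#' @param path file path.
#' @param frame coordinate frame of the stored coordinates.
#' @return `read_points_csv()` returns a [located_points] object;
#'   `write_points_csv()` returns `path` invisibly.
#' @export
read_points_csv <- function(path, frame = c("planar-meters", "geographic-wgs84")) {
  frame <- match.arg(frame)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) stop_spaccess("cannot read %s: %s", path,
                                      conditionMessage(e),
                                      class = "spaccess_io_error"))
  if (!all(c("id", "x", "y") %in% names(df)))
    stop_spaccess("%s: header must contain id,x,y", path,
                  class = "spaccess_io_error")
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$x))) |
               !is.finite(suppressWarnings(as.numeric(df$y))))
  if (length(bad))
    stop_spaccess("%s: non-numeric coordinates on data line(s) %s", path,
                  paste(utils::head(bad + 1L, 5), collapse = ", "),
                  class = "spaccess_io_error")
  df$x <- as.numeric(df$x); df$y <- as.numeric(df$y)
  located_points(df, frame)
}

#' @rdname read_points_csv
#' @param points a [located_points] object.
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write point collections as GeoJSON
#'
#' Reads/writes a FeatureCollection of `Point` features. The feature `id` is
#' taken from the feature-level `id` member or, failing that, from an `id`
#' property; all other properties become columns.
#'
#' @inheritParams read_points_csv
#' @return `read_points_geojson()` returns a [located_points] object.
#' @export
read_points_geojson <- function(path, frame = c("planar-meters", "geographic-wgs84")) {
  frame <- match.arg(frame)
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop_spaccess("%s: not a GeoJSON FeatureCollection", path,
                  class = "spaccess_io_error")
  feats <- gj$features %||% list()
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    if (!identical(f$geometry$type, "Point"))
      stop_spaccess("%s: feature %d is not a Point", path, i,
                    class = "spaccess_io_error")
    props <- f$properties %||% list()
    id <- f$id %||% props$id
    if (is.null(id))
      stop_spaccess("%s: feature %d has no id", path, i,
                    class = "spaccess_io_error")
    props$id <- NULL
    c(list(id = as.character(id),
           x = as.numeric(f$geometry$coordinates[[1]]),
           y = as.numeric(f$geometry$coordinates[[2]])),
      lapply(props, function(p) p %||% NA))
  })
  cols <- unique(unlist(lapply(rows, names)))
  df <- as.data.frame(lapply(cols, function(cn)
    unlist(lapply(rows, function(r) r[[cn]] %||% NA))), stringsAsFactors = FALSE)
  names(df) <- cols
  located_points(df, frame)
}

#' @rdname read_points_geojson
#' @param points a [located_points] object.
#' @export
write_points_geojson <- function(points, path) {
  extra <- setdiff(names(points), c("id", "x", "y"))
  feats <- lapply(seq_len(nrow(points)), function(i) {
    props <- as.list(as.data.frame(points)[i, extra, drop = FALSE])
    list(type = "Feature",
         id = points$id[i],
         geometry = list(type = "Point",
                         coordinates = c(points$x[i], points$y[i])),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
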