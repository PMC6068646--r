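#' Construct a planar polyline
#'
#' A polyline is an ordered sequence of planar vertices (meters, projected
#' coordinates) used to represent the contaminating canal. Consecutive
#' vertices must be distinct so every segment has positive length.
#'
#' @param x,y Numeric vectors of vertex coordinates (meters). Alternatively
#'   `x` may be a two-column matrix or data frame of coordinates.
#' @return An object of class `"polyline"`: a list with a `vertices` matrix
#'   (columns `x`, `y`) and the cumulative `length` in meters.
#' @examples
#' canal <- polyline(c(0, 100, 250), c(0, 10, -5))
#' canal
#' @export
polyline <- function(x, y = NULL) {
  if (is.null(y)) {
    x <- as.matrix(x)
    stopifnot(ncol(x) == 2)
    y <- x[, 2]
    x <- x[, 1]
  }
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("a polyline needs at least 2 vertices")
  v <- cbind(x = as.numeric(x), y = as.numeric(y))
  if (!all(is.finite(v))) stop("polyline vertices must be finite")
  seg <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
  if (any(seg == 0)) stop("consecutive polyline vertices must be distinct")
  structure(list(vertices = v, length = sum(seg)), class = "polyline")
}

#' @export
print.polyline <- function(x, ...) {
  cat(sprintf("Polyline: %d vertices, total length %.1f m\n",
              nrow(x$vertices), x$length))
  invisible(x)
}

#' Minimum distance from points to a polyline
#'
#' Shortest Euclidean distance from each query point to any segment of the
#' polyline, in the planar (projected) coordinate system. This is the
#' distance-to-canal covariate that drives the external drift.
#'
#' @param x,y Numeric vectors of point coordinates (meters), or `x` a
#'   two-column matrix/data frame.
#' @param canal A [polyline()].
#' @return Numeric vector of distances (meters), one per point.
#' @examples
#' canal <- polyline(c(0, 4), c(0, 0))
#' distance_to_polyline(2, 3, canal) # perpendicular foot inside the segment
#' @export
distance_to_polyline <- function(x, y = NULL, canal) {
  if (is.null(y)) {
    x <- as.matrix(x)
    y <- x[, 2]
    x <- x[, 1]
  }
  stopifnot(inherits(canal, "polyline"))
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("query coordinates must be finite")
  }
  v <- canal$vertices
  n <- length(x)
  d2 <- rep(Inf, n)
  # point-to-segment distance, one segment at a time (vectorized over points)
  for (i in seq_len(nrow(v) - 1L)) {
    ax <- v[i, 1]; ay <- v[i, 2]
    bx <- v[i + 1L, 1]; by <- v[i + 1L, 2]
    ux <- bx - ax; uy <- by - ay
    L2 <- ux * ux + uy * uy
    t <- ((x - ax) * ux + (y - ay) * uy) / L2
    t <- pmin(1, pmax(0, t))
    dx <- x - (ax + t * ux)
    dy <- y - (ay + t * uy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

#' Floored base-10 log distance
#'
#' The drift covariate: `log10(max(d, floor))`. Distances below the floor
#' (default 1 m) are clamped so the logarithm stays finite; at the scale of
#' the study region (kilometers) the clamp is negligible.
#'
#' @param d Distances in meters (non-negative).
#' @param floor Positive clamp in meters, default 1.
#' @return `log10(pmax(d, floor))`, dimensionless.
#' @export
log_distance <- function(d, floor = 1) {
  stopifnot(floor > 0)
  if (any(d < 0, na.rm = TRUE)) stop("distances must be non-negative")
  log10(pmax(d, floor))
}

#' Read canal geometry from GeoJSON or WKT
#'
#' Accepts a GeoJSON file containing a `LineString` geometry (possibly
#' wrapped in a Feature or FeatureCollection) or a WKT `LINESTRING` string /
#' file. Coordinates must be planar meters, matching the soil table.
#'
#' @param path Path to a `.geojson`/`.json` file, a file containing WKT, or
#'   a literal WKT `LINESTRING(...)` string.
#' @return A [polyline()].
#' @export
read_canal <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path, warn = FALSE), collapse = "\n") else path
  if (grepl("^\\s*LINESTRING", txt, ignore.case = TRUE)) {
    return(parse_wkt_linestring(txt))
  }
  g <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  coords <- extract_linestring_coords(g)
  xy <- do.call(rbind, lapply(coords, function(p) as.numeric(unlist(p)[1:2])))
  polyline(xy)
}

extract_linestring_coords <- function(g) {
  if (identical(g$type, "LineString")) return(g$coordinates)
  if (identical(g$type, "Feature")) return(extract_linestring_coords(g$geometry))
  if (identical(g$type, "FeatureCollection")) {
    for (f in g$features) {
      out <- tryCatch(extract_linestring_coords(f), error = function(e) NULL)
      if (!is.null(out)) return(out)
    }
  }
  stop("no LineString geometry found in GeoJSON")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal WKT LINESTRING reader (planar coordinates)
parse_wkt_linestring <- function(txt) {
  body <- sub("^\\s*LINESTRING\\s*\\(", "", txt, ignore.case = TRUE)
  body <- sub("\\)\\s*$", "", body)
  pairs <- strsplit(trimws(strsplit(body, ",")[[1]]), "\\s+")
  xy <- do.call(rbind, lapply(pairs, function(p) as.numeric(p[1:2])))
  polyline(xy)
}

#' Write canal geometry as GeoJSON
#'
#' @param canal A [polyline()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_canal_geojson <- function(canal, path) {
  stopifnot(inherits(canal, "polyline"))
  obj <- list(type = "LineString",
              coordinates = unname(apply(canal$vertices, 1, as.list)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
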