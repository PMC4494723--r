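#' Read region polygons from GeoJSON
#'
#' Supports `FeatureCollection`s of `Polygon`/`MultiPolygon` features in
#' WGS84 lon/lat. The region identifier is taken from the feature's
#' `properties$region_id`, then `properties$name`, then the feature `id`.
#' Rings must be closed (first point equals last) with at least four points;
#' interior rings are holes, handled by even-odd counting.
#'
#' @param path Path to a GeoJSON file.
#' @return A `region_polygons` object: a named list of regions, each a list
#'   with `region_id` and `rings` (two-column lon/lat matrices).
#' @export
read_region_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else if (identical(gj$type, "Feature")) list(gj)
           else abort("GeoJSON must be a Feature or FeatureCollection")
  ring_mat <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (nrow(m) < 4) abort("polygon ring must have at least 4 points")
    if (!isTRUE(all.equal(m[1, ], m[nrow(m), ]))) {
      abort("polygon ring must be closed (first point = last point)")
    }
    colnames(m) <- c("lon", "lat")
    m
  }
  regions <- lapply(feats, function(f) {
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(poly) lapply(poly, ring_mat)),
                            recursive = FALSE),
      abort(sprintf("unsupported geometry type: %s", geom$type))
    )
    id <- f$properties$region_id %||% f$properties$name %||% f$id %||% "region"
    list(region_id = as.character(id), rings = rings)
  })
  names(regions) <- vapply(regions, `[[`, character(1), "region_id")
  structure(regions, class = "region_polygons")
}

#' Synthetic two-state region fixture
#'
#' Coarse rectangular stand-ins for Mississippi and Alabama, shipped for
#' deterministic offline testing of containment logic. They are not
#' cartographic boundaries; load real ones with [read_region_geojson()].
#'
#' @return A `region_polygons` object with regions `"MS"` and `"AL"`.
#' @export
synthetic_regions <- function() {
  read_region_geojson(system.file("extdata", "synthetic_ms_al_regions.geojson",
                                  package = "crisistri", mustWork = TRUE))
}

# Even-odd crossing count for points against one ring; boundary -> inside.
# px, py vectors; ring a closed lon/lat matrix.
ring_crossings <- function(px, py, ring) {
  n <- nrow(ring) - 1L
  inside <- rep(FALSE, length(px))
  boundary <- rep(FALSE, length(px))
  eps <- 1e-12
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1L, 1]; y2 <- ring[i + 1L, 2]
    # on-segment test (collinear and within bounding box)
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    seg_len2 <- (x2 - x1)^2 + (y2 - y1)^2
    on_seg <- abs(cross) <= eps * max(1, seg_len2) &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    boundary <- boundary | on_seg
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xint))
    }
  }
  list(inside = inside, boundary = boundary)
}

#' Point-in-region containment lookup
#'
#' Even-odd (ray-casting) containment of lon/lat points against a set of
#' region polygons. Points on a ring boundary count as inside; holes are
#' supported via even-odd counting over a region's rings.
#'
#' @param lon,lat Numeric vectors of equal length, WGS84 degrees.
#' @param polygons A `region_polygons` object.
#' @return Character vector: the containing `region_id`, or `NA` when no
#'   region contains the point. Points with `NA` coordinates return `NA`.
#' @export
point_in_region <- function(lon, lat, polygons) {
  if (length(lon) != length(lat)) abort("lon and lat must have equal length")
  ok <- !is.na(lon) & !is.na(lat)
  if (any(lon[ok] < -180 | lon[ok] > 180 | lat[ok] < -90 | lat[ok] > 90)) {
    abort("coordinates out of WGS84 range")
  }
  out <- rep(NA_character_, length(lon))
  if (!any(ok)) return(out)
  for (reg in polygons) {
    undecided <- ok & is.na(out)
    if (!any(undecided)) break
    px <- lon[undecided]; py <- lat[undecided]
    inside <- rep(FALSE, length(px)); boundary <- rep(FALSE, length(px))
    for (ring in reg$rings) {
      rc <- ring_crossings(px, py, ring)
      inside <- xor(inside, rc$inside)
      boundary <- boundary | rc$boundary
    }
    hit <- inside | boundary
    out[which(undecided)[hit]] <- reg$region_id
  }
  out
}
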