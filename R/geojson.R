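# Minimal GeoJSON polygon I/O via jsonlite. Only Polygon / MultiPolygon
# geometries are read; holes (inner rings) are ignored, which is documented
# behaviour for the layer-association tests.

#' Read polygons from a GeoJSON FeatureCollection
#'
#' @param path GeoJSON file path (WGS84 lon/lat).
#' @param name_property Feature property used to name polygons (default
#'   `"name"`; falls back to feature `id`, then a running index).
#' @return A named list of polygons; each polygon is a list of outer-ring
#'   matrices (lon, lat).
#' @export
read_geojson_polygons <- function(path, name_property = "name") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else if (identical(gj$type, "Feature")) list(gj)
           else stop("expected a Feature or FeatureCollection")
  ring_mat <- function(ring)
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  out <- list()
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    g <- f$geometry
    rings <- switch(g$type,
      Polygon = list(ring_mat(g$coordinates[[1]])),
      MultiPolygon = lapply(g$coordinates, function(poly) ring_mat(poly[[1]])),
      NULL)
    if (is.null(rings)) next
    nm <- f$properties[[name_property]] %||% f$id %||% paste0("feature", k)
    out[[as.character(nm)]] <- rings
  }
  out
}

#' Write polygons to a GeoJSON FeatureCollection
#'
#' @param polys Named list of polygons (ring matrix or list of ring
#'   matrices each).
#' @param path Output path.
#' @param properties Optional data.frame of per-feature properties (row order
#'   matching `polys`).
#' @return `path`, invisibly.
#' @export
write_geojson_polygons <- function(polys, path, properties = NULL) {
  close_ring <- function(r) if (all(r[1, ] == r[nrow(r), ])) r else rbind(r, r[1, ])
  feats <- lapply(seq_along(polys), function(k) {
    rings <- .as_rings(polys[[k]])
    coords <- lapply(rings, function(r) {
      r <- close_ring(r)
      list(lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2])))
    })
    props <- list(name = names(polys)[k] %||% paste0("feature", k))
    if (!is.null(properties)) props <- c(props, as.list(properties[k, , drop = FALSE]))
    list(type = "Feature", properties = props,
         geometry = if (length(coords) == 1)
           list(type = "Polygon", coordinates = coords[[1]])
         else list(type = "MultiPolygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
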