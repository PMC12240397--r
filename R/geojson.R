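#' Write polygon layers to GeoJSON
#'
#' Serializes a polygon tibble (`layer`, `name`, `polygon_id`, `lon`,
#' `lat`; one ring per polygon, WGS84) as a GeoJSON FeatureCollection.
#' Rings are closed on write.
#'
#' @param polygons Polygon tibble.
#' @param path Output `.geojson` path.
#' @return The path, invisibly.
#' @export
write_polygons_geojson <- function(polygons, path) {
  feats <- lapply(split(polygons, polygons$polygon_id), function(p) {
    ring <- cbind(p$lon, p$lat)
    ring <- rbind(ring, ring[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(layer = p$layer[1], name = p$name[1],
                        polygon_id = p$polygon_id[1]),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  fc <- list(type = "FeatureCollection", features = unname(feats))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygon layers from GeoJSON
#'
#' Reads a FeatureCollection of (multi)polygons back into the package's
#' polygon tibble. Degenerate rings (fewer than three distinct vertices)
#' are rejected with a report; duplicated closing vertices are dropped.
#'
#' @param path A `.geojson` file.
#' @return A polygon tibble (`layer`, `name`, `polygon_id`, `lon`, `lat`).
#' @export
read_polygons_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- list()
  pid <- 0L
  n_rejected <- 0L
  for (ft in fc$features) {
    props <- ft$properties %||% list()
    geom <- ft$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      abort(sprintf("unsupported geometry type '%s'", geom$type))
    )
    for (poly in polys) {
      ring <- do.call(rbind, lapply(poly[[1]], function(v) {
        c(as.numeric(v[[1]]), as.numeric(v[[2]]))
      }))
      if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ])) {
        ring <- ring[-nrow(ring), , drop = FALSE]
      }
      if (nrow(unique(ring)) < 3) {
        n_rejected <- n_rejected + 1L
        next
      }
      pid <- pid + 1L
      rows[[pid]] <- tibble::tibble(
        layer = props$layer %||% NA_character_,
        name = props$name %||% NA_character_,
        polygon_id = pid, lon = ring[, 1], lat = ring[, 2]
      )
    }
  }
  if (n_rejected > 0) {
    warn(sprintf("%d degenerate ring(s) rejected", n_rejected))
  }
  dplyr::bind_rows(rows)
}

#' Write a per-cell grid table (and optional GeoJSON priority layer)
#'
#' @param grid A `discovery_grid` tibble.
#' @param path Output `.csv` path for the per-cell table.
#' @param geojson_path Optional `.geojson` path: each cell is written as a
#'   rectangle feature with its per-cell attributes.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, geojson_path = NULL) {
  readr::write_csv(tibble::as_tibble(grid), path, progress = FALSE)
  if (!is.null(geojson_path)) {
    feats <- lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      ring <- rbind(c(g$xmin, g$ymin), c(g$xmax, g$ymin),
                    c(g$xmax, g$ymax), c(g$xmin, g$ymax),
                    c(g$xmin, g$ymin))
      props <- as.list(g[setdiff(names(g),
                                 c("xmin", "xmax", "ymin", "ymax"))])
      list(type = "Feature", properties = props,
           geometry = list(type = "Polygon", coordinates = list(ring)))
    })
    jsonlite::write_json(
      list(type = "FeatureCollection", features = unname(feats)),
      geojson_path, auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  invisible(path)
}
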