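#' Build a rectangular analysis grid over an extent
#'
#' Non-overlapping cells tiling the extent with a half-open boundary
#' convention (`[min, max)` on both axes), so a point on a shared edge
#' falls in exactly one cell. Supported resolutions are 0.1, 0.5, 1 and 2
#' decimal degrees, plus `"geohash156"`: 1.40625-degree cells anchored to
#' the global geohash lattice (about 156 km at the equator).
#'
#' @param extent Named numeric vector `c(xmin, xmax, ymin, ymax)` in WGS84
#'   decimal degrees.
#' @param resolution One of 0.1, 0.5, 1, 2 (degrees) or `"geohash156"`.
#' @return A tibble of class `discovery_grid` with `cell_id`, `xmin`,
#'   `xmax`, `ymin`, `ymax`.
#' @export
#' @examples
#' build_grid(c(xmin = 0, xmax = 4, ymin = 0, ymax = 4), 2)
build_grid <- function(extent, resolution = 1) {
  ext <- extent
  stopifnot(all(c("xmin", "xmax", "ymin", "ymax") %in% names(ext)))
  if (identical(resolution, "geohash156")) {
    h <- 1.40625
    x0 <- -180 + h * floor((ext[["xmin"]] + 180) / h)
    y0 <- -90 + h * floor((ext[["ymin"]] + 90) / h)
  } else {
    if (!is.numeric(resolution) || !resolution %in% c(0.1, 0.5, 1, 2)) {
      abort("unsupported resolution; use 0.1, 0.5, 1, 2 or \"geohash156\"")
    }
    h <- resolution
    x0 <- ext[["xmin"]]
    y0 <- ext[["ymin"]]
  }
  nx <- ceiling((ext[["xmax"]] - x0) / h - 1e-9)
  ny <- ceiling((ext[["ymax"]] - y0) / h - 1e-9)
  xs <- x0 + h * (seq_len(nx) - 1)
  ys <- y0 + h * (seq_len(ny) - 1)
  grid <- tidyr::expand_grid(ymin = ys, xmin = xs)
  out <- tibble::tibble(
    cell_id = sprintf("c%05d", seq_len(nrow(grid))),
    xmin = grid$xmin, xmax = grid$xmin + h,
    ymin = grid$ymin, ymax = grid$ymin + h
  )
  attr(out, "extent") <- ext
  attr(out, "cell_size") <- h
  class(out) <- c("discovery_grid", class(out))
  out
}

#' Count occurrence records and observed richness per grid cell
#'
#' Exact point-in-cell assignment under the grid's half-open boundary
#' convention. Records with malformed coordinates or falling outside the
#' grid are rejected and counted in the `"n_rejected"` attribute.
#'
#' @param occurrences A data frame with `decimalLongitude`,
#'   `decimalLatitude` and (for richness) `species` columns.
#' @param grid A `discovery_grid` from [build_grid()].
#' @return The grid with `n_records` and `s_obs_cell` columns added.
#' @export
count_points_in_cells <- function(occurrences, grid) {
  lon <- occurrences$decimalLongitude
  lat <- occurrences$decimalLatitude
  bad <- !is.finite(lon) | !is.finite(lat)
  h <- attr(grid, "cell_size")
  x0 <- min(grid$xmin)
  y0 <- min(grid$ymin)
  nx <- length(unique(grid$xmin))
  ny <- length(unique(grid$ymin))
  ix <- floor((lon - x0) / h)
  iy <- floor((lat - y0) / h)
  outside <- !bad & (ix < 0 | ix >= nx | iy < 0 | iy >= ny)
  keep <- !bad & !outside
  # cells are laid out row-major (y outer, x inner) by build_grid
  cell_idx <- iy[keep] * nx + ix[keep] + 1
  counts <- tabulate(cell_idx, nbins = nrow(grid))
  sp <- occurrences$species %||% rep(NA_character_, length(lon))
  rich <- rep(0L, nrow(grid))
  if (any(keep)) {
    rich_tb <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(cell = cell_idx, species = sp[keep]),
                      .data$cell),
      s = dplyr::n_distinct(.data$species), .groups = "drop"
    )
    rich[rich_tb$cell] <- rich_tb$s
  }
  out <- dplyr::mutate(grid, n_records = counts, s_obs_cell = rich)
  attr(out, "extent") <- attr(grid, "extent")
  attr(out, "cell_size") <- h
  attr(out, "n_rejected") <- sum(bad) + sum(outside)
  class(out) <- class(grid)
  out
}

#' Equal-count (quantile) classification
#'
#' Bins cell values into `n_classes` classes holding approximately equal
#' numbers of cells, the classification used for the collection-density
#' colour scale. Class boundaries sit at empirical quantiles; tied values
#' are assigned to the lower class (all-equal input is all class 1).
#'
#' @param values Numeric vector (one per cell).
#' @param n_classes Number of classes (default 10).
#' @return Integer class per value, 1 (lowest) to `n_classes`.
#' @export
#' @examples
#' table(classify_quantiles(1:100, 10))
classify_quantiles <- function(values, n_classes = 10) {
  n <- length(values)
  if (n < n_classes) {
    warn(sprintf("only %d cells for %d classes: degenerate classification",
                 n, n_classes))
  }
  r <- rank(values, ties.method = "min")
  cls <- ceiling(n_classes * r / n)
  pmin(pmax(as.integer(cls), 1L), as.integer(n_classes))
}

#' Per-cell inventory completeness from occurrence incidence
#'
#' Estimates each cell's true richness with a Chao-type nonparametric
#' incidence estimator -- `S_est = S_obs + f1^2 / (2 f2)` where `f1`, `f2`
#' are the numbers of species seen once and twice; when `f2 = 0` the
#' bias-corrected form `S_obs + f1 (f1 - 1) / 2` is used -- and reports
#' `100 * S_obs / S_est`. Cells with fewer than `min_records` records get
#' a missing completeness (too little signal to estimate).
#'
#' @param occurrences Data frame with `decimalLongitude`,
#'   `decimalLatitude`, `species`.
#' @param grid A `discovery_grid` (with or without counts).
#' @param min_records Minimum records per cell (default 5).
#' @return The grid with `s_est_cell` and `completeness_cell` columns.
#' @export
cell_completeness <- function(occurrences, grid, min_records = 5) {
  if (!"n_records" %in% names(grid)) {
    grid <- count_points_in_cells(occurrences, grid)
  }
  h <- attr(grid, "cell_size")
  x0 <- min(grid$xmin)
  y0 <- min(grid$ymin)
  nx <- length(unique(grid$xmin))
  ny <- length(unique(grid$ymin))
  lon <- occurrences$decimalLongitude
  lat <- occurrences$decimalLatitude
  keep <- is.finite(lon) & is.finite(lat)
  ix <- floor((lon[keep] - x0) / h)
  iy <- floor((lat[keep] - y0) / h)
  inside <- ix >= 0 & ix < nx & iy >= 0 & iy < ny
  cell_idx <- iy[inside] * nx + ix[inside] + 1
  sp <- occurrences$species[keep][inside]

  ab <- dplyr::count(tibble::tibble(cell = cell_idx, species = sp),
                     .data$cell, .data$species)
  est <- ab |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(
      s_obs = dplyr::n(),
      f1 = sum(.data$n == 1), f2 = sum(.data$n == 2),
      .groups = "drop"
    ) |>
    dplyr::mutate(s_est = .data$s_obs +
                    ifelse(.data$f2 > 0, .data$f1^2 / (2 * .data$f2),
                           .data$f1 * (.data$f1 - 1) / 2))
  s_est <- rep(NA_real_, nrow(grid))
  s_est[est$cell] <- est$s_est
  out <- dplyr::mutate(
    grid,
    s_est_cell = s_est,
    completeness_cell = ifelse(
      .data$n_records >= min_records & !is.na(s_est) & s_est > 0,
      100 * .data$s_obs_cell / s_est, NA_real_
    )
  )
  attr(out, "extent") <- attr(grid, "extent")
  attr(out, "cell_size") <- h
  class(out) <- class(grid)
  out
}

#' Discovery-priority score per cell
#'
#' Combines the collection-density deficit (`1 - density_class / 10`) and
#' the completeness deficit (`1 - completeness / 100`, with missing
#' completeness treated as a full deficit of 1: an unsurveyed cell is
#' maximally attractive) by an equal-weight mean, scaled to 0-10 and
#' rounded half-up. 10 marks the highest discovery potential; lower
#' density and lower completeness never decrease the score.
#'
#' @param grid A grid with `n_records` and `completeness_cell` columns
#'   (`density_class` is computed from `n_records` if absent).
#' @param weights Length-2 weights for the density and completeness
#'   deficits (default equal).
#' @return The grid with `density_class` and `priority` (integer 0-10)
#'   columns.
#' @export
priority_score <- function(grid, weights = c(0.5, 0.5)) {
  stopifnot(length(weights) == 2, all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  if (!"density_class" %in% names(grid)) {
    grid$density_class <- classify_quantiles(grid$n_records, 10)
  }
  deficit_density <- 1 - grid$density_class / 10
  deficit_completeness <- ifelse(is.na(grid$completeness_cell), 1,
                                 1 - grid$completeness_cell / 100)
  score <- 10 * (weights[1] * deficit_density +
                   weights[2] * deficit_completeness)
  out <- dplyr::mutate(grid,
                       priority = pmin(pmax(floor(score + 0.5), 0), 10))
  attr(out, "extent") <- attr(grid, "extent")
  attr(out, "cell_size") <- attr(grid, "cell_size")
  class(out) <- class(grid)
  out
}

# --- rectangle/polygon intersection primitives -------------------------------

# Sutherland-Hodgman clip of a polygon ring (matrix with columns x, y)
# against an axis-aligned rectangle.
clip_ring_rect <- function(ring, xmin, xmax, ymin, ymax) {
  clip_edge <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      prev <- pts[if (i == 1) n else i - 1, ]
      cin <- inside(cur)
      pin <- inside(prev)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p, q, val, axis) {
    # intersection of segment p-q with the line axis = val
    tt <- (val - p[axis]) / (q[axis] - p[axis])
    p + tt * (q - p)
  }
  pts <- ring
  pts <- clip_edge(pts, function(p) p[1] >= xmin,
                   function(p, q) ix(p, q, xmin, 1))
  pts <- clip_edge(pts, function(p) p[1] <= xmax,
                   function(p, q) ix(p, q, xmax, 1))
  pts <- clip_edge(pts, function(p) p[2] >= ymin,
                   function(p, q) ix(p, q, ymin, 2))
  pts <- clip_edge(pts, function(p) p[2] <= ymax,
                   function(p, q) ix(p, q, ymax, 2))
  pts
}

shoelace_area <- function(pts) {
  n <- nrow(pts)
  if (is.null(n) || n < 3) return(0)
  x <- pts[, 1]
  y <- pts[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Area of intersection between a rectangle and one polygon ring.
rect_polygon_intersection_area <- function(xmin, xmax, ymin, ymax, ring) {
  shoelace_area(clip_ring_rect(ring, xmin, xmax, ymin, ymax))
}

polygon_rings <- function(polygons, layer = NULL) {
  tb <- tibble::as_tibble(polygons)
  if (!is.null(layer)) tb <- dplyr::filter(tb, .data$layer %in% !!layer)
  split(tb, tb$polygon_id) |>
    lapply(function(p) list(name = p$name[1], layer = p$layer[1],
                            ring = cbind(p$lon, p$lat)))
}

#' Assign grid cells to domains by majority area
#'
#' Each cell takes the domain polygon with the largest positive-area
#' intersection (ties break alphabetically); cells touching no domain get
#' NA.
#'
#' @param grid A `discovery_grid`.
#' @param polygons A polygon tibble (`layer`, `name`, `polygon_id`, `lon`,
#'   `lat`) whose `"domain"` layer is used.
#' @return The grid with a `domain` column.
#' @export
assign_cell_domains <- function(grid, polygons) {
  rings <- polygon_rings(polygons, "domain")
  dom <- vapply(seq_len(nrow(grid)), function(i) {
    areas <- vapply(rings, function(r) {
      rect_polygon_intersection_area(grid$xmin[i], grid$xmax[i],
                                     grid$ymin[i], grid$ymax[i], r$ring)
    }, numeric(1))
    if (all(areas <= 1e-12)) return(NA_character_)
    names <- vapply(rings, function(r) r$name, character(1))
    best <- which(areas == max(areas))
    sort(names[best])[1]
  }, character(1))
  out <- dplyr::mutate(grid, domain = dom)
  attr(out, "extent") <- attr(grid, "extent")
  attr(out, "cell_size") <- attr(grid, "cell_size")
  class(out) <- class(grid)
  out
}

#' Overlap of top-priority cells with a polygon layer
#'
#' Ranks cells by discovery priority, takes the top `n_top`, and reports
#' how many have a positive-area intersection with at least one polygon of
#' the layer (duplicated polygons change nothing: union semantics). Ties at
#' the priority cutoff break toward lower completeness, then fewer records,
#' then cell id, so the top set is deterministic.
#'
#' @param grid A grid with a `priority` column (see [priority_score()]).
#' @param polygons Polygon tibble (`layer`, `name`, `polygon_id`, `lon`,
#'   `lat`); pass the layer to test via `layer`. An empty layer gives 0%.
#' @param layer Layer name(s) to test (e.g., `"PA"` or `"TI"`).
#' @param n_top Number of top-priority cells to examine (default 30).
#' @return A one-row tibble of class `overlap_summary`: `layer`, `n_top`,
#'   `n_overlapping`, `pct_overlap`; the per-domain breakdown (when the
#'   grid has a `domain` column) is in the `"by_domain"` attribute, and the
#'   top cells themselves in `"top_cells"`.
#' @export
overlap_stats <- function(grid, polygons, layer, n_top = 30) {
  ord <- order(-grid$priority,
               dplyr::coalesce(grid$completeness_cell, -1),
               grid$n_records, grid$cell_id)
  top <- grid[ord[seq_len(min(n_top, nrow(grid)))], ]
  rings <- if (is.null(polygons) || nrow(polygons) == 0) {
    list()
  } else {
    polygon_rings(polygons, layer)
  }
  hit <- vapply(seq_len(nrow(top)), function(i) {
    for (r in rings) {
      if (rect_polygon_intersection_area(top$xmin[i], top$xmax[i],
                                         top$ymin[i], top$ymax[i],
                                         r$ring) > 1e-12) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  out <- tibble::tibble(
    layer = paste(layer, collapse = "+"),
    n_top = nrow(top), n_overlapping = sum(hit),
    pct_overlap = 100 * sum(hit) / nrow(top)
  )
  if ("domain" %in% names(top)) {
    attr(out, "by_domain") <- top |>
      dplyr::mutate(overlaps = hit) |>
      dplyr::group_by(.data$domain) |>
      dplyr::summarise(n_top = dplyr::n(),
                       n_overlapping = sum(.data$overlaps),
                       .groups = "drop")
  }
  attr(out, "top_cells") <- dplyr::mutate(top, overlaps = hit)
  class(out) <- c("overlap_summary", class(out))
  out
}

#' Grid-based discovery-priority mapping, end to end
#'
#' Convenience wrapper: builds the grid, counts records and richness,
#' estimates per-cell completeness, classifies collection density into
#' decile classes, scores discovery priority, and (optionally) assigns
#' domains.
#'
#' @param occurrences Occurrence data frame (`decimalLongitude`,
#'   `decimalLatitude`, `species`).
#' @param extent Extent vector (see [build_grid()]).
#' @param resolution Grid resolution (see [build_grid()]).
#' @param polygons Optional polygon tibble with a `"domain"` layer.
#' @param min_records Completeness floor (see [cell_completeness()]).
#' @param weights Priority weights (see [priority_score()]).
#' @return A `discovery_grid` tibble with all per-cell columns.
#' @export
map_discovery_priority <- function(occurrences, extent, resolution = 1,
                                   polygons = NULL, min_records = 5,
                                   weights = c(0.5, 0.5)) {
  grid <- build_grid(extent, resolution)
  grid <- count_points_in_cells(occurrences, grid)
  grid <- cell_completeness(occurrences, grid, min_records)
  grid <- priority_score(grid, weights)
  if (!is.null(polygons) && any(polygons$layer == "domain")) {
    grid <- assign_cell_domains(grid, polygons)
  }
  grid
}
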