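sq_extent <- c(xmin = 0, xmax = 4, ymin = 0, ymax = 4)

test_that("grids tile the extent at the supported resolutions", {
  expect_equal(nrow(build_grid(sq_extent, 2)), 4)
  expect_equal(nrow(build_grid(sq_extent, 1)), 4 * nrow(build_grid(sq_extent, 2)))
  expect_equal(nrow(build_grid(sq_extent, 0.5)), 64)
  expect_error(build_grid(sq_extent, 3), "unsupported")
  gh <- build_grid(c(xmin = -10, xmax = 0, ymin = -10, ymax = 0),
                   "geohash156")
  expect_equal(attr(gh, "cell_size"), 1.40625)
  # anchored to the global lattice
  expect_equal((gh$xmin[1] + 180) %% 1.40625, 0)
})

test_that("a point on a shared edge lands in exactly one cell", {
  grid <- build_grid(sq_extent, 2)
  occ <- tibble::tibble(decimalLongitude = 2, decimalLatitude = 2,
                        species = "s1")
  counted <- count_points_in_cells(occ, grid)
  expect_equal(sum(counted$n_records), 1)
  # half-open convention: it belongs to the cell whose min edge it touches
  expect_equal(counted$n_records[counted$xmin == 2 & counted$ymin == 2], 1)
})

test_that("point-in-cell counts match a brute-force double loop", {
  withr::with_seed(99, {
    occ <- tibble::tibble(
      decimalLongitude = runif(1000, 0, 4),
      decimalLatitude = runif(1000, 0, 4),
      species = sample(sprintf("sp%02d", 1:40), 1000, replace = TRUE)
    )
  })
  grid <- build_grid(sq_extent, 1)
  counted <- count_points_in_cells(occ, grid)
  for (i in seq_len(nrow(grid))) {
    inside <- occ$decimalLongitude >= grid$xmin[i] &
      occ$decimalLongitude < grid$xmax[i] &
      occ$decimalLatitude >= grid$ymin[i] &
      occ$decimalLatitude < grid$ymax[i]
    expect_equal(counted$n_records[i], sum(inside))
    expect_equal(counted$s_obs_cell[i],
                 dplyr::n_distinct(occ$species[inside]))
  }
  expect_equal(sum(counted$n_records), 1000)
})

test_that("counts are conserved across resolutions; bad rows are rejected", {
  withr::with_seed(12, {
    occ <- tibble::tibble(decimalLongitude = runif(500, 0, 4),
                          decimalLatitude = runif(500, 0, 4),
                          species = "s")
  })
  for (res in c(0.5, 1, 2)) {
    expect_equal(sum(count_points_in_cells(occ, build_grid(sq_extent,
                                                           res))$n_records),
                 500)
  }
  occ$decimalLongitude[1] <- NA
  occ$decimalLatitude[2] <- 99
  counted <- count_points_in_cells(occ, build_grid(sq_extent, 1))
  expect_equal(attr(counted, "n_rejected"), 2)
  expect_equal(sum(counted$n_records), 498)
})

test_that("quantile classification is equal-count with ties to lower class", {
  cls <- classify_quantiles(1:100, 10)
  expect_equal(as.integer(table(cls)), rep(10L, 10))
  expect_equal(classify_quantiles(rep(7, 20), 10), rep(1L, 20))
  withr::with_seed(2, v <- sample(1:30, 60, replace = TRUE))
  cls <- classify_quantiles(v, 10)
  n_ties <- sum(duplicated(v))
  expect_lte(max(abs(table(factor(cls, levels = 1:10)) - 6)), n_ties)
  expect_warning(classify_quantiles(1:5, 10), "degenerate")
})

test_that("cell completeness follows the Chao-type closed form", {
  # one cell: 4 singletons, 2 doubletons, 4 species seen three times
  occ <- tibble::tibble(
    species = c(sprintf("s%d", 1:4),
                rep(sprintf("d%d", 1:2), each = 2),
                rep(sprintf("t%d", 1:4), each = 3)),
    decimalLongitude = 0.5, decimalLatitude = 0.5
  )
  grid <- build_grid(c(xmin = 0, xmax = 1, ymin = 0, ymax = 1), 1)
  out <- cell_completeness(occ, grid)
  expect_equal(out$s_obs_cell, 10)
  expect_equal(out$s_est_cell, 10 + 4^2 / (2 * 2))
  expect_equal(round(out$completeness_cell, 1), 71.4)
  # every species seen >= 3 times: the inventory is complete
  occ3 <- dplyr::filter(occ, grepl("^t", species))
  expect_equal(cell_completeness(occ3, grid)$completeness_cell, 100)
  # f2 = 0 triggers the bias-corrected form
  occ_f1 <- tibble::tibble(species = sprintf("s%d", 1:5),
                           decimalLongitude = 0.5, decimalLatitude = 0.5)
  out_f1 <- cell_completeness(occ_f1, grid, min_records = 1)
  expect_equal(out_f1$s_est_cell, 5 + 5 * 4 / 2)
  # empty and data-poor cells are missing, not zero
  empty <- cell_completeness(occ[0, ], grid)
  expect_true(is.na(empty$completeness_cell))
  sparse <- cell_completeness(occ[1:3, ], grid, min_records = 5)
  expect_true(is.na(sparse$completeness_cell))
})

test_that("priority scoring is bounded, extreme at the corners, monotone", {
  mk <- function(density_class, completeness) {
    tibble::tibble(cell_id = "c", n_records = 1,
                   density_class = density_class,
                   completeness_cell = completeness)
  }
  expect_equal(priority_score(mk(1, 0))$priority, 10)    # 9.5 rounds up
  expect_equal(priority_score(mk(10, 100))$priority, 0)
  expect_equal(priority_score(mk(1, NA))$priority, 10)   # unsurveyed
  # pairwise dominance: lower density class/completeness never lowers it
  withr::with_seed(44, {
    dc <- sample(1:10, 50, replace = TRUE)
    comp <- runif(50, 0, 100)
  })
  pr <- priority_score(mk(dc, comp))$priority
  for (i in 1:49) {
    for (j in (i + 1):50) {
      if (dc[i] <= dc[j] && comp[i] <= comp[j]) expect_gte(pr[i], pr[j])
    }
  }
  expect_true(all(pr >= 0 & pr <= 10))
})

test_that("priority is scale-free in the record counts", {
  withr::with_seed(7, {
    grid <- build_grid(sq_extent, 1)
    grid$n_records <- rpois(nrow(grid), 20)
    grid$completeness_cell <- runif(nrow(grid), 20, 90)
  })
  p1 <- priority_score(grid)
  grid2 <- grid
  grid2$n_records <- grid$n_records * 7
  p2 <- priority_score(grid2)
  expect_equal(p1$density_class, p2$density_class)
  expect_equal(p1$priority, p2$priority)
})

test_that("overlap statistics count positive-area intersections only", {
  # 30 cells in a 6 x 5 strip; priorities make the top-30 the whole strip
  grid <- build_grid(c(xmin = 0, xmax = 6, ymin = 0, ymax = 5), 1)
  grid$n_records <- 0
  grid$completeness_cell <- NA_real_
  grid$density_class <- 1
  grid <- priority_score(grid)
  rect_poly <- function(id, x0, x1, y0, y1, layer = "PA") {
    tibble::tibble(layer = layer, name = paste0(layer, id),
                   polygon_id = id, lon = c(x0, x1, x1, x0),
                   lat = c(y0, y0, y1, y1))
  }
  # one polygon covering 6 cells (bottom row) -> 20% of 30
  pa <- rect_poly(1, 0.2, 5.8, 0.2, 0.8)
  ov <- overlap_stats(grid, pa, "PA", n_top = 30)
  expect_equal(ov$n_top, 30)
  expect_equal(ov$n_overlapping, 6)
  expect_equal(ov$pct_overlap, 20)
  # covering rows 1-2 and half of row 3 via two polygons -> 15 cells, 50%
  ti <- dplyr::bind_rows(rect_poly(2, 0.1, 5.9, 0.1, 1.9, "TI"),
                         rect_poly(3, 0.1, 2.9, 2.1, 2.9, "TI"))
  ov2 <- overlap_stats(grid, ti, "TI", n_top = 30)
  expect_equal(ov2$n_overlapping, 15)
  expect_equal(ov2$pct_overlap, 50)
  # a polygon touching only an edge has zero intersection area
  edge <- rect_poly(4, -1, 0, 0, 5)
  expect_equal(overlap_stats(grid, edge, "PA", n_top = 30)$n_overlapping, 0)
  # empty layer and duplicated polygons
  expect_equal(overlap_stats(grid, pa[0, ], "PA", n_top = 30)$pct_overlap,
               0)
  doubled <- dplyr::bind_rows(pa, dplyr::mutate(pa, polygon_id = 99))
  expect_equal(overlap_stats(grid, doubled, "PA", n_top = 30)$n_overlapping,
               6)
})

test_that("cells take the domain with the majority of their area", {
  grid <- build_grid(sq_extent, 2)
  polys <- dplyr::bind_rows(
    tibble::tibble(layer = "domain", name = "West", polygon_id = 1,
                   lon = c(0, 1.5, 1.5, 0), lat = c(0, 0, 4, 4)),
    tibble::tibble(layer = "domain", name = "East", polygon_id = 2,
                   lon = c(1.5, 4, 4, 1.5), lat = c(0, 0, 4, 4))
  )
  out <- assign_cell_domains(grid, polys)
  expect_equal(out$domain[out$xmin == 0], c("West", "West"))
  expect_equal(out$domain[out$xmin == 2], c("East", "East"))
})

test_that("polygon GeoJSON round-trips", {
  cfg <- synthetic_config(seed = 8, n_strata = 2, true_asymptote = 100)
  sl <- generate_spatial_layers(cfg)
  path <- tempfile(fileext = ".geojson")
  write_polygons_geojson(sl$polygons, path)
  back <- read_polygons_geojson(path)
  expect_equal(nrow(back), nrow(sl$polygons))
  expect_setequal(unique(back$layer), unique(sl$polygons$layer))
  orig <- dplyr::arrange(sl$polygons, polygon_id)
  expect_equal(back$lon, orig$lon)
  expect_equal(back$lat, orig$lat)
})
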