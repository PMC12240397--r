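test_that("same seed gives byte-identical outputs", {
  cfg <- synthetic_config(seed = 7, n_strata = 2, true_asymptote = 200)
  expect_identical(generate_name_table(cfg), generate_name_table(cfg))
  expect_identical(generate_effort_and_density(cfg),
                   generate_effort_and_density(cfg))
  a <- generate_spatial_layers(cfg)
  b <- generate_spatial_layers(cfg)
  expect_identical(a$occurrences, b$occurrences)
  expect_identical(a$polygons, b$polygons)
})

test_that("without synonyms the all-names and basionym datasets coincide", {
  cfg <- small_cfg(synonym_rate = 0, discordance_rate = 0,
                   missing_primary_rate = 0)
  ds <- build_datasets(generate_name_table(cfg))
  expect_equal(nrow(ds$all_names), nrow(ds$basionyms))
  expect_equal(sort(ds$all_names$year), sort(ds$basionyms$year))
})

test_that("realized species count matches the generating curve at end_year", {
  cfg <- synthetic_config(seed = 11, n_strata = 1, true_asymptote = 500)
  nt <- generate_name_table(cfg)
  n_acc <- sum(nt$status == "accepted" & nt$rank == "species" & nt$native)
  expect_lte(n_acc, 500)
  expect_gte(n_acc, 0.95 * 500)
  # oracle: saturation of the generating curve at the window end
  sat <- exp(-exp(-0.35 * (27 - 8)))
  expect_lt(abs(n_acc - 500 * sat), 4 * sqrt(500 * sat * (1 - sat)) + 3)
})

test_that("cumulative basionym curve is non-decreasing and bounded by N*", {
  cfg <- small_cfg()
  ds <- build_datasets(generate_name_table(cfg))
  ser <- bin_by_decade(ds$basionyms$year)
  expect_true(all(diff(ser$cumulative) >= 0))
  expect_lte(max(ser$cumulative), 400)
  expect_equal(nrow(ser), 27)
})

test_that("realized source discordance is within 3 SE of the configured rate", {
  cfg <- synthetic_config(seed = 3, n_strata = 2, true_asymptote = 800,
                          discordance_rate = 0.05)
  nt <- generate_name_table(cfg)
  acc <- nt[nt$status == "accepted" & nt$rank == "species" & nt$native, ]
  disagree <- !(acc$basionym_year_fb == acc$basionym_year_tropicos &
                  acc$basionym_year_fb == acc$basionym_year_wcvp)
  p_hat <- mean(disagree)
  se <- sqrt(0.05 * 0.95 / nrow(acc))
  expect_lt(abs(p_hat - 0.05), 3 * se)
})

test_that("effort-driven discovery follows the taxonomist schedule", {
  sched <- c(rep(5L, 10), 0L, rep(20L, 16))
  cfg <- synthetic_config(seed = 9, n_strata = 1, true_asymptote = 2000,
                          discovery_shape = "effort_driven",
                          effort_schedule = sched, synonym_rate = 0,
                          nonnative_rate = 0, n_genus_rows = 0)
  nt <- generate_name_table(cfg)
  ser <- bin_by_decade(nt$year_primary[!is.na(nt$year_primary)])
  # a zero-effort decade forces zero descriptions
  expect_equal(ser$described[11], 0)
  # described counts correlate positively with effort (sign check)
  expect_gt(suppressWarnings(
    cor(sched, ser$described, method = "spearman")
  ), 0)
})

test_that("constant effort schedule is reproduced exactly", {
  cfg <- small_cfg(effort_schedule = c(5, 5, 5))
  ed <- generate_effort_and_density(cfg)
  expect_true(all(ed$taxonomists == 5))
  expect_true(all(ed$pop_density > 0))
  expect_true(all(diff(ed$pop_density) >= 0))
})

test_that("spatial layers respect the extent and configured area fractions", {
  cfg <- synthetic_config(seed = 5, n_strata = 2, true_asymptote = 300)
  sl <- generate_spatial_layers(cfg)
  ext <- sl$extent
  expect_true(all(sl$occurrences$decimalLongitude >= ext[["xmin"]] &
                    sl$occurrences$decimalLongitude <= ext[["xmax"]]))
  expect_true(all(sl$occurrences$decimalLatitude >= ext[["ymin"]] &
                    sl$occurrences$decimalLatitude <= ext[["ymax"]]))
  # Monte-Carlo area check of the 30% Indigenous-land coverage
  ti <- dplyr::filter(sl$polygons, layer == "TI")
  withr::with_seed(1, {
    px <- runif(2e4, ext[["xmin"]], ext[["xmax"]])
    py <- runif(2e4, ext[["ymin"]], ext[["ymax"]])
  })
  inside <- rep(FALSE, 2e4)
  for (p in split(ti, ti$polygon_id)) {
    inside <- inside | (px >= min(p$lon) & px < max(p$lon) &
                          py >= min(p$lat) & py < max(p$lat))
  }
  expect_gte(100 * mean(inside), 28)
  expect_lte(100 * mean(inside), 32)
})

test_that("zero cluster count gives spatially uniform occurrences", {
  cfg <- synthetic_config(seed = 13, n_strata = 1, true_asymptote = 500,
                          spatial = list(n_clusters = 0,
                                         n_occurrences = 4000))
  sl <- generate_spatial_layers(cfg)
  grid <- count_points_in_cells(sl$occurrences, build_grid(sl$extent, 2))
  # per-cell counts compatible with an equal-probability multinomial
  p <- suppressWarnings(
    stats::chisq.test(grid$n_records,
                      p = rep(1 / nrow(grid), nrow(grid)))$p.value
  )
  expect_gt(p, 1e-4)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(discovery_shape = "quadratic"), "shape")
  expect_error(synthetic_config(start_year = 2020, end_year = 1753))
  expect_error(synthetic_config(true_asymptote = 0))
  expect_error(synthetic_config(discordance_rate = 1.5))
})
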