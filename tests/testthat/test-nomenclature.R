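test_that("cleaning drops genus/section and non-native rows, resolves years", {
  rows <- dplyr::bind_rows(
    base_name_row("n1", year_primary = 1850),
    base_name_row("g1", rank = "genus"),
    base_name_row("s1", rank = "section"),
    base_name_row("x1", native = FALSE),
    base_name_row("n2", year_primary = NA, year_fallback = 1855)
  )
  rec <- load_names(write_name_fixture(rows))
  expect_setequal(rec$name_id, c("n1", "n2"))
  expect_equal(rec$year[rec$name_id == "n2"], 1855L)
  expect_equal(rec$year_source[rec$name_id == "n2"], "fallback")
  expect_equal(rec$year_source[rec$name_id == "n1"], "primary")
  expect_equal(attr(rec, "n_excluded"), 3)
})

test_that("schema errors name the missing column; empty files load cleanly", {
  rows <- base_name_row("n1")
  p <- write_name_fixture(dplyr::select(rows, -"rank"))
  expect_error(load_names(p), "rank")
  empty <- write_name_fixture(rows[0, ])
  expect_silent(rec <- load_names(empty))
  expect_equal(nrow(rec), 0)
})

test_that("unparseable and out-of-window years are flagged, not fatal", {
  rows <- dplyr::bind_rows(
    base_name_row("n1"),
    base_name_row("n2", year_primary = 1492),
    base_name_row("n3", year_primary = 1900)
  ) |>
    dplyr::mutate(year_primary = as.character(year_primary))
  rows$year_primary[1] <- "MDCCCL"
  expect_warning(expect_warning(rec <- load_names(write_name_fixture(rows)),
                                "parsed"), "outside")
  expect_equal(rec$year_source[rec$name_id %in% c("n1", "n2")],
               c("missing", "missing"))
  expect_equal(rec$year[rec$name_id == "n3"], 1900L)
})

test_that("superseded family names are remapped, unknown ones pass through", {
  expect_equal(remap_family("Caesalpiniaceae"), "Fabaceae")
  expect_equal(remap_family("Leguminosae"), "Fabaceae")
  expect_equal(remap_family("Myrsinaceae"), "Primulaceae")
  expect_equal(remap_family("Bromeliaceae"), "Bromeliaceae")
  expect_equal(remap_family(c("Mimosaceae", "Madeupaceae")),
               c("Fabaceae", "Madeupaceae"))
})

test_that("basionym-year majority rule and earliest-year tie-break", {
  res <- resolve_basionym_year(rbind(
    c(1820, 1820, 1835),
    c(1820, 1820, 1820),
    c(1800, 1810, 1820),
    c(1850, NA, NA)
  ))
  expect_equal(res$year, c(1820L, 1820L, 1800L, 1850L))
  expect_equal(res$flag, c("majority", "unanimous", "conflict", "single"))
  expect_error(resolve_basionym_year(rbind(c(NA, NA, NA))), "missing")
})

test_that("dataset sizes follow the synonym structure", {
  rows <- dplyr::bind_rows(
    base_name_row("a1"),
    base_name_row("a1-s1", status = "synonym", accepted_id = "a1",
                  year_primary = 1860),
    base_name_row("a1-s2", status = "synonym", accepted_id = "a1",
                  year_primary = 1875)
  )
  ds <- build_datasets(rows)
  expect_equal(nrow(ds$all_names), 3)
  expect_equal(nrow(ds$basionyms), 1)
})

test_that("basionym totals equal distinct accepted species (oracle)", {
  cfg <- synthetic_config(seed = 21, n_strata = 2, true_asymptote = 200)
  nt <- generate_name_table(cfg)
  ds <- build_datasets(nt)
  native_species <- nt[nt$native & nt$rank == "species" &
                         nt$status == "accepted", ]
  expect_equal(nrow(ds$basionyms),
               dplyr::n_distinct(native_species$accepted_id))
})

test_that("stratum invariants hold: domination, family partition, overlap", {
  cfg <- synthetic_config(seed = 23, n_strata = 3, true_asymptote = 300,
                          domain_overlap_rate = 0.2)
  ds <- build_datasets(generate_name_table(cfg))
  all_dom <- dplyr::count(stratify_years(ds, "all_names", "domain"),
                          stratum)
  bas_dom <- dplyr::count(stratify_years(ds, "basionyms", "domain"),
                          stratum)
  joined <- dplyr::left_join(bas_dom, all_dom, by = "stratum",
                             suffix = c("_bas", "_all"))
  expect_true(all(joined$n_bas <= joined$n_all))
  # families partition the species list
  fam <- dplyr::count(stratify_years(ds, "basionyms", "family"), stratum)
  expect_equal(sum(fam$n), nrow(ds$basionyms))
  # a species in k domains appears in k domain strata
  k <- lengths(strsplit(ds$basionyms$domains, "|", fixed = TRUE))
  expect_equal(sum(bas_dom$n), sum(k))
  expect_gt(sum(bas_dom$n), nrow(ds$basionyms))
})

test_that("build_datasets is order-independent", {
  cfg <- small_cfg()
  nt <- generate_name_table(cfg)
  shuffled <- nt[withr::with_seed(1, sample(nrow(nt))), ]
  a <- build_datasets(nt)
  b <- build_datasets(shuffled)
  expect_equal(a$all_names, b$all_names)
  expect_equal(a$basionyms, b$basionyms)
})

test_that("family strata can be restricted to large families", {
  cfg <- synthetic_config(seed = 2, n_strata = 2, true_asymptote = 400)
  ds <- build_datasets(generate_name_table(cfg))
  counts <- dplyr::count(ds$basionyms, family)
  thr <- sort(counts$n, decreasing = TRUE)[2] - 1
  kept <- stratify_years(ds, "basionyms", "family", min_species = thr)
  expect_setequal(unique(kept$stratum), counts$family[counts$n > thr])
})
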