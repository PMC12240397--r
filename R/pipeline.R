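#' Default pipeline configuration
#'
#' @param ... Overrides merged into the defaults (nested lists are merged
#'   recursively).
#' @return A named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    synthetic = list(n_strata = 2L, true_asymptote = 500),
    input = NULL,                    # list(names=, polygons=, occurrences=)
    window = c(1753, 2020),
    dataset_mode = "both",           # all_names | basionyms | both
    strata = list(domains = TRUE, family_min_species = 500,
                  habits = FALSE),
    models = GROWTH_MODELS,
    criterion = "aicc",
    averaging_candidates = "growth", # or "growth+effort"
    spatial = list(resolution = 1, top_n = 30, min_records = 5),
    output_dir = NULL
  )
  utils::modifyList(defaults, list(...))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
  })
}

#' Run the full discovery-estimation pipeline
#'
#' Orchestrates the stages end to end for every requested stratum:
#' nomenclature (dataset assembly) -> decade binning -> growth-model fits
#' and the taxonomic-effort fit -> Akaike-weight model averaging and
#' completeness -> predictor regressions -> spatial priority mapping with
#' protected-area / Indigenous-land overlap. Inputs come either from the
#' synthetic generator (`config$synthetic`, seeded by `config$seed`) or
#' from files (`config$input$names`, `config$input$occurrences`,
#' `config$input$polygons`). Identical config + seed gives identical
#' outputs; when `output_dir` is set every artifact is written as
#' delimited text/GeoJSON next to a manifest recording the seed, config
#' hash and per-file checksums.
#'
#' @param config A list from [pipeline_config()], or the path of a YAML
#'   file holding one.
#' @return A list of class `pipeline_result` with elements `datasets`,
#'   `series`, `fits`, `estimates`, `aggregate`, `effort`, `regressions`,
#'   `grid`, `overlap`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(pipeline_config(), config)
  window <- as.numeric(config$window)

  # --- inputs ---------------------------------------------------------------
  syn_layers <- NULL
  if (!is.null(config$input) && !is.null(config$input$names)) {
    records <- stage("load", load_names(config$input$names,
                                        window = window))
    effort_density <- if (!is.null(config$input$effort_density)) {
      readr::read_csv(config$input$effort_density, show_col_types = FALSE)
    } else {
      NULL
    }
    occurrences <- if (!is.null(config$input$occurrences)) {
      readr::read_csv(config$input$occurrences, show_col_types = FALSE)
    } else {
      NULL
    }
    polygons <- if (!is.null(config$input$polygons)) {
      read_polygons_geojson(config$input$polygons)
    } else {
      NULL
    }
  } else {
    cfg <- stage("simulate", do.call(synthetic_config, c(
      list(seed = config$seed,
           start_year = window[1], end_year = window[2]),
      config$synthetic
    )))
    records <- stage("simulate", generate_name_table(cfg))
    effort_density <- stage("simulate", generate_effort_and_density(cfg))
    syn_layers <- stage("simulate", generate_spatial_layers(cfg))
    occurrences <- syn_layers$occurrences
    polygons <- syn_layers$polygons
  }

  datasets <- stage("build-datasets", build_datasets(records))

  # --- strata ---------------------------------------------------------------
  dataset_modes <- if (config$dataset_mode == "both") {
    c("all_names", "basionyms")
  } else {
    config$dataset_mode
  }
  strata_tbl <- list()
  for (dm in dataset_modes) {
    if (isTRUE(config$strata$domains)) {
      strata_tbl[[length(strata_tbl) + 1]] <-
        dplyr::mutate(stratify_years(datasets, dm, "domain"),
                      dataset = dm, by = "domain")
    }
    fam_thr <- config$strata$family_min_species %||% 0
    if (!is.null(fam_thr) && is.finite(fam_thr)) {
      fam <- stratify_years(datasets, dm, "family", min_species = fam_thr)
      if (nrow(fam) > 0) {
        strata_tbl[[length(strata_tbl) + 1]] <-
          dplyr::mutate(fam, dataset = dm, by = "family")
      }
    }
    if (isTRUE(config$strata$habits)) {
      strata_tbl[[length(strata_tbl) + 1]] <-
        dplyr::mutate(stratify_years(datasets, dm, "habit"),
                      dataset = dm, by = "habit")
    }
  }
  strata_tbl <- dplyr::bind_rows(strata_tbl)

  # --- per-stratum curve fitting and averaging ------------------------------
  groups <- dplyr::distinct(strata_tbl, .data$dataset, .data$by,
                            .data$stratum)
  series_list <- list()
  fit_rows <- list()
  est_rows <- list()
  effort_rows <- list()
  regression_rows <- list()
  for (g in seq_len(nrow(groups))) {
    dm <- groups$dataset[g]
    b <- groups$by[g]
    st <- groups$stratum[g]
    yrs <- strata_tbl$year[strata_tbl$dataset == dm & strata_tbl$by == b &
                             strata_tbl$stratum == st]
    ser <- stage("curves",
                 suppressWarnings(bin_by_decade(yrs, window = window,
                                                stratum = st)))
    ser$dataset <- dm
    series_list[[g]] <- ser

    fits <- stage("fit", fit_growth_models(ser, config$models))
    fits <- stage("fit", akaike_weights(fits, config$criterion))

    # effort model needs per-stratum authorships (domain strata only)
    eff_fit <- NULL
    eff_series <- NULL
    if (b == "domain" && all(c("authorship", "domains") %in%
                               names(records))) {
      rec_st <- records[grepl(st, records$domains, fixed = TRUE), ]
      if (!"year" %in% names(rec_st)) {
        rec_st$year <- dplyr::coalesce(
          suppressWarnings(as.numeric(rec_st$year_primary)),
          suppressWarnings(as.numeric(rec_st$year_fallback))
        )
      }
      rec_st <- rec_st[!is.na(rec_st$year), ]
      if (nrow(rec_st) > 0) {
        eff_series <- suppressWarnings(
          count_taxonomists(rec_st, window = window, stratum = st)
        )
        eff_fit <- tryCatch(
          fit_effort_model(ser, eff_series$taxonomists),
          error = function(e) NULL
        )
      }
    }
    if (!is.null(eff_fit)) {
      effort_rows[[length(effort_rows) + 1]] <-
        dplyr::mutate(tibble::as_tibble(eff_fit), stratum = st,
                      dataset = dm, .before = 1)
    }

    cand <- fits
    if (identical(config$averaging_candidates, "growth+effort") &&
        !is.null(eff_fit) && any(eff_fit$converged)) {
      eg <- glance(eff_fit)
      extra <- tibble::tibble(
        model = "taxonomic_effort", converged = TRUE, n = nrow(ser),
        k = 4, rss = eg$rss, aic = eg$aic, aicc = eg$aic,
        bic = eg$bic, asymptote = eg$n_total, asymptote_se = NA_real_,
        ci_lower = NA_real_, ci_upper = NA_real_
      )
      cand <- dplyr::bind_rows(fits[setdiff(names(fits),
                                            c("weight", "fit"))], extra)
      cand <- akaike_weights(cand, config$criterion)
    }
    s_obs <- max(ser$cumulative)
    est <- tryCatch(average_models(cand, s_obs = s_obs, stratum = st),
                    error = function(e) NULL)
    if (!is.null(est)) {
      est$dataset <- dm
      est$by <- b
      est_rows[[length(est_rows) + 1]] <- est
    }
    fit_rows[[g]] <- dplyr::mutate(
      fits[setdiff(names(fits), "fit")], stratum = st, dataset = dm,
      by = b, .before = 1
    )

    # predictor regressions (domain strata with density series only)
    if (b == "domain" && !is.null(effort_density) && !is.null(eff_series)) {
      dens <- effort_density[effort_density$stratum == st, ]
      if (nrow(dens) > 0) {
        regression_rows[[length(regression_rows) + 1]] <- tryCatch(
          dplyr::mutate(regress_predictors(ser, eff_series, dens),
                        dataset = dm),
          error = function(e) NULL
        )
      }
    }
  }
  series <- dplyr::bind_rows(series_list)
  fits_tbl <- dplyr::bind_rows(fit_rows)
  estimates <- dplyr::bind_rows(est_rows)
  effort_tbl <- dplyr::bind_rows(effort_rows)
  regressions <- dplyr::bind_rows(regression_rows)

  agg <- NULL
  dom_est <- dplyr::filter(estimates, .data$by == "domain",
                           .data$dataset == dataset_modes[length(dataset_modes)])
  if (nrow(dom_est) > 0) {
    agg <- stage("average", aggregate_estimates(dom_est))
  }

  # --- spatial --------------------------------------------------------------
  grid <- NULL
  overlap <- NULL
  if (!is.null(occurrences)) {
    ext <- if (!is.null(syn_layers)) {
      syn_layers$extent
    } else {
      c(xmin = floor(min(occurrences$decimalLongitude)),
        xmax = ceiling(max(occurrences$decimalLongitude)),
        ymin = floor(min(occurrences$decimalLatitude)),
        ymax = ceiling(max(occurrences$decimalLatitude)))
    }
    grid <- stage("map-priority", map_discovery_priority(
      occurrences, ext, config$spatial$resolution, polygons,
      min_records = config$spatial$min_records
    ))
    if (!is.null(polygons)) {
      overlap <- dplyr::bind_rows(lapply(
        intersect(c("PA", "TI"), unique(polygons$layer)),
        function(ly) stage("map-priority", overlap_stats(
          grid, polygons, ly, n_top = config$spatial$top_n
        ))
      ))
    }
  }

  result <- list(
    datasets = datasets, series = series, fits = fits_tbl,
    estimates = estimates, aggregate = agg, effort = effort_tbl,
    regressions = regressions, grid = grid, overlap = overlap,
    config = config
  )
  result$manifest <- tibble::tibble(
    package_version = as.character(utils::packageVersion("linnean")),
    seed = config$seed, config_hash = config_hash(config)
  )
  class(result) <- "pipeline_result"

  if (!is.null(config$output_dir)) {
    write_pipeline_outputs(result, config$output_dir)
  }
  result
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  unname(tools::md5sum(tmp))
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(tb, name) {
    if (is.null(tb) || nrow(tb) == 0) return(NULL)
    p <- file.path(dir, name)
    readr::write_csv(tibble::as_tibble(tb), p, progress = FALSE)
    p
  }
  paths <- c(
    wr(result$series, "decade_series.csv"),
    wr(result$fits, "growth_fits.csv"),
    wr(result$estimates, "averaged_estimates.csv"),
    wr(result$effort, "effort_fits.csv"),
    wr(result$regressions, "regressions.csv"),
    wr(if (is.null(result$aggregate)) NULL else result$aggregate$strata,
       "aggregate_strata.csv"),
    wr(if (is.null(result$aggregate)) NULL else result$aggregate$totals,
       "aggregate_totals.csv"),
    wr(result$grid, "grid_cells.csv"),
    wr(result$overlap, "overlap_summary.csv")
  )
  manifest <- list(
    package_version = result$manifest$package_version,
    seed = result$manifest$seed,
    config_hash = result$manifest$config_hash,
    files = lapply(paths, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  strata analysed : %d series\n",
              nrow(dplyr::distinct(x$series, .data$stratum, .data$dataset))))
  cat(sprintf("  growth fits     : %d rows\n", nrow(x$fits)))
  if (!is.null(x$aggregate)) {
    cat(sprintf("  total remaining : %.1f (upper %.1f)\n",
                x$aggregate$totals$total_remaining,
                x$aggregate$totals$total_remaining_upper))
  }
  if (!is.null(x$overlap) && nrow(x$overlap) > 0) {
    for (i in seq_len(nrow(x$overlap))) {
      cat(sprintf("  %s overlap      : %.0f%% of top %d cells\n",
                  x$overlap$layer[i], x$overlap$pct_overlap[i],
                  x$overlap$n_top[i]))
    }
  }
  invisible(x)
}
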