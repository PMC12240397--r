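#' Configuration for the synthetic flora generator
#'
#' Builds a validated configuration for the synthetic-data generator. The
#' generator produces every input the estimation pipeline consumes -- a
#' name-level nomenclature table, per-decade taxonomist and population-density
#' series, and spatially clustered occurrence records over toy polygon layers
#' -- with known ground truth (the true asymptote per stratum, the realized
#' species set, per-cell richness), so every downstream stage can be tested
#' without external downloads.
#'
#' Discovery years are drawn by inverting the chosen growth curve
#' (inverse-CDF sampling of description dates), which guarantees the
#' asymptotic shape the curve fitters assume. Under `"effort_driven"` the
#' per-decade described counts instead follow a binomial thinning of the
#' undescribed pool with success probability proportional to the number of
#' active taxonomists, so decades with zero effort yield zero descriptions.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_strata Number of strata (phytogeographic domains) to simulate,
#'   1 to 6.
#' @param true_asymptote True total species richness N* per stratum
#'   (recycled to `n_strata`). This is the ground truth the fitted
#'   asymptotes are judged against.
#' @param start_year,end_year Calendar window of nomenclatural activity
#'   (defaults 1753 and 2020). Discovery is right-censored at `end_year`.
#' @param discovery_shape One of `"gompertz"`, `"logistic"`, `"weibull"`,
#'   `"effort_driven"`: the shape of the generating cumulative curve.
#' @param shape_params Named list of curve parameters on the decade-index
#'   scale (`b`, `c` for gompertz/logistic; `b`, `c` for weibull). Defaults
#'   place the inflection well before `end_year` so the curve is close to its
#'   asymptote by the end of the window.
#' @param effort_schedule Integer vector of taxonomists active per decade
#'   (length = number of decades, recycled). Default: an exponentially
#'   growing pool, mirroring the long-run growth of the taxonomic workforce.
#' @param effort_efficiency Per-taxonomist, per-decade description
#'   probability coefficient for the `"effort_driven"` shape. Default scales
#'   with the schedule so the pool is ~95% described by `end_year`.
#' @param synonym_rate Expected number of later synonyms per accepted
#'   species (Poisson), >= 0.
#' @param discordance_rate Probability that one of the three nomenclatural
#'   sources disagrees on a species' basionym year, in \[0, 1\].
#' @param missing_primary_rate Fraction of names whose primary year field is
#'   blank and must be resolved from the fallback (reference) field.
#' @param domain_overlap_rate Probability an accepted species is recorded in
#'   a second domain as well as its own. Default 0 so per-stratum ground
#'   truth equals `true_asymptote` exactly.
#' @param infraspecific_rate Fraction of synonym rows published at
#'   infraspecific rank.
#' @param ex_author_rate Fraction of authorship strings written in the
#'   botanical "A ex B" form.
#' @param nonnative_rate Fraction of extra non-native species rows appended
#'   (excluded by the cleaning step).
#' @param n_genus_rows Number of genus-rank rows appended (excluded by the
#'   cleaning step).
#' @param spatial Named list of landscape settings: `extent`
#'   (xmin, xmax, ymin, ymax in degrees), `n_clusters` (species clusters per
#'   stratum; 0 = uniform), `pa_fraction` and `ti_fraction` (area fractions
#'   covered by protected-area / Indigenous-land polygons), `n_occurrences`
#'   (observed records drawn from the latent point set), `latent_per_species`
#'   (mean latent points per species), `cluster_sd` and `point_sd` (degrees).
#'
#' @return A list of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1, n_strata = 2, true_asymptote = 300)
#' names(generate_name_table(cfg))
synthetic_config <- function(seed = 1L,
                             n_strata = 2L,
                             true_asymptote = 500,
                             start_year = 1753L,
                             end_year = 2020L,
                             discovery_shape = c("gompertz", "logistic",
                                                 "weibull", "effort_driven"),
                             shape_params = NULL,
                             effort_schedule = NULL,
                             effort_efficiency = NULL,
                             synonym_rate = 0.5,
                             discordance_rate = 0.05,
                             missing_primary_rate = 0.05,
                             domain_overlap_rate = 0,
                             infraspecific_rate = 0.2,
                             ex_author_rate = 0.05,
                             nonnative_rate = 0.05,
                             n_genus_rows = 5L,
                             spatial = list()) {
  if (is.character(discovery_shape)) {
    ok <- c("gompertz", "logistic", "weibull", "effort_driven")
    if (!discovery_shape[1] %in% ok) {
      abort(sprintf("unknown discovery_shape '%s' (configuration error)",
                    discovery_shape[1]))
    }
    discovery_shape <- discovery_shape[1]
  }
  if (end_year <= start_year) abort("end_year must exceed start_year")
  if (n_strata < 1 || n_strata > length(PHYTOGEOGRAPHIC_DOMAINS)) {
    abort("n_strata must be between 1 and 6")
  }
  if (any(true_asymptote < 1)) abort("true_asymptote must be >= 1")
  for (r in c(discordance_rate, missing_primary_rate, domain_overlap_rate,
              infraspecific_rate, ex_author_rate, nonnative_rate)) {
    if (r < 0 || r > 1) abort("rates must lie in [0, 1]")
  }
  if (synonym_rate < 0) abort("synonym_rate must be >= 0")

  starts <- decade_starts(start_year, end_year)
  n_dec <- length(starts)
  if (is.null(effort_schedule)) {
    effort_schedule <- pmax(1L, round(3 * exp(0.12 * (seq_len(n_dec) - 1))))
  }
  effort_schedule <- as.integer(rep_len(effort_schedule, n_dec))
  if (any(effort_schedule < 0)) abort("effort_schedule must be >= 0")
  if (is.null(effort_efficiency)) {
    tot <- sum(effort_schedule)
    effort_efficiency <- if (tot > 0) 3 / tot else 0
  }
  defaults_sp <- list(
    extent = c(xmin = -10, xmax = 0, ymin = -10, ymax = 0),
    n_clusters = 12L, pa_fraction = 0.2, ti_fraction = 0.3,
    n_occurrences = 5000L, latent_per_species = 12, cluster_sd = 0.3,
    point_sd = 0.2
  )
  spatial <- modifyList(defaults_sp, spatial)
  if (spatial$pa_fraction < 0 || spatial$pa_fraction > 1 ||
      spatial$ti_fraction < 0 || spatial$ti_fraction > 1) {
    abort("polygon area fractions must lie in [0, 1]")
  }
  defaults_shape <- switch(discovery_shape,
    gompertz = list(b = 0.35, c = 8),
    logistic = list(b = 0.5, c = 10),
    weibull  = list(b = 10, c = 2),
    effort_driven = list()
  )
  shape_params <- modifyList(defaults_shape, shape_params %||% list())

  structure(list(
    seed = as.integer(seed), n_strata = as.integer(n_strata),
    true_asymptote = rep_len(round(true_asymptote), n_strata),
    start_year = as.integer(start_year), end_year = as.integer(end_year),
    decade_starts = starts, n_decades = n_dec,
    discovery_shape = discovery_shape, shape_params = shape_params,
    effort_schedule = effort_schedule, effort_efficiency = effort_efficiency,
    synonym_rate = synonym_rate, discordance_rate = discordance_rate,
    missing_primary_rate = missing_primary_rate,
    domain_overlap_rate = domain_overlap_rate,
    infraspecific_rate = infraspecific_rate,
    ex_author_rate = ex_author_rate, nonnative_rate = nonnative_rate,
    n_genus_rows = as.integer(n_genus_rows),
    strata = PHYTOGEOGRAPHIC_DOMAINS[seq_len(n_strata)],
    spatial = spatial
  ), class = "synthetic_config")
}

# Saturation fraction of the generating curve at continuous decade coordinate
# t (t = 0 at the start of the first decade). Values in (0, 1).
curve_saturation <- function(shape, t, p) {
  switch(shape,
    gompertz = exp(-exp(-p$b * (t - p$c))),
    logistic = 1 / (1 + exp(-p$b * (t - p$c))),
    weibull  = 1 - exp(-(pmax(t, 0) / p$b)^p$c),
    abort(sprintf("unknown discovery_shape '%s'", shape))
  )
}

curve_saturation_inverse <- function(shape, u, p) {
  switch(shape,
    gompertz = p$c - log(-log(u)) / p$b,
    logistic = p$c - log(1 / u - 1) / p$b,
    weibull  = p$b * (-log(1 - u))^(1 / p$c),
    abort(sprintf("unknown discovery_shape '%s'", shape))
  )
}

# Draw description years for one stratum pool of size n_star. Returns an
# integer vector of years for the species described by end_year (the rest of
# the pool stays undiscovered: right censoring).
draw_description_years <- function(cfg, n_star) {
  starts <- cfg$decade_starts
  n_dec <- cfg$n_decades
  if (cfg$discovery_shape == "effort_driven") {
    remaining <- n_star
    years <- integer(0)
    for (i in seq_len(n_dec)) {
      p <- min(1, cfg$effort_efficiency * cfg$effort_schedule[i])
      d <- if (remaining > 0 && p > 0) rbinom(1, remaining, p) else 0L
      if (d > 0) {
        lo <- max(starts[i], cfg$start_year)
        hi <- min(starts[i] + 9L, cfg$end_year)
        years <- c(years, sample(seq(lo, hi), d, replace = TRUE))
        remaining <- remaining - d
      }
    }
    return(sort(years))
  }
  u <- runif(n_star)
  sat_end <- curve_saturation(cfg$discovery_shape, n_dec, cfg$shape_params)
  u <- u[u <= sat_end]
  t <- curve_saturation_inverse(cfg$discovery_shape, u, cfg$shape_params)
  yr <- floor(starts[1] + 10 * t)
  yr <- pmin(pmax(yr, cfg$start_year), cfg$end_year)
  sort(as.integer(yr))
}

active_authors <- function(cfg, decade_index) {
  t_i <- cfg$effort_schedule[decade_index]
  if (t_i == 0) character(0) else sprintf("Auth%03d", seq_len(t_i))
}

# Assign authorship strings for the names of one decade, guaranteeing that
# every scheduled author appears at least once when the decade has enough
# names (so authorship-derived taxonomist counts recover the schedule).
assign_authorships <- function(cfg, decade_index, n_names) {
  act <- active_authors(cfg, decade_index)
  if (length(act) == 0 || n_names == 0) return(rep("", n_names))
  first <- rep_len(sample(act), n_names)
  second <- ifelse(runif(n_names) < 0.3,
                   sample(act, n_names, replace = TRUE), NA_character_)
  out <- ifelse(is.na(second) | second == first,
                first, paste(first, "&", second))
  isex <- runif(n_names) < cfg$ex_author_rate
  if (any(isex)) {
    pre <- sample(act, sum(isex), replace = TRUE)
    out[isex] <- paste(pre, "ex", first[isex])
  }
  out
}

#' Generate a synthetic name-level nomenclature table
#'
#' One row per published name: accepted species (each with exactly one
#' basionym year drawn from the configured discovery curve), optional later
#' synonyms and infraspecific names, three per-source basionym-year columns
#' that agree except at the configured discordance rate, plus genus-rank and
#' non-native filler rows that the cleaning step must discard.
#'
#' @param cfg A [synthetic_config()].
#' @return A tibble with Darwin-Core-like columns (`name_id`,
#'   `scientific_name`, `authorship`, `rank`, `status`, `accepted_id`,
#'   `family`, `year_primary`, `year_fallback`, three `basionym_year_*`
#'   vote columns, `domains`, `habit`, `native`). The attribute
#'   `"true_asymptote"` carries the per-stratum ground truth.
#' @export
generate_name_table <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed + 1L, generate_name_table_impl(cfg))
}

generate_name_table_impl <- function(cfg) {
  fams <- c("Fabaceae", "Orchidaceae", "Asteraceae", "Rubiaceae",
            "Melastomataceae", "Myrtaceae", "Poaceae", "Bromeliaceae")
  habits <- c("tree", "shrub", "herb", "climber", "liana")
  abbrev <- c("Amazonia" = "AMZ", "Atlantic Forest" = "ATL",
              "Caatinga" = "CAA", "Cerrado" = "CER",
              "Pampa" = "PAM", "Pantanal" = "PAN")
  rows <- vector("list", cfg$n_strata)
  for (s in seq_len(cfg$n_strata)) {
    stratum <- cfg$strata[s]
    years <- draw_description_years(cfg, cfg$true_asymptote[s])
    n_sp <- length(years)
    if (n_sp == 0) next
    ids <- sprintf("sp%s%05d", abbrev[[stratum]], seq_len(n_sp))
    genus <- sprintf("Genus%02d", sample(20, n_sp, replace = TRUE))
    sciname <- sprintf("%s %s", genus, sprintf("species%05d", seq_len(n_sp)))
    family <- sample(fams, n_sp, replace = TRUE,
                     prob = c(4, 3, 3, 2, 2, 2, 2, 1))
    habit <- sample(habits, n_sp, replace = TRUE,
                    prob = c(0.25, 0.25, 0.3, 0.1, 0.1))
    extra <- runif(n_sp) < cfg$domain_overlap_rate
    other <- sample(setdiff(PHYTOGEOGRAPHIC_DOMAINS, stratum), n_sp,
                    replace = TRUE)
    domains <- ifelse(extra, paste(stratum, other, sep = "|"), stratum)

    votes <- matrix(rep(years, 3), ncol = 3)
    disc <- runif(n_sp) < cfg$discordance_rate
    if (any(disc)) {
      which_src <- sample(3, sum(disc), replace = TRUE)
      bump <- sample(15, sum(disc), replace = TRUE)
      votes[cbind(which(disc), which_src)] <-
        pmin(years[disc] + bump, cfg$end_year)
    }

    dec_idx <- findInterval(years, cfg$decade_starts)
    auth <- character(n_sp)
    for (d in unique(dec_idx)) {
      sel <- dec_idx == d
      auth[sel] <- assign_authorships(cfg, d, sum(sel))
    }

    prim_missing <- runif(n_sp) < cfg$missing_primary_rate
    acc <- tibble::tibble(
      name_id = ids, scientific_name = sciname, authorship = auth,
      rank = "species", status = "accepted", accepted_id = ids,
      family = family,
      year_primary = ifelse(prim_missing, NA_integer_, years),
      year_fallback = ifelse(prim_missing, years, NA_integer_),
      basionym_year_fb = votes[, 1], basionym_year_tropicos = votes[, 2],
      basionym_year_wcvp = votes[, 3],
      domains = domains, habit = habit, native = TRUE
    )

    n_syn <- rpois(n_sp, cfg$synonym_rate)
    syn <- NULL
    if (sum(n_syn) > 0) {
      parent <- rep(seq_len(n_sp), n_syn)
      syr <- years[parent] +
        floor(runif(length(parent)) * (cfg$end_year - years[parent] + 1))
      sdec <- findInterval(syr, cfg$decade_starts)
      sauth <- character(length(parent))
      for (d in unique(sdec)) {
        sel <- sdec == d
        sauth[sel] <- assign_authorships(cfg, d, sum(sel))
      }
      srank <- ifelse(runif(length(parent)) < cfg$infraspecific_rate,
                      "infraspecific", "species")
      spm <- runif(length(parent)) < cfg$missing_primary_rate
      syn <- tibble::tibble(
        name_id = sprintf("%s-syn%02d", ids[parent],
                          sequence(n_syn[n_syn > 0])),
        scientific_name = sprintf("Synonymus name%s", seq_along(parent)),
        authorship = sauth, rank = srank, status = "synonym",
        accepted_id = ids[parent], family = family[parent],
        year_primary = ifelse(spm, NA_integer_, as.integer(syr)),
        year_fallback = ifelse(spm, as.integer(syr), NA_integer_),
        basionym_year_fb = NA_integer_, basionym_year_tropicos = NA_integer_,
        basionym_year_wcvp = NA_integer_,
        domains = domains[parent], habit = habit[parent], native = TRUE
      )
    }
    rows[[s]] <- dplyr::bind_rows(acc, syn)
  }
  out <- dplyr::bind_rows(rows)

  # filler rows the cleaning step must discard
  n_nn <- round(cfg$nonnative_rate * nrow(out))
  if (n_nn > 0) {
    nn_years <- sample(seq(cfg$start_year, cfg$end_year), n_nn, replace = TRUE)
    out <- dplyr::bind_rows(out, tibble::tibble(
      name_id = sprintf("nn%05d", seq_len(n_nn)),
      scientific_name = sprintf("Aliena species%04d", seq_len(n_nn)),
      authorship = "Auth001", rank = "species", status = "accepted",
      accepted_id = sprintf("nn%05d", seq_len(n_nn)),
      family = "Poaceae", year_primary = nn_years,
      year_fallback = NA_integer_, basionym_year_fb = nn_years,
      basionym_year_tropicos = nn_years, basionym_year_wcvp = nn_years,
      domains = cfg$strata[1], habit = "herb", native = FALSE
    ))
  }
  if (cfg$n_genus_rows > 0) {
    gy <- sample(seq(cfg$start_year, cfg$end_year), cfg$n_genus_rows,
                 replace = TRUE)
    out <- dplyr::bind_rows(out, tibble::tibble(
      name_id = sprintf("gen%03d", seq_len(cfg$n_genus_rows)),
      scientific_name = sprintf("Genus%02d", seq_len(cfg$n_genus_rows)),
      authorship = "Auth001", rank = "genus", status = "accepted",
      accepted_id = sprintf("gen%03d", seq_len(cfg$n_genus_rows)),
      family = "Fabaceae", year_primary = gy, year_fallback = NA_integer_,
      basionym_year_fb = NA_integer_, basionym_year_tropicos = NA_integer_,
      basionym_year_wcvp = NA_integer_,
      domains = cfg$strata[1], habit = "tree", native = TRUE
    ))
  }
  attr(out, "true_asymptote") <- setNames(cfg$true_asymptote, cfg$strata)
  out
}

#' Generate per-decade taxonomist and population-density series
#'
#' Taxonomist counts follow the configured `effort_schedule` exactly; human
#' population density per stratum is a positive, monotone non-decreasing
#' exponential series with mild multiplicative noise (monotonicity enforced
#' by a running maximum), emulating census-era density growth.
#'
#' @param cfg A [synthetic_config()].
#' @param monotone Enforce a non-decreasing density series (default TRUE).
#' @return A tibble with `stratum`, `decade_start`, `t` (decade index),
#'   `taxonomists`, `pop_density`.
#' @export
generate_effort_and_density <- function(cfg, monotone = TRUE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed + 2L, {
    purrr::map_dfr(seq_len(cfg$n_strata), function(s) {
      d0 <- runif(1, 0.5, 2)
      g <- runif(1, 0.08, 0.15)
      i <- seq_len(cfg$n_decades)
      dens <- d0 * exp(g * (i - 1)) * exp(rnorm(cfg$n_decades, 0, 0.03))
      if (monotone) dens <- cummax(dens)
      tibble::tibble(
        stratum = cfg$strata[s], decade_start = cfg$decade_starts,
        t = i, taxonomists = cfg$effort_schedule, pop_density = dens
      )
    })
  })
}

#' Generate clustered occurrence records over toy polygon layers
#'
#' Lays out one rectangular domain band per stratum across the landscape
#' extent, places protected-area and Indigenous-land rectangles covering the
#' configured area fractions exactly, gives each species a home cluster, and
#' draws a latent point set per species (the ground truth) from which the
#' observed occurrence records are subsampled.
#'
#' @param cfg A [synthetic_config()].
#' @return A list of class `synthetic_layers`: `occurrences` (tibble with
#'   `species`, `stratum`, `decimalLongitude`, `decimalLatitude`, `year`),
#'   `latent` (the full ground-truth point set), `polygons` (tibble with
#'   `layer`, `name`, `polygon_id`, `lon`, `lat`; layers `domain`, `PA`,
#'   `TI`), and `extent`.
#' @export
generate_spatial_layers <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed + 3L, generate_spatial_layers_impl(cfg))
}

generate_spatial_layers_impl <- function(cfg) {
  sp <- cfg$spatial
  ext <- sp$extent
  bw <- (ext[["xmax"]] - ext[["xmin"]]) / cfg$n_strata
  abbrev <- c("Amazonia" = "AMZ", "Atlantic Forest" = "ATL",
              "Caatinga" = "CAA", "Cerrado" = "CER",
              "Pampa" = "PAM", "Pantanal" = "PAN")

  rect_ring <- function(x0, x1, y0, y1) {
    tibble::tibble(lon = c(x0, x1, x1, x0), lat = c(y0, y0, y1, y1))
  }
  polys <- list()
  pid <- 0L
  add_poly <- function(layer, name, ring) {
    pid <<- pid + 1L
    polys[[pid]] <<- dplyr::mutate(ring, layer = layer, name = name,
                                   polygon_id = pid, .before = 1)
  }
  place_fraction_rect <- function(x0, x1, frac) {
    # a rectangle covering exactly `frac` of the band area
    w <- (x1 - x0) * sqrt(frac)
    h <- (ext[["ymax"]] - ext[["ymin"]]) * sqrt(frac)
    ox <- runif(1, x0, x1 - w)
    oy <- runif(1, ext[["ymin"]], ext[["ymax"]] - h)
    rect_ring(ox, ox + w, oy, oy + h)
  }

  latent <- list()
  for (s in seq_len(cfg$n_strata)) {
    stratum <- cfg$strata[s]
    x0 <- ext[["xmin"]] + (s - 1) * bw
    x1 <- x0 + bw
    add_poly("domain", stratum, rect_ring(x0, x1, ext[["ymin"]], ext[["ymax"]]))
    if (sp$pa_fraction > 0) {
      add_poly("PA", paste0("PA-", abbrev[[stratum]]),
               place_fraction_rect(x0, x1, sp$pa_fraction))
    }
    if (sp$ti_fraction > 0) {
      add_poly("TI", paste0("TI-", abbrev[[stratum]]),
               place_fraction_rect(x0, x1, sp$ti_fraction))
    }

    n_sp_s <- cfg$true_asymptote[s]
    species <- sprintf("sp%s%05d", abbrev[[stratum]], seq_len(n_sp_s))
    if (sp$n_clusters > 0) {
      cx <- runif(sp$n_clusters, x0, x1)
      cy <- runif(sp$n_clusters, ext[["ymin"]], ext[["ymax"]])
      cl <- sample(sp$n_clusters, n_sp_s, replace = TRUE)
      scx <- rnorm(n_sp_s, cx[cl], sp$cluster_sd)
      scy <- rnorm(n_sp_s, cy[cl], sp$cluster_sd)
    } else {
      scx <- runif(n_sp_s, x0, x1)
      scy <- runif(n_sp_s, ext[["ymin"]], ext[["ymax"]])
    }
    npts <- 1L + rpois(n_sp_s, max(sp$latent_per_species - 1, 0))
    idx <- rep(seq_len(n_sp_s), npts)
    px <- rnorm(length(idx), scx[idx], sp$point_sd)
    py <- rnorm(length(idx), scy[idx], sp$point_sd)
    if (sp$n_clusters > 0) {
      px <- pmin(pmax(px, x0), x1 - 1e-9)
      py <- pmin(pmax(py, ext[["ymin"]]), ext[["ymax"]] - 1e-9)
    } else {
      # uniform mode: resample instead of clamping so cells stay equiprobable
      px <- runif(length(idx), x0, x1)
      py <- runif(length(idx), ext[["ymin"]], ext[["ymax"]])
    }
    latent[[s]] <- tibble::tibble(
      species = species[idx], stratum = stratum,
      decimalLongitude = px, decimalLatitude = py,
      year = sample(seq(cfg$start_year, cfg$end_year), length(idx),
                    replace = TRUE)
    )
  }
  latent <- dplyr::bind_rows(latent)
  n_obs <- min(sp$n_occurrences, nrow(latent))
  occurrences <- latent[sort(sample(nrow(latent), n_obs)), ]

  structure(list(
    occurrences = occurrences, latent = latent,
    polygons = dplyr::bind_rows(polys), extent = ext, config = cfg
  ), class = "synthetic_layers")
}
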