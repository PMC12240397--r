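#' Load and clean a name-level nomenclature table
#'
#' Reads a delimited text file of published names (comma- or tab-separated,
#' auto-detected from the extension), applies the cleaning protocol, and
#' resolves one publication year per surviving record:
#' genus- and section-rank rows are excluded, non-native rows are excluded,
#' and the year is taken from the primary year field, falling back to the
#' reference-field year, else flagged missing.
#'
#' @param path Path to a `.csv` (comma) or `.tsv`/`.txt`/`.tab` (tab) file
#'   with a header row, UTF-8.
#' @param col_map Optional named character vector mapping the canonical
#'   column names (`name_id`, `scientific_name`, `authorship`, `rank`,
#'   `status`, `accepted_id`, `family`, `year_primary`, `year_fallback`,
#'   `domains`, `habit`, `native`) to the file's column names.
#' @param window Calendar window years are expected to fall in; years
#'   outside it are flagged missing with a warning (default 1753-2020).
#' @return A tibble of name records with resolved `year` and `year_source`
#'   (`"primary"`, `"fallback"`, or `"missing"`) columns, family names
#'   remapped to their modern (APG-IV) family. The number of excluded rows
#'   is recorded in the `"n_excluded"` attribute.
#' @export
load_names <- function(path, col_map = NULL, window = c(1753, 2020)) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("tsv", "tab", "txt")) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (!is.null(col_map)) {
    hit <- col_map[col_map %in% names(raw)]
    raw <- dplyr::rename(raw, !!!setNames(as.list(unname(hit)), names(hit)))
  }
  mandatory <- c("name_id", "scientific_name", "rank", "status",
                 "accepted_id", "family", "year_primary")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  for (opt in c("authorship", "year_fallback", "domains", "habit")) {
    if (!opt %in% names(raw)) raw[[opt]] <- NA_character_
  }
  if (!"native" %in% names(raw)) raw$native <- TRUE

  n0 <- nrow(raw)
  out <- dplyr::filter(raw, !.data$rank %in% c("genus", "section"),
                       .data$native %in% TRUE)
  parse_year <- function(x) {
    y <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(y)
    if (any(bad)) {
      warn(sprintf("%d year value(s) could not be parsed; flagged missing",
                   sum(bad)))
    }
    y
  }
  yp <- parse_year(out$year_primary)
  yf <- parse_year(out$year_fallback)
  year <- dplyr::coalesce(yp, yf)
  source <- dplyr::case_when(!is.na(yp) ~ "primary",
                             !is.na(yf) ~ "fallback",
                             TRUE ~ "missing")
  oob <- !is.na(year) & (year < window[1] | year > window[2])
  if (any(oob)) {
    warn(sprintf("%d year(s) outside [%d, %d]; flagged missing",
                 sum(oob), window[1], window[2]))
    year[oob] <- NA_real_
    source[oob] <- "missing"
  }
  out$year <- as.integer(year)
  out$year_source <- source
  out$family <- remap_family(out$family)
  attr(out, "n_excluded") <- n0 - nrow(out)
  out
}

# Superseded family names folded into their modern (APG-IV) family.
FAMILY_REMAP <- c(
  Alliaceae = "Amaryllidaceae",
  Asclepiadaceae = "Apocynaceae",
  Avicenniaceae = "Acanthaceae",
  Caesalpiniaceae = "Fabaceae",
  Leguminosae = "Fabaceae",
  Mimosaceae = "Fabaceae",
  Buddlejaceae = "Scrophulariaceae",
  Callitrichaceae = "Plantaginaceae",
  Myrsinaceae = "Primulaceae",
  Sterculiaceae = "Malvaceae"
)

#' Remap superseded family names to their modern family
#'
#' Applies a fixed mapping (e.g., Caesalpiniaceae, Leguminosae and
#' Mimosaceae into Fabaceae; Myrsinaceae into Primulaceae). Families not in
#' the mapping pass through unchanged.
#'
#' @param family_raw Character vector of family names.
#' @return Character vector of remapped family names.
#' @export
#' @examples
#' remap_family(c("Caesalpiniaceae", "Bromeliaceae"))
remap_family <- function(family_raw) {
  hit <- unname(FAMILY_REMAP[family_raw])
  dplyr::coalesce(hit, family_raw)
}

#' Resolve basionym years by majority rule across sources
#'
#' Each species carries up to three per-source basionym-year assignments.
#' If at least two sources agree that year is used; if all three disagree
#' the earliest year is taken (a basionym is by definition the earliest
#' name) and the row is flagged `conflict` so either convention can be
#' audited.
#'
#' @param votes A data frame or matrix with up to three year columns, one
#'   row per species (NAs allowed, but each row needs at least one vote).
#' @return A tibble with `year` and `flag` (`unanimous`, `majority`,
#'   `single`, or `conflict`).
#' @export
#' @examples
#' resolve_basionym_year(cbind(c(1820, 1800), c(1820, 1810), c(1835, 1820)))
resolve_basionym_year <- function(votes) {
  m <- as.matrix(as.data.frame(votes))
  storage.mode(m) <- "double"
  res <- apply(m, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(c(NA_real_, NA_real_))
    tab <- table(v)
    if (length(v) == 1) return(c(v, 1))               # single
    if (length(tab) == 1) return(c(v[1], 2))          # unanimous
    if (max(tab) >= 2) {
      return(c(as.numeric(names(tab)[which.max(tab)]), 3)) # majority
    }
    c(min(v), 4)                                      # conflict
  })
  if (anyNA(res[1, ])) {
    abort("all basionym votes missing for at least one species")
  }
  tibble::tibble(
    year = as.integer(res[1, ]),
    flag = c("single", "unanimous", "majority", "conflict")[res[2, ]]
  )
}

#' Build the all-names and basionyms analysis datasets
#'
#' From cleaned name records, assembles the two datasets the discovery
#' curves are computed on: `all_names` (every accepted name, synonym and
#' infraspecific name with its publication year, tracking total
#' nomenclatural activity) and `basionyms` (one earliest name per accepted
#' species, tracking genuine additions to the inventory). Basionym years
#' come from the per-source vote columns when present (majority rule),
#' otherwise from the earliest species-rank year in the lineage.
#'
#' @param records A tibble as returned by [load_names()] (or
#'   [generate_name_table()] after year resolution; a `year` column is
#'   required -- `year_primary`/`year_fallback` are resolved if it is
#'   absent).
#' @return A list of class `name_datasets` with tibbles `all_names`
#'   (`name_id`, `accepted_id`, `year`, `family`, `habit`, `domains`) and
#'   `basionyms` (`accepted_id`, `year`, `flag`, `family`, `habit`,
#'   `domains`), plus `unresolved` (records without a usable year).
#' @export
build_datasets <- function(records) {
  if (!"year" %in% names(records)) {
    records$year <- as.integer(dplyr::coalesce(
      suppressWarnings(as.numeric(records$year_primary)),
      suppressWarnings(as.numeric(records$year_fallback))
    ))
  }
  records <- dplyr::filter(records,
                           !.data$rank %in% c("genus", "section"),
                           !("native" %in% names(records)) |
                             .data$native %in% TRUE)
  if (!"habit" %in% names(records)) records$habit <- NA_character_
  if (!"domains" %in% names(records)) records$domains <- NA_character_
  records$family <- remap_family(records$family)

  unresolved <- dplyr::filter(records, is.na(.data$year))
  resolved <- dplyr::filter(records, !is.na(.data$year))

  # species-level attributes come from the accepted record
  acc <- dplyr::filter(resolved, .data$status == "accepted",
                       .data$rank == "species")
  acc_attr <- dplyr::select(acc, "accepted_id", acc_family = "family",
                            acc_habit = "habit", acc_domains = "domains")

  all_names <- resolved |>
    dplyr::left_join(acc_attr, by = "accepted_id") |>
    dplyr::transmute(
      name_id = .data$name_id, accepted_id = .data$accepted_id,
      year = .data$year,
      family = dplyr::coalesce(.data$acc_family, .data$family),
      habit = dplyr::coalesce(.data$acc_habit, .data$habit),
      domains = dplyr::coalesce(.data$acc_domains, .data$domains)
    ) |>
    dplyr::arrange(.data$accepted_id, .data$year, .data$name_id)

  vote_cols <- grep("^basionym_year", names(acc), value = TRUE)
  if (length(vote_cols) >= 1 &&
      any(!is.na(unlist(acc[vote_cols])))) {
    votes <- acc[vote_cols]
    # species with no votes at all fall back to their own resolved year
    none <- !rowSums(!is.na(as.data.frame(votes)))
    votes[none, 1] <- acc$year[none]
    rb <- resolve_basionym_year(votes)
    basionyms <- tibble::tibble(
      accepted_id = acc$accepted_id, year = rb$year, flag = rb$flag,
      family = acc$family, habit = acc$habit, domains = acc$domains
    )
  } else {
    # earliest species-rank year in each lineage
    lineage <- resolved |>
      dplyr::filter(.data$rank == "species") |>
      dplyr::group_by(.data$accepted_id) |>
      dplyr::summarise(year = min(.data$year), .groups = "drop")
    basionyms <- acc |>
      dplyr::select("accepted_id", family = "family", habit = "habit",
                    domains = "domains") |>
      dplyr::left_join(lineage, by = "accepted_id") |>
      dplyr::mutate(flag = "earliest") |>
      dplyr::select("accepted_id", "year", "flag", "family", "habit",
                    "domains")
  }
  basionyms <- dplyr::arrange(basionyms, .data$accepted_id)

  structure(list(all_names = all_names, basionyms = basionyms,
                 unresolved = unresolved),
            class = "name_datasets")
}

#' @export
print.name_datasets <- function(x, ...) {
  cat(sprintf(
    "<name_datasets> %d names (all names), %d accepted species (basionyms), %d unresolved\n",
    nrow(x$all_names), nrow(x$basionyms), nrow(x$unresolved)
  ))
  invisible(x)
}

#' Extract per-stratum publication years from a name dataset
#'
#' Strata can be the whole flora (`"all"`), phytogeographic domains
#' (species occurring in k domains contribute to all k domain strata),
#' families, or habits.
#'
#' @param ds A `name_datasets` list from [build_datasets()].
#' @param dataset `"all_names"` or `"basionyms"`.
#' @param by `"all"`, `"domain"`, `"family"`, or `"habit"`.
#' @param min_species For `by = "family"`, keep only families whose
#'   basionym (species) count exceeds this threshold (default 0 = all).
#' @return A tibble with `stratum` and `year`, one row per name (or
#'   name-by-domain combination).
#' @export
stratify_years <- function(ds, dataset = c("all_names", "basionyms"),
                           by = c("all", "domain", "family", "habit"),
                           min_species = 0) {
  stopifnot(inherits(ds, "name_datasets"))
  dataset <- match.arg(dataset)
  by <- match.arg(by)
  tb <- ds[[dataset]]
  out <- switch(by,
    all = dplyr::transmute(tb, stratum = "all", year = .data$year),
    domain = tb |>
      dplyr::mutate(stratum = strsplit(.data$domains, "|", fixed = TRUE)) |>
      tidyr::unnest("stratum") |>
      dplyr::transmute(stratum = .data$stratum, year = .data$year),
    family = dplyr::transmute(tb, stratum = .data$family, year = .data$year),
    habit = dplyr::transmute(tb, stratum = .data$habit, year = .data$year)
  )
  if (by == "family" && min_species > 0) {
    counts <- dplyr::count(ds$basionyms, .data$family)
    keep <- counts$family[counts$n > min_species]
    out <- dplyr::filter(out, .data$stratum %in% keep)
  }
  dplyr::filter(out, !is.na(.data$stratum))
}
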