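#' Decade starts covering a calendar window
#'
#' Decades are the calendar intervals 1751-1760, 1761-1770, ..., so the
#' 1753-2020 study window spans 27 decades whose first bin absorbs
#' 1753-1760.
#'
#' @param start_year,end_year Calendar window.
#' @return Integer vector of decade start years.
#' @export
#' @examples
#' decade_starts(1753, 2020)
decade_starts <- function(start_year, end_year) {
  first <- 10L * ((as.integer(start_year) - 1L) %/% 10L) + 1L
  seq.int(first, as.integer(end_year), by = 10L)
}

#' Bin publication years into a decade-resolved discovery series
#'
#' Counts names described per decade and the running cumulative total, the
#' series the asymptotic growth models are fitted to. The regression
#' abscissa is the integer decade index `t = 1..n`, not the calendar year.
#'
#' @param data A data frame with a year column, or a bare numeric vector of
#'   years.
#' @param year Column holding publication years (tidy-eval; default `year`).
#' @param window Calendar window (default `c(1753, 2020)`, 27 decades).
#'   Years outside it are rejected and counted in the `"n_rejected"`
#'   attribute.
#' @param stratum Optional stratum label stored in the output.
#' @return A tibble of class `decade_series` with `stratum`,
#'   `decade_start`, `t`, `described`, `cumulative`.
#' @export
#' @examples
#' bin_by_decade(c(1753, 1760, 1761))
bin_by_decade <- function(data, year = year, window = c(1753, 2020),
                          stratum = NA_character_) {
  years <- if (is.data.frame(data)) {
    dplyr::pull(data, {{ year }})
  } else {
    data
  }
  years <- years[!is.na(years)]
  keep <- years >= window[1] & years <= window[2]
  n_rejected <- sum(!keep)
  if (n_rejected > 0) {
    warn(sprintf("%d year(s) outside [%d, %d] rejected",
                 n_rejected, window[1], window[2]))
  }
  years <- years[keep]
  starts <- decade_starts(window[1], window[2])
  idx <- findInterval(years, starts)
  counts <- tabulate(idx, nbins = length(starts))
  out <- tibble::tibble(
    stratum = stratum, decade_start = starts,
    t = seq_along(starts), described = counts, cumulative = cumsum(counts)
  )
  attr(out, "n_rejected") <- n_rejected
  class(out) <- c("decade_series", class(out))
  out
}

#' Tokenize botanical authorship strings into author tokens
#'
#' Splits on `"&"`, `","` and `" et "`; for `"A ex B"` citations the
#' pre-"ex" author is discarded and the publishing author kept (standard
#' botanical citation semantics). Tokens are normalized by case-folding and
#' stripping periods and whitespace.
#'
#' @param x Character vector of authorship strings.
#' @return A list of character vectors of normalized author tokens (empty
#'   for empty or missing authorship).
#' @export
#' @examples
#' tokenize_authors("Mart. & Zucc.")
tokenize_authors <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character(0))
    s <- strsplit(s, "\\bex\\b")[[1]]
    s <- s[length(s)]                       # keep the publishing author(s)
    toks <- strsplit(s, "&|,|\\bet\\b")[[1]]
    toks <- gsub("[. [:space:]]", "", tolower(toks))
    unique(toks[nzchar(toks)])
  })
}

#' Count taxonomists active per decade
#'
#' Taxonomic effort is measured as the number of distinct describing
#' authors among the names published in each decade (the same author active
#' in several decades counts once in each). Also reports species described
#' per taxonomist per decade.
#'
#' @param records A data frame with `authorship` and `year` columns (e.g.,
#'   from [load_names()]).
#' @param window Calendar window (default `c(1753, 2020)`).
#' @param stratum Optional stratum label stored in the output.
#' @return A tibble of class `effort_series` with `stratum`,
#'   `decade_start`, `t`, `described`, `taxonomists`,
#'   `species_per_taxonomist` (NA where no taxonomist was active).
#' @export
count_taxonomists <- function(records, window = c(1753, 2020),
                              stratum = NA_character_) {
  stopifnot(all(c("authorship", "year") %in% names(records)))
  rec <- dplyr::filter(records, !is.na(.data$year),
                       .data$year >= window[1], .data$year <= window[2])
  empty <- is.na(rec$authorship) | !nzchar(trimws(rec$authorship))
  if (any(empty)) {
    warn(sprintf("%d record(s) with empty authorship skipped", sum(empty)))
  }
  starts <- decade_starts(window[1], window[2])
  idx <- findInterval(rec$year, starts)
  toks <- tokenize_authors(rec$authorship)
  t_i <- vapply(seq_along(starts), function(d) {
    length(unique(unlist(toks[idx == d & !empty])))
  }, integer(1))
  described <- tabulate(idx, nbins = length(starts))
  out <- tibble::tibble(
    stratum = stratum, decade_start = starts, t = seq_along(starts),
    described = described, taxonomists = t_i,
    species_per_taxonomist = ifelse(t_i > 0, described / t_i, NA_real_)
  )
  class(out) <- c("effort_series", class(out))
  out
}
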