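# Shared fixtures, built in code.

small_cfg <- function(seed = 42, ...) {
  synthetic_config(seed = seed, n_strata = 1, true_asymptote = 400, ...)
}

# Deterministic decade series from a known curve, with optional noise.
simulated_series <- function(model, params, n = 27, sigma = 0) {
  y <- growth_curve(model, seq_len(n), params)
  if (sigma > 0) y <- y + rnorm(n, 0, sigma)
  y <- cummax(pmax(y, 0))  # keep a valid cumulative series
  tibble::tibble(stratum = "sim", decade_start = 1751 + 10 * (seq_len(n) - 1),
                 t = seq_len(n), described = c(y[1], diff(y)),
                 cumulative = y)
}

# Minimal raw name-table CSV on disk; returns the path.
write_name_fixture <- function(rows, path = tempfile(fileext = ".csv")) {
  readr::write_csv(rows, path, progress = FALSE, na = "")
  path
}

base_name_row <- function(name_id = "n1", rank = "species",
                          status = "accepted", accepted_id = name_id,
                          year_primary = 1850, year_fallback = NA,
                          family = "Fabaceae", native = TRUE,
                          authorship = "Mart.", domains = "Amazonia",
                          habit = "tree") {
  tibble::tibble(
    name_id = name_id, scientific_name = paste("Genus", name_id),
    authorship = authorship, rank = rank, status = status,
    accepted_id = accepted_id, family = family,
    year_primary = year_primary, year_fallback = year_fallback,
    domains = domains, habit = habit, native = native
  )
}
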