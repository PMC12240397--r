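#' The five trendline regression families
#' @export
REGRESSION_FAMILIES <- c("linear", "logarithmic", "exponential", "power",
                         "polynomial2")

family_n_params <- c(linear = 2, logarithmic = 2, exponential = 2,
                     power = 2, polynomial2 = 3)

#' Fit one regression family to a predictor/response pair
#'
#' The five trendline families used to relate described-species numbers to
#' human population density or taxonomist counts:
#' linear `y = alpha + beta*x`; logarithmic `y = alpha + beta*ln(x)`;
#' exponential `y = alpha*exp(beta*x)` (fitted as `ln y` linear in `x`);
#' power `y = alpha*x^beta` (ln-ln fit); quadratic polynomial
#' `y = alpha + beta*x + gamma*x^2`. For the transformed families r^2 is
#' computed on the fitting (transformed) scale, matching spreadsheet
#' trendline conventions; a back-transformed diagnostic r^2 on the original
#' scale is also reported. A constant response (zero total sum of squares)
#' yields r^2 = 0.
#'
#' @param x,y Numeric vectors (>= 4 paired finite points). Logarithmic and
#'   power require positive `x`; exponential and power require positive
#'   `y`.
#' @param family One of `"linear"`, `"logarithmic"`, `"exponential"`,
#'   `"power"`, `"polynomial2"`.
#' @return A one-row tibble: `family`, `r2`, `r2_original_scale`,
#'   `n_params`, `coefficients` (named-list column), `n`.
#' @export
fit_family <- function(x, y, family = REGRESSION_FAMILIES) {
  family <- match.arg(family)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 4) abort("need at least 4 paired points")
  if (family %in% c("logarithmic", "power") && any(x <= 0)) {
    abort(sprintf("family '%s' requires positive x", family))
  }
  if (family %in% c("exponential", "power") && any(y <= 0)) {
    abort(sprintf("family '%s' requires positive y", family))
  }
  fit_scale <- switch(family,
    linear = list(xx = x, yy = y),
    logarithmic = list(xx = log(x), yy = y),
    exponential = list(xx = x, yy = log(y)),
    power = list(xx = log(x), yy = log(y)),
    polynomial2 = list(xx = x, yy = y)
  )
  r2_of <- function(obs, pred) {
    sst <- sum((obs - mean(obs))^2)
    if (sst <= 0) return(0)
    1 - sum((obs - pred)^2) / sst
  }
  if (family == "polynomial2") {
    m <- lm(yy ~ xx + I(xx^2), data = fit_scale)
    cf <- coef(m)
    coefs <- list(alpha = unname(cf[1]), beta = unname(cf[2]),
                  gamma = unname(cf[3]))
    pred_orig <- stats::fitted(m)
  } else {
    m <- lm(yy ~ xx, data = fit_scale)
    cf <- coef(m)
    if (family == "exponential") {
      coefs <- list(alpha = exp(unname(cf[1])), beta = unname(cf[2]))
      pred_orig <- coefs$alpha * exp(coefs$beta * x)
    } else if (family == "power") {
      coefs <- list(alpha = exp(unname(cf[1])), beta = unname(cf[2]))
      pred_orig <- coefs$alpha * x^coefs$beta
    } else {
      coefs <- list(alpha = unname(cf[1]), beta = unname(cf[2]))
      pred_orig <- stats::fitted(m)
    }
  }
  tibble::tibble(
    family = family,
    r2 = r2_of(fit_scale$yy, stats::fitted(m)),
    r2_original_scale = r2_of(y, pred_orig),
    n_params = unname(family_n_params[family]),
    coefficients = list(coefs),
    n = length(x)
  )
}

#' Choose the regression family with the best fit
#'
#' Fits every applicable family and returns the one with the highest r^2
#' (on the fitting scale); ties break toward the family with fewest
#' parameters. Families whose positivity requirements the data violate are
#' skipped silently; at least one family must apply.
#'
#' @inheritParams fit_family
#' @param families Candidate families (default all five).
#' @return A one-row tibble as from [fit_family()], with an `all_fits`
#'   attribute carrying every applicable fit.
#' @export
best_family <- function(x, y, families = REGRESSION_FAMILIES) {
  fits <- purrr::map(families, function(f) {
    tryCatch(fit_family(x, y, f), error = function(e) NULL)
  })
  fits <- dplyr::bind_rows(fits[!vapply(fits, is.null, logical(1))])
  if (nrow(fits) == 0) abort("no applicable regression family")
  fits <- dplyr::arrange(fits, dplyr::desc(.data$r2), .data$n_params,
                         .data$family)
  out <- fits[1, ]
  attr(out, "all_fits") <- fits
  out
}

#' Analysis windows for predictor regressions
#'
#' The long-run relationship uses the cumulative series over the whole
#' window (27 decade points for 1753-2020); the recent-effort view uses
#' per-decade counts for the decades starting 1961 through 2011 (the six
#' bins covering 1960-2020).
#'
#' @param series A `decade_series` tibble.
#' @param recent_start First calendar year of the recent window (default
#'   1960).
#' @return A list with `cumulative` (full window, `value = cumulative`)
#'   and `per_decade` (recent window, `value = described`) tibbles.
#' @export
window_modes <- function(series, recent_start = 1960) {
  cumulative <- dplyr::transmute(
    tibble::as_tibble(series), stratum = .data$stratum,
    decade_start = .data$decade_start, t = .data$t,
    mode = "cumulative", value = .data$cumulative
  )
  per_decade <- series |>
    tibble::as_tibble() |>
    dplyr::filter(.data$decade_start + 9 > recent_start) |>
    dplyr::transmute(stratum = .data$stratum,
                     decade_start = .data$decade_start, t = .data$t,
                     mode = "per_decade", value = .data$described)
  list(cumulative = cumulative, per_decade = per_decade)
}

#' Regress described-species numbers on density and taxonomist counts
#'
#' Produces the summary-table-shaped report: for each predictor (human
#' population density, taxonomists) and each analysis window (cumulative
#' full-window, per-decade recent), the best-fitting regression family and
#' its r^2.
#'
#' @param series A `decade_series` tibble for one stratum.
#' @param effort An `effort_series` tibble (column `taxonomists`) on the
#'   same decades.
#' @param density A tibble with `decade_start` and `pop_density` on the
#'   same decades.
#' @param recent_start First calendar year of the recent window.
#' @return A tibble: `stratum`, `predictor`, `mode`, `family`, `r2`, `n`.
#' @export
regress_predictors <- function(series, effort, density,
                               recent_start = 1960) {
  modes <- window_modes(series, recent_start)
  joined <- function(mode_tbl) {
    mode_tbl |>
      dplyr::left_join(
        dplyr::select(tibble::as_tibble(effort), "decade_start",
                      "taxonomists"),
        by = "decade_start"
      ) |>
      dplyr::left_join(
        dplyr::select(tibble::as_tibble(density), "decade_start",
                      "pop_density"),
        by = "decade_start"
      )
  }
  purrr::map_dfr(names(modes), function(mode) {
    tb <- joined(modes[[mode]])
    purrr::map_dfr(
      c(population_density = "pop_density", taxonomists = "taxonomists"),
      function(col) {
        bf <- best_family(tb[[col]], tb$value)
        tibble::tibble(family = bf$family, r2 = bf$r2, n = bf$n)
      },
      .id = "predictor"
    ) |>
      dplyr::mutate(stratum = series$stratum[1], mode = mode,
                    .before = 1)
  })
}
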