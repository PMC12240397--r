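#' Akaike-weighted model-averaged asymptote with unconditional SE
#'
#' Combines converged fits into a single asymptote estimate
#' `theta_bar = sum(w_i * a_i)` with the unconditional standard error
#' `se_u = sqrt(sum(w_i * (se_i^2 + (a_i - theta_bar)^2)))`, which folds
#' both within-model variance and between-model spread into the 95% CI
#' (`theta_bar +/- 1.96 * se_u`). A fit lacking an SE (singular covariance)
#' has its `se_i^2` term replaced by the largest available `se_j^2` among
#' positive-weight fits -- a conservative inflation rather than an
#' understatement of uncertainty.
#'
#' When `s_obs` (species catalogued to date) is supplied the estimate is
#' converted to remaining species (`theta_bar - s_obs`, flagged if
#' negative), the upper-bound remaining, and completeness percentages.
#'
#' @param fits A tibble from [akaike_weights()] (columns `asymptote`,
#'   `asymptote_se`, `weight`, `converged`).
#' @param s_obs Observed species count for the stratum (optional).
#' @param stratum Stratum label stored in the output.
#' @return A one-row tibble of class `averaged_estimate`: `stratum`,
#'   `s_obs`, `theta_bar`, `se_u`, `ci_lower`, `ci_upper`, `remaining`,
#'   `remaining_upper`, `completeness_pct`, `completeness_lower_pct`,
#'   `negative_remaining` flag.
#' @export
average_models <- function(fits, s_obs = NULL, stratum = NA_character_) {
  if (!"weight" %in% names(fits)) {
    abort("fits must carry Akaike weights; run akaike_weights() first")
  }
  pos <- fits$weight > 0
  if (!any(pos)) abort("no positive-weight fits to average")
  a <- fits$asymptote[pos]
  w <- fits$weight[pos]
  se <- fits$asymptote_se[pos]
  if (anyNA(a)) abort("positive-weight fit with missing asymptote")
  theta <- sum(w * a)
  se2 <- se^2
  if (anyNA(se2)) {
    if (all(is.na(se2))) {
      se2[] <- 0
    } else {
      se2[is.na(se2)] <- max(se2, na.rm = TRUE)
    }
  }
  se_u <- sqrt(sum(w * (se2 + (a - theta)^2)))
  ci_lower <- theta - 1.96 * se_u
  ci_upper <- theta + 1.96 * se_u

  out <- tibble::tibble(
    stratum = stratum,
    s_obs = if (is.null(s_obs)) NA_real_ else s_obs,
    theta_bar = theta, se_u = se_u,
    ci_lower = ci_lower, ci_upper = ci_upper
  )
  if (!is.null(s_obs)) {
    out$remaining <- theta - s_obs
    out$remaining_upper <- ci_upper - s_obs
    out$completeness_pct <- 100 * s_obs / theta
    out$completeness_lower_pct <- 100 * s_obs / ci_upper
    out$negative_remaining <- out$remaining < 0
  } else {
    out$remaining <- NA_real_
    out$remaining_upper <- NA_real_
    out$completeness_pct <- NA_real_
    out$completeness_lower_pct <- NA_real_
    out$negative_remaining <- NA
  }
  class(out) <- c("averaged_estimate", class(out))
  out
}

#' Completeness Index
#'
#' The extent to which observed species richness represents the total
#' estimated richness: `100 * S_obs / (S_obs + predicted_remaining)`,
#' reported as a percentage (conventionally printed to one decimal).
#'
#' @param s_obs Observed (catalogued) species count, > 0.
#' @param predicted_remaining Predicted species remaining to be described;
#'   `s_obs + predicted_remaining` must be positive.
#' @return Completeness percentage (numeric, full precision).
#' @export
#' @examples
#' completeness_index(11903, 3086) # 79.4
completeness_index <- function(s_obs, predicted_remaining) {
  if (any(s_obs <= 0)) abort("s_obs must be positive")
  denom <- s_obs + predicted_remaining
  if (any(denom <= 0)) abort("s_obs + predicted_remaining must be positive")
  100 * s_obs / denom
}

#' Aggregate per-stratum averaged estimates
#'
#' Sums the model-averaged remaining-species estimates and their upper 95%
#' bounds across strata, and reports the per-stratum and total "media"
#' (the midpoint of the averaged estimate and its upper bound). Rounding
#' happens only at presentation; totals equal the sums of their addends
#' exactly.
#'
#' @param estimates A tibble with columns `stratum`, `remaining`,
#'   `remaining_upper` (e.g., stacked [average_models()] rows).
#' @return A list of class `aggregate_report`: `strata` (the input plus a
#'   `media` column) and `totals` (one-row tibble with `total_remaining`,
#'   `total_remaining_upper`, `total_media`).
#' @export
aggregate_estimates <- function(estimates) {
  stopifnot(all(c("remaining", "remaining_upper") %in% names(estimates)))
  if (nrow(estimates) < 1) abort("need at least one stratum")
  strata <- dplyr::mutate(
    estimates, media = (.data$remaining + .data$remaining_upper) / 2
  )
  totals <- tibble::tibble(
    total_remaining = sum(strata$remaining),
    total_remaining_upper = sum(strata$remaining_upper),
    total_media = sum(strata$media)
  )
  structure(list(strata = strata, totals = totals),
            class = "aggregate_report")
}

#' @export
print.aggregate_report <- function(x, ...) {
  cat(sprintf(
    "<aggregate_report> %d strata: %.2f remaining (upper %.2f, media %.2f)\n",
    nrow(x$strata), x$totals$total_remaining,
    x$totals$total_remaining_upper, x$totals$total_media
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.aggregate_report <- function(x, ...) x$strata

#' @exportS3Method generics::glance
glance.aggregate_report <- function(x, ...) x$totals
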