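#' Asymptotic growth-curve values
#'
#' The four candidate curves for cumulative discovery series, in their
#' common statistical-software ("3P"/"4P") parameterizations:
#' \describe{
#'   \item{gompertz3p}{`y = a * exp(-exp(-b * (t - c)))`}
#'   \item{gompertz4p}{`y = d + (a - d) * exp(-exp(-b * (t - c)))`}
#'   \item{logistic3p}{`y = a / (1 + exp(-b * (t - c)))`}
#'   \item{weibull}{`y = a * (1 - exp(-(t / b)^c))`}
#' }
#' In every case `a` is the asymptote: the estimated total (described +
#' undescribed) species richness.
#'
#' @param model One of `"gompertz3p"`, `"gompertz4p"`, `"logistic3p"`,
#'   `"weibull"`.
#' @param t Abscissa (decade index).
#' @param params Named numeric vector/list of curve parameters.
#' @return Numeric vector of curve values.
#' @export
growth_curve <- function(model, t, params) {
  p <- as.list(params)
  switch(model,
    gompertz3p = p$a * exp(-exp(-p$b * (t - p$c))),
    gompertz4p = p$d + (p$a - p$d) * exp(-exp(-p$b * (t - p$c))),
    logistic3p = p$a / (1 + exp(-p$b * (t - p$c))),
    weibull    = p$a * (1 - exp(-(pmax(t, 1e-12) / p$b)^p$c)),
    abort(sprintf("unknown growth model '%s'", model))
  )
}

#' The four asymptotic growth-model identifiers
#' @export
GROWTH_MODELS <- c("gompertz3p", "gompertz4p", "logistic3p", "weibull")

growth_formula <- function(model) {
  switch(model,
    gompertz3p = cumulative ~ a * exp(-exp(-b * (t - c))),
    gompertz4p = cumulative ~ d + (a - d) * exp(-exp(-b * (t - c))),
    logistic3p = cumulative ~ a / (1 + exp(-b * (t - c))),
    weibull    = cumulative ~ a * (1 - exp(-(t / b)^c))
  )
}

# Geometry-informed multi-start grid. The asymptote grid spans
# {1.05, 1.2, 1.5, 2, 4} x max(cumulative); b and c start from the curve
# geometry at each candidate asymptote.
growth_starts <- function(model, t, y) {
  ymax <- max(y)
  starts <- list()
  for (mult in c(1.05, 1.2, 1.5, 2, 4)) {
    a0 <- mult * ymax
    frac <- pmin(pmax(y / a0, 1e-6), 1 - 1e-6)
    if (model %in% c("gompertz3p", "gompertz4p")) {
      # linearize: -log(-log(y/a)) = b*(t - c)
      z <- -log(-log(frac))
      fit <- stats::lm(z ~ t)
      b0 <- max(unname(coef(fit)[2]), 1e-3)
      c0 <- unname(-coef(fit)[1]) / b0
      st <- list(a = a0, b = b0, c = c0)
      if (model == "gompertz4p") st$d <- min(y)
      starts[[length(starts) + 1]] <- st
    } else if (model == "logistic3p") {
      z <- log(frac / (1 - frac))
      fit <- stats::lm(z ~ t)
      b0 <- max(unname(coef(fit)[2]), 1e-3)
      c0 <- unname(-coef(fit)[1]) / b0
      starts[[length(starts) + 1]] <- list(a = a0, b = b0, c = c0)
    } else {
      # weibull: log(-log(1 - y/a)) = c*log(t) - c*log(b)
      z <- log(-log(1 - frac))
      lt <- log(t)
      fit <- stats::lm(z ~ lt)
      c0 <- max(unname(coef(fit)[2]), 0.1)
      b0 <- exp(unname(-coef(fit)[1]) / c0)
      b0 <- min(max(b0, min(t)), 10 * max(t))
      starts[[length(starts) + 1]] <- list(a = a0, b = b0, c = c0)
    }
  }
  starts
}

#' Fit one asymptotic growth model to a cumulative discovery series
#'
#' Nonlinear least squares (Levenberg-Marquardt, multi-start) of the chosen
#' curve to cumulative described-species counts on the decade index.
#' Information criteria use the Gaussian-error forms
#' `AIC = n*log(RSS/n) + 2k`, `AICc = AIC + 2k(k+1)/(n-k-1)`,
#' `BIC = n*log(RSS/n) + k*log(n)`, where `k` counts the curve parameters
#' plus the residual variance. Non-convergence is reported, never raised;
#' a perfect fit (RSS = 0) gets `-Inf` criteria (the limit of the Gaussian
#' criterion) and wins any weighting.
#'
#' @param series A `decade_series` tibble from [bin_by_decade()] (or any
#'   data frame with `t` and `cumulative` columns, `cumulative`
#'   non-decreasing).
#' @param model One of `"gompertz3p"`, `"gompertz4p"`, `"logistic3p"`,
#'   `"weibull"`.
#' @return An object of class `growth_fit`: a list with `model`, `params`,
#'   `n`, `k`, `rss`, `aic`, `aicc`, `bic`, `asymptote`, `asymptote_se`,
#'   `ci_lower`/`ci_upper` (asymptote +/- 1.96 SE), `converged`, `fitted`,
#'   and the input `data`. Use [tidy()] / [glance()] to extract tibbles.
#' @export
fit_growth_model <- function(series, model = GROWTH_MODELS) {
  model <- match.arg(model)
  t <- series$t
  y <- series$cumulative
  n <- length(y)
  n_par <- if (model == "gompertz4p") 4L else 3L
  k <- n_par + 1L
  if (n < k + 2) abort(sprintf("need at least %d decades to fit %s",
                               k + 2, model))
  if (any(diff(y) < 0)) abort("cumulative series must be non-decreasing")

  dat <- data.frame(t = t, cumulative = y)
  best <- NULL
  for (st in growth_starts(model, t, y)) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        growth_formula(model), data = dat, start = st,
        lower = if (model == "weibull") c(1e-8, 1e-8, 1e-8) else NULL,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }

  if (is.null(best) || !all(is.finite(coef(best$fit)))) {
    out <- list(model = model, params = NULL, n = n, k = k, rss = NA_real_,
                aic = NA_real_, aicc = NA_real_, bic = NA_real_,
                asymptote = NA_real_, asymptote_se = NA_real_,
                ci_lower = NA_real_, ci_upper = NA_real_,
                converged = FALSE, fitted = rep(NA_real_, n), data = series)
    class(out) <- "growth_fit"
    return(out)
  }

  fit <- best$fit
  rss <- best$rss
  params <- coef(fit)
  if (rss <= 0 || rss < 1e-12 * sum(y^2)) {
    aic <- aicc <- bic <- -Inf
  } else {
    aic <- n * log(rss / n) + 2 * k
    aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
    bic <- n * log(rss / n) + k * log(n)
  }
  se <- tryCatch({
    v <- vcov(fit)
    sqrt(v["a", "a"])
  }, error = function(e) NA_real_)
  if (!is.na(se) && !is.finite(se)) se <- NA_real_
  a_hat <- unname(params["a"])
  out <- list(
    model = model, params = params, n = n, k = k, rss = rss,
    aic = aic, aicc = aicc, bic = bic,
    asymptote = a_hat, asymptote_se = se,
    ci_lower = if (is.na(se)) NA_real_ else a_hat - 1.96 * se,
    ci_upper = if (is.na(se)) NA_real_ else a_hat + 1.96 * se,
    converged = TRUE, fitted = stats::fitted(fit), data = series
  )
  class(out) <- "growth_fit"
  out
}

#' @export
print.growth_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<growth_fit> %s: asymptote %.1f (SE %.1f), AICc %.2f\n",
                x$model, x$asymptote, x$asymptote_se, x$aicc))
  } else {
    cat(sprintf("<growth_fit> %s: did not converge\n", x$model))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.growth_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @exportS3Method generics::glance
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, converged = x$converged, n = x$n, k = x$k,
    rss = x$rss, aic = x$aic, aicc = x$aicc, bic = x$bic,
    asymptote = x$asymptote, asymptote_se = x$asymptote_se,
    ci_lower = x$ci_lower, ci_upper = x$ci_upper
  )
}

#' @exportS3Method generics::augment
augment.growth_fit <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x$data), .fitted = x$fitted,
                .resid = .data$cumulative - x$fitted)
}

#' Fit all four growth models to one series
#'
#' @param series A `decade_series` tibble (see [bin_by_decade()]).
#' @param models Subset of [GROWTH_MODELS] to fit.
#' @return A tibble with one row per model (glance columns) and the fitted
#'   object in the `fit` list-column. Fits that fail to converge carry NA
#'   asymptotes and criteria, mirroring the blank entries a summary table
#'   would print.
#' @export
fit_growth_models <- function(series, models = GROWTH_MODELS) {
  fits <- lapply(models, function(m) fit_growth_model(series, m))
  out <- dplyr::bind_rows(lapply(fits, glance))
  out$fit <- fits
  out
}

#' Akaike weights over a set of model fits
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = IC_i - min(IC)` over converged fits; non-converged fits get
#' weight 0. A model whose weight approaches 1 is unambiguously supported
#' by the data. Weights default to AICc (better behaved at n = 27) but AIC
#' and BIC are selectable.
#'
#' @param fits A tibble from [fit_growth_models()] (needs `converged` and
#'   the chosen criterion column), or a list of `growth_fit` objects.
#' @param criterion `"aicc"`, `"aic"`, or `"bic"`.
#' @return The input tibble with a `weight` column (weights sum to 1).
#' @export
akaike_weights <- function(fits, criterion = c("aicc", "aic", "bic")) {
  criterion <- match.arg(criterion)
  if (!is.data.frame(fits)) {
    fits <- dplyr::bind_rows(lapply(fits, glance))
  }
  ic <- fits[[criterion]]
  conv <- fits$converged & !is.na(ic)
  if (!any(conv)) abort("no converged fits: no model support")
  w <- numeric(nrow(fits))
  icc <- ic[conv]
  if (any(icc == -Inf)) {
    # perfect fits dominate: split the weight among them
    w[conv] <- as.numeric(icc == -Inf) / sum(icc == -Inf)
  } else {
    delta <- icc - min(icc)
    w[conv] <- exp(-delta / 2) / sum(exp(-delta / 2))
  }
  fits$weight <- w
  fits
}
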