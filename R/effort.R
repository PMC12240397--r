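#' Expected descriptions per decade under the taxonomic-effort model
#'
#' The effort model says that the more taxonomists are active in a decade,
#' the more of the still-undescribed pool they describe:
#' `D_hat_i = (a_e + b_e * s_i) * T_i * (N_T - C_{i-1})`, where `T_i` is
#' the number of taxonomists, `C_{i-1}` the cumulative described count at
#' the start of the decade (`C_0 = 0`), `N_T` the total species pool, and
#' `s_i` the decade index rescaled to \[0, 1\] so the per-taxonomist
#' efficiency can drift linearly over time without conditioning problems.
#'
#' @param n_total Total species pool `N_T`.
#' @param a_e,b_e Efficiency intercept and slope.
#' @param taxonomists Vector `T_i` of taxonomists per decade.
#' @param cumulative_lag Vector `C_{i-1}` (defaults assume prediction along
#'   an observed series is wanted; see [effort_trajectory()] for the
#'   self-consistent recursion).
#' @return Vector of expected per-decade description counts.
#' @export
predict_effort <- function(n_total, a_e, b_e, taxonomists, cumulative_lag) {
  n <- length(taxonomists)
  s <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
  (a_e + b_e * s) * taxonomists * (n_total - cumulative_lag)
}

#' Self-consistent trajectory of the effort model
#'
#' Iterates the effort model forward from an empty inventory, feeding each
#' decade's prediction back into the next decade's undescribed pool. With
#' `b_e = 0` and constant effort `T` this reproduces the closed-form
#' monomolecular curve `C_i = N_T * (1 - (1 - a_e * T)^i)`.
#'
#' @inheritParams predict_effort
#' @return A tibble with `t`, `described`, `cumulative`.
#' @export
effort_trajectory <- function(n_total, a_e, b_e, taxonomists) {
  n <- length(taxonomists)
  s <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
  described <- numeric(n)
  cum <- 0
  for (i in seq_len(n)) {
    described[i] <- (a_e + b_e * s[i]) * taxonomists[i] * (n_total - cum)
    cum <- cum + described[i]
  }
  tibble::tibble(t = seq_len(n), described = described,
                 cumulative = cumsum(described))
}

# For a fixed pool size the efficiency parameters enter linearly, so they
# are profiled out by ordinary least squares.
effort_profile_rss <- function(n_total, d, taxonomists, cum_lag, s) {
  x1 <- taxonomists * (n_total - cum_lag)
  x2 <- s * x1
  if (all(x1 == 0)) return(list(rss = Inf, a_e = NA_real_, b_e = NA_real_))
  fit <- stats::lm.fit(cbind(x1, x2), d)
  cf <- coef(fit)
  cf[is.na(cf)] <- 0
  list(rss = sum(fit$residuals^2), a_e = unname(cf[1]), b_e = unname(cf[2]))
}

#' Fit the taxonomic-effort discovery model
#'
#' Estimates the total species pool `N_T` and the efficiency parameters
#' `(a_e, b_e)` by nonlinear least squares on per-decade description
#' counts. For fixed `N_T` the efficiency parameters are linear and are
#' profiled out exactly; `N_T` is then optimized in one dimension. Two
#' multi-start tiers are fitted and both reported: a `coarse` tier that
#' searches around the grid `{1.05, 1.2, 1.5, 2, 4} x C_final`, and a
#' `dense` tier that scans a fine grid over the whole admissible range
#' before local refinement. A Poisson-likelihood objective is available
#' behind `objective = "poisson"`; the default is ordinary least squares so
#' the Gaussian AIC/BIC are comparable with the growth-model criteria.
#'
#' @param series A `decade_series` tibble (columns `t`, `described`,
#'   `cumulative`).
#' @param effort An `effort_series` tibble (column `taxonomists`) aligned
#'   on the same decades, or a bare vector of taxonomist counts.
#' @param objective `"ls"` (default) or `"poisson"`.
#' @param tiers Which multi-start tiers to fit.
#' @return An object of class `effort_fit`: a tibble with one row per tier
#'   (`tier`, `n_total`, `a_e`, `b_e`, `rss`, `aic`, `bic`,
#'   `predicted_remaining`, `converged`). The best tier (lowest objective)
#'   is marked in `best`. [glance()] returns the best row.
#' @export
fit_effort_model <- function(series, effort, objective = c("ls", "poisson"),
                             tiers = c("coarse", "dense")) {
  objective <- match.arg(objective)
  taxonomists <- if (is.data.frame(effort)) effort$taxonomists else effort
  d <- series$described
  n <- length(d)
  if (length(taxonomists) != n) {
    abort("effort and series must cover the same decades")
  }
  if (sum(taxonomists > 0) < 6) {
    abort("need at least 6 decades with active taxonomists")
  }
  cum <- cumsum(d)
  c_final <- cum[n]
  cum_lag <- c(0, cum[-n])
  s <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0

  obj <- function(n_total) {
    pr <- effort_profile_rss(n_total, d, taxonomists, cum_lag, s)
    if (objective == "ls") return(pr$rss)
    mu <- pmax((pr$a_e + pr$b_e * s) * taxonomists * (n_total - cum_lag),
               1e-9)
    2 * sum(mu - d * log(mu))
  }

  lo <- c_final * (1 + 1e-4)
  hi <- c_final * 8
  fit_tier <- function(tier) {
    opt <- tryCatch({
      if (tier == "coarse") {
        grid <- c(1.05, 1.2, 1.5, 2, 4) * c_final
        vals <- vapply(grid, obj, numeric(1))
        i <- which.min(vals)
        lo_i <- if (i == 1) lo else grid[i - 1]
        hi_i <- if (i == length(grid)) hi else grid[i + 1]
        optimize(obj, c(lo_i, hi_i), tol = 1e-6 * c_final)
      } else {
        grid <- seq(lo, hi, length.out = 200)
        vals <- vapply(grid, obj, numeric(1))
        i <- which.min(vals)
        lo_i <- grid[max(i - 1, 1)]
        hi_i <- grid[min(i + 1, length(grid))]
        optimize(obj, c(lo_i, hi_i), tol = 1e-6 * c_final)
      }
    }, error = function(e) NULL)
    if (is.null(opt)) {
      return(tibble::tibble(
        tier = tier, n_total = NA_real_, a_e = NA_real_, b_e = NA_real_,
        rss = NA_real_, aic = NA_real_, bic = NA_real_,
        predicted_remaining = NA_real_, converged = FALSE
      ))
    }
    nt <- opt$minimum
    pr <- effort_profile_rss(nt, d, taxonomists, cum_lag, s)
    k <- 4  # N_T, a_e, b_e + residual variance
    rss <- pr$rss
    if (rss <= 0) {
      aic <- bic <- -Inf
    } else {
      aic <- n * log(rss / n) + 2 * k
      bic <- n * log(rss / n) + k * log(n)
    }
    tibble::tibble(
      tier = tier, n_total = nt, a_e = pr$a_e, b_e = pr$b_e, rss = rss,
      aic = aic, bic = bic, predicted_remaining = nt - c_final,
      converged = TRUE
    )
  }

  out <- dplyr::bind_rows(lapply(tiers, fit_tier))
  conv <- which(out$converged)
  out$best <- FALSE
  if (length(conv) > 0) {
    out$best[conv[which.min(out$rss[conv])]] <- TRUE
  }
  attr(out, "c_final") <- c_final
  attr(out, "objective") <- objective
  class(out) <- c("effort_fit", class(out))
  out
}

#' @exportS3Method generics::glance
glance.effort_fit <- function(x, ...) {
  best <- x[x$best, , drop = FALSE]
  if (nrow(best) == 0) best <- x[1, , drop = FALSE]
  tibble::as_tibble(best)
}

#' Species remaining to be described under an effort fit
#'
#' @param fit An `effort_fit` (the best converged tier is used) or a
#'   single row of one.
#' @param c_final Final cumulative described count; defaults to the count
#'   the fit was made on.
#' @return `N_T - C_final` (negative values are a flagged fit pathology,
#'   floored only at reporting time).
#' @export
predict_remaining <- function(fit, c_final = NULL) {
  row <- if (inherits(fit, "effort_fit")) glance(fit) else fit
  if (!isTRUE(row$converged[1])) abort("effort fit did not converge")
  cf <- c_final %||% attr(fit, "c_final")
  rem <- row$n_total[1] - cf
  if (!is.na(rem) && rem < 0) {
    warn("predicted pool smaller than described count (negative remaining)")
  }
  rem
}
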