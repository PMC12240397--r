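test_that("noiseless logistic data is fitted essentially exactly", {
  ser <- simulated_series("logistic3p", c(a = 1000, b = 0.5, c = 14))
  fit <- fit_growth_model(ser, "logistic3p")
  expect_true(fit$converged)
  expect_lt(abs(fit$asymptote - 1000) / 1000, 1e-3)
  expect_lt(fit$rss, 1e-6)
  expect_identical(fit$aicc, -Inf)  # perfect-fit sentinel
})

test_that("each model recovers its own asymptote under 1% noise", {
  params <- list(
    gompertz3p = c(a = 1000, b = 0.35, c = 8),
    gompertz4p = c(a = 1000, d = 30, b = 0.35, c = 8),
    logistic3p = c(a = 1000, b = 0.5, c = 10),
    weibull    = c(a = 1000, b = 10, c = 2)
  )
  for (m in names(params)) {
    ok <- withr::with_seed(100 + match(m, names(params)), {
      vapply(1:10, function(i) {
        ser <- simulated_series(m, params[[m]], sigma = 10)
        fit <- fit_growth_model(ser, m)
        fit$converged && abs(fit$asymptote - 1000) / 1000 <= 0.05
      }, logical(1))
    })
    expect_gte(sum(ok), 9)
  }
})

test_that("the generating model family attains the lowest AIC most often", {
  # gompertz4p nests gompertz3p, so on 3P-generated data the 4P variant
  # wins the AIC a non-negligible fraction of the time by chance; the
  # selection property that identifies the generating *shape* is that a
  # Gompertz-family model beats the non-nested families.
  res <- withr::with_seed(77, {
    vapply(1:100, function(i) {
      ser <- simulated_series("gompertz3p", c(a = 1000, b = 0.35, c = 8),
                              sigma = 20)
      fits <- fit_growth_models(ser)
      conv <- fits[fits$converged, ]
      winner <- conv$model[which.min(conv$aic)]
      aic3p <- conv$aic[conv$model == "gompertz3p"]
      others <- conv$aic[conv$model %in% c("logistic3p", "weibull")]
      c(family_wins = winner %in% c("gompertz3p", "gompertz4p"),
        beats_non_nested = length(aic3p) == 1 && all(aic3p < others))
    }, numeric(2))
  })
  expect_gte(mean(res["family_wins", ]), 0.9)
  expect_gte(mean(res["beats_non_nested", ]), 0.9)
})

test_that("degenerate constant series is handled without error", {
  ser <- tibble::tibble(t = 1:27, cumulative = rep(100, 27))
  fit <- fit_growth_model(ser, "weibull")
  expect_type(fit$converged, "logical")
  if (fit$converged) {
    expect_true(is.finite(fit$asymptote))
    # a (numerically) perfect fit carries the -Inf sentinel, otherwise the
    # Gaussian criterion is finite
    expect_true(is.finite(fit$aic) || fit$aic == -Inf)
  }
})

test_that("preconditions are enforced", {
  expect_error(fit_growth_model(tibble::tibble(t = 1:4,
                                               cumulative = 1:4),
                                "gompertz3p"), "decades")
  expect_error(fit_growth_model(tibble::tibble(t = 1:10,
                                               cumulative = c(5:1, 6:10)),
                                "gompertz3p"), "non-decreasing")
  expect_error(growth_curve("badmodel", 1, c(a = 1)), "unknown")
})

test_that("information criteria have the Gaussian closed forms", {
  ser <- simulated_series("gompertz3p", c(a = 500, b = 0.3, c = 9),
                          sigma = 0)
  ser$cumulative <- ser$cumulative + withr::with_seed(5, rnorm(27, 0, 5))
  ser$cumulative <- cummax(ser$cumulative)
  fit <- fit_growth_model(ser, "gompertz3p")
  n <- 27; k <- 4
  expect_equal(fit$aic, n * log(fit$rss / n) + 2 * k)
  expect_equal(fit$aicc, fit$aic + 2 * k * (k + 1) / (n - k - 1))
  expect_equal(fit$bic, n * log(fit$rss / n) + k * log(n))
  expect_gte(fit$aicc, fit$aic)
  expect_equal(fit$k, 4L)  # 3 curve parameters + residual variance
})

test_that("Akaike weights match the closed form and behave as weights", {
  mk <- function(aicc, converged = TRUE) {
    tibble::tibble(model = paste0("m", seq_along(aicc)),
                   converged = converged, aicc = aicc,
                   asymptote = 1000, asymptote_se = 10)
  }
  w <- akaike_weights(mk(c(100, 100)))$weight
  expect_equal(w, c(0.5, 0.5))
  w <- akaike_weights(mk(c(0, 20)))$weight
  expect_equal(w, c(1, exp(-10)) / (1 + exp(-10)), tolerance = 1e-12)
  expect_equal(akaike_weights(mk(50))$weight, 1)
  # non-converged fits get zero weight
  w <- akaike_weights(mk(c(10, 12, 999), converged = c(TRUE, TRUE, FALSE)))
  expect_equal(w$weight[3], 0)
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
  # invariance to adding a constant to every criterion
  w1 <- akaike_weights(mk(c(3, 7, 11)))$weight
  w2 <- akaike_weights(mk(c(3, 7, 11) + 1234.5))$weight
  expect_equal(w1, w2, tolerance = 1e-12)
  expect_error(akaike_weights(mk(5, converged = FALSE)), "no model support")
})

test_that("tidy/glance/augment expose the fit in broom shape", {
  ser <- simulated_series("logistic3p", c(a = 300, b = 0.4, c = 10))
  fit <- fit_growth_model(ser, "logistic3p")
  td <- tidy(fit)
  expect_setequal(td$term, c("a", "b", "c"))
  gl <- glance(fit)
  expect_equal(gl$model, "logistic3p")
  expect_equal(nrow(gl), 1)
  au <- augment(fit)
  expect_true(all(abs(au$.resid) < 1e-4))
})
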