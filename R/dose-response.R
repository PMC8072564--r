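# Constrained variable-slope sigmoidal dose-response fitting and
# method-comparison regression.

#' Evaluate the four-parameter logistic (variable-slope sigmoid)
#'
#' `y = bottom + (top - bottom) / (1 + 10^((log10(ld50) - log10(c)) * hill))`.
#' At `c = ld50` the response is the midpoint `(top + bottom) / 2`.
#'
#' @param concentration concentrations (> 0), nM.
#' @param top,bottom asymptotes (%).
#' @param ld50 half-maximal concentration (nM).
#' @param hill slope factor.
#' @return response values.
#' @export
fourParamLogistic <- function(concentration, top, bottom, ld50, hill) {
  bottom + (top - bottom) /
    (1 + 10^((log10(ld50) - log10(concentration)) * hill))
}

#' Fit a constrained variable-slope dose-response curve
#'
#' Least-squares fit of the four-parameter logistic with the upper
#' asymptote fixed to the solvent-control value (`topValue`), the lower
#' asymptote constrained to be non-negative and the slope free. The fit is
#' multi-started over log-spaced LD50 seeds and several slope seeds; the
#' lowest residual sum of squares wins. Controls (concentration 0) must be
#' excluded by the caller — they enter only through `topValue`.
#'
#' @param concentrations >= 4 distinct positive concentrations (nM).
#' @param responses responses (% of solvent control), same length.
#' @param topValue fixed upper asymptote (%), from the solvent control.
#' @return a [DoseResponseFit-class]. If the responses carry no dose effect
#'   (all equal), `converged` is `FALSE` and `ld50` is `NA`.
#' @export
fitFourParamLogistic <- function(concentrations, responses, topValue = 100) {
  if (length(concentrations) != length(responses))
    stop("concentrations and responses differ in length")
  if (any(concentrations <= 0))
    stop("concentrations must be positive (exclude controls)")
  if (length(unique(concentrations)) < 4L)
    stop("need >= 4 distinct positive concentrations")
  fail <- function() new("DoseResponseFit", top = topValue,
                         bottom = NA_real_, hillSlope = NA_real_,
                         ld50 = NA_real_, rss = NA_real_, converged = FALSE)
  if (stats::sd(responses) == 0) return(fail())
  df <- data.frame(lc = log10(concentrations), y = responses)
  lcr <- range(df$lc)
  best <- NULL
  for (l0 in seq(lcr[1], lcr[2], length.out = 7)) {
    for (h0 in c(0.5, 1, 2)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ bottom + (topValue - bottom) / (1 + 10^((lld - lc) * hill)),
          data = df,
          start = list(bottom = max(0, min(responses)), hill = h0, lld = l0),
          lower = c(bottom = 0, hill = -10, lld = lcr[1] - 3),
          upper = c(bottom = Inf, hill = 10, lld = lcr[2] + 3),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12)
        best <- list(rss = rss, par = stats::coef(fit))
    }
  }
  if (is.null(best)) return(fail())
  new("DoseResponseFit",
      top = topValue,
      bottom = unname(best$par["bottom"]),
      hillSlope = unname(best$par["hill"]),
      ld50 = 10^unname(best$par["lld"]),
      rss = best$rss,
      converged = TRUE)
}

setMethod("show", "DoseResponseFit", function(object) {
  if (object@converged) {
    cat(sprintf(paste0("DoseResponseFit: LD50 = %.1f nM, hill = %.3f, ",
                       "top = %.1f (fixed), bottom = %.1f, RSS = %.3g\n"),
                object@ld50, object@hillSlope, object@top, object@bottom,
                object@rss))
  } else {
    cat("DoseResponseFit: not converged (no dose effect or fit failure)\n")
  }
})

#' Ordinary least-squares regression for method comparison
#'
#' Closed-form simple linear regression of automated (`y`) on manual (`x`)
#' measurements, with `r_squared = 1 - SSE/SST`.
#'
#' @param x,y paired measurements (>= 3 points; `x` not constant).
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
olsRegression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need >= 3 paired points")
  if (stats::sd(x) == 0) stop("x is constant")
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  sse <- sum((y - intercept - slope * x)^2)
  sst <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept,
       r_squared = if (sst > 0) 1 - sse / sst else NA_real_)
}
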