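#' Least-squares validation fit of algorithmic against manual measurements
#'
#' Simple linear regression `y = a x + b` fitted by least squares in closed
#' form: `a = sum((x - xbar)(y - ybar)) / sum((x - xbar)^2)`,
#' `b = ybar - a xbar`. Agreement statistics reported alongside: Pearson
#' `r = Cov(X, Y) / sqrt(Var(X) Var(Y))`, the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot`, and the sample-size/predictor-count
#' corrected `adjusted R^2 = 1 - (1 - R^2)(n - 1)/(n - k - 1)` with `k = 1`
#' predictor.
#'
#' @param x manual measurements (mm^2).
#' @param y algorithmic measurements (mm^2), same length as `x`.
#' @return a `leaf_regression`: `a` (slope), `b` (intercept), `r`, `R2`,
#'   `adjusted_R2` (`NA` when `n < 3`), `n`, `k`, `residuals`, `fitted`.
#' @export
fit_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) stop("non-finite values in paired measurements")
  n <- length(x)
  if (n < 2) stop("need at least two paired measurements")
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  if (sxx == 0) stop("x is constant: slope undefined")
  sxy <- sum((x - xbar) * (y - ybar))
  syy <- sum((y - ybar)^2)
  a <- sxy / sxx
  b <- ybar - a * xbar
  fitted <- a * x + b
  res <- y - fitted
  r <- if (syy == 0) NA_real_ else sxy / sqrt(sxx * syy)
  R2 <- if (syy == 0) NA_real_ else 1 - sum(res^2) / syy
  k <- 1L
  adj <- if (n > k + 1 && !is.na(R2)) 1 - (1 - R2) * (n - 1) / (n - k - 1)
         else NA_real_
  structure(list(a = a, b = b, r = r, R2 = R2, adjusted_R2 = adj,
                 n = n, k = k, x = x, y = y,
                 fitted = fitted, residuals = res),
            class = "leaf_regression")
}

#' @export
print.leaf_regression <- function(x, ...) {
  cat(sprintf("y = %.4f x + %.4f   (n = %d)\n", x$a, x$b, x$n))
  cat(sprintf("r = %.4f, R2 = %.4f, adjusted R2 = %.4f\n",
              x$r, x$R2, x$adjusted_R2))
  invisible(x)
}

#' Residual diagnostics for a validation fit
#'
#' Summarises the residuals of a [fit_regression()] fit: mean (expected
#' ~0 for least squares with intercept), standard deviation, and a
#' Shapiro-Wilk omnibus normality statistic. Quantile-plot coordinates are
#' returned so residual and normal-probability plots can be drawn.
#'
#' @param fit a `leaf_regression`.
#' @return list: `mean`, `sd`, `shapiro_W`, `shapiro_p`, and `qq` (data
#'   frame of theoretical vs sample quantiles).
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "leaf_regression"))
  res <- fit$residuals
  if (length(res) < 3) stop("diagnostics unavailable for n < 3")
  sw <- if (stats::sd(res) > 0 && length(res) <= 5000) {
    stats::shapiro.test(res)
  } else {
    list(statistic = c(W = NA_real_), p.value = NA_real_)
  }
  qq <- stats::qqnorm(res, plot.it = FALSE)
  list(mean = mean(res), sd = stats::sd(res),
       shapiro_W = unname(sw$statistic), shapiro_p = sw$p.value,
       qq = data.frame(theoretical = qq$x, sample = qq$y))
}

#' Write the validation report (paired CSV + JSON summary)
#'
#' @param fit a `leaf_regression`.
#' @param csv_path path for the per-pair table `(x, y, residual)`.
#' @param json_path path for the summary `{a, b, r, R2, adjusted_R2, n}`.
#' @export
write_validation_report <- function(fit, csv_path, json_path) {
  df <- data.frame(x = sprintf("%.6f", fit$x), y = sprintf("%.6f", fit$y),
                   residual = sprintf("%.6f", fit$residuals))
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(a = fit$a, b = fit$b, r = fit$r, R2 = fit$R2,
         adjusted_R2 = fit$adjusted_R2, n = fit$n),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(csv = csv_path, json = json_path))
}
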