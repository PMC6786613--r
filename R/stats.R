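#' Standardized-coefficient multiple regression
#'
#' Ordinary least squares on z-scored response and predictors, so the
#' slope coefficients are fully standardized "beta" coefficients (the
#' convention of classic statistics packages): each beta is the expected
#' change, in response standard deviations, per standard deviation of the
#' predictor. Used for sensitivity analysis of simulation output on the
#' swept environmental variables.
#'
#' @param data A data frame (e.g. a [run_sweep()] table).
#' @param response Name of the response column.
#' @param predictors Character vector of predictor columns. With a single
#'   predictor the fit reduces to simple regression and `r` equals the
#'   absolute Pearson correlation.
#' @return An object of class `herd_ols` with elements `response`, `n`,
#'   `r` (multiple correlation), `r.squared`, and `coefficients` (a tibble
#'   of term, beta, t statistic and two-sided p value on n - k - 1 degrees
#'   of freedom). Supports [tidy()], [glance()] and `print()`.
#' @examples
#' d <- data.frame(x1 = rnorm(50), x2 = rnorm(50))
#' d$y <- 2 * d$x1 + rnorm(50, sd = 0.1)
#' standardized_ols(d, "y", c("x1", "x2"))
#' @export
standardized_ols <- function(data, response, predictors) {
  stopifnot(is.data.frame(data), length(predictors) >= 1)
  cols <- c(response, predictors)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0)
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  d <- as.data.frame(data)[, cols, drop = FALSE]
  sds <- vapply(d, sd, numeric(1))
  if (any(sds == 0 | !is.finite(sds)))
    stop("constant column(s): ",
         paste(cols[sds == 0 | !is.finite(sds)], collapse = ", "))
  dz <- as.data.frame(scale(d))
  fit <- lm(stats::reformulate(predictors, response), data = dz)
  s <- summary(fit)
  co <- s$coefficients[predictors, , drop = FALSE]
  out <- structure(
    list(
      response = response,
      n = nrow(d),
      r.squared = unname(s$r.squared),
      r = sqrt(unname(s$r.squared)),
      coefficients = tibble::tibble(
        term = predictors,
        beta = unname(co[, "Estimate"]),
        statistic = unname(co[, "t value"]),
        p.value = unname(co[, "Pr(>|t|)"])
      )
    ),
    class = "herd_ols"
  )
  out
}

#' @export
print.herd_ols <- function(x, ...) {
  cat(sprintf("Standardized OLS: %s ~ %s\n", x$response,
              paste(x$coefficients$term, collapse = " + ")))
  cat(sprintf("  n = %d, R = %.3f, R^2 = %.3f\n", x$n, x$r, x$r.squared))
  print(x$coefficients)
  invisible(x)
}

#' @rdname standardized_ols
#' @param x A `herd_ols` object.
#' @param ... Unused.
#' @export
tidy.herd_ols <- function(x, ...) x$coefficients

#' @rdname standardized_ols
#' @export
glance.herd_ols <- function(x, ...) {
  tibble::tibble(response = x$response, r = x$r, r.squared = x$r.squared,
                 nobs = x$n)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over the standard correlation with the input checks used
#' throughout the package.
#'
#' @param x,y Equal-length numeric vectors (length >= 3, non-constant).
#' @return The correlation coefficient in `[-1, 1]`.
#' @examples
#' pearson_r(1:10, 2 * (1:10) + 1)  # 1
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (sd(x) == 0 || sd(y) == 0) stop("correlation undefined for constant input")
  cor(x, y)
}
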