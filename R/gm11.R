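#' Accumulated generating operation (1-AGO)
#'
#' Cumulative-sum transform of a grey series:
#' \eqn{x^{(1)}(k) = \sum_{i \le k} x^{(0)}(i)}. Strictly increasing for
#' positive input.
#'
#' @param x Numeric series \eqn{x^{(0)}}, nonempty.
#' @return The accumulated series \eqn{x^{(1)}}, same length.
#' @seealso [iago()] for the inverse first-difference transform.
#' @export
ago <- function(x) {
  if (!is.numeric(x) || length(x) == 0) {
    stop("`x` must be a nonempty numeric series", call. = FALSE)
  }
  cumsum(x)
}

#' Inverse accumulated generating operation (1-IAGO)
#'
#' First differences with the first value kept: `iago(ago(x))` returns `x`
#' exactly.
#'
#' @param x1 Accumulated series.
#' @return The restored original-scale series.
#' @export
iago <- function(x1) {
  if (!is.numeric(x1) || length(x1) == 0) {
    stop("`x1` must be a nonempty numeric series", call. = FALSE)
  }
  c(x1[1], diff(x1))
}

#' Background value sequence of the grey differential equation
#'
#' The discretized grey equation replaces \eqn{x^{(1)}} by the background
#' value \eqn{z^{(1)}(k) = w\,x^{(1)}(k) + (1-w)\,x^{(1)}(k-1)} for
#' \eqn{k = 2..n}; the classical choice is the half-sum, `weight = 0.5`.
#'
#' @param cumulative Accumulated series \eqn{x^{(1)}}, length >= 2.
#' @param weight Interpolation weight in \[0, 1\]; default 0.5.
#' @return Numeric of length `length(cumulative) - 1`.
#' @export
background_sequence <- function(cumulative, weight = 0.5) {
  if (!is.numeric(cumulative) || length(cumulative) < 2) {
    stop("`cumulative` must have length >= 2", call. = FALSE)
  }
  if (!is.numeric(weight) || length(weight) != 1 || is.na(weight) ||
      weight < 0 || weight > 1) {
    stop("`weight` must be a single number in [0, 1]", call. = FALSE)
  }
  n <- length(cumulative)
  weight * cumulative[-1] + (1 - weight) * cumulative[-n]
}

#' Fit a GM(1,1) grey model
#'
#' Fits the first-order one-variable grey model to a short positive series.
#' The accumulated series \eqn{x^{(1)}} is assumed to follow
#' \eqn{dx^{(1)}/dt + a\,x^{(1)} = u}; its discretization
#' \eqn{x^{(0)}(k) = -a\,z^{(1)}(k) + u} is solved for the development
#' coefficient `a` and control coefficient `u` by ordinary least squares over
#' \eqn{k = 2..n}. The time response, anchored at the first observation, is
#' \deqn{\hat x^{(1)}(t+1) = (x^{(0)}(1) - u/a)\,e^{-a t} + u/a,}
#' and original-scale fitted values are restored by first differences
#' (IAGO). When `|a|` falls below `degeneracy_tol` the exponential is
#' numerically meaningless and the fit degenerates to the constant model
#' \eqn{\hat x^{(0)} \equiv u} (flagged in the result).
#'
#' @param values Positive numeric series, length >= 4.
#' @param years Optional integer labels, same length (used in reports and to
#'   label forecasts).
#' @param background_weight Weight of the background sequence; default 0.5
#'   (half-sum).
#' @param degeneracy_tol Threshold on `|a|` below which the constant-model
#'   branch is taken; default 1e-10.
#' @return A `gm11` object: list with coefficients `a`, `u`, the anchor
#'   `initial_value` = \eqn{x^{(0)}(1)}, `asymptote` = `u/a`, `amplitude` =
#'   \eqn{x^{(0)}(1) - u/a}, `fitted_cumulative`, `restored` (restored(1) is
#'   the anchor itself), `residuals`, `relative_errors` (k = 2..n),
#'   `mean_relative_error`, `grade` (see [accuracy_report()]), `degenerate`,
#'   plus the inputs.
#' @export
#' @examples
#' fit <- fit_gm11(c(1.5270, 1.4782, 2.3897, 1.9143, 1.2611),
#'                 years = 2013:2017)
#' fit$a          # ~0.0538
#' fit$asymptote  # ~37.92
fit_gm11 <- function(values, years = NULL, background_weight = 0.5,
                     degeneracy_tol = 1e-10) {
  if (!is.numeric(values) || length(values) < 4) {
    stop("GM(1,1) needs a numeric series of length >= 4", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("GM(1,1) requires strictly positive, finite values", call. = FALSE)
  }
  if (!is.null(years) && length(years) != length(values)) {
    stop("`years` must match the series length", call. = FALSE)
  }
  n <- length(values)
  x1 <- ago(values)
  z <- background_sequence(x1, weight = background_weight)
  # Normal equations of the least-squares problem
  #   minimize sum_k ( x0(k) - (-a z(k) + u) )^2 ,  k = 2..n.
  B <- cbind(-z, 1)
  Y <- values[-1]
  BtB <- crossprod(B)
  if (abs(det(BtB)) < 1e-300 || !is.finite(rcond(BtB)) || rcond(BtB) < 1e-15) {
    stop("singular normal equations: background sequence is degenerate",
         call. = FALSE)
  }
  theta <- solve(BtB, crossprod(B, Y))
  a <- theta[1]
  u <- theta[2]
  degenerate <- abs(a) < degeneracy_tol
  if (degenerate) {
    fitted_cumulative <- values[1] + c(0, u * seq_len(n - 1))
    restored <- c(values[1], rep(u, n - 1))
  } else {
    asym <- u / a
    fitted_cumulative <- (values[1] - asym) * exp(-a * (seq_len(n) - 1)) + asym
    fitted_cumulative[1] <- values[1]  # anchor is exact by construction
    restored <- iago(fitted_cumulative)
  }
  residuals <- values - restored
  rel <- abs(residuals[-1]) / values[-1]
  mre <- mean(rel)
  fit <- structure(
    list(a = a, u = u,
         initial_value = values[1],
         asymptote = if (degenerate) NA_real_ else u / a,
         amplitude = if (degenerate) NA_real_ else values[1] - u / a,
         fitted_cumulative = fitted_cumulative,
         restored = restored,
         residuals = residuals,
         relative_errors = rel,
         mean_relative_error = mre,
         degenerate = degenerate,
         background_weight = background_weight,
         values = values,
         years = if (is.null(years)) seq_len(n) else as.integer(years)),
    class = "gm11")
  fit$grade <- accuracy_report(fit)$grade
  fit
}

#' @export
print.gm11 <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("GM(1,1) fit [degenerate, a ~ 0]: x^(0) = %.6g (constant)\n",
                x$u))
  } else {
    cat(sprintf("GM(1,1) fit: x^(1)(t+1) = %.6g %+.6g * exp(%.6g * t)\n",
                x$asymptote, x$amplitude, -x$a))
    cat(sprintf("  a = %.6g  u = %.6g  (n = %d)\n", x$a, x$u,
                length(x$values)))
  }
  cat(sprintf("  mean relative error %.2f%%  grade: %s\n",
              100 * x$mean_relative_error, x$grade))
  invisible(x)
}

#' Forecast from a GM(1,1) fit
#'
#' Restored-scale forecasts \eqn{\hat x^{(0)}(n+1), \ldots, \hat x^{(0)}(n+
#' steps)}: first differences of the fitted cumulative time response. With
#' `n` observations at years \eqn{Y_1..Y_n}, step 1 is year \eqn{Y_{n+1}}.
#' For `a > 0` the forecasts form a strictly decreasing geometric sequence
#' with ratio \eqn{e^{-a}}; in the degenerate constant branch the constant
#' `u` is repeated.
#'
#' @param fit A `gm11` object from [fit_gm11()].
#' @param steps Number of forecast steps, >= 1.
#' @return Numeric of length `steps`, named by forecast year when the fit
#'   carries year labels.
#' @export
gm11_forecast <- function(fit, steps) {
  stopifnot(inherits(fit, "gm11"))
  if (!is.numeric(steps) || length(steps) != 1 || is.na(steps) || steps < 1) {
    stop("`steps` must be a positive integer", call. = FALSE)
  }
  steps <- as.integer(steps)
  n <- length(fit$values)
  if (fit$degenerate) {
    out <- rep(fit$u, steps)
  } else {
    t_idx <- n + seq_len(steps) - 1   # x^(1) index (n+1..) minus 1
    x1 <- fit$amplitude * exp(-fit$a * t_idx) + fit$asymptote
    x1_prev <- fit$amplitude * exp(-fit$a * (t_idx - 1)) + fit$asymptote
    out <- x1 - x1_prev
  }
  names(out) <- fit$years[length(fit$years)] + seq_len(steps)
  out
}

#' @rdname gm11_forecast
#' @param object,... Method arguments for [stats::predict()]; `steps` is
#'   passed through.
#' @export
predict.gm11 <- function(object, steps = 1, ...) {
  gm11_forecast(object, steps)
}

#' Accuracy diagnostics of a GM(1,1) fit
#'
#' Per-point relative errors of the restored in-sample values
#' (\eqn{k = 2..n}), their mean, and a grade assigned from the mean relative
#' error by a threshold ladder. Boundaries are inclusive: a mean error
#' exactly at a threshold gets the better grade.
#'
#' @param fit A `gm11` object.
#' @param thresholds Named increasing numeric ladder mapping grades to upper
#'   bounds on the mean relative error (as fractions); anything above the
#'   last bound is graded `"unqualified"`. Default: excellent <= 1%,
#'   good <= 3%, qualified <= 5%.
#' @return List with a per-point tibble (`k`, `year`, `observed`, `restored`,
#'   `relative_error`), `mean_relative_error` and `grade`.
#' @export
accuracy_report <- function(fit,
                            thresholds = c(excellent = 0.01, good = 0.03,
                                           qualified = 0.05)) {
  stopifnot(inherits(fit, "gm11"))
  if (is.null(names(thresholds)) || is.unsorted(thresholds)) {
    stop("`thresholds` must be a named increasing numeric vector",
         call. = FALSE)
  }
  n <- length(fit$values)
  tbl <- tibble::tibble(
    k = 2:n,
    year = fit$years[-1],
    observed = fit$values[-1],
    restored = fit$restored[-1],
    relative_error = fit$relative_errors)
  mre <- fit$mean_relative_error
  hit <- which(mre <= thresholds)
  grade <- if (length(hit)) names(thresholds)[hit[1]] else "unqualified"
  list(by_point = tbl, mean_relative_error = mre, grade = grade)
}
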