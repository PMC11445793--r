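#' Fit the macro-level polynomial trendline to each dream chart
#'
#' Dream charts typically oscillate between peaks and troughs, so a
#' polynomial trendline (rather than a straight line) is fitted by least
#' squares to `(x, y)` to summarize the macro direction of emotion across
#' the dream. The scalar "emotion gradient" is the mean slope of the fitted
#' polynomial over the chart's domain, `(p(x_W) - p(x_1)) / (x_W - x_1)`:
#' for a degree-1 fit this is exactly the line's slope, and its sign encodes
#' the overall direction of emotional change (positive = toward positive
#' emotion).
#'
#' Charts with fewer points than `degree + 1` are marked ineligible and
#' receive a degenerate linear fit (or, for a single-point chart, gradient
#' 0). `r_squared` is `1 - SS_res/SS_tot`, defined as 1 when `SS_tot = 0`
#' (constant chart). Eligibility additionally requires
#' `r_squared >= r2_floor`; the default floor of 0 excludes nothing, leaving
#' chart exclusion to the analyst.
#'
#' @param charts tibble from [dream_charts()].
#' @param degree polynomial degree (default 2).
#' @param r2_floor minimum r-squared for `eligible = TRUE` (default 0).
#' @return tibble with one row per report: `report_id`, `degree` (degree
#'   actually fitted), `coefficients` (list column, constant term first),
#'   `r_squared`, `emotion_gradient`, `linear_slope` (slope of a plain
#'   degree-1 fit, for comparison), `eligible`.
#' @examples
#' ch <- data.frame(report_id = "d1", x = 1:6, y = (1:6)^2)
#' fit_trends(ch, degree = 2)
#' @export
fit_trends <- function(charts, degree = 2, r2_floor = 0) {
  stopifnot(is.data.frame(charts),
            all(c("report_id", "x", "y") %in% names(charts)))
  degree <- as.integer(degree)
  if (degree < 1L) abort("`degree` must be >= 1.")
  charts <- dplyr::arrange(charts, .data$report_id, .data$x)
  .map_reports(charts, function(d) .fit_one(d$x, d$y, degree, r2_floor))
}

.fit_one <- function(x, y, degree, r2_floor) {
  W <- length(x)
  if (W < 2L) {
    return(tibble::new_tibble(list(
      degree = 0L, coefficients = list(y[1]),
      r_squared = 1, emotion_gradient = 0, linear_slope = 0,
      eligible = FALSE
    ), nrow = 1L))
  }
  deg_used <- if (W >= degree + 1L) degree else 1L
  cf <- .polyfit(x, y, deg_used)
  fitted <- .polyval(cf, x)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot <= .Machine$double.eps * max(1, sum(y^2))) 1 else 1 - ss_res / ss_tot
  r2 <- min(1, max(0, r2))
  grad <- (.polyval(cf, x[W]) - .polyval(cf, x[1])) / (x[W] - x[1])
  lin <- .polyfit(x, y, 1L)[2L]
  tibble::new_tibble(list(
    degree = deg_used,
    coefficients = list(unname(cf)),
    r_squared = r2,
    emotion_gradient = grad,
    linear_slope = unname(lin),
    eligible = (W >= degree + 1L) && r2 >= r2_floor
  ), nrow = 1L)
}

## Least-squares polynomial, coefficients constant-term first. Centering x
## before the fit keeps the Vandermonde system well conditioned; the QR
## solve is the same normal-equations-free route lm takes.
.polyfit <- function(x, y, degree) {
  xm <- mean(x)
  V <- outer(x - xm, 0:degree, `^`)
  b <- qr.coef(qr(V), y)
  b[is.na(b)] <- 0
  # shift back: p(x) = sum b_k (x - xm)^k  ->  coefficients in powers of x
  cf <- numeric(degree + 1L)
  for (k in 0:degree) {
    for (j in 0:k) {
      cf[j + 1L] <- cf[j + 1L] + b[k + 1L] * choose(k, j) * (-xm)^(k - j)
    }
  }
  cf
}

.polyval <- function(cf, x) {
  out <- 0
  for (k in rev(seq_along(cf))) out <- out * x + cf[k]
  out
}

#' Emotion gradient of a fitted trendline
#'
#' Convenience accessor: the mean slope of the fitted polynomial over the
#' chart's domain, the scalar summarizing the overall direction of
#' sequential emotion change within the dream.
#'
#' @param fit one row of [fit_trends()] output.
#' @return scalar gradient.
#' @export
emotion_gradient <- function(fit) {
  stopifnot(is.data.frame(fit), nrow(fit) == 1L, "emotion_gradient" %in% names(fit))
  fit$emotion_gradient[[1L]]
}
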