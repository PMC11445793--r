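#' Trapezoid-rule area under a segment
#'
#' Approximates the area under a peak or trough by treating each span
#' between consecutive data points as a trapezoid and summing their areas:
#' `sum (x[i+1] - x[i]) * (y[i] + y[i+1]) / 2`. The result is signed —
#' positive for peaks, negative for troughs — and its magnitude is the
#' cumulative emotional intensity of that excursion. A single-point segment
#' with no boundary points has zero width and area 0.
#'
#' @param points data frame with numeric columns `x` (strictly increasing)
#'   and `y`; boundary zeros included.
#' @return signed area (scalar).
#' @examples
#' trapezoid_auc(data.frame(x = 0:2, y = c(0, 1, 0)))   # unit triangle
#' trapezoid_auc(data.frame(x = 0:3, y = c(0, 1, 1, 0)))
#' @export
trapezoid_auc <- function(points) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  if (nrow(points) >= 2L && is.unsorted(points$x, strictly = TRUE)) {
    abort("`points$x` must be strictly increasing.")
  }
  .trapz(points$x, points$y)
}

.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-n] + y[-1]) / 2)
}

#' Positive, negative, and overall emotion intensity
#'
#' `positive_emotion_intensity()` sums the trapezoid-rule areas of all peaks
#' in a chart's segmentation (0 when there are no peaks);
#' `negative_emotion_intensity()` does the same over troughs, yielding a
#' value `<= 0` whose larger magnitude denotes higher negative emotion
#' intensity. `overall_emotion_intensity()` combines them as `pei + |nei|`:
#' the absolute value is taken for troughs so their intensity adds to, not
#' subtracts from, the total range of emotion.
#'
#' @param segments segmentation tibble for a single report (rows of
#'   [segment_charts()] output).
#' @return scalar intensity.
#' @export
positive_emotion_intensity <- function(segments) {
  sum(segments$auc[segments$kind == "peak"])
}

#' @rdname positive_emotion_intensity
#' @export
negative_emotion_intensity <- function(segments) {
  sum(segments$auc[segments$kind == "trough"])
}

#' @rdname positive_emotion_intensity
#' @param pei,nei positive / negative emotion intensity scalars.
#' @export
overall_emotion_intensity <- function(pei, nei) {
  stopifnot(pei >= 0, nei <= 0)
  pei + abs(nei)
}

#' Compute the six per-dream emotion indicators
#'
#' Assembles, for each dream chart, the full indicator set: total peaks,
#' total troughs, positive emotion intensity (PEI), negative emotion
#' intensity (NEI), overall emotion intensity (OEI = PEI + |NEI|), and the
#' emotion gradient of the fitted polynomial trendline.
#'
#' @param charts tibble from [dream_charts()].
#' @param eps zero tolerance passed to [segment_charts()].
#' @param degree polynomial degree for the trendline (default 2); see
#'   [fit_trends()].
#' @param r2_floor eligibility floor on the trendline r-squared (default 0).
#' @return tibble with one row per report: `report_id`, `total_peaks`,
#'   `total_troughs`, `pei`, `nei`, `oei`, `emotion_gradient`.
#' @examples
#' sc <- data.frame(report_id = "d1", position = 1:70,
#'                  valence = c(rep(0, 20), rep(0.5, 15), rep(0, 20),
#'                              rep(-0.5, 10), rep(0, 5)))
#' dream_indicators(dream_charts(sc))
#' @export
dream_indicators <- function(charts, eps = 1e-12, degree = 2, r2_floor = 0) {
  segs <- segment_charts(charts, eps = eps)
  trends <- fit_trends(charts, degree = degree, r2_floor = r2_floor)
  .indicators_from(charts, segs, trends)
}

## Assemble the indicator table from precomputed parts (shared with the
## pipeline so intermediates are computed once).
.indicators_from <- function(charts, segments, trends) {
  ids <- unique(charts$report_id)
  counts <- count_segments(segments, report_ids = ids)
  intensities <- tibble::tibble(report_id = ids) |>
    dplyr::left_join(
      segments |>
        dplyr::group_by(.data$report_id) |>
        dplyr::summarise(
          pei = sum(.data$auc[.data$kind == "peak"]),
          nei = sum(.data$auc[.data$kind == "trough"]),
          .groups = "drop"
        ),
      by = "report_id"
    ) |>
    dplyr::mutate(
      pei = dplyr::coalesce(.data$pei, 0),
      nei = dplyr::coalesce(.data$nei, 0),
      oei = .data$pei + abs(.data$nei)
    )
  counts |>
    dplyr::left_join(intensities, by = "report_id") |>
    dplyr::left_join(
      dplyr::select(trends, "report_id", "emotion_gradient"),
      by = "report_id"
    )
}
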