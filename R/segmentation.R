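#' Demarcate peaks and troughs of dream charts
#'
#' A peak starts at the first positive value above the zero midline and ends
#' at the first zero following the run of positive values; a trough is
#' defined symmetrically below the midline. A chart may contain no, one, or
#' several peaks and troughs, and a peak or trough may consist of a single
#' point. Where consecutive chart points change sign with no intervening
#' zero, a synthetic boundary point is placed at the linearly interpolated
#' zero crossing, closing one segment and opening the next; chart edges act
#' as boundaries for excursions that begin or end mid-emotion.
#'
#' @param charts tibble as returned by [dream_charts()] (columns
#'   `report_id`, `x`, `y`).
#' @param eps values with `|y| <= eps` are treated as exactly zero
#'   (default `1e-12`, absorbing floating-point noise in the window sums).
#' @return tibble with one row per segment: `report_id`, `kind`
#'   (`"peak"`/`"trough"`), `start_x`, `end_x` (possibly fractional at
#'   interpolated crossings), `n_points` (interior points), `auc` (signed
#'   trapezoid-rule area, positive for peaks, negative for troughs), and a
#'   `points` list column of `(x, y)` tibbles including boundary zeros.
#'   Charts with no excursions contribute no rows.
#' @examples
#' ch <- data.frame(report_id = "d1", x = 1:5, y = c(0, 2, 0, -1, 0))
#' segment_charts(ch)
#' @export
segment_charts <- function(charts, eps = 1e-12) {
  stopifnot(is.data.frame(charts),
            all(c("report_id", "x", "y") %in% names(charts)),
            is.numeric(eps), length(eps) == 1L, eps >= 0)
  charts <- dplyr::arrange(charts, .data$report_id, .data$x)
  .map_reports(charts, function(d) .segment_one(d$x, d$y, eps))
}

## Segment one chart. Returns a tibble of segments (possibly 0 rows).
.segment_one <- function(x, y, eps) {
  stopifnot(length(x) == length(y), !is.unsorted(x, strictly = TRUE))
  s <- sign(y)
  s[abs(y) <= eps] <- 0
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0)
  nk <- length(keep)
  if (nk == 0L) {
    return(tibble::tibble(kind = character(), start_x = numeric(),
                          end_x = numeric(), n_points = integer(),
                          auc = numeric(), points = list()))
  }
  n <- length(x)
  kind <- character(nk); sx <- numeric(nk); ex <- numeric(nk)
  np <- integer(nk); auc <- numeric(nk); pts_list <- vector("list", nk)
  for (m in seq_len(nk)) {
    k <- keep[m]
    i0 <- starts[k]; i1 <- ends[k]
    px <- x[i0:i1]; py <- y[i0:i1]
    # left boundary: preceding zero point, or interpolated crossing on a
    # direct sign flip; nothing at the chart edge
    if (i0 > 1L) {
      xl <- if (s[i0 - 1L] == 0) x[i0 - 1L] else
        .zero_cross(x[i0 - 1L], y[i0 - 1L], x[i0], y[i0])
      px <- c(xl, px); py <- c(0, py)
    }
    if (i1 < n) {
      xr <- if (s[i1 + 1L] == 0) x[i1 + 1L] else
        .zero_cross(x[i1], y[i1], x[i1 + 1L], y[i1 + 1L])
      px <- c(px, xr); py <- c(py, 0)
    }
    kind[m] <- if (r$values[k] > 0) "peak" else "trough"
    sx[m] <- px[1L]; ex[m] <- px[length(px)]
    np[m] <- i1 - i0 + 1L
    auc[m] <- .trapz(px, py)
    pts_list[[m]] <- tibble::new_tibble(list(x = px, y = py), nrow = length(px))
  }
  tibble::new_tibble(list(kind = kind, start_x = sx, end_x = ex,
                          n_points = np, auc = auc, points = pts_list),
                     nrow = nk)
}

## x-coordinate where the line through (x0,y0)-(x1,y1) crosses zero;
## y0 and y1 have opposite signs.
.zero_cross <- function(x0, y0, x1, y1) {
  x0 + (x1 - x0) * y0 / (y0 - y1)
}

#' Count peaks and troughs per report
#'
#' @param segments tibble from [segment_charts()].
#' @param report_ids optional character vector of all report ids, so that
#'   charts with no excursions appear with zero counts.
#' @return tibble `report_id`, `total_peaks`, `total_troughs`.
#' @export
count_segments <- function(segments, report_ids = NULL) {
  counts <- segments |>
    dplyr::group_by(.data$report_id) |>
    dplyr::summarise(
      total_peaks = sum(.data$kind == "peak"),
      total_troughs = sum(.data$kind == "trough"),
      .groups = "drop"
    )
  if (!is.null(report_ids)) {
    counts <- tibble::tibble(report_id = unique(report_ids)) |>
      dplyr::left_join(counts, by = "report_id") |>
      dplyr::mutate(
        total_peaks = dplyr::coalesce(.data$total_peaks, 0L),
        total_troughs = dplyr::coalesce(.data$total_troughs, 0L)
      )
  }
  counts
}
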