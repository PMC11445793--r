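#' Sliding-window standardization: build dream charts
#'
#' Applies the sliding-window standardization to per-word valence series.
#' Each report is divided into fixed-length windows of `window_length` words
#' overlapping by `overlap` words (default 30 and 29, i.e. stride 1); the
#' valence ratings within each window are summed and the sum divided by the
#' report's window count. The resulting sequence, plotted against a
#' uniformly spaced chronological axis, is the "dream chart" on which all
#' emotion indicators are computed. Dividing by the per-report window count
#' controls for varying word counts across dreams and counteracts the
#' flattening effect of long neutral stretches.
#'
#' Reports shorter than `window_length` collapse to a single window spanning
#' the whole report. At the defaults the number of windows is
#' `W = max(1, L - 29)` for a report of `L` words.
#'
#' @param scores tibble as returned by [score_dreams()]: columns
#'   `report_id`, `position`, `valence` (a `token` column is ignored).
#' @param window_length window size in tokens (default 30).
#' @param overlap overlap between consecutive windows in tokens (default
#'   29); must satisfy `1 <= overlap < window_length`.
#' @param normalizer divisor applied to each window sum: `"n_windows"` (the
#'   report's window count, the default), `"window_length"` (a plain moving
#'   average), or `"none"`.
#' @return tibble with columns `report_id`, `x` (chronological position
#'   `1..W`, unit spacing), `y` (standardized valence), `n_windows`, and
#'   `raw_length` (the report's word count `L`).
#' @examples
#' lex <- dream_lexicon(c("joy", "fear"), c(3, -2.5))
#' sc <- data.frame(report_id = "d1", position = 1:40,
#'                  valence = rep(c(0, 0.75), each = 20))
#' dream_charts(sc)
#' @export
dream_charts <- function(scores, window_length = 30, overlap = 29,
                         normalizer = c("n_windows", "window_length", "none")) {
  normalizer <- match.arg(normalizer)
  stopifnot(is.data.frame(scores),
            all(c("report_id", "position", "valence") %in% names(scores)))
  window_length <- as.integer(window_length)
  overlap <- as.integer(overlap)
  if (!(overlap >= 1L && overlap < window_length)) {
    abort("need 1 <= overlap < window_length.")
  }
  stride <- window_length - overlap
  scores <- dplyr::arrange(scores, .data$report_id, .data$position)
  .map_reports(scores, function(d) {
    .chart_one(d$valence, window_length, stride, normalizer)
  })
}

## Apply fn to each report's rows (sorted by report_id) and row-bind the
## results with the report_id column restored. Base split is used instead of
## a grouped-df walk: the pipeline runs this per report thousands of times
## in simulations.
.map_reports <- function(df, fn) {
  parts <- split(df, df$report_id)
  out <- lapply(names(parts), function(id) {
    res <- fn(parts[[id]])
    res$report_id <- if (nrow(res) > 0L) id else character(0)
    res
  })
  dplyr::bind_rows(out) |>
    dplyr::relocate("report_id")
}

## Chart for one valence vector. Rolling window sums via cumsum; a report
## shorter than the window collapses to one whole-report window.
.chart_one <- function(v, window_length, stride, normalizer) {
  L <- length(v)
  if (L < window_length) {
    sums <- sum(v)
    W <- 1L
  } else {
    cs <- cumsum(v)
    starts <- seq.int(1L, L - window_length + 1L, by = stride)
    ends <- starts + window_length - 1L
    sums <- cs[ends] - c(0, cs)[starts]
    W <- length(starts)
  }
  div <- switch(normalizer,
    n_windows = W,
    window_length = window_length,
    none = 1
  )
  tibble::new_tibble(list(
    x = as.numeric(seq_len(W)),
    y = sums / div,
    n_windows = rep.int(W, W),
    raw_length = rep.int(L, W)
  ), nrow = W)
}
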