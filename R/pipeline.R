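#' Run the full dream-emotion pipeline
#'
#' Orchestrates every stage for a batch of reports: word-for-word valence
#' scoring, sliding-window standardization into dream charts, peak/trough
#' segmentation, the six emotion indicators, the polynomial trendline, and
#' (when an external-variables table is supplied) the tie-aware correlation
#' of indicators against external sleep/state/trait variables. The run is
#' deterministic for fixed inputs and configuration.
#'
#' @param reports data frame with columns `id`, `text` (see
#'   [read_reports()]).
#' @param lexicon a [dream_lexicon()].
#' @param externals optional data frame with `report_id` and numeric
#'   external-variable columns.
#' @param mode scoring mode, see [score_dreams()].
#' @param window_length,overlap,normalizer see [dream_charts()].
#' @param eps zero tolerance, see [segment_charts()].
#' @param degree,r2_floor trendline settings, see [fit_trends()].
#' @param alpha,tie_policy,adjust correlation settings, see
#'   [correlate_indicators()].
#' @return A `dream_analysis` object: a list with tibbles `scores`,
#'   `charts`, `segments`, `trends`, `indicators`, `correlations` (NULL
#'   without externals), `skipped` (ids of unusable reports), and `config`.
#'   [tidy()] returns the indicator table, [glance()] a one-row batch
#'   summary, [autoplot()] the faceted dream charts.
#' @examples
#' gen <- generate_cohort(n_reports = 4, seed = 7, word_range = c(46, 90))
#' fit <- dream_pipeline(gen$reports, toy_lexicon(), externals = gen$externals)
#' tidy(fit)
#' @export
dream_pipeline <- function(reports, lexicon, externals = NULL,
                           mode = "lexicon_only",
                           window_length = 30, overlap = 29,
                           normalizer = "n_windows",
                           eps = 1e-12, degree = 2, r2_floor = 0,
                           alpha = 0.05, tie_policy = "either",
                           adjust = "none") {
  reports <- .as_reports(reports)
  scores <- score_dreams(reports, lexicon, mode = mode)
  skipped <- setdiff(reports$id, unique(scores$report_id))
  charts <- dream_charts(scores, window_length = window_length,
                         overlap = overlap, normalizer = normalizer)
  segments <- segment_charts(charts, eps = eps)
  trends <- fit_trends(charts, degree = degree, r2_floor = r2_floor)
  indicators <- .indicators_from(charts, segments, trends)
  correlations <- NULL
  if (!is.null(externals)) {
    missing_ids <- setdiff(indicators$report_id, externals$report_id)
    if (length(missing_ids) > 0) {
      abort(paste0("externals table lacks report_id(s): ",
                   paste(missing_ids, collapse = ", ")))
    }
    correlations <- correlate_indicators(indicators, externals, alpha = alpha,
                                         tie_policy = tie_policy,
                                         adjust = adjust)
  }
  structure(list(
    scores = scores, charts = charts, segments = segments, trends = trends,
    indicators = indicators, correlations = correlations,
    skipped = skipped,
    config = list(mode = mode, window_length = window_length,
                  overlap = overlap, normalizer = normalizer, eps = eps,
                  degree = degree, r2_floor = r2_floor, alpha = alpha,
                  tie_policy = tie_policy, adjust = adjust)
  ), class = "dream_analysis")
}

#' @export
print.dream_analysis <- function(x, ...) {
  n <- nrow(x$indicators)
  cat(sprintf("<dream_analysis: %d report(s)>\n", n))
  wc <- x$charts |>
    dplyr::distinct(.data$report_id, .data$raw_length)
  cat(sprintf("  mean word count: %.3f (range %d-%d)\n",
              mean(wc$raw_length), min(wc$raw_length), max(wc$raw_length)))
  cat(sprintf("  peaks: %s | troughs: %s\n",
              paste(range(x$indicators$total_peaks), collapse = "-"),
              paste(range(x$indicators$total_troughs), collapse = "-")))
  if (!is.null(x$correlations)) {
    cat(sprintf("  correlations: %d pairs, %d significant at alpha = %g\n",
                nrow(x$correlations), sum(x$correlations$significant),
                x$config$alpha))
  }
  if (length(x$skipped) > 0) {
    cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy the per-report indicator table from a pipeline run
#'
#' @param x a `dream_analysis` object.
#' @param ... unused.
#' @return the indicator tibble (one row per report, six indicators).
#' @method tidy dream_analysis
#' @export
tidy.dream_analysis <- function(x, ...) {
  x$indicators
}

#' One-row summary of a pipeline run
#'
#' @param x a `dream_analysis` object.
#' @param ... unused.
#' @return one-row tibble: report count, mean word count, indicator means,
#'   significant-correlation count (NA without externals).
#' @method glance dream_analysis
#' @export
glance.dream_analysis <- function(x, ...) {
  wc <- x$charts |> dplyr::distinct(.data$report_id, .data$raw_length)
  tibble::tibble(
    n_reports = nrow(x$indicators),
    n_skipped = length(x$skipped),
    mean_word_count = mean(wc$raw_length),
    mean_total_peaks = mean(x$indicators$total_peaks),
    mean_total_troughs = mean(x$indicators$total_troughs),
    mean_pei = mean(x$indicators$pei),
    mean_nei = mean(x$indicators$nei),
    mean_oei = mean(x$indicators$oei),
    mean_emotion_gradient = mean(x$indicators$emotion_gradient),
    n_significant = if (is.null(x$correlations)) NA_integer_
                    else sum(x$correlations$significant)
  )
}

#' Write all pipeline outputs as CSV plus a JSON run manifest
#'
#' Writes `charts.csv` (`report_id,x,y`), `segments.csv`
#' (`report_id,kind,start_x,end_x,n_points,auc`), `trends.csv`,
#' `indicators.csv`, optionally `correlations.csv`, and `manifest.json`
#' echoing the configuration. Output is deterministic: identical analyses
#' produce byte-identical files.
#'
#' @param x a `dream_analysis` object.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_dream_analysis <- function(x, dir) {
  stopifnot(inherits(x, "dream_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    readr::write_csv(df, p, progress = FALSE)
    paths <<- c(paths, p)
  }
  wr(dplyr::select(x$charts, "report_id", "x", "y"), "charts.csv")
  wr(dplyr::select(x$segments, "report_id", "kind", "start_x", "end_x",
                   "n_points", "auc"), "segments.csv")
  trends_flat <- x$trends |>
    dplyr::mutate(coefficients = vapply(
      .data$coefficients,
      function(cf) paste(format(cf, digits = 17, trim = TRUE), collapse = ";"),
      character(1)
    ))
  wr(trends_flat, "trends.csv")
  wr(x$indicators, "indicators.csv")
  if (!is.null(x$correlations)) wr(x$correlations, "correlations.csv")
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(config = x$config, n_reports = nrow(x$indicators),
         skipped = x$skipped),
    mp, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  paths <- c(paths, mp)
  invisible(paths)
}
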